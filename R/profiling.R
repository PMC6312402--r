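# miRNA profiling utilities: NanoString-style normalization, detection
# filtering, percent-of-control profiling and delta-Ct quantitation. A
# profile matrix is a tibble with a `mirna` id column and one numeric
# column per sample.

profile_samples <- function(pm) {
  num <- names(pm)[vapply(pm, is.numeric, logical(1))]
  if (!"mirna" %in% names(pm)) abort("profile matrix needs a 'mirna' column")
  if (!length(num)) abort("profile matrix has no numeric sample columns")
  num
}

#' Normalize cellular miRNA profiles by top-expressed geometric mean
#'
#' Per sample, the normalization factor is the geometric mean of its
#' `top_n` highest raw counts (with a +1 offset so zeros are tolerated);
#' each sample is rescaled so its factor equals the geometric mean of all
#' samples' factors. Idempotent, and rescaling any one sample changes all
#' normalized values only by a single common constant.
#'
#' @param pm Profile tibble (`mirna` + numeric sample columns).
#' @param top_n Number of top-expressed miRNAs per sample (default 100).
#' @return The normalized profile tibble.
#' @export
normalize_cellular <- function(pm, top_n = 100L) {
  samples <- profile_samples(pm)
  factors <- vapply(samples, function(s) {
    x <- pm[[s]]
    if (sum(x > 0) < top_n)
      abort(sprintf("sample '%s' has fewer than %d nonzero miRNAs", s, top_n))
    geomean(sort(x, decreasing = TRUE)[seq_len(top_n)] + 1)
  }, numeric(1))
  target <- geomean(factors)
  for (s in samples) pm[[s]] <- pm[[s]] * target / factors[[s]]
  pm
}

#' Normalize EV miRNA profiles by a synthetic spike-in
#'
#' Each EV sample is divided by its spike-in count and rescaled to the
#' (geometric) mean spike level, so the spike-in row is constant after
#' normalization.
#'
#' @param pm Profile tibble.
#' @param spike_id `mirna` id of the spike-in oligo (e.g. `ath-miR-159a`).
#' @return The normalized profile tibble.
#' @export
normalize_ev <- function(pm, spike_id) {
  samples <- profile_samples(pm)
  row <- which(pm$mirna == spike_id)
  if (length(row) != 1) abort(sprintf("spike-in '%s' not found exactly once", spike_id))
  spikes <- vapply(samples, function(s) pm[[s]][row], numeric(1))
  if (any(spikes <= 0))
    abort(sprintf("zero spike-in count in sample '%s'",
                  samples[which(spikes <= 0)[1]]))
  target <- geomean(spikes)
  for (s in samples) pm[[s]] <- pm[[s]] * target / spikes[[s]]
  pm
}

#' Filter miRNAs by signal above negative-control noise
#'
#' Keeps miRNAs whose count exceeds the sample-specific noise threshold
#' (mean + 2 SD of the negative-control probes) in *every* sample, i.e.
#' consistently detected across the fraction.
#'
#' @param pm Profile tibble.
#' @param negatives Character vector of `mirna` ids of negative-control
#'   probes (at least 2).
#' @return The filtered profile tibble (negative probes removed).
#' @export
detection_filter <- function(pm, negatives) {
  samples <- profile_samples(pm)
  neg <- pm$mirna %in% negatives
  if (sum(neg) < 2) abort("need at least 2 negative-control probes")
  keep <- rep(TRUE, nrow(pm))
  for (s in samples) {
    thr <- mean(pm[[s]][neg]) + 2 * sd(pm[[s]][neg])
    keep <- keep & pm[[s]] > thr
  }
  pm[keep & !neg, , drop = FALSE]
}

#' Percent-of-control miRNA abundance
#'
#' Divides knockout-sample counts by control counts per miRNA and
#' experiment (columns paired by position), reports 100 x the ratio and the
#' per-miRNA mean across experiments. miRNAs with a zero control count in
#' any experiment are flagged and carry no mean.
#'
#' @param ko,ctrl Profile tibbles with identical sample layouts.
#' @return A tibble: `mirna`, one `pct_*` column per experiment,
#'   `percent` (mean across experiments), `flagged`.
#' @export
percent_of_control <- function(ko, ctrl) {
  s_ko <- profile_samples(ko)
  s_ct <- profile_samples(ctrl)
  if (length(s_ko) != length(s_ct))
    abort("ko and ctrl must have the same number of sample columns")
  shared <- intersect(ko$mirna, ctrl$mirna)
  if (!length(shared)) abort("no shared miRNA ids")
  ko <- ko[match(shared, ko$mirna), ]
  ctrl <- ctrl[match(shared, ctrl$mirna), ]
  out <- tibble::tibble(mirna = shared)
  flagged <- rep(FALSE, length(shared))
  for (i in seq_along(s_ko)) {
    zero <- ctrl[[s_ct[i]]] == 0
    flagged <- flagged | zero
    pct <- ifelse(zero, NA_real_, 100 * ko[[s_ko[i]]] / ctrl[[s_ct[i]]])
    out[[paste0("pct_", i)]] <- pct
  }
  out$percent <- rowMeans(as.matrix(out[grepl("^pct_", names(out))]))
  out$percent[flagged] <- NA_real_
  out$flagged <- flagged
  out
}

#' Relative transcript level by the delta-Ct method
#'
#' \eqn{2^{-(Ct_{target} - Ct_{reference})}}: one cycle later than the
#' reference means half the level.
#'
#' @param ct_target,ct_reference Numeric Ct values (vectorized).
#' @return Relative levels.
#' @examples
#' delta_ct(21, 20)  # 0.5
#' @export
delta_ct <- function(ct_target, ct_reference) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference)))
    abort("Ct values must be finite")
  2^(-(ct_target - ct_reference))
}
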