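#' Replicate concordance of barcode abundances
#'
#' \eqn{R^2} of log2(count + pseudocount) between two samples over their
#' shared elements, the standard replicate-reproducibility QC for pooled
#' barcode sequencing.
#'
#' @param counts Counts tibble.
#' @param sample_a,sample_b Sample column names.
#' @param pseudocount Added before the log (default 0.5).
#' @return The squared Pearson correlation (single number).
#' @export
qc_concordance <- function(counts, sample_a, sample_b, pseudocount = 0.5) {
  for (s in c(sample_a, sample_b))
    if (!s %in% names(counts)) abort(sprintf("sample '%s' not in counts", s))
  x <- counts[[sample_a]]
  y <- counts[[sample_b]]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) abort("need at least 2 shared elements")
  cor(log2(x[ok] + pseudocount), log2(y[ok] + pseudocount))^2
}

#' Pair growth and EV-release phenotypes per gene
#'
#' Joins two gene-result tables (typically growth: cells at 48 h vs 0 h;
#' and EV release: Cas9 EVs vs WT EVs) for correlation analysis: in an
#' EV-release screen the two phenotypes are expected to be uncorrelated.
#'
#' @param results_growth,results_ev Gene result tibbles (e.g. from
#'   [tidy.screen_fit()]).
#' @return A tibble with per-gene `effect_growth`, `score_growth`,
#'   `effect_ev`, `score_ev`; the Pearson correlation of the two effects is
#'   attached as attribute `"correlation"`.
#' @export
qc_growth_vs_ev <- function(results_growth, results_ev) {
  out <- dplyr::inner_join(
    dplyr::select(results_growth, "gene", effect_growth = "effect",
                  score_growth = "score"),
    dplyr::select(results_ev, "gene", effect_ev = "effect",
                  score_ev = "score"),
    by = "gene")
  if (nrow(out) < 2) abort("need at least 2 shared genes")
  attr(out, "correlation") <- cor(out$effect_growth, out$effect_ev)
  out
}

#' Scatter plot of two samples' log counts
#'
#' @param counts Counts tibble.
#' @param sample_a,sample_b Sample column names.
#' @param pseudocount Added before the log.
#' @return A ggplot object annotated with the concordance \eqn{R^2}.
#' @export
plot_concordance <- function(counts, sample_a, sample_b, pseudocount = 0.5) {
  r2 <- qc_concordance(counts, sample_a, sample_b, pseudocount)
  df <- tibble::tibble(x = log2(counts[[sample_a]] + pseudocount),
                       y = log2(counts[[sample_b]] + pseudocount))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_abline(linetype = "dashed", linewidth = 0.3) +
    ggplot2::labs(x = paste0("log2 counts: ", sample_a),
                  y = paste0("log2 counts: ", sample_b),
                  subtitle = sprintf("R² = %.3f", r2)) +
    ggplot2::theme_minimal()
}

#' Scatter plot of growth versus EV-release effects
#'
#' @param paired Output of [qc_growth_vs_ev()].
#' @return A ggplot object.
#' @export
plot_growth_vs_ev <- function(paired) {
  ggplot2::ggplot(paired, ggplot2::aes(.data$effect_growth, .data$effect_ev)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "growth effect (log2)", y = "EV-release effect (log2)",
                  subtitle = sprintf("r = %.3f", attr(paired, "correlation"))) +
    ggplot2::theme_minimal()
}
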