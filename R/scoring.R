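#' Screen scoring configuration
#'
#' Parameters of the gene-level effect model. Enrichments are
#' median-centered log2 count ratios with a pseudocount; the gene effect is
#' the maximum-likelihood shift under an efficacy-mixture model in which
#' each guide realizes an unknown fraction (on a uniform grid over
#' \[0, 1\]) of the gene's maximal phenotype; confidence is a
#' log-likelihood-ratio score against effect zero; p-values come from
#' permutations of targeting elements.
#'
#' @param pseudocount Added to both counts before the log ratio.
#' @param low_count_min Elements with reference count strictly below this
#'   are excluded (default 10).
#' @param effect_grid Candidate effect sizes (log2 units); must contain 0.
#' @param efficacy_points Number of efficacy grid points on \[0, 1\].
#' @param n_permutations Permutations per gene size.
#' @param effect_cutoff,logp_cutoff Hit thresholds: `|effect| >=
#'   effect_cutoff` (inclusive) and `-log10(p) > logp_cutoff`. Use
#'   `logp_cutoff = 1.5` for focused sublibraries and `2.5` for
#'   genome-wide screens.
#' @param density_floor Floor applied to the null density to keep
#'   log-likelihoods finite.
#' @param rng_seed Default seed for permutation draws.
#' @return A `scoring_config` list.
#' @export
scoring_config <- function(pseudocount = 0.5, low_count_min = 10,
                           effect_grid = (-160:160) * 0.05,
                           efficacy_points = 21L,
                           n_permutations = 10000L,
                           effect_cutoff = 2, logp_cutoff = 1.5,
                           density_floor = 1e-12,
                           rng_seed = 1L) {
  if (!length(effect_grid)) abort("effect_grid must be nonempty")
  if (!any(effect_grid == 0)) abort("effect_grid must contain 0")
  if (efficacy_points < 1) abort("efficacy_points must be >= 1")
  if (n_permutations < 1) abort("n_permutations must be >= 1")
  structure(list(pseudocount = pseudocount, low_count_min = low_count_min,
                 effect_grid = effect_grid,
                 efficacy_grid = seq(0, 1, length.out = efficacy_points),
                 n_permutations = as.integer(n_permutations),
                 effect_cutoff = effect_cutoff, logp_cutoff = logp_cutoff,
                 density_floor = density_floor,
                 rng_seed = as.integer(rng_seed)),
            class = "scoring_config")
}

#' Per-element enrichments (median-centered log2 count ratios)
#'
#' Elements with reference count strictly below `low_count_min` are
#' flagged `filtered` and carry no enrichment. For the remaining elements,
#' \eqn{\rho_i = \log_2((c_{treated,i} + ps)/(c_{ref,i} + ps))} minus the
#' median over included elements, so the median enrichment is exactly zero.
#' For the EV-release phenotype use treated = Cas9 EVs, reference = WT EVs;
#' for growth use treated = cells at 48 h, reference = cells at 0 h.
#'
#' @param counts Counts tibble (see [count_screen()] / [read_counts()]).
#' @param lib Library tibble supplying gene and category annotation.
#' @param treated,reference Sample column names.
#' @param cfg A [scoring_config()].
#' @return A tibble: `element_id`, `gene`, `category`, `count_reference`,
#'   `count_treated`, `filtered`, `rho`.
#' @export
compute_enrichment <- function(counts, lib, treated, reference,
                               cfg = scoring_config()) {
  for (s in c(treated, reference))
    if (!s %in% names(counts)) abort(sprintf("sample '%s' not in counts", s))
  enr <- lib |>
    dplyr::select("element_id", "gene", "category") |>
    dplyr::inner_join(
      dplyr::select(counts, "element_id",
                    count_treated = dplyr::all_of(treated),
                    count_reference = dplyr::all_of(reference)),
      by = "element_id") |>
    dplyr::mutate(filtered = .data$count_reference < cfg$low_count_min)
  if (all(enr$filtered)) abort("no elements pass the low-count filter")
  ps <- cfg$pseudocount
  rho_raw <- log2((enr$count_treated + ps) / (enr$count_reference + ps))
  rho_raw[enr$filtered] <- NA_real_
  enr$rho <- rho_raw - median(rho_raw, na.rm = TRUE)
  dplyr::select(enr, "element_id", "gene", "category",
                "count_reference", "count_treated", "filtered", "rho")
}

#' Fit the control null distribution
#'
#' Gaussian-kernel density over the enrichments of non-targeting and
#' safe-targeting control elements, bandwidth by Scott's rule, evaluated on
#' an equally spaced grid; later evaluations interpolate linearly and are
#' floored to keep log-likelihoods finite.
#'
#' @param enr Enrichment tibble from [compute_enrichment()].
#' @param cfg A [scoring_config()].
#' @param min_controls Minimum number of unfiltered control elements.
#' @return An `ev_null` object.
#' @export
fit_null <- function(enr, cfg = scoring_config(), min_controls = 50L) {
  x <- enr$rho[!enr$filtered &
                 enr$category %in% c("nontargeting", "safe_targeting")]
  x <- x[!is.na(x)]
  if (length(x) < min_controls)
    abort(sprintf(paste0(
      "only %d control enrichments available (need >= %d); ",
      "simulate or include more non-targeting/safe-targeting controls"),
      length(x), min_controls))
  bw <- suppressWarnings(bw.nrd(x))
  if (!is.finite(bw) || bw <= 0) {
    warn("degenerate control distribution; applying bandwidth floor")
    bw <- 0.01
  }
  d <- density(x, bw = bw, n = 2048, cut = 6)
  # renormalize on the evaluation grid so the discrete density is a proper
  # probability density there
  d$y <- d$y / (sum(d$y) * (d$x[2] - d$x[1]))
  structure(list(x0 = d$x[1], dx = d$x[2] - d$x[1], fx = d$y,
                 grid_x = d$x, bw = bw, n = length(x),
                 floor = cfg$density_floor),
            class = "ev_null")
}

#' @export
print.ev_null <- function(x, ...) {
  cat(sprintf("<ev_null> KDE over %d control enrichments, bw = %.4f, grid [%.2f, %.2f]\n",
              x$n, x$bw, min(x$grid_x), max(x$grid_x)))
  invisible(x)
}

#' Evaluate a fitted null density
#'
#' Linear interpolation on the fitted grid with the configured floor
#' outside the grid or below it.
#'
#' @param null An `ev_null` object from [fit_null()].
#' @param q Numeric vector of enrichment values.
#' @return Density values (always `>= null$floor`).
#' @export
null_density <- function(null, q) {
  pos <- (q - null$x0) / null$dx
  lo <- floor(pos)
  out <- rep(null$floor, length(q))
  ok <- pos > 0 & pos < length(null$fx) - 1
  w <- pos[ok] - lo[ok]
  v <- null$fx[lo[ok] + 1] * (1 - w) + null$fx[lo[ok] + 2] * w
  out[ok] <- pmax(v, null$floor)
  out
}

element_loglik_curves <- function(rho, null, cfg) {
  loglik_curves_cpp(rho, cfg$effect_grid, cfg$efficacy_grid,
                    null$x0, null$dx, null$fx, null$floor)
}

pick_effect <- function(curve, cfg) {
  # argmax with conservative tie-breaking: smaller |effect|, then negative
  mx <- max(curve)
  cand <- which(curve >= mx - 1e-9)
  e <- cfg$effect_grid[cand]
  e <- e[order(abs(e), e)]
  e0_idx <- which(cfg$effect_grid == 0)
  list(effect = e[1], score = max(0, 2 * (mx - curve[e0_idx])))
}

#' Maximum-likelihood gene effect from element enrichments
#'
#' For each candidate effect \eqn{e} on the grid, the likelihood of element
#' \eqn{i} is the mean over the efficacy grid \eqn{t \in [0,1]} of
#' \eqn{f_0(\rho_i - t e)}: the element is assumed to realize an unknown
#' fraction of the gene's maximal phenotype, so targeting elements are most
#' likely found between the phenotype and zero. The estimate is the grid
#' argmax of the summed log-likelihood (ties broken toward smaller
#' magnitude, then negative); the score is twice the log-likelihood ratio
#' against effect zero, floored at 0.
#'
#' @param rho Numeric vector of element enrichments for one gene.
#' @param null An `ev_null` from [fit_null()].
#' @param cfg A [scoring_config()].
#' @return A list: `effect`, `score`, and the `loglik` curve over
#'   `cfg$effect_grid`.
#' @export
gene_effect <- function(rho, null, cfg = scoring_config()) {
  rho <- rho[!is.na(rho)]
  if (!length(rho)) abort("no enrichments supplied")
  E <- element_loglik_curves(rho, null, cfg)
  curve <- colSums(E)
  c(pick_effect(curve, cfg), list(loglik = curve))
}

#' Combine replicate log-likelihood curves
#'
#' Replicates (or screen types) sharing one effect grid are combined by
#' summing their gene log-likelihood curves, i.e. by finding a single
#' effect size consistent with all data; effect and score are re-derived
#' from the summed curve.
#'
#' @param curves A list of numeric log-likelihood curves on
#'   `cfg$effect_grid` (e.g. the `loglik` entries of [gene_effect()]).
#' @param cfg A [scoring_config()].
#' @return A list: `effect`, `score`, combined `loglik`.
#' @export
combine_replicates <- function(curves, cfg = scoring_config()) {
  if (!length(curves)) abort("no curves supplied")
  len <- unique(lengths(curves))
  if (length(len) != 1 || len != length(cfg$effect_grid))
    abort("replicate curves must share the configured effect grid")
  curve <- Reduce(`+`, curves)
  c(pick_effect(curve, cfg), list(loglik = curve))
}

perm_pvalues_from_curves <- function(obs, E_pool, cfg) {
  # obs: tibble with columns score and k; per-k permutation null cache
  e0_idx <- which(cfg$effect_grid == 0)
  p <- numeric(nrow(obs))
  for (k in unique(obs$k)) {
    null_scores <- perm_scores_cpp(E_pool, e0_idx, as.integer(k),
                                   cfg$n_permutations)
    rows <- which(obs$k == k)
    n_ge <- vapply(obs$score[rows],
                   function(s) sum(null_scores >= s), numeric(1))
    p[rows] <- (1 + n_ge) / (cfg$n_permutations + 1)
  }
  p
}

#' Permutation p-values for gene scores
#'
#' Draws `cfg$n_permutations` random size-`k` subsets of the targeting
#' element pool per distinct gene size `k`, scores each subset exactly as a
#' gene, and reports the add-one permutation p-value
#' \eqn{p = (1 + \#\{perm \ge obs\})/(B + 1)}.
#'
#' @param observed Tibble with columns `gene`, `score`, and `k` (number of
#'   elements used for the gene).
#' @param pool_rho Enrichments of all targeting elements (the permutation
#'   pool).
#' @param null An `ev_null` from [fit_null()].
#' @param cfg A [scoring_config()].
#' @param seed Seed for the permutation draws.
#' @return `observed` with columns `p` and `neg_log_p` appended.
#' @export
permutation_pvalues <- function(observed, pool_rho, null,
                                cfg = scoring_config(),
                                seed = cfg$rng_seed) {
  pool_rho <- pool_rho[!is.na(pool_rho)]
  E_pool <- element_loglik_curves(pool_rho, null, cfg)
  set.seed(seed)
  observed$p <- perm_pvalues_from_curves(observed, E_pool, cfg)
  observed$neg_log_p <- -log10(observed$p)
  observed
}

#' Apply hit thresholds to gene results
#'
#' A gene is a hit when its effect passes the inclusive magnitude cutoff
#' (`effect <= -cutoff` or `>= +cutoff`) and `-log10(p)` strictly exceeds
#' the p-value cutoff. Negative effects label *activators* of EV release
#' (knockout decreases barcode output); positive effects label
#' *suppressors*.
#'
#' @param results Tibble with columns `effect` and `neg_log_p`.
#' @param cfg A [scoring_config()], or override the two cutoffs directly.
#' @param effect_cutoff,logp_cutoff Threshold overrides.
#' @return `results` with `hit` and `direction` columns.
#' @export
call_hits <- function(results, cfg = scoring_config(),
                      effect_cutoff = cfg$effect_cutoff,
                      logp_cutoff = cfg$logp_cutoff) {
  dplyr::mutate(results,
    hit = (.data$effect <= -effect_cutoff | .data$effect >= effect_cutoff) &
      .data$neg_log_p > logp_cutoff,
    direction = dplyr::case_when(
      .data$hit & .data$effect < 0 ~ "activator",
      .data$hit & .data$effect > 0 ~ "suppressor",
      TRUE ~ NA_character_))
}

#' Score a screen: gene effects, confidence scores, permutation p-values
#'
#' End-to-end gene-level analysis of one or more replicate comparisons
#' (`treated[j]` vs `reference[j]`): per-replicate enrichment and control
#' null, per-element efficacy-mixture log-likelihood curves, replicate
#' combination by curve summation, maximum-likelihood effects and LLR
#' scores per gene, permutation p-values from the targeting-element pool
#' (combined across replicates the same way), and hit calls.
#'
#' @param counts Counts tibble.
#' @param lib Library tibble.
#' @param treated,reference Equal-length character vectors of sample
#'   columns; positions pair replicates.
#' @param cfg A [scoring_config()].
#' @param seed Seed for permutation draws.
#' @return A `screen_fit` object; see [tidy.screen_fit()],
#'   [glance.screen_fit()], [autoplot.screen_fit()].
#' @examples
#' \donttest{
#' lib <- build_library(paste0("G", 1:20), n_controls = 60,
#'                      constraints = design_constraints(candidate_budget = 1e5))
#' sim <- screen_simulation(lib, depth = 2e5, seed = 7,
#'                          gene_effects = c(G1 = -3, G2 = 3))
#' cm <- simulate_screen(sim)$counts
#' fit <- score_screen(cm, lib, treated = c("ev_cas9_r1", "ev_cas9_r2"),
#'                     reference = c("ev_wt_r1", "ev_wt_r2"),
#'                     cfg = scoring_config(n_permutations = 200))
#' tidy(fit)
#' }
#' @export
score_screen <- function(counts, lib, treated, reference,
                         cfg = scoring_config(), seed = cfg$rng_seed) {
  if (length(treated) != length(reference) || !length(treated))
    abort("treated and reference must be nonempty and of equal length")
  reps <- seq_along(treated)
  enr <- purrr::map(reps, function(j)
    compute_enrichment(counts, lib, treated[j], reference[j], cfg))
  nulls <- purrr::map(enr, fit_null, cfg = cfg)

  # per-element combined log-likelihood curves over targeting elements
  targ_ids <- lib$element_id[lib$category == "targeting"]
  E_comb <- NULL
  used <- stats::setNames(rep(FALSE, length(targ_ids)), targ_ids)
  for (j in reps) {
    ej <- enr[[j]]
    keep <- !ej$filtered & ej$category == "targeting"
    ids <- ej$element_id[keep]
    Ej <- element_loglik_curves(ej$rho[keep], nulls[[j]], cfg)
    if (is.null(E_comb))
      E_comb <- matrix(0, length(targ_ids), length(cfg$effect_grid),
                       dimnames = list(targ_ids, NULL))
    E_comb[ids, ] <- E_comb[ids, , drop = FALSE] + Ej
    used[ids] <- TRUE
  }
  E_comb <- E_comb[used, , drop = FALSE]
  if (!nrow(E_comb)) abort("no targeting elements survive the count filter")

  gene_of <- lib$gene[match(rownames(E_comb), lib$element_id)]
  genes <- unique(gene_of)
  res <- purrr::map_dfr(genes, function(g) {
    rows <- which(gene_of == g)
    pe <- pick_effect(colSums(E_comb[rows, , drop = FALSE]), cfg)
    tibble::tibble(gene = g, effect = pe$effect, score = pe$score,
                   k = length(rows))
  })
  set.seed(seed)
  res$p <- perm_pvalues_from_curves(res, E_comb, cfg)
  res$neg_log_p <- -log10(res$p)
  res <- res |>
    dplyr::rename(n_elements = "k") |>
    call_hits(cfg) |>
    dplyr::arrange(dplyr::desc(.data$score))
  structure(list(results = res, config = cfg, treated = treated,
                 reference = reference, enrichment = enr, null = nulls,
                 seed = seed),
            class = "screen_fit")
}

#' @export
print.screen_fit <- function(x, ...) {
  cat(sprintf("<screen_fit> %d genes, %d replicate comparison(s), %d permutations\n",
              nrow(x$results), length(x$treated), x$config$n_permutations))
  cat(sprintf("hits: %d (%d activators, %d suppressors)\n",
              sum(x$results$hit),
              sum(x$results$direction == "activator", na.rm = TRUE),
              sum(x$results$direction == "suppressor", na.rm = TRUE)))
  print(head(x$results, 5))
  invisible(x)
}

#' Tidy gene-level screen results
#'
#' @param x A `screen_fit`.
#' @param ... Unused.
#' @return The gene results tibble (`gene`, `effect`, `score`,
#'   `n_elements`, `p`, `neg_log_p`, `hit`, `direction`), ordered by
#'   decreasing score.
#' @export
tidy.screen_fit <- function(x, ...) x$results

#' One-row summary of a screen fit
#'
#' @param x A `screen_fit`.
#' @param ... Unused.
#' @return A one-row tibble: gene/element tallies, hit counts, permutation
#'   settings.
#' @export
glance.screen_fit <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$results),
    n_elements = sum(x$results$n_elements),
    n_replicates = length(x$treated),
    n_hits = sum(x$results$hit),
    n_activators = sum(x$results$direction == "activator", na.rm = TRUE),
    n_suppressors = sum(x$results$direction == "suppressor", na.rm = TRUE),
    n_permutations = x$config$n_permutations)
}

#' Volcano plot of screen results
#'
#' Effect size against `-log10(p)`, hit thresholds drawn as reference
#' lines, hits colored by direction.
#'
#' @param object A `screen_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.screen_fit <- function(object, ...) {
  cfg <- object$config
  df <- dplyr::mutate(object$results,
                      class = dplyr::coalesce(.data$direction, "other"))
  ggplot2::ggplot(df, ggplot2::aes(.data$effect, .data$neg_log_p,
                                   color = .data$class)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * cfg$effect_cutoff,
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = cfg$logp_cutoff,
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_color_manual(values = c(activator = "#c0392b",
                                           suppressor = "#2980b9",
                                           other = "grey60")) +
    ggplot2::labs(x = "effect size (log2)", y = expression(-log[10]~p),
                  color = NULL) +
    ggplot2::theme_minimal()
}
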