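# handmade enrichment table: controls plus a few targeting elements
make_enr <- function(rho_ctrl, rho_targ = numeric(0)) {
  n_c <- length(rho_ctrl); n_t <- length(rho_targ)
  tibble::tibble(
    element_id = paste0("e", seq_len(n_c + n_t)),
    gene = c(rep(NA_character_, n_c), rep("G1", n_t)),
    category = c(rep("nontargeting", n_c), rep("targeting", n_t)),
    count_reference = 100L, count_treated = 100L,
    filtered = FALSE,
    rho = c(rho_ctrl, rho_targ))
}

test_that("enrichments are median-centered log2 ratios with low-count filtering", {
  lib <- toy_library(c("AAAAACCCCCGGGGG", "TTTTACCCCCGGGGG",
                       "ACGTGACTGACTGAC", "GGGGGTTTTTAAAAA"))
  cfg <- scoring_config()
  cm <- tibble::tibble(element_id = lib$element_id,
                       ref = c(100L, 200L, 50L, 9L),
                       trt = c(100L, 200L, 50L, 9L))
  enr <- compute_enrichment(cm, lib, "trt", "ref", cfg)
  expect_true(all(enr$rho[!enr$filtered] == 0))       # identical columns
  expect_true(enr$filtered[4])                        # ref 9 < 10
  expect_true(is.na(enr$rho[4]))

  # arbitrary counts: included median is exactly zero
  cm2 <- tibble::tibble(element_id = lib$element_id,
                        ref = c(100L, 120L, 300L, 80L),
                        trt = c(150L, 90L, 700L, 20L))
  enr2 <- compute_enrichment(cm2, lib, "trt", "ref", cfg)
  expect_equal(median(enr2$rho, na.rm = TRUE), 0)

  # doubling one element's treated count adds exactly 1 to its rho
  # (pseudocount 0 isolates the closed-form log2 arithmetic)
  cfg0 <- scoring_config(pseudocount = 0)
  base <- tibble::tibble(element_id = lib$element_id, ref = 100L,
                         trt = c(400L, 400L, 400L, 400L))
  dbl <- dplyr::mutate(base, trt = c(800L, 400L, 400L, 400L))
  r1 <- compute_enrichment(base, lib, "trt", "ref", cfg0)$rho
  r2 <- compute_enrichment(dbl, lib, "trt", "ref", cfg0)$rho
  expect_equal(r2[1] - r1[1], 1.0)

  # swapping treated and reference negates rho
  fwd <- compute_enrichment(cm2, lib, "trt", "ref", cfg)$rho
  rev <- compute_enrichment(cm2, lib, "ref", "trt", cfg)$rho
  expect_equal(fwd, -rev)

  expect_error(compute_enrichment(cm, lib, "missing", "ref", cfg), "not in counts")
})

test_that("the control null density matches the analytic standard normal", {
  set.seed(30)
  enr <- make_enr(rnorm(5000))
  null <- fit_null(enr)
  expect_equal(null_density(null, 0), dnorm(0), tolerance = 0.1)
  # integrates to one on its grid
  expect_equal(sum(null$fx) * null$dx, 1, tolerance = 1e-6)
  # translation equivariance of the density mode
  enr_shift <- make_enr(enr$rho + 2)
  null_s <- fit_null(enr_shift)
  expect_equal(null_s$grid_x[which.max(null_s$fx)],
               null$grid_x[which.max(null$fx)] + 2, tolerance = 0.05)
})

test_that("degenerate and undersized control sets are handled", {
  expect_warning(fit_null(make_enr(rep(1.0, 100))), "degenerate")
  expect_error(fit_null(make_enr(rnorm(20))), "control")
})

test_that("gene_effect maximizes the efficacy-mixture likelihood", {
  set.seed(31)
  cfg <- scoring_config()
  null <- fit_null(make_enr(rnorm(2000, 0, 0.2)))

  # elements at the null center: effect and score pinned near zero
  g0 <- gene_effect(rep(0, 20), null, cfg)
  expect_lte(abs(g0$effect), 0.1)
  expect_lte(g0$score, 1)

  # 10 elements at rho = +3 against a narrow null: effect recovered at +3
  # (the coarse efficacy grid can push the argmax slightly past the
  # phenotype when the null is much narrower than the grid spacing)
  g3 <- gene_effect(rep(3, 10), null, cfg)
  expect_gte(g3$effect, 2.9)
  expect_lte(g3$effect, 3.5)
  expect_gt(g3$score, 10)

  # the curve agrees with a direct (e, t) grid evaluation
  rho <- c(-0.3, 0.1, 2.5, 3.1)
  g <- gene_effect(rho, null, cfg)
  direct <- vapply(cfg$effect_grid, function(e) {
    sum(vapply(rho, function(r)
      log(mean(null_density(null, r - cfg$efficacy_grid * e))), numeric(1)))
  }, numeric(1))
  expect_equal(g$loglik, direct, tolerance = 1e-8)
  expect_equal(g$effect, cfg$effect_grid[which.max(direct)])

  # invariance under element permutation
  g_perm <- gene_effect(sample(rho), null, cfg)
  expect_equal(g_perm$effect, g$effect)
  expect_equal(g_perm$score, g$score)

  expect_error(gene_effect(numeric(0), null, cfg), "no enrichments")
})

test_that("replicate curves combine by summation", {
  cfg <- scoring_config()
  e <- cfg$effect_grid
  curve_at <- function(mu) -(e - mu)^2
  one <- combine_replicates(list(curve_at(2)), cfg)
  expect_equal(one$effect, 2)

  # identical replicates: same effect, doubled score
  two <- combine_replicates(list(curve_at(2), curve_at(2)), cfg)
  expect_equal(two$effect, one$effect)
  expect_equal(two$score, 2 * one$score)

  # opposite effects of equal curvature cancel
  opp <- combine_replicates(list(curve_at(2), curve_at(-2)), cfg)
  expect_equal(opp$effect, 0)

  expect_error(combine_replicates(list(curve_at(2), curve_at(2)[-1]), cfg),
               "grid")
})

test_that("permutation p-values are calibrated add-one tail probabilities", {
  set.seed(32)
  cfg <- scoring_config(n_permutations = 400)
  null <- fit_null(make_enr(rnorm(1000)))
  pool <- rnorm(300)
  obs <- tibble::tibble(gene = c("null_gene", "strong"),
                        score = c(0, 1e6), k = c(10, 10))
  res <- permutation_pvalues(obs, pool, null, cfg, seed = 33)
  expect_gte(res$p[1], 0.5)                 # score 0 beats nothing
  expect_equal(res$p[2], 1 / 401)           # add-one lower bound
  expect_true(all(res$p > 0 & res$p <= 1))
})

test_that("hit calls respect inclusive effect and strict p cutoffs", {
  res <- tibble::tibble(gene = c("a", "b", "c", "d"),
                        effect = c(-3, -1.5, 2.0, 2.5),
                        neg_log_p = c(2.0, 9.0, 3.0, 1.2))
  out <- call_hits(res, scoring_config(effect_cutoff = 2, logp_cutoff = 1.5))
  expect_equal(out$hit, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(out$direction, c("activator", NA, "suppressor", NA))
  # genome-wide style threshold is stricter
  gw <- call_hits(res, scoring_config(logp_cutoff = 2.5))
  expect_equal(gw$hit, c(FALSE, FALSE, TRUE, FALSE))
})

test_that("replicate concordance and growth-vs-EV pairing behave", {
  set.seed(34)
  cm <- tibble::tibble(element_id = paste0("e", 1:2000),
                       a = rpois(2000, 200), b = rpois(2000, 200))
  expect_equal(qc_concordance(cm, "a", "a"), 1)
  cm$shuffled <- sample(cm$b)
  expect_lt(qc_concordance(cm, "a", "shuffled"), 0.05)
  expect_error(qc_concordance(cm[1, ], "a", "b"), "at least 2")

  g <- tibble::tibble(gene = paste0("g", 1:50), effect = rnorm(50),
                      score = runif(50))
  e <- tibble::tibble(gene = paste0("g", 1:50), effect = rnorm(50),
                      score = runif(50))
  paired <- qc_growth_vs_ev(g, e)
  expect_equal(nrow(paired), 50)
  expect_true(abs(attr(paired, "correlation")) <= 1)
})

test_that("score_screen recovers planted effects end to end", {
  cst <- design_constraints(candidate_budget = 3e5)
  lib <- build_library(paste0("g", 1:25), n_controls = 80,
                       constraints = cst, seed = 40)
  sim <- screen_simulation(lib, gene_effects = c(g1 = -3, g2 = 2.5),
                           depth = 1e6, seed = 41)
  cm <- simulate_screen(sim)$counts
  fit <- score_screen(cm, lib, treated = c("ev_cas9_r1", "ev_cas9_r2"),
                      reference = c("ev_wt_r1", "ev_wt_r2"),
                      cfg = scoring_config(n_permutations = 1000), seed = 42)
  res <- tidy(fit)
  expect_s3_class(res, "tbl_df")
  top2 <- res$gene[1:2]
  expect_setequal(top2, c("g1", "g2"))
  expect_equal(res$effect[res$gene == "g1"], -3, tolerance = 0.75)
  expect_equal(res$effect[res$gene == "g2"], 2.5, tolerance = 0.75)
  expect_true(all(res$hit[res$gene %in% c("g1", "g2")]))
  expect_lte(max(res$p), 1)
  g <- glance(fit)
  expect_equal(g$n_genes, 25)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
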