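test_that("check_barcode applies each design rule and reports the first failure", {
  cst <- design_constraints()
  res <- check_barcode(c("AAAACGTGCATGCAT",   # AAAA run
                         "ATATATATATATATA",   # GC 0
                         "ACGTCATGCAGTCAT",   # clean
                         "GAATTCGTACGTCAG",   # EcoRI site
                         "ACGTCATGCAGTCATA"), # 16 nt
                       cst)
  expect_equal(res$ok, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(res$reason,
               c("homopolymer", "gc_content", NA, "forbidden_site:EcoRI", "length"))
  # degenerate BlpI site (GCTNAGC) is caught for any realization of N
  blp <- check_barcode("GCTTAGCACGTACGT", cst)
  expect_equal(blp$reason, "forbidden_site:BlpI")
  # BstXI with its six inner Ns
  bst <- check_barcode("CCATTCATCTGGCAT", cst)
  expect_equal(bst$reason, "forbidden_site:BstXI")
  expect_error(check_barcode("ACGTNATGCAGTCAT", cst), "non-ACGT")
})

test_that("check_barcode agrees with an independent rule-by-rule oracle", {
  cst <- design_constraints()
  set.seed(42)
  seqs <- exoscreen:::random_dna(500, 15)
  got <- check_barcode(seqs, cst)
  want <- vapply(seqs, bf_barcode_reason, character(1))
  expect_equal(got$reason, unname(want))
})

test_that("designed barcode sets satisfy all constraints (brute-force verified)", {
  cst <- design_constraints(candidate_budget = 1e5)
  one <- design_barcodes(1, cst, seed = 5)
  expect_equal(nrow(one), 1)
  expect_true(check_barcode(one$barcode, cst)$ok)

  bc <- design_barcodes(50, cst, seed = 1)
  expect_equal(nrow(bc), 50)
  v <- bf_verify_set(bc$barcode)
  expect_true(v$all_rules_ok)
  expect_gte(v$min_pairwise, 4)
  # package-side verifier agrees with the oracle
  expect_equal(min_pairwise_hamming(bc$barcode), as.integer(v$min_pairwise))
  expect_true(verify_barcode_set(bc, cst)$all_ok)
})

test_that("design_barcodes is reproducible and rejects bad input", {
  cst <- design_constraints(candidate_budget = 1e4)
  a <- design_barcodes(30, cst, seed = 7)
  b <- design_barcodes(30, cst, seed = 7)
  expect_identical(a$barcode, b$barcode)
  c <- design_barcodes(30, cst, seed = 8)
  expect_false(identical(a$barcode, c$barcode))
  expect_error(design_barcodes(0, cst), "positive")
})

test_that("exhausting the candidate budget yields a partial set and report", {
  cst <- design_constraints(candidate_budget = 100)
  expect_message(bc <- design_barcodes(1000, cst, seed = 2), "budget")
  feas <- attr(bc, "feasibility")
  expect_true(feas$budget_exhausted)
  expect_lt(nrow(bc), 1000)
  expect_equal(feas$candidates_tried, 100)
})

test_that("tightening the distance floor never grows the achievable set", {
  sizes <- vapply(4:7, function(h) {
    cst <- design_constraints(min_hamming = h, candidate_budget = 2000)
    nrow(suppressMessages(design_barcodes(1e6, cst, seed = 3)))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("mature assembly appends the EXO motif (22 nt at defaults)", {
  m <- assemble_mature("ACGTCATGCAGTCAT")
  expect_equal(m, "ACGTCATGCAGTCATGGAGGAG")
  expect_equal(nchar(m), 22)
  set.seed(1)
  any_bc <- exoscreen:::random_dna(20, 15)
  expect_true(all(endsWith(assemble_mature(any_bc), "GGAGGAG")))
  expect_error(assemble_mature(""), "empty")
})

test_that("hairpin assembly pairs the stem exactly, except the declared mismatch", {
  cfg <- hairpin_config()
  hp <- assemble_hairpin("ACGTCATGCAGTCAT", cfg, variant = "none")
  expect_equal(hp$hairpin,
               paste0(cfg$context_5p, hp$mature, cfg$loop_seq, hp$passenger,
                      cfg$context_3p))
  # perfect complementarity under variant = none
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(hp$mature)))
  expect_equal(hp$passenger, rc)

  # auto variant is keyed to the first base and perturbs exactly one
  # passenger base, opposite stem position 1
  firsts <- c(A = "AGTTCATGCAGTCAT", T = "TCGTCATGCAGTCAT",
              G = "GCGTCATGCAGTCAT", C = "CAGTCATGCAGTCAT")
  want_var <- c(A = "AC", T = "TC", G = "GA", C = "CA")
  want_base <- c(A = "C", T = "C", G = "A", C = "A")
  for (b in names(firsts)) {
    v <- assemble_hairpin(firsts[[b]], cfg, variant = "auto")
    expect_equal(v$variant, unname(want_var[b]))
    perfect <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(v$mature)))
    diffs <- which(strsplit(v$passenger, "")[[1]] != strsplit(perfect, "")[[1]])
    expect_equal(diffs, nchar(perfect))  # the base paired with position 1
    expect_equal(substr(v$passenger, diffs, diffs), unname(want_base[b]))
    # mature is untouched by the mismatch
    expect_equal(v$mature, assemble_hairpin(firsts[[b]], cfg, "none")$mature)
  }
  expect_error(assemble_hairpin("GCGTCATGCAGTCAT", cfg, variant = "AC"),
               "incompatible")
  expect_error(assemble_hairpin("", cfg), "empty")
})

test_that("two-version expansion doubles the construct count, matures unchanged", {
  cst <- design_constraints(candidate_budget = 1e4)
  bc <- design_barcodes(25, cst, seed = 9)
  plain <- make_mismatch_variants(bc$barcode, which = "none")
  mm <- make_mismatch_variants(bc$barcode, which = "auto")
  both <- dplyr::bind_rows(plain, mm)
  expect_equal(nrow(both), 50)
  expect_equal(plain$mature, mm$mature)
  expect_false(any(plain$hairpin == mm$hairpin))
})

test_that("cassettes order the modules and police stray restriction sites", {
  hp <- assemble_hairpin("ACGTCATGCAGTCAT", variant = "auto")
  cfg <- cassette_config()
  cs <- build_cassette("GTTCACGTAGCAGTACGATT", hp$hairpin, cfg)
  o <- cs$full_oligo
  i_sg <- regexpr("GTTCACGTAGCAGTACGATT", o, fixed = TRUE)
  i_blp <- regexpr(cfg$site_blpI, o, fixed = TRUE)
  i_eco <- regexpr(cfg$site_ecoRI, o, fixed = TRUE)
  i_hp <- regexpr(hp$hairpin, o, fixed = TRUE)
  expect_true(i_sg < i_blp && i_blp < i_eco && i_eco < i_hp)
  expect_true(cs$valid)
  # empty flanks: the oligo is exactly sgRNA + sites + hairpin
  expect_equal(o, paste0("GTTCACGTAGCAGTACGATT", cfg$site_blpI,
                         cfg$site_ecoRI, hp$hairpin))

  # an EcoRI site hidden inside the hairpin trips strict validation
  bad_hp <- paste0("ACGTGAATTCACGT", hp$hairpin)
  expect_error(build_cassette("GTTCACGTAGCAGTACGATT", bad_hp, cfg),
               "stray")
  lax <- build_cassette("GTTCACGTAGCAGTACGATT", bad_hp, cfg, strict = FALSE)
  expect_false(lax$valid)
  expect_true("EcoRI" %in% lax$stray_sites[[1]]$site)
})
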