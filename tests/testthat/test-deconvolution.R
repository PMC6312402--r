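test_that("RNA reads are trimmed to the fragment and short reads dropped", {
  r30 <- paste(rep("ACGTA", 6), collapse = "")
  expect_equal(trim_rna_read(r30), substr(r30, 1, 14))
  r14 <- substr(r30, 1, 14)
  expect_equal(trim_rna_read(r14), r14)            # identity at exact length
  expect_true(is.na(trim_rna_read("ACGTACGTAC")))  # 10 nt: too short
  expect_equal(trim_rna_read(r30, trim_len = 5, offset = 2), "GTAAC")
})

test_that("fragments assign to all nearest elements within tolerance", {
  # four barcodes, pairwise distance exactly 4 between bc1 and bc2
  bc1 <- "AAAAACCCCCGGGGG"
  bc2 <- "TTTTACCCCCGGGGG"  # differs from bc1 at positions 1-4
  bc3 <- "ACGTGACTGACTGAC"
  bc4 <- "GGGGGTTTTTAAAAA"
  lib <- toy_library(c(bc1, bc2, bc3, bc4))

  # error-free prefix -> its own element only
  asn <- assign_barcode(substr(bc3, 1, 14), lib)
  expect_equal(asn[[1]], "el3")

  # equidistant fragment (distance 2 from bc1 and bc2 prefixes) -> both
  frag <- "TTAAACCCCCGGGG"  # 14 nt: first 4 = TTAA, 2 from AAAA and TTTT
  expect_equal(bf_assign(frag, lib$barcode_seq), c(1, 2))
  expect_setequal(assign_barcode(frag, lib)[[1]], c("el1", "el2"))

  # more than two mismatches from everything -> unassigned
  far <- "CCCCCAAAAATTTT"
  d <- vapply(substr(lib$barcode_seq, 1, 14), bf_hamming, numeric(1), a = far)
  expect_gt(min(d), 2)
  expect_length(assign_barcode(far, lib)[[1]], 0)

  # N counts as a mismatch at its position
  n2 <- paste0("NN", substr(bc3, 3, 14))
  expect_equal(assign_barcode(n2, lib)[[1]], "el3")
  n3 <- paste0("NNN", substr(bc3, 4, 14))
  expect_equal(length(assign_barcode(n3, lib)[[1]]), 0L)
})

test_that("assignment matches the brute-force nearest-neighbour oracle", {
  cst <- design_constraints(candidate_budget = 1e5)
  lib <- toy_library(design_barcodes(40, cst, seed = 12)$barcode)
  set.seed(13)
  frags <- c(substr(lib$barcode_seq, 1, 14),
             exoscreen:::random_dna(60, 14))
  got <- assign_barcode(frags, lib)
  for (i in seq_along(frags)) {
    expect_equal(got[[i]], lib$element_id[bf_assign(frags[i], lib$barcode_seq)],
                 info = paste("fragment", i))
  }
})

test_that("one substitution never changes the assignment of a designed library", {
  cst <- design_constraints(candidate_budget = 1e5)
  lib <- toy_library(design_barcodes(60, cst, seed = 14)$barcode)
  set.seed(15)
  src <- sample.int(nrow(lib), 200, replace = TRUE)
  clean <- substr(lib$barcode_seq[src], 1, 14)
  hit <- vapply(clean, function(f) mutate_one_base(f, sample.int(14, 1)),
                character(1))
  asn <- assign_barcode(unname(hit), lib)
  expect_true(all(vapply(seq_along(src),
                         function(i) identical(asn[[i]], lib$element_id[src[i]]),
                         logical(1))))
})

test_that("sgRNA counting is anchored and strictly exact", {
  cst <- design_constraints(candidate_budget = 1e5)
  lib <- toy_library(design_barcodes(6, cst, seed = 16)$barcode)
  reads <- c(paste0("CACCG", lib$sgrna_seq[1]),             # exact
             paste0("CACCG", lib$sgrna_seq[1]),
             paste0("TTT", "CACCG", lib$sgrna_seq[2]),      # anchor not at start
             paste0("CACCG", mutate_one_base(lib$sgrna_seq[3], 5)), # 1 mm
             paste0("GGGGG", lib$sgrna_seq[4]))             # no anchor
  set.seed(17)
  cnt <- count_sgrnas(reads, lib, anchor = "CACCG")
  expect_equal(unname(cnt[1:4]), c(2L, 1L, 0L, 0L))
  st <- attr(cnt, "read_stats")
  expect_equal(st$assigned, 3)
  expect_equal(st$dropped, 2)
  # empty batch -> all-zero column
  zero <- count_sgrnas(character(0), lib, anchor = "CACCG")
  expect_true(all(zero == 0L))
})

test_that("count_screen reproduces simulator ground truth and tracks metadata", {
  cst <- design_constraints(candidate_budget = 2e5)
  lib <- build_library(paste0("g", 1:10), n_controls = 10,
                       constraints = cst, seed = 18)
  sim <- screen_simulation(lib, depth = 5e3, seed = 19)
  dir <- withr::local_tempdir()
  rna <- simulate_reads(sim, "ev_wt_r1", n_reads = 5e3, error_rate = 0,
                        path = file.path(dir, "ev.fastq"))
  dna <- simulate_reads(sim, "cells_cas9_t0_r1", n_reads = 5e3, error_rate = 0,
                        path = file.path(dir, "dna.fastq"))
  samples <- tibble::tibble(
    sample = c("ev_wt", "cells_t0"),
    path = c(rna$path, dna$path),
    type = c("rna", "dna"))
  cm <- count_screen(samples, lib, anchor = "CACCG")
  expect_equal(cm$ev_wt, unname(rna$truth_counts))
  expect_equal(cm$cells_t0, unname(dna$truth_counts))
  st <- attr(cm, "read_stats")
  expect_equal(st$total, c(5e3, 5e3))
  expect_equal(st$dropped, c(0, 0))
  # column sums >= assigned reads (equality without multi-mapping)
  expect_equal(sum(cm$ev_wt), st$assigned[1])

  expect_error(count_screen(dplyr::mutate(samples, sample = "same"), lib),
               "duplicate sample label")
})

test_that("gzipped and plain FASTQ deconvolve identically", {
  cst <- design_constraints(candidate_budget = 1e5)
  lib <- toy_library(design_barcodes(10, cst, seed = 20)$barcode)
  sim <- screen_simulation(lib, depth = 1000, seed = 21)
  dir <- withr::local_tempdir()
  rr <- simulate_reads(sim, "ev_wt_r1", n_reads = 1000, error_rate = 0.01,
                       path = file.path(dir, "a.fastq"))
  write_fq <- exoscreen:::write_fastq
  write_fq(rr$reads$read_id, rr$reads$sequence, file.path(dir, "a.fastq.gz"))
  c1 <- count_barcode_reads(file.path(dir, "a.fastq"), lib)
  c2 <- count_barcode_reads(file.path(dir, "a.fastq.gz"), lib)
  expect_identical(c(c1), c(c2))
})
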