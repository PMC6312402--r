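#' Barcode design constraints
#'
#' Bundle the rules a bEXOmiR barcode set must satisfy: fixed length, a GC
#' window, a homopolymer-run cap, exclusion of the restriction sites used in
#' library cloning, and a pairwise Hamming-distance floor that makes the set
#' an error-tolerant code. Defaults correspond to the platform's published
#' test-library rules: 15 nt, 40-60% GC, no run of four or more identical
#' bases, no EcoRI/MfeI/BlpI/BstXI site, minimum pairwise distance 4.
#'
#' @param barcode_length Barcode length in nt.
#' @param gc_min,gc_max Allowed GC fraction window (inclusive).
#' @param min_hamming Minimum pairwise Hamming distance between any two
#'   barcodes in a set. Distance 4 guarantees unique decoding of reads
#'   carrying a single substitution.
#' @param homopolymer_max_run Longest tolerated run of one base; runs of
#'   `homopolymer_max_run + 1` or more are rejected.
#' @param forbidden_sites Named character vector of IUPAC-degenerate DNA
#'   motifs that must not occur in a barcode (nor, when `scan_revcomp` is
#'   `TRUE`, in its reverse complement). Defaults are the four cloning
#'   enzymes' recognition sites, all of which are palindromic.
#' @param candidate_budget Maximum number of random candidates the designer
#'   may draw before giving up.
#' @param rng_seed Default seed used by [design_barcodes()].
#' @param scan_revcomp Also scan the reverse complement for forbidden sites.
#'   Redundant for palindromic sites, so off by default.
#' @return A `design_constraints` list.
#' @examples
#' cst <- design_constraints()
#' check_barcode("ACGTCATGCAGTCAT", cst)
#' @export
design_constraints <- function(barcode_length = 15L,
                               gc_min = 0.40, gc_max = 0.60,
                               min_hamming = 4L,
                               homopolymer_max_run = 3L,
                               forbidden_sites = c(
                                 EcoRI = "GAATTC", MfeI = "CAATTG",
                                 BlpI = "GCTNAGC", BstXI = "CCANNNNNNTGG"),
                               candidate_budget = 1e6,
                               rng_seed = 1L,
                               scan_revcomp = FALSE) {
  if (!(gc_min >= 0 && gc_min <= gc_max && gc_max <= 1))
    abort("need 0 <= gc_min <= gc_max <= 1")
  if (min_hamming < 0) abort("min_hamming must be >= 0")
  if (barcode_length < 1) abort("barcode_length must be positive")
  if (length(forbidden_sites) &&
      any(grepl("[^ACGTURYSWKMBDHVN]", toupper(forbidden_sites))))
    abort("forbidden_sites must contain only IUPAC nucleotide letters")
  structure(list(
    barcode_length = as.integer(barcode_length),
    gc_min = gc_min, gc_max = gc_max,
    min_hamming = as.integer(min_hamming),
    homopolymer_max_run = as.integer(homopolymer_max_run),
    forbidden_sites = forbidden_sites,
    candidate_budget = candidate_budget,
    rng_seed = as.integer(rng_seed),
    scan_revcomp = isTRUE(scan_revcomp)
  ), class = "design_constraints")
}

#' @export
print.design_constraints <- function(x, ...) {
  cat(sprintf(
    "<design_constraints> length %d nt, GC [%.0f%%, %.0f%%], run <= %d, min Hamming %d\n",
    x$barcode_length, 100 * x$gc_min, 100 * x$gc_max,
    x$homopolymer_max_run, x$min_hamming))
  cat("forbidden sites:", paste(sprintf("%s (%s)", names(x$forbidden_sites),
                                        x$forbidden_sites), collapse = ", "), "\n")
  invisible(x)
}

forbidden_site_hits <- function(seqs, constraints) {
  # which forbidden motif (if any) first matches each sequence
  subj <- Biostrings::DNAStringSet(seqs)
  hit <- rep(NA_character_, length(seqs))
  sites <- constraints$forbidden_sites
  site_names <- if (is.null(names(sites))) sites else names(sites)
  for (i in seq_along(sites)) {
    pats <- toupper(sites[[i]])
    if (constraints$scan_revcomp) {
      rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(pats)))
      pats <- unique(c(pats, rc))
    }
    for (p in pats) {
      n <- Biostrings::vcountPattern(p, subj, fixed = FALSE)
      hit[is.na(hit) & n > 0] <- site_names[i]
    }
  }
  hit
}

#' Validate candidate barcodes rule by rule
#'
#' Applies every per-sequence design rule (length, GC window, homopolymer
#' cap, forbidden-site scan) and reports, for each input, whether it is
#' acceptable and the first rule it failed. The pairwise distance floor is a
#' property of a *set*, not a single sequence, and is enforced by
#' [design_barcodes()] / checked by [verify_barcode_set()].
#'
#' @param seq Character vector of DNA sequences (A/C/G/T only).
#' @param constraints A [design_constraints()] object.
#' @return A tibble with columns `sequence`, `ok`, `reason` (`NA` when
#'   accepted; otherwise one of `"length"`, `"gc_content"`, `"homopolymer"`,
#'   or `"forbidden_site:<name>"`).
#' @examples
#' check_barcode(c("AAAACGTGCATGCAT", "ACGTCATGCAGTCAT"), design_constraints())
#' @export
check_barcode <- function(seq, constraints = design_constraints()) {
  seq <- assert_dna(seq, "barcode")
  reason <- rep(NA_character_, length(seq))
  bad_len <- nchar(seq) != constraints$barcode_length
  reason[bad_len] <- "length"
  gc <- gc_fraction(seq)
  bad_gc <- is.na(reason) &
    (gc < constraints$gc_min - 1e-9 | gc > constraints$gc_max + 1e-9)
  reason[bad_gc] <- "gc_content"
  runs <- max_homopolymer_run(seq)
  bad_run <- is.na(reason) & runs > constraints$homopolymer_max_run
  reason[bad_run] <- "homopolymer"
  open <- is.na(reason)
  if (any(open) && length(constraints$forbidden_sites)) {
    hits <- forbidden_site_hits(seq[open], constraints)
    reason[open][!is.na(hits)] <- paste0("forbidden_site:", hits[!is.na(hits)])
  }
  tibble::tibble(sequence = seq, ok = is.na(reason), reason = reason)
}

#' Design an error-tolerant barcode set
#'
#' Greedy code growth over rejection-sampled random sequences: candidates
#' are drawn uniformly, filtered by the per-sequence rules of
#' [check_barcode()], and admitted only when at Hamming distance
#' `min_hamming` or more from every barcode already in the set. The result
#' is deterministic for a given seed and constraints.
#'
#' If the candidate budget runs out before `n` barcodes are found, the
#' partial set is returned with a message; the feasibility report is
#' attached as the `"feasibility"` attribute either way.
#'
#' @param n Number of barcodes requested (use a large `n` together with
#'   `constraints$candidate_budget` to ask for "as many as possible").
#' @param constraints A [design_constraints()] object.
#' @param seed Integer seed; defaults to `constraints$rng_seed`.
#' @return A tibble with column `barcode`, plus attributes `"feasibility"`
#'   (candidates tried/valid, rejections by distance, whether the budget was
#'   exhausted) and `"constraints"`.
#' @examples
#' bc <- design_barcodes(50, design_constraints(candidate_budget = 1e4))
#' attr(bc, "feasibility")
#' @export
design_barcodes <- function(n, constraints = design_constraints(),
                            seed = constraints$rng_seed) {
  if (length(n) != 1 || is.na(n) || n < 1) abort("n must be a positive integer")
  set.seed(seed)
  res <- design_barcodes_cpp(
    n = as.integer(min(n, .Machine$integer.max)),
    len = constraints$barcode_length,
    gc_min = constraints$gc_min, gc_max = constraints$gc_max,
    max_run = constraints$homopolymer_max_run,
    forbidden = as.character(constraints$forbidden_sites),
    scan_revcomp = constraints$scan_revcomp,
    min_hamming = constraints$min_hamming,
    budget = constraints$candidate_budget
  )
  out <- tibble::tibble(barcode = res$barcodes)
  feas <- list(requested = n, returned = nrow(out),
               candidates_tried = res$candidates_tried,
               candidates_valid = res$candidates_valid,
               rejected_by_distance = res$rejected_by_distance,
               budget_exhausted = res$budget_exhausted)
  if (res$budget_exhausted) {
    message(sprintf(
      "candidate budget (%g) exhausted: returning %d of %g requested barcodes",
      constraints$candidate_budget, nrow(out), n))
  }
  attr(out, "feasibility") <- feas
  attr(out, "constraints") <- constraints
  out
}

#' Brute-force verification of a barcode set
#'
#' Independent check that every barcode passes the per-sequence rules and
#' that all pairwise Hamming distances meet the floor, by exhaustive
#' \eqn{O(n^2)} scan. Intended as a verifier for sets produced elsewhere.
#'
#' @param barcodes Character vector (or tibble with a `barcode` column).
#' @param constraints A [design_constraints()] object.
#' @return A list with `all_ok`, `n`, `min_pairwise_hamming` (Inf for n < 2)
#'   and the per-sequence `checks` tibble.
#' @export
verify_barcode_set <- function(barcodes, constraints = design_constraints()) {
  if (is.data.frame(barcodes)) barcodes <- barcodes$barcode
  checks <- check_barcode(barcodes, constraints)
  dmin <- min_pairwise_hamming(barcodes)
  list(all_ok = all(checks$ok) && dmin >= constraints$min_hamming,
       n = length(barcodes), min_pairwise_hamming = dmin, checks = checks)
}

#' Minimum pairwise Hamming distance of a sequence set
#'
#' Exhaustive scan over all pairs of equal-length sequences.
#'
#' @param x Character vector of equal-length sequences.
#' @return Integer minimum distance; `Inf` when fewer than two sequences.
#' @export
min_pairwise_hamming <- function(x) {
  n <- length(x)
  if (n < 2) return(Inf)
  if (length(unique(nchar(x))) != 1) abort("sequences must share one length")
  m <- do.call(rbind, strsplit(x, ""))
  dmin <- Inf
  for (i in seq_len(n - 1)) {
    d <- rowSums(m[(i + 1):n, , drop = FALSE] !=
                   matrix(m[i, ], n - i, ncol(m), byrow = TRUE))
    dmin <- min(dmin, d)
    if (dmin == 0) break
  }
  as.integer(dmin)
}
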