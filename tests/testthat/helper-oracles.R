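# Independent brute-force oracles, deliberately written with a different
# implementation style (regex, character loops) than the package internals.

bf_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

bf_min_pairwise <- function(x) {
  n <- length(x)
  if (n < 2) return(Inf)
  chars <- do.call(rbind, strsplit(x, ""))
  best <- Inf
  for (i in seq_len(n - 1)) {
    ref <- chars[rep(i, n - i), , drop = FALSE]
    best <- min(best, min(rowSums(chars[(i + 1):n, , drop = FALSE] != ref)))
  }
  best
}

IUPAC_CLASS <- c(A = "A", C = "C", G = "G", T = "T", U = "T",
                 R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
                 K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
                 H = "[ACT]", V = "[ACG]", N = "[ACGT]")

iupac_regex <- function(motif) {
  paste(IUPAC_CLASS[strsplit(toupper(motif), "")[[1]]], collapse = "")
}

bf_barcode_reason <- function(seq, len = 15, gc_lo = 0.40, gc_hi = 0.60,
                              max_run = 3,
                              motifs = c(EcoRI = "GAATTC", MfeI = "CAATTG",
                                         BlpI = "GCTNAGC",
                                         BstXI = "CCANNNNNNTGG")) {
  if (nchar(seq) != len) return("length")
  s <- strsplit(seq, "")[[1]]
  gc <- mean(s %in% c("G", "C"))
  if (gc < gc_lo - 1e-9 || gc > gc_hi + 1e-9) return("gc_content")
  if (max(rle(s)$lengths) > max_run) return("homopolymer")
  for (nm in names(motifs)) {
    if (grepl(iupac_regex(motifs[[nm]]), seq)) {
      return(paste0("forbidden_site:", nm))
    }
  }
  NA_character_
}

bf_verify_set <- function(barcodes, min_hamming = 4, ...) {
  reasons <- vapply(barcodes, bf_barcode_reason, character(1), ...)
  list(all_rules_ok = all(is.na(reasons)),
       reasons = reasons,
       min_pairwise = bf_min_pairwise(barcodes))
}

# nearest-neighbour decode oracle over barcode prefixes
bf_assign <- function(fragment, barcodes, trim_len = 14, max_mm = 2) {
  pre <- substr(barcodes, 1, trim_len)
  d <- unname(vapply(pre, bf_hamming, numeric(1), a = fragment))
  if (min(d) > max_mm) return(integer(0))
  which(d == min(d))
}

# small handmade library that satisfies validate_library()
toy_library <- function(barcodes, guides_per_gene = 2) {
  n <- length(barcodes)
  n_genes <- n %/% guides_per_gene
  gene <- rep(paste0("G", seq_len(n_genes)), each = guides_per_gene,
              length.out = n)
  tibble::tibble(
    element_id = paste0("el", seq_len(n)),
    sublibrary = "toy",
    gene = gene,
    category = "targeting",
    sgrna_seq = exoscreen:::random_dna(n, 20),
    barcode_seq = barcodes)
}

mutate_one_base <- function(seq, pos) {
  b <- substr(seq, pos, pos)
  alt <- setdiff(c("A", "C", "G", "T"), b)
  substr(seq, pos, pos) <- sample(alt, 1)
  seq
}
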