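# Internal sequence helpers. Kept in base R so they are trivially auditable;
# heavy lifting (set design, read matching) lives in src/.

DNA_BASES <- c("A", "C", "G", "T")

assert_dna <- function(x, arg = "sequence") {
  bad <- grepl("[^ACGTacgt]", x)
  if (any(bad)) {
    abort(sprintf("%s contains non-ACGT characters (first offender: '%s')",
                  arg, x[which(bad)[1]]))
  }
  toupper(x)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complement_base <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A")[b]
}

gc_fraction <- function(x) {
  vapply(strsplit(x, ""), function(s) mean(s %in% c("G", "C")), numeric(1))
}

max_homopolymer_run <- function(x) {
  vapply(strsplit(x, ""), function(s) max(rle(s)$lengths), numeric(1))
}

random_dna <- function(n, len) {
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  apply(m, 1, paste0, collapse = "")
}

geomean <- function(x) exp(mean(log(x)))

# FASTQ I/O. Reading goes through Biostrings (handles gzip transparently);
# writing emits plain four-line records, gzipped when the path ends in .gz.
read_fastq_seqs <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTQ file not found: %s", path))
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

write_fastq <- function(ids, seqs, path, qual_char = "I") {
  stopifnot(length(ids) == length(seqs))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (length(seqs) == 0) {
    # an empty batch still produces a valid (empty) file
    writeLines(character(0), con)
    return(invisible(path))
  }
  quals <- vapply(nchar(seqs), function(n) strrep(qual_char, n), character(1))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), con, sep = "\n")
  invisible(path)
}
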