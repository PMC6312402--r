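#' Trim RNA barcode reads
#'
#' bEXOmiR RNA reads carry the barcode at a fixed position (the mature
#' sequence starts with the barcode); reads are trimmed to a short fragment
#' before matching. Reads too short to yield the fragment become `NA` and
#' are tallied as drops by the counting functions.
#'
#' @param bases Character vector of read sequences.
#' @param trim_len Fragment length (default 14 nt).
#' @param offset 0-based offset of the fragment within the read.
#' @return Character vector of fragments, `NA` where the read is too short.
#' @examples
#' trim_rna_read(c("ACGTACGTACGTACGTACGT", "ACGTACGTAC"))
#' @export
trim_rna_read <- function(bases, trim_len = 14L, offset = 0L) {
  out <- substr(bases, offset + 1L, offset + trim_len)
  out[nchar(bases) < offset + trim_len] <- NA_character_
  out
}

#' Assign trimmed fragments to library elements
#'
#' Best-hit-within-`max_mismatch` Hamming matching against the
#' `trim_len`-nt prefixes of the library barcodes: each fragment is
#' assigned to *all* elements at the minimum distance when that minimum is
#' at most `max_mismatch` (multi-mapping fragments count once for every
#' tied element), and to none otherwise. Non-ACGT characters (e.g. `N`)
#' count as mismatches at their position.
#'
#' @param fragment Character vector of fragments (see [trim_rna_read()]).
#' @param lib Library tibble.
#' @param max_mismatch Mismatch tolerance (default 2).
#' @param trim_len Prefix length compared (default 14).
#' @return A list (one entry per fragment) of element-id character vectors;
#'   empty when unassignable.
#' @export
assign_barcode <- function(fragment, lib, max_mismatch = 2L, trim_len = 14L) {
  validate_library(lib)
  refs <- substr(lib$barcode_seq, 1, trim_len)
  ok <- !is.na(fragment)
  idx <- vector("list", length(fragment))
  idx[ok] <- hamming_match_cpp(fragment[ok], refs, as.integer(max_mismatch))
  purrr::map(idx, function(i) if (is.null(i)) character(0) else lib$element_id[i])
}

count_assignments <- function(assignments, lib, n_short = 0L) {
  hits_per_read <- lengths(assignments)
  counts <- integer(nrow(lib))
  names(counts) <- lib$element_id
  tab <- table(unlist(assignments))
  counts[names(tab)] <- as.integer(tab)
  stats <- tibble::tibble(
    total = length(assignments) + n_short,
    assigned = sum(hits_per_read > 0),
    multi_assigned = sum(hits_per_read > 1),
    dropped = n_short + sum(hits_per_read == 0))
  list(counts = counts, stats = stats)
}

#' Count barcode (RNA) reads for one sample
#'
#' Trims each read to the barcode fragment and assigns it by
#' mismatch-tolerant prefix matching ([assign_barcode()]). Multi-mapping
#' reads increment every tied element, so column sums can exceed the number
#' of assigned reads; the metadata tracks this explicitly.
#'
#' @param reads Character vector of read sequences, or a FASTQ path
#'   (plain or gzipped).
#' @param lib Library tibble.
#' @param trim_len,offset See [trim_rna_read()].
#' @param max_mismatch See [assign_barcode()].
#' @return Named integer vector of per-element counts with a `"read_stats"`
#'   attribute (`total`, `assigned`, `multi_assigned`, `dropped`).
#' @export
count_barcode_reads <- function(reads, lib, trim_len = 14L, offset = 0L,
                                max_mismatch = 2L) {
  if (length(reads) == 1 && file.exists(reads)) reads <- read_fastq_seqs(reads)
  frag <- trim_rna_read(reads, trim_len = trim_len, offset = offset)
  short <- is.na(frag)
  asn <- assign_barcode(frag[!short], lib, max_mismatch = max_mismatch,
                        trim_len = trim_len)
  res <- count_assignments(asn, lib, n_short = sum(short))
  structure(res$counts, read_stats = res$stats)
}

#' Count sgRNA (DNA) reads for one sample
#'
#' Locates the constant 5' anchor in each read, takes the following
#' protospacer-length bases, and requires an exact (zero-mismatch) match to
#' a library sgRNA. Reads without the anchor, too short after it, or not
#' matching exactly are dropped and tallied.
#'
#' @param reads Character vector of read sequences or a FASTQ path.
#' @param lib Library tibble (sgRNA sequences must be unique and of one
#'   length).
#' @param anchor Constant sequence immediately 5' of the protospacer; `""`
#'   means the protospacer starts at the first base.
#' @return Named integer vector of per-element counts with `"read_stats"`.
#' @export
count_sgrnas <- function(reads, lib, anchor = "") {
  validate_library(lib)
  if (length(reads) == 1 && file.exists(reads)) reads <- read_fastq_seqs(reads)
  sg_len <- unique(nchar(lib$sgrna_seq))
  if (length(sg_len) != 1) abort("library sgRNAs must share one length")
  if (anyDuplicated(lib$sgrna_seq)) abort("library sgRNAs must be unique")
  if (nzchar(anchor)) {
    pos <- regexpr(anchor, reads, fixed = TRUE)
    start <- ifelse(pos > 0, pos + nchar(anchor), NA_integer_)
  } else {
    start <- rep(1L, length(reads))
  }
  frag <- substr(reads, start, start + sg_len - 1L)
  frag[is.na(start) | nchar(frag) < sg_len] <- NA_character_
  hit <- match(frag, lib$sgrna_seq)
  counts <- integer(nrow(lib))
  names(counts) <- lib$element_id
  tab <- table(hit)
  counts[as.integer(names(tab))] <- as.integer(tab)
  stats <- tibble::tibble(
    total = length(reads), assigned = sum(!is.na(hit)),
    multi_assigned = 0L, dropped = sum(is.na(hit)))
  structure(counts, read_stats = stats)
}

#' Deconvolve a whole screen into a count matrix
#'
#' Runs barcode counting on RNA samples and exact sgRNA counting on DNA
#' samples, one FASTQ per sample, and assembles the element-by-sample count
#' matrix with per-sample read-accounting metadata.
#'
#' @param samples A tibble with columns `sample` (unique labels), `path`
#'   (FASTQ path) and `type` (`"rna"` or `"dna"`); extra annotation columns
#'   (compartment, genotype, replicate, ...) are carried into the
#'   `"sample_info"` attribute.
#' @param lib Library tibble.
#' @param trim_len,offset,max_mismatch RNA-side parameters.
#' @param anchor DNA-side constant anchor.
#' @return A counts tibble (`element_id` plus one integer column per
#'   sample) with attributes `"read_stats"` and `"sample_info"`.
#' @export
count_screen <- function(samples, lib, trim_len = 14L, offset = 0L,
                         max_mismatch = 2L, anchor = "") {
  if (!all(c("sample", "path", "type") %in% names(samples)))
    abort("samples needs columns sample, path, type")
  if (anyDuplicated(samples$sample))
    abort(sprintf("duplicate sample label: %s",
                  samples$sample[duplicated(samples$sample)][1]))
  if (!all(samples$type %in% c("rna", "dna")))
    abort("sample type must be 'rna' or 'dna'")
  validate_library(lib)
  cols <- purrr::map(seq_len(nrow(samples)), function(i) {
    if (samples$type[i] == "rna") {
      count_barcode_reads(samples$path[i], lib, trim_len = trim_len,
                          offset = offset, max_mismatch = max_mismatch)
    } else {
      count_sgrnas(samples$path[i], lib, anchor = anchor)
    }
  })
  counts <- tibble::tibble(element_id = lib$element_id)
  for (i in seq_len(nrow(samples)))
    counts[[samples$sample[i]]] <- as.integer(cols[[i]])
  stats <- dplyr::bind_rows(purrr::map(cols, attr, "read_stats"))
  stats <- dplyr::bind_cols(tibble::tibble(sample = samples$sample), stats)
  attr(counts, "read_stats") <- stats
  attr(counts, "sample_info") <- dplyr::select(samples, -"path")
  counts
}

#' Read / write count matrices
#'
#' Tab-delimited tables with `element_id` as the row key and one integer
#' column per sample.
#'
#' @param path File path.
#' @param counts A counts tibble.
#' @return `read_counts()` returns the counts tibble; `write_counts()`
#'   invisibly returns `path`.
#' @export
read_counts <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    element_id = readr::col_character(), .default = readr::col_double()))
}

#' @rdname read_counts
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}
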