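LIBRARY_COLS <- c("element_id", "sublibrary", "gene", "category",
                  "sgrna_seq", "barcode_seq")
CATEGORIES <- c("targeting", "nontargeting", "safe_targeting")

validate_library <- function(lib, where = "library") {
  missing <- setdiff(LIBRARY_COLS, names(lib))
  if (length(missing))
    abort(sprintf("%s is missing column(s): %s", where,
                  paste(missing, collapse = ", ")))
  dup <- which(duplicated(lib$barcode_seq))
  if (length(dup))
    abort(sprintf("%s: duplicate barcode at row %d (%s)", where, dup[1],
                  lib$barcode_seq[dup[1]]))
  dupid <- which(duplicated(lib$element_id))
  if (length(dupid))
    abort(sprintf("%s: duplicate element_id at row %d (%s)", where, dupid[1],
                  lib$element_id[dupid[1]]))
  bad_cat <- which(!lib$category %in% CATEGORIES)
  if (length(bad_cat))
    abort(sprintf("%s: unknown category '%s' at row %d", where,
                  lib$category[bad_cat[1]], bad_cat[1]))
  nogene <- which(lib$category == "targeting" & (is.na(lib$gene) | lib$gene == ""))
  if (length(nogene))
    abort(sprintf("%s: targeting element without gene at row %d (%s)", where,
                  nogene[1], lib$element_id[nogene[1]]))
  hasgene <- which(lib$category != "targeting" & !is.na(lib$gene) & lib$gene != "")
  if (length(hasgene))
    abort(sprintf("%s: control element with a gene at row %d", where, hasgene[1]))
  invisible(lib)
}

#' Build an sgRNA-bEXOmiR library
#'
#' Pairs every guide with a unique barcode designed under `constraints`:
#' `guides_per_gene` targeting elements per gene plus `n_controls` control
#' elements split (50/50 by default) between non-targeting and
#' safe-targeting guides. Guide sequences here are opaque unique 20-mers;
#' in practice they come from a published genome-wide guide set.
#'
#' @param genes Character vector of gene names (must be unique).
#' @param n_controls Total number of control elements.
#' @param constraints [design_constraints()] used for barcode design.
#' @param guides_per_gene Elements per targeted gene (default 10).
#' @param sublibrary Sublibrary label stored with every element.
#' @param sgrna_length Length of the generated guide sequences.
#' @param seed Seed forwarded to barcode design and guide generation.
#' @return A library tibble with columns `element_id`, `sublibrary`,
#'   `gene`, `category`, `sgrna_seq`, `barcode_seq`.
#' @examples
#' lib <- build_library(paste0("GENE", 1:3), n_controls = 4,
#'                      constraints = design_constraints(candidate_budget = 1e4))
#' dplyr::count(lib, category)
#' @export
build_library <- function(genes, n_controls = 0,
                          constraints = design_constraints(),
                          guides_per_gene = 10L, sublibrary = "sub1",
                          sgrna_length = 20L,
                          seed = constraints$rng_seed) {
  if (length(genes) == 0) abort("genes must be nonempty")
  if (anyDuplicated(genes)) abort("gene names must be unique")
  n_total <- length(genes) * guides_per_gene + n_controls
  bc <- design_barcodes(n_total, constraints, seed = seed)
  if (nrow(bc) < n_total)
    abort(sprintf(
      "barcode design infeasible at this scale: %d of %d designable within budget",
      nrow(bc), n_total))
  # unique opaque guide sequences
  sg <- unique(random_dna(ceiling(n_total * 1.2), sgrna_length))
  while (length(sg) < n_total)
    sg <- unique(c(sg, random_dna(n_total, sgrna_length)))
  sg <- sg[seq_len(n_total)]

  n_nt <- ceiling(n_controls / 2)
  n_safe <- n_controls - n_nt
  targ <- tibble::tibble(
    element_id = paste0(rep(genes, each = guides_per_gene), "_sg",
                        sprintf("%02d", rep(seq_len(guides_per_gene),
                                            length(genes)))),
    gene = rep(genes, each = guides_per_gene),
    category = "targeting")
  ctrl <- tibble::tibble(
    element_id = c(sprintf("nontarget_%05d", seq_len(n_nt)),
                   sprintf("safe_%05d", seq_len(n_safe))),
    gene = NA_character_,
    category = rep(c("nontargeting", "safe_targeting"), c(n_nt, n_safe)))
  lib <- dplyr::bind_rows(targ, ctrl) |>
    dplyr::mutate(sublibrary = sublibrary, sgrna_seq = sg,
                  barcode_seq = bc$barcode) |>
    dplyr::select(dplyr::all_of(LIBRARY_COLS))
  validate_library(lib)
}

#' Refine a sublibrary by wild-type EV detection
#'
#' Drops elements whose barcode is effectively undetectable in wild-type EV
#' samples (count strictly below `low`) or so over-represented that it eats
#' sequencing depth (count strictly above `high`).
#'
#' @param lib A library tibble.
#' @param wt_counts A counts tibble containing `element_id` and the WT EV
#'   sample column.
#' @param sample Name of the WT EV column; defaults to the single numeric
#'   column when unambiguous.
#' @param low,high Strict detection bounds (defaults 10 and 10,000).
#' @return The filtered library tibble.
#' @export
refine_sublibrary <- function(lib, wt_counts, sample = NULL,
                              low = 10, high = 10000) {
  validate_library(lib)
  if (is.null(sample)) {
    num <- names(wt_counts)[vapply(wt_counts, is.numeric, logical(1))]
    if (length(num) != 1)
      abort("sample must be given when wt_counts has several numeric columns")
    sample <- num
  }
  missing <- setdiff(lib$element_id, wt_counts$element_id)
  if (length(missing))
    abort(sprintf("wt_counts does not cover %d library element(s), e.g. %s",
                  length(missing), missing[1]))
  cnt <- wt_counts[[sample]][match(lib$element_id, wt_counts$element_id)]
  dplyr::filter(lib, cnt >= low, cnt <= high)
}

#' Read / write library tables
#'
#' Libraries are stored as UTF-8, tab-delimited tables with a fixed header:
#' `element_id, sublibrary, gene, category, sgrna_seq, barcode_seq`.
#' Reading validates structure (duplicate barcodes or element ids, targeting
#' rows without a gene, unknown categories) and reports the offending row.
#'
#' @param path File path.
#' @return `read_library()` returns a validated library tibble;
#'   `write_library()` invisibly returns `path`.
#' @export
read_library <- function(path) {
  lib <- readr::read_tsv(path, col_types = readr::cols(
    element_id = readr::col_character(), sublibrary = readr::col_character(),
    gene = readr::col_character(), category = readr::col_character(),
    sgrna_seq = readr::col_character(), barcode_seq = readr::col_character()))
  validate_library(lib, where = path)
}

#' @rdname read_library
#' @param lib A library tibble.
#' @export
write_library <- function(lib, path) {
  validate_library(lib)
  readr::write_tsv(lib, path)
  invisible(path)
}

#' Export library references as FASTA
#'
#' Writes one FASTA of barcode sequences and one of sgRNA sequences, with
#' record ids equal to element ids, for use as aligner references.
#'
#' @param lib A library tibble.
#' @param barcode_path,sgrna_path Output FASTA paths (`NULL` to skip one).
#' @return Invisibly, the written paths.
#' @export
write_library_fasta <- function(lib, barcode_path = NULL, sgrna_path = NULL) {
  validate_library(lib)
  if (!is.null(barcode_path)) {
    x <- Biostrings::DNAStringSet(setNames(lib$barcode_seq, lib$element_id))
    Biostrings::writeXStringSet(x, barcode_path)
  }
  if (!is.null(sgrna_path)) {
    x <- Biostrings::DNAStringSet(setNames(lib$sgrna_seq, lib$element_id))
    Biostrings::writeXStringSet(x, sgrna_path)
  }
  invisible(c(barcode_path, sgrna_path))
}
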