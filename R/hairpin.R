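#' Hairpin assembly configuration
#'
#' Sequence context used to fold a barcode into a pri-miRNA-style hairpin:
#' the constant EXO targeting motif appended to the barcode, the loop, and
#' the 5'/3' flanking context in which the stem is embedded. The defaults
#' are the widely used miR-30-style loop and context arms; substitute your
#' own (e.g. miR-601-derived loop) sequences for a different backbone. The
#' `mature_arm` switch places the mature (barcode-carrying) strand on the
#' 5' or 3' arm of the stem.
#'
#' @param exo_motif Constant EV-targeting motif appended to the barcode.
#' @param loop_seq Loop sequence between the two stem arms.
#' @param context_5p,context_3p Flanking context sequences.
#' @param mature_arm `"5p"` (default) or `"3p"`.
#' @return A `hairpin_config` list.
#' @export
hairpin_config <- function(exo_motif = "GGAGGAG",
                           loop_seq = "TAGTGAAGCCACAGATGTA",
                           context_5p = "TGCTGTTGACAGTGAGCG",
                           context_3p = "TGCCTACTGCCTCGGA",
                           mature_arm = c("5p", "3p")) {
  mature_arm <- match.arg(mature_arm)
  for (nm in c("exo_motif", "loop_seq", "context_5p", "context_3p")) {
    v <- get(nm)
    if (is.null(v) || is.na(v)) abort(sprintf("missing config sequence: %s", nm))
  }
  structure(list(exo_motif = assert_dna(exo_motif, "exo_motif"),
                 loop_seq = assert_dna(loop_seq, "loop_seq"),
                 context_5p = assert_dna(context_5p, "context_5p"),
                 context_3p = assert_dna(context_3p, "context_3p"),
                 mature_arm = mature_arm),
            class = "hairpin_config")
}

#' Mature bEXOmiR sequence for a barcode
#'
#' The mature product is simply the barcode followed by the constant EXO
#' motif; at the default 15-nt barcode and 7-nt motif this is 22 nt.
#'
#' @param barcode Character vector of barcodes.
#' @param exo_motif Constant motif (default `GGAGGAG`).
#' @return Character vector of mature sequences.
#' @examples
#' assemble_mature("ACGTCATGCAGTCAT")  # 22 nt, ends in GGAGGAG
#' @export
assemble_mature <- function(barcode, exo_motif = "GGAGGAG") {
  barcode <- assert_dna(barcode, "barcode")
  if (any(nchar(barcode) == 0)) abort("empty barcode")
  paste0(barcode, assert_dna(exo_motif, "exo_motif"))
}

# passenger base replacing the perfect complement at the stem-base pair,
# keyed by the first (guide-strand) base: A-C, T-C, G-A, C-A
MISMATCH_PARTNER <- c(A = "C", T = "C", G = "A", C = "A")
VARIANT_FOR_BASE <- c(A = "AC", T = "TC", G = "GA", C = "CA")

passenger_strand <- function(mature, variant) {
  # reverse complement of the mature strand; the declared variant replaces
  # the base paired with mature position 1 (the last passenger base when the
  # mature strand is written 5'->3' first)
  pas <- revcomp(mature)
  if (variant != "none") {
    first <- substr(mature, 1, 1)
    expected <- unname(VARIANT_FOR_BASE[first])
    if (variant != expected) {
      abort(sprintf("variant %s incompatible with leading base %s (needs %s)",
                    variant, first, expected))
    }
    substr(pas, nchar(pas), nchar(pas)) <- unname(MISMATCH_PARTNER[first])
  }
  pas
}

#' Assemble bEXOmiR hairpin constructs
#'
#' Builds the full pri-miRNA-style construct for each barcode: flanking
#' context, a stem whose mature arm is barcode + EXO motif, the loop, and
#' the passenger arm (exact reverse complement, except for an optional
#' single mismatch at the stem-base pair that aids primary-miRNA
#' processing). The mature sequence is never altered by the mismatch.
#'
#' @param barcode Character vector of barcodes.
#' @param config A [hairpin_config()].
#' @param variant One of `"none"`, `"auto"`, `"AC"`, `"TC"`, `"GA"`, `"CA"`
#'   (recycled across barcodes). `"auto"` picks the variant matching each
#'   barcode's first base; an explicit variant incompatible with the first
#'   base is an error.
#' @return A tibble with columns `barcode`, `variant`, `mature`,
#'   `passenger`, `hairpin`.
#' @examples
#' assemble_hairpin("ACGTCATGCAGTCAT", variant = "auto")
#' @export
assemble_hairpin <- function(barcode, config = hairpin_config(),
                             variant = "none") {
  if (!inherits(config, "hairpin_config")) abort("config must be a hairpin_config()")
  barcode <- assert_dna(barcode, "barcode")
  if (any(nchar(barcode) == 0)) abort("empty barcode")
  variant <- rep(variant, length.out = length(barcode))
  auto <- variant == "auto"
  variant[auto] <- unname(VARIANT_FOR_BASE[substr(barcode[auto], 1, 1)])
  bad <- !variant %in% c("none", "AC", "TC", "GA", "CA")
  if (any(bad)) abort(sprintf("unknown variant '%s'", variant[which(bad)[1]]))
  mature <- assemble_mature(barcode, config$exo_motif)
  pas <- vapply(seq_along(barcode),
                function(i) passenger_strand(mature[i], variant[i]),
                character(1))
  hairpin <- if (config$mature_arm == "5p") {
    paste0(config$context_5p, mature, config$loop_seq, pas, config$context_3p)
  } else {
    paste0(config$context_5p, pas, config$loop_seq, mature, config$context_3p)
  }
  tibble::tibble(barcode = barcode, variant = variant, mature = mature,
                 passenger = pas, hairpin = hairpin)
}

#' Stem-base mismatch variants of bEXOmiR constructs
#'
#' For each barcode, emits hairpin constructs carrying the requested
#' stem-base mismatch (A-C, T-C, G-A or C-A, chosen by the barcode's first
#' base under `"auto"`). Only the passenger strand changes; the mature
#' sequence is identical to the unmismatched construct's.
#'
#' @inheritParams assemble_hairpin
#' @param which `"auto"`, `"none"`, or an explicit variant code.
#' @return A tibble as in [assemble_hairpin()].
#' @export
make_mismatch_variants <- function(barcode, which = "auto",
                                   config = hairpin_config()) {
  assemble_hairpin(barcode, config = config, variant = which)
}

#' Cloning cassette configuration
#'
#' Concrete site sequences and primer flanks used when concatenating an
#' sgRNA with a bEXOmiR hairpin into a synthesis oligo. BlpI's recognition
#' site (GCTNAGC) is degenerate, so a concrete realization is used in the
#' oligo. Per-sublibrary primer flanks default to empty strings.
#'
#' @param site_blpI,site_ecoRI Restriction sites placed between sgRNA and
#'   hairpin (5' to 3': sgRNA, BlpI, EcoRI, hairpin).
#' @param primer_flank_5p,primer_flank_3p Sublibrary-specific PCR flanks.
#' @return A `cassette_config` list.
#' @export
cassette_config <- function(site_blpI = "GCTCAGC", site_ecoRI = "GAATTC",
                            primer_flank_5p = "", primer_flank_3p = "") {
  structure(list(site_blpI = toupper(site_blpI),
                 site_ecoRI = toupper(site_ecoRI),
                 primer_flank_5p = toupper(primer_flank_5p),
                 primer_flank_3p = toupper(primer_flank_3p)),
            class = "cassette_config")
}

#' Build sgRNA-bEXOmiR cloning cassettes
#'
#' Concatenates, 5' to 3': primer flank, sgRNA, BlpI site, EcoRI site,
#' hairpin, primer flank, and validates that no forbidden restriction site
#' occurs outside its designated inter-module position.
#'
#' @param sgrna Character vector of sgRNA protospacer sequences.
#' @param hairpin Character vector of full hairpin sequences (e.g. the
#'   `hairpin` column of [assemble_hairpin()]), recycled against `sgrna`.
#' @param config A [cassette_config()].
#' @param constraints [design_constraints()] supplying the forbidden-site
#'   motifs scanned during validation.
#' @param strict If `TRUE` (default), stray internal sites raise an error
#'   listing their positions; otherwise they are reported in the result.
#' @return A tibble with columns `sgrna_seq`, `hairpin`, `full_oligo`,
#'   `valid`, and list-column `stray_sites` (per-oligo tibble of site name
#'   and 1-based position).
#' @export
build_cassette <- function(sgrna, hairpin, config = cassette_config(),
                           constraints = design_constraints(),
                           strict = TRUE) {
  sgrna <- assert_dna(sgrna, "sgrna")
  if (any(nchar(sgrna) == 0)) abort("sgrna must be nonempty")
  hairpin <- assert_dna(hairpin, "hairpin")
  n <- max(length(sgrna), length(hairpin))
  sgrna <- rep(sgrna, length.out = n)
  hairpin <- rep(hairpin, length.out = n)
  oligo <- paste0(config$primer_flank_5p, sgrna, config$site_blpI,
                  config$site_ecoRI, hairpin, config$primer_flank_3p)
  # designated window: the two inter-module sites between sgRNA and hairpin
  win_start <- nchar(config$primer_flank_5p) + nchar(sgrna) + 1
  win_end <- win_start + nchar(config$site_blpI) + nchar(config$site_ecoRI) - 1
  stray <- purrr::map(seq_len(n), function(i) {
    subj <- Biostrings::DNAString(oligo[i])
    hits <- purrr::imap_dfr(as.list(constraints$forbidden_sites), function(pat, nm) {
      m <- Biostrings::matchPattern(toupper(pat), subj, fixed = FALSE)
      tibble::tibble(site = nm, start = BiocGenerics::start(m),
                     end = BiocGenerics::end(m))
    })
    dplyr::filter(hits, .data$start < win_start[i] | .data$end > win_end[i])
  })
  valid <- purrr::map_int(stray, nrow) == 0
  if (strict && !all(valid)) {
    bad <- which(!valid)[1]
    pos <- paste(sprintf("%s@%d", stray[[bad]]$site, stray[[bad]]$start),
                 collapse = ", ")
    abort(sprintf("stray restriction site(s) in cassette %d: %s", bad, pos))
  }
  tibble::tibble(sgrna_seq = sgrna, hairpin = hairpin, full_oligo = oligo,
                 valid = valid, stray_sites = stray)
}
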