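# The tetraplex primer panel: four mitochondrial mini-barcodes, each primer
# carrying a tandemly repeated 13-bp tail at its 5' end so that the rapid-kit
# transposase has a larger non-informative target to land in.

#' Construct a primer panel
#'
#' One row per barcode (CYTB, COI, 16S, 12S): forward and reverse primers
#' (IUPAC DNA, written 5'->3'), the 13-bp tail unit tandemly repeated at each
#' primer's 5' end, the number of tail repeats, and the expected insert length
#' between the primers.
#'
#' @param barcode character vector of barcode names
#' @param forward_primer,reverse_primer primer sequences, 5'->3'
#' @param tail_unit 13-bp tail unit per barcode
#' @param tail_repeats integer number of tandem repeats (default 2)
#' @param expected_insert_length integer expected insert length per barcode
#' @return a `primer_panel` data frame
#' @export
primer_panel <- function(barcode, forward_primer, reverse_primer, tail_unit,
                         tail_repeats = 2L, expected_insert_length) {
  forward_primer <- normalize_dna(forward_primer, "forward primer")
  reverse_primer <- normalize_dna(reverse_primer, "reverse primer")
  tail_unit <- normalize_dna(tail_unit, "tail unit")
  if (any(nchar(tail_unit) != 13L)) stop("tail units must be exactly 13 bp")
  if (anyDuplicated(barcode)) stop("duplicate barcode in panel")
  panel <- data.frame(barcode = as.character(barcode),
                      forward_primer = forward_primer,
                      reverse_primer = reverse_primer,
                      tail_unit = tail_unit,
                      tail_repeats = as.integer(tail_repeats),
                      expected_insert_length = as.integer(expected_insert_length),
                      stringsAsFactors = FALSE)
  structure(panel, class = c("primer_panel", "data.frame"))
}

#' The default tetraplex panel
#'
#' Tail units and expected insert lengths are the published panel values
#' (CYTB 307 bp, COI 214 bp, 12S 111 bp, 16S 103 bp; 13-bp tails repeated
#' twice, giving 26-nt 5' extensions). The primer sequences shipped here are
#' SYNTHETIC placeholders: the validated panel primers are supplied with the
#' laboratory protocol and should be passed via `forward` / `reverse` (or a
#' panel TSV) for real data.
#'
#' @param forward,reverse optional named character vectors (names CYTB, COI,
#'   16S, 12S) overriding the placeholder primers
#' @return a `primer_panel`
#' @export
default_panel <- function(forward = NULL, reverse = NULL) {
  fwd <- c(CYTB = "CAAGTGACACGATATTTACG", COI = "CCCCATCCCAAAATTTGGAC",
           `16S` = "GGAAGGACTCAAACGGACAG", `12S` = "TCCCACTATATCGCTCCGTG")
  rev <- c(CYTB = "TAAGTAACCCCCTTAGCTTA", COI = "AGGAACCTGAGGTGCACTTT",
           `16S` = "ATGAGCGCCTTAGCCGGGCA", `12S` = "TATATCGAGTCATTCGTTGG")
  if (!is.null(forward)) fwd[names(forward)] <- forward
  if (!is.null(reverse)) rev[names(reverse)] <- reverse
  primer_panel(
    barcode = PANEL_BARCODES,
    forward_primer = unname(fwd[PANEL_BARCODES]),
    reverse_primer = unname(rev[PANEL_BARCODES]),
    tail_unit = c(CYTB = "AGTGTCCTGCTAG", COI = "CTGAGGTGATCAG",
                  `16S` = "AACATGTGGTAAG", `12S` = "TTATTCGCACACT")[PANEL_BARCODES],
    tail_repeats = 2L,
    expected_insert_length = c(CYTB = 307L, COI = 214L,
                               `16S` = 103L, `12S` = 111L)[PANEL_BARCODES])
}

#' Read a primer panel from TSV
#' @param path TSV with columns barcode, forward_primer, reverse_primer,
#'   tail_unit, tail_repeats, expected_insert_length
#' @return a `primer_panel`
#' @export
read_panel <- function(path) {
  p <- read.delim(path, stringsAsFactors = FALSE)
  primer_panel(p$barcode, p$forward_primer, p$reverse_primer, p$tail_unit,
               p$tail_repeats, p$expected_insert_length)
}

# Full 5' tail (unit x repeats) for one panel row.
panel_tail <- function(panel, barcode) {
  i <- match(barcode, panel$barcode)
  if (is.na(i)) stop("unknown barcode: ", barcode)
  strrep(panel$tail_unit[i], panel$tail_repeats[i])
}
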