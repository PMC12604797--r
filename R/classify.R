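# Local-alignment search of consensus sequences against the reference
# database, a BLAST-outfmt-7-compatible hit table, and the sort / dedupe /
# top-hit filtering rules applied to it.

#' Alignment scoring parameters and E-value constants
#'
#' Defaults are BLASTN-like (+2/-3 match/mismatch, affine gaps, lambda =
#' 0.625, K = 0.41). A gap of length L costs `|gap_open| + L * |gap_extend|`.
#' The E-value is a Karlin-Altschul-style surrogate used for ranking only.
#'
#' @param match,mismatch substitution scores (match > 0 > mismatch)
#' @param gap_open,gap_extend gap penalties (negative)
#' @param lambda,K E-value constants (positive)
#' @return a `scoring_params` list
#' @export
scoring_params <- function(match = 2, mismatch = -3, gap_open = -5,
                           gap_extend = -2, lambda = 0.625, K = 0.41) {
  stopifnot(match > 0, mismatch < 0, lambda > 0, K > 0,
            gap_open <= 0, gap_extend <= 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K),
            class = "scoring_params")
}

scoring_submat <- function(scoring) {
  Biostrings::nucleotideSubstitutionMatrix(match = scoring$match,
                                           mismatch = scoring$mismatch,
                                           baseOnly = FALSE)
}

#' Optimal affine-gap local alignment of a query against a subject
#'
#' Percent identity is `100 * matches / alignment columns`; query coverage is
#' `100 * (query bases inside the aligned span) / query length`.
#'
#' @param query,subject DNA strings
#' @param scoring a `scoring_params`
#' @return list: `score`, `pident`, `qcovs`, `q_start`, `q_end`, `s_start`,
#'   `s_end` (1-based inclusive). A score of 0 means no positive-scoring
#'   local alignment exists.
#' @export
local_align <- function(query, subject, scoring = scoring_params()) {
  stopifnot(nzchar(query), nzchar(subject))
  a <- Biostrings::pairwiseAlignment(
    query, subject, type = "local",
    substitutionMatrix = scoring_submat(scoring),
    gapOpening = abs(scoring$gap_open), gapExtension = abs(scoring$gap_extend))
  S <- Biostrings::score(a)
  cols <- Biostrings::nchar(a)
  if (cols == 0L || S <= 0) {
    return(list(score = 0, pident = 0, qcovs = 0,
                q_start = 0L, q_end = 0L, s_start = 0L, s_end = 0L))
  }
  qs <- Biostrings::start(Biostrings::pattern(a))
  qe <- Biostrings::end(Biostrings::pattern(a))
  list(score = S,
       pident = 100 * Biostrings::nmatch(a) / cols,
       qcovs = 100 * (qe - qs + 1L) / nchar(query),
       q_start = qs, q_end = qe,
       s_start = Biostrings::start(Biostrings::subject(a)),
       s_end = Biostrings::end(Biostrings::subject(a)))
}

#' Karlin-Altschul-style E-value surrogate
#'
#' `E = K * m * n * exp(-lambda * S)` for raw score `S`, query length `m` and
#' database length `n`. Used to populate and rank the hit table; not a
#' calibrated BLAST E-value.
#'
#' @param S raw alignment score (>= 0)
#' @param m query length
#' @param n total database length
#' @param scoring a `scoring_params`
#' @return numeric E-value
#' @export
evalue <- function(S, m, n, scoring = scoring_params()) {
  stopifnot(S >= 0)
  evalue_vec(S, m, n, scoring)
}

evalue_vec <- function(S, m, n, scoring) {
  scoring$K * m * n * exp(-scoring$lambda * S)
}

empty_hit_table <- function() {
  data.frame(qseqid = character(), qlen = integer(), evalue = numeric(),
             qcovs = numeric(), pident = numeric(), staxids = integer(),
             stitle = character(), scomnames = character(), score = numeric(),
             saccession = character(), molecule = character(),
             record_class = character(), stringsAsFactors = FALSE)
}

#' Search one consensus sequence against the reference database
#'
#' Aligns the query locally against every record, in both orientations (the
#' better-scoring one is reported, so bottom-strand consensuses are handled),
#' and emits one hit-table row
#' per subject with a positive score, sorted ascending by E-value with ties
#' broken by pident (descending), qcovs (descending), accession (ascending).
#' `scomnames` carries the taxonomy name of the subject taxid.
#'
#' @param query query sequence string
#' @param qseqid query identifier for the table
#' @param db a `reference_db`
#' @param scoring a `scoring_params`
#' @return hit-table data frame (columns qseqid, qlen, evalue, qcovs, pident,
#'   staxids, stitle, scomnames, plus internal score/saccession/molecule/
#'   record_class columns used by the filters)
#' @export
search_db <- function(query, qseqid, db, scoring = scoring_params()) {
  if (!nrow(db$records)) stop("empty reference database")
  m <- nchar(query)
  dblen <- sum(nchar(db$records$sequence))
  # both query orientations are searched (the consensus may be the bottom
  # strand); local alignment is symmetric in pattern/subject, so all records
  # are aligned against the query in one vectorised call per orientation
  subjects <- Biostrings::DNAStringSet(db$records$sequence)
  align_all <- function(q) Biostrings::pairwiseAlignment(
    subjects, q, type = "local",
    substitutionMatrix = scoring_submat(scoring),
    gapOpening = abs(scoring$gap_open), gapExtension = abs(scoring$gap_extend))
  a_plus <- align_all(query)
  a_minus <- align_all(revcomp(query))
  use_minus <- Biostrings::score(a_minus) > Biostrings::score(a_plus)
  pick <- function(f) ifelse(use_minus, f(a_minus), f(a_plus))
  S <- pick(Biostrings::score)
  cols <- pick(function(a) Biostrings::nchar(a))
  nmatches <- pick(Biostrings::nmatch)
  q_start <- pick(function(a) Biostrings::start(Biostrings::subject(a)))
  q_end <- pick(function(a) Biostrings::end(Biostrings::subject(a)))
  keep <- S > 0 & cols > 0L
  rows <- empty_hit_table()
  if (any(keep)) {
    qs <- q_start[keep]
    qe <- q_end[keep]
    tax_i <- match(db$records$taxid[keep], db$taxonomy$taxid)
    rows <- data.frame(
      qseqid = qseqid, qlen = m,
      evalue = evalue_vec(S[keep], m, dblen, scoring),
      qcovs = 100 * (qe - qs + 1L) / m,
      pident = 100 * nmatches[keep] / cols[keep],
      staxids = db$records$taxid[keep],
      stitle = db$records$stitle[keep],
      scomnames = db$taxonomy$name[tax_i],
      score = S[keep],
      saccession = db$records$accession[keep],
      molecule = db$records$molecule[keep],
      record_class = db$records$record_class[keep],
      stringsAsFactors = FALSE)
  }
  if (nrow(rows)) {
    rows <- rows[order(rows$evalue, -rows$pident, -rows$qcovs,
                       rows$saccession), , drop = FALSE]
    rownames(rows) <- NULL
  }
  rows
}

#' Hit filtering parameters
#' @param min_pident minimum percent identity of the top match (default 90)
#' @param require_species_level drop hits whose taxid is not species-ranked
#' @param exclude_ncrna drop hits to `ncRNA_other` records
#' @param mode `single_source` or `mixture` (recorded for reports)
#' @return a `hit_filter_params` list
#' @export
hit_filter_params <- function(min_pident = 90, require_species_level = TRUE,
                              exclude_ncrna = TRUE,
                              mode = c("single_source", "mixture")) {
  stopifnot(min_pident >= 0, min_pident <= 100)
  structure(list(min_pident = min_pident,
                 require_species_level = require_species_level,
                 exclude_ncrna = exclude_ncrna,
                 mode = match.arg(mode)), class = "hit_filter_params")
}

#' Filter a sorted hit table down to the retained top hit(s) per query
#'
#' Per query: the best row per taxid is kept (duplicate taxids removed); rows
#' failing the identity floor, the species-level-label requirement or the
#' non-coding-RNA exclusion are dropped; all rows tied with the best
#' surviving row (equal E-value and pident) are retained.
#'
#' @param hits hit table as produced by [search_db()] (already sorted)
#' @param db a `reference_db` (for taxonomy ranks)
#' @param params a `hit_filter_params`
#' @return retained rows of the hit table
#' @export
filter_hits <- function(hits, db, params = hit_filter_params()) {
  if (!nrow(hits)) return(hits)
  out <- list()
  for (q in unique(hits$qseqid)) {
    h <- hits[hits$qseqid == q, , drop = FALSE]
    h <- h[!duplicated(h$staxids), , drop = FALSE]        # best row per taxid
    h <- h[h$pident >= params$min_pident, , drop = FALSE]
    if (params$require_species_level && nrow(h)) {
      ranks <- db$taxonomy$rank[match(h$staxids, db$taxonomy$taxid)]
      h <- h[!is.na(ranks) & ranks == "species", , drop = FALSE]
    }
    if (params$exclude_ncrna && nrow(h)) {
      h <- h[h$record_class != "ncRNA_other", , drop = FALSE]
    }
    if (!nrow(h)) next
    top <- h$evalue == h$evalue[1] & h$pident == h$pident[1]
    out[[length(out) + 1L]] <- h[top, , drop = FALSE]
  }
  if (!length(out)) return(empty_hit_table())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a hit table in BLAST outfmt-7-compatible TSV
#'
#' Emits comment lines mimicking `-outfmt 7` followed by tab-separated rows
#' with the printed column order
#' `qseqid qlen evalue qcovs pident staxids stitle scomnames`.
#'
#' @param hits hit table data frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_hit_table <- function(hits, path) {
  cols <- c("qseqid", "qlen", "evalue", "qcovs", "pident", "staxids",
            "stitle", "scomnames")
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("# mitopanel local-alignment search",
               paste("# Fields:", paste(cols, collapse = ", ")),
               sprintf("# %d hits found", nrow(hits))), con)
  if (nrow(hits)) {
    body <- hits[, cols]
    body$evalue <- formatC(body$evalue, format = "e", digits = 3)
    body$qcovs <- formatC(body$qcovs, format = "f", digits = 1)
    body$pident <- formatC(body$pident, format = "f", digits = 3)
    write.table(body, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

#' Read an externally produced hit table in the same tabular dialect
#'
#' Accepts tab-separated rows with columns
#' `qseqid qlen evalue qcovs pident staxids stitle scomnames` and `#` comment
#' lines, so a real BLAST run can substitute for the built-in aligner.
#' Internal columns absent from the dialect (molecule, record_class,
#' saccession) are filled by matching staxids/stitle against `db` when given.
#'
#' @param path input TSV path
#' @param db optional `reference_db` used to recover record metadata
#' @return hit table data frame
#' @export
read_hit_table <- function(path, db = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) return(empty_hit_table())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 8L)) stop("hit table rows must have 8 columns")
  pm <- do.call(rbind, parts)
  hits <- data.frame(qseqid = pm[, 1], qlen = as.integer(pm[, 2]),
                     evalue = as.numeric(pm[, 3]), qcovs = as.numeric(pm[, 4]),
                     pident = as.numeric(pm[, 5]), staxids = as.integer(pm[, 6]),
                     stitle = pm[, 7], scomnames = pm[, 8],
                     score = NA_real_, saccession = NA_character_,
                     molecule = NA_character_, record_class = NA_character_,
                     stringsAsFactors = FALSE)
  if (!is.null(db)) {
    i <- match(hits$stitle, db$records$stitle)
    hits$saccession <- db$records$accession[i]
    hits$molecule <- db$records$molecule[i]
    hits$record_class <- db$records$record_class[i]
  }
  hits
}
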