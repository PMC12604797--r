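# Quality/length filtering, sample-index demultiplexing, and distal-end
# primer search assigning each read to a (barcode, strand) with primer and
# tail trimming. Under the rapid-kit read model every informative read starts
# with the sample index and ends (distal end) with the reverse complement of
# one panel primer followed by the reverse-complemented tail.

#' Read filter parameters
#' @param min_quality minimum mean read quality (Phred), default 11
#' @param min_length,max_length inclusive length bounds, defaults 100 and 500
#' @return a `filter_params` list
#' @export
filter_params <- function(min_quality = 11, min_length = 100L,
                          max_length = 500L) {
  stopifnot(min_length <= max_length, min_quality >= 0)
  structure(list(min_quality = min_quality, min_length = as.integer(min_length),
                 max_length = as.integer(max_length)), class = "filter_params")
}

#' Mean read quality on the Phred scale
#'
#' The mean error probability over bases is converted back to Phred:
#' `Q = -10 * log10(mean(10^(-q_i / 10)))`. This is the usual long-read
#' "mean read quality" (arithmetic mean of error probabilities, not of
#' Phred values).
#'
#' @param reads a `nanopore_reads` object
#' @return numeric vector of mean read qualities
#' @export
read_quality <- function(reads) {
  if (any(nchar(reads$sequence) == 0L)) {
    stop("empty read: ", reads$read_id[which(nchar(reads$sequence) == 0L)[1]])
  }
  vapply(reads$quality, function(qs) {
    q <- utf8ToInt(qs) - 33L
    -10 * log10(mean(10^(-q / 10)))
  }, 0, USE.NAMES = FALSE)
}

#' Filter reads on mean quality and length
#'
#' A read passes iff its mean quality is `>= min_quality` and its length lies
#' in `[min_length, max_length]` (bounds inclusive). Rejection reasons are
#' counted with length checked first, so the counts partition the input.
#'
#' @param reads a `nanopore_reads` object
#' @param params a `filter_params`
#' @return list with `reads` (passing subset) and `counts` (named integer
#'   vector: passed, too_short, too_long, low_quality)
#' @export
filter_reads <- function(reads, params = filter_params()) {
  len <- nchar(reads$sequence)
  if (nrow(reads) == 0L) {
    return(list(reads = reads,
                counts = c(passed = 0L, too_short = 0L, too_long = 0L,
                           low_quality = 0L)))
  }
  q <- read_quality(reads)
  too_short <- len < params$min_length
  too_long <- !too_short & len > params$max_length
  low_q <- !too_short & !too_long & q < params$min_quality
  passed <- !too_short & !too_long & !low_q
  list(reads = reads[passed, , drop = FALSE],
       counts = c(passed = sum(passed), too_short = sum(too_short),
                  too_long = sum(too_long), low_quality = sum(low_q)))
}

# Best approximate occurrence of pattern in subject; returns list(dist, start,
# end) in 1-based subject coordinates.
edit_search <- function(pattern, subject) {
  r <- .cpp_edit_search(pattern, subject)
  list(dist = r[1], start = r[2], end = r[3])
}

#' Demultiplex one or more reads by their leading sample index
#'
#' Searches the first `window` bases of each read for the best approximate
#' occurrence of every sheet index (plain edit distance). The best index wins
#' if its distance is `<= max_edit`; a tie between two indices at the best
#' distance leaves the read unassigned. Trimming removes everything through
#' the end of the index match.
#'
#' @param reads a `nanopore_reads` object
#' @param sheet a validated sample sheet
#' @param max_edit maximum edit distance (default 3)
#' @param window leading window searched for the index (default 60 bases)
#' @return data frame with columns `read_id`, `index_id` (NA if unassigned),
#'   `sequence`, `quality` (index-trimmed)
#' @export
demux_index <- function(reads, sheet, max_edit = 3L, window = 60L) {
  sheet <- sample_sheet(sheet)
  n <- nrow(reads)
  index_id <- rep(NA_character_, n)
  seq_out <- reads$sequence
  qual_out <- reads$quality
  for (i in seq_len(n)) {
    win <- substr(reads$sequence[i], 1L, window)
    best <- lapply(sheet$index_sequence, edit_search, subject = win)
    d <- vapply(best, `[[`, 0L, "dist")
    dmin <- min(d)
    if (dmin <= max_edit && sum(d == dmin) == 1L) {
      j <- which.min(d)
      index_id[i] <- sheet$index_id[j]
      cut <- best[[j]]$end
      seq_out[i] <- substring(reads$sequence[i], cut + 1L)
      qual_out[i] <- substring(reads$quality[i], cut + 1L)
    }
  }
  data.frame(read_id = reads$read_id, index_id = index_id,
             sequence = seq_out, quality = qual_out, stringsAsFactors = FALSE)
}

# Per-primer maximum edit distance: ceil(0.25 * primer length).
primer_max_edit <- function(primer) ceiling(0.25 * nchar(primer))

#' Assign index-trimmed reads to a (barcode, strand) by distal primer search
#'
#' The distal (3') window of each read is searched for the reverse complement
#' of each of the panel's eight primers (IUPAC-aware edit distance). A hit to
#' `rc(reverse_primer)` of barcode b implies the read runs along the top
#' strand: (b, forward); a hit to `rc(forward_primer)` implies the bottom
#' strand: (b, reverse). The primer and everything distal of it (the tail)
#' are trimmed. Ties are broken by lowest edit distance, then longest primer,
#' then fixed panel order.
#'
#' @param reads data frame from [demux_index()] (or a `nanopore_reads`)
#' @param panel a `primer_panel`
#' @param max_edit optional fixed maximum edit distance; by default
#'   `ceiling(0.25 * primer length)` per primer
#' @param window_factor distal window size as a multiple of primer + tail
#'   length (default 1.5)
#' @return data frame: `read_id`, `barcode` (NA if unassigned), `strand`,
#'   `primer_edit_distance`, `sequence`, `quality` (distal-trimmed)
#' @export
assign_barcode_strand <- function(reads, panel = default_panel(),
                                  max_edit = NULL, window_factor = 1.5) {
  pats <- list()
  for (i in seq_len(nrow(panel))) {
    tail_len <- nchar(panel$tail_unit[i]) * panel$tail_repeats[i]
    for (dir in c("reverse", "forward")) {
      primer <- if (dir == "reverse") panel$reverse_primer[i] else panel$forward_primer[i]
      pats[[length(pats) + 1L]] <- list(
        barcode = panel$barcode[i],
        # rc(reverse primer) seen => read follows the top strand
        strand = if (dir == "reverse") "forward" else "reverse",
        rc = revcomp(primer),
        plen = nchar(primer),
        max_edit = if (is.null(max_edit)) primer_max_edit(primer) else max_edit,
        window = ceiling(window_factor * (nchar(primer) + tail_len)),
        order = i)
    }
  }
  n <- nrow(reads)
  barcode <- rep(NA_character_, n)
  strand <- rep(NA_character_, n)
  dist_out <- rep(NA_integer_, n)
  seq_out <- reads$sequence
  qual_out <- reads$quality
  for (r in seq_len(n)) {
    s <- reads$sequence[r]
    L <- nchar(s)
    if (L == 0L) next
    hits <- list()
    for (p in pats) {
      w0 <- max(1L, L - p$window + 1L)
      res <- edit_search(p$rc, substring(s, w0))
      if (res$dist <= p$max_edit) {
        hits[[length(hits) + 1L]] <- list(p = p, dist = res$dist,
                                          start = w0 + res$start - 1L)
      }
    }
    if (!length(hits)) next
    d <- vapply(hits, `[[`, 0L, "dist")
    plen <- vapply(hits, function(h) h$p$plen, 0L)
    ord <- vapply(hits, function(h) h$p$order, 0L)
    best <- order(d, -plen, ord)[1]
    h <- hits[[best]]
    barcode[r] <- h$p$barcode
    strand[r] <- h$p$strand
    dist_out[r] <- h$dist
    seq_out[r] <- substr(s, 1L, h$start - 1L)
    qual_out[r] <- substr(reads$quality[r], 1L, h$start - 1L)
  }
  out <- data.frame(read_id = reads$read_id, barcode = barcode,
                    strand = strand, primer_edit_distance = dist_out,
                    sequence = seq_out, quality = qual_out,
                    stringsAsFactors = FALSE)
  if ("index_id" %in% names(reads)) out$index_id <- reads$index_id
  out
}

#' Run the full read-preparation stage
#'
#' Filters reads, demultiplexes by index, and assigns (barcode, strand); the
#' stage counts partition the input: every read ends up in exactly one of
#' filtered-out, unassigned-index, unassigned-barcode, or assigned.
#'
#' @param reads a `nanopore_reads` object
#' @param sheet a validated sample sheet
#' @param panel a `primer_panel`
#' @param params a `filter_params`
#' @param index_max_edit,primer_max_edit edit limits (NULL = per-primer default)
#' @return list with `assigned` (data frame of assigned, trimmed reads with
#'   index_id, barcode, strand) and `counts` (named stage counts)
#' @export
prepare_reads <- function(reads, sheet, panel = default_panel(),
                          params = filter_params(), index_max_edit = 3L,
                          primer_max_edit = NULL) {
  filt <- filter_reads(reads, params)
  dmx <- demux_index(filt$reads, sheet, max_edit = index_max_edit)
  indexed <- dmx[!is.na(dmx$index_id), , drop = FALSE]
  asg <- assign_barcode_strand(indexed, panel, max_edit = primer_max_edit)
  assigned <- asg[!is.na(asg$barcode), , drop = FALSE]
  counts <- c(input = nrow(reads),
              filtered_out = sum(filt$counts[c("too_short", "too_long",
                                               "low_quality")]),
              unassigned_index = sum(is.na(dmx$index_id)),
              unassigned_barcode = sum(is.na(asg$barcode)),
              assigned = nrow(assigned))
  list(assigned = assigned, counts = counts)
}
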