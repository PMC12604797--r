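# Integration of per-barcode, per-strand classifications into the final
# single-source species call or mixture species list: the both-strand rule,
# numt flagging, taxonomic-level escalation via the lowest common ancestor,
# and the mixture presence rules.

#' Merge the two strands' retained hits into one barcode call
#'
#' A barcode identifies only when both its forward and reverse consensus have
#' retained hits. The candidate taxa are the intersection of the two strands'
#' top-tied taxid sets; when the intersection is empty the union is kept and
#' the call marked strand-discordant (the cross-barcode majority then
#' decides). One strand only gives status `one_strand_only`; neither gives
#' `no_consensus`.
#'
#' @param barcode barcode name
#' @param fwd_hits,rev_hits retained hit rows ([filter_hits()] output) of the
#'   strand's top-ranked consensus; `NULL` or zero rows when absent
#' @param support_fwd,support_rev supporting-read counts per strand
#' @return a `barcode_call` list: barcode, status, candidates (integer
#'   taxids), discordant, strands_present, supporting_reads, top_molecule
#'   (molecule of the best row over both strands), top_mito_taxid
#' @export
merge_strands <- function(barcode, fwd_hits = NULL, rev_hits = NULL,
                          support_fwd = 0L, support_rev = 0L) {
  has_f <- !is.null(fwd_hits) && nrow(fwd_hits) > 0L
  has_r <- !is.null(rev_hits) && nrow(rev_hits) > 0L
  strands <- c(if (has_f) "forward", if (has_r) "reverse")
  out <- list(barcode = barcode, status = "no_consensus",
              candidates = integer(), discordant = FALSE,
              strands_present = strands,
              supporting_reads = c(forward = as.integer(support_fwd),
                                   reverse = as.integer(support_rev)),
              top_molecule = NA_character_, top_mito_taxid = NA_integer_)
  if (!has_f && !has_r) return(structure(out, class = "barcode_call"))
  both <- rbind(if (has_f) fwd_hits, if (has_r) rev_hits)
  both <- both[order(both$evalue, -both$pident), , drop = FALSE]
  out$top_molecule <- both$molecule[1]
  mito <- both[!is.na(both$molecule) & both$molecule == "mitochondrial", ,
               drop = FALSE]
  if (nrow(mito)) out$top_mito_taxid <- mito$staxids[1]
  if (xor(has_f, has_r)) {
    out$status <- "one_strand_only"
    return(structure(out, class = "barcode_call"))
  }
  fset <- unique(fwd_hits$staxids)
  rset <- unique(rev_hits$staxids)
  cand <- intersect(fset, rset)
  if (!length(cand)) {
    cand <- union(fset, rset)
    out$discordant <- TRUE
  }
  out$status <- "identifying"
  out$candidates <- sort(cand)
  structure(out, class = "barcode_call")
}

#' Flag numt-derived barcode results
#'
#' A barcode call is flagged as a numt if its top hit is to a nuclear-flagged
#' record, or if its top mitochondrial match disagrees with the majority
#' species across the other identifying barcodes (candidate sets disjoint
#' from the majority species). Ties for the majority species flag nothing
#' (conservative). Flagged barcodes are excluded from the final call.
#'
#' @param calls list of `barcode_call` objects
#' @return the calls, with flagged entries' status set to `"numt"`
#' @export
flag_numts <- function(calls) {
  if (!length(calls)) stop("flag_numts requires at least one barcode call")
  # a nuclear top match marks the barcode result as numt-derived, whether the
  # consensus existed on both strands or one
  idx_hit <- which(vapply(calls, function(x) {
    x$status %in% c("identifying", "one_strand_only") && !is.na(x$top_molecule)
  }, TRUE))
  for (i in idx_hit) {
    if (calls[[i]]$top_molecule == "nuclear") calls[[i]]$status <- "numt"
  }
  # recompute identifying set after nuclear flags; a single majority species
  # is derived over all identifying barcodes, and any identifying barcode
  # whose candidate set is disjoint from it is flagged. A tied majority
  # flags nothing (conservative).
  idx_ident <- which(vapply(calls, function(x) x$status == "identifying", TRUE))
  if (length(idx_ident) >= 2L) {
    votes <- unlist(lapply(calls[idx_ident], `[[`, "candidates"))
    if (length(votes)) {
      tab <- table(votes)
      winners <- as.integer(names(tab)[tab == max(tab)])
      if (length(winners) == 1L) {
        for (i in idx_ident) {
          own <- calls[[i]]$candidates
          own_mito <- calls[[i]]$top_mito_taxid
          disagree <- length(own) > 0L && !(winners %in% own) &&
            (!is.na(own_mito) && own_mito != winners)
          if (disagree) calls[[i]]$status <- "numt"
        }
      }
    }
  }
  calls
}

#' Final single-source species call from a sample's barcode calls
#'
#' Candidate taxa are pooled over identifying (non-numt) barcodes. If exactly
#' one species is a candidate of every identifying barcode (strict consensus;
#' with `rule = "majority"`, of a strict majority of them), the call is at
#' species level. Otherwise the call ascends to the lowest common ancestor of
#' all pooled candidates and reports that ancestor's rank (genus, tribe,
#' family, ...). With no identifying barcode the level is `"none"`.
#'
#' @param calls list of `barcode_call` objects (after [flag_numts()])
#' @param db a `reference_db` (taxonomy)
#' @param rule `"consensus"` (default) or `"majority"`
#' @return a `species_call` list: taxid, name, level, supporting_barcodes,
#'   numt_barcodes, discordant_barcodes
#' @export
call_single_source <- function(calls, db, rule = c("consensus", "majority")) {
  rule <- match.arg(rule)
  tax <- db$taxonomy
  ident <- Filter(function(x) x$status == "identifying", calls)
  numt_bc <- unname(vapply(Filter(function(x) x$status == "numt", calls),
                           `[[`, "", "barcode"))
  disc_bc <- unname(vapply(Filter(function(x) isTRUE(x$discordant), calls),
                           `[[`, "", "barcode"))
  out <- list(taxid = NA_integer_, name = NA_character_, level = "none",
              supporting_barcodes = character(0), numt_barcodes = numt_bc,
              discordant_barcodes = disc_bc)
  if (!length(ident)) return(structure(out, class = "species_call"))
  cand_sets <- lapply(ident, `[[`, "candidates")
  pooled <- sort(unique(unlist(cand_sets)))
  n_need <- if (rule == "consensus") length(ident) else floor(length(ident) / 2) + 1L
  counts <- vapply(pooled, function(t) sum(vapply(cand_sets, function(s) t %in% s, TRUE)), 0L)
  unanimous <- pooled[counts >= n_need]
  out$supporting_barcodes <- unname(vapply(ident, `[[`, "", "barcode"))
  if (length(unanimous) == 1L) {
    out$taxid <- unanimous
    out$name <- tax$name[match(unanimous, tax$taxid)]
    out$level <- tax$rank[match(unanimous, tax$taxid)]
    return(structure(out, class = "species_call"))
  }
  anc <- lca_taxid(tax, pooled)
  out$taxid <- anc
  out$name <- tax$name[match(anc, tax$taxid)]
  out$level <- tax$rank[match(anc, tax$taxid)]
  structure(out, class = "species_call")
}

#' @export
print.species_call <- function(x, ...) {
  cat(sprintf("species_call: %s (%s level), barcodes [%s], numts [%s]\n",
              x$name, x$level, paste(x$supporting_barcodes, collapse = ","),
              paste(x$numt_barcodes, collapse = ",")))
  invisible(x)
}

#' Mixture presence calls from per-consensus species evidence
#'
#' A species is reported present iff at least `min_barcodes` barcodes each
#' have both-strand consensuses whose retained top hits include that species.
#' The report is qualitative: supporting reads are listed for transparency
#' but no proportions are derived.
#'
#' @param evidence data frame with one row per (barcode, strand, taxid) where
#'   a retained consensus' top hits included the species: columns `barcode`,
#'   `strand`, `taxid`, `supporting_reads`
#' @param db a `reference_db` (taxonomy, for names)
#' @param min_barcodes minimum barcodes with both-strand evidence (default 2)
#' @return a `mixture_report` data frame: taxid, name, n_barcodes,
#'   barcodes (comma-joined), total_supporting_reads
#' @export
call_mixture <- function(evidence, db, min_barcodes = 2L) {
  out <- data.frame(taxid = integer(), name = character(),
                    n_barcodes = integer(), barcodes = character(),
                    total_supporting_reads = integer(),
                    stringsAsFactors = FALSE)
  if (!nrow(evidence)) return(structure(out, class = c("mixture_report", "data.frame")))
  for (t in sort(unique(evidence$taxid))) {
    e <- evidence[evidence$taxid == t, , drop = FALSE]
    bc_both <- character()
    for (b in unique(e$barcode)) {
      strands <- unique(e$strand[e$barcode == b])
      if (all(c("forward", "reverse") %in% strands)) bc_both <- c(bc_both, b)
    }
    if (length(bc_both) >= min_barcodes) {
      keep <- e$barcode %in% bc_both
      out <- rbind(out, data.frame(
        taxid = t,
        name = db$taxonomy$name[match(t, db$taxonomy$taxid)],
        n_barcodes = length(bc_both),
        barcodes = paste(sort(bc_both), collapse = ","),
        total_supporting_reads = sum(e$supporting_reads[keep]),
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  structure(out, class = c("mixture_report", "data.frame"))
}

#' Derive the mixture support threshold from a negative control
#'
#' The mixture supporting-read cut-off is set to about three times the
#' highest cluster support observed in the negative control, with a
#' configured floor (default 21, i.e. retain clusters with more than 20
#' supporting reads).
#'
#' @param negative_control_supports integer vector of cluster supporting-read
#'   counts from the processed negative control (may be empty)
#' @param floor configured minimum threshold (default 21)
#' @return integer minimum supporting reads
#' @export
derive_mixture_threshold <- function(negative_control_supports, floor = 21L) {
  if (!length(negative_control_supports) ||
      max(negative_control_supports) <= 0L) {
    if (!length(negative_control_supports)) {
      warning("no negative control supplied; using the configured floor")
    }
    return(as.integer(floor))
  }
  max(as.integer(floor), 3L * max(as.integer(negative_control_supports)))
}
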