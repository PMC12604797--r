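# Within-bin clustering, abundance/support filtering and strand-wise
# consensus building. A bin is one (index_id, barcode, strand) combination;
# under the tagmentation read model all reads in a bin share their distal
# (3') terminus and are ragged at the proximal end, so alignments are
# effectively anchored at the distal end.

# Canonical read order: length descending, then sequence, then read id.
# Applied before clustering so results are invariant to input order.
canonical_order <- function(seqs, ids) {
  order(-nchar(seqs), seqs, ids)
}

# Identity of `read` against (longer) `rep`: global on the read, local on the
# representative; identity = matches / alignment columns.
read_rep_identity <- function(read, rep) {
  .cpp_rep_identity(read, rep)
}

#' Greedy star clustering of one bin's reads
#'
#' Reads are sorted canonically (length descending) and each read joins the
#' first existing cluster whose representative it matches at
#' `>= identity_threshold` (alignment identity with the read aligned globally
#' against the representative); otherwise it founds a new cluster. The
#' representative of a cluster is its founding (longest) read.
#'
#' @param reads data frame with `read_id` and `sequence` (same bin)
#' @param identity_threshold minimum identity to join a cluster (default 0.80)
#' @return list of clusters, each a list with `representative` (read id),
#'   `rep_sequence`, `members` (read ids)
#' @export
cluster_reads <- function(reads, identity_threshold = 0.80) {
  if (nrow(reads) == 0L) return(list())
  ord <- canonical_order(reads$sequence, reads$read_id)
  seqs <- reads$sequence[ord]
  ids <- reads$read_id[ord]
  reps <- character()
  rep_ids <- character()
  members <- list()
  for (i in seq_along(seqs)) {
    k <- NA_integer_
    # reads are never longer than earlier-founded representatives
    # (length-descending order), so the read-global alignment identity is
    # well defined against every representative
    for (r in seq_along(reps)) {
      if (.cpp_rep_identity(seqs[i], reps[r]) >= identity_threshold) {
        k <- r
        break
      }
    }
    if (!is.na(k)) {
      members[[k]] <- c(members[[k]], ids[i])
    } else {
      reps <- c(reps, seqs[i])
      rep_ids <- c(rep_ids, ids[i])
      members[[length(members) + 1L]] <- ids[i]
    }
  }
  lapply(seq_along(reps), function(k) {
    list(representative = rep_ids[k], rep_sequence = reps[k],
         members = members[[k]])
  })
}

#' Apply the cluster abundance and read-support filters
#'
#' A cluster is retained iff its size is at least `abundance_ratio` times the
#' bin total AND at least `min_supporting_reads`. The single-source run uses
#' a 100-read floor (consensus discarded below 100 supporting reads); the
#' mixture run retains clusters with more than 20 supporting reads, i.e. a
#' floor of 21.
#'
#' @param clusters list from [cluster_reads()]
#' @param bin_total total reads in the bin (abundance denominator)
#' @param abundance_ratio cluster abundance ratio (default 0.001, i.e. 0.1%)
#' @param min_supporting_reads support floor (100 single-source, 21 mixture)
#' @return retained clusters, ranked by size (descending; ties by canonical
#'   representative order), each with `cluster_rank` set
#' @export
apply_abundance_filter <- function(clusters, bin_total,
                                   abundance_ratio = 0.001,
                                   min_supporting_reads = 100L) {
  if (!length(clusters)) return(list())
  sizes <- vapply(clusters, function(cl) length(cl$members), 0L)
  keep <- sizes >= abundance_ratio * bin_total & sizes >= min_supporting_reads
  retained <- clusters[keep]
  sizes <- sizes[keep]
  if (!length(retained)) return(list())
  reps <- vapply(retained, `[[`, "", "rep_sequence")
  ord <- order(-sizes, reps)
  retained <- retained[ord]
  for (k in seq_along(retained)) retained[[k]]$cluster_rank <- k
  retained
}

#' Build a consensus sequence from one cluster
#'
#' Members are aligned to the representative (anchored by the shared distal
#' end), and the consensus is the per-column majority base in representative
#' coordinates; majority deletions remove a column and majority insertions at
#' a junction add the most common inserted string. Ties resolve to the
#' representative's base. Proximal columns with coverage below
#' `max(3, 30% of members)` are trimmed (the ragged breakpoint side). At most
#' `max_members` longest members are used.
#'
#' @param cluster one cluster from [cluster_reads()]
#' @param reads the bin's read data frame (`read_id`, `sequence`)
#' @param max_members cap on members used for the consensus (default 500)
#' @return list: `sequence`, `supporting_reads`, `representative`
#' @export
build_consensus <- function(cluster, reads, max_members = 500L) {
  ids <- cluster$members
  seqs <- reads$sequence[match(ids, reads$read_id)]
  stopifnot(!anyNA(seqs))
  ord <- canonical_order(seqs, ids)
  use <- head(ord, max_members)
  seqs_u <- seqs[use]
  rep_seq <- cluster$rep_sequence
  L <- nchar(rep_seq)
  n_use <- length(seqs_u)
  bases <- c("A", "C", "G", "T", "N", "-")
  vote_idx_all <- list()   # (pos - 1) * 6 + base index, accumulated later
  cov_all <- list()
  ins_votes <- vector("list", L + 1L)  # insertions before rep position j
  exact <- seqs_u == rep_seq
  if (any(exact)) {
    bi <- match(strsplit(rep_seq, "")[[1]], bases)
    idx <- (seq_len(L) - 1L) * 6L + bi
    vote_idx_all[[1L]] <- rep(idx, sum(exact))
    cov_all[[1L]] <- rep(seq_len(L), sum(exact))
  }
  for (s in seqs_u[!exact]) {
    al <- .cpp_align_to_rep(s, rep_seq)
    if (al$epos < al$spos) next
    pos <- al$spos:al$epos
    bi <- match(strsplit(al$aligned, "")[[1]], bases)
    ok <- !is.na(bi)
    vote_idx_all[[length(vote_idx_all) + 1L]] <- (pos[ok] - 1L) * 6L + bi[ok]
    cov_all[[length(cov_all) + 1L]] <- pos
    if (length(al$ins_pos)) {
      for (q in seq_along(al$ins_pos)) {
        j <- al$ins_pos[q]
        ins_votes[[j]] <- c(ins_votes[[j]], al$ins_str[q])
      }
    }
  }
  votes <- matrix(tabulate(unlist(vote_idx_all), nbins = 6L * L),
                  nrow = 6L, dimnames = list(bases, NULL))
  covered <- tabulate(unlist(cov_all), nbins = L)
  min_cov <- max(3L, ceiling(0.3 * n_use))
  first <- which(covered >= min_cov)
  if (!length(first)) {
    start_pos <- 1L
  } else {
    start_pos <- first[1]
  }
  rep_ch <- strsplit(rep_seq, "")[[1]]
  out <- character()
  for (j in start_pos:L) {
    if (j > start_pos && length(ins_votes[[j]]) > covered[j] / 2) {
      tab <- sort(table(ins_votes[[j]]), decreasing = TRUE)
      out <- c(out, names(tab)[1])
    }
    v <- votes[, j]
    if (sum(v) == 0L) next
    vmax <- max(v)
    winners <- bases[v == vmax]
    pick <- if (rep_ch[j] %in% winners) rep_ch[j] else winners[1]
    if (pick != "-") out <- c(out, pick)
  }
  list(sequence = paste(out, collapse = ""),
       supporting_reads = length(ids),
       representative = cluster$representative)
}

#' Cluster, filter and build consensuses for all bins of a prepared read set
#'
#' @param assigned assigned read data frame from [prepare_reads()]
#'   (columns index_id, barcode, strand, sequence, read_id)
#' @param abundance_ratio cluster abundance ratio
#' @param min_supporting_reads support floor (mode-dependent)
#' @param identity_threshold clustering identity threshold
#' @param max_members consensus member cap
#' @return data frame of consensus sequences: index_id, barcode, strand,
#'   cluster_rank, supporting_reads, sequence
#' @export
bin_consensus <- function(assigned, abundance_ratio = 0.001,
                          min_supporting_reads = 100L,
                          identity_threshold = 0.80, max_members = 500L) {
  out <- list()
  if (nrow(assigned)) {
    key <- paste(assigned$index_id, assigned$barcode, assigned$strand, sep = "\r")
    for (k in sort(unique(key))) {
      bin <- assigned[key == k, , drop = FALSE]
      clusters <- cluster_reads(bin, identity_threshold)
      retained <- apply_abundance_filter(clusters, nrow(bin), abundance_ratio,
                                         min_supporting_reads)
      for (cl in retained) {
        cons <- build_consensus(cl, bin, max_members)
        out[[length(out) + 1L]] <- data.frame(
          index_id = bin$index_id[1], barcode = bin$barcode[1],
          strand = bin$strand[1], cluster_rank = cl$cluster_rank,
          supporting_reads = cons$supporting_reads,
          sequence = cons$sequence, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(index_id = character(), barcode = character(),
                      strand = character(), cluster_rank = integer(),
                      supporting_reads = integer(), sequence = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write consensus sequences as FASTA
#'
#' Headers carry `index_id|barcode|strand|supporting_reads` (rank appended
#' when a bin retains several clusters).
#'
#' @param consensuses data frame from [bin_consensus()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_consensus_fasta <- function(consensuses, path) {
  hdr <- sprintf("%s|%s|%s|%d rank=%d", consensuses$index_id,
                 consensuses$barcode, consensuses$strand,
                 consensuses$supporting_reads, consensuses$cluster_rank)
  writeLines(paste0(">", hdr, "\n", consensuses$sequence), path)
  invisible(path)
}
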