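# Panel-validation computations: Kimura two-parameter distances,
# neighbour-joining trees with column-resampling bootstrap supports, and
# per-barcode plus combined species-resolvability scoring.

#' Kimura two-parameter distance between two aligned sequences
#'
#' With P the proportion of transitions (A<->G, C<->T) and Q the proportion
#' of transversions over compared sites,
#' `d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))`. Sites where either base is
#' not A/C/G/T are skipped for that pair (pairwise deletion).
#'
#' @param a,b equal-length aligned DNA strings
#' @return the K2P distance
#' @export
k2p_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences must be aligned (equal length)")
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  ok <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  n <- sum(ok)
  if (n == 0L) stop("no comparable sites between the two sequences")
  ca <- ca[ok]; cb <- cb[ok]
  diff <- ca != cb
  purine <- c("A", "G")
  transition <- diff & ((ca %in% purine) == (cb %in% purine))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    stop(sprintf("K2P distance saturated (P=%.3f, Q=%.3f)", P, Q))
  }
  -0.5 * log(w1 * sqrt(w2))
}

#' K2P distance matrix for a set of aligned sequences
#' @param seqs named character vector of equal-length aligned sequences
#' @return a symmetric `matrix` of distances with the sequence names
#' @export
k2p_matrix <- function(seqs) {
  n <- length(seqs)
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%03d", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- k2p_distance(seqs[i], seqs[j])
    }
  }
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via ape). Branch lengths are kept as estimated;
#' negative lengths are clamped to zero only when the tree is written out.
#'
#' @param d symmetric distance matrix with labelled taxa (>= 3)
#' @return an unrooted `phylo` tree
#' @export
nj_tree <- function(d) {
  if (nrow(d) < 3L) stop("neighbour joining requires at least 3 taxa")
  ape::nj(as.dist(d))
}

#' Write a tree as Newick, clamping negative branch lengths to zero
#' @param tree a `phylo` tree (optionally with `node.label` supports)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_tree_newick <- function(tree, path) {
  tree$edge.length <- pmax(tree$edge.length, 0)
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Bootstrap supports for the NJ tree of an alignment
#'
#' Alignment columns are resampled with replacement `n_replicates` times; an
#' NJ tree is rebuilt from the K2P matrix of each replicate and the support
#' of each internal bipartition of the original tree is the fraction of
#' successful replicates containing it. Replicates in which any pairwise
#' distance saturates are skipped (with a warning) and excluded from the
#' denominator.
#'
#' @param seqs named character vector of equal-length aligned sequences
#' @param n_replicates number of bootstrap replicates (default 100)
#' @param seed integer seed
#' @return list: `tree` (original NJ tree with `node.label` set to supports),
#'   `supports` (numeric vector between 0 and 1 per internal node),
#'   `n_effective` (replicates used), `n_skipped`
#' @export
bootstrap_supports <- function(seqs, n_replicates = 100L, seed = 1L) {
  L <- nchar(seqs[1])
  stopifnot(L >= 1L, all(nchar(seqs) == L))
  tree <- nj_tree(k2p_matrix(seqs))
  mat <- do.call(rbind, strsplit(seqs, ""))
  rownames(mat) <- names(seqs)
  set.seed(seed)
  boot_trees <- list()
  skipped <- 0L
  for (r in seq_len(n_replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    rs <- apply(mat[, cols, drop = FALSE], 1, paste, collapse = "")
    bt <- tryCatch(nj_tree(k2p_matrix(rs)), error = function(e) NULL)
    if (is.null(bt)) skipped <- skipped + 1L else {
      boot_trees[[length(boot_trees) + 1L]] <- bt
    }
  }
  if (skipped > 0L) {
    warning(sprintf("%d bootstrap replicate(s) skipped due to distance saturation",
                    skipped))
  }
  n_eff <- length(boot_trees)
  counts <- ape::prop.clades(tree, boot_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  supports <- counts / max(n_eff, 1L)
  tree$node.label <- formatC(supports, format = "f", digits = 2)
  list(tree = tree, supports = supports, n_effective = n_eff,
       n_skipped = skipped)
}

# All bipartitions (as tip-label sets, the side not containing tip 1) of an
# unrooted tree, internal edges only.
tree_bipartitions <- function(tree) {
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  lapply(parts, function(p) labs[p])
}

# Is the tip set an edge-separable (exclusive) group of the unrooted tree?
is_exclusive_clade <- function(tree, tips) {
  all_tips <- tree$tip.label
  tips <- sort(tips)
  if (length(tips) <= 1L) return(TRUE)           # trivial (single leaf)
  if (length(tips) == length(all_tips)) return(TRUE)
  if (length(tips) == length(all_tips) - 1L) return(TRUE)  # complement is a leaf
  for (side in tree_bipartitions(tree)) {
    if (setequal(side, tips) || setequal(setdiff(all_tips, side), tips)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Assess the species-discrimination power of a barcode panel
#'
#' For each barcode alignment, builds a K2P/NJ tree and scores every species:
#' `resolved` iff its sequences form an exclusive group separable by a single
#' edge of the unrooted tree with no other species inside and no foreign
#' sequence is identical to one of its members; `incorrect` iff some sequence
#' lies strictly closer (K2P) to a foreign sequence than to every conspecific
#' (possible only when a conspecific exists); `unresolved` otherwise (e.g.
#' species sharing an identical barcode sequence).
#' Species represented by a single sequence cannot fail the nearest-neighbour
#' test and are flagged (`single_sequence`). The combined rule: a species is
#' resolved overall iff at least one barcode resolves it and no barcode
#' places it incorrectly. Species absent from a barcode are data-deficient
#' there, not unresolved.
#'
#' @param alignments named list (one element per barcode) of named character
#'   vectors: equal-length aligned sequences whose names are
#'   `<species>|<seqid>` (text before the first `|` is the species label)
#' @param n_bootstrap bootstrap replicates per barcode (0 to skip)
#' @param seed seed for the bootstrap
#' @return a `discrimination_report`: list with `per_barcode` (data frame
#'   species x barcode status), `combined` (data frame with the overall
#'   status per species), `trees` (NJ trees per barcode), `summary`
#'   (resolved fraction under the combined rule)
#' @export
assess_discrimination <- function(alignments, n_bootstrap = 0L, seed = 1L) {
  stopifnot(length(alignments) >= 1L, !is.null(names(alignments)))
  all_species <- sort(unique(unlist(lapply(alignments, function(al) {
    sub("\\|.*$", "", names(al))
  }))))
  per_bc <- list()
  trees <- list()
  for (b in names(alignments)) {
    al <- alignments[[b]]
    if (is.null(names(al)) || !all(nzchar(names(al)))) {
      stop("alignment sequences must be named '<species>|<seqid>'")
    }
    species <- sub("\\|.*$", "", names(al))
    d <- k2p_matrix(setNames(al, names(al)))
    status <- setNames(rep("data_deficient", length(all_species)), all_species)
    flag_single <- setNames(rep(FALSE, length(all_species)), all_species)
    if (length(al) >= 3L) {
      tree <- nj_tree(d)
      if (n_bootstrap > 0L) {
        bs <- bootstrap_supports(al, n_bootstrap, seed)
        tree <- bs$tree
      }
      trees[[b]] <- tree
    } else {
      trees[[b]] <- NULL
    }
    diag(d) <- Inf
    for (sp in unique(species)) {
      idx <- which(species == sp)
      others <- which(species != sp)
      # nearest-neighbour rule: a member sitting strictly closer to a foreign
      # sequence than to every conspecific is an incorrect placement
      incorrect <- FALSE
      if (length(idx) > 1L && length(others)) {
        for (i in idx) {
          if (min(d[i, others]) < min(d[i, setdiff(idx, i)])) {
            incorrect <- TRUE
            break
          }
        }
      }
      if (length(idx) == 1L) flag_single[sp] <- TRUE
      # a foreign sequence identical to a member makes the species
      # indistinguishable at this barcode regardless of tree shape
      min_foreign <- if (length(others)) min(d[idx, others]) else Inf
      if (incorrect) {
        status[sp] <- "incorrect"
      } else if (min_foreign > 0 &&
                 (length(al) < 3L ||
                  is_exclusive_clade(trees[[b]], names(al)[idx]))) {
        status[sp] <- "resolved"
      } else {
        status[sp] <- "unresolved"
      }
    }
    per_bc[[b]] <- data.frame(species = all_species, barcode = b,
                              status = unname(status[all_species]),
                              single_sequence = unname(flag_single[all_species]),
                              stringsAsFactors = FALSE)
  }
  per_barcode <- do.call(rbind, per_bc)
  rownames(per_barcode) <- NULL
  combined <- data.frame(species = all_species, status = NA_character_,
                         stringsAsFactors = FALSE)
  for (i in seq_along(all_species)) {
    st <- per_barcode$status[per_barcode$species == all_species[i]]
    st <- st[st != "data_deficient"]
    combined$status[i] <- if (!length(st)) "data_deficient"
      else if (any(st == "incorrect")) "incorrect"
      else if (any(st == "resolved")) "resolved"
      else "unresolved"
  }
  assessed <- combined$status != "data_deficient"
  structure(list(per_barcode = per_barcode, combined = combined,
                 trees = trees,
                 summary = c(n_species = sum(assessed),
                             n_resolved = sum(combined$status == "resolved"),
                             resolved_fraction =
                               sum(combined$status == "resolved") /
                               max(1L, sum(assessed)))),
            class = "discrimination_report")
}

#' @export
print.discrimination_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("discrimination_report: %d/%d species resolved (%.1f%%) under the combined rule\n",
              s[["n_resolved"]], s[["n_species"]],
              100 * s[["resolved_fraction"]]))
  invisible(x)
}

#' Read per-barcode alignment FASTAs for discrimination assessment
#'
#' Each file `<barcode>.fasta` in `dir` holds equal-length aligned sequences
#' with headers `<species>|<seqid>`; sequences flagged as nuclear/numt
#' (header containing `|nuclear`) are excluded.
#'
#' @param dir directory of per-barcode alignment FASTAs
#' @return named list of named character vectors
#' @export
read_barcode_alignments <- function(dir) {
  files <- list.files(dir, pattern = "\\.(fa|fasta)$", full.names = TRUE)
  if (!length(files)) stop("no alignment FASTAs found in ", dir)
  out <- list()
  for (f in files) {
    ss <- Biostrings::readDNAStringSet(f)
    seqs <- setNames(as.character(ss), names(ss))
    seqs <- seqs[!grepl("\\|nuclear", names(seqs))]
    out[[sub("\\.(fa|fasta)$", "", basename(f))]] <- seqs
  }
  out
}
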