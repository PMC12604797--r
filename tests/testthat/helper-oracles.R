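# Independent brute-force oracles used to validate the fast implementations.
# These share no code with the package paths they check.

# Quadratic Gotoh local aligner: gap of length k costs open + k * extend.
# Returns the optimal raw score and (matches, columns) of one optimal
# traceback (diag > up > left preference).
oracle_local_align <- function(a, b, match = 2, mismatch = -3, open = 5,
                               extend = 2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)   # best ending in a match/mismatch (or empty)
  X <- matrix(NEG, n + 1, m + 1) # gap in b (consume a)
  Y <- matrix(NEG, n + 1, m + 1) # gap in a (consume b)
  best <- 0; bi <- 0; bj <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      s <- if (av[i] == bv[j]) match else mismatch
      M[i + 1, j + 1] <- max(0, M[i, j] + s, X[i, j] + s, Y[i, j] + s)
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - extend,
                             X[i, j + 1] - extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                             Y[i + 1, j] - extend)
      sc <- max(M[i + 1, j + 1], X[i + 1, j + 1], Y[i + 1, j + 1])
      if (sc > best) { best <- sc; bi <- i; bj <- j }
    }
  }
  best
}

iupac_sets <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

# Brute-force semi-global IUPAC edit-distance search (pattern fully aligned,
# free subject ends): plain R dynamic program.
oracle_edit_search <- function(pattern, subject) {
  p <- strsplit(pattern, "")[[1]]; s <- strsplit(subject, "")[[1]]
  m <- length(p); n <- length(s)
  prev <- rep(0L, n + 1)
  for (i in 1:m) {
    cur <- integer(n + 1)
    cur[1] <- i
    for (j in seq_len(n)) {
      cost <- if (s[j] %in% iupac_sets[[p[i]]]) 0L else 1L
      cur[j + 1] <- min(prev[j] + cost, prev[j + 1] + 1L, cur[j] + 1L)
    }
    prev <- cur
  }
  min(prev)
}

# All unrooted topologies on the given labels (recursive leaf insertion on an
# edge list); trees returned as ape::phylo without branch lengths.
oracle_all_topologies <- function(labels) {
  n <- length(labels)
  stopifnot(n >= 3)
  base <- ape::read.tree(text = sprintf("(%s,%s,%s);", labels[1], labels[2],
                                        labels[3]))
  trees <- list(base)
  for (k in 4:n) {
    if (k > n) break
    new_trees <- list()
    for (tr in trees) {
      for (e in seq_len(nrow(tr$edge))) {
        t2 <- suppressWarnings(
          ape::bind.tree(tr,
                         ape::read.tree(text = sprintf("(%s:1);", labels[k])),
                         where = tr$edge[e, 2], position = 0.5))
        t2$edge.length <- NULL
        new_trees[[length(new_trees) + 1L]] <- t2
      }
    }
    # deduplicate by unrooted bipartition signature
    sig <- vapply(new_trees, function(t) {
      parts <- ape::prop.part(t)
      labs <- attr(parts, "labels")
      paste(sort(vapply(parts, function(pp) {
        side <- sort(labs[pp])
        other <- sort(setdiff(labs, side))
        if (paste(side, collapse = ",") < paste(other, collapse = ","))
          paste(side, collapse = ",") else paste(other, collapse = ",")
      }, "")), collapse = ";")
    }, "")
    trees <- new_trees[!duplicated(sig)]
  }
  trees
}

# Least-squares fit of edge lengths to a distance matrix for a fixed
# topology; returns the residual sum of squares.
oracle_ls_rss <- function(topology, d) {
  labs <- topology$tip.label
  nt <- length(labs)
  tr <- ape::unroot(topology)
  tr$edge.length <- rep(1, nrow(tr$edge))
  # tips below each edge (child side)
  below <- lapply(seq_len(nrow(tr$edge)), function(e) {
    node <- tr$edge[e, 2]
    if (node <= nt) return(tr$tip.label[node])
    ape::extract.clade(tr, node)$tip.label
  })
  pairs <- t(combn(nt, 2))
  X <- matrix(0, nrow(pairs), nrow(tr$edge))
  y <- numeric(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    a <- labs[pairs[r, 1]]; b <- labs[pairs[r, 2]]
    X[r, ] <- vapply(below, function(tips) xor(a %in% tips, b %in% tips), TRUE)
    y[r] <- d[a, b]
  }
  fit <- lm.fit(X, y)
  sum(fit$residuals^2)
}

# Brute-force best topology by least squares.
oracle_best_topology <- function(d) {
  labs <- rownames(d)
  tops <- oracle_all_topologies(labs)
  rss <- vapply(tops, oracle_ls_rss, 0, d = d)
  tops[[which.min(rss)]]
}

same_topology <- function(t1, t2) {
  suppressWarnings(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0)
}
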