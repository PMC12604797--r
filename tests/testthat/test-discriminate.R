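# Build an equal-length pair with exact transition/transversion fractions.
pq_pair <- function(P, Q, L = 1000L) {
  nP <- round(P * L); nQ <- round(Q * L)
  a <- strrep("A", L)
  b <- paste0(strrep("G", nP), strrep("C", nQ), strrep("A", L - nP - nQ))
  list(a = a, b = b, P = nP / L, Q = nQ / L)
}

test_that("K2P distance matches the closed form and handles its domain", {
  expect_equal(k2p_distance("ACGTACGT", "ACGTACGT"), 0)
  # P = 0.1, Q = 0.05 -> -1/2 ln(0.75 * sqrt(0.9)) ~ 0.17023
  pq <- pq_pair(0.1, 0.05, 1000L)
  expect_equal(k2p_distance(pq$a, pq$b), -0.5 * log(0.75 * sqrt(0.9)),
               tolerance = 1e-12)
  expect_equal(k2p_distance(pq$a, pq$b), 0.17018, tolerance = 1e-4)
  # saturation: P = 0.5, Q = 0 makes the log argument zero
  sat <- pq_pair(0.5, 0, 100L)
  expect_error(k2p_distance(sat$a, sat$b), "saturated")
  # ambiguous sites are skipped pairwise
  expect_equal(k2p_distance("ACGTN", "ACGTA"), 0)
  expect_error(k2p_distance("NNNN", "ACGT"), "comparable")
  expect_error(k2p_distance("ACG", "ACGT"), "equal length")
})

test_that("K2P is symmetric and zero on the diagonal", {
  set.seed(57)
  for (i in 1:30) {
    a <- rand_dna(60)
    v <- strsplit(a, "")[[1]]
    p <- sample(60, 6)
    v[p] <- vapply(v[p], function(x) sample(setdiff(c("A","C","G","T"), x), 1), "")
    b <- paste(v, collapse = "")
    expect_identical(k2p_distance(a, b), k2p_distance(b, a))
    expect_equal(k2p_distance(a, a), 0)
  }
})

test_that("K2P estimates low Jukes-Cantor divergence without bias", {
  set.seed(59)
  d_true <- 0.02
  L <- 1000L
  ests <- replicate(200, {
    a <- rand_dna(L)
    v <- strsplit(a, "")[[1]]
    hit <- runif(L) < d_true
    v[hit] <- vapply(v[hit], function(x) sample(setdiff(c("A","C","G","T"), x), 1), "")
    k2p_distance(a, paste(v, collapse = ""))
  })
  se <- sd(ests) / sqrt(200)
  expect_lt(abs(mean(ests) - d_true), 3 * se + 2 * d_true^2)
})

test_that("NJ reproduces the three-taxon closed form", {
  d <- matrix(c(0, 0.2, 0.3,
                0.2, 0, 0.4,
                0.3, 0.4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["A"]], 0.05, tolerance = 1e-12)
  expect_equal(bl[["B"]], 0.15, tolerance = 1e-12)
  expect_equal(bl[["C"]], 0.25, tolerance = 1e-12)
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
  # all-zero matrix: star tree with zero branch lengths
  z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  tz <- nj_tree(z)
  expect_true(all(abs(tz$edge.length) < 1e-12))
})

test_that("NJ recovers the generating split of an additive 4-taxon matrix", {
  gen <- ape::read.tree(text = "((A:0.1,B:0.1):0.1,(C:0.1,D:0.1):0.0);")
  d <- cophenetic(gen)
  d <- d[LETTERS[1:4], LETTERS[1:4]]
  tr <- nj_tree(d)
  expect_true(same_topology(tr, gen))
  expect_equal(sort(cophenetic(tr)[lower.tri(d)]),
               sort(d[lower.tri(d)]), tolerance = 1e-12)
  # and matches the brute-force least-squares oracle
  expect_true(same_topology(tr, oracle_best_topology(d)))
})

test_that("clearly separated clusters get full bootstrap support deterministically", {
  # two clusters 14 transitions apart (well inside the K2P domain), members
  # within a cluster one substitution apart
  seqs <- c(`spA|1` = strrep("A", 60), `spA|2` = strrep("A", 60),
            `spB|1` = paste0(strrep("G", 14), strrep("A", 46)),
            `spB|2` = paste0(strrep("G", 14), strrep("A", 46)))
  substr(seqs[2], 60, 60) <- "G"
  substr(seqs[4], 59, 59) <- "T"
  bs1 <- bootstrap_supports(seqs, n_replicates = 50, seed = 3)
  expect_true(all(bs1$supports >= 0 & bs1$supports <= 1))
  internal <- bs1$supports[length(bs1$supports)]
  expect_equal(unname(max(bs1$supports)), 1)
  bs2 <- bootstrap_supports(seqs, n_replicates = 50, seed = 3)
  expect_identical(bs1$supports, bs2$supports)
})

test_that("discrimination assessment matches a brute-force nearest-neighbour oracle", {
  set.seed(61)
  n_sp <- 20
  anc <- rand_dna(150)
  mut <- function(s, d) {
    v <- strsplit(s, "")[[1]]
    hit <- runif(length(v)) < d
    v[hit] <- vapply(v[hit], function(x) sample(setdiff(c("A","C","G","T"), x), 1), "")
    paste(v, collapse = "")
  }
  seqs <- c()
  for (i in seq_len(n_sp)) {
    base <- mut(anc, 0.12)
    for (k in 1:2) {
      seqs[sprintf("sp%02d|%d", i, k)] <- mut(base, 0.004)
    }
  }
  rep <- assess_discrimination(list(COI = seqs))
  # oracle: species incorrect iff any member lies strictly closer to a
  # foreign sequence than to every conspecific (exhaustive pairwise check)
  d <- k2p_matrix(seqs)
  diag(d) <- Inf
  sp <- sub("\\|.*", "", rownames(d))
  oracle_incorrect <- vapply(unique(sp), function(s) {
    any(vapply(which(sp == s), function(i) {
      min(d[i, sp != s]) < min(d[i, sp == s & seq_along(sp) != i])
    }, TRUE))
  }, TRUE)
  got <- rep$per_barcode
  for (s in unique(sp)) {
    if (oracle_incorrect[[s]]) {
      expect_equal(got$status[got$species == s], "incorrect")
    } else {
      expect_true(got$status[got$species == s] %in% c("resolved", "unresolved"))
    }
  }
})

test_that("a barcode shared between species is rescued by the combined rule", {
  set.seed(63)
  anc12 <- rand_dna(100)
  ancCOI <- rand_dna(120)
  x <- mutate_fixture(anc12, 0.10)
  y <- mutate_fixture(anc12, 0.10)
  distinct_a <- mutate_fixture(ancCOI, 0.10)
  distinct_b <- mutate_fixture(ancCOI, 0.10)
  distinct_c <- mutate_fixture(ancCOI, 0.10)
  mut1 <- function(s) { substr(s, 1, 1) <- "T"; s }
  alignments <- list(
    # two species sharing one identical 12S haplotype (plus an outgroup)
    `12S` = c(`spA|1` = x, `spA|2` = x, `spB|1` = x, `spB|2` = x,
              `spC|1` = y, `spC|2` = mut1(y)),
    # distinct at COI
    COI = c(`spA|1` = distinct_a, `spA|2` = mut1(distinct_a),
            `spB|1` = distinct_b, `spB|2` = mut1(distinct_b),
            `spC|1` = distinct_c, `spC|2` = mut1(distinct_c)))
  rep <- assess_discrimination(alignments)
  s12 <- rep$per_barcode[rep$per_barcode$barcode == "12S", ]
  expect_true(all(s12$status[s12$species %in% c("spA", "spB")] == "unresolved"))
  expect_equal(rep$combined$status[rep$combined$species == "spA"], "resolved")
  expect_equal(rep$combined$status[rep$combined$species == "spB"], "resolved")
  # fully distinct species resolve at every barcode
  expect_equal(rep$combined$status[rep$combined$species == "spC"], "resolved")
})

test_that("NJ recovers 5-leaf additive topologies against the brute-force oracle", {
  set.seed(65)
  tops <- oracle_all_topologies(LETTERS[1:5])
  expect_length(tops, 15)
  for (i in 1:20) {
    gen <- tops[[sample(15, 1)]]
    gen$edge.length <- runif(nrow(gen$edge), 0.05, 0.3)
    d <- cophenetic(gen)[LETTERS[1:5], LETTERS[1:5]]
    tr <- nj_tree(d)
    expect_true(same_topology(tr, gen))
    expect_true(same_topology(tr, oracle_best_topology(d)))
  }
})
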