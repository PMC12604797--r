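toy_db <- function() reference_db(toy_records("A1", 100L, "ACGTACGT"),
                                  toy_taxonomy())

test_that("strand merging applies the both-direction rule", {
  f <- hit_row(staxids = 100L)
  r <- hit_row(staxids = 100L)
  bc <- merge_strands("COI", f, r, 120L, 110L)
  expect_equal(bc$status, "identifying")
  expect_equal(bc$candidates, 100L)
  expect_false(bc$discordant)

  one <- merge_strands("COI", f, NULL, 120L, 0L)
  expect_equal(one$status, "one_strand_only")
  expect_length(one$candidates, 0)

  none <- merge_strands("COI", NULL, NULL)
  expect_equal(none$status, "no_consensus")

  # tied forward candidates narrowed by the reverse strand
  f2 <- rbind(hit_row(staxids = 100L), hit_row(staxids = 101L))
  bc2 <- merge_strands("COI", f2, r, 50L, 60L)
  expect_equal(bc2$candidates, 100L)

  # disjoint strand top sets: union kept, discordance flagged
  r3 <- hit_row(staxids = 102L)
  bc3 <- merge_strands("COI", f, r3, 50L, 60L)
  expect_equal(bc3$status, "identifying")
  expect_true(bc3$discordant)
  expect_setequal(bc3$candidates, c(100L, 102L))
})

test_that("numt flagging catches nuclear top hits and cross-barcode disagreement", {
  mito_call <- function(b, taxid) merge_strands(
    b, hit_row(staxids = taxid), hit_row(staxids = taxid), 100L, 100L)

  # nuclear top match flags the barcode; the call proceeds from the others
  f_nuc <- hit_row(staxids = 100L, molecule = "nuclear", evalue = 1e-40)
  calls <- list(CYTB = mito_call("CYTB", 100L),
                COI = merge_strands("COI", f_nuc,
                                    hit_row(staxids = 100L,
                                            molecule = "nuclear"), 90L, 80L),
                `16S` = mito_call("16S", 100L),
                `12S` = mito_call("12S", 100L))
  flagged <- flag_numts(calls)
  expect_equal(flagged$COI$status, "numt")
  final <- call_single_source(flagged, toy_db())
  expect_equal(final$taxid, 100L)
  expect_equal(final$level, "species")
  expect_equal(final$numt_barcodes, "COI")

  # one mitochondrial barcode disagreeing with the other three is flagged
  calls2 <- list(CYTB = mito_call("CYTB", 100L), COI = mito_call("COI", 100L),
                 `16S` = mito_call("16S", 100L),
                 `12S` = mito_call("12S", 102L))
  flagged2 <- flag_numts(calls2)
  expect_equal(flagged2$`12S`$status, "numt")
  expect_equal(call_single_source(flagged2, toy_db())$taxid, 100L)

  # full agreement flags nothing
  calls3 <- lapply(c("CYTB", "COI", "16S", "12S"), mito_call, taxid = 101L)
  expect_true(all(vapply(flag_numts(calls3), `[[`, "", "status") ==
                    "identifying"))

  # a 2 vs 2 tie is conservative: nothing flagged
  calls4 <- list(CYTB = mito_call("CYTB", 100L), COI = mito_call("COI", 100L),
                 `16S` = mito_call("16S", 102L), `12S` = mito_call("12S", 102L))
  expect_true(all(vapply(flag_numts(calls4), `[[`, "", "status") ==
                    "identifying"))
  expect_error(flag_numts(list()), "at least one")
})

test_that("the final call escalates to the lowest common ancestor when needed", {
  db <- toy_db()
  mk <- function(b, taxids) {
    h <- do.call(rbind, lapply(taxids, function(t) hit_row(staxids = t)))
    merge_strands(b, h, h, 100L, 100L)
  }
  # unanimous single species
  calls <- lapply(c("CYTB", "COI", "16S", "12S"), mk, taxids = 100L)
  out <- call_single_source(calls, db)
  expect_equal(out$level, "species")
  expect_equal(out$taxid, 100L)

  # two congeners tied everywhere -> genus-level call (LCA of 100, 101)
  calls <- lapply(c("CYTB", "COI", "16S", "12S"), mk, taxids = c(100L, 101L))
  out <- call_single_source(calls, db)
  expect_equal(out$level, "genus")
  expect_equal(out$name, "GenA")

  # candidates spanning two genera within one tribe -> tribe-level call
  calls <- lapply(c("CYTB", "COI"), mk, taxids = c(100L, 102L))
  out <- call_single_source(calls, db)
  expect_equal(out$level, "tribe")
  expect_equal(out$name, "TribeA")

  # no identifying barcode -> none
  out <- call_single_source(list(merge_strands("COI", NULL, NULL)), db)
  expect_equal(out$level, "none")
})

test_that("removing one barcode's evidence never changes a species call to another species", {
  db <- toy_db()
  set.seed(53)
  species <- c(100L, 101L, 102L, 103L)
  mk <- function(b, taxids) {
    h <- do.call(rbind, lapply(taxids, function(t) hit_row(staxids = t)))
    merge_strands(b, h, h, 100L, 100L)
  }
  for (rep in 1:40) {
    bcs <- c("CYTB", "COI", "16S", "12S")
    calls <- lapply(bcs, function(b) {
      mk(b, sample(species, sample(1:2, 1)))
    })
    names(calls) <- bcs
    full <- call_single_source(calls, db)
    for (drop in bcs) {
      reduced <- call_single_source(calls[setdiff(bcs, drop)], db)
      if (full$level == "species" && reduced$level == "species") {
        expect_equal(reduced$taxid, full$taxid)
      }
    }
  }
})

test_that("mixture presence needs two both-strand barcodes", {
  db <- toy_db()
  ev <- data.frame(
    barcode = c("16S", "16S", "12S", "12S", "COI", "COI", "CYTB"),
    strand = c("forward", "reverse", "forward", "reverse",
               "forward", "reverse", "forward"),
    taxid = c(100L, 100L, 100L, 100L, 101L, 101L, 102L),
    supporting_reads = c(40L, 35L, 30L, 25L, 50L, 45L, 22L),
    stringsAsFactors = FALSE)
  rep <- call_mixture(ev, db)
  # species 100: both strands on 16S and 12S -> present
  expect_true(100L %in% rep$taxid)
  # species 101: both strands but only one barcode -> absent
  expect_false(101L %in% rep$taxid)
  # species 102: one strand, one barcode -> absent
  expect_false(102L %in% rep$taxid)
  expect_equal(rep$total_supporting_reads[rep$taxid == 100L], 130L)
})

test_that("a species with evidence in a single barcode is never reported", {
  db <- toy_db()
  set.seed(55)
  for (rep in 1:60) {
    n <- sample(1:10, 1)
    ev <- data.frame(
      barcode = sample(c("CYTB", "COI", "16S", "12S"), n, TRUE),
      strand = sample(c("forward", "reverse"), n, TRUE),
      taxid = sample(c(100L, 101L, 102L), n, TRUE),
      supporting_reads = sample(21:80, n, TRUE),
      stringsAsFactors = FALSE)
    out <- call_mixture(ev, db)
    for (t in unique(ev$taxid)) {
      both <- unique(ev$barcode[ev$taxid == t][
        vapply(ev$barcode[ev$taxid == t], function(b) {
          all(c("forward", "reverse") %in% ev$strand[ev$taxid == t & ev$barcode == b])
        }, TRUE)])
      if (length(both) < 2) expect_false(t %in% out$taxid)
      else expect_true(t %in% out$taxid)
    }
  }
})

test_that("the mixture threshold derives from the negative control", {
  expect_equal(derive_mixture_threshold(c(3L, 7L, 2L)), 21L)
  expect_equal(derive_mixture_threshold(c(3L, 12L)), 36L)
  expect_warning(out <- derive_mixture_threshold(integer(0)), "negative control")
  expect_equal(out, 21L)
  expect_equal(derive_mixture_threshold(c(0L, 0L)), 21L)
})
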