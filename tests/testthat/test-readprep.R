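test_that("mean read quality follows the mean-error-probability formula", {
  r <- const_q_read("r", strrep("A", 50), 20L)
  expect_equal(read_quality(r), 20)
  r2 <- nanopore_reads("r2", "AC", phred_string(c(10L, 30L)))
  # mean error = (0.1 + 0.001) / 2 = 0.0505 -> -10 log10 = 12.9666...
  expect_equal(read_quality(r2), -10 * log10(0.0505), tolerance = 1e-12)
  # appending a high-quality base never lowers the mean quality
  r3 <- nanopore_reads("r3", "ACG", phred_string(c(10L, 30L, 93L)))
  expect_gte(read_quality(r3), read_quality(r2))
  expect_error(read_quality(nanopore_reads("e", "", "")), "empty read")
})

test_that("the length/quality filter applies inclusive published bounds", {
  reads <- rbind(const_q_read("len99", strrep("A", 99), 30L),
                 const_q_read("q11_len250", strrep("A", 250), 11L),
                 const_q_read("q10_len500", strrep("A", 500), 10L),
                 const_q_read("len501", strrep("A", 501), 30L),
                 const_q_read("ok", strrep("A", 100), 12L))
  class(reads) <- c("nanopore_reads", "data.frame")
  out <- filter_reads(reads, filter_params())
  expect_setequal(out$reads$read_id, c("q11_len250", "ok"))
  expect_equal(unname(out$counts),
               c(2L, 1L, 1L, 1L)[match(names(out$counts),
                                       c("passed", "too_short", "too_long",
                                         "low_quality"))])
  expect_equal(sum(out$counts), nrow(reads))
})

test_that("index demultiplexing assigns exact and noisy indices, ties unassign", {
  sheet <- test_sheet()
  payload <- strrep("ACGT", 40)
  exact <- nanopore_reads("e", paste0(test_indices[["BC01"]], payload),
                          phred_string(rep(20, 24 + 160)))
  out <- demux_index(exact, sheet)
  expect_equal(out$index_id, "BC01")
  expect_equal(out$sequence, payload)  # trimmed through the index

  noisy_idx <- test_indices[["BC02"]]
  substr(noisy_idx, 3, 3) <- "A"; substr(noisy_idx, 10, 10) <- "C"
  expect_equal(sum(strsplit(noisy_idx, "")[[1]] !=
                     strsplit(test_indices[["BC02"]], "")[[1]]), 2)
  noisy <- nanopore_reads("n", paste0(noisy_idx, payload),
                          phred_string(rep(20, 24 + 160)))
  expect_equal(demux_index(noisy, sheet, max_edit = 3)$index_id, "BC02")

  # equidistant tie -> unassigned
  tie_sheet <- sample_sheet(data.frame(
    index_id = c("L", "R"), index_sequence = c("AAAAAAAA", "AAAAAATT"),
    sample_name = c("a", "b"), mode = "single_source"))
  tie <- nanopore_reads("t", paste0("AAAAAAAT", payload),
                        phred_string(rep(20, 168)))
  expect_true(is.na(demux_index(tie, tie_sheet, max_edit = 3)$index_id))
})

test_that("barcode assignment needs the primer at the distal end", {
  panel <- default_panel()
  i <- match("COI", panel$barcode)
  rcR <- revcomp(panel$reverse_primer[i])
  rcT <- revcomp(panel_tail(panel, "COI"))
  body <- strrep("A", 150)
  distal <- nanopore_reads("d", paste0(body, rcR, rcT),
                           phred_string(rep(20, 150 + nchar(rcR) + nchar(rcT))))
  out <- assign_barcode_strand(distal, panel)
  expect_equal(out$barcode, "COI")
  expect_equal(out$strand, "forward")
  expect_equal(out$primer_edit_distance, 0L)
  expect_equal(out$sequence, body)  # primer and tail trimmed

  # same primer at the proximal end only -> unassigned
  proximal <- nanopore_reads("p", paste0(rcR, rcT, body),
                             phred_string(rep(20, 150 + nchar(rcR) + nchar(rcT))))
  expect_true(is.na(assign_barcode_strand(proximal, panel)$barcode))

  # rc(forward primer) at the distal end -> reverse strand
  rcF <- revcomp(panel$forward_primer[i])
  revread <- nanopore_reads("r", paste0(body, rcF, rcT),
                            phred_string(rep(20, 150 + nchar(rcF) + nchar(rcT))))
  out_r <- assign_barcode_strand(revread, panel)
  expect_equal(out_r$barcode, "COI")
  expect_equal(out_r$strand, "reverse")

  # two substitutions in the primer still assign with max_edit = 3
  noisy <- rcR
  substr(noisy, 4, 4) <- "A"; substr(noisy, 12, 12) <- "A"
  stopifnot(sum(strsplit(noisy, "")[[1]] != strsplit(rcR, "")[[1]]) == 2)
  nread <- nanopore_reads("n", paste0(body, noisy, rcT),
                          phred_string(rep(20, 150 + nchar(noisy) + nchar(rcT))))
  out_n <- assign_barcode_strand(nread, panel, max_edit = 3)
  expect_equal(out_n$barcode, "COI")
  expect_equal(out_n$strand, "forward")
})

test_that("the approximate matcher agrees with the brute-force IUPAC oracle", {
  set.seed(21)
  codes <- c("A", "C", "G", "T", "R", "Y", "N")
  for (i in 1:300) {
    pat <- paste(sample(codes, sample(3:12, 1), TRUE,
                        prob = c(rep(0.22, 4), 0.04, 0.04, 0.04)), collapse = "")
    subj <- rand_dna(sample(5:20, 1))
    fast <- mitopanel:::edit_search(pat, subj)
    expect_equal(fast$dist, oracle_edit_search(pat, subj),
                 info = paste(pat, subj))
  }
  # degenerate base matches its code set at zero cost
  expect_equal(mitopanel:::edit_search("RRRR", "AGAG")$dist, 0L)
  expect_equal(mitopanel:::edit_search("RRRR", "CTCT")$dist, 4L)
})

test_that("read preparation partitions every input read exactly once", {
  cfg <- simulation_config(n_species = 2, reads_per_sample = 300, seed = 23)
  run <- simulate_run(test_sheet(n = 2), cfg)
  prep <- prepare_reads(run$reads, test_sheet(n = 2), run$panel)
  cts <- prep$counts
  expect_equal(cts[["input"]],
               cts[["filtered_out"]] + cts[["unassigned_index"]] +
                 cts[["unassigned_barcode"]] + cts[["assigned"]])
})

test_that("zero-noise simulated reads are assigned to their true bin", {
  cfg <- simulation_config(n_species = 2, reads_per_sample = 400,
                           sub_rate = 0, ins_rate = 0, del_rate = 0,
                           mean_quality = 20, quality_sd = 0, seed = 29)
  sheet <- test_sheet(n = 2)
  run <- simulate_run(sheet, cfg)
  prep <- prepare_reads(run$reads, sheet, run$panel)
  asg <- prep$assigned
  tr <- run$truth[match(asg$read_id, run$truth$read_id), ]
  # every assigned read matches its true index, barcode and strand
  expect_equal(asg$index_id, tr$index_id)
  expect_equal(asg$barcode, tr$barcode)
  expect_equal(asg$strand, tr$strand)

  # every filter-passing read whose fragment retains the full distal
  # primer + tail is assigned
  panel <- run$panel
  tru <- run$truth
  lens <- nchar(run$reads$sequence)
  amp_len <- vapply(seq_len(nrow(tru)), function(i) {
    ins <- run$refset$truth$inserts[[as.character(tru$taxid[i])]][[tru$barcode[i]]]
    nchar(make_amplicon(ins, tru$barcode[i], panel))
  }, 0)
  pi <- match(tru$barcode, panel$barcode)
  distal_need <- ifelse(tru$strand == "forward",
                        nchar(panel$reverse_primer[pi]) + 26L,
                        nchar(panel$forward_primer[pi]) + 26L)
  frag_len <- ifelse(tru$strand == "forward",
                     amp_len - tru$breakpoint, tru$breakpoint)
  intact <- frag_len >= distal_need + 1L
  passes <- lens >= 100 & lens <= 500
  expect_true(all(run$reads$read_id[intact & passes] %in% asg$read_id))
})
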