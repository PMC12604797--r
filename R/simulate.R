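# Synthetic-data generator: reference databases with a known divergence
# structure, tetraplex amplicons, tagmented indexed reads with nanopore-style
# noise, and per-read ground truth. Every downstream stage is testable against
# these outputs without any external download.

#' Configuration for the synthetic-data generator
#'
#' Divergences are expected substitutions per site applied i.i.d. from a
#' common random ancestor (species level) or from the species sequence
#' (within-species copies, numts). Error rates are per-base probabilities.
#'
#' @param n_species number of species in the reference set
#' @param sequences_per_species reference copies per species and barcode
#' @param within_species_divergence divergence of extra within-species copies
#' @param between_species_divergence divergence of each species from the
#'   common ancestor (pairwise species divergence is roughly twice this)
#' @param numt_rate probability that a species carries a nuclear copy of one
#'   barcode locus
#' @param numt_divergence divergence of a numt from its mitochondrial locus
#' @param numt_read_fraction fraction of a numt-carrying species' reads for
#'   the affected barcode that are amplified from the nuclear copy
#' @param sub_rate,ins_rate,del_rate per-base read error probabilities
#' @param mean_quality,quality_sd per-base Phred quality model (Normal,
#'   clipped to the range 2 to 40)
#' @param reads_per_sample reads emitted per sample
#' @param n_ncrna_decoys number of mitochondrial ncRNA decoy records added to
#'   the reference set (for exercising the ncRNA exclusion rule)
#' @param seed integer seed fixing all generator output
#' @return a `simulation_config` list
#' @export
simulation_config <- function(n_species = 5L,
                              sequences_per_species = 1L,
                              within_species_divergence = 0.005,
                              between_species_divergence = 0.15,
                              numt_rate = 0,
                              numt_divergence = 0.08,
                              numt_read_fraction = 0.35,
                              sub_rate = 0.04,
                              ins_rate = 0.02,
                              del_rate = 0.02,
                              mean_quality = 14,
                              quality_sd = 3,
                              reads_per_sample = 2000L,
                              n_ncrna_decoys = 0L,
                              seed = 1L) {
  cfg <- list(n_species = as.integer(n_species),
              sequences_per_species = as.integer(sequences_per_species),
              within_species_divergence = within_species_divergence,
              between_species_divergence = between_species_divergence,
              numt_rate = numt_rate, numt_divergence = numt_divergence,
              numt_read_fraction = numt_read_fraction,
              sub_rate = sub_rate, ins_rate = ins_rate, del_rate = del_rate,
              mean_quality = mean_quality, quality_sd = quality_sd,
              reads_per_sample = as.integer(reads_per_sample),
              n_ncrna_decoys = as.integer(n_ncrna_decoys),
              seed = as.integer(seed))
  if (cfg$n_species < 1L) stop("n_species must be >= 1")
  rates <- c(cfg$numt_rate, cfg$sub_rate, cfg$ins_rate, cfg$del_rate,
             cfg$numt_read_fraction)
  if (any(rates < 0 | rates >= 1 + 1e-12) || cfg$numt_read_fraction > 1) {
    stop("rates must lie in [0, 1)")
  }
  if (cfg$sequences_per_species > 1L &&
      cfg$within_species_divergence >= cfg$between_species_divergence) {
    stop("within_species_divergence must be < between_species_divergence")
  }
  structure(cfg, class = "simulation_config")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# i.i.d. substitution of each site with probability d (to a different base).
mutate_seq <- function(seq, d) {
  if (d <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- runif(length(ch)) < d
  if (any(hit)) {
    ch[hit] <- vapply(ch[hit],
                      function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                      "", USE.NAMES = FALSE)
  }
  paste(ch, collapse = "")
}

#' Generate a synthetic reference set with known structure
#'
#' Each species receives one `barcode_locus` record per panel barcode, all
#' derived from a shared random ancestor so that barcode inserts are natively
#' aligned (no indel divergence). With probability `numt_rate` a species also
#' carries a nuclear-flagged divergent copy of one randomly chosen barcode.
#' Species are grouped two per genus under a single family/order/class chain.
#'
#' @param config a `simulation_config`
#' @param panel a `primer_panel`
#' @return list with `db` (a `reference_db`) and `truth` (species table, numt
#'   table, and the clean insert sequences per taxid and barcode)
#' @export
generate_reference_set <- function(config, panel = default_panel()) {
  set.seed(config$seed)
  n <- config$n_species
  taxids <- 1000L + seq_len(n)
  genus_of <- (seq_len(n) - 1L) %/% 2L + 1L
  species <- data.frame(
    taxid = taxids,
    name = sprintf("Simulosaurus sp%03d", seq_len(n)),
    genus_taxid = 200L + genus_of,
    stringsAsFactors = FALSE)
  genera <- data.frame(taxid = unique(species$genus_taxid))
  genera$name <- sprintf("Genus%02d", genera$taxid - 200L)
  taxonomy <- rbind(
    data.frame(taxid = 1L, parent_taxid = 1L, rank = "higher", name = "root"),
    data.frame(taxid = 2L, parent_taxid = 1L, rank = "class", name = "SimClass"),
    data.frame(taxid = 3L, parent_taxid = 2L, rank = "order", name = "SimOrder"),
    data.frame(taxid = 100L, parent_taxid = 3L, rank = "family", name = "Simulidae"),
    data.frame(taxid = genera$taxid, parent_taxid = 100L, rank = "genus",
               name = genera$name),
    data.frame(taxid = species$taxid, parent_taxid = species$genus_taxid,
               rank = "species", name = species$name))

  ancestors <- setNames(
    vapply(panel$expected_insert_length, random_dna, ""),
    panel$barcode)

  inserts <- list()   # inserts[[as.character(taxid)]][[barcode]]
  rec <- list()
  add_rec <- function(accession, taxid, molecule, record_class, gene_label,
                      stitle, sequence) {
    rec[[length(rec) + 1L]] <<- data.frame(
      accession = accession, taxid = taxid, molecule = molecule,
      record_class = record_class, gene_label = gene_label, stitle = stitle,
      sequence = sequence, stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    tid <- taxids[i]
    inserts[[as.character(tid)]] <- list()
    for (b in panel$barcode) {
      ins <- mutate_seq(ancestors[[b]], config$between_species_divergence)
      inserts[[as.character(tid)]][[b]] <- ins
      add_rec(sprintf("SIM%03d_%s", i, b), tid, "mitochondrial",
              "barcode_locus", b,
              sprintf("%s %s mini-barcode", species$name[i], b), ins)
      if (config$sequences_per_species > 1L) {
        for (k in 2:config$sequences_per_species) {
          add_rec(sprintf("SIM%03d_%s_c%d", i, b, k), tid, "mitochondrial",
                  "barcode_locus", b,
                  sprintf("%s %s mini-barcode copy %d", species$name[i], b, k),
                  mutate_seq(ins, config$within_species_divergence))
        }
      }
    }
  }
  numts <- data.frame(taxid = integer(), barcode = character(),
                      accession = character(), sequence = character(),
                      stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (runif(1) < config$numt_rate) {
      tid <- taxids[i]
      b <- sample(panel$barcode, 1L)
      nseq <- mutate_seq(inserts[[as.character(tid)]][[b]],
                         config$numt_divergence)
      acc <- sprintf("NUMT%03d_%s", i, b)
      add_rec(acc, tid, "nuclear", "other", b,
              sprintf("%s %s nuclear pseudogene", species$name[i], b), nseq)
      numts <- rbind(numts, data.frame(taxid = tid, barcode = b,
                                       accession = acc, sequence = nseq,
                                       stringsAsFactors = FALSE))
    }
  }
  if (config$n_ncrna_decoys > 0L) {
    for (k in seq_len(config$n_ncrna_decoys)) {
      i <- sample(n, 1L)
      b <- sample(panel$barcode, 1L)
      add_rec(sprintf("NCRNA%03d", k), taxids[i], "mitochondrial",
              "ncRNA_other", "misc_ncRNA",
              sprintf("%s predicted non-coding RNA", species$name[i]),
              mutate_seq(inserts[[as.character(taxids[i])]][[b]], 0.01))
    }
  }
  db <- reference_db(do.call(rbind, rec), taxonomy)
  list(db = db,
       truth = list(species = species, numts = numts, inserts = inserts,
                    ancestors = ancestors))
}

#' Assemble the double-stranded amplicon (top strand) for one barcode
#'
#' Top strand layout: `tail x repeats + forward_primer + insert +
#' rc(reverse_primer) + rc(tail x repeats)`, i.e. each primer contributes a
#' 26-nt 5' extension with the default twice-repeated 13-bp tails.
#'
#' @param insert insert sequence (between-primer region)
#' @param barcode barcode name present in `panel`
#' @param panel a `primer_panel`
#' @return amplicon top-strand string
#' @export
make_amplicon <- function(insert, barcode, panel = default_panel()) {
  if (!nzchar(insert)) stop("insert length must be > 0")
  i <- match(barcode, panel$barcode)
  if (is.na(i)) stop("unknown barcode: ", barcode)
  tail <- panel_tail(panel, barcode)
  paste0(tail, panel$forward_primer[i], insert,
         revcomp(panel$reverse_primer[i]), revcomp(tail))
}

#' Tagment an amplicon and emit the two read templates
#'
#' Models the rapid-kit transposase: one double-strand break at a uniformly
#' random internal position, with the sample index attached to each of the
#' two newly created internal 5' ends. The right fragment is read along the
#' top strand towards the amplicon 3' end (distal end carries
#' `rc(reverse_primer) + rc(tail)`); the left fragment is read along the
#' bottom strand towards the amplicon 5' end (distal end carries
#' `rc(forward_primer) + rc(tail)`).
#'
#' @param amplicon amplicon top-strand string
#' @param index_sequence sample index sequence prepended to each read
#' @param breakpoint optional fixed break position `b` (break between bases
#'   `b` and `b+1`, `1 <= b <= nchar(amplicon) - 1`); drawn uniformly if NULL
#' @return list with `right` and `left` template strings (index included),
#'   their strands (`forward`, `reverse`) and the `breakpoint`
#' @export
tagment_and_read <- function(amplicon, index_sequence, breakpoint = NULL) {
  L <- nchar(amplicon)
  if (L < 2L) stop("amplicon shorter than 2 bases cannot be tagmented")
  b <- if (is.null(breakpoint)) sample.int(L - 1L, 1L) else as.integer(breakpoint)
  stopifnot(b >= 1L, b <= L - 1L)
  list(right = paste0(index_sequence, substr(amplicon, b + 1L, L)),
       left = paste0(index_sequence, revcomp(substr(amplicon, 1L, b))),
       right_strand = "forward", left_strand = "reverse",
       breakpoint = b)
}

#' Apply nanopore-style noise to a read template
#'
#' Substitutions, insertions and deletions are applied i.i.d. per base at the
#' configured rates; per-base qualities are drawn from a Normal clipped to
#' the range 2 to 40. Qualities describe the nominal basecaller confidence and are not
#' coupled to the realised errors.
#'
#' @param template template sequence string
#' @param config a `simulation_config` (uses sub/ins/del rates and the
#'   quality model)
#' @param read_id read identifier for the output read
#' @return a one-row `nanopore_reads` object
#' @export
corrupt <- function(template, config, read_id = "read") {
  ch <- strsplit(template, "")[[1]]
  n <- length(ch)
  bases <- c("A", "C", "G", "T")
  keep <- runif(n) >= config$del_rate
  sub <- keep & (runif(n) < config$sub_rate)
  ins <- runif(n) < config$ins_rate
  if (any(sub)) {
    # shift each substituted base by 1..3 in the base alphabet (never itself);
    # N substitutes to a uniform random base
    cur <- match(ch[sub], bases)
    shift <- sample.int(3L, sum(sub), replace = TRUE)
    new <- bases[((ifelse(is.na(cur), sample.int(4L, sum(sub), TRUE), cur) - 1L
                   + shift) %% 4L) + 1L]
    ch[sub] <- new
  }
  emit <- ifelse(keep, ch, "")
  if (any(ins)) {
    emit[ins] <- paste0(emit[ins], sample(bases, sum(ins), replace = TRUE))
  }
  seq <- paste(emit, collapse = "")
  m <- nchar(seq)
  q <- pmin(40L, pmax(2L, as.integer(round(rnorm(m, config$mean_quality,
                                                 config$quality_sd)))))
  nanopore_reads(read_id, seq, phred_string(q))
}

#' Simulate a full sequencing run
#'
#' For every sample-sheet entry, amplicon molecules are drawn (species by the
#' sample's proportions, barcode uniformly over the panel), tagmented with
#' the sample's index, and both fragment reads are emitted with noise. When a
#' species carries a numt on a barcode, a fraction `numt_read_fraction` of
#' that (species, barcode)'s molecules amplify from the nuclear copy.
#'
#' @param sheet a validated sample sheet (see [sample_sheet()])
#' @param config a `simulation_config`
#' @param panel a `primer_panel`
#' @param refset optional result of [generate_reference_set()]; generated
#'   from `config` when NULL
#' @param proportions optional named list: `proportions[[sample_name]]` is a
#'   named numeric vector over species taxids summing to 1. By default
#'   single-source samples cycle through the species and mixtures contain all
#'   species in equal proportions.
#' @param out_dir optional directory; when given, writes `reads.fastq`,
#'   `truth.tsv`, `reference.fasta`, `taxonomy.tsv`
#' @return list with `reads` (a `nanopore_reads`), `truth` (per-read data
#'   frame), `refset`, `panel`, `expected_species` (list per sample)
#' @export
simulate_run <- function(sheet, config, panel = default_panel(),
                         refset = NULL, proportions = NULL, out_dir = NULL) {
  sheet <- sample_sheet(sheet)
  if (is.null(refset)) refset <- generate_reference_set(config, panel)
  set.seed(config$seed + 104729L)  # run stream distinct from reference stream
  taxids <- refset$truth$species$taxid
  if (is.null(proportions)) {
    proportions <- list()
    k <- 0L
    for (s in seq_len(nrow(sheet))) {
      nm <- sheet$sample_name[s]
      if (sheet$mode[s] == "single_source") {
        k <- k + 1L
        tid <- taxids[(k - 1L) %% length(taxids) + 1L]
        proportions[[nm]] <- setNames(1, tid)
      } else {
        proportions[[nm]] <- setNames(rep(1 / length(taxids), length(taxids)),
                                      taxids)
      }
    }
  }
  for (nm in sheet$sample_name) {
    p <- proportions[[nm]]
    if (is.null(p)) stop("no proportions given for sample ", nm)
    if (abs(sum(p) - 1) > 1e-8) stop("proportions for sample ", nm,
                                     " do not sum to 1")
  }
  numts <- refset$truth$numts
  reads_list <- list()
  truth_list <- list()
  for (s in seq_len(nrow(sheet))) {
    nm <- sheet$sample_name[s]
    idx <- sheet$index_sequence[s]
    p <- proportions[[nm]]
    rps <- config$reads_per_sample
    n_mol <- ceiling(rps / 2)
    for (mol in seq_len(n_mol)) {
      tid <- as.integer(sample(names(p), 1L, prob = p))
      b <- sample(panel$barcode, 1L)
      template_src <- "mito"
      ins <- refset$truth$inserts[[as.character(tid)]][[b]]
      hit <- which(numts$taxid == tid & numts$barcode == b)
      if (length(hit) && runif(1) < config$numt_read_fraction) {
        ins <- numts$sequence[hit[1]]
        template_src <- "numt"
      }
      amp <- make_amplicon(ins, b, panel)
      frag <- tagment_and_read(amp, idx)
      for (side in c("right", "left")) {
        if (side == "left" && 2L * mol > rps) next  # odd read budget
        rid <- sprintf("%s_m%05d_%s", nm, mol, side)
        rd <- corrupt(frag[[side]], config, rid)
        reads_list[[length(reads_list) + 1L]] <- rd
        truth_list[[length(truth_list) + 1L]] <- data.frame(
          read_id = rid, sample_name = nm, index_id = sheet$index_id[s],
          taxid = tid, barcode = b,
          strand = if (side == "right") "forward" else "reverse",
          breakpoint = frag$breakpoint, template = template_src,
          stringsAsFactors = FALSE)
      }
    }
  }
  reads <- do.call(rbind, reads_list)
  class(reads) <- c("nanopore_reads", "data.frame")
  truth <- do.call(rbind, truth_list)
  # interleave samples deterministically
  perm <- sample.int(nrow(reads))
  reads <- reads[perm, , drop = FALSE]
  truth <- truth[perm, , drop = FALSE]
  rownames(reads) <- rownames(truth) <- NULL
  expected <- lapply(proportions, function(p) as.integer(names(p)[p > 0]))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fastq(reads, file.path(out_dir, "reads.fastq"))
    write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_reference_fasta(refset$db, file.path(out_dir, "reference.fasta"))
    write_taxonomy(refset$db$taxonomy, file.path(out_dir, "taxonomy.tsv"))
  }
  list(reads = reads, truth = truth, refset = refset, panel = panel,
       expected_species = expected)
}
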