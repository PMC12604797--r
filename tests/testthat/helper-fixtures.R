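# Shared fixtures, all built in code.

# Two rapid-kit-style 24-bp indices.
test_indices <- c(BC01 = "AAGAAAGTTGTCGGTGTCTTTGTG",
                  BC02 = "TCGATTCCGTTTGTAGTCGTCTGT")

test_sheet <- function(modes = "single_source", n = NULL) {
  if (is.null(n)) n <- max(length(modes), 2L)
  modes <- rep_len(modes, n)
  idx <- test_indices[seq_len(n)]
  sample_sheet(data.frame(index_id = names(idx),
                          index_sequence = unname(idx),
                          sample_name = paste0("s", seq_len(n)),
                          mode = modes, stringsAsFactors = FALSE))
}

# i.i.d. substitutions at rate d (used to build related fixture sequences)
mutate_fixture <- function(s, d) {
  v <- strsplit(s, "")[[1]]
  hit <- runif(length(v)) < d
  v[hit] <- vapply(v[hit], function(x) sample(setdiff(c("A","C","G","T"), x), 1), "")
  paste(v, collapse = "")
}

# Taxonomy with a tribe level:
# root(1) > class(2) > order(3) > family(10) > tribe(20) > genus(30, 31)
# genus 30 > species 100, 101 ; genus 31 > species 102
# plus genus 40 (other family 11) > species 103
toy_taxonomy <- function() {
  data.frame(
    taxid = c(1L, 2L, 3L, 10L, 11L, 20L, 30L, 31L, 40L, 100L, 101L, 102L, 103L),
    parent_taxid = c(1L, 1L, 2L, 3L, 3L, 10L, 20L, 20L, 11L, 30L, 30L, 31L, 40L),
    rank = c("higher", "class", "order", "family", "family", "tribe", "genus",
             "genus", "genus", "species", "species", "species", "species"),
    name = c("root", "ClassA", "OrderA", "FamA", "FamB", "TribeA", "GenA",
             "GenB", "GenC", "Species100", "Species101", "Species102",
             "Species103"),
    stringsAsFactors = FALSE)
}

toy_records <- function(accession, taxid, sequence,
                        molecule = "mitochondrial",
                        record_class = "barcode_locus", gene_label = "COI",
                        stitle = accession) {
  data.frame(accession = accession, taxid = taxid, molecule = molecule,
             record_class = record_class, gene_label = gene_label,
             stitle = stitle, sequence = sequence, stringsAsFactors = FALSE)
}

# Deterministic pseudo-random DNA.
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# Reads with constant per-base quality q (mean read quality is then exactly q).
const_q_read <- function(id, sequence, q) {
  nanopore_reads(id, sequence, phred_string(rep(q, nchar(sequence))))
}

# One-row hit-table in the shape emitted by search_db.
hit_row <- function(qseqid = "q", qlen = 100L, evalue = 1e-10, qcovs = 100,
                    pident = 99, staxids = 100L, stitle = "t",
                    scomnames = "n", score = 100, saccession = "ACC",
                    molecule = "mitochondrial", record_class = "barcode_locus") {
  data.frame(qseqid = qseqid, qlen = qlen, evalue = evalue, qcovs = qcovs,
             pident = pident, staxids = staxids, stitle = stitle,
             scomnames = scomnames, score = score, saccession = saccession,
             molecule = molecule, record_class = record_class,
             stringsAsFactors = FALSE)
}
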