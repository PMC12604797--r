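# Readers/writers for reads, reference sequences, taxonomy and sample sheets,
# plus the shared data model used across the pipeline.

#' Construct a set of nanopore reads
#'
#' Reads are held as a data frame with one row per read: `read_id`, `sequence`
#' (uppercase DNA over A/C/G/T/N) and `quality` (Sanger Phred+33 string, one
#' character per base, Phred values 0-93).
#'
#' @param read_id character vector of read identifiers
#' @param sequence character vector of DNA sequences
#' @param quality character vector of Phred+33 quality strings
#' @return a `nanopore_reads` data frame
#' @export
nanopore_reads <- function(read_id, sequence, quality) {
  stopifnot(length(read_id) == length(sequence),
            length(sequence) == length(quality))
  sequence <- if (length(sequence)) normalize_dna(sequence, "read sequence") else character()
  bad_chr <- grepl("[^ACGTN]", sequence)
  if (any(bad_chr)) {
    stop(sprintf("read '%s': sequence contains IUPAC ambiguity codes other than N",
                 read_id[which(bad_chr)[1]]))
  }
  len_mismatch <- nchar(sequence) != nchar(quality)
  if (any(len_mismatch)) {
    stop(sprintf("read '%s': sequence length %d != quality length %d",
                 read_id[which(len_mismatch)[1]],
                 nchar(sequence)[which(len_mismatch)[1]],
                 nchar(quality)[which(len_mismatch)[1]]))
  }
  qcat <- paste(quality, collapse = "")
  if (nzchar(qcat)) {
    qr <- range(utf8ToInt(qcat))
    if (qr[1] < 33L || qr[2] > 126L) {
      stop("quality characters outside the Phred+33 printable range [!, ~]")
    }
  }
  structure(
    data.frame(read_id = as.character(read_id), sequence = sequence,
               quality = quality, stringsAsFactors = FALSE),
    class = c("nanopore_reads", "data.frame"))
}

#' Per-base Phred qualities of reads
#' @param reads a `nanopore_reads` object
#' @return list of integer vectors, one per read
#' @export
phred_qualities <- function(reads) {
  lapply(reads$quality, function(q) utf8ToInt(q) - 33L)
}

#' Encode integer Phred values as a Phred+33 quality string
#' @param q integer vector of Phred values, 0 to 93
#' @return single quality string
#' @export
phred_string <- function(q) {
  stopifnot(all(q >= 0 & q <= 93))
  intToUtf8(as.integer(q) + 33L)
}

#' Read a FASTQ file into a `nanopore_reads` object
#'
#' Expects 4-line-per-record FASTQ, plain or gzipped. Sequences are
#' uppercased and U is mapped to T. A record whose sequence and quality line
#' lengths differ is reported by its read id.
#'
#' @param path path to a `.fastq` or `.fastq.gz` file
#' @return a `nanopore_reads` object, record order preserved
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ (line count ", length(lines), " not a multiple of 4): ", path)
  }
  n <- length(lines) %/% 4L
  if (n == 0L) return(nanopore_reads(character(), character(), character()))
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  if (any(substr(hdr, 1, 1) != "@")) {
    stop("malformed FASTQ record header at record ",
         which(substr(hdr, 1, 1) != "@")[1])
  }
  ids <- sub("\\s.*$", "", substring(hdr, 2))
  nanopore_reads(ids,
                 lines[seq(2L, by = 4L, length.out = n)],
                 lines[seq(4L, by = 4L, length.out = n)])
}

#' Write reads as FASTQ
#' @param reads a `nanopore_reads` object
#' @param path output path (gzipped if it ends in .gz)
#' @return `path`, invisibly
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (nrow(reads)) {
    writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n",
                      reads$quality), con, sep = "\n")
  }
  invisible(path)
}

#' Load a reference database (structured FASTA + taxonomy TSV)
#'
#' FASTA id lines carry pipe-delimited metadata,
#' `accession|taxid|molecule|record_class|gene_label`, with free text after
#' the first whitespace used as the subject title (stitle). The taxonomy TSV
#' has columns `taxid`, `parent_taxid`, `rank`, `name` (header required); the
#' root is the single node with `parent_taxid == taxid`.
#'
#' @param fasta_path path to the reference FASTA
#' @param taxonomy_path path to the taxonomy TSV
#' @return a `reference_db` object: list with `records` and `taxonomy` data frames
#' @export
load_reference_db <- function(fasta_path, taxonomy_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  headers <- names(seqs)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  fields <- strsplit(id, "|", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 5L)) {
    stop("reference FASTA header must have 5 pipe-delimited fields ",
         "(accession|taxid|molecule|record_class|gene_label): ", id[nf != 5L][1])
  }
  fm <- do.call(rbind, fields)
  records <- data.frame(
    accession = fm[, 1],
    taxid = suppressWarnings(as.integer(fm[, 2])),
    molecule = fm[, 3],
    record_class = fm[, 4],
    gene_label = fm[, 5],
    stitle = ifelse(nzchar(desc), desc, id),
    sequence = normalize_dna(as.character(seqs), "reference sequence"),
    stringsAsFactors = FALSE)
  taxonomy <- read.delim(taxonomy_path, stringsAsFactors = FALSE)
  reference_db(records, taxonomy)
}

#' Construct and validate a reference database from its two tables
#' @param records data frame with columns accession, taxid, molecule,
#'   record_class, gene_label, stitle, sequence
#' @param taxonomy data frame with columns taxid, parent_taxid, rank, name
#' @return a `reference_db` object
#' @export
reference_db <- function(records, taxonomy) {
  need_rec <- c("accession", "taxid", "molecule", "record_class", "gene_label",
                "stitle", "sequence")
  need_tax <- c("taxid", "parent_taxid", "rank", "name")
  stopifnot(all(need_rec %in% names(records)), all(need_tax %in% names(taxonomy)))
  if (anyNA(records$taxid)) stop("non-integer taxid in reference records")
  dup <- duplicated(records$accession)
  if (any(dup)) stop("duplicate accession in reference FASTA: ",
                     records$accession[dup][1])
  if (!all(records$molecule %in% c("mitochondrial", "nuclear"))) {
    stop("molecule field must be 'mitochondrial' or 'nuclear'")
  }
  if (!all(records$record_class %in% c("barcode_locus", "ncRNA_other", "other"))) {
    stop("record_class must be one of barcode_locus, ncRNA_other, other")
  }
  if (!all(taxonomy$rank %in% RANK_ORDER)) {
    stop("unknown taxonomy rank: ",
         taxonomy$rank[!taxonomy$rank %in% RANK_ORDER][1])
  }
  if (anyDuplicated(taxonomy$taxid)) stop("duplicate taxid in taxonomy")
  root <- taxonomy$taxid == taxonomy$parent_taxid
  if (sum(root) != 1L) stop("taxonomy must have exactly one root (parent == self)")
  if (!all(taxonomy$parent_taxid %in% taxonomy$taxid)) {
    stop("taxonomy parent_taxid not present as a node")
  }
  missing <- setdiff(records$taxid, taxonomy$taxid)
  if (length(missing)) {
    acc <- records$accession[match(missing[1], records$taxid)]
    stop(sprintf("record '%s' has taxid %d absent from the taxonomy", acc, missing[1]))
  }
  # acyclicity: every lineage must reach the root within depth steps
  parent <- setNames(taxonomy$parent_taxid, taxonomy$taxid)
  depth <- nrow(taxonomy)
  for (t in taxonomy$taxid) {
    cur <- t
    for (i in seq_len(depth + 1L)) {
      if (parent[[as.character(cur)]] == cur) break
      cur <- parent[[as.character(cur)]]
      if (i > depth) stop("taxonomy contains a cycle involving taxid ", t)
    }
    if (parent[[as.character(cur)]] != cur) stop("taxonomy contains a cycle involving taxid ", t)
  }
  structure(list(records = records, taxonomy = taxonomy), class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("reference_db: %d records, %d taxonomy nodes (%d species)\n",
              nrow(x$records), nrow(x$taxonomy),
              sum(x$taxonomy$rank == "species")))
  invisible(x)
}

#' Write the records of a reference database as a structured FASTA
#' @param db a `reference_db` object
#' @param path output FASTA path
#' @return `path`, invisibly
#' @export
write_reference_fasta <- function(db, path) {
  r <- db$records
  hdr <- sprintf("%s|%d|%s|%s|%s %s", r$accession, r$taxid, r$molecule,
                 r$record_class, r$gene_label, r$stitle)
  writeLines(paste0(">", hdr, "\n", r$sequence), path)
  invisible(path)
}

#' Write a taxonomy table as TSV
#' @param taxonomy taxonomy data frame (taxid, parent_taxid, rank, name)
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_taxonomy <- function(taxonomy, path) {
  write.table(taxonomy, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Full lineage of a taxid, self first, root last.
lineage <- function(taxonomy, taxid) {
  i <- match(taxid, taxonomy$taxid)
  if (is.na(i)) stop("unknown taxid: ", taxid)
  out <- integer()
  cur <- taxid
  repeat {
    out <- c(out, cur)
    p <- taxonomy$parent_taxid[match(cur, taxonomy$taxid)]
    if (p == cur) break
    cur <- p
  }
  out
}

#' Name of a taxon's ancestor at a given rank
#'
#' Walks the lineage from the taxon towards the root and returns the name of
#' the first node (self included) whose rank equals `rank`, or `NA_character_`
#' if the lineage skips that rank.
#'
#' @param db a `reference_db` object (or a taxonomy data frame)
#' @param taxid query taxid
#' @param rank one of `"species"`, `"genus"`, `"tribe"`, `"family"`,
#'   `"order"`, `"class"`, `"higher"`
#' @return taxon name, or `NA_character_` if absent
#' @export
lineage_at_rank <- function(db, taxid, rank) {
  taxonomy <- if (inherits(db, "reference_db")) db$taxonomy else db
  rank <- match.arg(rank, RANK_ORDER)
  lin <- lineage(taxonomy, taxid)
  ranks <- taxonomy$rank[match(lin, taxonomy$taxid)]
  hit <- which(ranks == rank)
  if (!length(hit)) return(NA_character_)
  taxonomy$name[match(lin[hit[1]], taxonomy$taxid)]
}

# Lowest common ancestor taxid of a set of taxids.
lca_taxid <- function(taxonomy, taxids) {
  taxids <- unique(taxids)
  if (length(taxids) == 1L) return(taxids)
  lins <- lapply(taxids, function(t) lineage(taxonomy, t))
  common <- Reduce(intersect, lins)
  # intersect preserves the order of the first lineage: deepest common first
  common[1]
}

#' Read a sample sheet CSV
#'
#' Columns: `index_id`, `index_sequence`, `sample_name`, `mode`
#' (`single_source` or `mixture`). Index sequences must be pairwise distinct.
#'
#' @param path path to the CSV
#' @return validated sample-sheet data frame
#' @export
read_sample_sheet <- function(path) {
  sheet <- read.csv(path, stringsAsFactors = FALSE)
  sample_sheet(sheet)
}

#' Validate a sample sheet data frame
#' @param sheet data frame with index_id, index_sequence, sample_name, mode
#' @return the validated sheet
#' @export
sample_sheet <- function(sheet) {
  need <- c("index_id", "index_sequence", "sample_name", "mode")
  stopifnot(all(need %in% names(sheet)))
  sheet$index_sequence <- normalize_dna(sheet$index_sequence, "index sequence")
  if (anyDuplicated(sheet$index_sequence)) stop("sample sheet index sequences must be pairwise distinct")
  if (anyDuplicated(sheet$index_id)) stop("duplicate index_id in sample sheet")
  if (!all(sheet$mode %in% c("single_source", "mixture"))) {
    stop("sample sheet mode must be 'single_source' or 'mixture'")
  }
  sheet
}

#' Write sequences as FASTA
#' @param sequences named character vector of sequences
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fasta <- function(sequences, path) {
  writeLines(paste0(">", names(sequences), "\n", unname(sequences)), path)
  invisible(path)
}
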