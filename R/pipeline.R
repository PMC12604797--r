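# End-to-end orchestration: filter -> demultiplex -> assign -> cluster ->
# consensus -> database search -> hit filtering -> species call, with
# per-stage read accounting and report writers.

#' Pipeline thresholds and parameters
#'
#' Defaults reproduce the published decision rules: mean read quality >= 11,
#' length 100-500 bp, top-match identity >= 90%, single-source consensuses
#' discarded below 100 supporting reads, mixture consensuses retained above
#' 20 supporting reads, cluster abundance ratio 0.1%.
#'
#' @param min_quality,min_length,max_length read filter (see [filter_params()])
#' @param min_pident top-match identity floor (percent)
#' @param single_source_min_reads support floor in single-source mode
#' @param mixture_min_reads support floor in mixture mode (21 = "> 20")
#' @param abundance_ratio cluster abundance ratio
#' @param identity_threshold clustering identity threshold
#' @param index_max_edit index demultiplexing edit limit
#' @param primer_max_edit primer search edit limit (NULL = 25% of primer length)
#' @param max_members consensus member cap per cluster
#' @param min_mixture_barcodes barcodes with both strands needed to report a
#'   mixture species
#' @param call_rule `"consensus"` or `"majority"` (see [call_single_source()])
#' @param scoring a `scoring_params`
#' @return a `pipeline_params` list
#' @export
pipeline_params <- function(min_quality = 11, min_length = 100L,
                            max_length = 500L, min_pident = 90,
                            single_source_min_reads = 100L,
                            mixture_min_reads = 21L,
                            abundance_ratio = 0.001,
                            identity_threshold = 0.80,
                            index_max_edit = 3L, primer_max_edit = NULL,
                            max_members = 500L,
                            min_mixture_barcodes = 2L,
                            call_rule = "consensus",
                            scoring = scoring_params()) {
  structure(list(min_quality = min_quality, min_length = min_length,
                 max_length = max_length, min_pident = min_pident,
                 single_source_min_reads = as.integer(single_source_min_reads),
                 mixture_min_reads = as.integer(mixture_min_reads),
                 abundance_ratio = abundance_ratio,
                 identity_threshold = identity_threshold,
                 index_max_edit = as.integer(index_max_edit),
                 primer_max_edit = primer_max_edit,
                 max_members = as.integer(max_members),
                 min_mixture_barcodes = as.integer(min_mixture_barcodes),
                 call_rule = call_rule, scoring = scoring),
            class = "pipeline_params")
}

#' Run the species-identification pipeline
#'
#' @param reads a `nanopore_reads` object (or path to a FASTQ file)
#' @param db a `reference_db`
#' @param sheet a validated sample sheet
#' @param panel a `primer_panel`
#' @param params a `pipeline_params`
#' @param out_dir optional output directory; when given, writes
#'   `report.json`, `report.tsv`, `consensus.fasta`, `hits.tsv`,
#'   `stage_counts.tsv`
#' @return a `pipeline_report`: list with `samples` (per-sample results),
#'   `consensuses`, `hits` (full sorted hit tables), `retained_hits`,
#'   `stage_counts`
#' @export
run_pipeline <- function(reads, db, sheet, panel = default_panel(),
                         params = pipeline_params(), out_dir = NULL) {
  if (is.character(reads)) reads <- read_fastq(reads)
  sheet <- sample_sheet(sheet)
  prep <- prepare_reads(reads, sheet, panel,
                        filter_params(params$min_quality, params$min_length,
                                      params$max_length),
                        index_max_edit = params$index_max_edit,
                        primer_max_edit = params$primer_max_edit)
  all_cons <- list()
  all_hits <- list()
  all_retained <- list()
  samples <- list()
  for (s in seq_len(nrow(sheet))) {
    idx <- sheet$index_id[s]
    mode <- sheet$mode[s]
    min_reads <- if (mode == "mixture") params$mixture_min_reads
                 else params$single_source_min_reads
    assigned <- prep$assigned[prep$assigned$index_id == idx, , drop = FALSE]
    cons <- bin_consensus(assigned, params$abundance_ratio, min_reads,
                          params$identity_threshold, params$max_members)
    hfp <- hit_filter_params(min_pident = params$min_pident, mode = mode)
    cons$qseqid <- if (nrow(cons)) {
      sprintf("%s|%s|%s|r%d", cons$index_id, cons$barcode, cons$strand,
              cons$cluster_rank)
    } else character(0)
    hits_s <- list()
    retained_s <- list()
    for (i in seq_len(nrow(cons))) {
      h <- search_db(cons$sequence[i], cons$qseqid[i], db, params$scoring)
      hits_s[[length(hits_s) + 1L]] <- h
      retained_s[[length(retained_s) + 1L]] <- filter_hits(h, db, hfp)
    }
    hits_s <- if (length(hits_s)) do.call(rbind, hits_s) else empty_hit_table()
    retained_s <- if (length(retained_s)) do.call(rbind, retained_s) else empty_hit_table()
    if (mode == "single_source") {
      calls <- list()
      for (b in panel$barcode) {
        get_top <- function(strand) {
          cb <- cons[cons$barcode == b & cons$strand == strand, , drop = FALSE]
          if (!nrow(cb)) return(list(hits = NULL, support = 0L))
          cb <- cb[cb$cluster_rank == min(cb$cluster_rank), , drop = FALSE]
          list(hits = retained_s[retained_s$qseqid == cb$qseqid[1], , drop = FALSE],
               support = cb$supporting_reads[1])
        }
        f <- get_top("forward"); r <- get_top("reverse")
        calls[[b]] <- merge_strands(b, f$hits, r$hits, f$support, r$support)
      }
      calls <- flag_numts(calls)
      final <- call_single_source(calls, db, params$call_rule)
      samples[[sheet$sample_name[s]]] <- list(
        sample_name = sheet$sample_name[s], mode = mode,
        barcode_calls = calls, call = final)
    } else {
      if (nrow(retained_s)) {
        m <- match(retained_s$qseqid, cons$qseqid)
        evidence <- data.frame(barcode = cons$barcode[m],
                               strand = cons$strand[m],
                               taxid = retained_s$staxids,
                               supporting_reads = cons$supporting_reads[m],
                               stringsAsFactors = FALSE)
      } else {
        evidence <- data.frame(barcode = character(), strand = character(),
                               taxid = integer(),
                               supporting_reads = integer(),
                               stringsAsFactors = FALSE)
      }
      report <- call_mixture(evidence, db, params$min_mixture_barcodes)
      samples[[sheet$sample_name[s]]] <- list(
        sample_name = sheet$sample_name[s], mode = mode,
        evidence = evidence, report = report)
    }
    all_cons[[length(all_cons) + 1L]] <- cons
    all_hits[[length(all_hits) + 1L]] <- hits_s
    all_retained[[length(all_retained) + 1L]] <- retained_s
  }
  consensuses <- if (length(all_cons)) do.call(rbind, all_cons) else NULL
  res <- structure(list(
    samples = samples,
    consensuses = consensuses,
    hits = do.call(rbind, all_hits),
    retained_hits = do.call(rbind, all_retained),
    stage_counts = prep$counts), class = "pipeline_report")
  if (!is.null(out_dir)) write_pipeline_report(res, out_dir)
  res
}

# Flat one-row-per-call table for the TSV report.
report_table <- function(res) {
  rows <- list()
  for (s in res$samples) {
    if (s$mode == "single_source") {
      cl <- s$call
      statuses <- vapply(s$barcode_calls, function(x) x$status, "")
      rows[[length(rows) + 1L]] <- data.frame(
        sample_name = s$sample_name, mode = s$mode,
        taxid = cl$taxid, name = cl$name, level = cl$level,
        supporting_barcodes = paste(cl$supporting_barcodes, collapse = ","),
        numt_barcodes = paste(cl$numt_barcodes, collapse = ","),
        barcode_statuses = paste(sprintf("%s:%s", names(statuses), statuses),
                                 collapse = ";"),
        stringsAsFactors = FALSE)
    } else if (nrow(s$report)) {
      for (i in seq_len(nrow(s$report))) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_name = s$sample_name, mode = s$mode,
          taxid = s$report$taxid[i], name = s$report$name[i],
          level = "species",
          supporting_barcodes = s$report$barcodes[i],
          numt_barcodes = "",
          barcode_statuses = sprintf("supporting_reads:%d",
                                     s$report$total_supporting_reads[i]),
          stringsAsFactors = FALSE)
      }
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_name = s$sample_name, mode = s$mode, taxid = NA_integer_,
        name = NA_character_, level = "none", supporting_barcodes = "",
        numt_barcodes = "", barcode_statuses = "", stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write the pipeline report files
#'
#' Writes `report.json` (per-sample calls, barcode statuses, numt flags,
#' supporting reads), `report.tsv` (one row per single-source sample and one
#' per mixture species), `consensus.fasta`, `hits.tsv` (outfmt-7-compatible)
#' and `stage_counts.tsv`.
#'
#' @param res a `pipeline_report`
#' @param out_dir output directory (created if needed)
#' @return `out_dir`, invisibly
#' @export
write_pipeline_report <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  json <- lapply(res$samples, function(s) {
    if (s$mode == "single_source") {
      list(sample_name = s$sample_name, mode = s$mode,
           call = list(taxid = s$call$taxid, name = s$call$name,
                       level = s$call$level,
                       supporting_barcodes = as.list(s$call$supporting_barcodes),
                       numt_barcodes = as.list(s$call$numt_barcodes)),
           barcodes = lapply(s$barcode_calls, function(x) {
             list(status = x$status, candidates = as.list(x$candidates),
                  discordant = x$discordant,
                  supporting_reads = as.list(x$supporting_reads))
           }))
    } else {
      list(sample_name = s$sample_name, mode = s$mode,
           species = if (nrow(s$report)) {
             lapply(seq_len(nrow(s$report)), function(i) {
               list(taxid = s$report$taxid[i], name = s$report$name[i],
                    barcodes = as.list(strsplit(s$report$barcodes[i], ",")[[1]]),
                    total_supporting_reads = s$report$total_supporting_reads[i])
             })
           } else list())
    }
  })
  jsonlite::write_json(list(samples = json,
                            stage_counts = as.list(res$stage_counts)),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write.table(report_table(res), file.path(out_dir, "report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(res$consensuses) && nrow(res$consensuses)) {
    write_consensus_fasta(res$consensuses, file.path(out_dir, "consensus.fasta"))
  } else {
    writeLines(character(), file.path(out_dir, "consensus.fasta"))
  }
  write_hit_table(res$hits %||% empty_hit_table(), file.path(out_dir, "hits.tsv"))
  sc <- data.frame(stage = names(res$stage_counts),
                   reads = as.integer(res$stage_counts))
  write.table(sc, file.path(out_dir, "stage_counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline_report: %d samples, %d consensus sequences\n",
              length(x$samples),
              if (is.null(x$consensuses)) 0L else nrow(x$consensuses)))
  for (s in x$samples) {
    if (s$mode == "single_source") {
      cat(sprintf("  %s [single_source]: %s (%s)\n", s$sample_name,
                  s$call$name, s$call$level))
    } else {
      cat(sprintf("  %s [mixture]: %d species present\n", s$sample_name,
                  nrow(s$report)))
    }
  }
  invisible(x)
}
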