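#' Pipeline configuration
#'
#' Collects input paths and thresholds for [run_pipeline()]. All files are
#' checked before any stage runs. A YAML file with the same field names can
#' be loaded with [read_trip_config()].
#'
#' @param genome_fasta,annotation_gff3 reference genome and gene
#'   annotation paths.
#' @param wt_regions_tsv wild-type transcribed regions
#'   (chrom/start/end/strand/fpkm TSV, 0-based half-open).
#' @param junction_fastq,dna_fastq,rna_fastq read libraries.
#' @param min_reads,min_dominance locus-calling thresholds.
#' @param min_count DNA/RNA read-number threshold for quantification.
#' @param max_mismatches flank-mapping substitution cap.
#' @param max_template_mismatch border-matching substitution cap.
#' @param merge_window locus merge window (bp).
#' @param min_flank_len minimal mappable flank length (nt).
#' @param scale level scale factor.
#' @param kmer_size seed k-mer size for the genome index.
#' @param wt_strand_matched require same-strand WT-region overlap for the
#'   reporter x WT classification.
#' @param seed integer seed recorded in outputs.
#' @param outdir optional output directory for the records TSV and
#'   summary JSON.
#' @return list of class `trip_config`.
#' @export
trip_config <- function(genome_fasta, annotation_gff3, wt_regions_tsv,
                        junction_fastq, dna_fastq, rna_fastq,
                        min_reads = 2L, min_dominance = 0.6, min_count = 5L,
                        max_mismatches = 3L, max_template_mismatch = 2L,
                        merge_window = 5L, min_flank_len = 20L,
                        scale = 10000, kmer_size = 5L,
                        wt_strand_matched = FALSE,
                        seed = NULL, outdir = NULL) {
  paths <- c(genome_fasta = genome_fasta, annotation_gff3 = annotation_gff3,
             wt_regions_tsv = wt_regions_tsv, junction_fastq = junction_fastq,
             dna_fastq = dna_fastq, rna_fastq = rna_fastq)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L)
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  if (min_dominance < 0 || min_dominance > 1)
    stop("min_dominance must lie in [0, 1]")
  if (max_mismatches < 0 || merge_window < 0 || min_reads < 1)
    stop("thresholds outside documented ranges")
  structure(c(as.list(paths),
              list(min_reads = as.integer(min_reads),
                   min_dominance = min_dominance,
                   min_count = as.integer(min_count),
                   max_mismatches = as.integer(max_mismatches),
                   max_template_mismatch = as.integer(max_template_mismatch),
                   merge_window = as.integer(merge_window),
                   min_flank_len = as.integer(min_flank_len),
                   scale = scale, kmer_size = as.integer(kmer_size),
                   wt_strand_matched = wt_strand_matched,
                   seed = seed, outdir = outdir)),
            class = "trip_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [trip_config()] arguments.
#' @return a `trip_config`.
#' @export
read_trip_config <- function(path) {
  do.call(trip_config, yaml::read_yaml(path))
}

#' Run the full promoter-trap analysis pipeline
#'
#' Executes extract -> map -> call -> quantify -> classify -> summarize on
#' the configured libraries and returns a `trip_result` with one record
#' per barcode, the cohort summary, and a stage-by-stage log of read and
#' barcode counts. When `outdir` is set, a records TSV and a summary JSON
#' are written there. The pipeline is deterministic: rerunning the same
#' configuration yields byte-identical outputs.
#'
#' @param config a [trip_config()].
#' @param template a [tdna_template()].
#' @return object of class `trip_result` with elements `records`,
#'   `summary`, `log`, `config`.
#' @export
run_pipeline <- function(config, template = tdna_template()) {
  stopifnot(inherits(config, "trip_config"))
  log <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed after ",
           length(log), " stage(s): ", conditionMessage(e), call. = FALSE))
  }

  genome <- stage("load", read_genome(config$genome_fasta, config$annotation_gff3))
  wt <- stage("load", read_wt_regions(config$wt_regions_tsv))
  jreads <- stage("load", read_fastq(config$junction_fastq))
  log$junction_reads_in <- nrow(jreads)

  ej <- stage("extract", extract_junctions(
    jreads, template, config$max_template_mismatch, config$min_flank_len))
  log$junction_reads_extracted <- sum(ej$status == "ok")

  index <- stage("map", build_genome_index(genome, config$kmer_size))
  ok <- ej$status == "ok"
  maps <- stage("map", map_flanks(ej$flank[ok], index, config$max_mismatches,
                                  min_flank_len = config$min_flank_len))
  log$junction_reads_mapped <- sum(maps$status == "mapped")

  junctions <- data.frame(barcode = ej$barcode[ok],
                          chrom = maps$chrom, position = maps$position,
                          strand = maps$strand, stringsAsFactors = FALSE)
  supports <- stage("call", aggregate_pairs(junctions, config$merge_window))
  calls <- stage("call", call_lines(supports, config$min_reads,
                                    config$min_dominance))
  log$barcodes_seen <- nrow(calls)
  log$barcodes_called <- sum(calls$status == "called")

  dna <- stage("quantify", count_barcodes(config$dna_fastq, template))
  rna <- stage("quantify", count_barcodes(config$rna_fastq, template))
  levels <- stage("quantify", compute_levels(dna, rna, config$min_count,
                                             config$scale))
  log$dna_reads_counted <- dna$total
  log$rna_reads_counted <- rna$total
  log$barcodes_quantified <- sum(!levels$omitted)

  records <- merge(calls, as.data.frame(levels), by = "barcode",
                   all.x = TRUE, sort = TRUE)
  records$insertion_type <- NA_character_
  records$wt_type <- NA_character_
  records$wt_fpkm <- NA_real_
  called <- records$status == "called"
  if (any(called)) {
    records$insertion_type[called] <- stage("classify", classify_insertions(
      records$chrom[called], records$position[called],
      records$strand[called], genome))
    usable <- called & !is.na(records$level)
    if (any(usable)) {
      cw <- stage("classify", classify_wt_overlaps(
        records$chrom[usable], records$position[usable],
        records$strand[usable], records$level[usable], wt,
        config$wt_strand_matched))
      records$wt_type[usable] <- cw$wt_type
      records$wt_fpkm[usable] <- cw$wt_fpkm
    }
  }
  records$level_bin <- NA_character_
  tx <- called & !is.na(records$level) & records$level > 0
  if (sum(tx) >= 3L)
    records$level_bin[tx] <- as.character(percentile_bins(records$level[tx]))
  records$decade_bin <- as.character(decade_bin(records$level))
  records$decade_bin[!called] <- NA_character_
  log$lines_classified <- sum(!is.na(records$wt_type))

  summary <- stage("summarize", cohort_summary(
    records[called, , drop = FALSE]))

  result <- structure(list(records = records, summary = summary,
                           log = log, config = config),
                      class = "trip_result")
  if (!is.null(config$outdir)) write_trip_result(result, config$outdir)
  result
}

#' Write pipeline outputs
#'
#' @param result a `trip_result`.
#' @param outdir output directory (created if needed); writes
#'   `records.tsv` and `summary.json`.
#' @return invisibly, the output paths.
#' @export
write_trip_result <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  rec_path <- file.path(outdir, "records.tsv")
  json_path <- file.path(outdir, "summary.json")
  write.table(result$records, rec_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  s <- result$summary
  payload <- list(
    n_called = s$n_called, n_transcribed = s$n_transcribed,
    insertion_type_counts = as.list(s$insertion_types$counts),
    insertion_type_percent = as.list(s$insertion_types$percent),
    wt_type_counts = if (!is.null(s$wt_types)) as.list(s$wt_types$counts),
    wt_type_percent = if (!is.null(s$wt_types)) as.list(s$wt_types$percent),
    activation_untranscribed = if (!is.null(s$wt_types))
      s$wt_types$activation_untranscribed,
    activation_transcribed = if (!is.null(s$wt_types))
      s$wt_types$activation_transcribed,
    spearman_type_i = s$spearman_type_i,
    log = result$log)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(rec_path, json_path))
}

#' @export
print.trip_result <- function(x, ...) {
  cat("Promoter-trap pipeline result\n")
  cat("  reads in:          ", x$log$junction_reads_in, "\n")
  cat("  barcodes seen:     ", x$log$barcodes_seen, "\n")
  cat("  lines called:      ", x$log$barcodes_called, "\n")
  cat("  lines transcribed: ", x$summary$n_transcribed, "\n")
  invisible(x)
}

#' @method summary trip_result
#' @export
summary.trip_result <- function(object, ...) {
  object$summary
}

#' Plot a pipeline result
#'
#' Per-insertion-type fractions of lines across the transcription-level
#' decade bins (ND, 10^1 .. 10^7), as grouped bars.
#'
#' @param x a `trip_result`.
#' @param ... passed to [graphics::barplot()].
#' @method plot trip_result
#' @export
plot.trip_result <- function(x, ...) {
  frac <- x$summary$decade_histogram$fraction
  graphics::barplot(frac, beside = TRUE, legend.text = rownames(frac),
                    xlab = "relative transcription level",
                    ylab = "fraction of lines", ...)
  invisible(x)
}
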