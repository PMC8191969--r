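#' T-DNA junction anchor template
#'
#' The vector-side anchor used both to build simulated reads and to extract
#' barcodes and genomic flanks from junction and count reads. On the strand
#' on which the reporter CDS reads 5'->3', the T-DNA begins (from the RB
#' junction inward) with the border sequence, then the 12-nt line barcode,
#' then the first codons of the luciferase ORF.
#'
#' @param border right-border-proximal vector sequence at the genome
#'   junction (case-insensitive).
#' @param barcode_len barcode length in nt.
#' @param luc_head 5' segment of the reporter ORF downstream of the
#'   barcode.
#' @return list of class `tdna_template`.
#' @export
tdna_template <- function(border = "tcaaggcctcgacgttatcagcttacag",
                          barcode_len = 12L,
                          luc_head = paste0("ATGGAAGACGCCAAAAACATAAAGAAAGGC",
                                            "CCGGCGCCATTCTATCCTCTAGAG")) {
  border <- assert_dna(border, "border")
  luc_head <- assert_dna(luc_head, "luc_head")
  if (nchar(border) == 0L || nchar(luc_head) == 0L)
    stop("border and luc_head must be non-empty")
  structure(list(border = border, barcode_len = as.integer(barcode_len),
                 luc_head = luc_head), class = "tdna_template")
}

# insert-strand 5' genomic flank of length len ending at the RB junction
junction_flank <- function(genome, chrom, rb_position, strand, len) {
  if (strand == "+") {
    genome_fetch(genome, chrom, rb_position - len + 1L, rb_position + 1L)
  } else {
    revcomp(genome_fetch(genome, chrom, rb_position, rb_position + len))
  }
}

mutate_one_base <- function(seq) {
  i <- sample.int(nchar(seq), 1L)
  old <- substr(seq, i, i)
  substr(seq, i, i) <- sample(setdiff(DNA_BASES, old), 1L)
  seq
}

#' Simulate a junction (inverse-PCR) read library
#'
#' Each clean read is the reverse-complement of the insert-strand junction
#' sequence `genomic flank + border + barcode + luc_head`, i.e. it runs,
#' 5'->3': reverse-complemented reporter ORF start, barcode, border, then
#' genomic flank, emulating sequencing outward from a primer in the
#' reporter ORF. Artefact reads (barcode substitutions, chimeric flanks)
#' are injected at the configured per-read rates. Base qualities are a
#' constant placeholder.
#'
#' @param truth a [generate_cohort()] table.
#' @param genome the [genome_model()] the cohort was placed on.
#' @param template a [tdna_template()].
#' @param depth_per_line reads per insertion.
#' @param read_len read length; must leave >= 20 nt of genomic flank.
#' @param barcode_sub_rate,chimera_rate per-read artefact probabilities;
#'   default to the rates in the truth table's cohort_config.
#' @param seed optional integer seed.
#' @param path optional FASTQ output path.
#' @return invisibly, data.frame with columns id, seq (also written to
#'   `path` when given).
#' @export
simulate_junction_library <- function(truth, genome, template = tdna_template(),
                                      depth_per_line = 10L, read_len = 150L,
                                      barcode_sub_rate = NULL,
                                      chimera_rate = NULL,
                                      seed = NULL, path = NULL) {
  cfg <- attr(truth, "config")
  if (is.null(barcode_sub_rate))
    barcode_sub_rate <- if (is.null(cfg)) 0 else cfg$barcode_sub_rate
  if (is.null(chimera_rate))
    chimera_rate <- if (is.null(cfg)) 0 else cfg$chimera_rate
  if (!is.null(seed)) set.seed(seed)
  tlen <- nchar(template$border) + template$barcode_len + nchar(template$luc_head)
  flank_len <- read_len - tlen
  if (flank_len < 20L)
    stop("read_len too short: needs >= 20 nt of genomic flank beyond the template")

  ids <- character(0); seqs <- character(0)
  if (depth_per_line > 0L && nrow(truth) > 0L) {
    n_reads <- nrow(truth) * depth_per_line
    ids <- character(n_reads); seqs <- character(n_reads)
    luc_rc <- revcomp(template$luc_head)
    border_rc <- revcomp(template$border)
    k <- 0L
    for (r in seq_len(nrow(truth))) {
      flank <- junction_flank(genome, truth$chrom[r], truth$rb_position[r],
                              truth$strand[r], flank_len)
      for (j in seq_len(depth_per_line)) {
        bc <- truth$barcode[r]
        fl <- flank
        if (barcode_sub_rate > 0 && runif(1) < barcode_sub_rate)
          bc <- mutate_one_base(bc)
        if (chimera_rate > 0 && runif(1) < chimera_rate) {
          alt <- sample_insertions(genome, 1L, flank_len + 1L)
          fl <- junction_flank(genome, alt$chrom, alt$rb_position,
                               alt$strand, flank_len)
        }
        k <- k + 1L
        ids[k] <- sprintf("line%d:ins%d:read%d", truth$line_id[r], r, j)
        seqs[k] <- paste0(luc_rc, revcomp(bc), border_rc, revcomp(fl))
      }
    }
  }
  reads <- data.frame(id = ids, seq = seqs, stringsAsFactors = FALSE)
  if (!is.null(path)) write_fastq(reads$id, reads$seq, path)
  invisible(reads)
}

#' Simulate DNA and RNA barcode-count libraries
#'
#' DNA reads are drawn multinomially over lines with near-equal weights
#' (log-normal copy-number jitter); RNA reads are drawn with weights
#' proportional to DNA weight x true transcription level, so untranscribed
#' lines contribute no RNA reads. Reads are barcode-bearing amplicons of
#' the T-DNA template: border + barcode + reporter ORF prefix.
#'
#' @param truth a [generate_cohort()] table.
#' @param template a [tdna_template()].
#' @param dna_depth,rna_depth library sizes (reads).
#' @param dna_weight_jitter_sd log-normal sd of per-line DNA weights;
#'   defaults to the cohort_config value.
#' @param amplicon_luc_len nt of reporter ORF included in each amplicon.
#' @param seed optional integer seed.
#' @param dna_path,rna_path optional FASTQ output paths.
#' @return list with data.frames `dna` and `rna` (columns id, seq).
#' @export
simulate_count_libraries <- function(truth, template = tdna_template(),
                                     dna_depth = 1e6, rna_depth = 1e6,
                                     dna_weight_jitter_sd = NULL,
                                     amplicon_luc_len = 20L, seed = NULL,
                                     dna_path = NULL, rna_path = NULL) {
  cfg <- attr(truth, "config")
  if (is.null(dna_weight_jitter_sd))
    dna_weight_jitter_sd <- if (is.null(cfg)) 0.15 else cfg$dna_weight_jitter_sd
  if (dna_depth < 0 || rna_depth < 0) stop("depths must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  lines <- truth[truth$role == "primary", , drop = FALSE]
  n <- nrow(lines)
  w_dna <- rlnorm(n, 0, dna_weight_jitter_sd)
  w_rna <- w_dna * lines$true_level

  amplicon <- paste0(template$border, lines$barcode,
                     substr(template$luc_head, 1L, amplicon_luc_len))
  draw <- function(depth, w, tag) {
    if (depth == 0 || sum(w) == 0) {
      return(data.frame(id = character(0), seq = character(0),
                        stringsAsFactors = FALSE))
    }
    counts <- as.integer(rmultinom(1L, depth, w))
    seqs <- rep(amplicon, counts)
    data.frame(id = sprintf("%s:read%d", tag, seq_along(seqs)),
               seq = seqs, stringsAsFactors = FALSE)
  }
  dna <- draw(dna_depth, w_dna, "dna")
  rna <- draw(rna_depth, w_rna, "rna")
  if (!is.null(dna_path)) write_fastq(dna$id, dna$seq, dna_path)
  if (!is.null(rna_path)) write_fastq(rna$id, rna$seq, rna_path)
  invisible(list(dna = dna, rna = rna))
}
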