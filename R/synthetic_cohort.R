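#' Configuration for a synthetic transgenic cohort
#'
#' Defaults encode the study conditions the analysis targets: per-type
#' activation probabilities (0.66, 0.27, 0.27) for genic-sense / genic-AS /
#' intergenic insertions, trap-type levels peaking at 10^5 and de novo
#' levels at 10^4 on a log10 scale, and 12-nt line barcodes. Artefact rates
#' default to zero (clean libraries).
#'
#' @param n_lines number of transgenic lines.
#' @param p_activate_genic_sense,p_activate_genic_as,p_activate_intergenic
#'   per-insertion-type activation probabilities.
#' @param log10_level_mean_trap mean log10 relative level for genic-sense
#'   (promoter-trap) activations.
#' @param log10_level_mean_denovo mean log10 level for de novo activations
#'   (genic-AS and intergenic).
#' @param log10_level_sd log10 level standard deviation.
#' @param barcode_length barcode length in nt.
#' @param barcode_sub_rate per-read probability of a single barcode
#'   substitution in the junction library.
#' @param chimera_rate per-read probability that the genomic flank is
#'   replaced by sequence from an unrelated locus.
#' @param collision_rate fraction of lines that share a barcode with
#'   another line.
#' @param multi_insert_rate fraction of lines carrying a second insertion.
#' @param dna_weight_jitter_sd log-normal sd of per-line DNA copy weights.
#' @param edge_margin minimal distance (bp) of an insertion from a
#'   chromosome end, so junction flanks never run off the sequence.
#' @param seed optional integer seed used by [generate_cohort()].
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_lines = 100L,
                          p_activate_genic_sense = 0.66,
                          p_activate_genic_as = 0.27,
                          p_activate_intergenic = 0.27,
                          log10_level_mean_trap = 5,
                          log10_level_mean_denovo = 4,
                          log10_level_sd = 1,
                          barcode_length = 12L,
                          barcode_sub_rate = 0,
                          chimera_rate = 0,
                          collision_rate = 0,
                          multi_insert_rate = 0,
                          dna_weight_jitter_sd = 0.15,
                          edge_margin = 200L,
                          seed = NULL) {
  p <- c(p_activate_genic_sense, p_activate_genic_as, p_activate_intergenic,
         barcode_sub_rate, chimera_rate, collision_rate, multi_insert_rate)
  if (any(p < 0 | p > 1)) stop("probabilities and rates must lie in [0, 1]")
  if (log10_level_mean_trap < 1 || log10_level_mean_trap > 7 ||
      log10_level_mean_denovo < 1 || log10_level_mean_denovo > 7)
    stop("log10 level means must lie within [1, 7]")
  if (log10_level_sd <= 0) stop("log10_level_sd must be positive")
  if (n_lines < 1L) stop("n_lines must be positive")
  structure(list(
    n_lines = as.integer(n_lines),
    p_activate_genic_sense = p_activate_genic_sense,
    p_activate_genic_as = p_activate_genic_as,
    p_activate_intergenic = p_activate_intergenic,
    log10_level_mean_trap = log10_level_mean_trap,
    log10_level_mean_denovo = log10_level_mean_denovo,
    log10_level_sd = log10_level_sd,
    barcode_length = as.integer(barcode_length),
    barcode_sub_rate = barcode_sub_rate,
    chimera_rate = chimera_rate,
    collision_rate = collision_rate,
    multi_insert_rate = multi_insert_rate,
    dna_weight_jitter_sd = dna_weight_jitter_sd,
    edge_margin = as.integer(edge_margin),
    seed = seed), class = "cohort_config")
}

# uniform insertion sites over the genome, away from chromosome ends
sample_insertions <- function(genome, n, margin) {
  lens <- vapply(genome$chromosomes, nchar, integer(1))
  if (any(lens <= 2L * margin)) stop("chromosomes too short for edge margin")
  chrom <- sample(names(lens), n, replace = TRUE, prob = lens)
  pos <- vapply(chrom, function(cn)
    sample.int(lens[[cn]] - 2L * margin, 1L) + margin - 1L, integer(1))
  data.frame(chrom = chrom, rb_position = as.integer(pos),
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Generate a cohort of barcoded single-insert reporter lines
#'
#' Places one promoterless-reporter insertion per line uniformly over the
#' genome, assigns each line a unique 12-nt barcode (unless a collision
#' rate is configured), decides transcriptional activation per insertion
#' type, and draws relative transcription levels as
#' 10^Normal(mean_type, sd) truncated to [10^1, 10^7]. Lines selected for
#' a second insertion (multi-insert rate) receive an extra row with
#' `role = "extra_insert"` sharing the line's barcode.
#'
#' @param genome a [genome_model()].
#' @param config a [cohort_config()].
#' @return data.frame of class `cohort_truth` with one row per insertion:
#'   line_id, barcode, chrom, rb_position (0-based first genomic base at
#'   the RB junction), strand (strand of the reporter CDS),
#'   insertion_type, true_transcribed, true_level, role.
#' @export
generate_cohort <- function(genome, config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_lines
  ins <- sample_insertions(genome, n, config$edge_margin)
  itype <- classify_insertions(ins$chrom, ins$rb_position, ins$strand, genome)

  p_act <- c(genic_sense = config$p_activate_genic_sense,
             genic_as = config$p_activate_genic_as,
             intergenic = config$p_activate_intergenic)[itype]
  active <- runif(n) < p_act
  mu <- ifelse(itype == "genic_sense",
               config$log10_level_mean_trap, config$log10_level_mean_denovo)
  lvl <- ifelse(active,
                pmin(1e7, pmax(1e1, 10^rnorm(n, mu, config$log10_level_sd))),
                0)

  # unique barcodes, then overwrite a configured fraction with collisions
  bc <- random_dna(n, config$barcode_length)
  while (anyDuplicated(bc)) {
    dup <- duplicated(bc)
    bc[dup] <- random_dna(sum(dup), config$barcode_length)
  }
  n_coll <- floor(config$collision_rate * n / 2)
  if (n_coll > 0L && n >= 2L) {
    pick <- matrix(sample.int(n, 2L * n_coll), ncol = 2L)
    bc[pick[, 2L]] <- bc[pick[, 1L]]
  }

  truth <- data.frame(line_id = seq_len(n), barcode = bc,
                      ins, insertion_type = itype,
                      true_transcribed = active, true_level = lvl,
                      role = "primary", stringsAsFactors = FALSE)

  n_multi <- round(config$multi_insert_rate * n)
  if (n_multi > 0L) {
    which_multi <- sample.int(n, n_multi)
    extra <- sample_insertions(genome, n_multi, config$edge_margin)
    extra_df <- data.frame(
      line_id = which_multi, barcode = bc[which_multi], extra,
      insertion_type = classify_insertions(extra$chrom, extra$rb_position,
                                           extra$strand, genome),
      true_transcribed = truth$true_transcribed[which_multi],
      true_level = truth$true_level[which_multi],
      role = "extra_insert", stringsAsFactors = FALSE)
    truth <- rbind(truth, extra_df)
  }
  rownames(truth) <- NULL
  attr(truth, "config") <- config
  class(truth) <- c("cohort_truth", "data.frame")
  truth
}
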