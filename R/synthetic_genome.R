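#' Generate a synthetic mini-genome with gene annotation
#'
#' Builds a multi-chromosome random genome and places non-overlapping
#' protein-coding genes on both strands so that a configurable fraction of
#' the genome is genic (default one half, mirroring the near-equal genic /
#' intergenic split of the A. thaliana genome). Gene lengths are drawn
#' around the value that hits the target fraction; placements use random
#' inter-gene gaps, so generation is deterministic for a fixed seed.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_len chromosome length in bp (>= 10 kb).
#' @param n_genes total number of genes across the genome.
#' @param genic_fraction target fraction of genic bp (default 0.5).
#' @param min_gene_len minimum gene length in bp.
#' @param seed optional integer seed.
#' @return a [genome_model()].
#' @export
generate_genome <- function(n_chrom = 3L, chrom_len = 100000L, n_genes = 60L,
                            genic_fraction = 0.5, min_gene_len = 200L,
                            seed = NULL) {
  if (chrom_len < 10000L) stop("chrom_len must be >= 10 kb")
  if (n_genes < 0L) stop("n_genes must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  chrom_names <- paste0("chr", seq_len(n_chrom))
  chroms <- setNames(random_dna(n_chrom, chrom_len), chrom_names)

  genes <- data.frame(id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), biotype = character(0),
                      stringsAsFactors = FALSE)
  if (n_genes > 0L) {
    per_chrom <- diff(floor(seq(0, n_genes, length.out = n_chrom + 1L)))
    gid <- 0L
    for (ci in seq_len(n_chrom)) {
      g <- per_chrom[ci]
      if (g == 0L) next
      target <- genic_fraction * chrom_len
      mean_len <- target / g
      lens <- NULL
      for (try in 1:20) {
        cand <- pmax(min_gene_len, round(rnorm(g, mean_len, 0.15 * mean_len)))
        if (sum(cand) <= 0.95 * chrom_len) { lens <- cand; break }
      }
      if (is.null(lens))
        stop("gene placement failed: requested gene density too high")
      free <- chrom_len - sum(lens)
      gaps <- as.integer(rmultinom(1L, free, rep(1, g + 1L)))
      starts <- cumsum(c(0L, lens)) [seq_len(g)] + cumsum(gaps[seq_len(g)])
      genes <- rbind(genes, data.frame(
        id = sprintf("gene%04d", gid + seq_len(g)),
        chrom = chrom_names[ci],
        start = as.integer(starts),
        end = as.integer(starts + lens),
        strand = sample(c("+", "-"), g, replace = TRUE),
        biotype = "protein_coding",
        stringsAsFactors = FALSE))
      gid <- gid + g
    }
  }
  genome_model(chroms, genes)
}

#' Simulate wild-type transcribed regions with expression levels
#'
#' Emulates a StringTie-style table of transcribed regions of the wild-type
#' genome: a fraction of annotated genes is marked transcribed (default
#' 0.704) and receives a log-normal FPKM, plus a small complement of
#' intergenic transcribed regions so that genic records make up
#' `genic_region_fraction` (default 0.978) of the table.
#'
#' @param genome a [genome_model()].
#' @param transcribed_gene_fraction fraction of genes transcribed in WT.
#' @param genic_region_fraction fraction of regions tied to gene intervals.
#' @param fpkm_meanlog,fpkm_sdlog log-normal FPKM parameters.
#' @param seed optional integer seed.
#' @return data.frame with columns chrom, start, end, strand, fpkm
#'   (0-based half-open).
#' @export
simulate_wt_expression <- function(genome, transcribed_gene_fraction = 0.704,
                                   genic_region_fraction = 0.978,
                                   fpkm_meanlog = log(10), fpkm_sdlog = 1.2,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- genome$genes
  if (nrow(g) == 0L) stop("genome has no genes to transcribe")
  n_tx <- round(transcribed_gene_fraction * nrow(g))
  tx <- g[sort(sample.int(nrow(g), n_tx)), , drop = FALSE]
  regions <- data.frame(chrom = tx$chrom, start = tx$start, end = tx$end,
                        strand = tx$strand,
                        fpkm = rlnorm(nrow(tx), fpkm_meanlog, fpkm_sdlog),
                        stringsAsFactors = FALSE)
  # intergenic transcribed regions to dilute the genic share
  n_ig <- round(nrow(regions) * (1 - genic_region_fraction) / genic_region_fraction)
  if (n_ig > 0L) {
    lens <- vapply(genome$chromosomes, nchar, integer(1))
    added <- 0L; tries <- 0L
    while (added < n_ig && tries < 200L * n_ig) {
      tries <- tries + 1L
      chrom <- sample(names(lens), 1L, prob = lens)
      w <- sample(300:1500, 1L)
      if (lens[[chrom]] <= w) next
      s <- sample.int(lens[[chrom]] - w, 1L) - 1L
      gc <- g[g$chrom == chrom, , drop = FALSE]
      if (nrow(gc) > 0 && any(s < gc$end & (s + w) > gc$start)) next
      regions <- rbind(regions, data.frame(
        chrom = chrom, start = s, end = s + w,
        strand = sample(c("+", "-"), 1L),
        fpkm = rlnorm(1L, fpkm_meanlog, fpkm_sdlog),
        stringsAsFactors = FALSE))
      added <- added + 1L
    }
  }
  rownames(regions) <- NULL
  regions
}
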