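#' Classify insertion sites as genic-sense, genic-antisense or intergenic
#'
#' The single RB-junction base is tested against annotated protein-coding
#' gene spans (full gene feature, UTRs and introns included). If it falls
#' within at least one gene, the insertion is genic-sense when any
#' overlapping gene lies on the insert strand, else genic-antisense;
#' otherwise it is intergenic.
#'
#' @param chrom,position,strand vectors describing insertion loci
#'   (0-based junction coordinate; strand of the reporter CDS).
#' @param genome a [genome_model()] providing the annotation.
#' @return character vector in {"genic_sense", "genic_as", "intergenic"}.
#' @export
classify_insertions <- function(chrom, position, strand, genome) {
  if (!all(chrom %in% names(genome$chromosomes)))
    stop("insertion on unknown chromosome")
  g <- genome$genes
  g <- g[g$biotype == "protein_coding", , drop = FALSE]
  n <- length(chrom)
  if (nrow(g) == 0L) return(rep("intergenic", n))
  pts <- GenomicRanges::GRanges(chrom,
                                IRanges::IRanges(position + 1L, width = 1L))
  gr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start + 1L, g$end),
                               strand = g$strand)
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(pts, gr, ignore.strand = TRUE))
  out <- rep("intergenic", n)
  if (length(ov) > 0L) {
    qh <- S4Vectors::queryHits(ov)
    same <- strand[qh] == g$strand[S4Vectors::subjectHits(ov)]
    sense <- unique(qh[same])
    any_hit <- unique(qh)
    out[any_hit] <- "genic_as"
    out[sense] <- "genic_sense"
  }
  out
}

#' @rdname classify_insertions
#' @param locus list or one-row data.frame with `chrom`, `position`,
#'   `strand`.
#' @export
classify_insertion_type <- function(locus, genome) {
  classify_insertions(locus$chrom, locus$position, locus$strand, genome)
}

#' Classify lines by reporter x wild-type transcriptional status
#'
#' Joint classification of each line's transcription (level > 0) with the
#' wild-type transcriptional status of its insertion locus: type "i"
#' (reporter transcribed, WT region transcribed), "ii" (untranscribed /
#' transcribed), "iii" (transcribed / untranscribed), "iv" (neither). A
#' locus counts as WT-transcribed when the RB-junction base overlaps at
#' least one WT transcribed region — by default on either strand. FPKM of
#' all overlapping isoform regions is summed.
#'
#' @param chrom,position,strand insertion loci (strand used only when
#'   `strand_matched = TRUE`).
#' @param level relative transcription levels (NA not allowed; omit such
#'   lines upstream).
#' @param wt_regions data.frame chrom/start/end/strand/fpkm (0-based
#'   half-open), as from [simulate_wt_expression()] or
#'   [read_wt_regions()].
#' @param strand_matched require the WT region to lie on the insert strand.
#' @return data.frame with columns wt_type ("i".."iv") and wt_fpkm (NA
#'   when the locus lies outside all WT regions).
#' @export
classify_wt_overlaps <- function(chrom, position, strand, level, wt_regions,
                                 strand_matched = FALSE) {
  if (any(is.na(level))) stop("level must be available for every locus")
  n <- length(chrom)
  pts <- GenomicRanges::GRanges(chrom,
                                IRanges::IRanges(position + 1L, width = 1L))
  wr <- GenomicRanges::GRanges(wt_regions$chrom,
                               IRanges::IRanges(wt_regions$start + 1L,
                                                wt_regions$end),
                               strand = wt_regions$strand)
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(pts, wr, ignore.strand = TRUE))
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  if (strand_matched) {
    keep <- strand[qh] == wt_regions$strand[sh]
    qh <- qh[keep]; sh <- sh[keep]
  }
  fpkm <- rep(NA_real_, n)
  if (length(qh) > 0L) {
    sums <- tapply(wt_regions$fpkm[sh], qh, sum)
    fpkm[as.integer(names(sums))] <- as.numeric(sums)
  }
  wt_tx <- !is.na(fpkm)
  luc_tx <- level > 0
  wt_type <- ifelse(luc_tx & wt_tx, "i",
             ifelse(!luc_tx & wt_tx, "ii",
             ifelse(luc_tx & !wt_tx, "iii", "iv")))
  data.frame(wt_type = wt_type, wt_fpkm = fpkm, stringsAsFactors = FALSE)
}

#' @rdname classify_wt_overlaps
#' @param locus list with `chrom`, `position`, `strand`.
#' @export
classify_wt_overlap <- function(locus, wt_regions, level,
                                strand_matched = FALSE) {
  r <- classify_wt_overlaps(locus$chrom, locus$position, locus$strand,
                            level, wt_regions, strand_matched)
  list(wt_type = r$wt_type[1L], wt_fpkm = r$wt_fpkm[1L])
}
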