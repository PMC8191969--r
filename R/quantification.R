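#' Count barcodes in a barcode-amplicon library
#'
#' Locates the T-DNA border in each read (exact match, both orientations)
#' and tallies the 12 nt immediately on the reporter side. The returned
#' total is the number of reads with a successfully extracted barcode;
#' reads without one are excluded from the total.
#'
#' @param reads character vector of sequences, a data.frame with a `seq`
#'   column, or a FASTQ file path.
#' @param template a [tdna_template()].
#' @return list with `counts` (named integer vector) and `total`.
#' @export
count_barcodes <- function(reads, template = tdna_template()) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_fastq(reads)
  seqs <- if (is.data.frame(reads)) toupper(reads$seq) else toupper(reads)
  if (length(seqs) == 0L)
    return(list(counts = setNames(integer(0), character(0)), total = 0L))
  m <- nchar(template$border)
  bl <- template$barcode_len

  pull <- function(s) {
    pos <- regexpr(template$border, s, fixed = TRUE)
    ifelse(pos > 0L, substr(s, pos + m, pos + m + bl - 1L), NA_character_)
  }
  bc <- pull(seqs)
  miss <- is.na(bc)
  if (any(miss)) bc[miss] <- pull(revcomp(seqs[miss]))
  ok <- !is.na(bc) & nchar(bc) == bl & !grepl("[^ACGT]", bc)
  tab <- table(bc[ok])
  list(counts = setNames(as.integer(tab), names(tab)), total = sum(ok))
}

#' Compute relative transcription levels from DNA/RNA barcode counts
#'
#' Barcodes with a DNA read number <= `min_count` are omitted from the
#' analysis; RNA read numbers <= `min_count` are set to zero before
#' normalization. Each remaining barcode's level is its RNA library
#' frequency divided by its DNA library frequency, multiplied by `scale`:
#' level = (rna / rna_total) / (dna / dna_total) * scale. Library totals
#' are the pre-threshold extracted-read totals. Barcodes absent from the
#' RNA library get level 0.
#'
#' @param dna,rna [count_barcodes()] results (or named count vectors, in
#'   which case the total is their sum).
#' @param min_count read-number threshold applied to both libraries.
#' @param scale multiplier for the frequency ratio.
#' @return data.frame of class `level_table` with columns barcode,
#'   dna_reads, rna_reads, level (NA where omitted), omitted; library
#'   totals in attributes `dna_total` and `rna_total`.
#' @export
compute_levels <- function(dna, rna, min_count = 5L, scale = 10000) {
  as_tab <- function(x) {
    if (is.list(x) && all(c("counts", "total") %in% names(x))) return(x)
    list(counts = x, total = sum(x))
  }
  dna <- as_tab(dna); rna <- as_tab(rna)
  if (rna$total == 0L && length(rna$counts) > 0L && sum(rna$counts) > 0L)
    stop("rna_total is zero but RNA counts are non-zero")
  bcs <- names(dna$counts)
  dna_n <- as.integer(dna$counts)
  rna_n <- as.integer(ifelse(bcs %in% names(rna$counts),
                             rna$counts[bcs], 0L))
  omitted <- dna_n <= min_count
  rna_eff <- ifelse(rna_n <= min_count, 0L, rna_n)
  level <- rep(NA_real_, length(bcs))
  keep <- !omitted
  if (any(keep)) {
    rna_freq <- if (rna$total > 0L) rna_eff[keep] / rna$total else 0
    level[keep] <- rna_freq / (dna_n[keep] / dna$total) * scale
  }
  out <- data.frame(barcode = bcs, dna_reads = dna_n, rna_reads = rna_n,
                    level = level, omitted = omitted,
                    stringsAsFactors = FALSE)
  attr(out, "dna_total") <- dna$total
  attr(out, "rna_total") <- rna$total
  class(out) <- c("level_table", "data.frame")
  out
}
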