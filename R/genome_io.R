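#' Genome model constructor
#'
#' A genome model couples chromosome sequences with a protein-coding gene
#' annotation. Coordinates are 0-based half-open in memory; GFF3 on disk is
#' 1-based inclusive and conversion happens only at the I/O boundary.
#'
#' @param chromosomes named character vector (or list) of chromosome
#'   sequences, A/C/G/T.
#' @param genes data.frame with columns `id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand` ("+"/"-"), `biotype`.
#' @return object of class `genome_model`.
#' @export
genome_model <- function(chromosomes, genes) {
  chromosomes <- as.list(chromosomes)
  if (is.null(names(chromosomes)) || any(names(chromosomes) == ""))
    stop("chromosomes must be named")
  chromosomes <- lapply(chromosomes, assert_dna, what = "chromosome")
  genes <- as.data.frame(genes)
  need <- c("id", "chrom", "start", "end", "strand", "biotype")
  if (!all(need %in% names(genes))) stop("genes must have columns: ", paste(need, collapse = ", "))
  if (nrow(genes) > 0) {
    if (!all(genes$chrom %in% names(chromosomes))) stop("gene on unknown chromosome")
    len <- vapply(chromosomes, nchar, integer(1))[genes$chrom]
    if (any(genes$start < 0 | genes$end > len | genes$start >= genes$end))
      stop("gene interval outside chromosome bounds")
    if (!all(genes$strand %in% c("+", "-"))) stop("gene strand must be + or -")
    # same-strand genes must not overlap (generator guarantee)
    for (key in unique(paste(genes$chrom, genes$strand))) {
      g <- genes[paste(genes$chrom, genes$strand) == key, , drop = FALSE]
      g <- g[order(g$start), , drop = FALSE]
      if (nrow(g) > 1 && any(g$start[-1] < g$end[-nrow(g)]))
        stop("overlapping same-strand genes in annotation")
    }
  }
  structure(list(chromosomes = chromosomes, genes = genes), class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  len <- vapply(x$chromosomes, nchar, integer(1))
  cat("genome_model:", length(len), "chromosome(s),",
      format(sum(len), big.mark = ","), "bp,", nrow(x$genes), "gene(s)\n")
  invisible(x)
}

#' Write a genome model to FASTA + GFF3
#'
#' @param genome a `genome_model`.
#' @param fasta,gff3 output paths.
#' @return invisibly, `c(fasta, gff3)`.
#' @export
write_genome <- function(genome, fasta, gff3) {
  ss <- Biostrings::DNAStringSet(unlist(genome$chromosomes))
  Biostrings::writeXStringSet(ss, fasta, width = 80L)
  g <- genome$genes
  lines <- "##gff-version 3"
  if (nrow(g) > 0) {
    lines <- c(lines, paste(g$chrom, "promtrap", "gene",
                            g$start + 1L, g$end, ".", g$strand, ".",
                            paste0("ID=", g$id, ";biotype=", g$biotype),
                            sep = "\t"))
  }
  writeLines(lines, gff3)
  invisible(c(fasta, gff3))
}

#' Read a genome model from FASTA + GFF3
#'
#' Only `gene` features are retained; `biotype` defaults to
#' "protein_coding" when the attribute is absent.
#'
#' @param fasta,gff3 input paths.
#' @return a `genome_model`.
#' @export
read_genome <- function(fasta, gff3) {
  ss <- Biostrings::readDNAStringSet(fasta)
  chroms <- as.list(as.character(ss))
  names(chroms) <- sub("\\s.*$", "", names(ss))
  gr <- rtracklayer::import(gff3, format = "gff3")
  gr <- gr[gr$type == "gene"]
  genes <- data.frame(
    id = if (length(gr)) as.character(gr$ID) else character(0),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    biotype = if (!is.null(gr$biotype)) as.character(gr$biotype)
              else rep("protein_coding", length(gr)),
    stringsAsFactors = FALSE)
  genome_model(chroms, genes)
}

#' Write / read wild-type transcribed regions
#'
#' BED-like TSV with columns chrom, start, end, strand, fpkm; coordinates
#' 0-based half-open.
#'
#' @param regions data.frame with those columns.
#' @param path file path.
#' @return `read_wt_regions` returns the data.frame; `write_wt_regions`
#'   returns the path invisibly.
#' @export
write_wt_regions <- function(regions, path) {
  stopifnot(all(c("chrom", "start", "end", "strand", "fpkm") %in% names(regions)))
  write.table(regions[, c("chrom", "start", "end", "strand", "fpkm")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_wt_regions
#' @export
read_wt_regions <- function(path) {
  r <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end", "strand", "fpkm") %in% names(r)))
  if (any(r$fpkm <= 0)) stop("wild-type region with non-positive FPKM")
  r
}
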