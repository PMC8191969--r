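#' @importFrom Biostrings DNAStringSet reverseComplement readDNAStringSet
#'   writeXStringSet matchPattern
#' @importFrom stats rnorm runif rbinom rmultinom rlnorm cor.test setNames
#' @importFrom utils write.table read.table head
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement DNA sequences
#'
#' @param x character vector of A/C/G/T sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA sequences
#'
#' @param n number of sequences.
#' @param len length of each sequence (nt).
#' @return character vector of length `n`.
#' @export
random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  apply(m, 1L, paste0, collapse = "")
}

# Hamming distance between two equal-length strings (raw-byte compare).
hamming <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  sum(ra != rb)
}

# round half away from zero at `digits` decimals (base round() is banker's)
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", toupper(x))
  if (any(bad)) stop(what, " contains non-ACGT characters", call. = FALSE)
  toupper(x)
}

#' Read a FASTQ file
#'
#' Qualities are ignored (the simulators emit constant placeholder
#' qualities); only read ids and sequences are returned.
#'
#' @param path path to an uncompressed FASTQ file.
#' @return data.frame with columns `id` and `seq`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) return(data.frame(id = character(0), seq = character(0)))
  if (length(lines) %% 4L != 0L) stop("malformed FASTQ: line count not a multiple of 4")
  idx <- seq(1L, length(lines), by = 4L)
  data.frame(id = sub("^@", "", sub("\\s.*$", "", lines[idx])),
             seq = toupper(lines[idx + 1L]),
             stringsAsFactors = FALSE)
}

#' Write reads to FASTQ
#'
#' @param ids,seqs read identifiers and sequences (equal length).
#' @param path output path.
#' @param qual_char single character used for every base quality.
#' @export
write_fastq <- function(ids, seqs, path, qual_char = "I") {
  stopifnot(length(ids) == length(seqs))
  if (length(ids) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  quals <- vapply(nchar(seqs), function(n) strrep(qual_char, n), character(1))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), path)
  invisible(path)
}

# fetch forward-strand genomic subsequence, 0-based half-open [start0, end0)
genome_fetch <- function(genome, chrom, start0, end0) {
  seqs <- genome$chromosomes
  if (!chrom %in% names(seqs)) stop("unknown chromosome: ", chrom)
  s <- seqs[[chrom]]
  if (start0 < 0 || end0 > nchar(s) || start0 > end0)
    stop("requested interval outside chromosome bounds")
  substr(s, start0 + 1L, end0)
}
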