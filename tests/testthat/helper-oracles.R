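# Independent oracles, coded separately from the package internals.

# literal transcription of the three calling criteria, for one barcode
oracle_call_status <- function(locus_counts, total,
                               min_reads = 2, min_dominance = 0.6) {
  if (length(locus_counts) == 0 || sum(locus_counts) == 0) return("unmapped")
  candidates <- which(locus_counts >= min_reads)
  if (length(candidates) >= 2) return("multi_insert")
  if (length(candidates) == 0) return("low_support")
  if (locus_counts[candidates] / total >= min_dominance) "called"
  else "low_dominance"
}

# exhaustive full-genome Hamming scan via Biostrings::matchPattern (an
# independent scanning engine; the package uses k-mer seed-and-verify)
oracle_scan_flank <- function(flank, genome, max_mm = 3) {
  hits <- NULL
  L <- nchar(flank)
  for (cn in names(genome$chromosomes)) {
    subj <- Biostrings::DNAString(genome$chromosomes[[cn]])
    for (ms in c("+", "-")) {
      pat <- if (ms == "+") flank else promtrap::revcomp(flank)
      m <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mm,
                                    with.indels = FALSE)
      if (length(m) == 0) next
      q0 <- BiocGenerics::start(m) - 1L
      d <- vapply(as.character(m), function(s)
        sum(charToRaw(s) != charToRaw(pat)), numeric(1))
      hits <- rbind(hits, data.frame(chrom = cn, start = q0,
                                     match_strand = ms, mism = as.integer(d),
                                     stringsAsFactors = FALSE))
    }
  }
  if (is.null(hits) || nrow(hits) == 0) return(list(status = "unmapped"))
  best <- min(hits$mism)
  top <- hits[hits$mism == best, , drop = FALSE]
  if (nrow(top) > 1) return(list(status = "multi_mapped"))
  # junction convention: border at the flank 3' end
  pos <- if (top$match_strand == "+") top$start + L - 1L else top$start
  list(status = "mapped", chrom = top$chrom, position = as.integer(pos),
       strand = top$match_strand, mismatches = best)
}

# naive O(n*m) interval scan for insertion-type classification
oracle_classify <- function(chrom, position, strand, genes) {
  vapply(seq_along(chrom), function(i) {
    hit <- genes$chrom == chrom[i] &
      genes$start <= position[i] & position[i] < genes$end
    if (!any(hit)) return("intergenic")
    if (any(genes$strand[hit] == strand[i])) "genic_sense" else "genic_as"
  }, character(1))
}

# plant k substitutions at distinct random positions
plant_substitutions <- function(seq, k) {
  if (k == 0) return(seq)
  pos <- sample.int(nchar(seq), k)
  for (i in pos) {
    old <- substr(seq, i, i)
    substr(seq, i, i) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
  }
  seq
}
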