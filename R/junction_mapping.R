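# -- border location and barcode/flank extraction -----------------------------

# all start offsets (1-based) where `pattern` occurs in `seq` with
# Hamming distance <= max_mm; returns data.frame(offset, mism)
border_hits <- function(seq_raw, pat_raw, max_mm) {
  n <- length(seq_raw); m <- length(pat_raw)
  if (n < m) return(data.frame(offset = integer(0), mism = integer(0)))
  offs <- integer(0); mm <- integer(0)
  for (i in seq_len(n - m + 1L)) {
    d <- sum(seq_raw[i:(i + m - 1L)] != pat_raw)
    if (d <= max_mm) { offs <- c(offs, i); mm <- c(mm, d) }
  }
  data.frame(offset = offs, mism = mm)
}

# collapse overlapping hit offsets (within one pattern length) to the best
collapse_hits <- function(h, m) {
  if (nrow(h) < 2L) return(h)
  h <- h[order(h$offset), , drop = FALSE]
  grp <- cumsum(c(1L, diff(h$offset) >= m))
  keep <- unlist(lapply(split(seq_len(nrow(h)), grp), function(i) {
    i[which.min(h$mism[i])]
  }))
  h[sort(keep), , drop = FALSE]
}

#' Extract barcode and genomic flank from a junction read
#'
#' Locates the T-DNA border in the read (testing both orientations)
#' allowing up to `max_template_mismatch` substitutions, then splits the
#' read at the border: the 12 nt on the reporter side are the line
#' barcode, everything on the genomic side is the flank. The flank is
#' returned in the orientation of the reporter-CDS (insert) strand, so its
#' 3' end abuts the border.
#'
#' @param read read sequence (character).
#' @param template a [tdna_template()].
#' @param max_template_mismatch substitution tolerance for the border.
#' @param min_flank_len flanks shorter than this are discarded.
#' @return list with `status` ("ok", "no_template", "ambiguous_template",
#'   "truncated", "short_flank") and, when ok: `barcode`, `flank`,
#'   `orientation` ("forward" if the border matched the read as given,
#'   "reverse" if it matched the reverse complement).
#' @export
extract_barcode_and_flank <- function(read, template = tdna_template(),
                                      max_template_mismatch = 2L,
                                      min_flank_len = 20L) {
  read <- toupper(read)
  pat_raw <- charToRaw(template$border)
  m <- nchar(template$border)
  # read as given carries the border reverse-complemented (sequencing runs
  # from the reporter ORF outwards); canonical orientation is the one in
  # which the border matches as written
  rc <- revcomp(read)
  hf <- collapse_hits(border_hits(charToRaw(read), pat_raw, max_template_mismatch), m)
  hr <- collapse_hits(border_hits(charToRaw(rc), pat_raw, max_template_mismatch), m)
  total <- nrow(hf) + nrow(hr)
  if (total == 0L) return(list(status = "no_template"))
  if (total > 1L) return(list(status = "ambiguous_template"))
  if (nrow(hf) == 1L) {
    canon <- read; o <- hf$offset[1L]; orient <- "forward"
  } else {
    canon <- rc; o <- hr$offset[1L]; orient <- "reverse"
  }
  bl <- template$barcode_len
  barcode <- substr(canon, o + m, o + m + bl - 1L)
  if (nchar(barcode) < bl || grepl("[^ACGT]", barcode))
    return(list(status = "truncated"))
  flank <- substr(canon, 1L, o - 1L)
  if (nchar(flank) < min_flank_len) return(list(status = "short_flank"))
  list(status = "ok", barcode = barcode, flank = flank, orientation = orient)
}

#' Extract junctions from many reads
#'
#' Vectorised wrapper around [extract_barcode_and_flank()].
#'
#' @param reads character vector of read sequences, or a data.frame with
#'   columns `id` and `seq` (as returned by [read_fastq()]).
#' @inheritParams extract_barcode_and_flank
#' @return data.frame with columns id, status, barcode, flank, orientation
#'   (NA fields where extraction failed).
#' @export
extract_junctions <- function(reads, template = tdna_template(),
                              max_template_mismatch = 2L, min_flank_len = 20L) {
  if (is.data.frame(reads)) {
    ids <- reads$id; seqs <- reads$seq
  } else {
    ids <- sprintf("read%d", seq_along(reads)); seqs <- reads
  }
  out <- lapply(seqs, extract_barcode_and_flank, template = template,
                max_template_mismatch = max_template_mismatch,
                min_flank_len = min_flank_len)
  data.frame(
    id = ids,
    status = vapply(out, `[[`, character(1), "status"),
    barcode = vapply(out, function(x) if (x$status == "ok") x$barcode else NA_character_, character(1)),
    flank = vapply(out, function(x) if (x$status == "ok") x$flank else NA_character_, character(1)),
    orientation = vapply(out, function(x) if (x$status == "ok") x$orientation else NA_character_, character(1)),
    stringsAsFactors = FALSE)
}

# -- k-mer genome index and bounded-mismatch flank mapping --------------------

#' Build an exact k-mer index of a genome
#'
#' Hash index of all forward-strand k-mer start positions per chromosome;
#' minus-strand lookups go through the reverse-complement k-mer. With
#' `k <= min_flank_len / (max_mismatches + 1)`, any flank alignment with at
#' most `max_mismatches` substitutions contains at least one exact seed
#' (pigeonhole), which [map_flank()] exploits.
#'
#' @param genome a [genome_model()].
#' @param k k-mer size.
#' @return object of class `genome_index`.
#' @export
build_genome_index <- function(genome, k = 5L) {
  lens <- vapply(genome$chromosomes, nchar, integer(1))
  if (all(k > lens)) stop("k is larger than every chromosome")
  chroms <- lapply(names(genome$chromosomes), function(cn) {
    s <- genome$chromosomes[[cn]]
    n <- nchar(s)
    if (k > n) return(list(len = n, raw = charToRaw(s), env = new.env(hash = TRUE)))
    kmers <- substring(s, 1:(n - k + 1L), k:n)
    kmap <- split(0:(n - k), kmers)
    list(len = n, raw = charToRaw(s), env = list2env(kmap, hash = TRUE))
  })
  names(chroms) <- names(genome$chromosomes)
  structure(list(k = as.integer(k), chroms = chroms), class = "genome_index")
}

#' Look up exact k-mer positions on both strands
#'
#' @param index a [build_genome_index()] handle.
#' @param kmer query of length `index$k`.
#' @return data.frame with columns chrom, pos (0-based start of the
#'   occupied window on the forward strand), strand.
#' @export
genome_index_lookup <- function(index, kmer) {
  kmer <- toupper(kmer)
  if (nchar(kmer) != index$k) stop("query length must equal index k")
  kmer_rc <- revcomp(kmer)
  res <- lapply(names(index$chroms), function(cn) {
    env <- index$chroms[[cn]]$env
    p_f <- if (!is.null(env[[kmer]])) env[[kmer]] else integer(0)
    p_r <- if (!is.null(env[[kmer_rc]])) env[[kmer_rc]] else integer(0)
    data.frame(chrom = rep(cn, length(p_f) + length(p_r)),
               pos = c(p_f, p_r),
               strand = rep(c("+", "-"), c(length(p_f), length(p_r))),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# all genome locations matching `pat` (as written, against the forward
# strand raws) with Hamming distance <= max_mm, via seed-and-verify
seed_verify <- function(pat, index, max_mm) {
  L <- nchar(pat)
  k <- index$k
  ns <- max_mm + 1L
  if (L < ns * k)
    stop("flank shorter than (max_mismatches + 1) * k; pigeonhole seeding invalid")
  offs0 <- floor((seq_len(ns) - 1L) * L / ns)      # disjoint seed offsets, 0-based
  seeds <- substring(pat, offs0 + 1L, offs0 + k)
  pat_raw <- charToRaw(pat)
  hits <- list()
  for (cn in names(index$chroms)) {
    ch <- index$chroms[[cn]]
    cand <- integer(0)
    for (j in seq_len(ns)) {
      p <- ch$env[[seeds[j]]]
      if (!is.null(p)) cand <- c(cand, p - offs0[j])
    }
    cand <- unique(cand[cand >= 0L & cand <= ch$len - L])
    if (length(cand) == 0L) next
    d <- vapply(cand, function(q) sum(ch$raw[(q + 1L):(q + L)] != pat_raw),
                numeric(1))
    keep <- d <= max_mm
    if (any(keep))
      hits[[cn]] <- data.frame(chrom = cn, start = cand[keep],
                               mism = as.integer(d[keep]),
                               stringsAsFactors = FALSE)
  }
  if (length(hits) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      mism = integer(0)))
  do.call(rbind, c(hits, list(make.row.names = FALSE)))
}

#' Map a genomic flank to the reference with bounded mismatches
#'
#' Seed-and-verify search over both strands for all locations within
#' `max_mismatches` substitutions of the full flank (no indels). The
#' single best-distance location is reported with `unique = TRUE`; ties at
#' the best distance are never broken and yield status "multi_mapped".
#' The reported `position` is the 0-based forward-strand coordinate of the
#' genomic base adjacent to the T-DNA border (the RB junction), and
#' `strand` is the strand on which the reporter CDS reads 5'->3'.
#'
#' @param flank flank sequence. With the default `border_end = "3prime"`
#'   the flank is oriented as on the insert strand (3' end at the border,
#'   the [extract_barcode_and_flank()] convention); use "5prime" for a
#'   flank reading away from the border.
#' @param index a [build_genome_index()] handle.
#' @param max_mismatches maximal substitutions over the full flank.
#' @param border_end which end of the flank abuts the border.
#' @param n_cap maximal number of non-ACGT characters tolerated.
#' @param min_flank_len flanks shorter than this are rejected.
#' @return list with `status` ("mapped", "multi_mapped", "unmapped",
#'   "low_quality", "short_flank") and, when mapped: `chrom`, `position`,
#'   `strand`, `mismatches`, `unique`.
#' @export
map_flank <- function(flank, index, max_mismatches = 3L,
                      border_end = c("3prime", "5prime"),
                      n_cap = 2L, min_flank_len = 20L) {
  border_end <- match.arg(border_end)
  flank <- toupper(flank)
  L <- nchar(flank)
  if (L < min_flank_len) return(list(status = "short_flank"))
  n_bad <- L - sum(charToRaw(flank) %in% charToRaw("ACGT"))
  if (n_bad > n_cap) return(list(status = "low_quality"))

  h_plus <- seed_verify(flank, index, max_mismatches)          # flank on + strand
  h_minus <- seed_verify(revcomp(flank), index, max_mismatches) # flank on - strand
  hits <- rbind(
    if (nrow(h_plus)) cbind(h_plus, match_strand = "+"),
    if (nrow(h_minus)) cbind(h_minus, match_strand = "-"))
  if (is.null(hits) || nrow(hits) == 0L) return(list(status = "unmapped"))
  best <- min(hits$mism)
  top <- hits[hits$mism == best, , drop = FALSE]
  if (nrow(top) > 1L) return(list(status = "multi_mapped", unique = FALSE))

  q <- top$start[1L]; m <- top$match_strand[1L]
  if (border_end == "3prime") {
    position <- if (m == "+") q + L - 1L else q
    strand <- m
  } else {
    position <- if (m == "+") q else q + L - 1L
    strand <- if (m == "+") "-" else "+"
  }
  list(status = "mapped", chrom = top$chrom[1L], position = as.integer(position),
       strand = strand, mismatches = best, unique = TRUE)
}

#' Map many flanks
#'
#' @param flanks character vector of flank sequences.
#' @inheritParams map_flank
#' @return data.frame with columns flank, status, chrom, position, strand,
#'   mismatches.
#' @export
map_flanks <- function(flanks, index, max_mismatches = 3L,
                       border_end = "3prime", n_cap = 2L, min_flank_len = 20L) {
  uf <- unique(flanks)
  res <- lapply(uf, map_flank, index = index, max_mismatches = max_mismatches,
                border_end = border_end, n_cap = n_cap,
                min_flank_len = min_flank_len)
  tab <- data.frame(
    flank = uf,
    status = vapply(res, `[[`, character(1), "status"),
    chrom = vapply(res, function(x) if (x$status == "mapped") x$chrom else NA_character_, character(1)),
    position = vapply(res, function(x) if (x$status == "mapped") x$position else NA_integer_, integer(1)),
    strand = vapply(res, function(x) if (x$status == "mapped") x$strand else NA_character_, character(1)),
    mismatches = vapply(res, function(x) if (x$status == "mapped") x$mismatches else NA_integer_, integer(1)),
    stringsAsFactors = FALSE)
  tab[match(flanks, uf), , drop = FALSE]
}
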