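#' Aggregate mapped junctions into per-barcode locus support tables
#'
#' Groups reads by exact barcode, collapses loci whose positions differ by
#' at most `merge_window` bp on the same chromosome and strand (summing
#' read counts, keeping the modal position; ties go to the smaller
#' coordinate), and records the total number of reads carrying each
#' barcode, including reads whose flank did not map — those contribute to
#' the total only.
#'
#' @param junctions data.frame with one row per extracted read: columns
#'   `barcode`, `chrom`, `position`, `strand` (`chrom` NA for unmapped
#'   reads).
#' @param merge_window maximal position difference (bp) collapsed into one
#'   locus.
#' @return list of class `pair_support` with elements `loci` (data.frame
#'   barcode, chrom, position, strand, count) and `totals` (data.frame
#'   barcode, total).
#' @export
aggregate_pairs <- function(junctions, merge_window = 5L) {
  if (merge_window < 0L) stop("merge_window must be >= 0")
  stopifnot(all(c("barcode", "chrom", "position", "strand") %in% names(junctions)))
  totals <- as.data.frame(table(barcode = junctions$barcode),
                          stringsAsFactors = FALSE)
  names(totals) <- c("barcode", "total")

  mapped <- junctions[!is.na(junctions$chrom), , drop = FALSE]
  loci <- data.frame(barcode = character(0), chrom = character(0),
                     position = integer(0), strand = character(0),
                     count = integer(0), stringsAsFactors = FALSE)
  if (nrow(mapped) > 0L) {
    key <- paste(mapped$barcode, mapped$chrom, mapped$strand, sep = "\r")
    parts <- split(mapped$position, key)
    rows <- lapply(names(parts), function(k) {
      pos <- sort(parts[[k]])
      grp <- cumsum(c(1L, diff(pos) > merge_window))
      info <- strsplit(k, "\r", fixed = TRUE)[[1L]]
      cl <- lapply(split(pos, grp), function(p) {
        tab <- table(p)
        modal <- as.integer(names(tab)[which.max(tab)])  # tie -> smallest
        c(modal, length(p))
      })
      data.frame(barcode = info[1L], chrom = info[2L],
                 position = vapply(cl, `[[`, numeric(1), 1L),
                 strand = info[3L],
                 count = as.integer(vapply(cl, `[[`, numeric(1), 2L)),
                 stringsAsFactors = FALSE)
    })
    loci <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  structure(list(loci = loci, totals = totals), class = "pair_support")
}

#' Call precise locus-barcode pairs
#'
#' Applies the three calling criteria per barcode: (1) candidate loci need
#' at least `min_reads` supporting reads; (2) the candidate must account
#' for at least `min_dominance` of ALL reads carrying the barcode,
#' artefact and unmapped reads included; (3) barcodes supporting two or
#' more distinct candidate loci are excluded as multi-insert (or barcode
#' collision) cases and never called.
#'
#' @param supports a [aggregate_pairs()] result.
#' @param min_reads minimal reads for a candidate locus.
#' @param min_dominance minimal fraction of the barcode's reads on the
#'   called locus.
#' @return data.frame with one row per barcode: barcode, status ("called",
#'   "low_support", "low_dominance", "multi_insert", "unmapped"), chrom,
#'   position, strand (NA unless called), support_reads,
#'   dominance_fraction, total_reads.
#' @export
call_lines <- function(supports, min_reads = 2L, min_dominance = 0.6) {
  stopifnot(inherits(supports, "pair_support"))
  totals <- supports$totals
  if (anyDuplicated(totals$barcode))
    stop("duplicate barcode entries in support table")
  loci_by_bc <- split(supports$loci, supports$loci$barcode)

  one <- function(bc, total) {
    l <- loci_by_bc[[bc]]
    na_row <- list(chrom = NA_character_, position = NA_integer_,
                   strand = NA_character_)
    if (is.null(l) || nrow(l) == 0L) {
      return(c(list(barcode = bc, status = "unmapped"), na_row,
               list(support_reads = 0L, dominance_fraction = 0,
                    total_reads = total)))
    }
    top <- l[which.max(l$count), , drop = FALSE]
    dom <- top$count / total
    cand <- l[l$count >= min_reads, , drop = FALSE]
    if (nrow(cand) >= 2L) {
      status <- "multi_insert"; locus <- na_row
    } else if (nrow(cand) == 1L) {
      if (dom >= min_dominance) {
        status <- "called"
        locus <- list(chrom = cand$chrom, position = cand$position,
                      strand = cand$strand)
      } else {
        status <- "low_dominance"; locus <- na_row
      }
    } else {
      status <- "low_support"; locus <- na_row
    }
    c(list(barcode = bc, status = status), locus,
      list(support_reads = top$count, dominance_fraction = dom,
           total_reads = total))
  }
  rows <- Map(one, totals$barcode, totals$total)
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
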