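INSERTION_TYPES <- c("genic_sense", "genic_as", "intergenic")
WT_TYPES <- c("i", "ii", "iii", "iv")

as_type_counts <- function(x, types, col) {
  if (is.data.frame(x)) {
    tab <- table(factor(x[[col]], levels = types))
    setNames(as.integer(tab), types)
  } else {
    if (!all(names(x) %in% types)) stop("unknown type names in counts")
    out <- setNames(integer(length(types)), types)
    out[names(x)] <- as.integer(x)
    out
  }
}

#' Insertion-type counts and percentages
#'
#' Counts and 1-decimal percentages (half-away-from-zero rounding) of the
#' genic-sense / genic-antisense / intergenic insertion types over all
#' called lines, plus the transcribed fraction per type when level data
#' are present.
#'
#' @param x data.frame of called records with column `insertion_type`
#'   (and optionally `level`), or a named count vector.
#' @return list with `counts`, `percent`, and (when levels are available)
#'   `transcribed_fraction` per type.
#' @export
type_fractions <- function(x) {
  counts <- as_type_counts(x, INSERTION_TYPES, "insertion_type")
  n <- sum(counts)
  if (n == 0L) stop("no called records")
  out <- list(counts = counts,
              percent = round_half_up(100 * counts / n, 1L))
  if (is.data.frame(x) && "level" %in% names(x)) {
    tx <- !is.na(x$level) & x$level > 0
    out$transcribed_fraction <- vapply(INSERTION_TYPES, function(tp) {
      sel <- x$insertion_type == tp & !is.na(x$level)
      if (!any(sel)) NA_real_ else mean(tx[sel])
    }, numeric(1))
  }
  out
}

#' Normalized activation fraction within a stratum
#'
#' 100 * active / (active + inactive), rounded to one decimal. Accepts
#' counts or already-rounded percentages (the ratio is scale-free).
#'
#' @param active,inactive abundances of the transcribed and untranscribed
#'   classes in the stratum.
#' @return percentage at one decimal; NA when the stratum is empty.
#' @export
normalize_activation <- function(active, inactive) {
  tot <- active + inactive
  if (tot == 0) return(NA_real_)
  round_half_up(100 * active / tot, 1L)
}

#' Fractions of the four reporter x wild-type transcription types
#'
#' Raw fractions of types i-iv over all lines, plus the stratum-normalized
#' activation fractions: within WT-untranscribed loci, n_iii /
#' (n_iii + n_iv); within WT-transcribed loci, n_i / (n_i + n_ii); both as
#' 1-decimal percentages.
#'
#' @param x data.frame with column `wt_type`, or a named count vector
#'   (names "i".."iv").
#' @return list with `counts`, `percent`, `activation_untranscribed`,
#'   `activation_transcribed`.
#' @export
wt_overlap_fractions <- function(x) {
  counts <- as_type_counts(x, WT_TYPES, "wt_type")
  n <- sum(counts)
  if (n == 0L) stop("no classified records")
  list(counts = counts,
       percent = round_half_up(100 * counts / n, 1L),
       activation_untranscribed = normalize_activation(counts[["iii"]],
                                                       counts[["iv"]]),
       activation_transcribed = normalize_activation(counts[["i"]],
                                                     counts[["ii"]]))
}

#' Percentile bins of transcription levels
#'
#' Percentile rank among the transcribed lines only, split into thirds:
#' Low (percentiles 1-33), Mid (34-66), High (67-100). Ties share the
#' higher bin.
#'
#' @param levels positive transcription levels of transcribed lines.
#' @return factor with levels Low/Mid/High.
#' @export
percentile_bins <- function(levels) {
  if (length(levels) < 3L) stop("need at least 3 transcribed lines")
  if (any(levels <= 0)) stop("percentile bins are defined for transcribed lines")
  n <- length(levels)
  r <- rank(levels, ties.method = "max")
  bin <- ifelse(3 * r <= n, "Low", ifelse(3 * r <= 2 * n, "Mid", "High"))
  factor(bin, levels = c("Low", "Mid", "High"))
}

# decade bin of a level: ND for 0/NA, else floor(log10) clamped to [1, 7]
decade_bin <- function(level) {
  lab <- c("ND", paste0("10^", 1:7))
  out <- rep("ND", length(level))
  pos <- !is.na(level) & level > 0
  out[pos] <- paste0("10^", pmin(7L, pmax(1L, floor(log10(level[pos])))))
  factor(out, levels = lab)
}

#' Decade histogram of transcription levels per insertion type
#'
#' Counts of lines per decade bin (ND, 10^1 .. 10^7; bin = floor(log10)
#' clamped to [1,7]) for each insertion type, with fractions normalized
#' within type.
#'
#' @param records data.frame with columns `insertion_type` and `level`
#'   (NA treated as ND).
#' @return list with matrices `counts` and `fraction`
#'   (type x bin; fraction rows sum to 1).
#' @export
decade_histogram <- function(records) {
  bins <- decade_bin(records$level)
  types <- factor(records$insertion_type, levels = INSERTION_TYPES)
  counts <- table(type = types, bin = bins)
  frac <- counts / pmax(1L, rowSums(counts))
  list(counts = unclass(counts), fraction = unclass(frac))
}

#' Lower/higher transcription-level split per insertion type
#'
#' Transcribed lines are split at the decade boundary: levels in the
#' 10^1-10^4 decades are "lower", 10^5-10^7 "higher"; fractions are
#' normalized to the transcribed lines of each insertion type.
#'
#' @param records data.frame with columns `insertion_type` and `level`.
#' @return matrix (type x c(lower, higher)) of fractions; rows of types
#'   with no transcribed line are NA.
#' @export
low_high_split <- function(records) {
  tx <- records[!is.na(records$level) & records$level > 0, , drop = FALSE]
  dec <- pmin(7L, pmax(1L, floor(log10(tx$level))))
  out <- matrix(NA_real_, nrow = length(INSERTION_TYPES), ncol = 2L,
                dimnames = list(INSERTION_TYPES, c("lower", "higher")))
  for (tp in INSERTION_TYPES) {
    sel <- tx$insertion_type == tp
    if (any(sel)) {
      lo <- mean(dec[sel] <= 4L)
      out[tp, ] <- c(lo, 1 - lo)
    }
  }
  out
}

#' Spearman correlation between reporter levels and wild-type FPKM
#'
#' Rank correlation (average ranks for ties) between the relative
#' transcription levels of type-i lines and the FPKM of their wild-type
#' loci.
#'
#' @param level,wt_fpkm paired numeric vectors (type-i lines).
#' @return list with `rho`, `p`, `n`; rho is NA (flagged) when either
#'   vector is constant.
#' @export
spearman_vs_wt <- function(level, wt_fpkm) {
  stopifnot(length(level) == length(wt_fpkm))
  if (length(level) < 3L) stop("need at least 3 type-i lines")
  if (length(unique(level)) < 2L || length(unique(wt_fpkm)) < 2L)
    return(list(rho = NA_real_, p = NA_real_, n = length(level),
                flagged = "constant input"))
  ct <- suppressWarnings(cor.test(level, wt_fpkm, method = "spearman",
                                  exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(level))
}

#' Expected Mendelian recovery of transgenic lines
#'
#' With a hemizygous T1 parent, one fourth of T2 seeds are expected to be
#' wild type; growing several seeds per line recovers the line unless all
#' sampled seeds are wild type. probability = 1 - wt_fraction ^
#' seeds_per_line; expected_count = round(n_lines * probability).
#'
#' @param n_lines number of transgenic lines.
#' @param seeds_per_line seeds grown per line (>= 1).
#' @param wt_fraction expected wild-type seed fraction.
#' @return list with `probability` and `expected_count`.
#' @export
expected_recovery <- function(n_lines, seeds_per_line, wt_fraction = 1 / 4) {
  if (seeds_per_line < 1L) stop("seeds_per_line must be >= 1")
  if (wt_fraction < 0 || wt_fraction > 1) stop("wt_fraction must lie in [0, 1]")
  p <- 1 - wt_fraction^seeds_per_line
  list(probability = p, expected_count = round(n_lines * p))
}

#' Cohort-level summary of an annotated insertion table
#'
#' Computes every cohort statistic in one pass: insertion-type fractions,
#' reporter x WT type fractions with stratum-normalized activation,
#' percentile bins, the per-type decade histogram, the lower/higher level
#' split, and the Spearman correlation between type-i levels and WT FPKM.
#'
#' @param records annotated insertion records: columns `insertion_type`,
#'   `level`, `wt_type`, `wt_fpkm`.
#' @return list of class `cohort_summary`.
#' @export
cohort_summary <- function(records) {
  has_level <- !is.na(records$level)
  tx_levels <- records$level[has_level & records$level > 0]
  sp <- NULL
  type_i <- records[has_level & !is.na(records$wt_type) &
                      records$wt_type == "i", , drop = FALSE]
  if (nrow(type_i) >= 3L) sp <- spearman_vs_wt(type_i$level, type_i$wt_fpkm)
  structure(list(
    n_called = nrow(records),
    n_transcribed = length(tx_levels),
    insertion_types = type_fractions(records),
    wt_types = if (any(!is.na(records$wt_type)))
      wt_overlap_fractions(records[!is.na(records$wt_type), , drop = FALSE])
      else NULL,
    percentile_bins = if (length(tx_levels) >= 3L)
      table(percentile_bins(tx_levels)) else NULL,
    decade_histogram = decade_histogram(records),
    low_high = low_high_split(records),
    spearman_type_i = sp), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary:", x$n_called, "called lines,",
      x$n_transcribed, "transcribed\n")
  cat("Insertion types (%):\n")
  print(x$insertion_types$percent)
  if (!is.null(x$wt_types)) {
    cat("Reporter x WT types (%):\n")
    print(x$wt_types$percent)
    cat(sprintf("Activation in WT-untranscribed loci: %.1f%%\n",
                x$wt_types$activation_untranscribed))
    cat(sprintf("Activation in WT-transcribed loci:   %.1f%%\n",
                x$wt_types$activation_transcribed))
  }
  if (!is.null(x$spearman_type_i) && !is.na(x$spearman_type_i$rho))
    cat(sprintf("Spearman (type i level vs WT FPKM): rho = %.3f, p = %.3g (n = %d)\n",
                x$spearman_type_i$rho, x$spearman_type_i$p,
                x$spearman_type_i$n))
  invisible(x)
}
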