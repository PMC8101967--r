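# Internal tandem-repeat detection (self-contained, in the spirit of Tandem
# Repeats Finder) and conserved/divergent region architecture of a family.

#' Find tandem repeats inside a sequence
#'
#' For every candidate period p (ranked by k-mer autocorrelation: the match
#' fraction between the sequence and itself shifted by p), positions where
#' `seq[i] == seq[i+p]` are scanned for maximal runs whose windowed match
#' fraction stays at or above `min_match`; each run is reported as a repeat
#' of period p with fractional copy number `(end-start)/p`. Overlapping
#' calls at similar periods are reduced to the best-scoring one
#' (`copy_number x period x percent_match`), while nested repeats at clearly
#' different scales (period ratio >= 2) are all reported.
#'
#' @param seq DNA string (at least `2*min_period` long)
#' @param min_period,max_period period bounds in bp
#' @param min_units minimum (fractional) copy number to report (default 1.5)
#' @param min_match minimum per-position match fraction within the run
#' @return data.frame: start, end (0-based half-open), period, copy_number,
#'   unit_consensus, percent_match, score; empty when none found
#' @export
find_tandem_repeats <- function(seq, min_period = 2L, max_period = 200L,
                                min_units = 1.5, min_match = 0.8) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 2L * min_period) stop("sequence shorter than twice min_period")
  v <- chars(seq)
  max_period <- min(max_period, n %/% 2L)
  calls <- list()
  for (p in min_period:max_period) {
    eq <- v[seq_len(n - p)] == v[(p + 1L):n]
    if (mean(eq) < min_match / 2 && sum(eq) < p) next   # autocorrelation gate
    runs <- match_runs(eq, min_match, min_len = max(p %/% 2L, 4L))
    for (r in runs) {
      start <- r[1] - 1L                      # 0-based
      end <- r[2] + p                         # half-open, includes last unit
      cn <- (end - start) / p
      if (cn < min_units) next
      pm <- mean(eq[r[1]:r[2]])
      unit <- unit_consensus(v, start, end, p)
      calls[[length(calls) + 1L]] <- data.frame(
        start = start, end = end, period = p, copy_number = round(cn, 2),
        unit_consensus = unit, percent_match = round(pm, 3),
        score = cn * p * pm, stringsAsFactors = FALSE)
    }
  }
  if (!length(calls)) return(empty_repeats())
  out <- do.call(rbind, calls)
  out <- out[order(-out$score), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(out))) {
      if (j == i || !keep[j] || out$score[j] > out$score[i]) next
      ov <- min(out$end[i], out$end[j]) - max(out$start[i], out$start[j])
      shorter <- min(out$end[i] - out$start[i], out$end[j] - out$start[j])
      ratio <- max(out$period[i], out$period[j]) / min(out$period[i], out$period[j])
      if (ov > 0.5 * shorter && ratio < 2) keep[j] <- FALSE
    }
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$start, out$period), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# maximal runs of eq (logical): grown while the cumulative match fraction
# stays at or above min_match AND the last `w` positions stay locally
# repeat-like (at least half matches), then trimmed to end on a match
match_runs <- function(eq, min_match, min_len, w = 12L) {
  runs <- list()
  n <- length(eq)
  i <- 1L
  while (i <= n) {
    if (!eq[i]) { i <- i + 1L; next }
    j <- i; mism <- 0L; last_good <- i; win_m <- 0L
    while (j <= n) {
      if (!eq[j]) mism <- mism + 1L else { last_good <- j; win_m <- win_m + 1L }
      if (j - i + 1L > w && eq[j - w]) win_m <- win_m - 1L
      if ((j - i + 1L) >= 4L && mism / (j - i + 1L) > 1 - min_match) break
      if ((j - i + 1L) >= w && win_m < w / 2) break
      j <- j + 1L
    }
    if (last_good - i + 1L >= min_len)
      runs[[length(runs) + 1L]] <- c(i, last_good)
    i <- max(j, last_good) + 1L
  }
  runs
}

unit_consensus <- function(v, start, end, p) {
  seg <- v[(start + 1L):min(end, length(v))]
  full <- length(seg) %/% p
  if (full == 0L) return(paste(seg[seq_len(min(p, length(seg)))], collapse = ""))
  m <- matrix(seg[seq_len(full * p)], ncol = p, byrow = TRUE)
  paste(apply(m, 2, function(col) names(sort(table(col), decreasing = TRUE))[1]),
        collapse = "")
}

empty_repeats <- function() data.frame(
  start = integer(), end = integer(), period = integer(),
  copy_number = numeric(), unit_consensus = character(),
  percent_match = numeric(), score = numeric(), stringsAsFactors = FALSE)

#' Conserved/divergent region architecture of an aligned family
#'
#' Sliding-window (default 50 columns) mean pairwise identity over the
#' family alignment; windows below `threshold` are labeled `divergent`,
#' adjacent same-label windows merged. Segments tile the alignment.
#'
#' @param aligned named character vector of >= 2 aligned copies
#' @param window window width in columns
#' @param threshold identity below which a window is divergent (default 0.6)
#' @return data.frame: start, end (1-based alignment columns, inclusive),
#'   label (conserved/divergent), mean_identity
#' @export
region_architecture <- function(aligned, window = 50L, threshold = 0.6) {
  m <- aln_matrix(aligned)
  if (nrow(m) < 2L)
    return(data.frame(start = 1L, end = ncol(m), label = "conserved",
                      mean_identity = NA_real_, stringsAsFactors = FALSE))
  ci <- column_identity(m)
  sm <- running_mean(ci, window)
  lab <- ifelse(!is.na(sm) & sm < threshold, "divergent", "conserved")
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  data.frame(start = starts, end = ends, label = r$values,
             mean_identity = vapply(seq_along(starts), function(i)
               mean(ci[starts[i]:ends[i]], na.rm = TRUE), 0),
             stringsAsFactors = FALSE)
}
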