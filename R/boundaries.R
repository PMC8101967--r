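# Element boundary inference from multi-copy alignments, imperfect-TIR
# detection by self inverted-repeat search, TSD detection, and per-copy
# classification into family candidates, group members and remnants.

aln_matrix <- function(aligned) {
  if (is.list(aligned)) aligned <- unlist(aligned)
  do.call(rbind, strsplit(toupper(aligned), "", fixed = TRUE))
}

# per-column mean pairwise identity with pairwise deletion of gaps
column_identity <- function(m) {
  apply(m, 2, function(col) {
    col <- col[col != "-" & col != "."]
    n <- length(col)
    if (n < 2L) return(NA_real_)
    tab <- table(col)
    same <- sum(tab * (tab - 1L)) / 2
    same / (n * (n - 1L) / 2)
  })
}

# windowed mean with NA (gap-dominated) columns counted as zero identity:
# otherwise small mafft-anchored islands of chance flank homology, padded by
# gap columns, would score as perfectly conserved
running_mean <- function(x, w) {
  x0 <- ifelse(is.na(x), 0, x)
  n <- length(x)
  if (n < w) return(rep(mean(x0), n))
  cs <- cumsum(c(0, x0))
  out <- numeric(n)
  for (i in seq_len(n)) {
    a <- max(1L, i - w %/% 2L); b <- min(n, i + w %/% 2L)
    out[i] <- (cs[b + 1L] - cs[a]) / (b - a + 1L)
  }
  out
}

#' Infer element limits from a multiple alignment of copies with flanks
#'
#' Flanks of independently transposed copies are unrelated, so mean pairwise
#' column identity collapses outside the element. Scanning outward from the
#' conserved core, the boundary is placed at the outermost column where the
#' identity (smoothed over a `window`-column running mean) stays at or above
#' `threshold`. An end is `sharp` when the identity transition happens within
#' 5 columns, `fuzzy` otherwise, and `unresolved` when the conserved run
#' touches the alignment edge (identical flanks, e.g. segmental duplication,
#' or an alignment lacking flanks).
#'
#' @param aligned named character vector of aligned copies (with flanks)
#' @param threshold column identity threshold (default 0.5)
#' @param window smoothing window in columns (default 15)
#' @return a `BoundaryCall`: list with `col_start`, `col_end` (1-based
#'   alignment columns, inclusive), `conf5`, `conf3` (sharp/fuzzy/unresolved),
#'   `support` (copy count), `per_copy` data.frame of 0-based half-open
#'   intervals on each ungapped copy sequence
#' @export
infer_boundaries <- function(aligned, threshold = 0.5, window = 15L) {
  m <- aln_matrix(aligned)
  if (nrow(m) < 2L) {
    return(structure(list(col_start = NA_integer_, col_end = NA_integer_,
                          conf5 = "unresolved", conf3 = "unresolved",
                          support = nrow(m), per_copy = NULL),
                     class = "BoundaryCall"))
  }
  ci <- column_identity(m)
  sm <- running_mean(ci, window)
  core <- which.max(running_mean(ci, 51L))
  conserved <- !is.na(sm) & sm >= threshold
  if (!conserved[core]) core <- which(conserved)[1]
  if (is.na(core) || !length(core)) {
    return(structure(list(col_start = NA_integer_, col_end = NA_integer_,
                          conf5 = "unresolved", conf3 = "unresolved",
                          support = nrow(m), per_copy = NULL),
                     class = "BoundaryCall"))
  }
  L <- core; while (L > 1L && conserved[L - 1L]) L <- L - 1L
  Rr <- core; while (Rr < length(conserved) && conserved[Rr + 1L]) Rr <- Rr + 1L
  # the running mean bleeds past a sharp transition by ~window/2 columns;
  # trim each end back to a column that clears the threshold AND starts a
  # sustained conserved stretch (10 columns inward), so isolated
  # chance-conserved flank columns do not stop the trim early
  ci0 <- ifelse(is.na(ci), 0, ci)
  inward_ok <- function(at, dir) {
    idx <- seq(at, by = dir, length.out = 10L)
    idx <- idx[idx >= 1L & idx <= length(ci0)]
    mean(ci0[idx]) >= max(threshold, 0.6)
  }
  while (L < Rr && (is.na(ci[L]) || ci[L] < threshold || !inward_ok(L, +1L)))
    L <- L + 1L
  while (Rr > L && (is.na(ci[Rr]) || ci[Rr] < threshold || !inward_ok(Rr, -1L)))
    Rr <- Rr - 1L
  conf_end <- function(at, dir) {
    if ((dir < 0 && at <= 1L) || (dir > 0 && at >= ncol(m))) return("unresolved")
    # transition width: columns between raw identity >=0.7 inside and <=0.3 outside
    ins <- at; steps <- 0L
    i <- at
    while (i >= 1L && i <= ncol(m) && steps <= 12L) {
      v <- ci[i]
      if (!is.na(v) && v <= 0.3) break
      i <- i + dir; steps <- steps + 1L
    }
    if (steps <= 5L) "sharp" else "fuzzy"
  }
  structure(list(col_start = L, col_end = Rr,
                 conf5 = conf_end(L, -1L), conf3 = conf_end(Rr, +1L),
                 support = nrow(m),
                 per_copy = map_columns(m, rownames(m) %||% names(aligned), L, Rr)),
            class = "BoundaryCall")
}

map_columns <- function(m, labels, L, Rr) {
  res <- lapply(seq_len(nrow(m)), function(r) {
    nongap <- m[r, ] != "-" & m[r, ] != "."
    cum <- cumsum(nongap)
    data.frame(label = labels[r] %||% as.character(r),
               start = if (L > 1L) cum[L - 1L] else 0L,   # 0-based
               end = cum[Rr], stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Search a sequence for terminal inverted repeats
#'
#' Enumerates anchor pairs near the two sequence ends and extends inward
#' while the cumulative mismatch fraction stays at or below
#' `max_mismatch_frac`, stopping after `stop_run` consecutive mismatches.
#' For each anchor pair the best-scoring prefix (score = length - 2 x
#' mismatches) of length at least `min_len` is reported. Candidates are
#' ranked by score; `require_gg` keeps only candidates whose 5' TIR starts
#' GG (and 3' TIR ends CC).
#'
#' @param seq element sequence, optionally with a little slack at both ends
#' @param min_len,max_len TIR length bounds (Merlin spans 24-462 bp; the
#'   floor default 10 also catches shorter degenerate repeats)
#' @param max_mismatch_frac maximum cumulative mismatch fraction (default 0.5,
#'   accommodating highly imperfect TIRs such as 12 mismatches in 26 bp)
#' @param require_gg keep only terminal-GG candidates (the family-defining
#'   convention); default FALSE for discovery
#' @param max_offset how far from each end anchors are tried (0-based offsets)
#' @param stop_run consecutive-mismatch run that stops extension
#' @return data.frame of ranked `TirPair`s: start5, end3 (0-based anchor
#'   positions), length, mismatches, tir5, tir3, terminal_gg, extendable,
#'   score; empty when none found
#' @export
find_tirs <- function(seq, min_len = 10L, max_len = 462L,
                      max_mismatch_frac = 0.5, require_gg = FALSE,
                      max_offset = 8L, stop_run = 4L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n <= 2L * min_len) stop("sequence shorter than twice min_len")
  v <- chars(seq)
  comp <- COMPLEMENT[v]
  cands <- list()
  for (s in 0:max_offset) for (e in (n - 1L):(n - 1L - max_offset)) {
    if (e <= s + 2L * min_len) next
    maxt <- min(max_len, (e - s + 1L) %/% 2L)
    mism <- 0L; run <- 0L
    best_score <- -Inf; best_len <- 0L; best_mism <- 0L; stopped_by_run <- FALSE
    t <- 0L
    while (t < maxt) {
      match <- v[s + t + 1L] == comp[e - t + 1L]
      if (match) run <- 0L else { mism <- mism + 1L; run <- run + 1L }
      t <- t + 1L
      if (mism / t > max_mismatch_frac && t >= min_len) { t <- t - 0L; break }
      if (run >= stop_run) { stopped_by_run <- TRUE; break }
      if (t >= min_len) {
        sc <- t - 2L * mism
        if (sc > best_score) { best_score <- sc; best_len <- t; best_mism <- mism }
      }
    }
    if (best_len < min_len) next
    tir5 <- substr(seq, s + 1L, s + best_len)
    tir3 <- substr(seq, e - best_len + 2L, e + 1L)
    gg <- startsWith(tir5, "GG") && endsWith(tir3, "CC")
    cands[[length(cands) + 1L]] <- data.frame(
      start5 = s, end3 = e, length = best_len, mismatches = best_mism,
      tir5 = tir5, tir3 = tir3, terminal_gg = gg,
      extendable = stopped_by_run, score = best_score,
      stringsAsFactors = FALSE)
  }
  if (!length(cands)) return(empty_tirs())
  out <- do.call(rbind, cands)
  if (require_gg) out <- out[out$terminal_gg, , drop = FALSE]
  if (!nrow(out)) return(empty_tirs())
  out <- out[order(-out$score, out$start5, -out$end3), , drop = FALSE]
  # drop dominated anchors: same start or end with lower score already sorted
  out <- out[!duplicated(out[, c("start5", "end3")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_tirs <- function() data.frame(
  start5 = integer(), end3 = integer(), length = integer(),
  mismatches = integer(), tir5 = character(), tir3 = character(),
  terminal_gg = logical(), extendable = logical(), score = numeric(),
  stringsAsFactors = FALSE)

#' Count TIR mismatches over the first n terminal positions
#'
#' Hamming distance between the first `n` bases of an element and the
#' reverse complement of its last `n` bases — the way imperfect-TIR
#' divergence is quoted when internal TIR limits are unclear and the
#' element limits come from a multi-copy alignment.
#'
#' @param element element sequence with boundary-exact termini
#' @param n terminal positions to compare
#' @return integer mismatch count
#' @export
count_tir_mismatches <- function(element, n) {
  element <- toupper(element)
  hamming(substr(element, 1L, n),
          revcomp(substr(element, nchar(element) - n + 1L, nchar(element))))
}

#' Search element flanks for a target site duplication
#'
#' Looks for the longest k in `k_range` such that the k-mer immediately 5'
#' of the element equals the k-mer immediately 3' of it, allowing the
#' element boundary to jitter by up to `jitter` bp on each side (published
#' elements often have unclear internal TIR borders). Matching is exact by
#' default.
#'
#' @param flank5 sequence immediately upstream of the (nominal) element start
#' @param flank3 sequence immediately downstream of the (nominal) element end
#' @param element optional element sequence, enabling jitter into the element
#' @param k_range candidate TSD lengths (default 7:10; Merlin uses 8 or 9)
#' @param jitter boundary slack in bp (default 3)
#' @param max_mismatch allowed mismatches between the two k-mers (default 0)
#' @param gg_convention penalise candidates whose implied element termini
#'   deviate from the GG...CC convention (used by the pipeline, where a
#'   chance match could otherwise steal the element's terminal base)
#' @return a `Tsd` list (k, left, right, exact, shift5, shift3) or NULL; a
#'   message explains truncated flanks
#' @export
find_tsd <- function(flank5, flank3, element = NULL, k_range = 7:10,
                     jitter = 3L, max_mismatch = 0L, gg_convention = FALSE) {
  kmax <- max(k_range)
  if (nchar(flank5) < kmax || nchar(flank3) < kmax) {
    message("find_tsd: flank shorter than max TSD length; copy truncated")
    return(NULL)
  }
  f5 <- toupper(flank5); f3 <- toupper(flank3)
  el <- if (!is.null(element)) toupper(element) else ""
  left_ctx <- paste0(f5, substr(el, 1L, jitter))
  b5 <- nchar(f5)
  right_ctx <- paste0(substr(el, nchar(el) - jitter + 1L, nchar(el)), f3)
  b3 <- if (nzchar(el)) min(jitter, nchar(el)) else 0L
  dmax <- if (nzchar(el)) jitter else 0L
  # candidates are scored k - |shift| (and, under gg_convention, penalised
  # 2 points per implied-terminus deviation from GG...CC): a longer
  # duplication wins unless it is bought by moving the boundary or by
  # stealing the element's conserved terminal G. Ties prefer the smaller
  # shift, then the longer k.
  shifts <- expand.grid(d5 = -jitter:dmax, d3 = -dmax:jitter)
  full <- paste0(f5, el, f3)
  nel <- nchar(el)
  best <- NULL
  for (k in sort(k_range, decreasing = TRUE)) {
    for (r in seq_len(nrow(shifts))) {
      d5 <- shifts$d5[r]; d3 <- shifts$d3[r]
      lpos <- b5 + d5
      if (lpos - k + 1L < 1L || lpos > nchar(left_ctx)) next
      left <- substr(left_ctx, lpos - k + 1L, lpos)
      rpos <- b3 + d3
      if (rpos < 0L || rpos + k > nchar(right_ctx)) next
      right <- substr(right_ctx, rpos + 1L, rpos + k)
      if (nchar(left) != k || nchar(right) != k ||
          hamming(left, right) > max_mismatch) next
      sh <- abs(d5) + abs(d3)
      sc <- k - sh
      if (gg_convention && nzchar(el)) {
        s0 <- nchar(f5) + d5          # implied 0-based element interval
        e0 <- nchar(f5) + nel + d3
        head2 <- substr(full, s0 + 1L, s0 + 2L)
        tail2 <- substr(full, e0 - 1L, e0)
        ggmm <- hamming(head2, "GG") + hamming(tail2, "CC")
        sc <- k - 2L * ggmm - min(sh, 3L)
      }
      if (is.null(best) || sc > best$sc ||
          (sc == best$sc && (sh < best$sh || (sh == best$sh && k > best$k)))) {
        best <- list(k = k, left = left, right = right, d5 = d5, d3 = d3,
                     sc = sc, sh = sh)
      }
    }
  }
  if (is.null(best)) return(NULL)
  structure(list(k = best$k, left = best$left, right = best$right,
                 exact = best$left == best$right,
                 shift5 = best$d5, shift3 = best$d3), class = "Tsd")
}

#' Mismatches of a TIR pair to the terminal GG...CC convention
#'
#' Counts how many of the four convention positions (first two bases of the
#' 5' TIR vs GG, last two of the 3' TIR vs CC) deviate. Exact conservation
#' gives 0; `terminal_gg` in [find_tirs()] output is `mismatches == 0`.
#'
#' @param tir one row of [find_tirs()] output
#' @return integer 0..4
#' @export
tir_gg_mismatches <- function(tir) {
  hamming(substr(tir$tir5[1], 1, 2), "GG") +
    hamming(substr(tir$tir3[1], nchar(tir$tir3[1]) - 1L, nchar(tir$tir3[1])), "CC")
}

#' Classify one copy from its TIR, TSD and motif evidence
#'
#' A `family_candidate` has a terminal-GG TIR pair and a TSD (a bona fide
#' transposition product); a `group_member` retains the transposase
#' ORF/motif but no TIR+TSD support (candidate domesticate or decaying
#' copy); everything else is a `remnant`.
#'
#' The GG...CC terminal convention is assessed with a small per-copy
#' tolerance (default 1 deviating position of 4): the convention holds at
#' the family-consensus level, while individual copies accumulate
#' substitutions after insertion, including at the termini.
#'
#' @param tir one row of [find_tirs()] output, or NULL
#' @param tsd a `Tsd` from [find_tsd()], or NULL
#' @param motif_status one of intact / truncated_domain / absent
#' @param gg_tolerance maximum [tir_gg_mismatches()] still counted as a
#'   terminal-GG TIR for family calling
#' @return one of `"family_candidate"`, `"group_member"`, `"remnant"`
#' @export
classify_copy <- function(tir, tsd, motif_status, gg_tolerance = 1L) {
  has_tir <- !is.null(tir) && NROW(tir) > 0 &&
    tir_gg_mismatches(tir[1, ]) <= gg_tolerance
  has_tsd <- !is.null(tsd)
  if (has_tir && has_tsd) return("family_candidate")
  if (identical(motif_status, "intact")) return("group_member")
  "remnant"
}
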