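# Translated homology search for transposase copies and extraction of
# candidate element windows with flanks. The search itself is delegated to
# command-line tblastn (the standard tool for this step); results are parsed
# from 12-column tabular output, and the same adapter reads externally
# produced tabular files.

blast_tool <- function(name) {
  p <- Sys.which(name)
  if (!nzchar(p)) stop("required external tool not found on PATH: ", name)
  p
}

as_named_seqs <- function(x) {
  if (inherits(x, "XStringSet")) return(setNames(as.character(x), names(x)))
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    ss <- Biostrings::readBStringSet(x)
    return(setNames(as.character(ss), sub("\\s.*$", "", names(ss))))
  }
  if (is.null(names(x)) || any(!nzchar(names(x))))
    names(x) <- sprintf("seq_%d", seq_along(x))
  x
}

write_temp_fasta <- function(seqs, path) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  path
}

#' Translated search of a genome with protein queries
#'
#' Runs tblastn (six-frame translated alignment with BLOSUM62 scoring and
#' Karlin-Altschul expect values) of the query transposases against the
#' genome, keeps hits with expect value at most `max_expect`, and merges
#' overlapping same-strand hits from different queries down to the
#' best-scoring one.
#'
#' @param genome named character vector / `DNAStringSet` / FASTA path
#' @param queries named character vector / `AAStringSet` / FASTA path of
#'   query proteins (non-empty)
#' @param max_expect expect-value cutoff (the curation default is 1e-3; the
#'   first-round discovery threshold in strict mode is 1e-4)
#' @param merge_overlaps merge overlapping same-strand hits to the best one
#' @return data.frame of `TransposaseHit`s: contig, start, end (0-based
#'   half-open), strand, query, identity (fraction), score (bit score),
#'   evalue; sorted by contig and start
#' @export
translated_search <- function(genome, queries, max_expect = 1e-3,
                              merge_overlaps = TRUE) {
  genome <- as_named_seqs(genome)
  queries <- as_named_seqs(queries)
  if (!length(queries)) stop("queries must be non-empty")
  if (!length(genome) || all(!nzchar(genome))) return(empty_hits())
  td <- tempfile("tblastn_")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  gfa <- write_temp_fasta(genome, file.path(td, "genome.fa"))
  qfa <- write_temp_fasta(queries, file.path(td, "queries.fa"))
  db <- file.path(td, "db")
  out <- file.path(td, "hits.tsv")
  system2(blast_tool("makeblastdb"),
          c("-in", gfa, "-dbtype", "nucl", "-out", db),
          stdout = FALSE, stderr = FALSE)
  status <- system2(blast_tool("tblastn"),
          c("-query", qfa, "-db", db, "-evalue", format(max_expect),
            "-outfmt", "6", "-out", out),
          stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("tblastn failed with exit status ", status)
  hits <- read_hits_table(out)
  hits <- hits[hits$evalue <= max_expect, , drop = FALSE]
  if (merge_overlaps && nrow(hits) > 1L) hits <- merge_overlapping_hits(hits)
  hits[order(hits$contig, hits$start), , drop = FALSE]
}

#' Read a standard 12-column tabular search result
#'
#' Adapter for externally produced results (BLAST `-outfmt 6` and
#' equivalents): qseqid sseqid pident length mismatch gapopen qstart qend
#' sstart send evalue bitscore. Subject coordinates are converted to 0-based
#' half-open intervals with strand from the sstart/send orientation.
#'
#' @param path tabular file path
#' @return data.frame of hits (see [translated_search()])
#' @export
read_hits_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) return(empty_hits())
  x <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(x) < 12L) stop("expected 12-column tabular input")
  names(x)[1:12] <- c("query", "contig", "pident", "length", "mismatch",
                      "gapopen", "qstart", "qend", "sstart", "send",
                      "evalue", "bitscore")
  data.frame(contig = x$contig,
             start = pmin(x$sstart, x$send) - 1L,
             end = pmax(x$sstart, x$send),
             strand = ifelse(x$sstart <= x$send, "+", "-"),
             query = x$query, identity = x$pident / 100,
             score = x$bitscore, evalue = x$evalue,
             stringsAsFactors = FALSE)
}

empty_hits <- function() data.frame(
  contig = character(), start = integer(), end = integer(),
  strand = character(), query = character(), identity = numeric(),
  score = numeric(), evalue = numeric(), stringsAsFactors = FALSE)

merge_overlapping_hits <- function(hits) {
  keep <- rep(TRUE, nrow(hits))
  ord <- order(-hits$score)
  for (i in ord) {
    if (!keep[i]) next
    ov <- which(keep & seq_len(nrow(hits)) != i &
                  hits$contig == hits$contig[i] & hits$strand == hits$strand[i] &
                  hits$start < hits$end[i] & hits$end > hits$start[i])
    keep[ov[hits$score[ov] <= hits$score[i]]] <- FALSE
  }
  hits[keep, , drop = FALSE]
}

#' Extract candidate element copies with flanking windows
#'
#' Clusters same-strand hits separated by at most `merge_gap` (frameshifted
#' copies split tblastn hits), takes the cluster span as the provisional
#' element interval, and extracts the window plus `flank_bp` on each side
#' (clipped at contig ends, with truncation flags). The ORF is re-called in
#' the window and the copy status set from the motif/frame analysis:
#' `intact` (ORF with full three-block motif), `frameshifted` (motif blocks
#' present across frames but no single intact ORF), else `remnant`.
#'
#' @param hits data.frame from [translated_search()] / [read_hits_table()]
#' @param genome named character vector / `DNAStringSet` / FASTA path
#' @param flank_bp flank window size (must exceed the TSD search window;
#'   default 2000 covers the largest reported TIR plus slack)
#' @param merge_gap maximum gap between hits merged into one copy
#' @param profile `BlockProfile` for the motif re-call
#' @param min_aa minimum ORF length considered
#' @return data.frame of `ElementCopy` rows: contig, start, end (provisional,
#'   0-based), strand, window coordinates and sequence, flank5/flank3,
#'   trunc5/trunc3 flags, orf_protein, status
#' @export
extract_copies <- function(hits, genome, flank_bp = 2000L, merge_gap = 300L,
                           profile = dde_profile(), min_aa = 80L) {
  genome <- as_named_seqs(genome)
  if (!nrow(hits)) return(empty_copies())
  if (flank_bp < 20L) stop("flank_bp must be at least the TSD search window")
  rows <- list()
  for (key in unique(paste(hits$contig, hits$strand))) {
    h <- hits[paste(hits$contig, hits$strand) == key, , drop = FALSE]
    h <- h[order(h$start), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(h$start[-1L] > cummax(h$end)[-nrow(h)] + merge_gap)))
    for (g in unique(grp)) {
      hg <- h[grp == g, , drop = FALSE]
      rows[[length(rows) + 1L]] <- list(contig = hg$contig[1],
        start = min(hg$start), end = max(hg$end), strand = hg$strand[1],
        score = max(hg$score))
    }
  }
  out <- list()
  for (r in rows) {
    contig_seq <- genome[[r$contig]]
    clen <- nchar(contig_seq)
    ws <- max(0L, r$start - flank_bp)
    we <- min(clen, r$end + flank_bp)
    window <- substr(contig_seq, ws + 1L, we)
    trunc5 <- ws == 0L && r$start < flank_bp
    trunc3 <- we == clen && clen - r$end < flank_bp
    orfs <- find_orfs(window, min_aa, partial = TRUE)
    # element interval relative to window
    rel_s <- r$start - ws; rel_e <- r$end - ws
    ov <- orfs[orfs$end > rel_s & orfs$start < rel_e & orfs$strand == r$strand, , drop = FALSE]
    status <- "remnant"; prot <- NA_character_; orf_iv <- c(NA_integer_, NA_integer_)
    if (nrow(ov)) {
      ov <- ov[order(-nchar(ov$protein)), , drop = FALSE]
      best <- NULL
      for (k in seq_len(nrow(ov))) {
        m <- scan_dde(ov$protein[k], profile)
        if (!is.null(m)) { best <- k; break }
      }
      if (!is.null(best)) {
        status <- "intact"; prot <- ov$protein[best]
        orf_iv <- c(ov$start[best], ov$end[best])
      } else {
        prot <- ov$protein[1]
        orf_iv <- c(ov$start[1], ov$end[1])
      }
    }
    if (status != "intact") {
      # frameshift: blocks recoverable from six-frame translations of the
      # hit region even though no single ORF carries the full motif
      nblocks <- count_blocks_sixframe(substr(window, max(1L, rel_s - 200L),
                                              min(nchar(window), rel_e + 200L)),
                                       profile)
      if (nblocks >= 2L) status <- "frameshifted"
    }
    out[[length(out) + 1L]] <- data.frame(
      contig = r$contig, start = r$start, end = r$end, strand = r$strand,
      win_start = ws, win_end = we, window = window,
      flank5 = substr(contig_seq, ws + 1L, r$start),
      flank3 = substr(contig_seq, r$end + 1L, we),
      trunc5 = trunc5, trunc3 = trunc3,
      orf_protein = prot, orf_start = orf_iv[1], orf_end = orf_iv[2],
      status = status, stringsAsFactors = FALSE)
  }
  cp <- do.call(rbind, out)
  cp <- cp[order(cp$contig, cp$start), , drop = FALSE]
  cp$copy_id <- sprintf("copy_%03d", seq_len(nrow(cp)))
  rownames(cp) <- NULL
  cp
}

count_blocks_sixframe <- function(dna, profile) {
  prots <- character(0)
  for (s in c(dna, revcomp(dna))) for (off in 0:2) {
    ncod <- (nchar(s) - off) %/% 3L
    if (ncod > 0) prots <- c(prots, translate_str(substr(s, off + 1L, off + 3L * ncod)))
  }
  found <- logical(3)
  for (p in prots) {
    aa <- chars(gsub("\\*", "X", p))
    for (b in 1:3) {
      if (found[b]) next
      sc <- block_scores_along(aa, profile$scores[[b]])
      if (length(sc) && max(sc) >= 0.7 * profile$max_score[b]) found[b] <- TRUE
    }
  }
  sum(found)
}

empty_copies <- function() data.frame(
  contig = character(), start = integer(), end = integer(), strand = character(),
  win_start = integer(), win_end = integer(), window = character(),
  flank5 = character(), flank3 = character(), trunc5 = logical(),
  trunc3 = logical(), orf_protein = character(), orf_start = integer(),
  orf_end = integer(), status = character(), copy_id = character(),
  stringsAsFactors = FALSE)

#' Flag copies that look like segmental duplications
#'
#' Two copies whose 5' AND 3' flanks each align at >= `min_identity` over
#' >= `min_len` bp share their insertion context and were multiplied by
#' segmental duplication, not transposition. Copies with truncated flanks
#' are undetermined (`NA`, distinct from `FALSE`).
#'
#' Only the proximal `flank_cap` bp of each flank are compared, and for
#' copies on the same contig the cap shrinks to half the gap between them so
#' that overlapping extraction windows (two nearby insertions sharing the
#' intervening host sequence) are never mistaken for shared flanks.
#'
#' @param copies data.frame from [extract_copies()]
#' @param min_identity flank identity threshold (default 0.9)
#' @param min_len minimum aligned flank length in bp (default 200)
#' @param flank_cap maximum proximal flank length compared (default 500)
#' @return logical vector (with NA) parallel to `copies` rows
#' @export
flag_segmental_duplication <- function(copies, min_identity = 0.9,
                                       min_len = 200L, flank_cap = 500L) {
  n <- nrow(copies)
  res <- rep(FALSE, n)
  undet <- copies$trunc5 | copies$trunc3 |
    nchar(copies$flank5) < min_len | nchar(copies$flank3) < min_len
  res[undet] <- NA
  if (n < 2L) return(res)
  ok <- which(!undet)
  if (length(ok) < 2L) return(res)
  for (i in ok) for (j in ok[ok > i]) {
    cap <- flank_cap
    if (copies$contig[i] == copies$contig[j]) {
      gap <- max(copies$start[i], copies$start[j]) - min(copies$end[i], copies$end[j])
      cap <- min(cap, max(0L, gap %/% 2L - 10L))
    }
    if (cap < min_len) next
    f5i <- substr(copies$flank5[i], nchar(copies$flank5[i]) - cap + 1L, nchar(copies$flank5[i]))
    f5j <- substr(copies$flank5[j], nchar(copies$flank5[j]) - cap + 1L, nchar(copies$flank5[j]))
    f3i <- substr(copies$flank3[i], 1L, cap)
    f3j <- substr(copies$flank3[j], 1L, cap)
    if (flanks_match(f5i, f5j, min_identity, min_len) &&
        flanks_match(f3i, f3j, min_identity, min_len)) {
      res[i] <- TRUE; res[j] <- TRUE
    }
  }
  res
}

flanks_match <- function(a, b, min_identity, min_len) {
  al <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                      Biostrings::DNAString(b), type = "local")
  w <- Biostrings::nchar(al)
  w >= min_len && Biostrings::pid(al, type = "PID1") / 100 >= min_identity
}
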