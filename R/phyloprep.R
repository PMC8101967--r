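# Preparation of the conserved-domain matrix for external tree inference:
# domain extraction around the three-block motif, the size filter (>115 aa),
# 70% identity clustering to representatives, gap-threshold column trimming,
# the final short-row filter (<110 aa), and PHYLIP/NEXUS export.

#' Extract the conserved domain region around a DDE motif
#'
#' Substring from `pad` residues before block 1 to `pad` residues after the
#' end of block 3, clipped at the protein termini.
#'
#' @param protein amino-acid sequence
#' @param motif `DdeMotif` from [scan_dde()] (error when NULL)
#' @param pad residues of padding on each side (default 10)
#' @return amino-acid substring
#' @export
extract_domain <- function(protein, motif, pad = 10L) {
  if (is.null(motif)) stop("motif absent; cannot extract domain")
  from <- max(1L, motif$block_positions[1] - pad)
  to <- min(nchar(protein), motif$block_positions[3] + motif$block_widths[3] - 1L + pad)
  substr(protein, from, to)
}

#' Filter sequences by length (strictly greater than)
#'
#' @param seqs named character vector
#' @param min_aa length floor; sequences of exactly `min_aa` are discarded
#' @return list with `kept` and `discarded`
#' @export
size_filter <- function(seqs, min_aa = 115L) {
  keep <- nchar(seqs) > min_aa
  list(kept = seqs[keep], discarded = seqs[!keep])
}

global_identity <- function(a, b) {
  al <- Biostrings::pairwiseAlignment(Biostrings::AAString(a),
                                      Biostrings::AAString(b),
                                      type = "global",
                                      substitutionMatrix = "BLOSUM62",
                                      gapOpening = 10, gapExtension = 0.5)
  pa <- chars(as.character(Biostrings::alignedPattern(al)))
  pb <- chars(as.character(Biostrings::alignedSubject(al)))
  sum(pa == pb & pa != "-") / length(pa)   # matches / alignment length
}

#' Greedy identity clustering to representatives
#'
#' Sequences are sorted longest-first; each joins the first existing
#' representative to which its global pairwise identity (matches over global
#' alignment length) reaches `threshold`, otherwise it founds a new cluster.
#'
#' @param seqs named character vector
#' @param threshold identity threshold (default 0.70)
#' @return list with `representatives` (named character vector) and
#'   `membership` (named character vector mapping each id to its
#'   representative's id)
#' @export
identity_cluster <- function(seqs, threshold = 0.70) {
  if (!length(seqs)) return(list(representatives = seqs, membership = character(0)))
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  reps <- character(0)
  membership <- setNames(character(length(seqs)), names(seqs))
  for (i in seq_along(seqs)) {
    placed <- FALSE
    for (r in names(reps)) {
      if (global_identity(seqs[[i]], reps[[r]]) >= threshold) {
        membership[names(seqs)[i]] <- r; placed <- TRUE; break
      }
    }
    if (!placed) {
      reps[names(seqs)[i]] <- seqs[[i]]
      membership[names(seqs)[i]] <- names(seqs)[i]
    }
  }
  list(representatives = reps, membership = membership)
}

#' Trim alignment columns by gap threshold
#'
#' Keeps columns whose non-gap fraction is at least `gap_threshold` (the
#' trimAl-style 0.4 GAP threshold reads as: at least 40% of rows must hold a
#' residue). `sim_threshold = 0` disables similarity-based removal; a
#' positive value additionally removes kept columns whose mean pairwise
#' identity falls below it.
#'
#' @param alignment named character vector of equal-length aligned sequences
#' @param gap_threshold minimum non-gap fraction per retained column
#' @param sim_threshold minimum column identity (0 disables)
#' @return trimmed alignment (named character vector); error if nothing is left
#' @export
trim_columns <- function(alignment, gap_threshold = 0.4, sim_threshold = 0) {
  m <- aln_matrix(alignment)
  nongap <- colMeans(m != "-" & m != ".")
  keep <- nongap >= gap_threshold
  if (sim_threshold > 0) {
    ci <- column_identity(m)
    keep <- keep & (!is.na(ci) & ci >= sim_threshold)
  }
  if (!any(keep)) stop("trimming removed all columns")
  setNames(apply(m[, keep, drop = FALSE], 1, paste, collapse = ""),
           names(alignment))
}

#' Drop alignment rows with short ungapped length
#'
#' @param alignment named character vector
#' @param min_aa rows with fewer than `min_aa` residues (gaps excluded) are
#'   dropped; exactly `min_aa` is kept
#' @return filtered alignment
#' @export
final_length_filter <- function(alignment, min_aa = 110L) {
  ungapped <- nchar(gsub("[-.]", "", alignment))
  alignment[ungapped >= min_aa]
}

#' Export / read an alignment matrix for external tree inference
#'
#' Relaxed PHYLIP (names of any length followed by two spaces, sequential)
#' or NEXUS (via ape). Round-trip safe with [read_matrix()].
#'
#' @param alignment named character vector of equal-length sequences (>= 1)
#' @param path output file
#' @param format `"phylip"` or `"nexus"`
#' @return the path, invisibly
#' @export
export_matrix <- function(alignment, path, format = c("phylip", "nexus")) {
  format <- match.arg(format)
  if (!length(alignment)) stop("cannot export an empty matrix")
  if (length(unique(nchar(alignment))) != 1L) stop("rows are not equal length")
  if (format == "phylip") {
    lines <- c(sprintf(" %d %d", length(alignment), nchar(alignment[[1]])),
               sprintf("%s  %s", names(alignment), unname(alignment)))
    writeLines(lines, path)
  } else {
    ape::write.nexus.data(setNames(strsplit(unname(alignment), ""),
                                   names(alignment)),
                          path, format = "protein", interleaved = FALSE)
  }
  invisible(path)
}

#' @rdname export_matrix
#' @export
read_matrix <- function(path, format = c("phylip", "nexus")) {
  format <- match.arg(format)
  if (format == "phylip") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
    rows <- lines[1 + seq_len(hdr[1])]
    parts <- regmatches(rows, regexpr("\\s\\s+", rows), invert = TRUE)
    out <- setNames(vapply(parts, function(p) trimws(p[2]), ""),
                    vapply(parts, function(p) trimws(p[1]), ""))
    stopifnot(all(nchar(out) == hdr[2]))
    out
  } else {
    x <- ape::read.nexus.data(path)
    setNames(vapply(x, function(s) toupper(paste(s, collapse = "")), ""), names(x))
  }
}
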