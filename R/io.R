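# File-format helpers: FASTA, aligned FASTA (via MAFFT), GFF3, Newick, TSV.
# Internal coordinates are 0-based half-open; GFF3 output is 1-based inclusive.

#' Read / write FASTA as a named character vector
#'
#' Thin wrappers over Biostrings that present sequences as plain named
#' character vectors, the representation used throughout the package.
#' Wrapped/unwrapped and CRLF/LF inputs parse identically.
#'
#' @param path FASTA file
#' @param seqs named character vector
#' @param width line wrap width on output
#' @return `read_fasta` returns a named character vector
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(ss)), sub("\\s.*$", "", names(ss)))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Multiple alignment via MAFFT
#'
#' Aligns nucleotide or protein sequences with command-line MAFFT (the
#' standard aligner for this kind of curation); externally produced aligned
#' FASTA can be used anywhere an alignment is accepted instead.
#'
#' @param seqs named character vector (>= 2 sequences)
#' @param type `"nt"` or `"aa"` (passed to mafft as --nuc / --amino)
#' @return named character vector of equal-length aligned sequences
#' @export
align_sequences <- function(seqs, type = c("nt", "aa")) {
  type <- match.arg(type)
  if (length(seqs) < 2L) stop("need at least 2 sequences to align")
  tool <- Sys.which("mafft")
  if (!nzchar(tool)) stop("mafft not found on PATH")
  fin <- tempfile(fileext = ".fa"); fout <- tempfile(fileext = ".fa")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  write_fasta(seqs, fin)
  args <- c("--auto", "--quiet", if (type == "nt") "--nuc" else "--amino", fin)
  status <- system2(tool, args, stdout = fout, stderr = FALSE)
  if (status != 0L) stop("mafft failed with exit status ", status)
  read_fasta(fout)
}

#' Export curated copies as GFF3
#'
#' One `transposable_element` feature per copy with TIR and TSD child
#' features where detected; coordinates 1-based inclusive per GFF3.
#'
#' @param copies data.frame with contig, start, end (0-based half-open),
#'   strand, copy_id, and optional classification/family_id columns
#' @param calls optional per-copy list carrying `tir` (a TirPair row) and
#'   `tsd` (a Tsd), named by copy_id
#' @param path output path
#' @return the path, invisibly
#' @export
write_copies_gff3 <- function(copies, path, calls = NULL) {
  grs <- list()
  for (i in seq_len(nrow(copies))) {
    r <- copies[i, ]
    meta <- S4Vectors::DataFrame(type = "transposable_element", ID = r$copy_id)
    if (!is.null(copies$classification)) meta$classification <- r$classification
    if (!is.null(copies$family_id)) meta$family_id <- r$family_id
    g <- GenomicRanges::GRanges(r$contig, IRanges::IRanges(r$start + 1L, r$end),
                                strand = r$strand)
    S4Vectors::mcols(g) <- meta
    grs[[length(grs) + 1L]] <- g
    cc <- calls[[r$copy_id]]
    tt <- cc$tir_gg %||% cc$tir
    if (!is.null(tt) && NROW(tt)) {
      t <- tt[1, ]
      # TIR offsets are in element orientation; mirror for minus strand
      o5 <- c(t$start5, t$start5 + t$length - 1L)
      o3 <- c(t$end3 - t$length + 1L, t$end3)
      if (r$strand == "-") {
        len <- r$end - r$start
        o5 <- sort(len - 1L - o5); o3 <- sort(len - 1L - o3)
      }
      grs[[length(grs) + 1L]] <- GenomicRanges::GRanges(r$contig,
        IRanges::IRanges(r$start + c(o5[1], o3[1]) + 1L,
                         r$start + c(o5[2], o3[2]) + 1L),
        strand = r$strand, type = "terminal_inverted_repeat",
        ID = paste0(r$copy_id, c("_tir5", "_tir3")), Parent = r$copy_id)
    }
    if (!is.null(cc$tsd)) {
      k <- cc$tsd$k
      grs[[length(grs) + 1L]] <- GenomicRanges::GRanges(r$contig,
        IRanges::IRanges(c(r$start - k + 1L, r$end + 1L), width = k),
        strand = "*", type = "target_site_duplication",
        ID = paste0(r$copy_id, c("_tsd5", "_tsd3")), Parent = r$copy_id)
    }
  }
  gr <- suppressWarnings(do.call(c, grs))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write a tree in Newick format with split supports as node labels
#' @param tree an `ape::phylo`
#' @param path output path
#' @return the path, invisibly
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, path)
  invisible(path)
}
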