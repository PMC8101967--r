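# Bacterial-contamination screening: best local-alignment identity of a
# candidate transposase against a bacterial reference set, with genomic-
# context corroboration from neighbouring ORFs. The protein rule is strict:
# identity must exceed 0.80 to call a contaminant; 0.40-0.80 is only
# suspect, and becomes credible when neighbouring ORFs are bacterial-like
# too.

best_decoy_identity <- function(protein, bacterial_set) {
  sub <- "BLOSUM62"
  best_id <- 0; best_cov <- 0; best_name <- NA_character_
  q <- Biostrings::AAString(protein)
  for (i in seq_along(bacterial_set)) {
    al <- Biostrings::pairwiseAlignment(q, Biostrings::AAString(bacterial_set[[i]]),
                                        type = "local", substitutionMatrix = sub,
                                        gapOpening = 10, gapExtension = 0.5)
    cov <- Biostrings::nchar(al) / nchar(protein)
    id <- Biostrings::pid(al, type = "PID1") / 100
    if (cov >= 0.5 && id > best_id) {
      best_id <- id; best_cov <- cov
      best_name <- names(bacterial_set)[i] %||% as.character(i)
    }
  }
  list(identity = best_id, coverage = best_cov, subject = best_name)
}

#' Screen a protein against a bacterial reference set
#'
#' Best local-alignment identity over the aligned region, requiring at
#' least 50% query coverage. Identity strictly greater than
#' `contaminant_identity` (default 0.80) is a `contaminant`; identities in
#' `[suspect_identity, contaminant_identity]` are `suspect` (to be
#' corroborated by [screen_context()]); below that, `clean`.
#'
#' @param protein amino-acid sequence (non-empty)
#' @param bacterial_set named character vector / `AAStringSet` / FASTA path
#' @param contaminant_identity strict threshold for a contaminant call
#' @param suspect_identity lower bound of the suspect band
#' @return `ContaminationVerdict` list: best_identity, coverage, subject,
#'   protein_verdict, rationale
#' @export
screen_protein <- function(protein, bacterial_set, contaminant_identity = 0.80,
                           suspect_identity = 0.40) {
  if (!nzchar(protein)) stop("empty protein")
  bacterial_set <- as_named_seqs(bacterial_set)
  if (!length(bacterial_set)) stop("bacterial_set must be non-empty")
  b <- best_decoy_identity(protein, bacterial_set)
  verdict <- if (b$identity > contaminant_identity) "contaminant"
             else if (b$identity >= suspect_identity) "suspect" else "clean"
  structure(list(best_identity = b$identity, coverage = b$coverage,
                 subject = b$subject, protein_verdict = verdict,
                 rationale = sprintf(
                   "best identity %.3f (coverage %.2f) vs %s; contaminant requires > %.2f",
                   b$identity, b$coverage, b$subject, contaminant_identity)),
            class = "ContaminationVerdict")
}

#' Corroborate contamination from the genomic context
#'
#' Calls ORFs in a window around the copy and screens each against the
#' bacterial set; the context is `suspect` when at least two neighbouring
#' ORFs independently reach identity > `neighbor_identity` (default 0.40).
#' With no callable neighbouring ORFs the context is clean-by-default, with
#' a note.
#'
#' @param contig contig sequence
#' @param copy_start,copy_end 0-based half-open element interval to exclude
#' @param bacterial_set reference proteins
#' @param window bp examined on each side of the copy (default 10000)
#' @param min_aa minimum neighbouring ORF length
#' @param neighbor_identity per-ORF identity threshold
#' @return list: context_verdict ("clean"/"suspect"), n_bacterial_orfs,
#'   n_orfs, note
#' @export
screen_context <- function(contig, copy_start, copy_end, bacterial_set,
                           window = 10000L, min_aa = 80L,
                           neighbor_identity = 0.40) {
  bacterial_set <- as_named_seqs(bacterial_set)
  ws <- max(0L, copy_start - window)
  we <- min(nchar(contig), copy_end + window)
  orfs <- find_orfs(substr(contig, ws + 1L, we), min_aa)
  if (nrow(orfs)) {
    # exclude ORFs overlapping the copy itself
    rel_s <- copy_start - ws; rel_e <- copy_end - ws
    orfs <- orfs[orfs$end <= rel_s | orfs$start >= rel_e, , drop = FALSE]
  }
  if (!nrow(orfs)) {
    return(list(context_verdict = "clean", n_bacterial_orfs = 0L, n_orfs = 0L,
                note = "no neighbouring ORFs callable; clean by default"))
  }
  nb <- sum(vapply(orfs$protein, function(p)
    best_decoy_identity(p, bacterial_set)$identity > neighbor_identity, NA))
  list(context_verdict = if (nb >= 2L) "suspect" else "clean",
       n_bacterial_orfs = nb, n_orfs = nrow(orfs), note = NA_character_)
}
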