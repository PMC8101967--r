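# Family/group assignment: pairwise p-distances, neighbor-joining trees with
# column-resampling bootstrap, single-linkage clustering of copies, and
# IUPAC-degenerate consensus sequences.

GAPCH <- c("-", ".", "N", "X", "?")

#' Pairwise p-distance matrix on an alignment
#'
#' Distance is the proportion of differing sites among pairwise-comparable
#' columns (gap and ambiguous positions removed per pair). Pairs with zero
#' comparable sites get `NA` and are flagged in the `"undefined"` attribute.
#'
#' @param seqs named character vector of equal-length aligned sequences
#'   (nucleotide or amino acid)
#' @return symmetric numeric matrix with zero diagonal, labels as dimnames
#' @export
p_distance_matrix <- function(seqs) {
  if (length(unique(nchar(seqs))) != 1L) stop("sequences are not equal length")
  m <- aln_matrix(seqs)
  n <- nrow(m)
  lab <- names(seqs) %||% as.character(seq_len(n))
  d <- matrix(0, n, n, dimnames = list(lab, lab))
  ok <- !(m %in% GAPCH); dim(ok) <- dim(m)
  undef <- character(0)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    comp <- ok[i, ] & ok[j, ]
    nc <- sum(comp)
    if (nc == 0L) {
      d[i, j] <- d[j, i] <- NA_real_
      undef <- c(undef, paste(lab[i], lab[j], sep = "|"))
    } else d[i, j] <- d[j, i] <- sum(m[i, comp] != m[j, comp]) / nc
  }
  stopifnot(isTRUE(all.equal(d, t(d))), all(diag(d) == 0))
  attr(d, "undefined") <- undef
  d
}

#' Neighbor-joining tree from a p-distance matrix
#'
#' @param d symmetric distance matrix from [p_distance_matrix()] (>= 3 taxa)
#' @return unrooted `ape::phylo` tree with branch lengths
#' @export
nj_tree <- function(d) {
  if (nrow(d) < 3L) stop("neighbor-joining needs at least 3 taxa")
  if (anyNA(d)) {
    bad <- attr(d, "undefined") %||% "unknown pair"
    stop("undefined distance for pair(s): ", paste(bad, collapse = ", "))
  }
  ape::nj(d)
}

#' Bootstrap support for internal splits of the NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for each internal edge of the reference tree the
#' fraction of replicate trees containing the same split.
#'
#' @param seqs aligned sequences (named character vector)
#' @param replicates bootstrap replicates (paper-scale default 1000)
#' @param seed integer seed
#' @return list with `tree` (reference NJ tree, node labels set to supports)
#'   and `support` (numeric vector per internal node, NA for the root node)
#' @export
bootstrap_support <- function(seqs, replicates = 1000L, seed = 1L) {
  ref <- nj_tree(p_distance_matrix(seqs))
  if (replicates == 0L) return(list(tree = ref, support = numeric(0)))
  m <- aln_matrix(seqs)
  rownames(m) <- names(seqs)
  trees <- with_seed(seed, lapply(seq_len(replicates), function(i) {
    cols <- sample(ncol(m), ncol(m), replace = TRUE)
    s <- setNames(apply(m[, cols, drop = FALSE], 1, paste, collapse = ""),
                  names(seqs))
    dd <- p_distance_matrix(s)
    if (anyNA(dd)) return(NULL)
    nj_tree(dd)
  }))
  trees <- trees[!vapply(trees, is.null, NA)]
  cnt <- ape::prop.clades(ref, trees, rooted = FALSE)
  support <- cnt / length(trees)
  ref$node.label <- formatC(support, digits = 2, format = "f")
  list(tree = ref, support = support)
}

IUPAC_TO_BASES <- c(A = "A", C = "C", G = "G", T = "T",
                    R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
                    B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

#' IUPAC-degenerate consensus of an alignment
#'
#' A plain base is emitted when a strict majority of the non-gap residues
#' carry it; any split column (including a 50/50 tie, the way mismatching
#' TIR positions are displayed) gets the minimal IUPAC code covering the
#' observed bases (R, Y, S, W, K, M, ... N). Degenerate input codes vote
#' fractionally for each base they cover, which makes the consensus
#' idempotent. All-gap columns are dropped, as are columns where most rows
#' are gapped (the consensus tracks the common element body).
#'
#' @param seqs aligned DNA (named character vector, equal lengths)
#' @return consensus DNA string with IUPAC degeneracy codes
#' @export
degenerate_consensus <- function(seqs) {
  m <- aln_matrix(seqs)
  out <- apply(m, 2, function(col) {
    obs <- col[col %in% names(IUPAC_TO_BASES)]
    if (!length(obs)) return("")
    if (length(obs) < length(col) / 2) return("")
    votes <- c(A = 0, C = 0, G = 0, T = 0)
    for (ch in obs) {
      b <- chars(IUPAC_TO_BASES[[ch]])
      votes[b] <- votes[b] + 1 / length(b)
    }
    if (max(votes) / length(obs) > 0.5) return(names(votes)[which.max(votes)])
    key <- paste(sort(unique(unlist(strsplit(IUPAC_TO_BASES[obs], "")))), collapse = "")
    IUPAC_FROM_BASES[[key]]
  })
  paste(out, collapse = "")
}

#' Date a family's activity from divergence and TSD evidence
#'
#' `recent` when copies are nearly identical (mean within-family p-distance
#' <= 0.02) and at least two distinct TSDs prove independent insertions;
#' `ancient` when no TIR/TSD survives and mean divergence >= 0.15; otherwise
#' `unclear`.
#'
#' @param mean_pdist mean pairwise p-distance among members
#' @param tsds character vector of member TSD sequences (may be empty)
#' @param has_tir does the family have a TIR call?
#' @return one of `"recent"`, `"ancient"`, `"unclear"`
#' @export
date_activity <- function(mean_pdist, tsds, has_tir) {
  tsds <- tsds[!is.na(tsds) & nzchar(tsds)]
  if (!is.na(mean_pdist) && mean_pdist <= 0.02 && length(unique(tsds)) >= 2L)
    return("recent")
  if (!has_tir && !length(tsds) && !is.na(mean_pdist) && mean_pdist >= 0.15)
    return("ancient")
  "unclear"
}

single_linkage_clusters <- function(d, h) {
  n <- nrow(d)
  if (n == 1L) return(setNames(1L, rownames(d)))
  dd <- d
  dd[is.na(dd)] <- 1
  cl <- stats::cutree(stats::hclust(stats::as.dist(dd), method = "single"), h = h)
  setNames(cl, rownames(d))
}

# dissimilarity between two TIRs of possibly different lengths: hamming over
# the shared prefix / shared length
tir_dissimilarity <- function(a, b) {
  k <- min(nchar(a), nchar(b))
  if (k == 0L) return(1)
  hamming(substr(a, 1, k), substr(b, 1, k)) / k
}

#' Assign classified copies to families and groups
#'
#' Family candidates (TIR+TSD copies) are single-linkage clustered on
#' element p-distance at `family_linkage`; clusters whose members' TIRs
#' differ at more than `tir_split` of positions are split. Group members
#' (motif, no TIR+TSD) are clustered the same way. Ids are numbered by
#' descending member count (`F1`, `F2`, ... / `G1`, ...).
#'
#' @param copy_ids character vector of copy identifiers
#' @param element_seqs named character vector of element sequences (unaligned)
#' @param classification per-copy value from [classify_copy()]
#' @param tir5 named character vector of 5' TIR sequences (family candidates)
#' @param tsds named character vector of TSD sequences ("" when absent)
#' @param family_linkage maximum within-family p-distance (default 0.25)
#' @param tir_split TIR dissimilarity above which clusters split (default 0.3)
#' @return list with `families` and `groups` (lists of member/consensus
#'   records) and `assignment` data.frame (copy_id, id)
#' @export
assign_families <- function(copy_ids, element_seqs, classification,
                            tir5 = NULL, tsds = NULL,
                            family_linkage = 0.25, tir_split = 0.3) {
  stopifnot(length(copy_ids) == length(element_seqs),
            length(copy_ids) == length(classification))
  names(element_seqs) <- copy_ids
  res_fam <- cluster_class(copy_ids[classification == "family_candidate"],
                           element_seqs, family_linkage, tir5, tir_split)
  res_grp <- cluster_class(copy_ids[classification == "group_member"],
                           element_seqs, family_linkage, NULL, NULL)
  families <- finalize_clusters(res_fam, "F", element_seqs, tir5, tsds)
  groups <- finalize_clusters(res_grp, "G", element_seqs, NULL, NULL)
  assignment <- rbind(
    do.call(rbind, lapply(families, function(f)
      data.frame(copy_id = f$members, id = f$id, stringsAsFactors = FALSE))),
    do.call(rbind, lapply(groups, function(g)
      data.frame(copy_id = g$members, id = g$id, stringsAsFactors = FALSE))))
  list(families = families, groups = groups,
       assignment = assignment %||% data.frame(copy_id = character(),
                                               id = character()))
}

cluster_class <- function(ids, element_seqs, linkage, tir5, tir_split) {
  if (!length(ids)) return(list())
  if (length(ids) == 1L) return(list(ids))
  aln <- align_sequences(element_seqs[ids], type = "nt")
  d <- p_distance_matrix(aln)
  cl <- single_linkage_clusters(d, linkage)
  clusters <- split(names(cl), cl)
  if (!is.null(tir5) && !is.null(tir_split)) {
    out <- list()
    for (cluster in clusters) {
      if (length(cluster) == 1L) { out[[length(out) + 1L]] <- cluster; next }
      td <- outer(cluster, cluster, Vectorize(function(a, b)
        tir_dissimilarity(tir5[[a]] %||% "", tir5[[b]] %||% "")))
      dimnames(td) <- list(cluster, cluster)
      sub <- single_linkage_clusters(td, tir_split)
      out <- c(out, unname(split(names(sub), sub)))
    }
    clusters <- out
  }
  unname(clusters)
}

finalize_clusters <- function(clusters, prefix, element_seqs, tir5, tsds) {
  if (!length(clusters)) return(list())
  ord <- order(-vapply(clusters, length, 0L),
               vapply(clusters, function(x) sort(x)[1], ""))
  clusters <- clusters[ord]
  lapply(seq_along(clusters), function(i) {
    members <- sort(clusters[[i]])
    seqs <- element_seqs[members]
    if (length(members) >= 2L) {
      aln <- align_sequences(seqs, type = "nt")
      cons <- degenerate_consensus(aln)
      mp <- mean(p_distance_matrix(aln)[upper.tri(diag(length(members)))])
    } else { cons <- unname(seqs); mp <- NA_real_ }
    member_tirs <- if (!is.null(tir5)) unlist(tir5[members]) else character(0)
    tirc <- if (length(member_tirs) >= 2L) {
      k <- min(nchar(member_tirs))
      degenerate_consensus(substr(member_tirs, 1, k))
    } else if (length(member_tirs)) member_tirs[[1]] else NA_character_
    member_tsds <- if (!is.null(tsds)) unlist(tsds[members]) else character(0)
    list(id = paste0(prefix, i), members = members, consensus = cons,
         tir_consensus = tirc,
         modal_tsd_len = if (length(member_tsds))
           as.integer(names(sort(table(nchar(member_tsds)), decreasing = TRUE))[1])
         else NA_integer_,
         mean_pdist = mp,
         activity = if (prefix == "F")
           date_activity(mp, member_tsds, has_tir = TRUE)
         else date_activity(mp, character(0), has_tir = FALSE))
  })
}
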