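# End-to-end curation: translated search -> copy extraction -> boundary
# refinement from multi-copy alignments -> TIR/TSD calls -> classification ->
# family/group assignment -> tandem repeats -> contamination screening ->
# report.

#' Pipeline configuration
#'
#' Houses every tunable threshold. Defaults follow the curation protocol:
#' expect-value 1e-4 for first-round discovery and 1e-3 for the second
#' round, bacterial-contamination identity strictly above 0.80, TSD lengths
#' 7-10 bp (8-9 preferred), domain size filter >115 aa, identity clustering
#' at 70%, trimming at 0.4 gap threshold, final row filter at 110 aa,
#' family linkage at 0.25 p-distance.
#'
#' @param ... overrides of the defaults listed above
#' @return a `PipelineConfig` list
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    evalue_round1 = 1e-4, evalue_round2 = 1e-3,
    contamination_identity = 0.80, suspect_identity = 0.40,
    tir_len_range = c(10L, 462L), tsd_k_range = 7:10,
    domain_min_aa = 115L, final_min_aa = 110L,
    cluster_identity = 0.70, trim_gap_threshold = 0.4,
    bootstrap_reps = 1000L, family_linkage = 0.25,
    flank_bp = 2000L, merge_gap = 300L, min_orf_aa = 80L,
    boundary_margin = 1500L, seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "PipelineConfig")
}

validate_config <- function(cfg) {
  if (cfg$evalue_round1 <= 0 || cfg$evalue_round2 <= 0) stop("e-values must be positive")
  if (cfg$contamination_identity <= 0 || cfg$contamination_identity > 1)
    stop("contamination_identity must be in (0, 1]")
  if (cfg$family_linkage <= 0 || cfg$family_linkage >= 1)
    stop("family_linkage must be in (0, 1)")
  if (cfg$trim_gap_threshold < 0 || cfg$trim_gap_threshold > 1)
    stop("trim_gap_threshold must be in [0, 1]")
  invisible(cfg)
}

#' Read / write a pipeline configuration as JSON
#' @param cfg a `PipelineConfig`
#' @param path file path
#' @return `read_config` returns a `PipelineConfig`
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, x)
}

#' Run the full curation pipeline on a genome
#'
#' @param genome named character vector / `DNAStringSet` / FASTA path
#' @param queries query transposase proteins (same forms)
#' @param config a [pipeline_config()]
#' @param bacterial_set optional bacterial reference proteins for the
#'   contamination screen
#' @param out_dir optional directory for GFF3/TSV/FASTA outputs
#' @return a `CurationReport`: list with `copies` (per-copy table),
#'   `families`, `groups`, `calls` (per-copy TIR/TSD records), `config`
#' @export
run_pipeline <- function(genome, queries, config = pipeline_config(),
                         bacterial_set = NULL, out_dir = NULL) {
  genome <- as_named_seqs(genome)
  queries <- as_named_seqs(queries)
  empty <- function() structure(list(copies = empty_copies(), families = list(),
                                     groups = list(), calls = list(),
                                     config = config), class = "CurationReport")
  if (!length(genome) || all(!nzchar(genome))) return(empty())
  hits <- translated_search(genome, queries, config$evalue_round2)
  if (!nrow(hits)) return(empty())
  copies <- extract_copies(hits, genome, flank_bp = config$flank_bp,
                           merge_gap = config$merge_gap,
                           min_aa = config$min_orf_aa)
  copies <- refine_boundaries(copies, genome, config)
  cf <- call_features(copies, config)
  calls <- cf$calls
  copies <- cf$copies
  copies$classification <- vapply(seq_len(nrow(copies)), function(i) {
    st <- copies$status[i]
    motif <- if (st == "intact") "intact" else if (st == "frameshifted")
      "truncated_domain" else "absent"
    classify_copy(calls[[copies$copy_id[i]]]$tir_gg, calls[[copies$copy_id[i]]]$tsd, motif)
  }, "")
  elements <- setNames(copies$element_seq, copies$copy_id)
  tir5 <- lapply(calls, function(x) if (!is.null(x$tir_gg)) x$tir_gg$tir5[1] else NULL)
  tsds <- lapply(calls, function(x) if (!is.null(x$tsd)) x$tsd$left else "")
  fam <- assign_families(copies$copy_id, elements, copies$classification,
                         tir5 = tir5, tsds = tsds,
                         family_linkage = config$family_linkage)
  copies$family_id <- fam$assignment$id[match(copies$copy_id, fam$assignment$copy_id)]
  copies$segdup <- flag_segmental_duplication(copies)
  if (!is.null(bacterial_set)) {
    copies$contamination <- vapply(seq_len(nrow(copies)), function(i) {
      p <- copies$orf_protein[i]
      if (is.na(p)) return("clean")
      v <- screen_protein(p, bacterial_set, config$contamination_identity,
                          config$suspect_identity)
      if (v$protein_verdict == "suspect") {
        ctx <- screen_context(genome[[copies$contig[i]]], copies$start[i],
                              copies$end[i], bacterial_set)
        if (ctx$context_verdict == "suspect") "suspect" else "clean"
      } else v$protein_verdict
    }, "")
  }
  rep <- structure(list(copies = copies, families = fam$families,
                        groups = fam$groups, calls = calls, config = config),
                   class = "CurationReport")
  if (!is.null(out_dir)) write_report(rep, out_dir)
  rep
}

# refinement windows must not swallow a neighbouring copy: clip each
# segment halfway into the gap separating it from the nearest other hit
seg_floor <- function(copies, i) {
  others <- which(copies$contig == copies$contig[i] &
                    copies$end <= copies$start[i] &
                    seq_len(nrow(copies)) != i)
  if (!length(others)) return(0L)
  prev_end <- max(copies$end[others])
  prev_end + max(0L, (copies$start[i] - prev_end) %/% 2L)
}

seg_ceiling <- function(copies, i) {
  others <- which(copies$contig == copies$contig[i] &
                    copies$start >= copies$end[i] &
                    seq_len(nrow(copies)) != i)
  if (!length(others)) return(.Machine$integer.max)
  nxt <- min(copies$start[others])
  nxt - max(0L, (nxt - copies$end[i]) %/% 2L)
}

# distance over all alignment columns where either row is ungapped; a column
# gapped in exactly one of the two rows counts as a difference
gap_aware_distance <- function(aligned) {
  m <- aln_matrix(aligned)
  n <- nrow(m)
  lab <- names(aligned) %||% as.character(seq_len(n))
  d <- matrix(0, n, n, dimnames = list(lab, lab))
  gap <- m == "-" | m == "."
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    use <- !(gap[i, ] & gap[j, ])
    nc <- sum(use)
    d[i, j] <- d[j, i] <- if (nc == 0L) NA_real_ else
      sum(m[i, use] != m[j, use]) / nc
  }
  d
}

# refine element intervals by aligning same-cluster copies with trimmed flanks
refine_boundaries <- function(copies, genome, config) {
  n <- nrow(copies)
  margin <- config$boundary_margin
  copies$el_start <- copies$start; copies$el_end <- copies$end
  copies$boundary_conf <- "unresolved"
  if (n == 0L) { copies$element_seq <- character(0); return(copies) }
  # cluster on protein where available, fall back to singletons
  withp <- which(!is.na(copies$orf_protein) & nchar(copies$orf_protein) >= 60)
  clusters <- as.list(setdiff(seq_len(n), withp))
  if (length(withp) >= 2L) {
    aln <- align_sequences(setNames(copies$orf_protein[withp],
                                    copies$copy_id[withp]), type = "aa")
    # gap-aware distance: pairwise deletion would see only the conserved
    # blocks shared by unrelated families and merge them
    d <- gap_aware_distance(aln)
    cl <- single_linkage_clusters(d, 0.4)
    clusters <- c(clusters, unname(lapply(split(names(cl), cl), function(ids)
      match(ids, copies$copy_id))))
  } else clusters <- c(clusters, as.list(withp))
  for (idx in clusters) {
    if (length(idx) < 2L) next
    segs <- vapply(idx, function(i) {
      contig <- genome[[copies$contig[i]]]
      s <- max(0L, copies$start[i] - margin, seg_floor(copies, i))
      e <- min(nchar(contig), copies$end[i] + margin, seg_ceiling(copies, i))
      substr(contig, s + 1L, e)
    }, "")
    offs <- vapply(idx, function(i)
      max(0L, copies$start[i] - margin, seg_floor(copies, i)), 0L)
    names(segs) <- copies$copy_id[idx]
    # orient minus-strand copies to the element strand before aligning
    minus <- copies$strand[idx] == "-"
    segs[minus] <- vapply(segs[minus], revcomp, "")
    aln <- align_sequences(segs, type = "nt")
    bc <- infer_boundaries(aln[copies$copy_id[idx]])
    if (is.null(bc$per_copy)) next
    for (k in seq_along(idx)) {
      i <- idx[k]
      pc <- bc$per_copy[bc$per_copy$label == copies$copy_id[i], ]
      if (!nrow(pc)) next
      seglen <- nchar(segs[[copies$copy_id[i]]])
      if (minus[k]) {   # map back through the reverse complement
        s0 <- seglen - pc$end; e0 <- seglen - pc$start
        ok_s <- bc$conf3 != "unresolved"; ok_e <- bc$conf5 != "unresolved"
      } else {
        s0 <- pc$start; e0 <- pc$end
        ok_s <- bc$conf5 != "unresolved"; ok_e <- bc$conf3 != "unresolved"
      }
      # an unresolved end carries no flank signal; keep the provisional bound
      if (ok_s) copies$el_start[i] <- offs[k] + s0
      if (ok_e) copies$el_end[i] <- offs[k] + e0
      copies$boundary_conf[i] <- paste(bc$conf5, bc$conf3, sep = "/")
    }
  }
  copies$element_seq <- vapply(seq_len(n), function(i) {
    contig <- genome[[copies$contig[i]]]
    el <- substr(contig, copies$el_start[i] + 1L, copies$el_end[i])
    if (copies$strand[i] == "-") revcomp(el) else el
  }, "")
  copies$flank5_ref <- vapply(seq_len(n), function(i) {
    contig <- genome[[copies$contig[i]]]
    s <- max(0L, copies$el_start[i] - 40L)
    f5 <- substr(contig, s + 1L, copies$el_start[i])
    f3 <- substr(contig, copies$el_end[i] + 1L,
                 min(nchar(contig), copies$el_end[i] + 40L))
    if (copies$strand[i] == "-") revcomp(f3) else f5
  }, "")
  copies$flank3_ref <- vapply(seq_len(n), function(i) {
    contig <- genome[[copies$contig[i]]]
    s <- max(0L, copies$el_start[i] - 40L)
    f5 <- substr(contig, s + 1L, copies$el_start[i])
    f3 <- substr(contig, copies$el_end[i] + 1L,
                 min(nchar(contig), copies$el_end[i] + 40L))
    if (copies$strand[i] == "-") revcomp(f5) else f3
  }, "")
  copies
}

# Per-copy TIR/TSD calling. The best TIR pair compatible with the terminal
# GG...CC convention (up to 1 deviating position) re-anchors the element
# limits before the TSD search, mirroring the manual practice of settling
# boundaries where TIR and TSD evidence agree.
call_features <- function(copies, config) {
  calls <- list()
  for (i in seq_len(nrow(copies))) {
    el <- copies$element_seq[i]
    f5 <- copies$flank5_ref[i]; f3 <- copies$flank3_ref[i]
    tir <- tir_gg <- NULL; tsd <- NULL
    if (nchar(el) > 2L * config$tir_len_range[1] + 10L) {
      # anchors searched up to ~30 bp from each nominal end, including into
      # the flanks: alignment-derived boundaries can be off by a few tens
      # of bp in either direction
      pad5 <- substr(f5, max(1L, nchar(f5) - 29L), nchar(f5))
      pad3 <- substr(f3, 1L, 30L)
      ext <- paste0(pad5, el, pad3)
      tirs <- find_tirs(ext, min_len = config$tir_len_range[1],
                        max_len = config$tir_len_range[2], require_gg = FALSE,
                        max_offset = nchar(pad5) + 30L)
      if (nrow(tirs)) {
        tirs$start5 <- tirs$start5 - nchar(pad5)
        tirs$end3 <- tirs$end3 - nchar(pad5)
        tir <- tirs[1, ]
        ggmm <- vapply(seq_len(nrow(tirs)), function(r)
          tir_gg_mismatches(tirs[r, ]), 0L)
        ok <- which(ggmm <= 1L)
        if (length(ok)) {
          # among GG anchors near the nominal termini pick the best score
          # (a weak genuine TIR at the boundary beats a stronger repeat
          # elsewhere in the window); only when none is near do distant
          # anchors compete on score alone
          prox <- abs(tirs$start5[ok]) + abs((nchar(el) - 1L) - tirs$end3[ok])
          near <- ok[prox <= 6L]
          pick <- if (length(near)) near[which.max(tirs$score[near])]
                  else ok[which.max(tirs$score[ok])]
          tir_gg <- tirs[pick, ]
        }
      }
    }
    # only a repeat clearly above chance is allowed to move the limits
    if (!is.null(tir_gg) && tir_gg$score >= 8) {
      # re-set the element limits to the TIR anchors; bases move between
      # element and flanks in either direction
      a <- tir_gg$start5; b <- tir_gg$end3
      ntrim3 <- nchar(el) - 1L - b
      full <- paste0(f5, el, f3)
      o5 <- nchar(f5)
      el <- substr(full, o5 + a + 1L, o5 + b + 1L)
      f5_new <- substr(full, 1L, o5 + a)
      f3 <- substr(full, o5 + b + 2L, nchar(full))
      f5 <- f5_new
      tir_gg$start5 <- 0L; tir_gg$end3 <- nchar(el) - 1L
      if (copies$strand[i] == "+") {
        copies$el_start[i] <- copies$el_start[i] + a
        copies$el_end[i] <- copies$el_end[i] - ntrim3
      } else {
        copies$el_start[i] <- copies$el_start[i] + ntrim3
        copies$el_end[i] <- copies$el_end[i] - a
      }
      copies$element_seq[i] <- el
    }
    if (nchar(f5) >= max(config$tsd_k_range) &&
        nchar(f3) >= max(config$tsd_k_range)) {
      tsd <- find_tsd(f5, f3, element = el, k_range = config$tsd_k_range,
                      gg_convention = TRUE)
      if (is.null(tsd) && grepl("fuzzy|unresolved", copies$boundary_conf[i])) {
        # a fuzzy alignment boundary can be off by more than the default
        # jitter; the exact flanking duplication is the sharper instrument
        tsd <- find_tsd(f5, f3, element = el, k_range = config$tsd_k_range,
                        jitter = 10L, gg_convention = TRUE)
      }
    }
    if (!is.null(tsd) && (tsd$shift5 != 0L || tsd$shift3 != 0L)) {
      # an exact flanking duplication pins the element limits: absorb the
      # boundary jitter the TSD search detected
      d5 <- tsd$shift5; d3 <- tsd$shift3
      new_el <- substr(paste0(el, substr(f3, 1L, max(0L, d3))),
                       d5 + 1L, nchar(el) + d3)
      if (d5 < 0L) new_el <- paste0(substr(f5, nchar(f5) + d5 + 1L, nchar(f5)), new_el)
      el <- new_el
      if (copies$strand[i] == "+") {
        copies$el_start[i] <- copies$el_start[i] + d5
        copies$el_end[i] <- copies$el_end[i] + d3
      } else {
        copies$el_start[i] <- copies$el_start[i] - d3
        copies$el_end[i] <- copies$el_end[i] - d5
      }
      copies$element_seq[i] <- el
      tsd$shift5 <- 0L; tsd$shift3 <- 0L
      # re-anchor the TIR call on the corrected termini
      if (nchar(el) > 2L * config$tir_len_range[1] + 10L) {
        tirs2 <- find_tirs(el, min_len = config$tir_len_range[1],
                           max_len = config$tir_len_range[2], max_offset = 2L)
        if (nrow(tirs2)) {
          tir <- tirs2[1, ]
          ggmm2 <- vapply(seq_len(nrow(tirs2)), function(r)
            tir_gg_mismatches(tirs2[r, ]), 0L)
          ok2 <- which(ggmm2 <= 1L)
          if (length(ok2)) tir_gg <- tirs2[ok2[1], ]
        }
      }
    }
    calls[[copies$copy_id[i]]] <- list(tir = tir, tir_gg = tir_gg, tsd = tsd)
  }
  list(calls = calls, copies = copies)
}

#' Write the report's tabular outputs
#' @param report a `CurationReport`
#' @param out_dir output directory (created if missing)
#' @return out_dir, invisibly
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cp <- report$copies
  if (nrow(cp)) {
    tab <- cp[, setdiff(names(cp), c("window", "flank5", "flank3",
                                     "element_seq", "flank5_ref", "flank3_ref"))]
    write.table(tab, file.path(out_dir, "copies.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_copies_gff3(within(cp, { start <- el_start; end <- el_end }),
                      file.path(out_dir, "copies.gff3"),
                      calls = report$calls)
    write_fasta(setNames(cp$element_seq, cp$copy_id),
                file.path(out_dir, "elements.fa"))
  }
  fams <- c(report$families, report$groups)
  if (length(fams)) {
    ft <- do.call(rbind, lapply(fams, function(f) data.frame(
      id = f$id, n_members = length(f$members),
      members = paste(f$members, collapse = ","),
      modal_tsd_len = f$modal_tsd_len, mean_pdist = f$mean_pdist,
      activity = f$activity, stringsAsFactors = FALSE)))
    write.table(ft, file.path(out_dir, "families.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_fasta(setNames(vapply(fams, `[[`, "", "consensus"),
                         vapply(fams, `[[`, "", "id")),
                file.path(out_dir, "consensus.fa"))
  }
  invisible(out_dir)
}
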