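# Reconstruction experiments: each function rebuilds one of the published
# structural findings as a simulated study condition (the printed parameters
# are the inputs), runs the real pipeline on it, and returns the measured
# quantities. The analysis scripts and the acceptance checks are thin
# wrappers over these.

modal <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  as.numeric(names(sort(table(x), decreasing = TRUE))[1])
}

bench_pipeline <- function(specs, seed, background_length = 40000L, ...) {
  sim <- simulate_genome(specs, background_length = background_length,
                         seed = seed, ...)
  q <- setNames(sim$truth$proteins, paste0("q_", names(sim$truth$proteins)))
  list(sim = sim, report = run_pipeline(sim$genome, q))
}

family_of <- function(report, min_members = 2L) {
  sizes <- vapply(report$families, function(f) length(f$members), 0L)
  if (!length(sizes) || max(sizes) < min_members) return(NULL)
  report$families[[which.max(sizes)]]
}

#' Reconstruction: red-algal family with 39-bp TIRs and 9-bp TSDs
#'
#' Two near-identical copies (99% nucleotide identity, imperfect 39-bp TIRs,
#' one 9-bp TSD per flank) planted and re-curated by the pipeline. Returns
#' the measured TIR length, modal TSD length, and pairwise nucleotide
#' identity (%) between the two recovered copies.
#'
#' @param seed integer seed
#' @return named list of measured quantities
#' @export
bench_rhodophyte <- function(seed = 1L) {
  spec <- family_spec("Ppur", tir_length = 39L, tir_mismatches = 2L,
                      tsd_length = 9L, orf_length = 319L, n_copies = 2L,
                      per_copy_divergence = 0.005, element_length = 1500L)
  bp <- bench_pipeline(list(spec), seed = seed * 1000L + 1L,
                       background_length = 15000L)
  rep <- bp$report
  fam <- family_of(rep)
  tirs <- vapply(fam$members, function(id) {
    t <- rep$calls[[id]]$tir_gg
    if (is.null(t)) NA_integer_ else t$length
  }, 0L)
  tsds <- vapply(fam$members, function(id) {
    t <- rep$calls[[id]]$tsd
    if (is.null(t)) NA_integer_ else t$k
  }, 0L)
  els <- setNames(rep$copies$element_seq, rep$copies$copy_id)[fam$members]
  d <- p_distance_matrix(align_sequences(els, "nt"))
  # the family TIR length is read from the best-preserved copy: private
  # substitutions shorten the detectable repeat on individual copies
  list(tir_length_bp = max(tirs, na.rm = TRUE), tsd_bp = modal(tsds),
       pairwise_nt_identity_pct = 100 * (1 - d[1, 2]),
       n = length(fam$members))
}

#' Reconstruction: dinoflagellate family Sy.m_F1
#'
#' A recently active family: 51-bp TIRs, 8-bp TSDs, ~2.57-kb element, and a
#' 5' tract of 2.3 units of a 52-bp tandem repeat containing 5 units of a
#' 6-bp repeat. Measures the recovered TIR length, element span, and the
#' nested tandem periods/copy number on the family consensus.
#'
#' @param seed integer seed
#' @return named list of measured quantities
#' @export
bench_symbiodinium_f1 <- function(seed = 1L) {
  spec <- family_spec("SymF1", tir_length = 51L, tir_mismatches = 2L,
                      tsd_length = 8L, orf_length = 450L, n_copies = 4L,
                      per_copy_divergence = 0.005, element_length = 2570L,
                      tandem_spec = list(period = 52L, units = 2.3,
                                         nested = list(period = 6L, units = 5L)))
  bp <- bench_pipeline(list(spec), seed = seed * 1000L + 2L,
                       background_length = 40000L)
  rep <- bp$report
  fam <- family_of(rep)
  tirs <- vapply(fam$members, function(id) {
    t <- rep$calls[[id]]$tir_gg
    if (is.null(t)) NA_integer_ else t$length
  }, 0L)
  spans <- rep$copies$el_end - rep$copies$el_start
  spans <- spans[rep$copies$copy_id %in% fam$members]
  # tandem scan over the 5' internal region of the family consensus
  region <- substr(fam$consensus, 52L, 900L)
  calls <- find_tandem_repeats(gsub("[^ACGT]", "N", region), min_period = 2L,
                               max_period = 80L)
  big <- calls[abs(calls$period - 52L) <= 1L, ]
  small <- calls[calls$period == 6L, ]
  list(tir_length_bp = max(tirs, na.rm = TRUE),
       element_span_kb = stats::median(spans) / 1000,
       tandem_period_bp = if (nrow(big)) big$period[which.max(big$score)] else NA,
       tandem_units = if (nrow(big)) big$copy_number[which.max(big$score)] else NA,
       nested_period_bp = if (nrow(small)) small$period[which.max(small$score)] else NA,
       n = length(fam$members))
}

#' Reconstruction: highly imperfect TIRs of Sy.k_F1
#'
#' Copies with 12 mismatches between the first 26 positions of the 5' TIR
#' and the reverse complement of the 3' TIR; limits are settled by the
#' pipeline via multi-copy alignment and TSD evidence, then the terminal
#' mismatches are counted.
#'
#' @param seed integer seed
#' @return named list with the modal mismatch count over 26 positions
#' @export
bench_symbiodinium_kawagutii_f1 <- function(seed = 1L) {
  spec <- family_spec("SykF1", tir_length = 26L, tir_mismatches = 12L,
                      tsd_length = 8L, orf_length = 350L, n_copies = 4L,
                      per_copy_divergence = 0.01, element_length = 1800L)
  bp <- bench_pipeline(list(spec), seed = seed * 1000L + 3L,
                       background_length = 30000L)
  rep <- bp$report
  fam <- family_of(rep)
  # counted on the strict-majority family consensus, where private per-copy
  # substitutions are voted away and only the fixed TIR divergence remains
  mism <- count_tir_mismatches(fam$consensus, 26L)
  list(tir_mismatches_in_26 = mism, n = length(fam$members))
}

#' Reconstruction: Sy.k_F2 tandem repeat (4 units of 163 bp)
#'
#' @param seed integer seed
#' @return named list with the recovered period and unit count
#' @export
bench_symbiodinium_kawagutii_f2 <- function(seed = 1L) {
  spec <- family_spec("SykF2", tir_length = 26L, tir_mismatches = 2L,
                      tsd_length = 8L, orf_length = 350L, n_copies = 2L,
                      per_copy_divergence = 0.005, element_length = 2400L,
                      tandem_spec = list(period = 163L, units = 4))
  bp <- bench_pipeline(list(spec), seed = seed * 1000L + 4L,
                       background_length = 25000L)
  rep <- bp$report
  copy1 <- rep$copies$element_seq[1]
  calls <- find_tandem_repeats(copy1, min_period = 10L, max_period = 200L)
  top <- calls[which.max(calls$score), ]
  list(tandem_period_bp = top$period, tandem_units = top$copy_number,
       n = nrow(rep$copies))
}

#' Reconstruction: seven co-existing families in one genome
#'
#' Seven families with distinct 23-29 bp TIRs, all with 8-bp TSDs, three
#' copies each; the pipeline must separate all seven.
#'
#' @param seed integer seed
#' @return named list with the number of recovered families
#' @export
bench_monocercomonoides <- function(seed = 1L) {
  specs <- lapply(1:7, function(i)
    family_spec(paste0("M", i), tir_length = 22L + i, tsd_length = 8L,
                orf_length = 280L, n_copies = 3L, per_copy_divergence = 0.02,
                element_length = 1300L))
  bp <- bench_pipeline(specs, seed = seed * 1000L + 5L,
                       background_length = 250000L, min_gap = 4000L)
  list(n_families = length(bp$report$families),
       n = nrow(bp$report$copies))
}

#' Reconstruction: kinetoplastid reference copies and their divergence
#'
#' A 762-bp reference copy whose two genomic copies show 85% nucleotide
#' identity over the ORF and 81% amino-acid identity over the 199-residue
#' conserved core, plus a cross-species protein pair at 43% identity over a
#' 219-residue region. All identities are measured, not asserted: p-distance
#' for the copy pair, local alignment for the cross-species pair.
#'
#' @param seed integer seed
#' @return named list of measured quantities
#' @export
bench_kinetoplastid <- function(seed = 1L) {
  pair <- sim_diverged_orf_pair(aa_len = 253L, core_len = 199L,
                                nt_divergence = 0.15, core_aa_divergence = 0.19,
                                seed = seed * 1000L + 6L)
  dnt <- p_distance_matrix(c(a = pair$nt1, b = pair$nt2))["a", "b"]
  core1 <- substr(pair$aa1, pair$core[1], pair$core[2])
  core2 <- substr(pair$aa2, pair$core[1], pair$core[2])
  daa <- p_distance_matrix(c(a = core1, b = core2))["a", "b"]
  hp <- sim_homolog_pair(region_len = 219L, identity = 0.43, similarity = 0.64,
                         seed = seed * 1000L + 7L)
  al <- Biostrings::pairwiseAlignment(Biostrings::AAString(hp$a),
                                      Biostrings::AAString(hp$b),
                                      type = "local",
                                      substitutionMatrix = "BLOSUM62",
                                      gapOpening = 10, gapExtension = 0.5)
  list(reference_copy_len_bp = nchar(pair$nt1),
       copy_nt_identity_pct = 100 * (1 - dnt),
       copy_aa_identity_pct = 100 * (1 - daa),
       cross_species_aa_identity_pct = Biostrings::pid(al, type = "PID1"),
       n = 2L)
}

#' Recall of intact planted copies under divergence
#'
#' Across `n_seeds` simulated genomes, five intact copies at 15% per-site
#' divergence are planted and searched with the family's own transposase;
#' returns the percentage of planted copies recovered by the translated
#' search + extraction stages.
#'
#' @param seed integer seed
#' @param n_seeds number of independent genomes (default 20)
#' @param divergence per-site substitution probability (default 0.15)
#' @return named list with recall_pct and the number of copies assessed
#' @export
bench_recall <- function(seed = 1L, n_seeds = 20L, divergence = 0.15) {
  found <- total <- 0L
  for (k in seq_len(n_seeds)) {
    sim <- simulate_genome(
      family_spec("F1", n_copies = 5L, per_copy_divergence = divergence,
                  orf_length = 300L),
      background_length = 40000L, seed = seed * 1000L + 100L + k)
    hits <- translated_search(sim$genome, c(q = sim$truth$proteins[["F1"]]), 1e-3)
    cp <- extract_copies(hits, sim$genome)
    tr <- sim$truth$copies
    for (i in seq_len(nrow(tr))) {
      total <- total + 1L
      if (nrow(cp) && any(cp$contig == tr$contig[i] & cp$start < tr$end[i] &
                            cp$end > tr$start[i])) found <- found + 1L
    }
  }
  list(recall_pct = 100 * found / total, n = total)
}
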