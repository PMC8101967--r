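test_that("family_spec rejects invalid fields by name", {
  expect_error(family_spec("F1", tir_length = 5), "tir_length")
  expect_error(family_spec("F1", tsd_length = 6), "tsd_length")
  expect_error(family_spec("F1", per_copy_divergence = 0.7), "per_copy_divergence")
  expect_error(family_spec("F1", tir_length = 20, tir_mismatches = 20), "tir_mismatches")
})

test_that("zero-divergence copies carry identical per-copy TSDs, distinct across copies", {
  sim <- simulate_genome(family_spec("F1", tir_length = 30, tsd_length = 8,
                                     n_copies = 3, per_copy_divergence = 0),
                         background_length = 20000, seed = 3)
  tr <- sim$truth$copies
  expect_equal(nrow(tr), 3L)
  g <- sim$genome[["contig_1"]]
  for (i in 1:3) {
    left <- substr(g, tr$start[i] - 7, tr$start[i])
    right <- substr(g, tr$end[i] + 1, tr$end[i] + 8)
    expect_identical(left, tr$tsd[i])
    expect_identical(right, tr$tsd[i])
  }
  expect_equal(length(unique(tr$tsd)), 3L)
})

test_that("planted imperfect TIRs have the requested Hamming distance", {
  # the highly imperfect case: 12 mismatches in a 26-bp TIR
  sim <- simulate_genome(family_spec("SykF1", tir_length = 26, tir_mismatches = 12,
                                     tsd_length = 8, n_copies = 2),
                         background_length = 15000, seed = 9)
  g <- sim$genome[["contig_1"]]
  tr <- sim$truth$copies[1, ]
  el <- substr(g, tr$start + 1, tr$end)
  tir5 <- substr(el, 1, 26)
  tir3 <- substr(el, nchar(el) - 25, nchar(el))
  expect_equal(hamming(tir5, revcomp(tir3)), 12L)
  expect_true(startsWith(tir5, "GG"))
  expect_true(endsWith(tir3, "CC"))
})

test_that("the same seed reproduces genome and truth byte-for-byte", {
  specs <- list(family_spec("F1", n_copies = 2, per_copy_divergence = 0.05,
                            frameshift_fraction = 0.5))
  a <- simulate_genome(specs, background_length = 15000, contaminant_count = 1, seed = 42)
  b <- simulate_genome(specs, background_length = 15000, contaminant_count = 1, seed = 42)
  expect_identical(a$genome, b$genome)
  expect_identical(a$truth$copies, b$truth$copies)
  c <- simulate_genome(specs, background_length = 15000, contaminant_count = 1, seed = 43)
  expect_false(identical(a$genome, c$genome))
})

test_that("background smaller than the element footprint is rejected", {
  expect_error(simulate_genome(family_spec("F1", n_copies = 10),
                               background_length = 2000, seed = 1),
               "footprint")
})

test_that("mutate_copy matches its binomial substitution model", {
  seq <- with_seed(1, random_dna(1000))
  expect_identical(mutate_copy(seq, 0), seq)
  subs <- vapply(1:100, function(s) hamming(seq, mutate_copy(seq, 0.15, seed = s)), 0)
  # substitutions ~ Binomial(1000, 0.15): mean 150, sd ~ 11.3
  expect_lt(abs(mean(subs) - 150), 3 * sqrt(1000 * 0.15 * 0.85))
  expect_error(mutate_copy("ACGU", 0.1), "non-DNA")
  expect_equal(hamming(seq, mutate_copy(seq, 0.15, seed = 7, exact = TRUE)), 150)
})

test_that("an ORF indel breaks the reading frame seen by the ORF scanner", {
  sim <- simulate_genome(family_spec("F1", n_copies = 1, orf_length = 300),
                         background_length = 10000, seed = 5)
  tr <- sim$truth$copies[1, ]
  el <- substr(sim$genome[["contig_1"]], tr$start + 1, tr$end)
  orfs0 <- find_orfs(el, 250)
  expect_equal(nrow(orfs0), 1L)
  broken <- mutate_copy(el, 0, indel_rate = 0.002, seed = 3)
  orfs1 <- find_orfs(broken, 250)
  expect_lt(nrow(orfs1), nrow(orfs0) + 1L)  # no full-length ORF survives
  expect_true(nrow(orfs1) == 0L || max(nchar(orfs1$protein)) < 299)
})

test_that("truth round-trips through write_truth/read_truth and exports valid GFF3", {
  sim <- simulate_genome(family_spec("F1", n_copies = 3), background_length = 20000,
                         contaminant_count = 2, seed = 8)
  pre <- file.path(tempdir(), "truth_test")
  write_truth(sim$truth, pre)
  back <- read_truth(pre)
  expect_equal(back$copies, sim$truth$copies)
  expect_equal(back$contaminants, sim$truth$contaminants)
  expect_equal(back$seed, sim$truth$seed)
  gff <- rtracklayer::import(paste0(pre, ".gff3"))
  expect_equal(sum(gff$type == "transposable_element"), 3)
  expect_equal(sum(gff$type == "terminal_inverted_repeat"), 6)
  expect_equal(sum(gff$type == "target_site_duplication"), 6)
  # 1-based inclusive GFF coordinates vs 0-based half-open internal
  el <- gff[gff$type == "transposable_element"]
  tr <- sim$truth$copies
  expect_equal(sort(GenomicRanges::start(el)), sort(tr$start + 1L))
  expect_equal(sort(GenomicRanges::end(el)), sort(tr$end))

  empty <- structure(list(copies = tircurator:::empty_truth_copies(),
                          contaminants = character(0), seed = 1L),
                     class = "SimTruth")
  pre2 <- file.path(tempdir(), "truth_empty")
  expect_no_error(write_truth(empty, pre2))
  expect_equal(nrow(read_truth(pre2)$copies), 0L)
})

test_that("remnant and frameshifted statuses are planted as requested", {
  sim <- simulate_genome(family_spec("F1", n_copies = 4, frameshift_fraction = 0.25,
                                     remnant_fraction = 0.25),
                         background_length = 30000, seed = 13)
  tab <- table(sim$truth$copies$status)
  expect_equal(unname(tab[["frameshifted"]]), 1L)
  expect_equal(unname(tab[["remnant"]]), 1L)
  expect_equal(unname(tab[["intact"]]), 2L)
  rem <- sim$truth$copies[sim$truth$copies$status == "remnant", ]
  full <- sim$truth$copies[sim$truth$copies$status == "intact", ][1, ]
  ratio <- (rem$end - rem$start) / (full$end - full$start)
  expect_gt(ratio, 0.35); expect_lt(ratio, 0.85)
})

test_that("segmental duplication copies share their recorded flanks", {
  sim <- simulate_genome(family_spec("F1", n_copies = 2, n_segdup = 1),
                         background_length = 25000, seed = 21)
  tr <- sim$truth$copies
  sd <- tr[tr$status == "segdup", ]
  orig <- tr[tr$copy_in_family == 1L & tr$status != "segdup", ]
  expect_equal(nrow(sd), 1L)
  g <- sim$genome[["contig_1"]]
  f5a <- substr(g, orig$start - orig$tsd_len - 299, orig$start - orig$tsd_len)
  f5b <- substr(g, sd$start - sd$tsd_len - 299, sd$start - sd$tsd_len)
  expect_identical(f5a, f5b)
})
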