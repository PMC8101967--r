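# literal re-statement of the TIR extension definition as a brute-force oracle
oracle_best_tir <- function(seq, min_len = 10, max_mismatch_frac = 0.5,
                            max_offset = 8, stop_run = 4) {
  v <- strsplit(toupper(seq), "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  n <- length(v)
  best <- NULL
  for (s in 0:max_offset) for (e in (n - 1):(n - 1 - max_offset)) {
    if (e <= s + 2 * min_len) next
    maxt <- min(462, (e - s + 1) %/% 2)
    mism <- 0; run <- 0
    for (t in seq_len(maxt)) {
      if (v[s + t] == comp[[v[e - t + 2]]]) run <- 0
      else { mism <- mism + 1; run <- run + 1 }
      if (run >= stop_run) break
      if (t >= min_len && mism / t <= max_mismatch_frac) {
        sc <- t - 2 * mism
        if (is.null(best) || sc > best$score)
          best <- list(score = sc, length = t, mismatches = mism, s = s, e = e)
      }
      if (mism / t > max_mismatch_frac && t >= min_len) break
    }
  }
  best
}

plant_tir_toy <- function(tir_len, mism, inner_len = 150, seed = 1) {
  with_seed(seed, {
    tir5 <- random_dna(tir_len)
    pos <- if (mism > 0) sample(tir_len, mism) else integer(0)
    t3 <- strsplit(tir5, "")[[1]]
    for (p in pos) t3[p] <- sample(setdiff(c("A","C","G","T"), t3[p]), 1)
    tir3 <- revcomp(paste(t3, collapse = ""))
    paste0(tir5, random_dna(inner_len), tir3)
  })
}

test_that("a perfect planted TIR is the top-ranked candidate", {
  el <- plant_tir_toy(30, 0, seed = 41)
  tirs <- find_tirs(el)
  expect_gt(nrow(tirs), 0)
  expect_equal(tirs$length[1], 30L)
  expect_equal(tirs$mismatches[1], 0L)
  expect_equal(tirs$start5[1], 0L)
})

test_that("a highly imperfect 26-bp TIR with 12 mismatches is recovered", {
  sim <- simulate_genome(family_spec("SykF1", tir_length = 26, tir_mismatches = 12,
                                     tsd_length = 8, n_copies = 1),
                         background_length = 8000, seed = 42)
  e <- truth_element(sim, 1)
  expect_equal(count_tir_mismatches(e$element, 26), 12L)
  # the detector still reports an imperfect repeat anchored at the termini
  tirs <- find_tirs(e$element, require_gg = FALSE, max_offset = 2)
  anchored <- tirs[tirs$start5 == 0 & tirs$end3 == nchar(e$element) - 1, ]
  expect_gt(nrow(anchored), 0)
  expect_gt(anchored$mismatches[1], 0)
})

test_that("the inverted-repeat search agrees with a brute-force oracle", {
  for (seed in 1:6) {
    el <- plant_tir_toy(sample(15:40, 1), sample(0:4, 1), inner_len = 200,
                        seed = 100 + seed)
    got <- find_tirs(el)
    want <- oracle_best_tir(el)
    expect_equal(got$score[1], want$score)
    expect_equal(got$length[1], want$length)
    expect_equal(got$mismatches[1], want$mismatches)
  }
})

test_that("mismatch counts are recomputable from the reported TIR pair", {
  for (seed in 1:5) {
    el <- plant_tir_toy(25, sample(0:6, 1), seed = 200 + seed)
    tirs <- find_tirs(el)
    for (i in seq_len(min(5, nrow(tirs)))) {
      expect_equal(hamming(tirs$tir5[i], revcomp(tirs$tir3[i])), tirs$mismatches[i])
      expect_equal(nchar(tirs$tir5[i]), tirs$length[i])
      expect_lte(tirs$mismatches[i], tirs$length[i])
      expect_identical(tirs$terminal_gg[i],
                       startsWith(tirs$tir5[i], "GG") && endsWith(tirs$tir3[i], "CC"))
    }
  }
})

test_that("the TIR search is strand-symmetric", {
  el <- plant_tir_toy(30, 2, seed = 43)
  a <- find_tirs(el)[1, ]
  b <- find_tirs(revcomp(el))[1, ]
  expect_equal(b$length, a$length)
  expect_equal(b$mismatches, a$mismatches)
  expect_identical(b$tir5, revcomp(a$tir3))
  expect_identical(b$tir3, revcomp(a$tir5))
})

test_that("boundary inference locates planted limits within 3 bp", {
  with_seed(44, {
    el <- mutate_copy(plant_tir_toy(30, 0, inner_len = 600), 0)
    copies <- setNames(lapply(1:3, function(i)
      paste0(random_dna(150), mutate_copy(el, 0.05, seed = i), random_dna(150))),
      paste0("c", 1:3))
    aln <- align_sequences(unlist(copies), type = "nt")
    bc <- infer_boundaries(aln)
    expect_equal(bc$support, 3L)
    for (r in seq_len(3)) {
      pc <- bc$per_copy[r, ]
      expect_lte(abs(pc$start - 150), 3)
      expect_lte(abs(pc$end - (150 + nchar(el))), 3)
    }
  })
})

test_that("identical flanks or missing flanks leave boundaries unresolved", {
  with_seed(45, {
    el <- plant_tir_toy(20, 0, inner_len = 400)
    flank5 <- random_dna(150); flank3 <- random_dna(150)
    segdup <- setNames(rep(paste0(flank5, el, flank3), 2), c("a", "b"))
    bc <- infer_boundaries(segdup)
    expect_true(bc$conf5 == "unresolved" && bc$conf3 == "unresolved")
    bare <- setNames(rep(el, 2), c("a", "b"))
    bc2 <- infer_boundaries(bare)
    expect_true(bc2$conf5 == "unresolved" && bc2$conf3 == "unresolved")
    single <- infer_boundaries(el[1])
    expect_equal(single$conf5, "unresolved")
  })
})

test_that("TSD detection finds flanking duplications with the longest-k tie rule", {
  with_seed(46, {
    f5 <- paste0(random_dna(30), "ACGTACGT")
    f3 <- paste0("ACGTACGT", random_dna(30))
    tsd <- find_tsd(f5, f3)
    expect_equal(tsd$k, 8L)
    expect_identical(tsd$left, "ACGTACGT")
    expect_true(tsd$exact)
    # both a 9-mer and its 8-mer suffix match: the 9-mer wins
    f5b <- paste0(random_dna(30), "TACGTACGT")
    f3b <- paste0("TACGTACGT", random_dna(30))
    expect_equal(find_tsd(f5b, f3b)$k, 9L)
    expect_null(find_tsd(random_dna(40), random_dna(40)))
    expect_message(out <- find_tsd("ACG", random_dna(40)), "truncated")
    expect_null(out)
  })
})

test_that("every intact simulated copy yields its planted TSD, all distinct", {
  sim <- simulate_genome(family_spec("F1", tsd_length = 9, n_copies = 4),
                         background_length = 30000, seed = 47)
  seen <- character(0)
  for (i in seq_len(4)) {
    e <- truth_element(sim, i)
    tsd <- find_tsd(e$flank5, e$flank3, element = e$element)
    expect_equal(tsd$k, 9L)
    expect_identical(tsd$left, e$truth$tsd)
    seen <- c(seen, tsd$left)
  }
  expect_equal(length(unique(seen)), 4L)
})

test_that("copy classification combines TIR, TSD and motif evidence", {
  tir <- data.frame(terminal_gg = TRUE, length = 10,
                    tir5 = "GGACGTACGT", tir3 = "ACGTACGTCC")
  tsd <- structure(list(k = 8), class = "Tsd")
  expect_equal(classify_copy(tir, tsd, "intact"), "family_candidate")
  expect_equal(classify_copy(NULL, NULL, "intact"), "group_member")
  expect_equal(classify_copy(NULL, NULL, "truncated_domain"), "remnant")
  tir_nogg <- data.frame(terminal_gg = FALSE, length = 10,
                         tir5 = "TTACGTACGT", tir3 = "ACGTACGTAA")
  expect_equal(classify_copy(tir_nogg, tsd, "absent"), "remnant")
  # one eroded convention base is tolerated, two are not
  tir_1mm <- data.frame(terminal_gg = FALSE, length = 10,
                        tir5 = "GAACGTACGT", tir3 = "ACGTACGTCC")
  expect_equal(classify_copy(tir_1mm, tsd, "intact"), "family_candidate")
})

test_that("family-candidate calls are precise and sensitive on simulated truth", {
  # 20 seeds; per-seed: one family of 3 intact copies at 5% divergence plus a
  # remnant, classified from truth windows without the search stage
  tp <- fp <- fn <- 0
  for (seed in 1:20) {
    sim <- simulate_genome(family_spec("F1", n_copies = 3, per_copy_divergence = 0.05,
                                       remnant_fraction = 0.25, orf_length = 220),
                           background_length = 20000, seed = 500 + seed)
    tr <- sim$truth$copies
    for (i in seq_len(nrow(tr))) {
      e <- truth_element(sim, i)
      tirs <- find_tirs(e$element, require_gg = FALSE, max_offset = 3)
      tir <- if (nrow(tirs)) {
        ggmm <- vapply(seq_len(nrow(tirs)), function(r) tir_gg_mismatches(tirs[r, ]), 0L)
        tirs[order(ggmm)[1], ]
      } else NULL
      tsd <- suppressMessages(find_tsd(e$flank5, e$flank3, element = e$element))
      orfs <- find_orfs(e$element, 100)
      motif <- if (nrow(orfs)) classify_protein(orfs$protein[which.max(nchar(orfs$protein))])
               else "absent"
      call <- classify_copy(tir, tsd, motif)
      if (tr$status[i] == "intact") {
        if (call == "family_candidate") tp <- tp + 1 else fn <- fn + 1
      } else if (call == "family_candidate") fp <- fp + 1
    }
  }
  expect_gte(tp / (tp + fn), 0.9)   # recall
  expect_gte(tp / (tp + fp), 0.9)   # precision
})
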