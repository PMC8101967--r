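test_that("p-distances match hand computations and flag undefined pairs", {
  expect_equal(p_distance_matrix(c(a = "ACGT", b = "ACGT"))["a", "b"], 0)
  expect_equal(p_distance_matrix(c(a = "ACGT", b = "ACGA"))["a", "b"], 0.25)
  # pairwise deletion: only 2 comparable columns, one differs
  d <- p_distance_matrix(c(a = "AC-T", b = "A-GA", c = "ACGT"))
  expect_equal(d["a", "b"], 0.5)
  d2 <- p_distance_matrix(c(a = "AC--", b = "--GT"))
  expect_true(is.na(d2["a", "b"]))
  expect_match(attr(d2, "undefined"), "a\\|b")
  expect_error(p_distance_matrix(c(a = "ACG", b = "ACGT")), "equal length")
})

test_that("diverged coding copies show the prescribed nt and aa divergence", {
  pair <- sim_diverged_orf_pair(aa_len = 253, core_len = 199,
                                nt_divergence = 0.15, core_aa_divergence = 0.19,
                                seed = 5)
  dn <- p_distance_matrix(c(a = pair$nt1, b = pair$nt2))["a", "b"]
  expect_equal(dn, 0.15, tolerance = 0.01)
  core1 <- substr(pair$aa1, pair$core[1], pair$core[2])
  core2 <- substr(pair$aa2, pair$core[1], pair$core[2])
  da <- p_distance_matrix(c(a = core1, b = core2))["a", "b"]
  expect_equal(da, 0.19, tolerance = 0.015)
})

test_that("3-taxon NJ branch lengths follow the closed form", {
  d <- matrix(c(0, 0.3, 0.4,
                0.3, 0, 0.5,
                0.4, 0.5, 0), 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl["a"]), (0.3 + 0.4 - 0.5) / 2, tolerance = 1e-9)
  expect_equal(unname(bl["b"]), (0.3 + 0.5 - 0.4) / 2, tolerance = 1e-9)
  expect_equal(unname(bl["c"]), (0.4 + 0.5 - 0.3) / 2, tolerance = 1e-9)
})

# additive distance matrix from a random tree with positive branch lengths
additive_matrix <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[order(rownames(d)), order(colnames(d))]
}

test_that("NJ recovers the generating topology from additive distances", {
  with_seed(6, for (rep in 1:5) {
    tree <- ape::rtree(4)
    tree$edge.length <- runif(nrow(tree$edge), 0.05, 0.5)
    got <- nj_tree(additive_matrix(tree))
    expect_equal(ape::dist.topo(ape::unroot(tree), got), 0, ignore_attr = TRUE)
  })
})

test_that("NJ agrees with exhaustive least-squares over all 5-taxon topologies", {
  ls_rss <- function(topo, d) {
    topo$edge.length <- rep(1, nrow(topo$edge))
    # design matrix: path indicator of each edge for each taxon pair
    n <- length(topo$tip.label)
    pairs <- t(combn(n, 2))
    X <- matrix(0, nrow(pairs), nrow(topo$edge))
    for (r in seq_len(nrow(pairs))) {
      p <- ape::nodepath(topo, pairs[r, 1], pairs[r, 2])
      for (k in seq_len(length(p) - 1)) {
        e <- which((topo$edge[, 1] == p[k] & topo$edge[, 2] == p[k + 1]) |
                     (topo$edge[, 2] == p[k] & topo$edge[, 1] == p[k + 1]))
        X[r, e] <- 1
      }
    }
    y <- d[cbind(topo$tip.label[pairs[, 1]], topo$tip.label[pairs[, 2]])]
    fit <- lm.fit(X, y)
    sum(fit$residuals^2)
  }
  with_seed(7, for (rep in 1:3) {
    tree <- ape::rtree(5)
    tree$edge.length <- runif(nrow(tree$edge), 0.05, 0.5)
    d <- additive_matrix(tree)
    topos <- phangorn::allTrees(5, rooted = FALSE, tip.label = rownames(d))
    rss <- vapply(topos, ls_rss, 0, d = d)
    best <- topos[[which.min(rss)]]
    expect_equal(ape::dist.topo(best, nj_tree(d)), 0, ignore_attr = TRUE)
  })
})

test_that("NJ on undefined distances fails naming the pair", {
  d <- p_distance_matrix(c(a = "AC--", b = "--GT", c = "ACGT"))
  expect_error(nj_tree(d), "a\\|b")
})

test_that("dropping a taxon from an additive matrix preserves unrelated splits", {
  with_seed(8, {
    tree <- ape::rtree(6)
    tree$edge.length <- runif(nrow(tree$edge), 0.05, 0.5)
    d <- additive_matrix(tree)
    full <- nj_tree(d)
    jack <- nj_tree(d[-1, -1])
    pruned <- ape::drop.tip(full, rownames(d)[1])
    expect_equal(ape::dist.topo(pruned, jack), 0, ignore_attr = TRUE)
  })
})

test_that("bootstrap supports separate two clear 4-taxon clusters", {
  with_seed(9, {
    base1 <- random_dna(300); base2 <- random_dna(300)
    seqs <- c(a1 = mutate_copy(base1, 0.02, seed = 1),
              a2 = mutate_copy(base1, 0.02, seed = 2),
              b1 = mutate_copy(base2, 0.02, seed = 3),
              b2 = mutate_copy(base2, 0.02, seed = 4))
    bs <- bootstrap_support(seqs, replicates = 200, seed = 10)
    expect_gte(min(bs$support, na.rm = TRUE), 0.95)
    bs2 <- bootstrap_support(seqs, replicates = 200, seed = 10)
    expect_identical(bs$support, bs2$support)
    expect_length(bootstrap_support(seqs, replicates = 0)$support, 0)
  })
})

test_that("degenerate consensus follows the IUPAC code table", {
  expect_equal(degenerate_consensus(c("AG", "AG")), "AG")
  expect_equal(degenerate_consensus(c("AA", "AG", "CG", "CA")), "MR")
  expect_equal(degenerate_consensus(c("A", "C", "G", "T")), "N")
  expect_equal(degenerate_consensus(c("A-", "A-", "A-")), "A")  # all-gap dropped
  # idempotence
  cons <- degenerate_consensus(c("ACGT", "ACGA", "ACTT"))
  expect_equal(degenerate_consensus(cons), cons)
})

test_that("family assignment recovers planted families and memberships", {
  sim <- two_family_sim()
  tr <- sim$truth$copies
  els <- setNames(vapply(seq_len(nrow(tr)), function(i)
    truth_element(sim, i)$element, ""), tr$copy_id)
  res <- assign_families(tr$copy_id, els,
                         rep("family_candidate", nrow(tr)),
                         tir5 = setNames(as.list(substr(els, 1, tr$tir_length)),
                                         tr$copy_id),
                         tsds = setNames(as.list(tr$tsd), tr$copy_id))
  expect_length(res$families, 2L)
  for (f in res$families) {
    fams <- unique(tr$family_id[match(f$members, tr$copy_id)])
    expect_length(fams, 1L)   # no family mixes planted truth families
    expect_true(startsWith(f$consensus, "GG"))
  }
})

test_that("family assignment is invariant to input order and handles remnants", {
  sim <- two_family_sim()
  tr <- sim$truth$copies
  els <- setNames(vapply(seq_len(nrow(tr)), function(i)
    truth_element(sim, i)$element, ""), tr$copy_id)
  cls <- rep("family_candidate", nrow(tr))
  t5 <- setNames(as.list(substr(els, 1, tr$tir_length)), tr$copy_id)
  ts <- setNames(as.list(tr$tsd), tr$copy_id)
  a <- assign_families(tr$copy_id, els, cls, t5, ts)
  perm <- rev(seq_len(nrow(tr)))
  b <- assign_families(tr$copy_id[perm], els[perm], cls[perm], t5, ts)
  expect_equal(lapply(a$families, `[[`, "members"),
               lapply(b$families, `[[`, "members"))
  # all remnants -> no families, no groups
  none <- assign_families(tr$copy_id, els, rep("remnant", nrow(tr)))
  expect_length(none$families, 0L)
  expect_length(none$groups, 0L)
})

test_that("activity dating reflects divergence and TSD diversity", {
  expect_equal(date_activity(0.001, c("ACGTACGT", "TTGCATCA"), TRUE), "recent")
  expect_equal(date_activity(0.2, character(0), FALSE), "ancient")
  expect_equal(date_activity(NA_real_, "ACGTACGT", TRUE), "unclear")
  expect_equal(date_activity(0.001, "ACGTACGT", TRUE), "unclear")  # single TSD
})
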