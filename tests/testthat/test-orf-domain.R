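# independent brute-force six-frame ORF enumerator used as an oracle
oracle_orfs <- function(contig, min_aa) {
  contig <- toupper(contig)
  n <- nchar(contig)
  gc <- Biostrings::GENETIC_CODE
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") contig else revcomp(contig)
    starts <- gregexpr("ATG", s, fixed = TRUE)[[1]]
    starts <- starts[starts > 0]
    claimed_stops <- list("1" = integer(), "2" = integer(), "0" = integer())
    for (a in starts) {
      prot <- character(0); p <- a; hit_stop <- FALSE
      while (p + 2 <= n) {
        aa <- gc[[substr(s, p, p + 2)]]
        if (is.null(aa) || aa == "*") { hit_stop <- !is.null(aa); break }
        prot <- c(prot, aa); p <- p + 3
      }
      if (!hit_stop) next
      fr <- as.character(a %% 3)
      if ((p + 2) %in% claimed_stops[[fr]]) next  # only the first ATG per stop
      claimed_stops[[fr]] <- c(claimed_stops[[fr]], p + 2)
      if (length(prot) < min_aa) next
      st <- a - 1L; en <- p + 2L
      if (strand == "-") { tmp <- st; st <- n - en; en <- n - tmp }
      res[[length(res) + 1L]] <- data.frame(start = st, end = en,
                                            strand = strand,
                                            protein = paste(prot, collapse = ""))
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(start = integer(), end = integer(), strand = character(),
               protein = character())
  out[order(out$start, out$end, out$strand), , drop = FALSE]
}

test_that("a minimal hand-translatable ORF is found", {
  o <- find_orfs("ATGAAATAA", min_aa = 2)
  expect_equal(nrow(o), 1L)
  expect_equal(o$protein, "MK")
  expect_equal(o$start, 0L); expect_equal(o$end, 9L)
  expect_equal((o$end - o$start) %% 3, 0)
  expect_equal(nchar(o$protein), (o$end - o$start) / 3 - 1)
})

test_that("six-frame ORF discovery matches a brute-force oracle", {
  for (seed in 1:3) {
    dna <- with_seed(seed, random_dna(6000))
    got <- find_orfs(dna, 40)
    want <- oracle_orfs(dna, 40)
    expect_equal(got[, c("start", "end", "strand", "protein")],
                 want, ignore_attr = TRUE)
  }
})

test_that("reverse-complementing the input swaps strands, preserving proteins", {
  dna <- with_seed(4, random_dna(4000))
  a <- find_orfs(dna, 40)
  b <- find_orfs(revcomp(dna), 40)
  expect_setequal(a$protein, b$protein)
  expect_equal(sort(a$start), sort(nchar(dna) - b$end))
  expect_equal(table(a$strand)[["+"]], table(b$strand)[["-"]])
})

test_that("ambiguous bases translate to X and empty input yields empty output", {
  o <- find_orfs("ATGAANAAATAA", min_aa = 2)
  expect_true(grepl("X", o$protein[1]))
  expect_equal(nrow(find_orfs("", 1)), 0L)
})

test_that("a constructed three-block protein is recovered at its construction offsets", {
  p <- dde_profile()
  with_seed(7, {
    nterm <- 40L; gap12 <- 55L; gap23 <- 20L
    prot <- paste0("M", rand_aa(nterm - 1L), p$consensus[1], rand_aa(gap12),
                   p$consensus[2], rand_aa(gap23), p$consensus[3], rand_aa(30))
    m <- scan_dde(prot, p)
    expect_false(is.null(m))
    expect_true(m$conserved)
    expect_equal(m$catalytic_residues, c("D", "D", "E"))
    b1 <- nterm + 1L
    expect_equal(m$block_positions,
                 c(b1, b1 + 12L + gap12, b1 + 12L + gap12 + 14L + gap23))
    expect_equal(m$spacing12, gap12)
    expect_equal(m$spacing23, gap23)
  })
})

test_that("a block-2 D-to-N variant is found but flagged non-conserved", {
  p <- dde_profile()
  with_seed(8, {
    b2 <- p$consensus[2]
    substr(b2, p$anchors[2], p$anchors[2]) <- "N"
    prot <- paste0("M", rand_aa(30), p$consensus[1], rand_aa(60), b2,
                   rand_aa(20), p$consensus[3], rand_aa(20))
    m <- scan_dde(prot, p)
    expect_false(is.null(m))
    expect_false(m$conserved)
    expect_equal(m$catalytic_residues, c("D", "N", "E"))
  })
})

test_that("negative controls return no motif", {
  p <- dde_profile()
  expect_null(scan_dde(strrep("A", 300), p))
  expect_null(scan_dde("MKLV", p))   # shorter than the minimal span
})

test_that("the motif call is invariant under terminal padding", {
  p <- dde_profile()
  with_seed(9, {
    prot <- sim_transposase(280)
    m1 <- scan_dde(prot, p)
    m2 <- scan_dde(paste0(rand_aa(50), prot, rand_aa(50)), p)
    expect_equal(m1$catalytic_residues, m2$catalytic_residues)
    expect_equal(m2$block_positions - m1$block_positions, rep(50L, 3))
  })
})

test_that("false-positive rate on random proteins is below 1%", {
  p <- dde_profile()
  hits <- with_seed(123, vapply(seq_len(1000), function(i)
    !is.null(scan_dde(paste0("M", rand_aa(399)), p)), NA))
  expect_lt(mean(hits), 0.01)
})

test_that("dynamic-programming placement equals exhaustive enumeration", {
  p <- dde_profile()
  exhaustive <- function(prot) {
    aa <- strsplit(prot, "")[[1]]
    s <- lapply(1:3, function(b) tircurator:::block_scores_along(aa, p$scores[[b]]))
    w <- p$widths
    best <- -Inf; pick <- NULL
    for (i in seq_along(s[[1]])) for (j in seq_along(s[[2]])) {
      g12 <- j - (i + w[1])
      if (g12 < p$spacing12[1] || g12 > p$spacing12[2]) next
      for (k in seq_along(s[[3]])) {
        g23 <- k - (j + w[2])
        if (g23 < p$spacing23[1] || g23 > p$spacing23[2]) next
        tot <- s[[1]][i] + s[[2]][j] + s[[3]][k]
        if (tot > best) { best <- tot; pick <- c(i, j, k) }
      }
    }
    list(score = best, pick = pick)
  }
  with_seed(10, for (rep in 1:5) {
    prot <- sim_transposase(sample(160:200, 1),
                            spacing12 = c(50, 70), spacing23 = c(12, 30))
    prot <- mutate_protein <- paste0(prot, "")   # plain copy
    m <- scan_dde(prot, p, score_threshold = -Inf)
    e <- exhaustive(prot)
    expect_equal(m$block_positions, e$pick)
    expect_equal(m$score, e$score, tolerance = 1e-9)
  })
})

test_that("domain completeness classification distinguishes partial blocks", {
  p <- dde_profile()
  with_seed(11, {
    full <- sim_transposase(250)
    expect_equal(classify_protein(full, p), "intact")
    partial <- paste0("M", rand_aa(40), p$consensus[2], rand_aa(20), p$consensus[3],
                      rand_aa(30))
    expect_equal(classify_protein(partial, p), "truncated_domain")
    expect_equal(classify_protein(paste0("M", rand_aa(200)), p), "absent")
  })
})

test_that("a block profile round-trips through JSON", {
  p <- dde_profile()
  f <- tempfile(fileext = ".json")
  write_profile(p, f)
  q <- read_profile(f)
  expect_equal(p$pwms, q$pwms)
  expect_equal(p$max_score, q$max_score)
  expect_equal(p$spacing12, q$spacing12)
})
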