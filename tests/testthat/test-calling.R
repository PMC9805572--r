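test_that("leave-one-out Log2R matches hand arithmetic and symmetry", {
  m4 <- matrix(rep(c(0.4, 1.3, 0.8), 4), 3, 4)
  expect_equal(loo_log2r(m4), matrix(0, 3, 4), ignore_attr = TRUE)
  # one amplicon, 10 samples: x = 0.5 against nine 1.0
  m <- matrix(c(0.5, rep(1, 9)), 1, 10)
  lr <- loo_log2r(m, eps = 1e-3)
  expect_equal(lr[1, 1], log2(0.501 / 1.001), tolerance = 1e-12)
  expect_equal(lr[1, 2], log2(1.001 / ((0.5 + 8) / 9 + 0.001)),
               tolerance = 1e-12)
  # doubling one cell raises its own ratio, lowers everyone else's
  m2 <- m; m2[1, 1] <- 1.0
  lr2 <- loo_log2r(m2)
  expect_gt(lr2[1, 1], lr[1, 1])
  expect_true(all(lr2[1, -1] < lr[1, -1]))
  expect_error(loo_log2r(matrix(1, 2, 2)), ">= 3 samples")
})

test_that("Log2R stays finite on zero and slightly negative input", {
  m <- matrix(c(0, 1, 1, 1, -1e-6, 1, 1, 1), 2, 4, byrow = TRUE)
  expect_true(all(is.finite(loo_log2r(m))))
})

test_that("CBS returns one segment for constant or null profiles", {
  seg <- cbs_segment(rep(0.25, 30), seed = 1)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$mean_log2r, 0.25)
  expect_equal(seg$sd_log2r, 0)
  expect_equal(c(seg$start_idx, seg$end_idx), c(1, 30))
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    x <- rnorm(100, 0, 0.1)
    if (nrow(cbs_segment(x, n_perm = 2000, seed = s)) == 1) hits <- hits + 1
  }
  expect_gte(hits, 9)  # >= 95% claimed; allow one slip in 10
})

test_that("CBS recovers a planted 40/15/40 event at the right boundaries", {
  set.seed(33)
  x <- c(rep(0, 40), rnorm(15, -1, 0.05), rep(0, 40))
  seg <- cbs_segment(x, n_perm = 5000, seed = 2)
  expect_equal(nrow(seg), 3)
  expect_lte(abs(seg$end_idx[1] - 40), 1)
  expect_lte(abs(seg$end_idx[2] - 55), 1)
  expect_lt(seg$mean_log2r[2], -0.9)
  # matches the exhaustive two-change-point oracle on the same statistic
  orc <- oracle_max_arc(x)
  expect_lte(abs(orc$i - seg$end_idx[1]), 1)
  expect_lte(abs(orc$j - seg$end_idx[2]), 1)
})

test_that("CBS first split agrees with the exhaustive arc oracle", {
  set.seed(17)
  for (rep in 1:8) {
    n <- sample(20:50, 1)
    x <- rnorm(n, 0, 0.1)
    if (rep %% 2 == 0) {
      lo <- sample(3:(n - 12), 1)
      x[lo:(lo + 9)] <- x[lo:(lo + 9)] - 1
    }
    orc <- oracle_max_arc(x)
    cpp <- ampliconcnv:::.cbs_max_arc(x)
    expect_equal(cpp$t, orc$t, tolerance = 1e-9)
    expect_equal(cpp$i, orc$i)
    expect_equal(cpp$j, orc$j)
    best <- ampliconcnv:::.cbs_best_split(x, 3000, 0.01, 42)
    if (best$p < 0.01) {
      seg <- cbs_segment(x, n_perm = 3000, seed = 42, smooth = FALSE)
      expect_gt(nrow(seg), 1)
      expect_true(any(abs(seg$end_idx - orc$j) <= 1) || orc$j >= n - 1)
    }
  }
})

test_that("segmentation output partitions each chromosome", {
  set.seed(19)
  chrom <- rep(c("chr1", "chr2"), c(60, 45))
  x <- rnorm(105, 0, 0.1)
  x[20:35] <- x[20:35] - 1
  x[81:95] <- x[81:95] + 0.8
  seg <- cbs_segment(x, chrom = chrom, n_perm = 2000, seed = 5)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    s <- seg[seg$chrom == ch, ]
    covered <- unlist(Map(seq, s$start_idx, s$end_idx))
    expect_identical(sort(covered), idx)   # contiguous, disjoint, complete
    expect_equal(sum(s$n_amplicons), length(idx))
  }
})

test_that("ds_filter applies threshold, amplicon-count and SD rules", {
  segs <- data.frame(
    mean_log2r = c(-0.6, -0.6, 0.49, 0.50, -0.70, 0.80),
    sd_log2r  = c(0.3, 0.3, 0.1, 0.2, 1.2, 0.9),
    n_amplicons = c(12, 9, 30, 10, 15, 10))
  out <- ds_filter(segs)
  # kept: row1 (deletion), row4 (boundary mean 0.50), row6 (sd boundary 0.9)
  expect_equal(out$n_amplicons, c(12, 10, 10))
  expect_identical(out$call, c("deletion", "duplication", "duplication"))
  # boundary n = 10 kept, 9 discarded; sd 1.0 kept
  segs2 <- data.frame(mean_log2r = -1, sd_log2r = 1.0, n_amplicons = 10)
  expect_equal(nrow(ds_filter(segs2)), 1)
})

test_that("aof_recalc is a bp-overlap-weighted mean with expected invariances", {
  expect_equal(aof_recalc(0, 100, 0, 100, -0.7), -0.7)
  expect_equal(aof_recalc(0, 150, c(0, 100), c(100, 200), c(-1.0, -0.4)),
               (100 * -1.0 + 50 * -0.4) / 150)
  # constant Log2R: weighted mean equals the constant
  expect_equal(aof_recalc(10, 500, c(0, 200, 400), c(150, 390, 600),
                          rep(0.31, 3)), 0.31)
  # scale equivariance and bounds
  a <- aof_recalc(0, 300, c(0, 100, 250), c(120, 260, 400), c(-1, -0.5, 0.2))
  expect_equal(aof_recalc(0, 300, c(0, 100, 250), c(120, 260, 400),
                          3 * c(-1, -0.5, 0.2)), 3 * a)
  expect_gte(a, -1); expect_lte(a, 0.2)
  expect_error(aof_recalc(0, 10, 50, 60, -1), "no amplicon overlaps")
})

test_that("call_pipeline recovers a seeded spike and stays quiet on nulls", {
  sim <- simulate_design(n_genes = 3, exons_per_gene = 3, seed = 51)
  tr <- spike_truth(sim$design, "sample01", 11, 22, 0.5)
  sc <- simulate_counts(sim$design, 20, truth = tr, seed = 52)
  dn <- pca_denoise(normalize_counts(sc$counts, sim$design)$autosomal)
  calls <- call_pipeline(dn$denoised, sim$design, mode = "ds", n_perm = 5000,
                         seed = 3)
  del <- calls[calls$call == "deletion" & calls$sample == "sample01", ]
  expect_equal(nrow(del), 1)
  expect_gte(del$n_amplicons, 10)
  a <- sim$design$amplicons
  member <- a$start < del$end & a$end > del$start
  expect_gte(sum(which(member) %in% 11:22), 10)
  # no-spike fixtures stay call-free in most replicates
  quiet <- 0
  for (s in 1:10) {
    sc0 <- simulate_counts(sim$design, 20, seed = 400 + s)
    dn0 <- pca_denoise(normalize_counts(sc0$counts, sim$design)$autosomal)
    n0 <- nrow(call_pipeline(dn0$denoised, sim$design, n_perm = 2000, seed = s))
    if (n0 == 0) quiet <- quiet + 1
  }
  expect_gte(quiet, 9)
})

test_that("DS-AOF score of a uniform segment equals its DS score", {
  # disjoint design: no neighbor amplicon straddles the segment interval,
  # so the overlap-weighted mean must coincide with the plain segment mean
  sim <- simulate_design(seed = 61, overlap_fraction = 0)
  na <- nrow(sim$design$amplicons)
  m <- matrix(1, na, 6, dimnames = list(sim$design$amplicons$id,
                                        sprintf("s%d", 1:6)))
  m[5:20, 1] <- 2 ^ -1.2   # exact uniform deletion, no noise
  calls <- call_pipeline(m, sim$design, mode = "ds-aof", n_perm = 2000,
                         seed = 9)
  del <- calls[calls$sample == "s1" & calls$call == "deletion", ]
  expect_equal(nrow(del), 1)
  expect_equal(del$aof_log2r, del$mean_log2r, tolerance = 0.02)
})

test_that("heterozygous deletion Log2R is recovered within the expected band", {
  # distributional check over several simulated deletions; the variance
  # removal can occasionally skew an individual event (a documented failure
  # mode of this class of methods), so the band applies to the average
  means <- numeric(); found <- 0
  for (r in 1:6) {
    sim <- simulate_design(n_genes = 3, exons_per_gene = 3, seed = 70 + r)
    tr <- spike_truth(sim$design, "sample05", 21, 32, 0.5)
    sc <- simulate_counts(sim$design, 20, truth = tr, seed = 80 + r)
    dn <- pca_denoise(normalize_counts(sc$counts, sim$design)$autosomal)
    calls <- call_pipeline(dn$denoised, sim$design, n_perm = 3000, seed = 8)
    del <- calls[calls$sample == "sample05" & calls$call == "deletion", ]
    if (nrow(del)) {
      found <- found + 1
      means <- c(means, del$mean_log2r[1])
    }
  }
  expect_gte(found, 5)
  expect_gte(mean(means), -1.3)
  expect_lte(mean(means), -0.7)
})

test_that("calls serialize to TSV and BED9", {
  calls <- data.frame(sample = "s1", chrom = "chr1", start = 100L, end = 900L,
                      n_amplicons = 12L, mean_log2r = -0.8, sd_log2r = 0.2,
                      aof_log2r = NA_real_, call = "deletion")
  tsv <- tempfile(fileext = ".tsv"); bed <- tempfile(fileext = ".bed")
  write_calls(calls, tsv, bed)
  expect_equal(nrow(utils::read.delim(tsv)), 1)
  expect_match(readLines(bed), "^chr1\t100\t900\ts1:deletion\t")
})
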