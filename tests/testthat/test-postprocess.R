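test_that("excess-CNV QC flags only high outliers", {
  expect_identical(sample_cnv_qc(c(a = 1, b = 1, c = 1, d = 1, e = 20)), "e")
  expect_identical(sample_cnv_qc(rep(3, 6)), character(0))
  # zero variance in the rest, differing value: flagged with p = 0
  expect_identical(sample_cnv_qc(c(s1 = 0, s2 = 0, s3 = 0, s4 = 0, s5 = 1)),
                   "s5")
  # low outliers are never flagged
  expect_identical(sample_cnv_qc(c(a = 9, b = 10, c = 11, d = 10, e = 0)),
                   character(0))
  expect_error(sample_cnv_qc(c(1, 2, 3)), ">= 4")
})

test_that("1-D k-means DP equals exhaustive contiguous-partition search", {
  v <- c(-0.7, -0.6, 0.6, 0.7)
  fit <- kmeans_1d_dp(v, 2)
  expect_equal(fit$centers, c(-0.65, 0.65))
  expect_equal(fit$assignments, c(1, 1, 2, 2))
  set.seed(13)
  for (rep in 1:15) {
    n <- sample(4:10, 1)
    vals <- round(rnorm(n), 2)
    for (k in 1:n) {
      fit <- kmeans_1d_dp(vals, k)
      expect_equal(fit$tot_withinss, oracle_kmeans_ss(vals, k),
                   tolerance = 1e-9)
      expect_true(all(diff(fit$centers) > 0) || k == 1)
      expect_equal(sum(fit$withinss), fit$tot_withinss, tolerance = 1e-9)
    }
    expect_equal(kmeans_1d_dp(vals, n)$tot_withinss, 0)
  }
  expect_error(kmeans_1d_dp(1:3, 4), "k exceeds")
})

test_that("BIC selects the generative cluster count", {
  set.seed(23)
  two <- c(rnorm(10, -5, 0.01), rnorm(10, 5, 0.01))
  expect_equal(select_k_bic(two)$k, 2)
  hits <- 0
  for (s in 1:10) {
    set.seed(200 + s)
    if (select_k_bic(rnorm(50))$k == 1) hits <- hits + 1
  }
  expect_gte(hits, 9)
  # deterministic for a fixed input
  expect_identical(select_k_bic(two)$bic_by_k, select_k_bic(two)$bic_by_k)
})

test_that("confusion metrics reproduce exact binomial arithmetic", {
  m <- confusion_metrics(tp = 9, fp = 6, fn = 0, tn = 458)
  expect_equal(m$sensitivity$estimate, 100)
  expect_equal(m$sensitivity$ci_lower, 66.37)
  expect_equal(m$specificity$estimate, 98.71)
  m2 <- confusion_metrics(tp = 9, fp = 1, fn = 0, tn = 458)
  expect_equal(m2$specificity$estimate, 99.78)
  m3 <- confusion_metrics(tp = 6, fp = 6, fn = 3, tn = 255)
  expect_equal(m3$sensitivity$estimate, 66.67)
  expect_equal(m3$specificity$estimate, 97.70)
  # undefined denominator reported as missing
  m4 <- confusion_metrics(tp = 0, fp = 3, fn = 0, tn = 10)
  expect_true(is.na(m4$sensitivity$estimate))
})

test_that("Clopper-Pearson lower bound for x = n equals 0.025^(1/n)", {
  for (n in c(4, 9, 20, 100)) {
    m <- confusion_metrics(tp = n, fp = 0, fn = 0, tn = 0)
    analytic <- 100 * 0.025^(1 / n)
    expect_equal(m$sensitivity$ci_lower, floor(analytic * 100 + 0.5) / 100)
  }
})

test_that("segment annotation lists overlapping TERs in coordinate order", {
  d <- make_parsed_design(
    c("chr1\t100\t200\ta1\tG1"),
    ter_lines = c("chr1\t100\t300\tG1|exon1", "chr1\t400\t600\tG1|exon2",
                  "chr1\t700\t900\tG1|exon3", "chr1\t1200\t1400\tG2|exon1",
                  "chr2\t100\t300\tG3|exon1"))
  call <- list(chrom = "chr1", start = 450, end = 1300)
  ann <- annotate_segment(call, d)
  expect_identical(ann$gene, c("G1", "G1", "G2"))
  expect_identical(ann$exon_label, c("exon2", "exon3", "exon1"))
  # agreement with brute-force overlap scan
  t <- d$ters
  expect_equal(nrow(ann),
               oracle_overlap_count(call$start, call$end, t$start, t$end) -
                 sum(t$chrom != "chr1" & t$start < call$end & t$end > call$start))
  expect_warning(annotate_segment(list(chrom = "chr1", start = 5000,
                                       end = 5100), d), "no TER")
})

test_that("partial single-exon calls are flagged as likely FPs", {
  d <- make_parsed_design(
    c("chr1\t100\t200\ta1\tG1"),
    ter_lines = c("chr1\t100\t300\tG1|exon1", "chr1\t400\t600\tG1|exon2",
                  "chr1\t700\t900\tG1|exon3"))
  expect_true(flag_partial_exon(list(chrom = "chr1", start = 120,
                                     end = 200), d))   # 40% of exon1
  expect_false(flag_partial_exon(list(chrom = "chr1", start = 90,
                                      end = 950), d))  # 3 full exons
  expect_false(flag_partial_exon(list(chrom = "chr1", start = 100,
                                      end = 300), d))  # exactly 100%
  expect_true(flag_partial_exon(list(chrom = "chr1", start = 101,
                                     end = 300), d))   # 1 bp short
})

test_that("segment plots are written with nonzero size", {
  sim <- simulate_design(seed = 31)
  sc <- simulate_counts(sim$design, 8, seed = 32)
  m <- mean_normalize(sc$counts)
  lr <- loo_log2r(m)
  call <- data.frame(sample = colnames(m)[1], chrom = "chr1",
                     start = sim$design$amplicons$start[3],
                     end = sim$design$amplicons$end[10],
                     mean_log2r = -0.8, aof_log2r = NA_real_)
  out <- tempfile(fileext = ".png")
  plot_segment(call, sim$design, lr, out)
  expect_true(file.exists(out))
  expect_gt(file.info(out)$size, 0)
})
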