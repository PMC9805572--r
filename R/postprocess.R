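# Post-processing: sample QC, FP triage, metrics, annotation -----------------

#' Flag samples carrying an excess of CNV calls
#'
#' For each sample, the remaining samples' CNV counts are compared against
#' its own count with a one-sample two-sided t test (rest vs the sample's
#' value); samples are flagged only when significant AND above the rest's
#' mean — too few CNVs is never penalized. Flagged samples should be removed
#' and the variance-control / Log2R / segmentation stages re-run, since an
#' aberrant sample contaminates every other sample's leave-one-out
#' reference.
#'
#' @param call_counts named integer vector of CNV calls per sample (>= 4).
#' @param alpha significance level (default 0.05).
#' @return character vector of flagged sample ids.
#' @export
sample_cnv_qc <- function(call_counts, alpha = 0.05) {
  n <- length(call_counts)
  stopifnot(n >= 4)
  ids <- names(call_counts)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  flagged <- character()
  for (i in seq_len(n)) {
    rest <- call_counts[-i]
    x <- call_counts[i]
    if (stats::sd(rest) == 0) {
      p <- if (x == mean(rest)) 1 else 0
    } else {
      p <- stats::t.test(rest, mu = x)$p.value
    }
    if (p < alpha && x > mean(rest)) flagged <- c(flagged, ids[i])
  }
  flagged
}

#' Optimal univariate k-means by dynamic programming
#'
#' Minimizes the within-cluster sum of squares over all partitions of the
#' sorted values into `k` contiguous groups, which is globally optimal for
#' one-dimensional k-means. Deterministic; no restarts needed.
#'
#' @param values numeric vector.
#' @param k number of clusters, `1 <= k <= length(values)`.
#' @return a `ClusterResult`: `k`, `centers` (increasing), `assignments`
#'   (per input value, cluster index into `centers`), `withinss` (per
#'   cluster), `tot_withinss`.
#' @export
kmeans_1d_dp <- function(values, k) {
  n <- length(values)
  if (k > n) stop("k exceeds number of values")
  if (k < 1) stop("k must be >= 1")
  ord <- order(values)
  x <- values[ord]
  cs <- c(0, cumsum(x))
  css <- c(0, cumsum(x^2))
  cost <- function(i, j) {  # ss of x[i..j]
    s <- cs[j + 1] - cs[i]
    q <- css[j + 1] - css[i]
    max(0, q - s^2 / (j - i + 1))
  }
  D <- matrix(Inf, k, n)      # D[q, j]: optimal ss of x[1..j] in q clusters
  B <- matrix(0L, k, n)       # start index of last cluster
  for (j in 1:n) { D[1, j] <- cost(1, j); B[1, j] <- 1L }
  if (k > 1) {
    for (q in 2:k) {
      for (j in q:n) {
        best <- Inf; arg <- q
        for (i in q:j) {
          v <- D[q - 1, i - 1] + cost(i, j)
          if (v < best) { best <- v; arg <- i }
        }
        D[q, j] <- best; B[q, j] <- arg
      }
    }
  }
  # backtrack cluster boundaries on the sorted order
  bounds <- integer(k + 1); bounds[k + 1] <- n
  j <- n
  for (q in k:1) { bounds[q] <- B[q, j] - 1L; j <- B[q, j] - 1L }
  assign_sorted <- integer(n)
  centers <- numeric(k); withinss <- numeric(k)
  for (q in 1:k) {
    lo <- bounds[q] + 1L; hi <- bounds[q + 1]
    assign_sorted[lo:hi] <- q
    centers[q] <- mean(x[lo:hi])
    withinss[q] <- cost(lo, hi)
  }
  assignments <- integer(n)
  assignments[ord] <- assign_sorted
  structure(list(k = k, centers = centers, assignments = assignments,
                 withinss = withinss, tot_withinss = D[k, n]),
            class = "ClusterResult")
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat(sprintf("ClusterResult: k=%d, centers = %s, total withinss = %.4g\n",
              x$k, paste(sprintf("%.3f", x$centers), collapse = ", "),
              x$tot_withinss))
  invisible(x)
}

cluster_bic <- function(values, fit, var_floor = 1e-6) {
  n <- length(values)
  ll <- 0
  for (q in seq_len(fit$k)) {
    idx <- fit$assignments == q
    nj <- sum(idx)
    vj <- max(fit$withinss[q] / nj, var_floor)
    ll <- ll + sum(log(nj / n) +
                     stats::dnorm(values[idx], fit$centers[q], sqrt(vj),
                                  log = TRUE))
  }
  2 * ll - (3 * fit$k - 1) * log(n)
}

#' Choose the cluster count by maximum BIC
#'
#' Each candidate `k` is fitted with [kmeans_1d_dp()] and scored with a
#' Gaussian-mixture BIC using hard assignments: mixing proportions n_j/n,
#' cluster means, and per-cluster ML variance floored at `var_floor`;
#' BIC = 2*loglik - (3k - 1)*log(n). Returns the argmax (ties toward
#' smaller k).
#'
#' @param values numeric vector, `n >= 2`.
#' @param k_max largest candidate `k` (default 8, capped at the number of
#'   distinct values).
#' @param var_floor variance floor for degenerate clusters.
#' @return list: `k`, `bic_by_k` (named numeric), `fit` (the chosen
#'   `ClusterResult`).
#' @export
select_k_bic <- function(values, k_max = 8, var_floor = 1e-6) {
  n <- length(values)
  stopifnot(n >= 2)
  kmax <- min(k_max, length(unique(values)))
  bic <- numeric(kmax)
  fits <- vector("list", kmax)
  for (k in seq_len(kmax)) {
    fits[[k]] <- kmeans_1d_dp(values, k)
    bic[k] <- cluster_bic(values, fits[[k]], var_floor)
  }
  names(bic) <- seq_len(kmax)
  k <- unname(which.max(bic))  # which.max takes the first (smallest) maximizer
  list(k = k, bic_by_k = bic, fit = fits[[k]])
}

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Sensitivity/specificity with exact binomial confidence intervals
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), reported as
#' percentages rounded half-up to two decimals, with exact Clopper-Pearson
#' 95% intervals. A metric whose denominator is zero is reported as `NA`.
#'
#' @param tp,fp,fn,tn nonnegative confusion counts.
#' @param conf confidence level (default 0.95).
#' @return list with `sensitivity`, `specificity`, each a list of
#'   `estimate`, `ci_lower`, `ci_upper` (percent, 2 decimals) and the
#'   underlying `x`, `n`.
#' @export
confusion_metrics <- function(tp, fp, fn, tn, conf = 0.95) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  one <- function(x, n) {
    if (n == 0) {
      return(list(estimate = NA_real_, ci_lower = NA_real_,
                  ci_upper = NA_real_, x = x, n = n))
    }
    a <- (1 - conf) / 2
    lo <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
    hi <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
    list(estimate = round_half_up(100 * x / n),
         ci_lower = round_half_up(100 * lo),
         ci_upper = round_half_up(100 * hi), x = x, n = n)
  }
  list(sensitivity = one(tp, tp + fn), specificity = one(tn, tn + fp))
}

#' Annotate a CNV call with overlapping target exon regions
#'
#' Attaches, in coordinate order, the gene and exon labels of every TER
#' intersecting the call interval, plus the overlap in bp per TER. Calls
#' with no overlapping TER are annotated "intergenic/off-target" with a
#' warning.
#'
#' @param call one-row data.frame (or list) with `chrom`, `start`, `end`.
#' @param design an `AmpliconDesign` whose `ters` are populated.
#' @return data.frame of overlapping TERs: chrom, start, end, gene,
#'   exon_label, overlap_bp, covered_fraction.
#' @export
annotate_segment <- function(call, design) {
  t <- design$ters
  if (is.null(t)) stop("design carries no TERs")
  hit <- t$chrom == call$chrom & t$start < call$end & t$end > call$start
  if (!any(hit)) {
    warning("call overlaps no TER; intergenic/off-target")
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      gene = character(), exon_label = character(),
                      overlap_bp = integer(), covered_fraction = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- t[hit, , drop = FALSE]
  out <- out[order(out$start, out$end), , drop = FALSE]
  out$overlap_bp <- pmin(out$end, call$end) - pmax(out$start, call$start)
  out$covered_fraction <- out$overlap_bp / (out$end - out$start)
  rownames(out) <- NULL
  out
}

#' Flag a call as a likely false positive from partial-exon overlap
#'
#' Amplicon panels resolve CNVs at single-exon granularity, so a call that
#' touches exactly one TER but covers less than its full length is below
#' the design's resolution and is flagged as a likely FP (it is retained,
#' only marked).
#'
#' @param call one-row data.frame/list with `chrom`, `start`, `end`.
#' @param design an `AmpliconDesign` with TERs.
#' @return logical flag.
#' @export
flag_partial_exon <- function(call, design) {
  ann <- suppressWarnings(annotate_segment(call, design))
  nrow(ann) == 1L && ann$covered_fraction[1] < 1
}

#' Plot one CNV segment in its amplicon/TER context
#'
#' Draws the genomic axis (1-based labels), TER boxes, the amplicon
#' intervals colored by their Log2R in this sample, and the segment span
#' with its score in the title.
#'
#' @param call one-row data.frame with `sample`, `chrom`, `start`, `end`,
#'   `mean_log2r`, and optionally `aof_log2r`.
#' @param design an `AmpliconDesign`.
#' @param log2r Log2R matrix (amplicons x samples).
#' @param out_path output image path (`.png`).
#' @param pad bp of flanking context to draw (default 200).
#' @return `out_path`, invisibly.
#' @export
plot_segment <- function(call, design, log2r, out_path, pad = 200) {
  a <- design$amplicons
  in_mat <- a$id %in% rownames(log2r)
  win_lo <- call$start - pad; win_hi <- call$end + pad
  sel <- which(a$chrom == call$chrom & a$start < win_hi & a$end > win_lo & in_mat)
  lr <- log2r[match(a$id[sel], rownames(log2r)), call$sample]
  grDevices::png(out_path, width = 900, height = 480)
  on.exit(grDevices::dev.off())
  lim <- max(1.5, max(abs(lr), na.rm = TRUE))
  graphics::plot(NA, xlim = c(win_lo, win_hi), ylim = c(-lim, lim),
                 xlab = sprintf("%s position (1-based)", call$chrom),
                 ylab = "Log2R",
                 main = sprintf("%s %s:%d-%d  score %.2f", call$sample,
                                call$chrom, call$start + 1, call$end,
                                if (!is.null(call$aof_log2r) && !is.na(call$aof_log2r))
                                  call$aof_log2r else call$mean_log2r))
  graphics::abline(h = c(-0.5, 0, 0.5), lty = c(2, 1, 2), col = "grey60")
  graphics::rect(call$start, -lim, call$end, lim,
                 col = grDevices::adjustcolor("gold", 0.2), border = NA)
  t <- design$ters
  if (!is.null(t)) {
    th <- t[t$chrom == call$chrom & t$start < win_hi & t$end > win_lo, , drop = FALSE]
    if (nrow(th)) {
      graphics::rect(th$start, -lim, th$end, -lim * 0.92, col = "grey40",
                     border = NA)
      graphics::text((th$start + th$end) / 2, -lim * 0.85,
                     paste(th$gene, th$exon_label), cex = 0.7)
    }
  }
  col <- ifelse(lr <= -0.5, "red3", ifelse(lr >= 0.5, "blue3", "grey30"))
  graphics::segments(a$start[sel], lr, a$end[sel], lr, lwd = 3, col = col)
  invisible(out_path)
}
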