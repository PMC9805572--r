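# Leave-one-out Log2R, segmentation, and CNV calling -------------------------

#' Leave-one-out log2 coverage ratio
#'
#' For each amplicon and sample, the reference coverage is the mean of the
#' remaining n-1 samples at that amplicon, so no matched control set is
#' needed. A pseudocount keeps the ratio finite when the normalized (and
#' possibly denoised) coverage touches zero; slightly negative values that
#' denoising can introduce are clamped to zero first.
#'
#' @param m normalized/denoised matrix (amplicons x samples), >= 3 samples.
#' @param eps pseudocount added to numerator and denominator (default 1e-3).
#' @return matrix of log2 ratios, same dimensions and dimnames.
#' @export
loo_log2r <- function(m, eps = 1e-3) {
  stopifnot(is.matrix(m))
  n <- ncol(m)
  if (n <= 2) stop("leave-one-out reference needs >= 3 samples")
  x <- pmax(m, 0)
  rs <- rowSums(x)
  ref <- (rs - x) / (n - 1)
  log2((x + eps) / (ref + eps))
}

new_seed_counter <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$base <- as.integer(seed %% .Machine$integer.max)
  env$k <- 0L
  env
}

next_seed <- function(env) {
  env$k <- env$k + 1L
  as.integer((as.double(env$base) + 1000003 * env$k) %% 2147483647)
}

# Clip isolated extreme points toward a running median before segmentation.
# A single outlier otherwise dominates the max-arc statistic in both the
# observed profile and every permutation (a one-point arc always attains it),
# stalling the recursion; the standard CBS toolchain median-smooths outliers
# for exactly this reason.
smooth_outliers <- function(x, width = 5, trim_sd = 4, shrink_sd = 2) {
  n <- length(x)
  if (n < width) return(x)
  med <- stats::runmed(x, k = width, endrule = "median")
  resid <- x - med
  s <- stats::mad(resid)
  if (!is.finite(s) || s <= 0) s <- stats::sd(resid)
  if (!is.finite(s) || s <= 0) return(x)
  hit <- abs(resid) > trim_sd * s
  x[hit] <- med[hit] + sign(resid[hit]) * shrink_sd * s
  x
}

cbs_one_run <- function(x, alpha, n_perm, seedenv) {
  n <- length(x)
  seg_stats <- function(lo, hi) {
    v <- x[lo:hi]
    data.frame(start_idx = lo, end_idx = hi, n_amplicons = hi - lo + 1L,
               mean_log2r = mean(v),
               sd_log2r = if (length(v) > 1) stats::sd(v) else 0)
  }
  recurse <- function(lo, hi) {
    len <- hi - lo + 1L
    if (len < 4L) return(seg_stats(lo, hi))
    res <- .cbs_best_split(x[lo:hi], n_perm, alpha, next_seed(seedenv))
    if (res$p >= alpha || res$t <= 0) return(seg_stats(lo, hi))
    i <- res$i; j <- res$j          # inside = local indices (i+1)..j
    bounds <- unique(c(0L, i, j, len))
    bounds <- sort(bounds)
    parts <- list()
    for (b in seq_len(length(bounds) - 1L)) {
      parts[[b]] <- recurse(lo + bounds[b], lo + bounds[b + 1L] - 1L)
    }
    do.call(rbind, parts)
  }
  recurse(1L, n)
}

#' Circular binary segmentation of one sample's Log2R profile
#'
#' Values must be ordered by design position. Each chromosome is segmented
#' independently by recursive circular binary splitting: every arc of the
#' circularly joined profile is scored with a pooled two-sample t statistic
#' (inside vs outside), the maximal statistic's significance is estimated by
#' permutation, and accepted splits are recursed until no further split
#' reaches `alpha`. Segments partition each chromosome's amplicon index
#' range.
#'
#' @param values numeric vector of Log2R values for one sample.
#' @param chrom chromosome per value (default: one chromosome).
#' @param alpha split significance level (default 0.01).
#' @param n_perm permutations for the max-statistic null (default 10000).
#' @param seed integer seed for the permutation RNG.
#' @param smooth clip isolated outliers toward a running median before
#'   segmentation (default `TRUE`); segment statistics are computed on the
#'   smoothed profile.
#' @return data.frame: chrom, start_idx, end_idx (1-based indices into
#'   `values`), n_amplicons, mean_log2r, sd_log2r.
#' @export
cbs_segment <- function(values, chrom = NULL, alpha = 0.01, n_perm = 10000,
                        seed = 1L, smooth = TRUE) {
  stopifnot(all(is.finite(values)))
  if (is.null(chrom)) chrom <- rep("chr1", length(values))
  stopifnot(length(chrom) == length(values))
  seedenv <- new_seed_counter(seed)
  out <- list()
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    if (length(idx) < 2L) {
      seg <- data.frame(start_idx = idx[1], end_idx = idx[length(idx)],
                        n_amplicons = length(idx),
                        mean_log2r = mean(values[idx]), sd_log2r = 0)
    } else {
      v <- if (smooth) smooth_outliers(values[idx]) else values[idx]
      seg <- cbs_one_run(v, alpha, n_perm, seedenv)
      seg$start_idx <- idx[seg$start_idx]
      seg$end_idx <- idx[seg$end_idx]
    }
    seg <- cbind(chrom = ch, seg, stringsAsFactors = FALSE)
    out[[ch]] <- seg
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Filter CBS segments into CNV calls (direct segmentation, DS)
#'
#' A segment is reported iff its mean Log2R lies outside the open neutral
#' band (-st, +st) — i.e. |mean| >= st, boundary values are calls — AND it
#' spans at least `min_amplicons` amplicons AND its SD does not exceed
#' `max_sd`. Calls are labeled deletion (negative) or duplication
#' (positive).
#'
#' @param segments data.frame with `mean_log2r`, `sd_log2r`, `n_amplicons`.
#' @param st segmentation threshold on |mean Log2R| (default 0.5).
#' @param min_amplicons minimum amplicons per reported segment (default 10).
#' @param max_sd maximum within-segment SD (default 1.0).
#' @return the surviving rows with an added `call` column.
#' @export
ds_filter <- function(segments, st = 0.5, min_amplicons = 10, max_sd = 1.0) {
  keep <- (abs(segments$mean_log2r) >= st) &
    (segments$n_amplicons >= min_amplicons) &
    (segments$sd_log2r <= max_sd)
  out <- segments[keep, , drop = FALSE]
  out$call <- ifelse(out$mean_log2r < 0, "deletion", "duplication")
  rownames(out) <- NULL
  out
}

#' Amplicon-overlap-weighted segment score (AOF)
#'
#' Re-scores a segment as the weighted mean of the Log2R of every design
#' amplicon overlapping the segment's genomic interval, each weighted by its
#' bp overlap. Amplicons fully inside contribute their full length. Because
#' HaloPlex amplicons overlap heavily, this score integrates evidence from
#' amplicons that straddle the segment boundary, which the plain segment
#' mean ignores.
#'
#' @param seg_start,seg_end segment interval (0-based half-open bp).
#' @param amp_start,amp_end amplicon intervals (same convention).
#' @param log2r per-amplicon Log2R for this sample.
#' @return the overlap-weighted mean Log2R.
#' @export
aof_recalc <- function(seg_start, seg_end, amp_start, amp_end, log2r) {
  w <- pmax(0, pmin(seg_end, amp_end) - pmax(seg_start, amp_start))
  if (sum(w) <= 0) stop("no amplicon overlaps the segment interval")
  sum(w * log2r) / sum(w)
}

#' Run Log2R computation, segmentation and filtering for all samples
#'
#' The DS mode is leave-one-out Log2R -> per-chromosome CBS -> threshold/
#' count/SD filtering. DS-AOF additionally re-scores each surviving segment
#' with [aof_recalc()] over every matrix amplicon intersecting the segment
#' interval and re-applies the +/-`st` classification to that score (the
#' count and SD filters still act on the original segment statistics).
#'
#' @param m denoised normalized matrix (amplicons x samples); rownames must
#'   be design amplicon ids.
#' @param design an `AmpliconDesign`.
#' @param mode `"ds"` or `"ds-aof"`.
#' @param st,min_amplicons,max_sd see [ds_filter()].
#' @param alpha,n_perm CBS parameters.
#' @param eps Log2R pseudocount.
#' @param seed integer seed for CBS permutations.
#' @return data.frame of calls: sample, chrom, start, end, n_amplicons,
#'   mean_log2r, sd_log2r, aof_log2r (NA in DS mode), call.
#' @export
call_pipeline <- function(m, design, mode = c("ds", "ds-aof"), st = 0.5,
                          min_amplicons = 10, max_sd = 1.0, alpha = 0.01,
                          n_perm = 10000, eps = 1e-3, seed = 1L,
                          smooth = TRUE) {
  mode <- match.arg(mode)
  a <- design$amplicons
  i <- match(rownames(m), a$id)
  if (anyNA(i)) stop("matrix rows missing from design")
  ord <- design_order(a$chrom[i], a$start[i], a$end[i], a$id[i])
  m <- m[ord, , drop = FALSE]
  i <- i[ord]
  chrom <- a$chrom[i]; astart <- a$start[i]; aend <- a$end[i]

  lr <- loo_log2r(m, eps = eps)
  seedenv <- new_seed_counter(seed)
  calls <- list()
  for (s in seq_len(ncol(lr))) {
    seg <- cbs_segment(lr[, s], chrom = chrom, alpha = alpha, n_perm = n_perm,
                       seed = next_seed(seedenv), smooth = smooth)
    seg$start <- astart[seg$start_idx]
    seg$end <- aend[seg$end_idx]
    kept <- ds_filter(seg, st = st, min_amplicons = min_amplicons,
                      max_sd = max_sd)
    if (!nrow(kept)) next
    kept$aof_log2r <- NA_real_
    if (mode == "ds-aof") {
      for (r in seq_len(nrow(kept))) {
        on_chrom <- chrom == kept$chrom[r]
        ov <- on_chrom & (astart < kept$end[r]) & (aend > kept$start[r])
        kept$aof_log2r[r] <- aof_recalc(kept$start[r], kept$end[r],
                                        astart[ov], aend[ov], lr[ov, s])
      }
      kept <- kept[abs(kept$aof_log2r) >= st, , drop = FALSE]
      kept$call <- ifelse(kept$aof_log2r < 0, "deletion", "duplication")
    }
    if (nrow(kept)) {
      kept$sample <- colnames(lr)[s]
      calls[[length(calls) + 1L]] <- kept
    }
  }
  cols <- c("sample", "chrom", "start", "end", "n_amplicons", "mean_log2r",
            "sd_log2r", "aof_log2r", "call")
  if (!length(calls)) {
    out <- data.frame(sample = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_amplicons = integer(), mean_log2r = numeric(),
                      sd_log2r = numeric(), aof_log2r = numeric(),
                      call = character(), stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, calls)[, cols]
  rownames(out) <- NULL
  out
}

#' Write CNV calls as TSV and BED9
#'
#' The TSV keeps the 0-based half-open internal convention; the BED9 track
#' colors deletions red and duplications blue for genome browsers.
#'
#' @param calls data.frame from [call_pipeline()].
#' @param tsv_path,bed_path output paths (either may be `NULL`).
#' @return `calls`, invisibly.
#' @export
write_calls <- function(calls, tsv_path = NULL, bed_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(calls, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(bed_path) && nrow(calls)) {
    col <- ifelse(calls$call == "deletion", "200,0,0", "0,0,200")
    bed <- paste(calls$chrom, calls$start, calls$end,
                 paste0(calls$sample, ":", calls$call),
                 0, ".", calls$start, calls$end, col, sep = "\t")
    writeLines(bed, bed_path)
  }
  invisible(calls)
}
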