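# GC correction and coverage normalization -----------------------------------

#' Loess GC-bias correction of a count matrix
#'
#' A degree-1 loess curve of coverage against amplicon GC fraction is fitted
#' and the counts are rescaled multiplicatively by `median(fitted)/fitted`,
#' which flattens the GC trend while preserving median coverage and
#' nonnegativity. Fitted values are floored at a small positive epsilon so
#' the ratio is always defined.
#'
#' With `fit = "pooled"` (default) one curve is fitted to the across-sample
#' median of the library-size-normalized profile and the per-amplicon
#' correction factor is applied to every sample. GC bias in an amplicon
#' batch is shared — it reflects amplification efficiency of the fragment,
#' not the sample — and a consensus fit is insensitive to a CNV present in
#' a single sample. `fit = "per-sample"` fits each sample independently;
#' note that a CNV spanning an appreciable fraction of amplicons then leaks
#' into its own sample's GC curve and is partly corrected away.
#'
#' @param m count matrix (amplicons x samples), nonnegative.
#' @param gc numeric vector of per-amplicon GC fractions (row-aligned).
#' @param span loess span (default 0.3).
#' @param fit `"pooled"` (consensus curve) or `"per-sample"`.
#' @return corrected numeric matrix, same dimensions and dimnames.
#' @export
gc_correct <- function(m, gc, span = 0.3, fit = c("pooled", "per-sample")) {
  fit <- match.arg(fit)
  stopifnot(is.matrix(m), length(gc) == nrow(m))
  if (anyNA(gc)) stop("gc_fraction undefined for some amplicons")
  if (nrow(m) < 20) {
    warning("fewer than 20 amplicons; GC correction skipped")
    return(m * 1.0)
  }
  if (length(unique(gc)) == 1L) {
    warning("degenerate GC (all equal); GC correction is the identity")
    return(m * 1.0)
  }
  loess_factor <- function(y) {
    f <- stats::loess(y ~ gc, span = span, degree = 1, family = "symmetric",
                      control = stats::loess.control(surface = "direct"))
    f <- pmax(stats::predict(f, gc), 1e-8)
    stats::median(f) / f
  }
  if (fit == "pooled") {
    prof <- apply(sweep(m, 2L, colMeans(m), "/"), 1L, stats::median)
    m * loess_factor(prof)
  } else {
    out <- m * 1.0
    for (j in seq_len(ncol(m))) out[, j] <- m[, j] * loess_factor(m[, j])
    out
  }
}

#' Split a matrix into autosomal and sex-chromosome row sets
#'
#' Downstream variance control and segmentation run independently per class:
#' sex-chromosome coverage carries sex-dependent structure that would
#' otherwise dominate the autosomal principal components.
#'
#' @param m matrix whose rownames are amplicon ids present in `design`.
#' @param design an `AmpliconDesign`.
#' @return list with `autosomal` and `sex` matrices (either may have 0 rows,
#'   with a warning).
#' @export
split_by_class <- function(m, design) {
  a <- design$amplicons
  i <- match(rownames(m), a$id)
  if (anyNA(i)) stop("matrix rows missing from design: ",
                     paste(utils::head(rownames(m)[is.na(i)], 5), collapse = ", "))
  cls <- a$class[i]
  res <- list(autosomal = m[cls == "autosomal", , drop = FALSE],
              sex = m[cls == "sex", , drop = FALSE])
  for (nm in names(res)) {
    if (nrow(res[[nm]]) == 0) warning("no ", nm, " amplicons; branch empty")
  }
  res
}

#' Normalize each sample by its average coverage
#'
#' Divides every column by its own mean, so each sample's normalized
#' coverage has mean exactly 1. Idempotent.
#'
#' @param m nonnegative matrix (amplicons x samples).
#' @return normalized numeric matrix.
#' @export
mean_normalize <- function(m) {
  stopifnot(is.matrix(m))
  mu <- colMeans(m)
  if (any(mu <= 0)) {
    stop("zero-mean sample(s): ", paste(colnames(m)[mu <= 0], collapse = ", "),
         " (should have been removed by the coverage filter)")
  }
  sweep(m, 2L, mu, "/")
}

#' Per-sample Pearson correlation between coverage and GC
#'
#' A reporting-only diagnostic: on well-behaved HaloPlex batches the mean
#' correlation is near zero for autosomal targets and modest for sex
#' targets. No filtering is performed.
#'
#' @param m matrix (amplicons x samples), at least 3 rows.
#' @param gc per-amplicon GC fractions.
#' @return list with `per_sample` (named numeric, `NA` when a sample or the
#'   GC vector has zero variance) and `mean` (over defined values).
#' @export
gc_rd_correlation <- function(m, gc) {
  stopifnot(is.matrix(m), nrow(m) >= 3, length(gc) == nrow(m))
  r <- vapply(seq_len(ncol(m)), function(j) {
    if (stats::sd(m[, j]) == 0 || stats::sd(gc) == 0) return(NA_real_)
    stats::cor(m[, j], gc)
  }, 0)
  names(r) <- colnames(m)
  list(per_sample = r, mean = mean(r, na.rm = TRUE))
}

#' Full normalization stage: GC correction, class split, mean normalization
#'
#' @param m raw count matrix.
#' @param design an `AmpliconDesign` providing GC fractions and classes.
#' @param gc_enabled logical; apply loess GC correction first.
#' @param span loess span.
#' @return list with `autosomal` and `sex` normalized matrices (empty-class
#'   branches are dropped) and `provenance`, the ordered transform record.
#' @export
normalize_counts <- function(m, design, gc_enabled = TRUE, span = 0.3) {
  prov <- character()
  gc <- design$amplicons$gc_fraction[match(rownames(m), design$amplicons$id)]
  if (gc_enabled && !anyNA(gc)) {
    m <- gc_correct(m, gc, span = span)
    prov <- c(prov, sprintf("gc_correct(span=%g)", span))
  }
  parts <- suppressWarnings(split_by_class(m, design))
  parts <- parts[vapply(parts, nrow, 0L) > 0]
  prov <- c(prov, "split_by_class")
  out <- lapply(parts, mean_normalize)
  prov <- c(prov, "mean_normalize")
  c(out, list(provenance = prov))
}
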