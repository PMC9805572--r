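# Variance control: PCA / classical MDS denoising ----------------------------

#' Choose how many leading components to remove
#'
#' Given a nonincreasing explained-variance spectrum, returns the number of
#' leading components `k` whose cumulative explained variance is *closest*
#' to `target` (ties broken toward smaller `k`, and `k = 0` is allowed).
#' The nearest rule — rather than "smallest k reaching at least target" —
#' lets the removed fraction land under or over the target depending on the
#' batch's spectrum, which matches how real batches behave (removals from 0
#' to several components, spanning a wide range of variance fractions).
#'
#' @param spectrum nonincreasing explained-variance fractions summing to 1.
#' @param target desired removed-variance fraction (default 0.80).
#' @return integer `k` in `0:(length(spectrum) - 1)`.
#' @export
select_num_components <- function(spectrum, target = 0.80) {
  if (!length(spectrum)) stop("empty spectrum")
  cum <- c(0, cumsum(spectrum))[seq_along(spectrum)]  # cumulative(0..len-1)
  which.min(abs(cum - target)) - 1L
}

denoise_core <- function(m, target, n_override, method) {
  stopifnot(is.matrix(m))
  if (ncol(m) < 3) stop("need >= 3 samples for denoising")
  if (nrow(m) < 2) stop("need >= 2 amplicons for denoising")
  mu <- colMeans(m)                       # samples are the variables
  xc <- sweep(m, 2L, mu, "-")

  if (method == "pca") {
    sv <- svd(xc)
    d2 <- sv$d^2
    u <- sv$u
  } else {
    # classical (Torgerson) MDS on Euclidean distances between amplicon rows:
    # the double-centered Gram matrix equals xc %*% t(xc) because column
    # centering removes the row-point centroid, so eigenvectors/values
    # reproduce the PCA solution exactly.
    gram <- tcrossprod(xc)
    eg <- eigen(gram, symmetric = TRUE)
    pos <- pmax(eg$values, 0)
    d2 <- pos
    u <- eg$vectors
  }
  tot <- sum(d2)
  keepn <- min(dim(xc))
  d2 <- d2[seq_len(keepn)]
  u <- u[, seq_len(keepn), drop = FALSE]
  spectrum <- if (tot > 0) d2 / tot else rep(0, keepn)

  n_removed <- if (!is.null(n_override)) {
    if (n_override >= ncol(m)) stop("n_override must be < number of samples")
    as.integer(n_override)
  } else {
    select_num_components(spectrum, target)
  }

  if (n_removed > 0) {
    uk <- u[, seq_len(n_removed), drop = FALSE]
    # deterministic sign convention (irrelevant to the projector, kept for
    # reproducible component output)
    for (j in seq_len(ncol(uk))) if (uk[which.max(abs(uk[, j])), j] < 0) uk[, j] <- -uk[, j]
    xc <- xc - uk %*% crossprod(uk, xc)
  }
  den <- sweep(xc, 2L, mu, "+")
  dimnames(den) <- dimnames(m)
  structure(list(denoised = den, n_removed = n_removed,
                 var_removed_fraction = sum(spectrum[seq_len(n_removed)]),
                 spectrum = spectrum, method = method),
            class = "DenoiseResult")
}

#' PCA denoising of a normalized coverage matrix
#'
#' Amplicons are the observations and samples the variables: each sample
#' column is centered by its mean, the centered matrix is decomposed by SVD,
#' the leading components chosen by [select_num_components()] (or
#' `n_override`) are zeroed, and the column means are restored. Removing the
#' dominant components strips batch-wide technical covariance while leaving
#' localized CNV signal, which occupies low-variance directions.
#'
#' @param m normalized matrix (amplicons x samples).
#' @param target removed-variance target (default 0.80).
#' @param n_override fixed number of components to remove, or `NULL`.
#' @return a `DenoiseResult`: `denoised`, `n_removed`,
#'   `var_removed_fraction`, `spectrum`.
#' @export
pca_denoise <- function(m, target = 0.80, n_override = NULL) {
  denoise_core(m, target, n_override, "pca")
}

#' Classical-MDS denoising (fast path, identical to PCA)
#'
#' Runs Torgerson classical multidimensional scaling on the Euclidean
#' distances between amplicon rows: double-centering the squared-distance
#' matrix yields the Gram matrix of the column-centered data, whose
#' eigendecomposition coincides with the PCA/SVD solution. Output is
#' identical to [pca_denoise()] to numerical precision.
#'
#' @inheritParams pca_denoise
#' @return a `DenoiseResult`.
#' @export
mds_denoise <- function(m, target = 0.80, n_override = NULL) {
  denoise_core(m, target, n_override, "mds")
}

#' @export
print.DenoiseResult <- function(x, ...) {
  cat(sprintf("DenoiseResult (%s): removed %d component(s), %.1f%% of variance\n",
              x$method, x$n_removed, 100 * x$var_removed_fraction))
  invisible(x)
}
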