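# End-to-end pipeline: counts -> QC -> normalize -> denoise -> call ----------

#' Run the full CNV-calling workflow on a count matrix
#'
#' Applies, in order: the low-coverage sample filter, zero-amplicon pruning,
#' GC correction, the autosomal/sex split, per-sample mean normalization,
#' PCA (or MDS) variance removal, leave-one-out Log2R, CBS segmentation and
#' DS / DS-AOF filtering. Afterwards the per-sample CNV-count QC runs; if
#' samples are flagged as carrying an excessive number of calls they are
#' removed and the variance-control, Log2R and segmentation stages are
#' repeated (up to `qc_rounds` times) so aberrant samples cannot pollute the
#' leave-one-out reference.
#'
#' @param counts raw integer count matrix (amplicons x samples).
#' @param design an `AmpliconDesign`.
#' @param method `"pca"` or `"mds"` variance control.
#' @param target removed-variance target (default 0.80).
#' @param n_override fixed component count, or `NULL` for the target rule.
#' @param mode `"ds"` or `"ds-aof"`.
#' @param st,min_amplicons,max_sd segment filters (see [ds_filter()]).
#' @param alpha,n_perm CBS parameters.
#' @param eps Log2R pseudocount.
#' @param min_mean low-coverage sample threshold (reads/amplicon).
#' @param gc_enabled apply loess GC correction when GC fractions exist.
#' @param qc_alpha significance level of the excess-CNV sample QC.
#' @param qc_min_calls a sample is only treated as aberrant when it carries
#'   at least this many calls (default 3): one or two CNVs are plausible
#'   clinical findings, not evidence of a failed library, even when the rest
#'   of a small batch is call-free.
#' @param qc_rounds maximum QC re-run rounds (default 1).
#' @param seed integer seed for CBS permutations.
#' @return list: `calls` (data.frame over all retained samples), `denoise`
#'   (per-class `DenoiseResult`s from the final round), `log2r` (per-class
#'   matrices), `removed_low_coverage`, `removed_zero_amplicons`,
#'   `removed_qc` (sample ids flagged by the CNV-count QC).
#' @export
run_pipeline <- function(counts, design, method = c("pca", "mds"),
                         target = 0.80, n_override = NULL,
                         mode = c("ds", "ds-aof"), st = 0.5,
                         min_amplicons = 10, max_sd = 1.0, alpha = 0.01,
                         n_perm = 10000, eps = 1e-3, min_mean = 100,
                         gc_enabled = TRUE, qc_alpha = 0.05, qc_min_calls = 3,
                         qc_rounds = 1, seed = 1L) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  denoise_fun <- if (method == "pca") pca_denoise else mds_denoise

  flt <- filter_low_coverage_samples(counts, min_mean = min_mean)
  prn <- prune_zero_amplicons(flt$counts)
  m <- prn$counts

  removed_qc <- character()
  round <- 0L
  repeat {
    norm <- normalize_counts(m, design, gc_enabled = gc_enabled)
    classes <- setdiff(names(norm), "provenance")
    denoise <- list(); log2r <- list(); calls <- list()
    for (cl in classes) {
      dn <- denoise_fun(norm[[cl]], target = target, n_override = n_override)
      denoise[[cl]] <- dn
      log2r[[cl]] <- loo_log2r(dn$denoised, eps = eps)
      calls[[cl]] <- call_pipeline(dn$denoised, design, mode = mode, st = st,
                                   min_amplicons = min_amplicons,
                                   max_sd = max_sd, alpha = alpha,
                                   n_perm = n_perm, eps = eps,
                                   seed = seed + round)
    }
    calls <- do.call(rbind, calls)
    rownames(calls) <- NULL

    if (round >= qc_rounds || ncol(m) < 5) break
    cnt <- table(factor(calls$sample, levels = colnames(m)))
    flagged <- sample_cnv_qc(as.integer(cnt), alpha = qc_alpha)
    flagged <- colnames(m)[as.integer(flagged)]
    flagged <- flagged[cnt[flagged] >= qc_min_calls]
    if (!length(flagged)) break
    removed_qc <- c(removed_qc, flagged)
    m <- m[, setdiff(colnames(m), flagged), drop = FALSE]
    round <- round + 1L
  }

  list(calls = calls, denoise = denoise, log2r = log2r,
       removed_low_coverage = flt$removed,
       removed_zero_amplicons = prn$removed, removed_qc = removed_qc)
}
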