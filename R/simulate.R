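# Seeded synthetic data: designs, spiked count matrices, fixture BAMs --------

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Simulate an overlapping amplicon design with TERs and a synthetic genome
#'
#' Emulates a HaloPlex-style enrichment: each gene has several exons, each
#' exon a target exon region (exon +/- 51 bp), and each TER is tiled by a
#' variable number of variable-length amplicons with stochastic overlaps.
#' `overlap_fraction = 0` yields disjoint amplicons. A synthetic genome
#' (random bases with locally varying GC) is generated alongside, so GC
#' fractions are real sequence-derived values. Deterministic per seed.
#'
#' @param n_genes,exons_per_gene design shape.
#' @param amplicons_per_exon mean amplicons tiling each TER (default 8).
#' @param length_range amplicon length range in bp (default 60-250).
#' @param overlap_fraction typical fractional overlap between successive
#'   amplicons, in `[0, 1)` (default 0.5).
#' @param exon_length_range exon length range in bp.
#' @param pad TER padding around each exon (default 51 bp).
#' @param chrom chromosome name for the design (default "chr1").
#' @param seed RNG seed.
#' @return list: `design` (an `AmpliconDesign` with `gc_fraction` filled)
#'   and `genome` (a named `DNAStringSet`).
#' @export
simulate_design <- function(n_genes = 2, exons_per_gene = 3,
                            amplicons_per_exon = 8,
                            length_range = c(60, 250),
                            overlap_fraction = 0.5,
                            exon_length_range = c(600, 900),
                            pad = 51, chrom = "chr1", seed = 1) {
  stopifnot(n_genes >= 1, exons_per_gene >= 1, amplicons_per_exon > 0,
            length_range[1] >= 10, length_range[2] >= length_range[1],
            overlap_fraction >= 0, overlap_fraction < 1)
  if (exon_length_range[1] + 2 * pad < length_range[2]) {
    stop("infeasible geometry: TERs shorter than the longest amplicon")
  }
  with_seed(seed, {
    amps <- list(); ters <- list()
    pos <- 1000L
    for (g in seq_len(n_genes)) {
      gene <- sprintf("GENE%d", g)
      for (e in seq_len(exons_per_gene)) {
        exon_len <- round(stats::runif(1, exon_length_range[1], exon_length_range[2]))
        ts <- pos - pad
        te <- pos + exon_len + pad
        ters[[length(ters) + 1L]] <- data.frame(
          chrom = chrom, start = ts, end = te, gene = gene,
          exon_label = sprintf("exon%d", e), stringsAsFactors = FALSE)
        n_draw <- max(1L, stats::rpois(1, amplicons_per_exon))
        s <- ts + sample.int(10L, 1) - 1L
        k <- 0L
        while (k < n_draw) {
          len <- round(stats::runif(1, length_range[1], length_range[2]))
          if (s + len > te) {
            if (k == 0L) { len <- te - s } else break
          }
          k <- k + 1L
          amps[[length(amps) + 1L]] <- data.frame(
            id = sprintf("amp_g%d_e%d_%d", g, e, k), chrom = chrom,
            start = as.integer(s), end = as.integer(s + len), gene = gene,
            stringsAsFactors = FALSE)
          step <- if (overlap_fraction == 0) len else
            max(1L, len - round(stats::runif(1, 0.5, 1) * overlap_fraction * len))
          s <- s + step
        }
        pos <- pos + exon_len + 500L
      }
      pos <- pos + 2000L
    }
    amp <- do.call(rbind, amps)
    ter <- do.call(rbind, ters)
    glen <- max(amp$end, ter$end) + 100L
    # genome in 500 bp blocks with block-specific GC, so amplicon GC varies
    blocks <- ceiling(glen / 500)
    seq <- unlist(lapply(seq_len(blocks), function(b) {
      gcp <- stats::runif(1, 0.3, 0.7)
      sample(c("G", "C", "A", "T"), 500,
             replace = TRUE, prob = c(gcp / 2, gcp / 2, (1 - gcp) / 2, (1 - gcp) / 2))
    }))[seq_len(glen)]
    genome <- Biostrings::DNAStringSet(paste(seq, collapse = ""))
    names(genome) <- chrom

    amp <- amp[design_order(amp$chrom, amp$start, amp$end, amp$id), , drop = FALSE]
    rownames(amp) <- NULL
    sub <- Biostrings::DNAStringSet(substring(as.character(genome[[1]]),
                                              amp$start + 1L, amp$end))
    freq <- Biostrings::letterFrequency(sub, c("A", "C", "G", "T"))
    amp$gc_fraction <- as.numeric((freq[, "G"] + freq[, "C"]) / rowSums(freq))
    amp$class <- chrom_class(amp$chrom)
    amp <- amp[, c("id", "chrom", "start", "end", "gene", "gc_fraction", "class")]
    design <- structure(list(amplicons = amp, ters = ter),
                        class = "AmpliconDesign")
    list(design = design, genome = genome)
  })
}

#' Build a spike truth table from amplicon index ranges
#'
#' Convenience constructor: expresses "a copy-ratio `ratio` event covering
#' design amplicons `from:to` in `sample_id`" as a genomic truth interval.
#'
#' @param design an `AmpliconDesign`.
#' @param sample_id sample carrying the event.
#' @param from,to first/last design amplicon index (design sort order).
#' @param ratio copy ratio (0.5 heterozygous deletion, 1.5 heterozygous
#'   duplication, 0 homozygous deletion, 2 homozygous duplication).
#' @return one-row truth data.frame (sample_id, chrom, start, end,
#'   copy_ratio).
#' @export
spike_truth <- function(design, sample_id, from, to, ratio = 0.5) {
  a <- design$amplicons
  stopifnot(from >= 1, to <= nrow(a), from <= to,
            length(unique(a$chrom[from:to])) == 1)
  data.frame(sample_id = sample_id, chrom = a$chrom[from],
             start = a$start[from], end = max(a$end[from:to]),
             copy_ratio = ratio, stringsAsFactors = FALSE)
}

#' Simulate an amplicon read-count matrix with spiked CNVs
#'
#' Counts follow a negative binomial with mean
#' `depth_mean * eff_a * lib_s * gc_curve(gc_a) * batch_factors(a, s) *
#' cn(a, s)`: lognormal per-amplicon efficiencies (HaloPlex amplicons are
#' heavily overdispersed), lognormal per-sample library size, a smooth GC
#' response, a small number of latent multiplicative batch factors creating
#' the dominant shared covariance that the variance-control stage is meant
#' to remove, and the spiked copy ratio where an amplicon overlaps a truth
#' interval. `dispersion = Inf` gives Poisson sampling. Deterministic per
#' seed.
#'
#' @param design an `AmpliconDesign`.
#' @param n_samples number of samples (>= 4).
#' @param truth spike truth data.frame (see [spike_truth()]) or `NULL`.
#' @param depth_mean mean reads per amplicon (default 4000).
#' @param dispersion negative binomial size (default 100; `Inf` = Poisson).
#' @param gc_bias_strength strength of the quadratic log-GC response
#'   (default 0.3; 0 disables).
#' @param sample_effect_sd lognormal sd of library-size factors (0.2).
#' @param amp_efficiency_sd lognormal sd of amplicon efficiencies (0.3).
#' @param n_factors,factor_sd latent batch factors and their per-cell
#'   log-scale sd (1 and 0.25).
#' @param seed RNG seed.
#' @return list: `counts` (integer matrix, amplicons x samples), `truth`,
#'   `params`.
#' @export
simulate_counts <- function(design, n_samples, truth = NULL,
                            depth_mean = 4000, dispersion = 100,
                            gc_bias_strength = 0.3, sample_effect_sd = 0.2,
                            amp_efficiency_sd = 0.3, n_factors = 1,
                            factor_sd = 0.25, seed = 1) {
  stopifnot(n_samples >= 4)
  a <- design$amplicons
  na <- nrow(a)
  with_seed(seed, {
    eff <- stats::rlnorm(na, 0, amp_efficiency_sd)
    lib <- stats::rlnorm(n_samples, 0, sample_effect_sd)
    gc <- a$gc_fraction
    gcur <- if (!anyNA(gc) && gc_bias_strength > 0) {
      exp(-gc_bias_strength * ((gc - 0.5) / 0.15)^2)
    } else rep(1, na)
    fac <- if (n_factors > 0 && factor_sd > 0) {
      loading <- matrix(stats::rnorm(na * n_factors), na, n_factors)
      score <- matrix(stats::rnorm(n_factors * n_samples), n_factors, n_samples)
      # fix each sample's technical amplitude so the exponent has per-cell sd
      # factor_sd exactly; unnormalized scores give occasional samples with
      # much larger amplitude, whose exp() is no longer near-low-rank
      score <- sweep(score, 2L, sqrt(colSums(score^2)), "/")
      exp(factor_sd * (loading %*% score))
    } else matrix(1, na, n_samples)
    cn <- matrix(1, na, n_samples,
                 dimnames = list(a$id, sprintf("sample%02d", seq_len(n_samples))))
    if (!is.null(truth) && nrow(truth)) {
      # an amplicon carries the full copy-ratio change only when fully
      # contained in the event; partially overlapping amplicons are left
      # neutral (their true ratio would be intermediate)
      for (r in seq_len(nrow(truth))) {
        ov <- a$chrom == truth$chrom[r] & a$start >= truth$start[r] &
          a$end <= truth$end[r]
        cn[ov, truth$sample_id[r]] <- truth$copy_ratio[r]
      }
    }
    mu <- depth_mean * (eff * gcur) %o% lib * fac * cn
    counts <- if (is.infinite(dispersion)) {
      matrix(stats::rpois(length(mu), mu), na, n_samples)
    } else {
      matrix(stats::rnbinom(length(mu), mu = mu, size = dispersion), na,
             n_samples)
    }
    dimnames(counts) <- dimnames(cn)
    list(counts = counts, truth = truth,
         params = list(depth_mean = depth_mean, dispersion = dispersion,
                       gc_bias_strength = gc_bias_strength,
                       sample_effect_sd = sample_effect_sd,
                       amp_efficiency_sd = amp_efficiency_sd,
                       n_factors = n_factors, factor_sd = factor_sd,
                       seed = seed))
  })
}

#' Write a miniature BAM whose reads exactly tile the design amplicons
#'
#' For each amplicon, emits `counts[i]` single-end reads whose aligned
#' reference span coincides exactly with the amplicon interval, so
#' re-counting the BAM with tolerance 0 reproduces the vector. Optional
#' decoy reads (arbitrary coordinates, matching no amplicon exactly) and a
#' duplicate-flagged fraction support the counting filters' tests. The SAM
#' text is converted, coordinate-sorted and indexed via Rsamtools.
#'
#' @param design an `AmpliconDesign`.
#' @param counts_column named integer vector in design order.
#' @param out_bam output BAM path (`.bam`).
#' @param decoys optional data.frame (chrom, start, end, n) of extra
#'   off-target reads.
#' @param duplicate_fraction fraction of each amplicon's reads flagged as
#'   duplicates (default 0).
#' @return path to the written BAM, invisibly.
#' @export
write_fixture_bam <- function(design, counts_column, out_bam, decoys = NULL,
                              duplicate_fraction = 0) {
  a <- design$amplicons
  stopifnot(length(counts_column) == nrow(a))
  chroms <- unique(a$chrom)
  clen <- vapply(chroms, function(ch)
    max(a$end[a$chrom == ch],
        if (!is.null(decoys)) decoys$end[decoys$chrom == ch] else 0L) + 100L, 0)
  rec <- list()
  for (i in seq_len(nrow(a))) {
    n <- counts_column[i]
    if (n == 0) next
    len <- a$end[i] - a$start[i]
    ndup <- floor(duplicate_fraction * n)
    flags <- c(rep(1024L, ndup), rep(0L, n - ndup))
    rec[[length(rec) + 1L]] <- data.frame(
      qname = sprintf("%s_r%d", a$id[i], seq_len(n)), flag = flags,
      chrom = a$chrom[i], pos = a$start[i] + 1L, len = len,
      stringsAsFactors = FALSE)
  }
  if (!is.null(decoys) && nrow(decoys)) {
    for (i in seq_len(nrow(decoys))) {
      n <- decoys$n[i]
      rec[[length(rec) + 1L]] <- data.frame(
        qname = sprintf("decoy%d_r%d", i, seq_len(n)), flag = 0L,
        chrom = decoys$chrom[i], pos = decoys$start[i] + 1L,
        len = decoys$end[i] - decoys$start[i], stringsAsFactors = FALSE)
    }
  }
  rec <- if (length(rec)) do.call(rbind, rec) else
    data.frame(qname = character(), flag = integer(), chrom = character(),
               pos = integer(), len = integer())
  rec <- rec[order(match(rec$chrom, chroms), rec$pos), , drop = FALSE]
  sam <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", chroms, as.integer(clen)))
  body <- if (nrow(rec)) {
    sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*", rec$qname, rec$flag,
            rec$chrom, rec$pos, rec$len,
            vapply(rec$len, function(l) strrep("A", l), ""))
  } else character()
  writeLines(c(hdr, body), sam)
  dest <- sub("\\.bam$", "", out_bam)
  Rsamtools::asBam(sam, dest, overwrite = TRUE, indexDestination = TRUE)
  unlink(sam)
  invisible(out_bam)
}
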