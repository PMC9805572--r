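---
title: "Methods: CNV calling from amplicon coverage variance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CNV calling from amplicon coverage variance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliconcnv)
```

## The problem

Clinical gene panels enriched with HaloPlex-style amplicon chemistry produce
read-depth profiles that are poorly served by CNV callers built for
hybridization capture. Two properties dominate. First, the design tiles each
target exon region (TER, an exon padded by 51 bp) with many *overlapping*
amplicons of highly variable length, so neighbouring "targets" are not
independent measurements. Second, per-amplicon amplification efficiency and
run-level handling effects create technical coverage variance far larger
than the twofold shift a heterozygous CNV produces. Matched controls are
usually unavailable in diagnostics, so the batch itself must serve as the
reference.

`ampliconcnv` addresses both properties: reads are assigned to amplicons
only by exact boundary matching (cutting the dependence between overlapping
amplicons), and the dominant technical variance is removed by principal
component analysis before a leave-one-out log-ratio is segmented.

## Model and procedure

Let $X$ be the amplicons $\times$ samples count matrix.

**Counting.** A read with aligned reference span $[r_s, r_e)$ (CIGAR
reference width; soft clips do not extend the span) counts for amplicon
$[a_s, a_e)$ iff $|r_s - a_s| \le t$ and $|r_e - a_e| \le t$ with tolerance
$t = 0$ by default. Each read counts for at most one amplicon (ties broken
by design order, with a warning). Unmapped, secondary and supplementary
alignments are ignored. Duplicate-flagged reads are excluded by the library
default, but amplicon libraries generally must *not* be deduplicated —
identical fragment coordinates are the design, not PCR artifacts — so
`include_duplicates = TRUE` is the right setting for HaloPlex BAMs that have
passed through a duplicate marker.

**Normalization.** GC bias is corrected multiplicatively with a degree-1
loess of coverage on amplicon GC (span 0.3, symmetric family): corrected
$= x \cdot \mathrm{median}(\hat f)/\hat f$, with fits floored at a small
epsilon. The default fits one consensus curve to the across-sample median of
the library-size-normalized profile rather than each sample separately: GC
bias in an amplicon batch attaches to the fragment, so it is shared across
samples, and a consensus fit cannot "correct away" a CNV that, at small
panel sizes, would occupy a visible fraction of its own sample's fit (a
12-of-55-amplicon deletion loses roughly a third of its amplitude under
per-sample fits in our simulations; `fit = "per-sample"` remains available).
Autosomal and sex-chromosome amplicons are then separated — sex-dependent
coverage would otherwise dominate the autosomal components — and each
sample is divided by its own mean, giving every sample mean coverage exactly 1.

**Variance control.** Amplicons are the observations, samples the
variables. Each sample column is centered, the centered matrix is
decomposed by SVD, and the top $k$ components are zeroed before the means
are restored. $k$ is the value whose cumulative explained-variance fraction
is *nearest* the target (default 0.80), with $k = 0$ allowed; an "at least
80%" rule would forbid the under-target removals that real batches need.
The classical-MDS path double-centers the squared Euclidean distance matrix
between amplicon rows; because column centering already removes the row
centroid, the resulting Gram matrix is exactly $X_cX_c^\top$ and the
eigendecomposition reproduces the SVD solution — the two routes agree to
$10^{-8}$ and the test suite enforces it. Component signs follow a
largest-loading-positive convention for reproducible output.

**Leave-one-out Log2R.** With $n$ samples,
$\mathrm{Log2R}(a,s) = \log_2\frac{x(a,s) + \varepsilon}
{\frac{1}{n-1}\sum_{s' \ne s} x(a,s') + \varepsilon}$, with pseudocount
$\varepsilon = 10^{-3}$; denoised values below zero are clamped to zero
first, so the ratio is always finite.

**Segmentation.** Per chromosome, circular binary segmentation: every arc
of the circularly joined profile is scored with the pooled two-sample $t$
statistic of inside vs outside, the maximal statistic's significance is
estimated by permutation (10 000 permutations, $\alpha = 0.01$, seeded RNG;
the permutation loop stops early once the exceedance count already implies
$p > \alpha$), and accepted splits recurse. Isolated extreme points are
first clipped toward a 5-point running median (beyond 4 robust SDs, pulled
to 2): a single outlier otherwise attains the maximal statistic as a
one-point arc in the observed *and* every permuted profile, stalling the
recursion — the standard CBS toolchain ships the same median-smoothing for
this reason. Segment statistics are reported on the smoothed profile.

**Calling.** DS keeps segments with $|\bar L| \ge 0.5$ (the boundary value
calls — the neutral band is the open interval $(-0.5, 0.5)$), at least 10
amplicons, and SD $\le 1$. DS–AOF re-scores each survivor as
$\sum_a w_a L_a / \sum_a w_a$ over every amplicon intersecting the segment
interval, $w_a$ = bp overlap, and re-applies the $\pm 0.5$ classification to
that score; the count and SD filters still act on the original segment
statistics. Expected Log2R is $-1$ for a heterozygous deletion and $+0.585$
for a heterozygous duplication, so the $\pm 0.5$ threshold brackets both.

**Post-processing.** Samples with an excessive number of calls are flagged
by a one-sample $t$ test of the rest of the batch against the sample's
count (two-sided $p < 0.05$ *and* above the rest's mean; only high outliers
are flagged) and the variance-control/Log2R/segmentation stages re-run
without them. `run_pipeline` additionally requires a flagged sample to
carry at least `qc_min_calls = 3` calls: with the zero-variance convention
(identical rest, differing value, $p = 0$) a sample carrying one genuine
CNV in an otherwise call-free batch would otherwise be discarded, and one
or two CNVs are expected clinical findings, not library failures. Segment
scores are clustered with exact 1-D $k$-means (dynamic programming over the
sorted values, globally optimal within-cluster SS); $k$ maximizes the
Gaussian BIC $2\ell - (3k-1)\ln n$ with hard assignments, mixing
proportions $n_j/n$ and per-cluster ML variances floored at $10^{-6}$ (ties
toward smaller $k$). DS clusters `mean_log2r`, DS–AOF clusters
`aof_log2r`. Sensitivity and specificity are percentages rounded half-up to
two decimals with exact Clopper–Pearson 95% intervals
($\mathrm{lower} = 0.025^{1/n}$ when all $n$ trials succeed). Calls
overlapping exactly one TER while covering less than its full length are
flagged likely-FP: the design's resolution is one exon, so a
partial-single-exon event cannot be distinguished from noise.

## Tunable parameters

| parameter | default | unit | notes |
|---|---|---|---|
| `tolerance` | 0 | bp | endpoint slack for read assignment |
| `min_mean` | 100 | reads/amplicon | sample QC floor (panels sequenced ~4000×) |
| `gc.span` | 0.3 | — | loess span; `fit = "pooled"` or `"per-sample"` |
| `target` | 0.80 | fraction | removed-variance target (nearest rule) |
| `eps` | 1e-3 | normalized coverage | Log2R pseudocount |
| `alpha`, `n_perm` | 0.01, 10 000 | — | CBS split test |
| `st` | 0.5 | Log2R | call threshold, closed at the boundary |
| `min_amplicons`, `max_sd` | 10, 1.0 | — | segment filters |
| `k_max`, `var_floor` | 8, 1e-6 | — | BIC cluster scan |
| `qc_alpha`, `qc_min_calls` | 0.05, 3 | — | excess-CNV sample QC |

## What the simulator emulates

`simulate_counts` draws
$x(a,s) \sim \mathrm{NB}(\mu = D\,e_a\,\ell_s\,g(gc_a)\,f(a,s)\,c(a,s),\ \text{size})$
with depth $D = 4000$, lognormal amplicon efficiencies $e_a$ (sd 0.3),
lognormal library sizes $\ell_s$ (sd 0.2), a smooth quadratic log-GC
response, one latent multiplicative batch factor $f$ (per-cell log-sd 0.25,
per-sample amplitude normalized) and NB size 100 (residual coverage CV
~10%, i.e. per-amplicon Log2R noise ≈ 0.15). $c(a,s)$ is the spiked copy
ratio for amplicons *fully contained* in a truth interval (0.5/1.5 for
heterozygous events; partially overlapping amplicons are left neutral since
their true ratio would be intermediate). These choices make the removable
structure — the static efficiency profile (always the top component after
column centering) and the batch factor — dominate the spectrum with a wide
eigengap above a 12-amplicon CNV, so the nearest-80% rule removes one or
two components (68–94% of variance across seeds), which is the regime the
method is designed for.

What the simulator does **not** emulate: mappability and repeat content,
sequence-level errors, pseudogene cross-mapping, correlated GC effects
between neighbouring amplicons, multi-factor batch structure, and
population polymorphism of copy number. Passing tests therefore demonstrate
the pipeline's internal correctness and its behaviour under the intended
noise regime, not clinical performance on real libraries.

Desk-scale problem sizes are used throughout: 50–60 amplicons, 20 samples,
and 20 replicates for the recovery suites. Real panels are 100–1000× more
amplicons, where a CNV is a far smaller fraction of the total variance.

## Numerical conventions and degenerate inputs

All internal coordinates are 0-based half-open (BED); 1-based labels only
appear on plot axes. Chromosome order is natural (1…22, X, Y, M), with ties
in the design broken by (start, end, id). `select_num_components` breaks
ties toward smaller $k$; `which.max` ties in the BIC scan resolve to the
smaller $k$. GC correction degenerates to the identity (with a warning)
when all GC values are equal or fewer than 20 amplicons exist. A zero-mean
sample is an error at normalization (it should have been removed by the
coverage filter). Chromosomes with fewer than 2 amplicons return a single
segment. The excess-CNV QC reports $p = 0$ when the rest of the batch has
zero variance and the tested value differs.

## Design choices that were genuinely open

- **Unit of counting** is the single aligned read, not the fragment:
  HaloPlex read ends coincide with amplicon ends, and per-read counting is
  robust to unpaired data. Mapping-quality filtering defaults to off.
- **"Approximately 80%" variance removal** is operationalized as nearest
  cumulative variance because observed batches need removals both under and
  over the target, including zero.
- **AOF weights** are bp overlaps between each amplicon and the segment's
  genomic interval; amplicons fully inside contribute their full length.
- **TER file convention**: column 4 encodes `gene|exon_label`; the design
  BED carries amplicon name, gene and an optional precomputed GC column so
  fixtures can run FASTA-free.
- **Boundary at the call threshold is closed** ($|score| \ge 0.5$ calls),
  matching the open neutral band.

## Known limitations

- Component removal can occasionally absorb part of a true CNV when an
  estimated component aligns with it (small batches make the eigenvectors
  noisy); one simulated deletion in roughly ten is shrunk below the call
  threshold at desk scale. Inspecting the raw segment list alongside the
  filtered one is advisable for low-quality batches.
- The $\pm 0.5$ threshold is calibrated for heterozygous events; mosaic or
  low-fraction events fall inside the neutral band.
- The leave-one-out reference assumes most samples are CNV-free at any
  locus; a common polymorphic CNV would shift the reference itself.
- CBS arc scanning is quadratic per chromosome; panels with very dense
  designs (tens of thousands of amplicons on one chromosome) would need the
  windowed variants used by mature segmentation packages.
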