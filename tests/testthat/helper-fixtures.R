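# Shared fixture builders and independent oracles (all generated in code).

# Write a BED-like design + TER pair to tempfiles and parse it back.
make_parsed_design <- function(bed_lines, ter_lines = NULL) {
  bed <- tempfile(fileext = ".bed")
  writeLines(bed_lines, bed)
  ter <- NULL
  if (!is.null(ter_lines)) {
    ter <- tempfile(fileext = ".bed")
    writeLines(ter_lines, ter)
  }
  parse_design(bed, ter)
}

# A tiny regular design: n amplicons of width `len` spaced `step` apart.
make_toy_design <- function(n = 5, chrom = "chr1", start0 = 1000, len = 100,
                            step = 150, gene = "G1", gc = NULL) {
  starts <- start0 + (seq_len(n) - 1L) * step
  lines <- paste(chrom, starts, starts + len, sprintf("amp%02d", seq_len(n)),
                 gene, if (is.null(gc)) 0.5 else gc, sep = "\t")
  make_parsed_design(lines)
}

# Exhaustive arc oracle: the same pooled two-sample t over every circular
# arc, in plain R. Returns the maximizing arc (inside = (i+1)..j, 1-based).
oracle_max_arc <- function(x) {
  n <- length(x)
  best <- list(t = -Inf, i = NA, j = NA)
  for (i in 0:(n - 1)) {
    for (j in (i + 1):n) {
      m <- j - i
      if (m == n) next
      inside <- x[(i + 1):j]
      outside <- x[-((i + 1):j)]
      ssw <- sum((inside - mean(inside))^2) + sum((outside - mean(outside))^2)
      sp2 <- ssw / (n - 2)
      se <- sqrt(sp2 * (1 / m + 1 / (n - m)))
      tt <- if (se <= 0) {
        if (mean(inside) == mean(outside)) 0 else 1e12
      } else abs(mean(inside) - mean(outside)) / se
      if (tt > best$t) best <- list(t = tt, i = i, j = j)
    }
  }
  best
}

# Exhaustive 1-D k-means oracle: minimum within-cluster SS over all
# partitions of the sorted values into k contiguous blocks.
oracle_kmeans_ss <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  ss <- function(v) sum((v - mean(v))^2)
  if (k == 1) return(ss(x))
  cuts <- utils::combn(n - 1, k - 1)
  best <- Inf
  for (c in seq_len(ncol(cuts))) {
    b <- c(0, cuts[, c], n)
    tot <- 0
    for (q in seq_len(k)) tot <- tot + ss(x[(b[q] + 1):b[q + 1]])
    best <- min(best, tot)
  }
  best
}

# Brute-force interval overlap count (O(n^2) style scan).
oracle_overlap_count <- function(qs, qe, starts, ends) {
  sum(vapply(seq_along(starts),
             function(i) starts[i] < qe && ends[i] > qs, TRUE))
}
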