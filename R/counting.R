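# Read counting: exact amplicon-boundary assignment --------------------------

#' Count reads per amplicon by exact coordinate matching
#'
#' A read is assigned to an amplicon when both of its aligned reference
#' endpoints match the amplicon's endpoints within `tolerance` bp
#' (`tolerance = 0` demands exact coincidence, the HaloPlex assumption that
#' read ends fall on amplicon boundaries). Each read is counted for at most
#' one amplicon; when several amplicons match (identical or near-identical
#' coordinates) the first in design sort order wins and a warning is issued.
#' Reads matching no amplicon are discarded, which drops off-target and
#' partially overlapping alignments. Unmapped, secondary and supplementary
#' alignments are always ignored; duplicate-flagged reads are ignored by
#' default but should usually be *included* for amplicon libraries, where
#' identical fragment coordinates are expected by design
#' (`include_duplicates = TRUE`).
#'
#' @param bam_path path to a coordinate-sorted, indexed BAM.
#' @param design an `AmpliconDesign`.
#' @param tolerance non-negative integer, bp slack on each endpoint.
#' @param include_duplicates logical; keep duplicate-flagged reads.
#' @param min_mapq minimum mapping quality (default 0, no filtering).
#' @return named integer vector of counts, in design amplicon order.
#' @export
count_sample <- function(bam_path, design, tolerance = 0L,
                         include_duplicates = FALSE, min_mapq = 0L) {
  stopifnot(tolerance >= 0)
  if (!file.exists(bam_path)) stop("BAM not found: ", bam_path)
  bai <- c(paste0(bam_path, ".bai"), sub("\\.bam$", ".bai", bam_path))
  if (!any(file.exists(bai))) stop("BAM index (.bai) missing for ", bam_path)

  amp <- design$amplicons
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE,
    isDuplicate = if (include_duplicates) NA else FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag, what = c("rname", "pos", "cigar", "mapq"))
  rec <- Rsamtools::scanBam(bam_path, param = param)[[1]]

  counts <- integer(nrow(amp))
  names(counts) <- amp$id
  if (!length(rec$pos) || all(is.na(rec$pos))) {
    warning("no usable alignments in ", bam_path, "; returning zero counts")
    return(counts)
  }
  keep <- !is.na(rec$pos) & rec$mapq >= min_mapq
  # 0-based half-open reference span of each alignment
  rstart <- rec$pos[keep] - 1L
  rwidth <- GenomicAlignments::cigarWidthAlongReferenceSpace(rec$cigar[keep])
  reads <- data.table::data.table(
    chrom = as.character(rec$rname[keep]),
    s_lo = rstart - tolerance, s_hi = rstart + tolerance,
    rend = rstart + rwidth, read = seq_along(rstart))

  adt <- data.table::data.table(
    chrom = amp$chrom, a_start = amp$start, a_end = amp$end,
    idx = seq_len(nrow(amp)))
  adt[, `:=`(s1 = a_start, s2 = a_start)]
  data.table::setkey(adt, chrom, s1, s2)

  hits <- data.table::foverlaps(
    reads, adt, by.x = c("chrom", "s_lo", "s_hi"),
    type = "any", nomatch = NULL)
  hits <- hits[abs(rend - a_end) <= tolerance]
  if (nrow(hits)) {
    multi <- hits[, .N, by = read][N > 1L]
    if (nrow(multi)) {
      warning(nrow(multi), " read(s) matched multiple amplicons; ",
              "assigned to first in design order")
    }
    assigned <- hits[, .(idx = min(idx)), by = read]
    tab <- tabulate(assigned$idx, nbins = nrow(amp))
    counts[] <- as.integer(tab)
  }
  counts
}

#' Assemble per-sample count vectors into a count matrix
#'
#' @param vectors named list of per-amplicon integer vectors (one per
#'   sample), all in the same design order.
#' @return integer matrix, amplicons x samples, with dimnames.
#' @export
assemble_matrix <- function(vectors) {
  stopifnot(is.list(vectors), length(vectors) >= 1)
  n <- unique(lengths(vectors))
  if (length(n) != 1L) stop("count vectors differ in length")
  ids <- names(vectors[[1]])
  for (v in vectors) {
    if (!identical(names(v), ids)) stop("count vectors differ in amplicon order")
  }
  m <- vapply(vectors, as.integer, integer(n))
  if (is.null(dim(m))) m <- matrix(m, ncol = length(vectors))
  rownames(m) <- ids
  colnames(m) <- if (!is.null(names(vectors))) names(vectors) else
    paste0("sample", seq_along(vectors))
  if (any(m < 0)) stop("negative counts are invalid")
  m
}

#' Remove samples with insufficient average coverage
#'
#' Samples whose mean read count per amplicon falls below `min_mean` are
#' dropped (the boundary value is retained). With the panels sequenced at an
#' average depth around 4000x, a sample averaging fewer than 100 reads per
#' amplicon indicates a failed library.
#'
#' @param m count matrix (amplicons x samples).
#' @param min_mean minimum mean reads/amplicon (default 100).
#' @return list with `counts` (filtered matrix) and `removed` (sample ids).
#' @export
filter_low_coverage_samples <- function(m, min_mean = 100) {
  stopifnot(is.matrix(m), ncol(m) >= 1)
  mu <- colMeans(m)
  drop <- mu < min_mean
  if (all(drop)) stop("no analyzable samples: all below mean coverage ", min_mean)
  list(counts = m[, !drop, drop = FALSE], removed = colnames(m)[drop])
}

#' Prune amplicons with zero reads across all samples
#'
#' @param m count matrix.
#' @return list with `counts` (pruned matrix) and `removed` (amplicon ids).
#' @export
prune_zero_amplicons <- function(m) {
  stopifnot(is.matrix(m))
  zero <- rowSums(m) == 0
  list(counts = m[!zero, , drop = FALSE], removed = rownames(m)[zero])
}

#' Write a count matrix to TSV (amplicon id + coordinates + one column per sample)
#' @param m count matrix; `design` an `AmpliconDesign`; `path` output file.
#' @param design an `AmpliconDesign` supplying coordinates for the rows.
#' @param path output TSV path.
#' @export
write_counts <- function(m, design, path) {
  a <- design$amplicons
  i <- match(rownames(m), a$id)
  df <- data.frame(amplicon = rownames(m), chrom = a$chrom[i],
                   start = a$start[i], end = a$end[i],
                   m, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix written by [write_counts()]
#' @param path TSV path.
#' @return integer matrix with amplicon rownames.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, setdiff(colnames(df), c("amplicon", "chrom", "start", "end")),
                    drop = FALSE])
  rownames(m) <- df$amplicon
  storage.mode(m) <- "double"
  m
}
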