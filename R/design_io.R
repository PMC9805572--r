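#' @useDynLib ampliconcnv, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

# Chromosome helpers ---------------------------------------------------------

strip_chr <- function(chrom) sub("^chr", "", chrom, ignore.case = TRUE)

#' Classify chromosomes as autosomal or sex
#'
#' X and Y (with or without a "chr" prefix) are sex chromosomes; everything
#' else is treated as autosomal. Original names are never modified.
#'
#' @param chrom character vector of chromosome names.
#' @return character vector, each element `"autosomal"` or `"sex"`.
#' @export
chrom_class <- function(chrom) {
  ifelse(toupper(strip_chr(chrom)) %in% c("X", "Y"), "sex", "autosomal")
}

# Deterministic total order on chromosome names: numeric chromosomes first in
# numeric order, then X, Y, M/MT, then anything else alphabetically.
chrom_rank <- function(chrom) {
  core <- toupper(strip_chr(chrom))
  num <- suppressWarnings(as.numeric(core))
  rank <- ifelse(!is.na(num), num,
    ifelse(core == "X", 1e6 + 1,
      ifelse(core == "Y", 1e6 + 2,
        ifelse(core %in% c("M", "MT"), 1e6 + 3, 2e6))))
  # unknown names tie at 2e6; break alphabetically via secondary key upstream
  rank
}

design_order <- function(chrom, start, end, id) {
  order(chrom_rank(chrom), chrom, start, end, id, method = "radix")
}

# Parsing --------------------------------------------------------------------

read_bedlike <- function(path, min_cols, what) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("no records in ", what, " file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < min_cols)) {
    bad <- lineno[which(nf < min_cols)[1]]
    stop(sprintf("%s parse error at line %d of %s: expected >= %d tab-separated columns",
                 what, bad, path, min_cols))
  }
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end   <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    bad <- lineno[which(is.na(start) | is.na(end))[1]]
    stop(sprintf("%s parse error at line %d of %s: non-numeric coordinate",
                 what, bad, path))
  }
  if (any(start >= end)) {
    bad <- lineno[which(start >= end)[1]]
    stop(sprintf("%s validation error at line %d of %s: start >= end",
                 what, bad, path))
  }
  list(fields = fields, start = as.integer(start), end = as.integer(end),
       lineno = lineno)
}

#' Parse an amplicon design and target exon region (TER) file
#'
#' Both files are BED-like (0-based half-open coordinates, tab-separated).
#' The design file needs at least four columns: chrom, start, end, amplicon
#' name; column 5, when present, is the gene symbol and column 6 an optional
#' precomputed GC fraction (used when no FASTA is supplied). The TER file's
#' fourth column encodes `gene|exon_label`. Overlapping amplicons and
#' duplicated coordinates are deliberately preserved — the design is never
#' merged — and amplicons are sorted by (chrom, start, end, id).
#'
#' @param bed_path path to the amplicon design BED file.
#' @param ter_path path to the TER BED file, or `NULL` to omit TERs.
#' @return an object of class `AmpliconDesign`: a list with data.frame
#'   components `amplicons` (id, chrom, start, end, gene, gc_fraction, class)
#'   and `ters` (chrom, start, end, gene, exon_label).
#' @export
parse_design <- function(bed_path, ter_path = NULL) {
  b <- read_bedlike(bed_path, 4L, "design")
  chrom <- vapply(b$fields, `[[`, "", 1L)
  id    <- vapply(b$fields, `[[`, "", 4L)
  gene  <- vapply(b$fields, function(f) if (length(f) >= 5) f[[5]] else NA_character_, "")
  gc    <- vapply(b$fields, function(f)
    if (length(f) >= 6) suppressWarnings(as.numeric(f[[6]])) else NA_real_, 0)
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    stop("duplicate amplicon ids in design: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  amp <- data.frame(id = id, chrom = chrom, start = b$start, end = b$end,
                    gene = gene, gc_fraction = gc,
                    class = chrom_class(chrom), stringsAsFactors = FALSE)
  amp <- amp[design_order(amp$chrom, amp$start, amp$end, amp$id), , drop = FALSE]
  rownames(amp) <- NULL

  ters <- NULL
  if (!is.null(ter_path)) {
    t <- read_bedlike(ter_path, 4L, "TER")
    lab <- vapply(t$fields, `[[`, "", 4L)
    parts <- strsplit(lab, "|", fixed = TRUE)
    ters <- data.frame(
      chrom = vapply(t$fields, `[[`, "", 1L),
      start = t$start, end = t$end,
      gene = vapply(parts, `[[`, "", 1L),
      exon_label = vapply(parts, function(p) if (length(p) >= 2) p[[2]] else NA_character_, ""),
      stringsAsFactors = FALSE)
    ters <- ters[design_order(ters$chrom, ters$start, ters$end, ters$gene), , drop = FALSE]
    rownames(ters) <- NULL
  }
  structure(list(amplicons = amp, ters = ters), class = "AmpliconDesign")
}

#' @export
print.AmpliconDesign <- function(x, ...) {
  cat(sprintf("AmpliconDesign: %d amplicons on %d chromosome(s)",
              nrow(x$amplicons), length(unique(x$amplicons$chrom))))
  if (!is.null(x$ters))
    cat(sprintf("; %d target exon regions, %d gene(s)",
                nrow(x$ters), length(unique(x$ters$gene))))
  cat("\n")
  invisible(x)
}

#' Write an amplicon design (and optionally its TERs) back to BED
#'
#' Round-trips [parse_design()]: coordinates and names are reproduced exactly.
#'
#' @param design an `AmpliconDesign`.
#' @param bed_path output path for the amplicon BED.
#' @param ter_path optional output path for the TER BED.
#' @return `design`, invisibly.
#' @export
write_design <- function(design, bed_path, ter_path = NULL) {
  a <- design$amplicons
  cols <- list(a$chrom, a$start, a$end, a$id)
  if (!all(is.na(a$gene))) cols <- c(cols, list(ifelse(is.na(a$gene), ".", a$gene)))
  if (!all(is.na(a$gc_fraction))) {
    if (length(cols) == 4L) cols <- c(cols, list(rep(".", nrow(a))))
    cols <- c(cols, list(format(a$gc_fraction, digits = 15, scientific = FALSE, trim = TRUE)))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), bed_path)
  if (!is.null(ter_path) && !is.null(design$ters)) {
    t <- design$ters
    lab <- ifelse(is.na(t$exon_label), t$gene, paste(t$gene, t$exon_label, sep = "|"))
    writeLines(paste(t$chrom, t$start, t$end, lab, sep = "\t"), ter_path)
  }
  invisible(design)
}

#' Compute per-amplicon GC fraction from a reference FASTA
#'
#' GC fraction is (G+C)/(A+C+G+T) over the amplicon interval, case
#' insensitive; ambiguous bases (N etc.) are excluded from numerator and
#' denominator. The FASTA must be faidx-indexed (an index is created when
#' missing).
#'
#' @param design an `AmpliconDesign`.
#' @param fasta_path path to the reference FASTA.
#' @return the design with `gc_fraction` filled in.
#' @export
compute_gc <- function(design, fasta_path) {
  if (!file.exists(paste0(fasta_path, ".fai"))) Rsamtools::indexFa(fasta_path)
  fa <- Rsamtools::FaFile(fasta_path)
  present <- as.character(GenomicRanges::seqnames(Rsamtools::scanFaIndex(fa)))
  a <- design$amplicons
  missing_chrom <- !(a$chrom %in% present)
  if (any(missing_chrom)) {
    stop("chromosomes absent from FASTA for amplicons: ",
         paste(utils::head(a$id[missing_chrom], 10), collapse = ", "))
  }
  gr <- GenomicRanges::GRanges(a$chrom, IRanges::IRanges(a$start + 1L, a$end))
  seqs <- Rsamtools::scanFa(fa, gr)
  freq <- Biostrings::letterFrequency(seqs, c("A", "C", "G", "T"))
  acgt <- rowSums(freq)
  gc <- ifelse(acgt > 0, (freq[, "G"] + freq[, "C"]) / acgt, NA_real_)
  design$amplicons$gc_fraction <- as.numeric(gc)
  design
}
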