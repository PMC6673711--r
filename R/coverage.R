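#' Count aligned reads in non-overlapping windows
#'
#' Assigns each mapped read to exactly one window: the window containing its
#' 0-based alignment start (windows are half-open `[i*w, (i+1)*w)`). Reads
#' starting in the dropped partial window at a chromosome tail are not
#' counted; reads starting beyond the chromosome end are an input error.
#'
#' @param alignments Either a data frame with columns `chrom` and `start`
#'   (0-based alignment start), or the path to a SAM/BAM file (requires
#'   Rsamtools; unmapped, secondary, supplementary and duplicate reads are
#'   excluded; SAM 1-based POS is converted).
#' @param ref A `cnv_reference` (or any list with `windows`, `chromosomes`,
#'   `window_size` elements).
#' @return Integer vector of counts, one per row of `ref$windows`.
#' @export
count_reads_in_windows <- function(alignments, ref) {
  if (is.character(alignments) && length(alignments) == 1L) {
    alignments <- read_alignment_starts(alignments)
  }
  stopifnot_cols(alignments, c("chrom", "start"), "'alignments'")
  w <- ref$window_size
  chroms <- ref$chromosomes
  clen <- setNames(chroms$length, chroms$chrom)
  if (any(!alignments$chrom %in% chroms$chrom)) {
    stop("alignment on unknown chromosome")
  }
  if (any(alignments$start < 0 | alignments$start >= clen[alignments$chrom])) {
    stop("alignment start beyond chromosome length")
  }
  win_idx <- floor(alignments$start / w)
  key <- paste(alignments$chrom, win_idx)
  ref_key <- paste(ref$windows$chrom, ref$windows$window)
  tab <- table(factor(key, levels = ref_key))
  as.integer(tab)
}

# Read (chrom, 0-based start) for primary mapped non-duplicate reads from a
# SAM or BAM file via Rsamtools.
read_alignment_starts <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("reading SAM/BAM requires the Rsamtools package")
  }
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isDuplicate = FALSE)
  p <- Rsamtools::ScanBamParam(flag = flag, what = c("rname", "pos"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  keep <- !is.na(b$pos)
  data.frame(chrom = as.character(b$rname)[keep], start = b$pos[keep] - 1L,
             stringsAsFactors = FALSE)
}

# Logical mask of windows usable for computing GC normalizing constants:
# autosomal and >= 90% accessible.
normalization_mask <- function(windows, chromosomes,
                               min_accessibility = 0.9) {
  auto <- chromosomes$chrom[chromosomes$is_autosome]
  windows$chrom %in% auto & windows$accessibility >= min_accessibility
}

#' Per-sample GC normalizing constants
#'
#' For each sample and each represented GC percentage, the mean raw read
#' count over autosomal windows with that GC percentage and at least 90%
#' accessible bases. Inaccessible and sex-chromosome windows are excluded so
#' that regions of unusual coverage do not distort the constants.
#'
#' @param counts Samples x windows integer matrix of raw counts.
#' @param windows Window track data frame (`chrom`, `gc`, `accessibility`).
#' @param chromosomes Chromosome table with `is_autosome`.
#' @param min_accessibility Accessibility threshold (default 0.9).
#' @return Samples x 101 matrix (columns GC 0..100), `NA` for unrepresented
#'   bins, with attribute `support`: the number of qualifying windows per bin.
#' @export
gc_normalizing_constants <- function(counts, windows, chromosomes,
                                     min_accessibility = 0.9) {
  mask <- normalization_mask(windows, chromosomes, min_accessibility)
  gc <- windows$gc
  gcf <- factor(gc[mask], levels = 0:100)
  support <- as.integer(table(gcf))
  const <- t(apply(counts[, mask, drop = FALSE], 1, function(x) {
    tapply(x, gcf, mean)
  }))
  colnames(const) <- as.character(0:100)
  attr(const, "support") <- setNames(support, as.character(0:100))
  const
}

#' GC-normalize windowed read counts to copy-number scale
#'
#' Divides each window's raw count by the sample's mean count over autosomal
#' accessible windows of the same GC percentage, then multiplies by 2, so
#' that diploid regions have expected normalized coverage 2 (and the haploid
#' male X about 1). Windows whose GC bin has no defined constant (or a
#' constant of zero) get `NA`.
#'
#' @param x A `cnv_coverage` object, or a raw counts matrix.
#' @param windows,chromosomes Required when `x` is a matrix.
#' @param constants Optional precomputed [gc_normalizing_constants()] matrix.
#' @return If `x` is a `cnv_coverage`, the object with `$norm` filled;
#'   otherwise the normalized matrix (attribute `constants` attached).
#' @export
normalize_coverage <- function(x, windows = NULL, chromosomes = NULL,
                               constants = NULL) {
  is_obj <- inherits(x, "cnv_coverage")
  counts <- if (is_obj) x$counts else x
  if (is_obj) {
    windows <- x$windows
    chromosomes <- x$chromosomes
  }
  if (is.null(constants)) {
    constants <- gc_normalizing_constants(counts, windows, chromosomes)
  }
  gc_col <- match(as.character(windows$gc), colnames(constants))
  norm <- matrix(NA_real_, nrow(counts), ncol(counts),
                 dimnames = dimnames(counts))
  for (i in seq_len(nrow(counts))) {
    k <- constants[i, gc_col]
    ok <- !is.na(k) & k > 0
    norm[i, ok] <- 2 * counts[i, ok] / k[ok]
  }
  attr(norm, "constants") <- constants
  if (is_obj) {
    x$norm <- norm
    x
  } else {
    norm
  }
}

#' Build the analysis window filter
#'
#' A window is dropped if more than 2% of its reads were aligned with mapping
#' quality zero (`MQ0_EXCESS`), or if its GC percentage is represented by
#' fewer than 100 accessible autosomal windows, making the GC normalizing
#' constant unreliable (`GC_RARE`). Both thresholds are strict: a window at
#' exactly 2% MQ0, or a bin with exactly 100 supporting windows, is kept.
#' Windows surviving both rules are the "kept" (filtered) windows on which
#' all downstream copy-number analysis operates.
#'
#' @param x A `cnv_coverage` object, or a window track data frame.
#' @param chromosomes Required when `x` is a data frame.
#' @param max_mq0 MQ0-fraction threshold (default 0.02).
#' @param min_bin_support Minimum accessible autosomal windows per GC bin
#'   (default 100).
#' @return If `x` is a `cnv_coverage`, the object with `$filter` filled;
#'   otherwise a data frame with logical `keep` and a `reason` string
#'   (`""`, `"MQ0_EXCESS"`, `"GC_RARE"` or both, `;`-separated).
#' @export
build_window_filter <- function(x, chromosomes = NULL, max_mq0 = 0.02,
                                min_bin_support = 100) {
  is_obj <- inherits(x, "cnv_coverage")
  windows <- if (is_obj) x$windows else x
  if (is_obj) chromosomes <- x$chromosomes
  mask <- normalization_mask(windows, chromosomes)
  support <- table(factor(windows$gc[mask], levels = 0:100))
  mq0_bad <- windows$mq0_frac > max_mq0
  gc_bad <- as.integer(support[as.character(windows$gc)]) < min_bin_support
  reason <- rep("", nrow(windows))
  reason[mq0_bad] <- "MQ0_EXCESS"
  reason[gc_bad] <- ifelse(nzchar(reason[gc_bad]),
                           paste0(reason[gc_bad], ";GC_RARE"), "GC_RARE")
  out <- data.frame(keep = !(mq0_bad | gc_bad), reason = reason,
                    stringsAsFactors = FALSE)
  if (is_obj) {
    x$filter <- out
    x
  } else {
    out
  }
}
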