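#' Simulate a windowed reference genome with annotation tracks
#'
#' Builds a small synthetic reference for testing the CNV pipeline: fixed-size
#' non-overlapping windows tiling each chromosome (the trailing partial window
#' is dropped), with per-window GC content, accessibility and MQ0-read
#' fraction, heterochromatin intervals at the chromosome ends, and ordered,
#' non-overlapping gene models, a configurable fraction of which are flagged
#' as metabolic detoxification genes (cytochrome P450s, glutathione
#' S-transferases, carboxylesterases).
#'
#' A chromosome named `"X"` is treated as the sex chromosome (haploid in
#' males); all others are autosomes.
#'
#' @param seed Integer seed; the reference is fully reproducible given the
#'   seed and parameters.
#' @param chrom_lengths Named integer vector of chromosome lengths in bp.
#' @param window_size Window size in bp (default 300).
#' @param gc_mean,gc_sd Mean and SD of the per-window GC percentage, drawn
#'   independently per window from a rounded, clamped normal. `gc_sd = 0`
#'   gives a uniform-GC genome (useful for small toy genomes where rare GC
#'   bins would otherwise be filtered out).
#' @param het_fraction Fraction of each chromosome annotated as
#'   heterochromatin, split equally between the two chromosome ends. 0 gives
#'   an empty heterochromatin set.
#' @param gene_density Genes per megabase.
#' @param detox_fraction Fraction of genes flagged as detox genes.
#' @param inaccessible_fraction Fraction of windows given accessibility < 0.9.
#' @param high_mq0_fraction Fraction of windows given an elevated MQ0-read
#'   fraction (some of which exceed the 2% filter threshold).
#'
#' @return An object of class `cnv_reference`: a list with elements
#'   `chromosomes` (data frame: `chrom`, `length`, `is_autosome`),
#'   `window_size`, `windows` (data frame: `chrom`, `window` 0-based index
#'   within chromosome, `start`, `end` 0-based half-open, `gc`,
#'   `accessibility`, `mq0_frac`), `heterochromatin` (data frame: `chrom`,
#'   `start`, `end`) and `genes` (data frame: `gene_id`, `chrom`, `start`,
#'   `end`, `description`, `detox`).
#' @export
simulate_reference <- function(seed,
                               chrom_lengths = c("2L" = 6e5, "2R" = 6e5, "X" = 3e5),
                               window_size = 300,
                               gc_mean = 45, gc_sd = 8,
                               het_fraction = 0.1,
                               gene_density = 50,
                               detox_fraction = 0.08,
                               inaccessible_fraction = 0.05,
                               high_mq0_fraction = 0.05) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    stop("'chrom_lengths' must be a named vector")
  }
  if (any(chrom_lengths < window_size)) {
    stop("every chromosome must be at least one window long")
  }
  with_seed(seed, {
    chroms <- data.frame(
      chrom = names(chrom_lengths),
      length = as.numeric(chrom_lengths),
      is_autosome = names(chrom_lengths) != "X",
      stringsAsFactors = FALSE
    )

    win_list <- lapply(seq_len(nrow(chroms)), function(i) {
      n <- floor(chroms$length[i] / window_size)  # partial tail window dropped
      idx <- seq_len(n) - 1L
      data.frame(
        chrom = chroms$chrom[i],
        window = idx,
        start = idx * window_size,
        end = (idx + 1L) * window_size,
        stringsAsFactors = FALSE
      )
    })
    windows <- do.call(rbind, win_list)
    nw <- nrow(windows)

    gc <- if (gc_sd > 0) {
      pmin(100L, pmax(0L, as.integer(round(rnorm(nw, gc_mean, gc_sd)))))
    } else {
      rep(as.integer(round(gc_mean)), nw)
    }
    windows$gc <- gc

    acc <- rep(1, nw)
    low <- runif(nw) < inaccessible_fraction
    acc[low] <- runif(sum(low), 0, 0.89)
    windows$accessibility <- acc

    mq0 <- runif(nw, 0, 0.01)
    hi <- runif(nw) < high_mq0_fraction
    mq0[hi] <- runif(sum(hi), 0, 0.2)
    windows$mq0_frac <- mq0

    het <- if (het_fraction > 0) {
      do.call(rbind, lapply(seq_len(nrow(chroms)), function(i) {
        L <- chroms$length[i]
        side <- het_fraction * L / 2
        data.frame(chrom = chroms$chrom[i],
                   start = c(0, L - side), end = c(side, L),
                   stringsAsFactors = FALSE)
      }))
    } else {
      data.frame(chrom = character(), start = numeric(), end = numeric(),
                 stringsAsFactors = FALSE)
    }

    genes <- do.call(rbind, lapply(seq_len(nrow(chroms)), function(i) {
      L <- chroms$length[i]
      ng <- max(0L, as.integer(round(gene_density * L / 1e6)))
      if (ng == 0L) return(NULL)
      len <- pmin(pmax(round(rexp(ng, 1 / 2000)), 500), L / 4)
      # lay genes left-to-right with random gaps, then drop overflow
      gaps <- rexp(ng, ng / max(1, L - sum(len)))
      starts <- cumsum(gaps + c(0, len[-ng]))
      keep <- starts + len <= L
      if (!any(keep)) return(NULL)
      data.frame(chrom = chroms$chrom[i],
                 start = floor(starts[keep]), end = floor(starts[keep] + len[keep]),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(genes)) {
      genes <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                          stringsAsFactors = FALSE)
    }
    ng <- nrow(genes)
    detox <- runif(ng) < detox_fraction
    fam <- sample(c("cytochrome P450", "glutathione S-transferase",
                    "carboxylesterase"), ng, replace = TRUE)
    genes$gene_id <- sprintf("GENE%04d", seq_len(ng))
    genes$description <- ifelse(detox, fam, "hypothetical protein")
    genes$detox <- detox
    genes <- genes[, c("gene_id", "chrom", "start", "end", "description", "detox")]

    structure(list(chromosomes = chroms, window_size = window_size,
                   windows = windows, heterochromatin = het, genes = genes),
              class = "cnv_reference")
  })
}

#' @export
print.cnv_reference <- function(x, ...) {
  cat("<cnv_reference>", nrow(x$chromosomes), "chromosome(s),",
      nrow(x$windows), "windows of", x$window_size, "bp,",
      nrow(x$genes), "genes\n")
  invisible(x)
}

#' Flag detoxification genes by annotation keyword
#'
#' Marks genes whose description contains one of the metabolic detox keywords
#' "P450", "glutathione S-transferase" or "carboxylesterase".
#'
#' @param genes Data frame with a `description` column.
#' @return The data frame with a logical `detox` column (re)computed.
#' @export
flag_detox_genes <- function(genes) {
  stopifnot_cols(genes, "description", "'genes'")
  pat <- "P450|glutathione S-transferase|carboxylesterase"
  genes$detox <- grepl(pat, genes$description)
  genes
}
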