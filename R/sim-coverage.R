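#' Simulate a cohort sample sheet
#'
#' @param n Number of samples.
#' @param populations Character vector of population labels to cycle over.
#' @param mean_depth Target mean read count per window at GC-bias factor 1 and
#'   copy number 2 (reads/window; 30 mimics ~30x short-read coverage in 300-bp
#'   windows with ~100-bp reads counted once at their start).
#' @param depth_sd Between-sample SD of the per-sample mean depth.
#' @param dispersion Negative-binomial variance inflation factor (variance =
#'   dispersion x mean); 1 gives Poisson counts.
#' @param prop_male Proportion of males (haploid X).
#' @param seed Integer seed.
#' @return Data frame with columns `sample_id`, `population`, `sex`,
#'   `mean_depth`, `dispersion`.
#' @export
simulate_samples <- function(n, populations = "popA", mean_depth = 30,
                             depth_sd = 0, dispersion = 1, prop_male = 0.5,
                             seed = NULL) {
  with_seed(seed, {
    data.frame(
      sample_id = sprintf("S%03d", seq_len(n)),
      population = rep_len(populations, n),
      sex = ifelse(runif(n) < prop_male, "M", "F"),
      mean_depth = pmax(1, rnorm(n, mean_depth, depth_sd)),
      dispersion = rep_len(dispersion, n),
      stringsAsFactors = FALSE
    )
  })
}

#' GC-dependent coverage bias factor
#'
#' Unimodal quadratic bias in expected coverage as a function of window GC
#' percentage, peaking at `peak` (default 45%), mimicking the depletion of
#' read depth at extreme base composition seen in Illumina libraries.
#'
#' @param gc Integer GC percentage (0-100), vectorized.
#' @param peak GC percentage of maximum coverage.
#' @param strength Relative depth loss at 50 GC points from the peak.
#' @return Multiplicative factor, floored at 0.05.
#' @export
gc_bias_factor <- function(gc, peak = 45, strength = 0.6) {
  pmax(0.05, 1 - strength * ((gc - peak) / 50)^2)
}

# Validate a planted-CNV table against a reference and sample sheet, and
# return it with a normalized column set.
validate_planted_cnvs <- function(ref, samples, planted) {
  stopifnot_cols(planted,
                 c("sample_id", "chrom", "start_window", "end_window",
                   "copies_added", "zygosity", "mechanism", "allele_id"),
                 "'planted'")
  bad <- !planted$sample_id %in% samples$sample_id
  if (any(bad)) stop("planted CNV references unknown sample: ",
                     planted$sample_id[bad][1])
  if (any(!planted$chrom %in% ref$chromosomes$chrom)) {
    stop("planted CNV references unknown chromosome")
  }
  if (any(planted$end_window < planted$start_window)) {
    stop("planted CNV run must span at least one window")
  }
  if (any(planted$copies_added < 1)) stop("'copies_added' must be >= 1")
  if (!all(planted$zygosity %in% 1:2)) stop("'zygosity' must be 1 or 2")
  nwin <- table(ref$windows$chrom)
  if (any(planted$end_window >= nwin[planted$chrom])) {
    stop("planted CNV extends beyond the window grid")
  }
  sex <- samples$sex[match(planted$sample_id, samples$sample_id)]
  if (any(planted$chrom == "X" & sex == "M" & planted$zygosity == 2)) {
    stop("a male sample cannot carry an X-linked CNV on two chromosomes")
  }
  planted
}

# Per-sample total copy number per window given planted CNVs.
total_copy_number <- function(ref, sample_row, planted) {
  win <- ref$windows
  cn <- ifelse(win$chrom == "X" & sample_row$sex == "M", 1, 2)
  if (!is.null(planted) && nrow(planted)) {
    mine <- planted[planted$sample_id == sample_row$sample_id, , drop = FALSE]
    for (i in seq_len(nrow(mine))) {
      sel <- win$chrom == mine$chrom[i] &
        win$window >= mine$start_window[i] & win$window <= mine$end_window[i]
      cn[sel] <- cn[sel] + mine$zygosity[i] * mine$copies_added[i]
    }
  }
  cn
}

#' Simulate raw windowed read counts for a cohort
#'
#' Draws per-window read counts from a negative binomial (Poisson when
#' `dispersion == 1`) with mean
#' `mean_depth x gc_bias_factor(gc) x CN / 2`, where CN is the window's total
#' copy number for the sample: 2 on autosomes, 1 on the male X, plus
#' `zygosity x copies_added` over each planted CNV run.
#'
#' @param ref A [simulate_reference()] object.
#' @param samples Sample sheet as from [simulate_samples()].
#' @param planted Optional planted-CNV table (columns `sample_id`, `chrom`,
#'   `start_window`, `end_window`, `copies_added`, `zygosity`, `mechanism`,
#'   `allele_id`), the truth for downstream tests.
#' @param seed Integer seed.
#' @param gc_bias_strength Passed to [gc_bias_factor()]; 0 disables GC bias.
#' @return An object of class `cnv_coverage`: list with `counts` (samples x
#'   windows integer matrix, rows named by sample), `samples`, `windows`,
#'   `chromosomes`, `window_size`, `truth` (the planted table) and
#'   placeholders `norm` / `filter` filled by [normalize_coverage()] and
#'   [build_window_filter()].
#' @export
simulate_window_counts <- function(ref, samples, planted = NULL, seed = NULL,
                                   gc_bias_strength = 0.6) {
  if (!inherits(ref, "cnv_reference")) stop("'ref' must be a cnv_reference")
  if (!is.null(planted)) planted <- validate_planted_cnvs(ref, samples, planted)
  win <- ref$windows
  gcf <- gc_bias_factor(win$gc, strength = gc_bias_strength)
  with_seed(seed, {
    counts <- matrix(0L, nrow(samples), nrow(win),
                     dimnames = list(samples$sample_id, NULL))
    for (i in seq_len(nrow(samples))) {
      cn <- total_copy_number(ref, samples[i, ], planted)
      mu <- samples$mean_depth[i] * gcf * cn / 2
      disp <- samples$dispersion[i]
      counts[i, ] <- if (disp > 1) {
        rnbinom(length(mu), mu = mu, size = ifelse(mu > 0, mu / (disp - 1), 1))
      } else {
        rpois(length(mu), mu)
      }
    }
    structure(list(counts = counts, samples = samples, windows = win,
                   chromosomes = ref$chromosomes, window_size = ref$window_size,
                   truth = planted, norm = NULL, filter = NULL),
              class = "cnv_coverage")
  })
}

#' @export
print.cnv_coverage <- function(x, ...) {
  cat("<cnv_coverage>", nrow(x$counts), "samples x", ncol(x$counts),
      "windows;", if (is.null(x$norm)) "raw counts only" else "normalized",
      "\n")
  invisible(x)
}
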