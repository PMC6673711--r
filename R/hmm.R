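#' Gaussian HMM parameters for copy-number state inference
#'
#' States are integer copy numbers `0..max_state`; emissions are Gaussian
#' with mean equal to the state (on the normalized-coverage scale where
#' diploid is 2) and variance affine in the state,
#' `var_k = var_base + k * var_slope`, reflecting the roughly linear growth
#' of coverage variance with copy number. Transitions between any two
#' distinct states share a single small probability `trans`; self-transition
#' is `1 - max_state * trans`.
#'
#' @param max_state Highest copy-number state (default 12).
#' @param trans Between-state transition probability (default 1e-5).
#' @param var_base,var_slope Emission variance intercept and per-state slope.
#' @return Object of class `hmm_params`.
#' @export
hmm_params <- function(max_state = 12, trans = 1e-5, var_base = 0.02,
                       var_slope = 0.1) {
  stopifnot(max_state >= 1, trans > 0, trans * max_state < 1,
            var_base > 0, var_slope >= 0)
  states <- 0:max_state
  structure(list(states = states, means = as.numeric(states),
                 vars = var_base + states * var_slope, trans = trans),
            class = "hmm_params")
}

#' Estimate per-sample emission variance from normalized coverage
#'
#' Uses the squared median absolute deviation (MAD, normal-consistent) of the
#' sample's autosomal kept-window normalized coverage as a robust estimate
#' `v2` of the variance at copy number 2 (robustness keeps CNV windows from
#' inflating it), then sets `var_slope = v2 / 2` (variance proportional to
#' copy number, equal to `v2` at CN 2) and a small positive floor
#' `var_base = v2 / 10` so that state 0 has non-degenerate variance.
#'
#' @param x Numeric vector: the sample's normalized coverage over autosomal
#'   kept windows.
#' @param max_state,trans Passed to [hmm_params()].
#' @return An `hmm_params` object.
#' @export
estimate_hmm_params <- function(x, max_state = 12, trans = 1e-5) {
  v2 <- max(mad(x, na.rm = TRUE)^2, 1e-4)
  hmm_params(max_state = max_state, trans = trans,
             var_base = v2 / 10, var_slope = v2 / 2)
}

#' Most likely copy-number state path for one sample and chromosome
#'
#' Viterbi decoding of the Gaussian HMM over the kept windows of a
#' chromosome. The male X is decoded with the same emission means (state =
#' copy number); the haploid baseline matters only for call extraction and
#' the likelihood-ratio null, not for decoding.
#'
#' @param x Normalized coverage over kept windows (no `NA`s).
#' @param params An [hmm_params()] object.
#' @return Integer vector of copy-number states, one per window; ties are
#'   broken toward the lower state.
#' @export
viterbi_cns <- function(x, params) {
  if (length(x) == 0) return(integer(0))
  if (anyNA(x)) stop("normalized coverage contains NA; restrict to kept windows")
  K <- length(params$states) - 1L
  viterbi_gaussian(as.numeric(x), params$means, params$vars,
                   log1p(-K * params$trans), log(params$trans))
}

#' Extract raw amplification calls from a state path
#'
#' Emits maximal contiguous runs of at least `min_windows` kept windows with
#' copy-number state above the baseline (2 on autosomes, 1 on the male X).
#' Contiguity is in kept-window index space: windows removed by the filter do
#' not interrupt a run. Genomic start/end are the first window's start and
#' the last window's end.
#'
#' @param states Integer state path from [viterbi_cns()].
#' @param kept_windows Data frame of the corresponding kept windows (columns
#'   `chrom`, `window`, `start`, `end`), same length as `states`.
#' @param sample_id Sample identifier recorded in the calls.
#' @param sex `"M"` or `"F"` (baseline 1 on the male X).
#' @param min_windows Minimum run length (default 5, i.e. 1500 bp at 300-bp
#'   windows).
#' @return Data frame of raw calls: `sample_id`, `chrom`, `start`, `end`,
#'   `start_window`, `end_window` (0-based genome-window indices),
#'   `first_kept`, `last_kept` (indices into the kept-window vector),
#'   `n_windows`, `cns` (modal state in the run, ties toward lower).
#' @export
extract_raw_cnvs <- function(states, kept_windows, sample_id, sex = "F",
                             min_windows = 5) {
  stopifnot(length(states) == nrow(kept_windows))
  empty <- data.frame(sample_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      start_window = integer(), end_window = integer(),
                      first_kept = integer(), last_kept = integer(),
                      n_windows = integer(), cns = integer(),
                      stringsAsFactors = FALSE)
  if (length(states) == 0) return(empty)
  chrom <- unique(kept_windows$chrom)
  if (length(chrom) != 1L) stop("extract_raw_cnvs works on one chromosome at a time")
  baseline <- if (chrom == "X" && sex == "M") 1L else 2L
  r <- rle(states > baseline)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- which(r$values & r$lengths >= min_windows)
  if (!length(sel)) return(empty)
  do.call(rbind, lapply(sel, function(j) {
    i1 <- starts[j]; i2 <- ends[j]
    data.frame(sample_id = sample_id, chrom = chrom,
               start = kept_windows$start[i1], end = kept_windows$end[i2],
               start_window = kept_windows$window[i1],
               end_window = kept_windows$window[i2],
               first_kept = i1, last_kept = i2,
               n_windows = i2 - i1 + 1L,
               cns = int_mode(states[i1:i2]),
               stringsAsFactors = FALSE)
  }))
}

# Log-likelihood of coverage x under a given state path (Gaussian emissions).
path_loglik <- function(x, states, params) {
  mu <- params$means[states + 1L]
  sd <- sqrt(params$vars[states + 1L])
  sum(dnorm(x, mu, sd, log = TRUE))
}

#' Likelihood-ratio filter for raw CNV calls
#'
#' Compares the likelihood of the coverage within a call under the
#' HMM-predicted state path against a null of constant baseline copy number
#' (2 on autosomes, 1 on the male X), in log space. Calls with a ratio below
#' `threshold` are dropped; a ratio of exactly `threshold` is kept.
#'
#' @param calls Raw calls from [extract_raw_cnvs()] (needs `first_kept`,
#'   `last_kept`).
#' @param x Normalized coverage over kept windows of the calls' chromosome.
#' @param states The corresponding state path.
#' @param params [hmm_params()] used for decoding.
#' @param sex Sample sex (null baseline on X).
#' @param threshold Minimum likelihood ratio (default 1000).
#' @return `calls` with columns `log10_lr` and logical `lr_pass`.
#' @export
likelihood_ratio_filter <- function(calls, x, states, params, sex = "F",
                                    threshold = 1000) {
  if (!nrow(calls)) {
    calls$log10_lr <- numeric(0)
    calls$lr_pass <- logical(0)
    return(calls)
  }
  baseline <- ifelse(calls$chrom == "X" & sex == "M", 1L, 2L)
  loglr <- vapply(seq_len(nrow(calls)), function(j) {
    idx <- calls$first_kept[j]:calls$last_kept[j]
    path_loglik(x[idx], states[idx], params) -
      path_loglik(x[idx], rep(baseline[j], length(idx)), params)
  }, numeric(1))
  calls$log10_lr <- loglr / log(10)
  calls$lr_pass <- calls$log10_lr >= log10(threshold)
  calls
}

#' Call amplification CNVs in every sample of a cohort
#'
#' Runs, per sample: emission-variance estimation from autosomal kept
#' windows, per-chromosome Viterbi decoding, raw-call extraction and the
#' likelihood-ratio filter.
#'
#' @param cov A `cnv_coverage` object with `$norm` and `$filter` filled (see
#'   [normalize_coverage()], [build_window_filter()]).
#' @param max_state,trans HMM structure (see [hmm_params()]).
#' @param min_windows Minimum call span in kept windows (default 5).
#' @param lr_threshold Likelihood-ratio cutoff (default 1000).
#' @param params Optional fixed [hmm_params()] shared by all samples; by
#'   default parameters are estimated per sample.
#' @return Data frame of calls (all raw calls, with `log10_lr`, `lr_pass`).
#' @export
call_cnvs <- function(cov, max_state = 12, trans = 1e-5, min_windows = 5,
                      lr_threshold = 1000, params = NULL) {
  if (is.null(cov$norm) || is.null(cov$filter)) {
    stop("coverage must be normalized and filtered first")
  }
  win <- cov$windows
  auto <- cov$chromosomes$chrom[cov$chromosomes$is_autosome]
  out <- list()
  for (i in seq_len(nrow(cov$samples))) {
    xs <- cov$norm[i, ]
    kept <- cov$filter$keep & !is.na(xs)
    p <- params %||%
      estimate_hmm_params(xs[kept & win$chrom %in% auto],
                          max_state = max_state, trans = trans)
    for (ch in unique(win$chrom)) {
      idx <- which(kept & win$chrom == ch)
      if (!length(idx)) next
      x <- xs[idx]
      states <- viterbi_cns(x, p)
      calls <- extract_raw_cnvs(states, win[idx, ], cov$samples$sample_id[i],
                                sex = cov$samples$sex[i],
                                min_windows = min_windows)
      if (nrow(calls)) {
        out[[length(out) + 1L]] <-
          likelihood_ratio_filter(calls, x, states, p,
                                  sex = cov$samples$sex[i],
                                  threshold = lr_threshold)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(sample_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      start_window = integer(), end_window = integer(),
                      first_kept = integer(), last_kept = integer(),
                      n_windows = integer(), cns = integer(),
                      log10_lr = numeric(), lr_pass = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' False-call rate under genome-wide coverage shuffling
#'
#' Estimates the false discovery behavior of the caller by permuting each
#' sample's kept-window normalized coverage across the genome (destroying
#' any spatial contiguity while preserving the value distribution) and
#' re-running the full per-sample calling. When a sample manifest is given,
#' shuffled calls are additionally matched across samples and passed through
#' the population-frequency filter to obtain a population-level rate.
#'
#' @param cov Normalized, filtered `cnv_coverage`.
#' @param reps Number of shuffle replicates (>= 1).
#' @param seed Integer seed.
#' @param manifest Optional manifest (`sample_id`, `population`) enabling the
#'   population-level rate.
#' @param ... Passed to [call_cnvs()].
#' @return List with `per_rep` (data frame: replicate, `n_calls`,
#'   `n_variants_pop` when manifest given), `calls_per_sample` (mean
#'   LR-passing calls per sample per replicate) and `variants_per_rep`.
#' @export
shuffle_fdr_simulation <- function(cov, reps, seed = NULL, manifest = NULL, ...) {
  if (!is.numeric(reps) || reps < 1) stop("'reps' must be >= 1")
  if (is.null(cov$norm) || is.null(cov$filter)) {
    stop("coverage must be normalized and filtered first")
  }
  n_samples <- nrow(cov$samples)
  with_seed(seed, {
    per_rep <- lapply(seq_len(reps), function(r) {
      shuf <- cov
      for (i in seq_len(n_samples)) {
        kept <- cov$filter$keep & !is.na(cov$norm[i, ])
        shuf$norm[i, kept] <- sample(cov$norm[i, kept])
      }
      calls <- call_cnvs(shuf, ...)
      calls <- calls[calls$lr_pass, , drop = FALSE]
      nv <- NA_integer_
      if (!is.null(manifest)) {
        if (nrow(calls)) {
          m <- match_cnvs(calls, shuf$window_size)
          pf <- population_frequency_filter(m$variants, m$calls, manifest)
          nv <- sum(pf$keep)
        } else nv <- 0L
      }
      data.frame(rep = r, n_calls = nrow(calls), n_variants_pop = nv)
    })
    per_rep <- do.call(rbind, per_rep)
    list(per_rep = per_rep,
         calls_per_sample = mean(per_rep$n_calls) / n_samples,
         variants_per_rep = if (is.null(manifest)) NA_real_ else
           mean(per_rep$n_variants_pop))
  })
}

#' Recovery rate for planted CNVs of given span and copy number
#'
#' Plants a single CNV of `n_windows_cnv` windows at total copy number
#' `copy_number` into a uniform-GC synthetic autosome, runs the full
#' per-sample pipeline (count simulation, GC normalization, window filter,
#' HMM calling, likelihood-ratio filter) and reports the fraction of
#' replicates in which an LR-passing amplification call overlaps the planted
#' region.
#'
#' @param n_windows_cnv CNV span in windows.
#' @param copy_number Total copy number of the planted region (2 = no gain,
#'   recovery is 0 by construction).
#' @param depth,dispersion Sample mean depth and NB dispersion.
#' @param reps Number of replicates.
#' @param seed Integer seed.
#' @param flank_windows Baseline windows on each side of the plant.
#' @param ... Passed to [call_cnvs()].
#' @return Recovery fraction in `[0, 1]`.
#' @export
sensitivity_simulation <- function(n_windows_cnv, copy_number, depth = 30,
                                   dispersion = 1, reps = 200, seed = NULL,
                                   flank_windows = 120, ...) {
  stopifnot(n_windows_cnv >= 1)
  n_total <- 2 * flank_windows + n_windows_cnv
  with_seed(seed, {
    ref <- simulate_reference(
      seed = sample.int(.Machine$integer.max, 1),
      chrom_lengths = c(chr1 = n_total * 300),
      gc_sd = 0, het_fraction = 0, gene_density = 0,
      inaccessible_fraction = 0.02, high_mq0_fraction = 0.02)
    samples <- data.frame(sample_id = "S001", population = "popA", sex = "F",
                          mean_depth = depth, dispersion = dispersion,
                          stringsAsFactors = FALSE)
    planted <- if (copy_number > 2) {
      data.frame(sample_id = "S001", chrom = "chr1",
                 start_window = flank_windows,
                 end_window = flank_windows + n_windows_cnv - 1L,
                 copies_added = copy_number - 2L, zygosity = 1L,
                 mechanism = "tandem_duplication", allele_id = "plant",
                 stringsAsFactors = FALSE)
    } else NULL
    hits <- vapply(seq_len(reps), function(r) {
      cc <- simulate_window_counts(ref, samples, planted,
                                   seed = sample.int(.Machine$integer.max, 1),
                                   gc_bias_strength = 0)
      cc <- build_window_filter(normalize_coverage(cc))
      calls <- call_cnvs(cc, ...)
      calls <- calls[calls$lr_pass, , drop = FALSE]
      if (is.null(planted) || !nrow(calls)) return(FALSE)
      any(calls$start < (planted$end_window + 1) * 300 &
            calls$end > planted$start_window * 300)
    }, logical(1))
    mean(hits)
  })
}
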