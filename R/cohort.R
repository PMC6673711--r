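#' Sample QC by variance of normalized coverage
#'
#' Samples whose normalized coverage is too erratic produce unreliable CNV
#' calls; any sample whose variance over autosomal kept windows exceeds the
#' threshold fails QC (a variance of exactly the threshold passes).
#'
#' @param cov Normalized, filtered `cnv_coverage`.
#' @param threshold Maximum allowed variance (default 0.2).
#' @return Data frame: `sample_id`, `variance`, `pass`.
#' @export
filter_samples_by_variance <- function(cov, threshold = 0.2) {
  if (is.null(cov$norm) || is.null(cov$filter)) {
    stop("coverage must be normalized and filtered first")
  }
  auto <- cov$chromosomes$chrom[cov$chromosomes$is_autosome]
  sel <- cov$filter$keep & cov$windows$chrom %in% auto
  if (!any(sel)) stop("no autosomal kept windows")
  v <- apply(cov$norm[, sel, drop = FALSE], 1, var, na.rm = TRUE)
  data.frame(sample_id = cov$samples$sample_id, variance = v,
             pass = v <= threshold, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Match per-sample CNV calls into cohort variants
#'
#' Two calls are treated as the same CNV when both breakpoints, as predicted
#' by the copy-number state transitions, are within one window of each other.
#' Matching is greedy and anchor-based: calls are sorted by (chrom, start,
#' end, sample); the first call seeds a variant, and each subsequent call
#' joins the earliest-seeded variant on its chromosome whose anchor call has
#' both |start difference| and |end difference| of at most one window,
#' otherwise it seeds a new variant. The variant's consensus start/end are
#' the medians of its member calls' start/ends.
#'
#' @param calls Call data frame with `sample_id`, `chrom`, `start`, `end`,
#'   `start_window`, `end_window` (as from [call_cnvs()]).
#' @param window_size Window size in bp, used when `start_window`/
#'   `end_window` are absent and must be derived from coordinates.
#' @param max_window_dist Maximum breakpoint distance in windows (default 1).
#' @return List with `variants` (data frame: `variant_id`, `chrom`, `start`,
#'   `end`, `n_carriers`) and `calls` (input with a `variant_id` column).
#' @export
match_cnvs <- function(calls, window_size = 300, max_window_dist = 1) {
  if (!nrow(calls)) {
    return(list(variants = data.frame(variant_id = character(),
                                      chrom = character(), start = numeric(),
                                      end = numeric(), n_carriers = integer(),
                                      stringsAsFactors = FALSE),
                calls = cbind(calls, variant_id = character(0))))
  }
  if (is.null(calls$start_window)) {
    calls$start_window <- as.integer(floor(calls$start / window_size))
    calls$end_window <- as.integer(floor((calls$end - 1) / window_size))
  }
  ord <- order(calls$chrom, calls$start, calls$end, calls$sample_id)
  calls <- calls[ord, , drop = FALSE]
  anchor_s <- integer(0); anchor_e <- integer(0); anchor_c <- character(0)
  vid <- integer(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    hit <- which(anchor_c == calls$chrom[i] &
                   abs(anchor_s - calls$start_window[i]) <= max_window_dist &
                   abs(anchor_e - calls$end_window[i]) <= max_window_dist)
    if (length(hit)) {
      vid[i] <- hit[1L]  # earliest anchor wins
    } else {
      anchor_s <- c(anchor_s, calls$start_window[i])
      anchor_e <- c(anchor_e, calls$end_window[i])
      anchor_c <- c(anchor_c, calls$chrom[i])
      vid[i] <- length(anchor_s)
    }
  }
  calls$variant_id <- sprintf("CNV%04d", vid)
  agg <- lapply(split(calls, calls$variant_id), function(d) {
    data.frame(variant_id = d$variant_id[1], chrom = d$chrom[1],
               start = median(d$start), end = median(d$end),
               n_carriers = length(unique(d$sample_id)),
               stringsAsFactors = FALSE)
  })
  variants <- do.call(rbind, agg)
  variants <- variants[order(variants$chrom, variants$start), , drop = FALSE]
  rownames(variants) <- NULL
  list(variants = variants, calls = calls)
}

#' Population-frequency filter for CNV variants
#'
#' Retains a variant if, in at least one population, it is carried by at
#' least 5% of individuals (populations of 40 or more) or by at least three
#' individuals (populations smaller than 40). Population sizes are counted
#' over the supplied (QC-passed) manifest.
#'
#' @param variants Variant table from [match_cnvs()].
#' @param calls Matched calls (with `variant_id`) from [match_cnvs()].
#' @param manifest Data frame `sample_id`, `population` of QC-passed samples.
#' @param min_freq Frequency threshold for large populations (default 0.05).
#' @param small_pop_size Populations below this size use the absolute rule
#'   (default 40).
#' @param min_carriers Absolute carrier threshold for small populations
#'   (default 3).
#' @return `variants` with a logical `keep` column and one carrier-count
#'   column per population (`carriers.<pop>`).
#' @export
population_frequency_filter <- function(variants, calls, manifest,
                                        min_freq = 0.05, small_pop_size = 40,
                                        min_carriers = 3) {
  stopifnot_cols(manifest, c("sample_id", "population"), "'manifest'")
  if (any(!calls$sample_id %in% manifest$sample_id)) {
    stop("calls contain samples absent from the manifest")
  }
  pops <- sort(unique(manifest$population))
  pop_size <- table(factor(manifest$population, levels = pops))
  carr <- matrix(0L, nrow(variants), length(pops),
                 dimnames = list(variants$variant_id, pops))
  u <- unique(calls[, c("variant_id", "sample_id")])
  u$population <- manifest$population[match(u$sample_id, manifest$sample_id)]
  tab <- table(factor(u$variant_id, levels = variants$variant_id),
               factor(u$population, levels = pops))
  carr[] <- as.integer(tab)
  keep <- rep(FALSE, nrow(variants))
  for (p in seq_along(pops)) {
    n <- as.integer(pop_size[p])
    ok <- if (n >= small_pop_size) carr[, p] / n >= min_freq
          else carr[, p] >= min_carriers
    keep <- keep | ok
  }
  variants$keep <- keep
  for (p in pops) variants[[paste0("carriers.", p)]] <- carr[, p]
  variants
}
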