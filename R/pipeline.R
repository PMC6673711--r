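#' Run the cohort CNV discovery pipeline
#'
#' Convenience wrapper chaining the discovery stages on a raw-count cohort:
#' GC normalization, window filtering, sample variance QC, per-sample
#' Gaussian-HMM calling with the likelihood-ratio filter, cross-sample
#' matching into variants, and the population-frequency filter.
#'
#' @param cov A `cnv_coverage` object (raw counts are enough; normalization
#'   and filtering are applied if absent).
#' @param variance_threshold Sample QC threshold (default 0.2).
#' @param lr_threshold Likelihood-ratio cutoff (default 1000).
#' @param min_windows Minimum call span in kept windows (default 5).
#' @param ... Further arguments to [call_cnvs()].
#' @return List: `qc` (sample QC report), `calls` (LR-passing calls from
#'   QC-passed samples, with `variant_id`), `variants` (matched variants
#'   with population carrier counts and `keep` flag) and `retained`
#'   (variants passing the population-frequency filter).
#' @export
cnv_discovery_pipeline <- function(cov, variance_threshold = 0.2,
                                   lr_threshold = 1000, min_windows = 5, ...) {
  if (is.null(cov$norm)) cov <- normalize_coverage(cov)
  if (is.null(cov$filter)) cov <- build_window_filter(cov)
  qc <- filter_samples_by_variance(cov, threshold = variance_threshold)
  passed <- qc$sample_id[qc$pass]
  sub <- cov
  keep_rows <- cov$samples$sample_id %in% passed
  sub$samples <- cov$samples[keep_rows, , drop = FALSE]
  sub$counts <- cov$counts[keep_rows, , drop = FALSE]
  sub$norm <- cov$norm[keep_rows, , drop = FALSE]
  calls <- call_cnvs(sub, min_windows = min_windows,
                     lr_threshold = lr_threshold, ...)
  calls <- calls[calls$lr_pass, , drop = FALSE]
  matched <- match_cnvs(calls, cov$window_size)
  manifest <- sub$samples[, c("sample_id", "population")]
  variants <- population_frequency_filter(matched$variants, matched$calls,
                                          manifest)
  list(qc = qc, calls = matched$calls, variants = variants,
       retained = variants[variants$keep, , drop = FALSE])
}
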