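#' Simulate haplotypes with a CNV allele riding a swept core haplotype
#'
#' Wild-type haplotypes are exchangeable draws from per-site allele
#' frequencies. Haplotypes carrying the CNV allele share a single core
#' haplotype: each carrier copies the core over the CNV region and outward
#' on both sides up to an exponentially distributed breakpoint distance with
#' mean `core_identity_length` (modeling recombination off the swept
#' background), with sites mutated independently at `mutation_rate`; beyond
#' the breakpoints the carrier reverts to its own background draw. With
#' `mutation_rate = 0` and `core_identity_length = Inf` all carriers are
#' identical.
#'
#' @param n_haplotypes,n_snps Matrix dimensions.
#' @param sweep_frequency Frequency of the CNV (carrier) allele in `[0, 1]`.
#' @param core_identity_length Mean one-sided extent of core identity (bp).
#' @param mutation_rate Per-site flip probability on the copied core.
#' @param region_length Total span of simulated positions (bp).
#' @param cnv_region Length-2 start/end of the CNV-containing region
#'   (default a central 30-kb segment); its variants are masked in the
#'   selection scans.
#' @param allele_id Core label given to carriers (default `"Dup1"`).
#' @param accessible_fraction Fraction of variants flagged accessible.
#' @param seed Integer seed.
#' @return Object of class `haplotype_set`: list with `hap` (haplotypes x
#'   variants 0/1 matrix), `positions`, `accessible`, `core` (per-haplotype
#'   `"WT"`/`allele_id`), `cnv_region` and `sample_id` (haplotypes paired
#'   into diploid samples when `n_haplotypes` is even).
#' @export
simulate_swept_haplotypes <- function(n_haplotypes = 100, n_snps = 400,
                                      sweep_frequency = 0.3,
                                      core_identity_length = 3e5,
                                      mutation_rate = 0.01,
                                      region_length = 2e6,
                                      cnv_region = NULL,
                                      allele_id = "Dup1",
                                      accessible_fraction = 1,
                                      seed = NULL) {
  if (sweep_frequency < 0 || sweep_frequency > 1) {
    stop("'sweep_frequency' must be in [0, 1]")
  }
  cnv_region <- cnv_region %||%
    c(region_length / 2 - 15000, region_length / 2 + 15000)
  with_seed(seed, {
    positions <- sort(sample.int(region_length, n_snps))
    p <- runif(n_snps, 0.1, 0.9)
    hap <- matrix(rbinom(n_haplotypes * n_snps, 1, rep(p, each = n_haplotypes)),
                  n_haplotypes, n_snps)
    core <- rep("WT", n_haplotypes)
    n_car <- round(sweep_frequency * n_haplotypes)
    if (n_car > 0) {
      carriers <- sample.int(n_haplotypes, n_car)
      core[carriers] <- allele_id
      core_hap <- rbinom(n_snps, 1, p)
      for (i in carriers) {
        bl <- if (is.finite(core_identity_length)) {
          rexp(1, 1 / core_identity_length)
        } else Inf
        br <- if (is.finite(core_identity_length)) {
          rexp(1, 1 / core_identity_length)
        } else Inf
        sel <- positions >= cnv_region[1] - bl & positions <= cnv_region[2] + br
        hap[i, sel] <- core_hap[sel]
        if (mutation_rate > 0) {
          flip <- sel & runif(n_snps) < mutation_rate
          hap[i, flip] <- 1L - hap[i, flip]
        }
      }
    }
    accessible <- runif(n_snps) < accessible_fraction
    sample_id <- if (n_haplotypes %% 2 == 0) {
      rep(sprintf("S%03d", seq_len(n_haplotypes / 2)), each = 2)
    } else NULL
    structure(list(hap = hap, positions = positions, accessible = accessible,
                   core = core, cnv_region = cnv_region,
                   sample_id = sample_id),
              class = "haplotype_set")
  })
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("<haplotype_set>", nrow(x$hap), "haplotypes x", ncol(x$hap),
      "variants;", sum(x$core != "WT"), "CNV-carrier haplotype(s)\n")
  invisible(x)
}
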