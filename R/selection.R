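## Haplotype-based selection scans: EHH decay around a CNV-containing
## region, pairwise shared haplotype lengths with bootstrap CIs, haplotype
## clustering and CNV-cluster association.

# Sites on one side of the CNV region, ordered by increasing distance from
# the region edge; variants inside the region are masked out.
side_sites <- function(positions, cnv_region, side, max_distance = Inf) {
  if (side == "right") {
    idx <- which(positions >= cnv_region[2] &
                   positions - cnv_region[2] <= max_distance)
    idx[order(positions[idx])]
  } else {
    idx <- which(positions < cnv_region[1] &
                   cnv_region[1] - positions <= max_distance)
    idx[order(positions[idx], decreasing = TRUE)]
  }
}

side_distance <- function(positions, cnv_region, side) {
  if (side == "right") positions - cnv_region[2] else cnv_region[1] - positions
}

#' Extended haplotype homozygosity around a CNV region
#'
#' For the haplotypes carrying a given core allele, EHH at distance x from
#' the edge of the CNV-containing region is the fraction of unordered
#' haplotype pairs that are identical at every included variant from the
#' edge out to x. Variants inside the CNV region are excluded. EHH is 1 at
#' distance 0 and non-increasing with distance; it is computed independently
#' to the left and to the right of the region.
#'
#' @param hap Haplotype matrix (haplotypes x variants, 0/1).
#' @param positions Variant positions (bp), strictly increasing.
#' @param core Per-haplotype core labels (e.g. `"WT"` or an allele id).
#' @param core_label Label selecting the haplotypes to analyze.
#' @param cnv_region Length-2 numeric, start/end of the CNV-containing
#'   region whose variants are masked.
#' @param max_distance Maximum distance from the region edge (default Inf).
#' @return List with data frames `left` and `right`, each with columns
#'   `distance` and `ehh` (first row is distance 0, EHH 1).
#' @export
compute_ehh <- function(hap, positions, core, core_label, cnv_region,
                        max_distance = Inf) {
  sel <- which(core == core_label)
  if (length(sel) < 2) stop("need at least 2 haplotypes with the core label")
  h <- hap[sel, , drop = FALSE]
  n <- nrow(h)
  npairs <- n * (n - 1) / 2
  one_side <- function(side) {
    sites <- side_sites(positions, cnv_region, side, max_distance)
    ehh <- numeric(length(sites))
    grp <- rep(1L, n)
    for (j in seq_along(sites)) {
      grp <- as.integer(factor(paste(grp, h[, sites[j]])))
      cnt <- tabulate(grp)
      ehh[j] <- sum(cnt * (cnt - 1) / 2) / npairs
    }
    data.frame(distance = c(0, side_distance(positions[sites], cnv_region, side)),
               ehh = c(1, ehh))
  }
  list(left = one_side("left"), right = one_side("right"))
}

#' Pairwise shared haplotype lengths around a CNV region
#'
#' For every unordered pair of haplotypes carrying the core label, extends
#' outward from each side of the CNV region to the first variant at which
#' the pair differs; the shared length on that side is the distance from the
#' region edge to the last concordant variant (0 when the pair differs at
#' the first variant, the full span of included variants when it never
#' differs). Reports per-side and summed lengths, the median of the summed
#' length, and a percentile bootstrap confidence interval for the median
#' obtained by resampling pairs.
#'
#' @inheritParams compute_ehh
#' @param n_boot Bootstrap resamples for the median CI (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed for the bootstrap.
#' @return List: `lengths` (data frame `i`, `j`, `left`, `right`, `total`),
#'   `median`, `ci` (length-2 vector), `n_boot`.
#' @export
shared_haplotype_lengths <- function(hap, positions, core, core_label,
                                     cnv_region, n_boot = 1000, conf = 0.95,
                                     seed = NULL) {
  sel <- which(core == core_label)
  if (length(sel) < 2) stop("need at least 2 haplotypes with the core label")
  h <- hap[sel, , drop = FALSE]
  n <- nrow(h)
  sides <- lapply(c(left = "left", right = "right"), function(side) {
    sites <- side_sites(positions, cnv_region, side)
    list(mat = h[, sites, drop = FALSE],
         dist = side_distance(positions[sites], cnv_region, side))
  })
  pair_len <- function(s, i, j) {
    if (!length(s$dist)) return(0)
    mism <- which(s$mat[i, ] != s$mat[j, ])
    if (!length(mism)) return(s$dist[length(s$dist)])
    if (mism[1] == 1L) return(0)
    s$dist[mism[1] - 1L]
  }
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  lens <- data.frame(
    i = sel[pairs[, 1]], j = sel[pairs[, 2]],
    left = apply(pairs, 1, function(p) pair_len(sides$left, p[1], p[2])),
    right = apply(pairs, 1, function(p) pair_len(sides$right, p[1], p[2])))
  lens$total <- lens$left + lens$right
  med <- median(lens$total)
  ci <- with_seed(seed, {
    boots <- vapply(seq_len(n_boot), function(b) {
      median(sample(lens$total, nrow(lens), replace = TRUE))
    }, numeric(1))
    quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  })
  list(lengths = lens, median = med, ci = ci, n_boot = n_boot)
}

#' Hierarchical clustering of haplotypes
#'
#' Computes a distance matrix as the proportion of accessible variants at
#' which two haplotypes differ (over the first `n_variants` accessible
#' variants), performs agglomerative hierarchical clustering and cuts the
#' tree at `cutoff`. Clusters are labeled 1, 2, ... by decreasing size (ties
#' by first occurrence).
#'
#' @param hap Haplotype matrix (haplotypes x variants, 0/1).
#' @param accessible Logical per-variant accessibility flags (default all).
#' @param n_variants Number of leading accessible variants to use (default
#'   1000).
#' @param cutoff Tree cut height on the distance scale (default 0.001).
#' @param method Linkage method (default `"complete"`, which guarantees the
#'   maximum within-cluster distance does not exceed the cutoff).
#' @return Integer vector of cluster labels, one per haplotype.
#' @export
cluster_haplotypes <- function(hap, accessible = NULL, n_variants = 1000,
                               cutoff = 0.001, method = "complete") {
  if (nrow(hap) < 2) stop("need at least 2 haplotypes")
  accessible <- accessible %||% rep(TRUE, ncol(hap))
  use <- which(accessible)
  if (!length(use)) stop("no accessible variants")
  use <- use[seq_len(min(n_variants, length(use)))]
  d <- dist(hap[, use, drop = FALSE], method = "manhattan") / length(use)
  cl <- cutree(hclust(d, method = method), h = cutoff)
  sizes <- table(cl)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relabel <- integer(length(sizes))
  relabel[as.integer(names(sizes)[ord])] <- seq_along(ord)
  relabel[cl]
}

#' Association between a haplotype cluster and a CNV allele
#'
#' In females (two X haplotypes), tests the association between the number
#' of cluster haplotypes a sample carries (0-2) and its CNV allele copy
#' number by Spearman rank correlation, also reporting the least-squares
#' slope of cluster count on copy number (a slope of 0.5 is the geometry
#' expected when every allele copy rides one cluster haplotype and copy
#' number is twice the cluster count). In males (one X haplotype), tests
#' cluster presence against
#' allele presence by Fisher's exact test.
#'
#' @param samples Data frame with `sample_id`, `sex`, `cluster_count`
#'   (haplotypes in the focal cluster) and `copy_number`.
#' @return List with elements `female` (`rho`, `p_value`, `slope`, `n`) and
#'   `male` (`table`, `p_value`, `n`); an element is `NULL` when that sex is
#'   absent.
#' @export
associate_cluster_with_cnv <- function(samples) {
  stopifnot_cols(samples, c("sex", "cluster_count", "copy_number"),
                 "'samples'")
  out <- list(female = NULL, male = NULL)
  f <- samples[samples$sex == "F", , drop = FALSE]
  if (nrow(f) >= 3) {
    ct <- suppressWarnings(
      cor.test(f$cluster_count, f$copy_number, method = "spearman"))
    slope <- if (var(f$copy_number) > 0) {
      unname(coef(lm(cluster_count ~ copy_number, data = f))[2])
    } else NA_real_
    out$female <- list(rho = unname(ct$estimate), p_value = ct$p.value,
                       slope = slope, n = nrow(f))
  }
  m <- samples[samples$sex == "M", , drop = FALSE]
  if (nrow(m) >= 2) {
    tab <- table(factor(m$cluster_count > 0, levels = c(FALSE, TRUE)),
                 factor(m$copy_number > 0, levels = c(FALSE, TRUE)))
    ft <- fisher.test(tab)
    out$male <- list(table = tab, p_value = ft$p.value, n = nrow(m))
  }
  out
}
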