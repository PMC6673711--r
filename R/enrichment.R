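## Permutation nulls for CNV placement and gene identity, plus the
## chromatin-class size comparison.

granges_from <- function(df) {
  # internal 0-based half-open intervals -> 1-based closed GRanges
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

#' Classify CNVs by chromatin type
#'
#' A CNV is heterochromatic if any part of it (a single bp suffices)
#' overlaps a heterochromatin interval; otherwise euchromatic.
#'
#' @param variants Data frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param het Heterochromatin intervals, same conventions.
#' @return Character vector `"heterochromatic"` / `"euchromatic"`.
#' @export
classify_chromatin <- function(variants, het) {
  if (!nrow(variants)) return(character(0))
  if (!nrow(het)) return(rep("euchromatic", nrow(variants)))
  ov <- IRanges::overlapsAny(granges_from(variants), granges_from(het))
  ifelse(ov, "heterochromatic", "euchromatic")
}

# Monte-Carlo enrichment result with the two-tailed "at least as extreme"
# convention: p = 2 * #(null >= observed) / n_sims, capped at 1; when no
# null draw reaches the observed value the p-value is the bound 2 / n_sims
# and is flagged as an upper bound ("p < 2/n_sims").
enrichment_result <- function(observed, null) {
  n <- length(null)
  cnt <- sum(null >= observed)
  structure(list(observed = observed, null = null, n_sims = n,
                 null_min = min(null), null_max = max(null),
                 null_mean = mean(null),
                 p_value = if (cnt == 0) 2 / n else min(1, 2 * cnt / n),
                 p_is_upper_bound = cnt == 0),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> observed = %g; null over %d sims: %g-%g (mean %.2f); p %s%g\n",
              x$observed, x$n_sims, x$null_min, x$null_max, x$null_mean,
              if (x$p_is_upper_bound) "< " else "= ", x$p_value))
  invisible(x)
}

# Per-gene window statistics used by the copy rules: how many windows
# overlap the gene, how many of those are kept, and the genomic span of the
# kept ones (plus their contiguous range in kept-window index space, used by
# the placement null).
gene_window_stats <- function(genes, windows, keep) {
  kept_rank <- cumsum(keep)  # rank of each kept window within its own order
  out <- genes
  out$n_overlap <- 0L; out$n_kept <- 0L
  out$kept_start <- NA_real_; out$kept_end <- NA_real_
  out$kept_first <- NA_integer_; out$kept_last <- NA_integer_
  for (i in seq_len(nrow(genes))) {
    ov <- which(windows$chrom == genes$chrom[i] &
                  windows$start < genes$end[i] & windows$end > genes$start[i])
    out$n_overlap[i] <- length(ov)
    kw <- ov[keep[ov]]
    out$n_kept[i] <- length(kw)
    if (length(kw)) {
      out$kept_start[i] <- windows$start[kw[1]]
      out$kept_end[i] <- windows$end[kw[length(kw)]]
      out$kept_first[i] <- kept_rank[kw[1]]
      out$kept_last[i] <- kept_rank[kw[length(kw)]]
    }
  }
  out$retained <- out$n_overlap > 0 & out$n_kept / pmax(out$n_overlap, 1) >= 0.5
  out
}

#' Genes copied by CNV variants
#'
#' A gene is retained for analysis if at least 50% of the windows it
#' overlaps are kept windows; a retained gene is "copied" by a CNV if all of
#' its kept windows lie inside the CNV (a retained gene whose only kept
#' windows are inside the CNV counts as copied even if dropped windows
#' extend beyond it).
#'
#' @param variants Variant table (`variant_id`, `chrom`, `start`, `end`).
#' @param genes Gene models (`gene_id`, `chrom`, `start`, `end`, optionally
#'   `detox`).
#' @param windows Window track; `keep` logical kept-window flags.
#' @return List: `genes` (with `retained` and window statistics) and
#'   `copies` (data frame `variant_id`, `gene_id`, one row per copied gene).
#' @export
gene_copy_table <- function(variants, genes, windows, keep) {
  gs <- gene_window_stats(genes, windows, keep)
  rows <- list()
  ret <- gs[gs$retained, , drop = FALSE]
  for (v in seq_len(nrow(variants))) {
    hit <- ret$chrom == variants$chrom[v] &
      ret$kept_start >= variants$start[v] & ret$kept_end <= variants$end[v]
    if (any(hit)) {
      rows[[length(rows) + 1L]] <- data.frame(
        variant_id = variants$variant_id[v], gene_id = ret$gene_id[hit],
        stringsAsFactors = FALSE)
    }
  }
  copies <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variant_id = character(), gene_id = character(),
               stringsAsFactors = FALSE)
  list(genes = gs, copies = copies)
}

#' Placement permutation null for chromatin and gene content
#'
#' Randomly reallocates the start position of every CNV within its
#' chromosome, keeping the number of kept windows it covers unchanged: each
#' simulated placement spans a run of the same number of kept windows,
#' chosen uniformly among all admissible runs. Per simulation the number of
#' CNVs overlapping heterochromatin and (when genes are supplied) the number
#' containing at least one retained gene are recorded, giving two-tailed
#' Monte-Carlo p-values for the observed counts. With
#' `euchromatin_only = TRUE`, placements overlapping heterochromatin are
#' excluded from the admissible set (used to test genic enrichment within
#' the euchromatin using only euchromatic CNVs).
#'
#' @param variants Variant table (`variant_id`, `chrom`, `start`, `end`).
#' @param windows Window track data frame; `keep` logical flags.
#' @param het Heterochromatin intervals.
#' @param genes Optional gene models.
#' @param n_sims Number of simulations (default 10000).
#' @param seed Integer seed.
#' @param euchromatin_only Restrict placements to heterochromatin-free runs.
#' @return List of [enrichment_result] objects: `het` (and `genic` when
#'   genes are supplied).
#' @export
simulate_position_null <- function(variants, windows, keep, het, genes = NULL,
                                   n_sims = 10000, seed = NULL,
                                   euchromatin_only = FALSE) {
  if (!nrow(variants)) stop("no variants supplied")
  chroms <- unique(windows$chrom)
  kept_by_chrom <- lapply(setNames(chroms, chroms), function(ch) {
    idx <- which(windows$chrom == ch & keep)
    list(start = windows$start[idx], end = windows$end[idx], n = length(idx))
  })
  gs <- if (!is.null(genes)) gene_window_stats(genes, windows, keep) else NULL

  # number of kept windows covered by each observed variant
  kcov <- vapply(seq_len(nrow(variants)), function(v) {
    kb <- kept_by_chrom[[variants$chrom[v]]]
    sum(kb$start < variants$end[v] & kb$end > variants$start[v])
  }, numeric(1))
  if (any(kcov == 0)) {
    stop("variant covers no kept windows: ",
         variants$variant_id[which(kcov == 0)[1]])
  }

  # per-variant admissible placements with their het/genic status
  placements <- lapply(seq_len(nrow(variants)), function(v) {
    ch <- variants$chrom[v]; k <- kcov[v]
    kb <- kept_by_chrom[[ch]]
    ns <- kb$n - k + 1
    if (ns < 1) stop("variant spans more kept windows than available: ",
                     variants$variant_id[v])
    span_start <- kb$start[seq_len(ns)]
    span_end <- kb$end[seq_len(ns) + k - 1]
    het_ch <- het[het$chrom == ch, , drop = FALSE]
    het_ov <- if (nrow(het_ch)) {
      IRanges::overlapsAny(
        IRanges::IRanges(span_start + 1, span_end),
        IRanges::IRanges(het_ch$start + 1, het_ch$end))
    } else rep(FALSE, ns)
    genic <- rep(FALSE, ns)
    if (!is.null(gs)) {
      g <- gs[gs$retained & gs$chrom == ch, , drop = FALSE]
      # kept-index rank within this chromosome
      offset <- if (nrow(g)) {
        min(cumsum(keep)[windows$chrom == ch & keep]) - 1L
      } else 0L
      for (j in seq_len(nrow(g))) {
        a <- g$kept_first[j] - offset; b <- g$kept_last[j] - offset
        if (b - a + 1 > k) next
        lo <- max(1, b - k + 1); hi <- min(a, ns)
        if (lo <= hi) genic[lo:hi] <- TRUE
      }
    }
    if (euchromatin_only) {
      adm <- which(!het_ov)
      if (!length(adm)) stop("no euchromatic placement fits variant: ",
                             variants$variant_id[v])
      list(het = het_ov[adm], genic = genic[adm], n = length(adm))
    } else {
      list(het = het_ov, genic = genic, n = ns)
    }
  })

  with_seed(seed, {
    het_counts <- integer(n_sims)
    genic_counts <- integer(n_sims)
    for (p in placements) {
      s <- sample.int(p$n, n_sims, replace = TRUE)
      het_counts <- het_counts + p$het[s]
      genic_counts <- genic_counts + p$genic[s]
    }
    obs_het <- sum(classify_chromatin(variants, het) == "heterochromatic")
    out <- list(het = enrichment_result(obs_het, het_counts))
    if (!is.null(genes)) {
      obs_genic <- length(unique(
        gene_copy_table(variants, genes, windows, keep)$copies$variant_id))
      out$genic <- enrichment_result(obs_genic, genic_counts)
    }
    out
  })
}

#' Gene-identity permutation null for detox-gene content
#'
#' Each genic CNV covers a run of consecutive retained genes; per
#' simulation every CNV is reassigned a uniformly random run of the same
#' number of consecutive genes (runs never cross a chromosome boundary) and
#' the number of CNVs containing at least one metabolic detox gene is
#' counted. A CNV counts once no matter how many detox genes it covers.
#'
#' @param gene_copies Data frame `variant_id`, `gene_id` (as from
#'   [gene_copy_table()]`$copies`) for the genic CNVs.
#' @param genes Retained genes in genomic order: `gene_id`, `chrom`,
#'   `detox`.
#' @param n_sims Number of simulations (default 10000).
#' @param seed Integer seed.
#' @return An [enrichment_result] for the detox-containing CNV count.
#' @export
simulate_gene_identity_null <- function(gene_copies, genes, n_sims = 10000,
                                        seed = NULL) {
  if (!nrow(gene_copies)) stop("no genic variants supplied")
  detox <- genes$detox
  k_per_variant <- table(gene_copies$variant_id)
  obs <- sum(vapply(split(gene_copies$gene_id, gene_copies$variant_id),
                    function(g) any(detox[match(g, genes$gene_id)]),
                    logical(1)))
  # admissible runs of length k, concatenated across chromosomes
  run_hits <- function(k) {
    unlist(lapply(split(detox, genes$chrom), function(d) {
      n <- length(d)
      if (n < k) return(logical(0))
      cs <- cumsum(c(0, d))
      (cs[(k + 1):(n + 1)] - cs[1:(n - k + 1)]) > 0
    }), use.names = FALSE)
  }
  ks <- sort(unique(as.integer(k_per_variant)))
  hits_by_k <- lapply(setNames(ks, ks), run_hits)
  if (any(vapply(hits_by_k, length, integer(1)) == 0)) {
    stop("a variant covers more consecutive genes than any chromosome holds")
  }
  with_seed(seed, {
    counts <- integer(n_sims)
    for (k in as.integer(k_per_variant)) {
      h <- hits_by_k[[as.character(k)]]
      counts <- counts + h[sample.int(length(h), n_sims, replace = TRUE)]
    }
    enrichment_result(obs, counts)
  })
}

#' Compare CNV sizes between chromatin classes
#'
#' Two-sided Wilcoxon rank-sum test on CNV lengths (bp) of heterochromatic
#' versus euchromatic CNVs.
#'
#' @param het_sizes,eu_sizes Numeric vectors of CNV lengths.
#' @return List: `W`, `p_value`, `median_het`, `median_eu`, `n1`, `n2`.
#' @export
compare_cnv_sizes <- function(het_sizes, eu_sizes) {
  if (!length(het_sizes) || !length(eu_sizes)) {
    stop("both groups must be non-empty")
  }
  wt <- wilcox.test(het_sizes, eu_sizes, exact = FALSE)
  list(W = unname(wt$statistic), p_value = wt$p.value,
       median_het = median(het_sizes), median_eu = median(eu_sizes),
       n1 = length(het_sizes), n2 = length(eu_sizes))
}

#' Fisher's exact test with Monte-Carlo fallback for large tables
#'
#' Runs `fisher.test` on a contingency table; when the exact computation is
#' infeasible for the table size, falls back to a simulated p-value with
#' `B` replicates.
#'
#' @param tab Contingency table (matrix).
#' @param B Monte-Carlo replicates for the fallback (default 1e6).
#' @param seed Integer seed for the fallback.
#' @return The `htest` object.
#' @export
contingency_test <- function(tab, B = 1e6, seed = NULL) {
  tryCatch(
    stats::fisher.test(tab),
    error = function(e) {
      with_seed(seed, stats::fisher.test(tab, simulate.p.value = TRUE, B = B))
    }
  )
}
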