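# Independent brute-force oracles and small fixture builders used across the
# test files. Oracles deliberately use naive algorithms (full enumeration,
# per-element loops) so they share no code path with the implementation.

# Exhaustive-enumeration Viterbi: scores every possible state path.
oracle_viterbi <- function(x, params) {
  S <- length(params$means)
  T_ <- length(x)
  stay <- log1p(-(S - 1) * params$trans)
  move <- log(params$trans)
  grid <- as.matrix(expand.grid(rep(list(seq_len(S)), T_)))
  E <- sapply(seq_len(S), function(s) {
    dnorm(x, params$means[s], sqrt(params$vars[s]), log = TRUE)
  })  # T x S
  ll <- numeric(nrow(grid))
  for (t in seq_len(T_)) {
    ll <- ll + E[t, grid[, t]]
    if (t > 1) ll <- ll + ifelse(grid[, t] == grid[, t - 1], stay, move)
  }
  as.integer(grid[which.max(ll), ] - 1L)
}

# Build a minimal cnv_coverage object directly from a normalized matrix.
make_cov <- function(norm, windows, samples, keep = NULL) {
  keep <- if (is.null(keep)) rep(TRUE, nrow(windows)) else keep
  chroms <- data.frame(chrom = unique(windows$chrom),
                       length = NA_real_, stringsAsFactors = FALSE)
  chroms$is_autosome <- chroms$chrom != "X"
  chroms$length <- vapply(chroms$chrom, function(ch) {
    max(windows$end[windows$chrom == ch])
  }, numeric(1))
  structure(list(counts = matrix(0L, nrow(norm), ncol(norm),
                                 dimnames = dimnames(norm)),
                 samples = samples, windows = windows, chromosomes = chroms,
                 window_size = windows$end[1] - windows$start[1],
                 truth = NULL, norm = norm,
                 filter = data.frame(keep = keep, reason = "")),
            class = "cnv_coverage")
}

tiny_windows <- function(n, chrom = "chr1", w = 300, gc = 45) {
  data.frame(chrom = chrom, window = 0:(n - 1), start = (0:(n - 1)) * w,
             end = (1:n) * w, gc = gc, accessibility = 1, mq0_frac = 0,
             stringsAsFactors = FALSE)
}

tiny_samples <- function(ids, sex = "F", depth = 30, dispersion = 1) {
  data.frame(sample_id = ids, population = "popA",
             sex = rep_len(sex, length(ids)),
             mean_depth = depth, dispersion = dispersion,
             stringsAsFactors = FALSE)
}

# All-pairs prefix-comparison EHH.
oracle_ehh <- function(h, positions, region, side) {
  if (side == "right") {
    idx <- which(positions >= region[2])
    idx <- idx[order(positions[idx])]
    d <- positions[idx] - region[2]
  } else {
    idx <- which(positions < region[1])
    idx <- idx[order(positions[idx], decreasing = TRUE)]
    d <- region[1] - positions[idx]
  }
  n <- nrow(h)
  pairs <- utils::combn(n, 2)
  ehh <- vapply(seq_along(idx), function(j) {
    sites <- idx[seq_len(j)]
    conc <- 0
    for (p in seq_len(ncol(pairs))) {
      if (all(h[pairs[1, p], sites] == h[pairs[2, p], sites])) conc <- conc + 1
    }
    conc / ncol(pairs)
  }, numeric(1))
  data.frame(distance = c(0, d), ehh = c(1, ehh))
}

# Per-pair outward scan for shared haplotype lengths (one side).
oracle_shared_side <- function(h, positions, region, side, i, j) {
  if (side == "right") {
    idx <- which(positions >= region[2])
    idx <- idx[order(positions[idx])]
    d <- positions[idx] - region[2]
  } else {
    idx <- which(positions < region[1])
    idx <- idx[order(positions[idx], decreasing = TRUE)]
    d <- region[1] - positions[idx]
  }
  len <- 0
  for (k in seq_along(idx)) {
    if (h[i, idx[k]] != h[j, idx[k]]) return(len)
    len <- d[k]
  }
  len
}

# Independent greedy matcher: repeatedly scans the sorted call list and
# builds variants one anchor at a time (different loop structure from the
# package's incremental-anchor implementation).
oracle_match <- function(calls) {
  calls <- calls[order(calls$chrom, calls$start, calls$end, calls$sample_id), ]
  assigned <- rep(NA_integer_, nrow(calls))
  vid <- 0L
  anchors <- list()
  for (i in seq_len(nrow(calls))) {
    found <- NA_integer_
    for (a in seq_along(anchors)) {
      an <- anchors[[a]]
      if (an$chrom == calls$chrom[i] &&
          abs(an$s - calls$start_window[i]) <= 1 &&
          abs(an$e - calls$end_window[i]) <= 1) { found <- a; break }
    }
    if (is.na(found)) {
      vid <- vid + 1L
      anchors[[vid]] <- list(chrom = calls$chrom[i],
                             s = calls$start_window[i],
                             e = calls$end_window[i])
      found <- vid
    }
    assigned[i] <- found
  }
  split(paste(calls$sample_id, calls$chrom, calls$start, calls$end), assigned)
}

# Monte-Carlo oracle for the exact HWE test: draws random pairings of the
# observed alleles and uses the empirical conditional distribution of the
# heterozygote count.
oracle_hwe_mc <- function(n_hom_ref, n_het, n_hom_alt, reps = 20000) {
  n <- n_hom_ref + n_het + n_hom_alt
  alleles <- c(rep(0, 2 * n_hom_ref + n_het), rep(1, n_het + 2 * n_hom_alt))
  hets <- vapply(seq_len(reps), function(r) {
    a <- sample(alleles)
    sum(a[seq(1, 2 * n, 2)] != a[seq(2, 2 * n, 2)])
  }, numeric(1))
  tab <- table(hets) / reps
  p_obs <- tab[as.character(n_het)]
  if (is.na(p_obs)) p_obs <- 0
  sum(tab[tab <= p_obs + 1e-12])
}
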