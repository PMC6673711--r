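## CNV allele typing from discordant read pairs and breakpoint soft-clips,
## allele-specific copy number, genotyping and Hardy-Weinberg filtering.

#' Classify read pairs by mapping pattern
#'
#' Assigns each pair to one of the diagnostic categories used to recognize
#' CNV alleles: `face_away` (mates on the same chromosome aligning outward,
#' the pattern of a tandem duplication junction), `same_orientation` (both
#' mates on the same strand, the pattern of a tandem inversion),
#' `long_insert` (properly oriented but with an implied insert size far
#' above expectation, the pattern of a deletion inside an amplification),
#' `crossmapped` (mates on different chromosomes) or `proper`.
#'
#' @param pairs Data frame with columns `chrom1`, `pos1`, `strand1`,
#'   `chrom2`, `pos2`, `strand2` and optionally `insert` (implied insert
#'   size in bp; reconstructed as `abs(pos2 - pos1) + read_length` when
#'   absent).
#' @param insert_mean,insert_sd Insert-size model of the library.
#' @param z Number of SDs above the mean defining `long_insert` (default 5).
#' @param read_length Read length for insert reconstruction (default 100).
#' @return Character vector of categories, one per pair.
#' @export
classify_read_pairs <- function(pairs, insert_mean, insert_sd, z = 5,
                                read_length = 100) {
  stopifnot_cols(pairs, c("chrom1", "pos1", "strand1", "chrom2", "pos2",
                          "strand2"), "'pairs'")
  if (!all(c(pairs$strand1, pairs$strand2) %in% c("+", "-"))) {
    stop("strands must be '+' or '-'")
  }
  n <- nrow(pairs)
  insert <- pairs$insert %||% (abs(pairs$pos2 - pairs$pos1) + read_length)
  left_strand <- ifelse(pairs$pos1 <= pairs$pos2, pairs$strand1, pairs$strand2)
  out <- rep("proper", n)
  out[insert > insert_mean + z * insert_sd] <- "long_insert"
  out[left_strand == "-"] <- "face_away"
  out[pairs$strand1 == pairs$strand2] <- "same_orientation"
  out[pairs$chrom1 != pairs$chrom2] <- "crossmapped"
  out
}

#' Call CNV allele presence from diagnostic reads
#'
#' A read pair supports a signature when its classified category matches the
#' signature's expected pattern and both mates fall within the signature's
#' anchor windows; a soft-clipped read supports a `breakpoint_clip`
#' signature when its clip position falls within either anchor's tolerance.
#' An allele is recorded as present in a sample when it has at least
#' `min_reads` supporting diagnostic reads.
#'
#' @param pairs Read-pair records (`sample_id` plus the columns of
#'   [classify_read_pairs()]); may be `NULL`.
#' @param clips Soft-clip records (`sample_id`, `chrom`, `pos`, `side`,
#'   `seq`); may be `NULL`.
#' @param signatures Signature registry: `allele_id`, `chrom`, `type`
#'   (one of face_away, same_orientation, long_insert, crossmapped,
#'   breakpoint_clip), `anchor1`, `anchor2`, `tol` (bp).
#' @param samples Character vector of all sample ids to report (samples with
#'   no reads get `present = FALSE`).
#' @param min_reads Minimum supporting reads (default 2).
#' @param insert_mean,insert_sd,z,read_length Passed to
#'   [classify_read_pairs()].
#' @return Data frame: `sample_id`, `allele_id`, `n_support`, `present`.
#' @export
call_alleles <- function(pairs, clips, signatures, samples,
                         min_reads = 2, insert_mean = 400, insert_sd = 50,
                         z = 5, read_length = 100) {
  stopifnot_cols(signatures, c("allele_id", "chrom", "type", "anchor1",
                               "anchor2", "tol"), "'signatures'")
  if (!is.null(pairs) && nrow(pairs)) {
    pairs$category <- classify_read_pairs(pairs, insert_mean, insert_sd,
                                          z = z, read_length = read_length)
  }
  out <- expand.grid(sample_id = samples,
                     allele_id = unique(signatures$allele_id),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$n_support <- 0L
  for (i in seq_len(nrow(signatures))) {
    sig <- signatures[i, ]
    lo <- pmin(sig$anchor1, sig$anchor2)
    hi <- pmax(sig$anchor1, sig$anchor2)
    if (sig$type == "breakpoint_clip") {
      if (is.null(clips) || !nrow(clips)) next
      hit <- clips$chrom == sig$chrom &
        (abs(clips$pos - sig$anchor1) <= sig$tol |
           abs(clips$pos - sig$anchor2) <= sig$tol)
      support <- table(clips$sample_id[hit])
    } else {
      if (is.null(pairs) || !nrow(pairs)) next
      p1 <- pmin(pairs$pos1, pairs$pos2)
      p2 <- pmax(pairs$pos1, pairs$pos2)
      hit <- pairs$category == sig$type & pairs$chrom1 == sig$chrom &
        abs(p1 - lo) <= sig$tol & abs(p2 - hi) <= sig$tol
      support <- table(pairs$sample_id[hit])
    }
    if (!length(support)) next
    sel <- out$allele_id == sig$allele_id
    add <- as.integer(support[match(out$sample_id[sel], names(support))])
    add[is.na(add)] <- 0L
    out$n_support[sel] <- out$n_support[sel] + add
  }
  out$present <- out$n_support >= min_reads
  out
}

#' Allele-specific copy numbers from coverage steps
#'
#' Models a sample's normalized coverage over the kept windows of a locus as
#' a baseline (2 on autosomes, 1 on the male X) plus, for every CNV allele
#' the sample carries, a constant gain over that allele's span, and solves
#' for the per-allele gains by non-negative least squares. Gains are rounded
#' to integers (half up), with one cohort-level exception: if exactly one
#' sample in the whole cohort reaches an estimate of 2.5 or more for an
#' allele, that estimate is assumed to be an error, recorded as 2 and
#' flagged (`ROUNDED_25_TO_2`). Samples in which two present alleles cover
#' identical kept-window sets are non-identifiable and get `NA` with flag
#' `NON_IDENTIFIABLE`.
#'
#' @param cov Normalized, filtered `cnv_coverage`.
#' @param presence Allele presence calls (`sample_id`, `allele_id`,
#'   `present`), as from [call_alleles()].
#' @param spans Allele spans: `allele_id`, `chrom`, `start`, `end`.
#' @return List with matrices `raw` and `copies` (samples x alleles), and
#'   `flags` (data frame `sample_id`, `allele_id`, `flag`).
#' @export
estimate_allele_copy_numbers <- function(cov, presence, spans) {
  stopifnot_cols(spans, c("allele_id", "chrom", "start", "end"), "'spans'")
  alleles <- spans$allele_id
  if (anyDuplicated(alleles)) stop("duplicate allele_id in 'spans'")
  samples <- cov$samples$sample_id
  raw <- matrix(0, length(samples), length(alleles),
                dimnames = list(samples, alleles))
  flags <- list()
  win <- cov$windows
  for (si in seq_along(samples)) {
    pres <- presence$allele_id[presence$sample_id == samples[si] &
                                 presence$present]
    pres <- intersect(alleles, pres)
    if (!length(pres)) next
    sp <- spans[spans$allele_id %in% pres, , drop = FALSE]
    for (ch in unique(sp$chrom)) {
      spc <- sp[sp$chrom == ch, , drop = FALSE]
      lo <- min(spc$start); hi <- max(spc$end)
      idx <- which(win$chrom == ch & cov$filter$keep &
                     !is.na(cov$norm[si, ]) &
                     win$start < hi + 3000 & win$end > lo - 3000)
      if (!length(idx)) next
      X <- vapply(seq_len(nrow(spc)), function(a) {
        as.numeric(win$start[idx] >= spc$start[a] & win$end[idx] <= spc$end[a])
      }, numeric(length(idx)))
      X <- matrix(X, nrow = length(idx))
      baseline <- if (ch == "X" && cov$samples$sex[si] == "M") 1 else 2
      if (ncol(X) > 1 && anyDuplicated(t(X))) {
        for (a in spc$allele_id) {
          flags[[length(flags) + 1L]] <- data.frame(
            sample_id = samples[si], allele_id = a,
            flag = "NON_IDENTIFIABLE", stringsAsFactors = FALSE)
        }
        raw[si, spc$allele_id] <- NA_real_
        next
      }
      y <- cov$norm[si, idx] - baseline
      fit <- pracma::lsqnonneg(X, y)
      raw[si, spc$allele_id] <- fit$x
    }
  }
  copies <- round_half_up(raw)
  # single-sample 2.5 exception, applied per allele across the cohort
  for (a in seq_along(alleles)) {
    high <- which(!is.na(raw[, a]) & raw[, a] >= 2.5)
    if (length(high) == 1L) {
      copies[high, a] <- 2
      flags[[length(flags) + 1L]] <- data.frame(
        sample_id = samples[high], allele_id = alleles[a],
        flag = "ROUNDED_25_TO_2", stringsAsFactors = FALSE)
    }
  }
  flags <- if (length(flags)) do.call(rbind, flags) else
    data.frame(sample_id = character(), allele_id = character(),
               flag = character(), stringsAsFactors = FALSE)
  list(raw = raw, copies = copies, flags = flags)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact conditional test: given the observed allele counts, the
#' p-value is the total probability of heterozygote counts whose conditional
#' probability does not exceed that of the observed count.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts.
#' @return P-value.
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0) return(1)
  n_a <- n_het + 2 * n_hom_alt      # rare-or-not, symmetry makes it moot
  # possible heterozygote counts share parity with the allele count
  hets <- seq(n_a %% 2, min(n_a, 2 * n - n_a), by = 2)
  logp <- vapply(hets, function(h) {
    aa <- (n_a - h) / 2
    rr <- n - h - aa
    lgamma(n + 1) - lgamma(h + 1) - lgamma(aa + 1) - lgamma(rr + 1) +
      h * log(2) + lgamma(n_a + 1) + lgamma(2 * n - n_a + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- which(hets == n_het)
  sum(p[p <= p[obs] * (1 + 1e-9)])
}

#' Genotype CNV alleles and filter by copy-number ceiling and HWE
#'
#' Converts allele-specific copy numbers to genotypes for single-copy
#' alleles: 0 copies = homozygote wild-type, 1 = heterozygote, 2 =
#' homozygote CNV. Alleles with any sample above 2 copies (after the
#' single-sample 2.5 exception) cannot be genotyped (a heterozygous
#' triplication is indistinguishable from a homozygous duplication) and are
#' excluded (`CN_GT2`). When every carrier of an allele has exactly 2
#' copies, the allele is interpreted as a triplication and all carriers are
#' genotyped heterozygous. Alleles whose genotype counts are inconsistent
#' with Hardy-Weinberg expectations (exact test, p < `alpha`) in any
#' population where they occur are excluded (`HWE_FAIL`). Samples are
#' assumed diploid at the locus.
#'
#' @param copies Samples x alleles integer copy matrix (from
#'   [estimate_allele_copy_numbers()]).
#' @param manifest Data frame `sample_id`, `population`.
#' @param alpha HWE significance threshold per population (default 0.05).
#' @return List: `genotypes` (samples x alleles, 0/1/2 or `NA` for excluded
#'   alleles), `excluded` (data frame `allele_id`, `reason`), `hwe` (data
#'   frame `allele_id`, `population`, `p_value`).
#' @export
genotype_alleles <- function(copies, manifest, alpha = 0.05) {
  stopifnot_cols(manifest, c("sample_id", "population"), "'manifest'")
  samples <- rownames(copies)
  pops <- manifest$population[match(samples, manifest$sample_id)]
  geno <- matrix(NA_integer_, nrow(copies), ncol(copies),
                 dimnames = dimnames(copies))
  excluded <- list(); hwe <- list()
  for (a in seq_len(ncol(copies))) {
    cn <- copies[, a]
    aid <- colnames(copies)[a]
    if (anyNA(cn)) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(allele_id = aid, reason = "NON_IDENTIFIABLE")
      next
    }
    if (any(cn > 2)) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(allele_id = aid, reason = "CN_GT2")
      next
    }
    carriers <- cn > 0
    g <- cn
    if (any(carriers) && all(cn[carriers] == 2)) {
      g[carriers] <- 1L  # pure triplication: every carrier is heterozygous
    }
    fail <- FALSE
    for (p in unique(pops[carriers])) {
      gp <- g[pops == p]
      pv <- hwe_exact_test(sum(gp == 0), sum(gp == 1), sum(gp == 2))
      hwe[[length(hwe) + 1L]] <-
        data.frame(allele_id = aid, population = p, p_value = pv)
      if (pv < alpha) fail <- TRUE
    }
    if (fail) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(allele_id = aid, reason = "HWE_FAIL")
      next
    }
    geno[, a] <- g
  }
  bind0 <- function(l, proto) if (length(l)) do.call(rbind, l) else proto
  list(genotypes = geno,
       excluded = bind0(excluded, data.frame(allele_id = character(),
                                             reason = character())),
       hwe = bind0(hwe, data.frame(allele_id = character(),
                                   population = character(),
                                   p_value = numeric())))
}

#' Majority-rule consensus of breakpoint soft-clip sequences
#'
#' Groups soft-clip records by allele and breakpoint side and builds a
#' per-position majority consensus. Clips on the `"end"` side (clipped bases
#' extend to the right of the alignment) are left-aligned; clips on the
#' `"start"` side are right-aligned, so bases adjacent to the breakpoint
#' line up. Ties are broken alphabetically.
#'
#' @param clips Data frame `allele_id`, `side` (`"start"`/`"end"`), `seq`.
#' @return Named character vector of consensus sequences
#'   (`"<allele_id>/<side>"`).
#' @export
breakpoint_clip_consensus <- function(clips) {
  stopifnot_cols(clips, c("allele_id", "side", "seq"), "'clips'")
  if (any(!nzchar(clips$seq))) stop("clipped sequence must be non-empty")
  groups <- split(clips$seq, paste(clips$allele_id, clips$side, sep = "/"))
  vapply(names(groups), function(g) {
    seqs <- groups[[g]]
    right_align <- grepl("/start$", g)
    L <- max(nchar(seqs))
    mat <- vapply(seqs, function(s) {
      pad <- strrep(" ", L - nchar(s))
      s2 <- if (right_align) paste0(pad, s) else paste0(s, pad)
      strsplit(s2, "")[[1]]
    }, character(L))
    cons <- apply(matrix(mat, nrow = L), 1, function(col) {
      col <- col[col != " "]
      names(sort(table(col), decreasing = TRUE))[1]
    })
    paste(cons, collapse = "")
  }, character(1))
}

#' Export breakpoint clip consensus sequences as FASTA
#'
#' @param clips Soft-clip records (see [breakpoint_clip_consensus()]).
#' @param path Output FASTA path.
#' @return Invisibly, the consensus vector.
#' @export
export_breakpoint_clips <- function(clips, path) {
  cons <- breakpoint_clip_consensus(clips)
  dss <- Biostrings::DNAStringSet(cons)
  Biostrings::writeXStringSet(dss, path)
  invisible(cons)
}
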