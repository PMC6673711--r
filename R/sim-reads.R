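#' Simulate diagnostic reads at planted CNV breakpoints
#'
#' Emits the read-level evidence a real aligner would produce at the
#' junctions of the planted CNVs: tandem duplications yield face-away read
#' pairs around the two breakpoints, tandem inversions yield
#' same-orientation pairs, and deletions inside an amplification yield
#' long-insert pairs; every junction also yields soft-clipped reads whose
#' clipped bases are the (per-allele deterministic) junction sequence.
#' Scattered background discordant pairs are added at a low rate. Every
#' carrier of a planted allele receives at least two diagnostic reads.
#'
#' @param ref A [simulate_reference()] object.
#' @param samples Sample sheet (needs `sample_id`, `mean_depth`).
#' @param planted Planted-CNV table (see [simulate_window_counts()]).
#' @param insert_mean,insert_sd Insert-size model; `insert_mean` must exceed
#'   twice the read length.
#' @param read_length Read length in bp (default 100).
#' @param diagnostic_rate Expected diagnostic pairs per junction as a
#'   fraction of mean depth (default 0.2, i.e. ~6 pairs at 30x).
#' @param background_pairs Expected random discordant pairs per sample
#'   (default 2).
#' @param clip_len Length of the junction sequence carried by soft-clips.
#' @param seed Integer seed.
#' @return List: `pairs` (data frame `sample_id`, `chrom1`, `pos1`,
#'   `strand1`, `chrom2`, `pos2`, `strand2`), `clips` (`sample_id`,
#'   `allele_id`, `chrom`, `pos`, `side`, `seq`) and `signatures` (the truth
#'   registry: `allele_id`, `chrom`, `type`, `anchor1`, `anchor2`, `tol`,
#'   including `breakpoint_clip` rows with 10-bp tolerance).
#' @export
simulate_breakpoint_reads <- function(ref, samples, planted,
                                      insert_mean = 400, insert_sd = 50,
                                      read_length = 100,
                                      diagnostic_rate = 0.2,
                                      background_pairs = 2,
                                      clip_len = 25, seed = NULL) {
  if (insert_mean <= 2 * read_length) {
    stop("'insert_mean' must exceed twice the read length")
  }
  type_of <- c(tandem_duplication = "face_away",
               tandem_inversion = "same_orientation",
               deletion_within_amplification = "long_insert")
  if (!is.null(planted) && nrow(planted)) {
    planted <- validate_planted_cnvs(ref, samples, planted)
    if (any(!planted$mechanism %in% names(type_of))) {
      stop("unknown CNV mechanism")
    }
  }
  w <- ref$window_size
  with_seed(seed, {
    pairs <- list(); clips <- list(); sigs <- list()
    if (!is.null(planted) && nrow(planted)) {
      # one deterministic junction sequence and signature per allele
      al <- unique(planted[, c("allele_id", "chrom", "start_window",
                               "end_window", "mechanism")])
      al <- al[!duplicated(al$allele_id), , drop = FALSE]
      al$bp_start <- al$start_window * w
      al$bp_end <- (al$end_window + 1) * w
      al$junction <- vapply(seq_len(nrow(al)), function(i) {
        paste(sample(c("A", "C", "G", "T"), clip_len, replace = TRUE),
              collapse = "")
      }, character(1))
      for (i in seq_len(nrow(al))) {
        sigs[[length(sigs) + 1L]] <- data.frame(
          allele_id = al$allele_id[i], chrom = al$chrom[i],
          type = c(unname(type_of[al$mechanism[i]]), "breakpoint_clip"),
          anchor1 = al$bp_start[i], anchor2 = al$bp_end[i],
          tol = c(300, 10), stringsAsFactors = FALSE)
      }
      for (r in seq_len(nrow(planted))) {
        a <- al[match(planted$allele_id[r], al$allele_id), ]
        sm <- samples[match(planted$sample_id[r], samples$sample_id), ]
        n <- max(2L, rpois(1, sm$mean_depth * diagnostic_rate))
        off1 <- round(runif(n, 0, 150))
        off2 <- round(runif(n, 0, 150))
        p <- switch(a$mechanism,
          tandem_duplication = data.frame(
            pos1 = a$bp_start + off1, strand1 = "-",
            pos2 = a$bp_end - off2, strand2 = "+"),
          tandem_inversion = data.frame(
            pos1 = a$bp_start + off1, strand1 = "+",
            pos2 = a$bp_end - off2, strand2 = "+"),
          deletion_within_amplification = data.frame(
            pos1 = a$bp_start - off1, strand1 = "+",
            pos2 = a$bp_end + off2, strand2 = "-"))
        pairs[[length(pairs) + 1L]] <- data.frame(
          sample_id = sm$sample_id, chrom1 = a$chrom, pos1 = p$pos1,
          strand1 = p$strand1, chrom2 = a$chrom, pos2 = p$pos2,
          strand2 = p$strand2, stringsAsFactors = FALSE)
        nclip <- max(1L, rpois(1, sm$mean_depth * diagnostic_rate / 2))
        clips[[length(clips) + 1L]] <- data.frame(
          sample_id = sm$sample_id, allele_id = a$allele_id, chrom = a$chrom,
          pos = rep(c(a$bp_end, a$bp_start), length.out = 2 * nclip),
          side = rep(c("end", "start"), length.out = 2 * nclip),
          seq = a$junction, stringsAsFactors = FALSE)
      }
    }
    # background discordant noise, scattered uniformly
    for (i in seq_len(nrow(samples))) {
      nb <- rpois(1, background_pairs)
      if (!nb) next
      ch <- sample(ref$chromosomes$chrom, nb, replace = TRUE)
      L <- ref$chromosomes$length[match(ch, ref$chromosomes$chrom)]
      p1 <- floor(runif(nb, 0, L * 0.9))
      pairs[[length(pairs) + 1L]] <- data.frame(
        sample_id = samples$sample_id[i], chrom1 = ch, pos1 = p1,
        strand1 = sample(c("+", "-"), nb, replace = TRUE),
        chrom2 = ch, pos2 = p1 + floor(runif(nb, 5000, 50000)),
        strand2 = sample(c("+", "-"), nb, replace = TRUE),
        stringsAsFactors = FALSE)
    }
    empty_pairs <- data.frame(sample_id = character(), chrom1 = character(),
                              pos1 = numeric(), strand1 = character(),
                              chrom2 = character(), pos2 = numeric(),
                              strand2 = character(), stringsAsFactors = FALSE)
    empty_clips <- data.frame(sample_id = character(), allele_id = character(),
                              chrom = character(), pos = numeric(),
                              side = character(), seq = character(),
                              stringsAsFactors = FALSE)
    list(pairs = if (length(pairs)) do.call(rbind, pairs) else empty_pairs,
         clips = if (length(clips)) do.call(rbind, clips) else empty_clips,
         signatures = if (length(sigs)) do.call(rbind, sigs) else
           data.frame(allele_id = character(), chrom = character(),
                      type = character(), anchor1 = numeric(),
                      anchor2 = numeric(), tol = numeric(),
                      stringsAsFactors = FALSE))
  })
}
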