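# Mirrored-BAF allelic-imbalance segmentation and mosaic cell-fraction
# estimation. Heterozygous SNPs sit at BAF 0.5 in pure diploid tissue; a
# CNV or copy-neutral LOH present in a fraction p of cells shifts them
# symmetrically away from 0.5. Mirroring folds the symmetric signal onto
# [0.5, 1], homozygous (uninformative) probes are filtered out, a
# change-point segmentation finds shifted stretches, and allele-dosage
# algebra converts the segment mean mBAF into the cell fraction p.

#' BAF segmentation configuration
#'
#' @param informative_threshold mBAF above which a probe is considered
#'   homozygous and filtered out (default 0.97).
#' @param triplet_threshold median mBAF of a probe's centered triplet above
#'   which a probe is protected from the homozygous filter (default 0.8).
#' @param ai_threshold minimum segment mean mBAF to call allelic imbalance
#'   (default 0.56).
#' @param ai_size minimum number of informative probes in a called segment
#'   (default 4).
#' @param lrr_del_max segments with mean LRR below this are typed
#'   mosaic_deletion (default -0.1).
#' @param lrr_dup_min segments with mean LRR above this are typed
#'   mosaic_duplication (default +0.05); in between is
#'   cn_neutral_imbalance.
#' @param penalty change-point acceptance penalty on the Gaussian
#'   log-likelihood-ratio scale; NULL (default) uses 2*log(n), the BIC cost
#'   of the two parameters (location and mean) a change point adds.
#' @return object of class `baf_seg_config`.
#' @export
baf_seg_config <- function(informative_threshold = 0.97,
                           triplet_threshold = 0.8,
                           ai_threshold = 0.56, ai_size = 4,
                           lrr_del_max = -0.1, lrr_dup_min = 0.05,
                           penalty = NULL) {
  stopifnot(0.5 < ai_threshold, ai_threshold < triplet_threshold,
            triplet_threshold < informative_threshold,
            informative_threshold <= 1, ai_size >= 1)
  structure(list(informative_threshold = informative_threshold,
                 triplet_threshold = triplet_threshold,
                 ai_threshold = ai_threshold, ai_size = as.integer(ai_size),
                 lrr_del_max = lrr_del_max, lrr_dup_min = lrr_dup_min,
                 penalty = penalty),
            class = "baf_seg_config")
}

#' Mirror a B-allele frequency
#'
#' @param baf numeric vector in \[0, 1\].
#' @return mirrored BAF `max(baf, 1 - baf)` in \[0.5, 1\].
#' @export
mirror_baf <- function(baf) {
  if (any(!is.na(baf) & (baf < 0 | baf > 1))) stop("BAF must lie in [0, 1]")
  pmax(baf, 1 - baf)
}

#' Filter uninformative (homozygous) probes
#'
#' Probes with mBAF above the informative threshold are homozygous and
#' removed, except when the median mBAF of the probe's centered triplet
#' (itself with its flanking non-NC neighbours) exceeds the triplet
#' threshold — dense stretches of true near-1 imbalance are thereby
#' protected from deletion as "homozygous". NC-genotype probes are always
#' removed.
#'
#' @param mbaf mirrored BAF series, position-sorted.
#' @param genotype matching genotype calls (optional; NC probes dropped).
#' @param config a [baf_seg_config()].
#' @return integer vector of retained indices into `mbaf`.
#' @export
informative_filter <- function(mbaf, genotype = NULL,
                               config = baf_seg_config()) {
  cand <- which(!is.na(mbaf))
  if (!is.null(genotype)) cand <- cand[genotype[cand] != "NC"]
  if (length(cand) == 0) return(integer(0))
  v <- mbaf[cand]
  n <- length(v)
  keep <- v <= config$informative_threshold
  high <- which(!keep)
  if (length(high) > 0) {
    prev <- pmax(high - 1L, 1L)
    nxt <- pmin(high + 1L, n)
    trip_med <- vapply(seq_along(high), function(i) {
      stats::median(v[unique(c(prev[i], high[i], nxt[i]))])
    }, numeric(1))
    keep[high[trip_med > config$triplet_threshold]] <- TRUE
  }
  cand[keep]
}

# Sum of squared errors of x about its mean, from prefix sums.
seg_sse <- function(s, s2, a, b) {
  m <- b - a + 1
  tot <- s[b + 1] - s[a]
  (s2[b + 1] - s2[a]) - tot * tot / m
}

#' Segment a mirrored-BAF series by recursive binary splitting
#'
#' Finds the change-point partition minimising within-segment squared
#' error: each segment is recursively split at its best change point, and a
#' split is accepted when the Gaussian log-likelihood-ratio statistic
#' `m * log(SSE_before / SSE_after)` exceeds the penalty (default
#' `2 * log(n)`, BIC-style). Segments are contiguous, exhaustive and
#' ordered.
#'
#' @param mbaf numeric series (informative probes only, position order).
#' @param penalty acceptance penalty; NULL for the default `2 * log(n)`.
#' @return data.frame with `start_idx`, `end_idx` (1-based, inclusive,
#'   indices into `mbaf`) and `mean_mbaf`.
#' @export
segment_mbaf <- function(mbaf, penalty = NULL) {
  n <- length(mbaf)
  if (n < 1) stop("need at least one informative probe")
  if (is.null(penalty)) penalty <- 2 * log(max(n, 2))
  s <- c(0, cumsum(mbaf))
  s2 <- c(0, cumsum(mbaf^2))
  eps <- 1e-12

  split_rec <- function(a, b) {
    m <- b - a + 1
    if (m < 2) return(c(a))
    sse0 <- seg_sse(s, s2, a, b)
    if (sse0 <= eps) return(c(a))
    cuts <- a:(b - 1)  # last index of the left part
    sse1 <- vapply(cuts, function(j) {
      seg_sse(s, s2, a, j) + seg_sse(s, s2, j + 1, b)
    }, numeric(1))
    j <- cuts[which.min(sse1)]
    gain <- m * log(sse0 / max(min(sse1), eps))
    if (gain > penalty) {
      c(split_rec(a, j), split_rec(j + 1, b))
    } else {
      c(a)
    }
  }
  starts <- split_rec(1L, n)
  ends <- c(starts[-1] - 1L, n)
  data.frame(
    start_idx = starts, end_idx = ends,
    mean_mbaf = vapply(seq_along(starts), function(i) {
      mean(mbaf[starts[i]:ends[i]])
    }, numeric(1))
  )
}

#' Expected mirrored BAF of a heterozygous SNP under mosaicism
#'
#' Allele-dosage expectations for a heterozygous SNP when a fraction `p` of
#' cells carries the event: deletion `1/(2-p)`, duplication
#' `(1+p)/(2+p)`, copy-neutral LOH `(1+p)/2`.
#'
#' @param p cell fraction in \[0, 1\].
#' @param event_type "mosaic_deletion", "mosaic_duplication" or
#'   "cn_neutral_imbalance".
#' @return expected mBAF in \[0.5, 1\].
#' @export
expected_mbaf <- function(p, event_type) {
  stopifnot(all(p >= 0 & p <= 1))
  switch(match.arg(event_type, c("mosaic_deletion", "mosaic_duplication",
                                 "cn_neutral_imbalance")),
         mosaic_deletion = 1 / (2 - p),
         mosaic_duplication = (1 + p) / (2 + p),
         cn_neutral_imbalance = (1 + p) / 2)
}

#' Estimate the mosaic cell fraction from a segment's mean mBAF
#'
#' Inverts the heterozygous-SNP dosage expectations of [expected_mbaf()]:
#' deletion `p = 2 - 1/mBAF`; duplication `p = (2*mBAF - 1)/(1 - mBAF)`
#' (capped at 1; mBAF = 1 returns the cap with an "at-bound" attribute);
#' copy-neutral LOH `p = 2*mBAF - 1`. The result is clipped to \[0, 1\].
#'
#' @param mean_mbaf segment mean mirrored BAF in \[0.5, 1\].
#' @param event_type "mosaic_deletion", "mosaic_duplication" or
#'   "cn_neutral_imbalance".
#' @return estimated fraction of cells carrying the event, in \[0, 1\].
#' @export
estimate_mosaic_fraction <- function(mean_mbaf, event_type) {
  stopifnot(all(mean_mbaf >= 0.5 - 1e-9 & mean_mbaf <= 1 + 1e-9))
  event_type <- match.arg(event_type, c("mosaic_deletion",
                                        "mosaic_duplication",
                                        "cn_neutral_imbalance"))
  at_bound <- FALSE
  p <- switch(event_type,
    mosaic_deletion = 2 - 1 / mean_mbaf,
    mosaic_duplication = {
      at_bound <- any(mean_mbaf >= 1 - 1e-12)
      ifelse(mean_mbaf >= 1 - 1e-12, 1, (2 * mean_mbaf - 1) / (1 - mean_mbaf))
    },
    cn_neutral_imbalance = 2 * mean_mbaf - 1
  )
  p <- pmin(pmax(p, 0), 1)
  if (at_bound) attr(p, "at_bound") <- TRUE
  p
}

#' Call allelic-imbalance segments
#'
#' A segment from [segment_mbaf()] becomes an allelic-imbalance call when
#' its mean mBAF reaches `ai_threshold` and it holds at least `ai_size`
#' informative probes. The event type comes from the segment's mean LRR
#' (deletion / duplication / copy-neutral), and the mosaic cell fraction
#' from [estimate_mosaic_fraction()].
#'
#' The mosaic fraction is estimated from the mean mBAF of the segment's
#' heterozygous-genotype probes when `het` is supplied (residual
#' near-homozygous probes would bias the dosage inversion upward). When
#' fewer than `ai_size` heterozygous calls remain — at high cell fractions
#' the shifted heterozygotes themselves get homozygous calls — the segment
#' median is used instead, which resists the homozygous-tail contamination
#' that the mean does not.
#'
#' @param segments data.frame from [segment_mbaf()].
#' @param mbaf the informative mBAF series the segments index into.
#' @param lrr matching per-probe LRR series.
#' @param positions matching bp positions.
#' @param chromosome chromosome name.
#' @param config a [baf_seg_config()].
#' @param het optional logical vector aligned to `mbaf`: TRUE where the
#'   genotype call is heterozygous.
#' @return data.frame of class `ai_segments`: `chromosome`, `start`, `end`,
#'   `n_informative`, `mean_mbaf`, `mean_lrr`, `event_type`,
#'   `mosaic_fraction`.
#' @export
call_ai <- function(segments, mbaf, lrr, positions, chromosome,
                    config = baf_seg_config(), het = NULL) {
  out <- list()
  for (i in seq_len(nrow(segments))) {
    a <- segments$start_idx[i]; b <- segments$end_idx[i]
    n_inf <- b - a + 1L
    m <- segments$mean_mbaf[i]
    if (m < config$ai_threshold || n_inf < config$ai_size) next
    m_est <- m
    if (!is.null(het)) {
      seg_mb <- mbaf[a:b]
      below <- seg_mb[seg_mb <= config$informative_threshold]
      m_est <- if (sum(het[a:b]) >= config$ai_size) {
        mean(seg_mb[het[a:b]])
      } else if (length(below) > 0) {
        # no heterozygous calls left (high cell fraction): the median of
        # the sub-threshold probes resists the homozygous tail that
        # triplet protection keeps in the segment
        stats::median(below)
      } else {
        stats::median(seg_mb)
      }
    }
    mean_lrr <- mean(lrr[a:b], na.rm = TRUE)
    type <- if (!is.na(mean_lrr) && mean_lrr < config$lrr_del_max) {
      "mosaic_deletion"
    } else if (!is.na(mean_lrr) && mean_lrr > config$lrr_dup_min) {
      "mosaic_duplication"
    } else {
      "cn_neutral_imbalance"
    }
    out[[length(out) + 1]] <- data.frame(
      chromosome = chromosome, start = positions[a], end = positions[b],
      n_informative = n_inf, mean_mbaf = m, mean_lrr = mean_lrr,
      event_type = type,
      mosaic_fraction = as.numeric(estimate_mosaic_fraction(
        max(m_est, 0.5), type)),
      stringsAsFactors = FALSE
    )
  }
  res <- if (length(out) > 0) do.call(rbind, out) else data.frame(
    chromosome = character(0), start = numeric(0), end = numeric(0),
    n_informative = integer(0), mean_mbaf = numeric(0),
    mean_lrr = numeric(0), event_type = character(0),
    mosaic_fraction = numeric(0), stringsAsFactors = FALSE
  )
  class(res) <- c("ai_segments", "data.frame")
  res
}

#' Run BAF segmentation on a sample
#'
#' Convenience pipeline: mirror the BAF of the requested chromosomes,
#' filter uninformative probes, segment, and call allelic-imbalance
#' segments with mosaic fractions. Typically run on the chromosomes
#' flagged by [screen_mosaic_chromosomes()].
#'
#' Probes with a confident constitutional homozygous signature — a
#' homozygous genotype call together with mBAF above the informative
#' threshold — are excluded before filtering: they carry no
#' allelic-imbalance dosage information, and on a tri-modal SNP series
#' their density would otherwise let the triplet-protection rule retain
#' them and dilute segment means. Heterozygotes whose calls flip to
#' homozygous under strong imbalance keep mBAF below that threshold and
#' are unaffected.
#'
#' @param sample a [sample_data()].
#' @param chromosomes chromosomes to analyse (default: all in the map).
#' @param config a [baf_seg_config()].
#' @return `ai_segments` data.frame over the requested chromosomes.
#' @export
segment_sample_baf <- function(sample, chromosomes = NULL,
                               config = baf_seg_config()) {
  map <- sample$map
  if (is.null(chromosomes)) chromosomes <- unique(map$chromosome)
  chromosomes <- normalize_chromosome(chromosomes)
  res <- list()
  for (ch in chromosomes) {
    rows <- which(map$chromosome == ch & map$is_snp)
    if (length(rows) == 0) next
    mb_all <- mirror_baf(sample$baf[rows])
    confident_hom <- sample$genotype[rows] %in% c("AA", "BB") &
      !is.na(mb_all) & mb_all > config$informative_threshold
    rows <- rows[!confident_hom]
    if (length(rows) == 0) next
    mb <- mb_all[!confident_hom]
    keep <- informative_filter(mb, sample$genotype[rows], config)
    if (length(keep) == 0) next
    segs <- segment_mbaf(mb[keep], penalty = config$penalty)
    res[[length(res) + 1]] <- call_ai(
      segs, mb[keep], sample$lrr[rows][keep],
      map$position[rows][keep], ch, config,
      het = sample$genotype[rows][keep] == "AB"
    )
  }
  if (length(res) == 0) {
    return(call_ai(data.frame(start_idx = integer(0), end_idx = integer(0),
                              mean_mbaf = numeric(0)),
                   numeric(0), numeric(0), numeric(0), NA_character_, config))
  }
  out <- do.call(rbind, res)
  class(out) <- c("ai_segments", "data.frame")
  out
}
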