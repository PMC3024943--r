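# Sample quality control: pass thresholds, GC-wave correction and the
# chromosome-level BAF-SD screen that triggers mosaicism analysis.

#' QC pass thresholds
#'
#' Defaults follow accepted practice for Illumina BeadArray data: genotype
#' call rate above 99.4%, autosomal LRR standard deviation below 0.2,
#' heterozygous-band BAF standard deviation below 0.6 and absolute genomic
#' wave factor below 0.03.
#'
#' @param min_call_rate minimum genotype call rate (fraction, default 0.994).
#' @param max_lrr_sd maximum autosomal LRR SD (default 0.2).
#' @param max_baf_sd maximum heterozygous-band BAF SD (default 0.6).
#' @param max_abs_wave maximum absolute GC-wave factor (default 0.03).
#' @return object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_call_rate = 0.994, max_lrr_sd = 0.2,
                          max_baf_sd = 0.6, max_abs_wave = 0.03) {
  stopifnot(min_call_rate > 0, min_call_rate <= 1,
            max_lrr_sd > 0, max_baf_sd > 0, max_abs_wave > 0)
  structure(list(min_call_rate = min_call_rate, max_lrr_sd = max_lrr_sd,
                 max_baf_sd = max_baf_sd, max_abs_wave = max_abs_wave),
            class = "qc_thresholds")
}

#' Compute the sample QC report
#'
#' Metrics (sex chromosomes are excluded throughout — hemizygosity would
#' distort the standard deviations):
#' * `call_rate` — fraction of SNP probes with a genotype call (not NC);
#' * `lrr_sd` — SD of autosomal LRR;
#' * `baf_sd` — SD of BAF over autosomal SNP probes whose BAF lies in the
#'   heterozygous band \[0.25, 0.75\] (the raw tri-modal BAF distribution
#'   would make a single SD meaningless);
#' * `wave_factor` — slope of the GC regression when `gc_track` is given
#'   (see [gc_wave_correct()]), otherwise NA (not evaluated);
#' * `per_chromosome_baf_sd` — the heterozygous-band BAF SD per autosome,
#'   feeding the mosaicism screen.
#'
#' Pass flags compare strictly against the thresholds.
#'
#' @param sample a [sample_data()].
#' @param thresholds a [qc_thresholds()].
#' @param gc_track optional GC track (see [read_gc_track()]); enables the
#'   wave factor.
#' @param k_mad MAD multiplier handed to [screen_mosaic_chromosomes()].
#' @return object of class `qc_report`: list with the metrics above,
#'   `pass` (named logical vector), `pass_all`, and
#'   `mosaic_flagged_chromosomes`.
#' @export
compute_qc <- function(sample, thresholds = qc_thresholds(),
                       gc_track = NULL, k_mad = 3) {
  map <- sample$map
  if (!any(map$is_snp)) stop("sample has no SNP probes")
  auto <- map$chromosome %in% AUTOSOMES
  snp <- map$is_snp

  call_rate <- mean(sample$genotype[snp] != "NC")
  lrr_sd <- stats::sd(sample$lrr[auto], na.rm = TRUE)
  het_band <- auto & snp & !is.na(sample$baf) &
    sample$baf >= 0.25 & sample$baf <= 0.75
  baf_sd <- stats::sd(sample$baf[het_band], na.rm = TRUE)

  per_chrom <- vapply(
    intersect(unique(map$chromosome), AUTOSOMES),
    function(ch) {
      sel <- het_band & map$chromosome == ch
      if (sum(sel) < 2) return(NA_real_)
      stats::sd(sample$baf[sel])
    }, numeric(1)
  )

  wave_factor <- NA_real_
  if (!is.null(gc_track)) {
    wave_factor <- gc_wave_correct(sample, gc_track)$wave_factor
  }

  pass <- c(
    call_rate = call_rate > thresholds$min_call_rate,
    lrr_sd = !is.na(lrr_sd) && lrr_sd < thresholds$max_lrr_sd,
    baf_sd = !is.na(baf_sd) && baf_sd < thresholds$max_baf_sd,
    wave = if (is.na(wave_factor)) NA
           else abs(wave_factor) < thresholds$max_abs_wave
  )
  if (call_rate == 0) pass[c("lrr_sd", "baf_sd")] <- FALSE

  qc <- structure(
    list(sample_id = sample$sample_id, call_rate = call_rate,
         lrr_sd = lrr_sd, baf_sd = baf_sd, wave_factor = wave_factor,
         per_chromosome_baf_sd = per_chrom, pass = pass,
         pass_all = all(pass, na.rm = TRUE),
         thresholds = thresholds,
         mosaic_flagged_chromosomes = character(0)),
    class = "qc_report"
  )
  qc$mosaic_flagged_chromosomes <-
    tryCatch(screen_mosaic_chromosomes(qc, k_mad = k_mad),
             error = function(e) character(0))
  qc
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    paste0("qc_report '%s': call_rate %.4f, lrr_sd %.4f, baf_sd %.4f, ",
           "wave %s, pass_all %s\n"),
    x$sample_id, x$call_rate, x$lrr_sd, x$baf_sd,
    ifelse(is.na(x$wave_factor), "n/e", sprintf("%.4f", x$wave_factor)),
    x$pass_all
  ))
  if (length(x$mosaic_flagged_chromosomes) > 0) {
    cat("  mosaicism suspected on chromosome(s): ",
        paste(x$mosaic_flagged_chromosomes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a GC-content track
#'
#' BED-like TSV with columns `chrom`, `start`, `end`, `gc_fraction`
#' (1 Mb bins recommended).
#'
#' @param path file path.
#' @return data.frame with normalised chromosome names, 1-based inclusive
#'   coordinates, and `gc` fractions.
#' @export
read_gc_track <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  gc_col <- intersect(c("gc_fraction", "gc"), names(df))[1]
  if (is.na(gc_col)) stop("GC track missing gc_fraction column")
  data.frame(chromosome = normalize_chromosome(df$chrom, strict = FALSE),
             start = as.numeric(df$start) + 1, end = as.numeric(df$end),
             gc = as.numeric(df[[gc_col]]), stringsAsFactors = FALSE)
}

# GC value of each probe's window; NA where uncovered.
probe_gc <- function(map, gc_track) {
  gc <- rep(NA_real_, nrow(map))
  win <- rep(NA_integer_, nrow(map))
  for (ch in unique(map$chromosome)) {
    rows <- which(map$chromosome == ch)
    trk <- which(gc_track$chromosome == ch)
    if (length(trk) == 0) next
    trk <- trk[order(gc_track$start[trk])]
    j <- findInterval(map$position[rows], gc_track$start[trk])
    inside <- j >= 1 & map$position[rows] <= gc_track$end[trk][pmax(j, 1)]
    gc[rows[inside]] <- gc_track$gc[trk][j[inside]]
    win[rows[inside]] <- trk[j[inside]]
  }
  list(gc = gc, window = win)
}

#' Correct genomic waves by GC regression
#'
#' Genomic waving — long-range LRR fluctuation correlated with local GC
#' content — is modelled as a single linear regression of per-window median
#' LRR on window GC fraction. The slope is the wave factor; the fitted
#' line is subtracted from each probe's LRR (probes in windows without GC
#' coverage are left unadjusted). A degenerate regressor (constant GC)
#' yields a zero slope and unchanged data.
#'
#' @param sample a [sample_data()].
#' @param gc_track GC track as from [read_gc_track()]; must cover at least
#'   half of the probes.
#' @param min_probes_per_window windows with fewer probes are ignored
#'   (default 1).
#' @return list with `sample` (adjusted copy) and `wave_factor` (the
#'   regression slope, LRR units per GC fraction).
#' @export
gc_wave_correct <- function(sample, gc_track, min_probes_per_window = 1) {
  pg <- probe_gc(sample$map, gc_track)
  covered <- !is.na(pg$gc) & !is.na(sample$lrr)
  if (mean(!is.na(pg$gc)) < 0.5) {
    stop("insufficient GC coverage: track covers < 50% of probes")
  }
  wins <- split(which(covered), pg$window[covered])
  wins <- wins[lengths(wins) >= min_probes_per_window]
  if (length(wins) < 2) stop("insufficient GC coverage: < 2 usable windows")
  med_lrr <- vapply(wins, function(ix) stats::median(sample$lrr[ix]), numeric(1))
  win_gc <- vapply(wins, function(ix) pg$gc[ix[1]], numeric(1))
  if (stats::sd(win_gc) < 1e-12) {
    return(list(sample = sample, wave_factor = 0))
  }
  fit <- stats::lm(med_lrr ~ win_gc)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  adj <- sample
  adj$lrr[covered] <- sample$lrr[covered] -
    (intercept + slope * pg$gc[covered])
  list(sample = adj, wave_factor = slope)
}

#' Screen per-chromosome BAF SD for mosaicism
#'
#' Chromosome-specific heterozygous-band BAF standard deviations are
#' screened for robust outliers: a chromosome is flagged when its SD
#' exceeds the median plus `k_mad` times the MAD (scaled for
#' SD-consistency) of the per-chromosome values. Flagged chromosomes are
#' candidates for allelic-imbalance (mosaicism) analysis with
#' [segment_sample_baf()].
#'
#' @param qc a `qc_report` from [compute_qc()], or a named numeric vector
#'   of per-chromosome BAF SDs.
#' @param k_mad MAD multiplier (default 3).
#' @return character vector of flagged chromosome names (possibly empty).
#' @export
screen_mosaic_chromosomes <- function(qc, k_mad = 3) {
  sds <- if (inherits(qc, "qc_report")) qc$per_chromosome_baf_sd else qc
  sds <- sds[!is.na(sds)]
  if (length(sds) < 5) {
    stop("need per-chromosome BAF SD on >= 5 autosomes")
  }
  med <- stats::median(sds)
  mad <- stats::mad(sds)  # constant 1.4826 for SD-consistency
  names(sds)[sds > med + k_mad * mad]
}
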