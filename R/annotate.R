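# Interval annotation of consensus regions against user-supplied tracks
# (control-variant sets, gene lists), ISCN-style naming, and BED/TSV/JSON
# report emission. Coordinates are 1-based inclusive internally; BED
# conversion to 0-based half-open happens only at the BED boundary.

#' Read a BED-format annotation track
#'
#' 3-6 column BED (chrom, start, end, name, score, strand); a
#' `sample_column` may name (or index) a column carrying per-sample
#' identifiers for control-frequency computation, and `direction_column` a
#' column with "loss"/"gain" per interval.
#'
#' @param path file path (gzip accepted).
#' @param name track name.
#' @param kind "control_variants", "genes" or "custom".
#' @param panel_size declared number of control samples in the panel
#'   (required for control frequencies).
#' @param sample_column,direction_column optional column index (1-based) of
#'   sample id / direction fields.
#' @return object of class `annotation_track`: list with `name`, `kind`,
#'   `panel_size` and `intervals` (1-based inclusive data.frame).
#' @export
read_bed_track <- function(path, name = basename(path),
                           kind = c("custom", "control_variants", "genes"),
                           panel_size = NA_integer_,
                           sample_column = NULL, direction_column = NULL) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 3) stop("BED track needs at least 3 columns")
  intervals <- data.frame(
    chromosome = normalize_chromosome(df[[1]], strict = FALSE),
    start = as.numeric(df[[2]]) + 1,  # BED is 0-based half-open
    end = as.numeric(df[[3]]),
    label = if (ncol(df) >= 4) as.character(df[[4]]) else
      paste0(name, "_", seq_len(nrow(df))),
    stringsAsFactors = FALSE
  )
  if (!is.null(sample_column)) {
    intervals$sample <- as.character(df[[sample_column]])
  }
  if (!is.null(direction_column)) {
    intervals$direction <- as.character(df[[direction_column]])
  }
  annotation_track(name, intervals, kind = kind, panel_size = panel_size)
}

#' Build an annotation track from intervals
#'
#' @param name track name.
#' @param intervals data.frame with `chromosome`, `start`, `end` (1-based
#'   inclusive), `label`, and optionally `sample` and `direction` columns.
#' @param kind "control_variants", "genes" or "custom".
#' @param panel_size declared control panel size (for frequencies).
#' @return object of class `annotation_track`.
#' @export
annotation_track <- function(name, intervals,
                             kind = c("custom", "control_variants", "genes"),
                             panel_size = NA_integer_) {
  kind <- match.arg(kind)
  intervals <- as.data.frame(intervals)
  need <- c("chromosome", "start", "end")
  if (length(miss <- setdiff(need, names(intervals))) > 0) {
    stop("track intervals missing column(s): ", paste(miss, collapse = ", "))
  }
  if (is.null(intervals$label)) {
    intervals$label <- paste0(name, "_", seq_len(nrow(intervals)))
  }
  intervals$chromosome <- normalize_chromosome(intervals$chromosome,
                                               strict = FALSE)
  intervals <- intervals[order(match(intervals$chromosome, VALID_CHROMOSOMES),
                               intervals$start), , drop = FALSE]
  rownames(intervals) <- NULL
  structure(list(name = name, kind = kind,
                 panel_size = as.integer(panel_size), intervals = intervals),
            class = "annotation_track")
}

#' Annotate regions by overlap with a track
#'
#' A track interval is a hit for a region when their overlap covers at
#' least `min_overlap_fraction` of the region's length (default any
#' overlap). For control tracks carrying per-interval sample identifiers,
#' the control frequency is the number of distinct control samples with an
#' overlapping same-direction variant divided by the declared panel size;
#' intervals without a direction column match either direction.
#'
#' @param regions `consensus_regions` data.frame (or any data.frame with
#'   `chromosome`, `start`, `end` and optionally `direction`).
#' @param track an [annotation_track()].
#' @param min_overlap_fraction minimum overlap as a fraction of the
#'   region's length (default 0 = any overlap).
#' @param frequency compute control frequencies (requires a track `sample`
#'   column and a declared panel size); default TRUE for
#'   control_variants tracks.
#' @return `regions` with added columns `<track>_hits` (comma-joined
#'   labels), `<track>_n_hits`, and for control tracks `<track>_frequency`.
#' @export
overlap_annotate <- function(regions, track, min_overlap_fraction = 0,
                             frequency = track$kind == "control_variants") {
  iv <- track$intervals
  if (frequency) {
    if (is.null(iv$sample)) {
      stop("control frequency requested but track '", track$name,
           "' has no sample column")
    }
    if (is.na(track$panel_size)) {
      stop("control frequency requested but track '", track$name,
           "' declares no panel size")
    }
  }
  n <- nrow(regions)
  hits <- character(n)
  n_hits <- integer(n)
  freq <- numeric(n)
  if (n > 0 && nrow(iv) > 0) {
    # IRanges overlap per shared chromosome
    for (ch in intersect(unique(regions$chromosome), unique(iv$chromosome))) {
      ri <- which(regions$chromosome == ch)
      ti <- which(iv$chromosome == ch)
      q <- IRanges::IRanges(start = regions$start[ri], end = regions$end[ri])
      s <- IRanges::IRanges(start = iv$start[ti], end = iv$end[ti])
      ov <- IRanges::findOverlaps(q, s)
      if (length(ov) == 0) next
      qh <- S4Vectors::queryHits(ov)
      sh <- S4Vectors::subjectHits(ov)
      w <- IRanges::width(IRanges::pintersect(q[qh], s[sh]))
      keep <- w >= min_overlap_fraction * IRanges::width(q[qh])
      qh <- qh[keep]; sh <- sh[keep]
      if (!is.null(iv$direction) && !is.null(regions$direction)) {
        same <- is.na(iv$direction[ti][sh]) |
          iv$direction[ti][sh] == regions$direction[ri][qh]
      } else {
        same <- rep(TRUE, length(qh))
      }
      for (j in unique(qh)) {
        sel <- sh[qh == j & same]
        if (length(sel) == 0) next
        r <- ri[j]
        hits[r] <- paste(unique(iv$label[ti][sel]), collapse = ",")
        n_hits[r] <- length(sel)
        if (frequency) {
          freq[r] <- length(unique(iv$sample[ti][sel])) / track$panel_size
        }
      }
    }
  }
  regions[[paste0(track$name, "_hits")]] <- hits
  regions[[paste0(track$name, "_n_hits")]] <- n_hits
  if (frequency) regions[[paste0(track$name, "_frequency")]] <- freq
  regions
}

#' Read a UCSC-style cytoband file
#'
#' Five columns: chrom, start (0-based), end, band name, Giemsa stain.
#'
#' @param path file path.
#' @return data.frame with `chromosome`, `start`, `end` (1-based
#'   inclusive) and `band`.
#' @export
read_cytoband <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(chromosome = normalize_chromosome(df[[1]], strict = FALSE),
             start = as.numeric(df[[2]]) + 1, end = as.numeric(df[[3]]),
             band = as.character(df[[4]]), stringsAsFactors = FALSE)
}

band_at <- function(cytobands, chromosome, position) {
  sel <- cytobands$chromosome == chromosome &
    cytobands$start <= position & cytobands$end >= position
  if (!any(sel)) return(NA_character_)
  cytobands$band[which(sel)[1]]
}

#' ISCN-style string for a region
#'
#' Formats `arr {chrom}{band_start}[{band_end}]({start}-{end})x{cn}` with
#' thousands-separated coordinates and an inheritance suffix: `dn` (de
#' novo), `pat` (paternal), `mat` (maternal), `inh` (both parents).
#'
#' @param region one-row region with `chromosome`, `start`, `end`,
#'   `copy_number`.
#' @param cytobands data.frame from [read_cytoband()]; must cover the
#'   region's chromosome.
#' @param inheritance optional tag in \{de_novo, paternal, maternal, both\}.
#' @return ISCN-style character string.
#' @export
iscn_string <- function(region, cytobands, inheritance = NULL) {
  ch <- region$chromosome
  if (!ch %in% cytobands$chromosome) {
    stop("cytoband track does not cover chromosome ", ch)
  }
  b1 <- band_at(cytobands, ch, region$start)
  b2 <- band_at(cytobands, ch, region$end)
  if (is.na(b1) || is.na(b2)) {
    stop("cytoband track does not cover region ", ch, ":", region$start,
         "-", region$end)
  }
  bands <- if (identical(b1, b2)) b1 else paste0(b1, b2)
  fmt <- function(x) formatC(x, format = "d", big.mark = ",")
  suffix <- ""
  if (!is.null(inheritance) && !is.na(inheritance)) {
    suffix <- switch(inheritance, de_novo = " dn", paternal = " pat",
                     maternal = " mat", both = " inh", "")
  }
  sprintf("arr %s%s(%s-%s)x%d%s", ch, bands, fmt(region$start),
          fmt(region$end), region$copy_number, suffix)
}

#' Write regions as a BED file
#'
#' Converts 1-based inclusive coordinates to BED's 0-based half-open
#' convention and prefixes chromosome names with "chr". The name field is
#' the region's `iscn` column when present, else `name`/`label`, else a
#' running id.
#'
#' @param regions data.frame with `chromosome`, `start`, `end`.
#' @param path output path.
#' @return number of lines written, invisibly.
#' @export
write_bed <- function(regions, path) {
  n <- nrow(regions)
  if (n == 0) {
    file.create(path)
    return(invisible(0L))
  }
  name <- regions$iscn %||% regions$name %||% regions$label %||%
    paste0("region_", seq_len(n))
  lines <- paste(paste0("chr", regions$chromosome),
                 format(regions$start - 1, scientific = FALSE, trim = TRUE),
                 format(regions$end, scientific = FALSE, trim = TRUE),
                 gsub("\t", " ", name), sep = "\t")
  writeLines(lines, path)
  invisible(length(lines))
}

#' Build a structured sample report
#'
#' Deterministic document combining the QC block, the (optionally
#' control-frequency-filtered) region table with ISCN strings, and trio
#' results. The same inputs always produce byte-identical JSON (stable
#' ordering, no timestamps).
#'
#' @param sample_id sample identifier.
#' @param qc a `qc_report` from [compute_qc()] (optional).
#' @param regions annotated `consensus_regions` (optional).
#' @param ai_segments `ai_segments` from [segment_sample_baf()] (optional).
#' @param upd `upd_events` from [detect_upd()] (optional).
#' @param nonpaternity result of [detect_nonpaternity()] (optional).
#' @param cytobands cytoband data.frame; enables ISCN strings.
#' @param max_control_frequency drop regions whose control frequency
#'   (any `*_frequency` column) exceeds this cutoff (default NULL = keep
#'   all; 0 keeps only regions absent from controls).
#' @return object of class `cnv_report` (a list); write with
#'   [write_report()].
#' @export
build_report <- function(sample_id, qc = NULL, regions = NULL,
                         ai_segments = NULL, upd = NULL,
                         nonpaternity = NULL, cytobands = NULL,
                         max_control_frequency = NULL) {
  rep <- list(sample = list(sample_id = sample_id))
  if (!is.null(qc)) {
    rep$qc <- list(
      call_rate = qc$call_rate, lrr_sd = qc$lrr_sd, baf_sd = qc$baf_sd,
      wave_factor = qc$wave_factor,
      pass = as.list(qc$pass), pass_all = qc$pass_all,
      mosaic_flagged_chromosomes = qc$mosaic_flagged_chromosomes
    )
  }
  if (!is.null(regions)) {
    regions <- as.data.frame(regions)
    if (!is.null(max_control_frequency)) {
      fcols <- grep("_frequency$", names(regions), value = TRUE)
      for (fc in fcols) {
        regions <- regions[regions[[fc]] <= max_control_frequency, ,
                           drop = FALSE]
      }
    }
    if (!is.null(cytobands) && nrow(regions) > 0) {
      regions$iscn <- vapply(seq_len(nrow(regions)), function(i) {
        iscn_string(regions[i, ], cytobands,
                    inheritance = regions$inheritance[i] %||% NULL)
      }, character(1))
    }
    rownames(regions) <- NULL
    rep$regions <- regions
  }
  if (!is.null(ai_segments)) rep$allelic_imbalance <-
    as.data.frame(ai_segments)
  if (!is.null(upd)) rep$upd <- as.data.frame(upd)
  if (!is.null(nonpaternity)) {
    rep$nonpaternity <- list(flag = nonpaternity$flag,
                             genome_rate = nonpaternity$genome_rate,
                             n_chromosomes_over =
                               nonpaternity$n_chromosomes_over)
  }
  class(rep) <- "cnv_report"
  rep
}

#' Write a report as JSON (and optional text summary)
#'
#' @param report a `cnv_report` from [build_report()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' Mean aberrations per sample in a cohort
#'
#' Cohort-level summary statistic: the total number of consensus
#' aberrations divided by the number of samples analysed.
#'
#' @param n_aberrations total aberration count, or a per-sample vector of
#'   counts (summed).
#' @param n_samples number of samples; defaults to `length(n_aberrations)`
#'   when a vector is given.
#' @return mean aberrations per sample.
#' @export
aberrations_per_sample <- function(n_aberrations,
                                   n_samples = length(n_aberrations)) {
  stopifnot(n_samples >= 1)
  sum(n_aberrations) / n_samples
}
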