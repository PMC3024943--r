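#' Direction of a copy-number state
#'
#' @param copy_number integer copy number(s); 2 is diploid and not allowed
#'   in a CNV call.
#' @return "loss" for cn < 2, "gain" for cn > 2.
#' @export
cnv_direction <- function(copy_number) {
  ifelse(copy_number < 2, "loss", ifelse(copy_number > 2, "gain", NA_character_))
}

#' One caller's CNV callset for one sample
#'
#' Calls are validated (1-based inclusive coordinates, copy number 0..4
#' excluding 2) and overlapping same-direction calls are merged so that the
#' set is interval-disjoint per direction before voting: merged calls take
#' the minimum start, maximum end, the copy number of the higher-confidence
#' member, the summed probe count and the maximum confidence.
#'
#' @param method caller name (e.g. "quantisnp", "penncnv").
#' @param sample_id sample identifier; all calls must share it.
#' @param calls data.frame with columns `chromosome`, `start`, `end`,
#'   `copy_number`, `n_probes`, `confidence`.
#' @param confidence_threshold the confidence cut-off that was applied when
#'   the set was read (NA when unfiltered).
#' @return object of class `callset`: list with `method`, `sample_id`,
#'   `calls` (merged, sorted data.frame) and `confidence_threshold`.
#' @export
callset <- function(method, sample_id, calls,
                    confidence_threshold = NA_real_) {
  calls <- as.data.frame(calls)
  if (nrow(calls) > 0) {
    need <- c("chromosome", "start", "end", "copy_number")
    if (length(miss <- setdiff(need, names(calls))) > 0) {
      stop("calls missing column(s): ", paste(miss, collapse = ", "))
    }
    if (is.null(calls$n_probes)) calls$n_probes <- NA_integer_
    if (is.null(calls$confidence)) calls$confidence <- Inf
    calls$chromosome <- normalize_chromosome(calls$chromosome)
    calls$start <- as.numeric(calls$start)
    calls$end <- as.numeric(calls$end)
    calls$copy_number <- as.integer(calls$copy_number)
    if (any(calls$start > calls$end)) stop("call start must be <= end")
    if (any(calls$copy_number == 2L) ||
        any(calls$copy_number < 0L) || any(calls$copy_number > 4L)) {
      stop("copy_number must lie in 0..4 and differ from 2")
    }
    if (any(!is.na(calls$n_probes) & calls$n_probes < 1)) {
      stop("n_probes must be >= 1")
    }
    calls <- merge_direction_overlaps(calls)
  } else {
    calls <- empty_calls()
  }
  structure(
    list(method = as.character(method), sample_id = as.character(sample_id),
         calls = calls, confidence_threshold = confidence_threshold),
    class = "callset"
  )
}

empty_calls <- function() {
  data.frame(chromosome = character(0), start = numeric(0), end = numeric(0),
             copy_number = integer(0), n_probes = integer(0),
             confidence = numeric(0), stringsAsFactors = FALSE)
}

# Merge overlapping same-direction calls; keeps per-direction disjointness.
merge_direction_overlaps <- function(calls) {
  calls$.dir <- cnv_direction(calls$copy_number)
  out <- list()
  for (key in unique(paste(calls$chromosome, calls$.dir))) {
    sub <- calls[paste(calls$chromosome, calls$.dir) == key, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    cur <- sub[1, , drop = FALSE]
    acc <- list()
    if (nrow(sub) > 1) {
      for (i in 2:nrow(sub)) {
        row <- sub[i, , drop = FALSE]
        if (row$start <= cur$end) {  # overlap or contiguity at shared bp
          if (!is.na(row$confidence) && !is.na(cur$confidence) &&
              row$confidence > cur$confidence) {
            cur$copy_number <- row$copy_number
            cur$confidence <- row$confidence
          }
          cur$end <- max(cur$end, row$end)
          cur$n_probes <- sum(cur$n_probes, row$n_probes, na.rm = FALSE)
        } else {
          acc[[length(acc) + 1]] <- cur
          cur <- row
        }
      }
    }
    acc[[length(acc) + 1]] <- cur
    out[[length(out) + 1]] <- do.call(rbind, acc)
  }
  res <- do.call(rbind, out)
  res$.dir <- NULL
  res <- res[order(match(res$chromosome, VALID_CHROMOSOMES), res$start), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' @export
print.callset <- function(x, ...) {
  cat(sprintf("callset '%s' for sample '%s': %d call(s)\n",
              x$method, x$sample_id, nrow(x$calls)))
  invisible(x)
}

#' Write a callset as generic TSV
#'
#' Columns: sample, method, chrom, start, end, copy_number, n_probes,
#' confidence. The file round-trips through [parse_generic_calls()] with the
#' default column map.
#'
#' @param cs a [callset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_callset <- function(cs, path) {
  df <- cs$calls
  out <- data.frame(
    sample = rep(cs$sample_id, nrow(df)),
    method = rep(cs$method, nrow(df)),
    chrom = df$chromosome, start = df$start, end = df$end,
    copy_number = df$copy_number, n_probes = df$n_probes,
    confidence = df$confidence, stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
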