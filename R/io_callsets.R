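# Readers for per-caller CNV callsets: QuantiSNP TSV, PennCNV rawcnv text
# and generic column-mapped TSV.

#' Column map for generic callset TSV parsing
#'
#' Maps the semantic fields \{sample, chrom, start, end, copy_number,
#' n_probes, confidence\} onto column names or 1-based column indices of a
#' tab-separated file.
#'
#' @param sample,chrom,start,end,copy_number mandatory column names or
#'   indices.
#' @param n_probes,confidence optional column names or indices (NULL =
#'   absent; `n_probes` is then recomputed from the genome map when one is
#'   supplied, `confidence` defaults to the `Inf` "unfiltered" sentinel).
#' @param header whether the file carries a header row (default TRUE;
#'   required when columns are named).
#' @param chrom_prefix chromosome-prefix convention: "strip" removes a
#'   leading "chr", "keep" leaves names untouched (they are still
#'   normalised internally).
#' @return object of class `column_map`.
#' @export
column_map <- function(sample = "sample", chrom = "chrom", start = "start",
                       end = "end", copy_number = "copy_number",
                       n_probes = "n_probes", confidence = "confidence",
                       header = TRUE, chrom_prefix = c("strip", "keep")) {
  chrom_prefix <- match.arg(chrom_prefix)
  cm <- list(sample = sample, chrom = chrom, start = start, end = end,
             copy_number = copy_number, n_probes = n_probes,
             confidence = confidence, header = header,
             chrom_prefix = chrom_prefix)
  mandatory <- c("sample", "chrom", "start", "end", "copy_number")
  for (f in mandatory) {
    if (is.null(cm[[f]])) stop("column map must resolve mandatory field: ", f)
  }
  structure(cm, class = "column_map")
}

resolve_column <- function(df, spec, field, mandatory = TRUE) {
  if (is.null(spec)) {
    if (mandatory) stop("column map must resolve mandatory field: ", field)
    return(NULL)
  }
  if (is.numeric(spec)) {
    if (spec < 1 || spec > ncol(df)) {
      stop("column index out of range for field '", field, "': ", spec)
    }
    return(df[[as.integer(spec)]])
  }
  if (!spec %in% names(df)) {
    if (mandatory) stop("mandatory column not found: '", spec,
                        "' (field '", field, "')")
    return(NULL)
  }
  df[[spec]]
}

#' Parse a generic column-mapped callset TSV
#'
#' Custom parser for any tab-separated callset: a [column_map()] names (or
#' indexes) the columns holding each semantic field. Missing optional
#' fields are defaulted: `n_probes` recomputed from `map` when given,
#' `confidence` set to the `Inf` "unfiltered" sentinel.
#'
#' @param path file path (gzip accepted).
#' @param cmap a [column_map()].
#' @param map optional [genome_map()] used to recompute probe counts.
#' @param method caller name stored on the callset (default "generic").
#' @param min_confidence optional inclusive confidence cut-off.
#' @return a [callset()]; attribute `n_dropped` counts calls removed by the
#'   confidence filter.
#' @export
parse_generic_calls <- function(path, cmap, map = NULL, method = "generic",
                                min_confidence = NULL) {
  stopifnot(inherits(cmap, "column_map"))
  df <- utils::read.delim(path, header = cmap$header,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0) {
    return(callset(method, sample_id = NA_character_, calls = empty_calls(),
                   confidence_threshold = min_confidence %||% NA_real_))
  }
  sample_id <- as.character(resolve_column(df, cmap$sample, "sample"))
  if (length(unique(sample_id)) > 1) {
    stop("callset file mixes samples: ", paste(unique(sample_id), collapse = ", "))
  }
  chrom <- as.character(resolve_column(df, cmap$chrom, "chrom"))
  if (cmap$chrom_prefix == "strip") chrom <- sub("^chr", "", chrom)
  calls <- data.frame(
    chromosome = chrom,
    start = as.numeric(resolve_column(df, cmap$start, "start")),
    end = as.numeric(resolve_column(df, cmap$end, "end")),
    copy_number = as.integer(resolve_column(df, cmap$copy_number, "copy_number")),
    stringsAsFactors = FALSE
  )
  np <- resolve_column(df, cmap$n_probes, "n_probes", mandatory = FALSE)
  cf <- resolve_column(df, cmap$confidence, "confidence", mandatory = FALSE)
  calls$n_probes <- if (is.null(np)) NA_integer_ else as.integer(np)
  calls$confidence <- if (is.null(cf)) Inf else as.numeric(cf)
  if (is.null(np) && !is.null(map)) {
    calls$n_probes <- mapply(n_probes_in, calls$chromosome, calls$start,
                             calls$end, MoreArgs = list(map = map))
  }
  n_dropped <- 0L
  if (!is.null(min_confidence)) {
    keep <- calls$confidence >= min_confidence
    n_dropped <- sum(!keep)
    calls <- calls[keep, , drop = FALSE]
  }
  cs <- callset(method, sample_id[1], calls,
                confidence_threshold = min_confidence %||% NA_real_)
  attr(cs, "n_dropped") <- n_dropped
  cs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse a QuantiSNP callset
#'
#' QuantiSNP-style TSV with columns for sample, chromosome, start, end,
#' copy number, number of probes and max log Bayes factor. Calls with log
#' Bayes factor below `min_lbf` are dropped (inclusive threshold: a call at
#' exactly `min_lbf` is retained).
#'
#' @param path file path.
#' @param min_lbf minimal log Bayes factor (default 8.5).
#' @return a [callset()] with attribute `n_dropped`.
#' @export
parse_quantisnp_calls <- function(path, min_lbf = 8.5) {
  cmap <- column_map(
    sample = "Sample Name", chrom = "Chromosome", start = "Start Position (bp)",
    end = "End Position (bp)", copy_number = "Copy Number",
    n_probes = "No. Probes", confidence = "Max. Log BF"
  )
  cs <- parse_generic_calls(path, cmap, method = "quantisnp",
                            min_confidence = min_lbf)
  cs
}

#' Parse a PennCNV rawcnv callset
#'
#' PennCNV's rawcnv line dialect:
#' `chrN:start-end numsnp=K length=L state S,cn=C sample startsnp=.. endsnp=.. conf=V`.
#' Calls with confidence below `min_conf` are dropped (inclusive threshold).
#'
#' @param path file path (gzip accepted).
#' @param min_conf minimal confidence (default 10).
#' @param error_budget tolerated malformed lines before the parse fails
#'   (default 0: any malformed line is an error).
#' @return a [callset()] with attribute `n_dropped`.
#' @export
parse_penncnv_calls <- function(path, min_conf = 10, error_budget = 0) {
  lines <- open_text_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  pat <- paste0(
    "^chr([0-9XY]+):([0-9]+)-([0-9]+)\\s+numsnp=([0-9]+)\\s+length=[0-9,]+",
    "\\s+state[0-9]+,cn=([0-9]+)\\s+(\\S+)\\s+startsnp=\\S+\\s+endsnp=\\S+",
    "(?:\\s+conf=([0-9.eE+-]+))?"
  )
  ok <- grepl(pat, lines)
  if (sum(!ok) > error_budget) {
    stop("malformed PennCNV line at line ", which(!ok)[1])
  }
  lines <- lines[ok]
  if (length(lines) == 0) {
    return(callset("penncnv", NA_character_, empty_calls(),
                   confidence_threshold = min_conf))
  }
  m <- regmatches(lines, regexec(pat, lines))
  m <- do.call(rbind, lapply(m, function(x) x[-1]))
  conf <- suppressWarnings(as.numeric(m[, 7]))
  conf[is.na(conf)] <- Inf  # lines without conf= token are kept
  calls <- data.frame(
    chromosome = m[, 1], start = as.numeric(m[, 2]), end = as.numeric(m[, 3]),
    copy_number = as.integer(m[, 5]), n_probes = as.integer(m[, 4]),
    confidence = conf, stringsAsFactors = FALSE
  )
  sample_id <- m[1, 6]
  if (length(unique(m[, 6])) > 1) {
    stop("PennCNV file mixes samples: ", paste(unique(m[, 6]), collapse = ", "))
  }
  keep <- calls$confidence >= min_conf
  cs <- callset("penncnv", sample_id, calls[keep, , drop = FALSE],
                confidence_threshold = min_conf)
  attr(cs, "n_dropped") <- sum(!keep)
  cs
}
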