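#' @keywords internal
"_PACKAGE"

VALID_CHROMOSOMES <- c(as.character(1:22), "X", "Y")
AUTOSOMES <- as.character(1:22)
GENOTYPES <- c("AA", "AB", "BB", "NC")

#' Normalise chromosome names
#'
#' Strips a leading "chr" prefix and validates against the declared
#' chromosome set (1..22, X, Y).
#'
#' @param chrom character vector of chromosome names.
#' @param strict error on names outside the declared set (default TRUE).
#' @return character vector of unprefixed chromosome names.
#' @export
normalize_chromosome <- function(chrom, strict = TRUE) {
  chrom <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  if (strict && length(bad <- setdiff(unique(chrom), VALID_CHROMOSOMES)) > 0) {
    stop("unknown chromosome name(s): ", paste(bad, collapse = ", "))
  }
  chrom
}

#' Build a genome map (probe manifest)
#'
#' The genome map is the ordered probe manifest of the array: one row per
#' probe with its chromosome and 1-based position. All probe-level data
#' (`sample_data`) is aligned to a map, and "consecutive probes" in the
#' consensus vote means consecutive rows of this map.
#'
#' @param probe_id character vector of unique probe identifiers.
#' @param chromosome chromosome per probe (1..22, X, Y; "chr" prefixes are
#'   stripped).
#' @param position 1-based bp position per probe; strictly increasing within
#'   each chromosome.
#' @param is_snp logical; whether the probe carries genotype information
#'   (default TRUE for all probes).
#' @return object of class `genome_map`: a data.frame with columns
#'   `probe_id`, `chromosome`, `position`, `is_snp`, sorted by chromosome
#'   (declared order) then position.
#' @export
genome_map <- function(probe_id, chromosome, position, is_snp = TRUE) {
  chromosome <- normalize_chromosome(chromosome)
  probe_id <- as.character(probe_id)
  position <- as.integer(position)
  is_snp <- rep_len(as.logical(is_snp), length(probe_id))
  if (anyDuplicated(probe_id)) stop("probe_ids must be unique")
  if (any(is.na(position)) || any(position < 1)) {
    stop("positions must be positive integers")
  }
  ord <- order(match(chromosome, VALID_CHROMOSOMES), position)
  map <- data.frame(
    probe_id = probe_id[ord], chromosome = chromosome[ord],
    position = position[ord], is_snp = is_snp[ord],
    stringsAsFactors = FALSE
  )
  for (ch in unique(map$chromosome)) {
    pos <- map$position[map$chromosome == ch]
    if (any(diff(pos) <= 0)) {
      stop("positions must be strictly increasing within chromosome ", ch)
    }
  }
  class(map) <- c("genome_map", "data.frame")
  map
}

#' @export
print.genome_map <- function(x, ...) {
  cat(sprintf(
    "genome_map: %d probes on %d chromosome(s) [%s]\n",
    nrow(x), length(unique(x$chromosome)),
    paste(unique(x$chromosome), collapse = ", ")
  ))
  invisible(x)
}

# Row indices of map probes on `chromosome` with start <= position <= end.
# findInterval on the per-chromosome sorted positions.
probe_indices <- function(map, chromosome, start, end) {
  chromosome <- normalize_chromosome(chromosome)
  rows <- which(map$chromosome == chromosome)
  if (length(rows) == 0) {
    if (!chromosome %in% map$chromosome) stop("chromosome not in map: ", chromosome)
    return(integer(0))
  }
  pos <- map$position[rows]
  lo <- findInterval(start - 1L, pos) + 1L
  hi <- findInterval(end, pos)
  if (lo > hi) return(integer(0))
  rows[lo:hi]
}

#' Count map probes inside an interval
#'
#' @param map a [genome_map()].
#' @param chromosome chromosome name.
#' @param start,end 1-based inclusive interval bounds.
#' @return integer count of probes with `start <= position <= end`.
#' @export
n_probes_in <- function(map, chromosome, start, end) {
  if (start > end) stop("start must be <= end")
  if (!normalize_chromosome(chromosome) %in% map$chromosome) {
    stop("chromosome not in map: ", chromosome)
  }
  length(probe_indices(map, chromosome, start, end))
}

#' Read a genome map from TSV
#'
#' Expects columns `probe_id`, `chromosome`, `position` and optionally
#' `is_snp`. Accepts gzip.
#'
#' @param path file path.
#' @return a [genome_map()].
#' @export
read_genome_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "chromosome", "position")
  if (length(miss <- setdiff(need, names(df))) > 0) {
    stop("genome map file missing column(s): ", paste(miss, collapse = ", "))
  }
  genome_map(df$probe_id, df$chromosome, df$position,
             if ("is_snp" %in% names(df)) df$is_snp else TRUE)
}

#' Write a genome map to TSV
#'
#' @param map a [genome_map()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genome_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
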