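#' Probe-level data for one sample
#'
#' Bundles the per-probe records of one array sample (genotype call,
#' B-allele frequency, log R ratio), aligned row-for-row to a
#' [genome_map()].
#'
#' @param sample_id sample identifier.
#' @param map a [genome_map()].
#' @param genotype character vector in \{AA, AB, BB, NC\}, one per map probe.
#' @param baf numeric B-allele frequencies in \[0, 1\] (NA allowed).
#' @param lrr numeric log2 R ratios (NA allowed).
#' @param gender one of "M", "F", "unknown".
#' @return object of class `sample_data`: a list with elements `sample_id`,
#'   `map`, `genotype`, `baf`, `lrr`, `gender`.
#' @export
sample_data <- function(sample_id, map, genotype, baf, lrr,
                        gender = "unknown") {
  stopifnot(inherits(map, "genome_map"))
  n <- nrow(map)
  genotype <- as.character(genotype)
  if (length(genotype) != n || length(baf) != n || length(lrr) != n) {
    stop("genotype/baf/lrr must have one entry per map probe (", n, ")")
  }
  if (length(bad <- setdiff(unique(genotype), GENOTYPES)) > 0) {
    stop("invalid genotype token(s): ", paste(bad, collapse = ", "))
  }
  if (any(!is.na(baf) & (baf < 0 | baf > 1))) stop("BAF must lie in [0, 1]")
  if (any(is.infinite(lrr))) stop("LRR must be finite or NA")
  gender <- match.arg(gender, c("M", "F", "unknown"))
  structure(
    list(sample_id = as.character(sample_id), map = map,
         genotype = genotype, baf = as.numeric(baf), lrr = as.numeric(lrr),
         gender = gender),
    class = "sample_data"
  )
}

#' @export
print.sample_data <- function(x, ...) {
  cat(sprintf(
    "sample_data '%s': %d probes, call rate %.4f, gender %s\n",
    x$sample_id, nrow(x$map),
    mean(x$genotype[x$map$is_snp] != "NC"), x$gender
  ))
  invisible(x)
}
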