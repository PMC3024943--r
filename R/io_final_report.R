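# Readers/writers for Illumina "Final Report"-style probe-level TSV.

open_text_lines <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

#' Parse an Illumina Final Report into sample data
#'
#' Accepts the sectioned layout (`[Header]` ... `[Data]` followed by a
#' header row) or a plain header-first TSV. Recognised columns: `SNP Name`,
#' `Chr`, `Position`, `GType` (or `Allele1`/`Allele2`), `B Allele Freq`,
#' `Log R Ratio`. Gzip input is accepted.
#'
#' Probes present in the file but absent from the map are counted and
#' reported as the `n_unknown_probes` attribute; map probes absent from the
#' file get NC genotype and NA BAF/LRR.
#'
#' @param path file path.
#' @param map a [genome_map()] to align records to.
#' @param sample_id sample identifier; defaults to the file's `Sample ID`
#'   column when present, else the file name.
#' @param gender "M", "F" or "unknown".
#' @param error_budget maximum tolerated unparseable data rows before the
#'   parse fails (default 100).
#' @return a [sample_data()] with attributes `n_unknown_probes` (file probes
#'   not in the map) and `n_missing_probes` (map probes not in the file).
#' @export
parse_final_report <- function(path, map, sample_id = NULL,
                               gender = "unknown", error_budget = 100) {
  lines <- open_text_lines(path)
  data_at <- which(trimws(lines) == "[Data]")
  if (length(data_at) > 0) {
    lines <- lines[(data_at[1] + 1):length(lines)]
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("final report has no header row")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  find_col <- function(names, mandatory = TRUE) {
    hit <- which(header %in% names)
    if (length(hit) == 0) {
      if (mandatory) stop("final report missing mandatory column: ", names[1])
      return(NA_integer_)
    }
    hit[1]
  }
  i_snp <- find_col(c("SNP Name", "SNP.Name", "probe_id"))
  i_chr <- find_col(c("Chr", "Chromosome"))
  i_pos <- find_col(c("Position", "MapInfo"))
  i_gt <- find_col(c("GType", "Genotype"), mandatory = FALSE)
  i_a1 <- find_col(c("Allele1", "Allele1 - Top", "Allele1 - AB"),
                   mandatory = FALSE)
  i_a2 <- find_col(c("Allele2", "Allele2 - Top", "Allele2 - AB"),
                   mandatory = FALSE)
  if (is.na(i_gt) && (is.na(i_a1) || is.na(i_a2))) {
    stop("final report missing mandatory column: GType (or Allele1/Allele2)")
  }
  i_baf <- find_col(c("B Allele Freq", "B.Allele.Freq", "BAF"))
  i_lrr <- find_col(c("Log R Ratio", "Log.R.Ratio", "LRR"))
  i_sid <- find_col(c("Sample ID", "Sample.ID"), mandatory = FALSE)

  n <- nrow(map)
  genotype <- rep("NC", n)
  baf <- rep(NA_real_, n)
  lrr <- rep(NA_real_, n)
  n_unknown <- 0L
  n_errors <- 0L

  rows <- lines[-1]
  if (length(rows) == 0) {
    warning("final report contains zero data rows")
  } else {
    fields <- strsplit(rows, "\t", fixed = TRUE)
    nf <- lengths(fields)
    need <- max(i_snp, i_chr, i_pos, i_baf, i_lrr,
                i_gt, i_a1, i_a2, na.rm = TRUE)
    bad_rows <- which(nf < need)
    n_errors <- n_errors + length(bad_rows)
    if (n_errors > error_budget) {
      stop("unparseable row at line ", bad_rows[1] + 1,
           ": expected >= ", need, " fields")
    }
    ok <- setdiff(seq_along(fields), bad_rows)
    m <- do.call(rbind, fields[ok])
    pid <- m[, i_snp]
    idx <- match(pid, map$probe_id)
    n_unknown <- sum(is.na(idx))
    keep <- which(!is.na(idx))
    v_baf <- suppressWarnings(as.numeric(m[keep, i_baf]))
    v_lrr <- suppressWarnings(as.numeric(m[keep, i_lrr]))
    bad_num <- which(is.na(v_baf) & m[keep, i_baf] != "NA" &
                       nzchar(m[keep, i_baf]))
    n_errors <- n_errors + length(bad_num)
    if (n_errors > error_budget) {
      stop("unparseable numeric at line ", ok[keep[bad_num[1]]] + 1)
    }
    if (!is.na(i_gt)) {
      gt <- toupper(m[keep, i_gt])
    } else {
      gt <- paste0(toupper(m[keep, i_a1]), toupper(m[keep, i_a2]))
      gt[gt %in% c("BA")] <- "AB"
    }
    gt[!gt %in% c("AA", "AB", "BB")] <- "NC"
    genotype[idx[keep]] <- gt
    baf[idx[keep]] <- pmin(pmax(v_baf, 0), 1)
    lrr[idx[keep]] <- v_lrr
    if (is.null(sample_id) && !is.na(i_sid)) sample_id <- m[1, i_sid]
  }
  if (is.null(sample_id)) sample_id <- basename(path)
  filled <- if (exists("idx", inherits = FALSE)) {
    length(unique(idx[!is.na(idx)]))
  } else 0L
  sd <- sample_data(sample_id, map, genotype, baf, lrr, gender)
  attr(sd, "n_unknown_probes") <- n_unknown
  attr(sd, "n_missing_probes") <- n - filled
  sd
}

#' Write sample data as an Illumina-style Final Report
#'
#' Emits a `[Header]`/`[Data]` sectioned TSV that [parse_final_report()]
#' reads back record-for-record.
#'
#' @param sample a [sample_data()].
#' @param path output path (".gz" suffix writes gzip).
#' @return `path`, invisibly.
#' @export
write_final_report <- function(sample, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(c("[Header]",
               "GSGT Version\tsynthetic",
               paste0("Num SNPs\t", nrow(sample$map)),
               "[Data]"), con)
  df <- data.frame(
    `SNP Name` = sample$map$probe_id,
    `Sample ID` = sample$sample_id,
    Chr = sample$map$chromosome,
    Position = sample$map$position,
    GType = sample$genotype,
    `B Allele Freq` = formatC(sample$baf, digits = 6, format = "f"),
    `Log R Ratio` = formatC(sample$lrr, digits = 6, format = "f"),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
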