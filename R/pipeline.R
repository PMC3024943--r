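# File-based pipeline orchestration: parse -> QC -> (mosaicism) ->
# consensus -> trio analytics -> annotate -> report. Outputs land in a run
# directory with a manifest (file list + md5 hashes) providing provenance;
# a run is reproducible bit-for-bit from the same inputs and seed.

#' Run the full analysis pipeline
#'
#' Stages, in order: read the genome map and probe-level final reports;
#' per-sample QC (with GC-wave correction when a GC track is given); BAF
#' segmentation on QC-flagged chromosomes (or everywhere with
#' `all_baf = TRUE`); majority-vote consensus over the per-caller
#' callsets; trio analytics (UPD, non-paternity, inheritance, parent of
#' origin) when a pedigree is given; annotation against supplied tracks;
#' report emission. Stages whose inputs are absent are skipped.
#'
#' @param map a [genome_map()] or path to a genome-map TSV.
#' @param samples named list: sample_id -> [sample_data()] or final-report
#'   path.
#' @param callsets named list: sample_id -> list of [callset()]s.
#' @param pedigree optional data.frame with columns `sample_id`,
#'   `father_id`, `mother_id` designating trios among `samples`.
#' @param tracks optional list of [annotation_track()]s.
#' @param cytobands optional cytoband data.frame ([read_cytoband()]).
#' @param gc_track optional GC track ([read_gc_track()]).
#' @param out_dir output directory (created if missing).
#' @param vote a [vote_config()].
#' @param thresholds a [qc_thresholds()].
#' @param baf_config a [baf_seg_config()].
#' @param trio_cfg a [trio_config()].
#' @param all_baf run BAF segmentation on every chromosome, not only
#'   QC-flagged ones.
#' @return invisible list with `manifest` (data.frame: file, md5) and the
#'   per-sample results.
#' @export
run_pipeline <- function(map, samples, callsets = list(), pedigree = NULL,
                         tracks = list(), cytobands = NULL, gc_track = NULL,
                         out_dir = "arraycnv_run", vote = vote_config(),
                         thresholds = qc_thresholds(),
                         baf_config = baf_seg_config(),
                         trio_cfg = trio_config(), all_baf = FALSE) {
  if (is.character(map)) map <- read_genome_map(map)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  samples <- lapply(samples, function(s) {
    if (is.character(s)) parse_final_report(s, map) else s
  })
  results <- list()
  files <- character(0)

  for (sid in names(samples)) {
    smp <- samples[[sid]]
    res <- list()

    # --- QC + mosaicism trigger
    qc <- compute_qc(smp, thresholds, gc_track = gc_track)
    if (!is.null(gc_track)) smp <- gc_wave_correct(smp, gc_track)$sample
    res$qc <- qc
    qc_path <- file.path(out_dir, paste0(sid, ".qc.json"))
    jsonlite::write_json(
      list(sample_id = qc$sample_id, call_rate = qc$call_rate,
           lrr_sd = qc$lrr_sd, baf_sd = qc$baf_sd,
           wave_factor = qc$wave_factor, pass = as.list(qc$pass),
           pass_all = qc$pass_all,
           mosaic_flagged_chromosomes = qc$mosaic_flagged_chromosomes),
      qc_path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
    files <- c(files, qc_path)

    # --- BAF segmentation on flagged chromosomes
    baf_chroms <- if (all_baf) unique(map$chromosome) else
      qc$mosaic_flagged_chromosomes
    if (length(baf_chroms) > 0) {
      ai <- segment_sample_baf(smp, baf_chroms, baf_config)
      res$ai_segments <- ai
      ai_path <- file.path(out_dir, paste0(sid, ".ai_segments.tsv"))
      utils::write.table(as.data.frame(ai), ai_path, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      files <- c(files, ai_path)
    }

    # --- consensus voting
    if (!is.null(callsets[[sid]]) && length(callsets[[sid]]) > 0) {
      cons <- vote_consensus(callsets[[sid]], map, vote)
      res$consensus <- cons
      cons_path <- file.path(out_dir, paste0(sid, ".consensus.tsv"))
      utils::write.table(as.data.frame(cons), cons_path, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      files <- c(files, cons_path)
    }
    results[[sid]] <- res
  }

  # --- trio analytics
  if (!is.null(pedigree)) {
    for (i in seq_len(nrow(pedigree))) {
      cid <- pedigree$sample_id[i]
      fid <- pedigree$father_id[i]
      mid <- pedigree$mother_id[i]
      if (!all(c(cid, fid, mid) %in% names(samples))) next
      tri <- trio(samples[[cid]], samples[[fid]], samples[[mid]])
      upd <- detect_upd(tri, trio_cfg,
                        consensus = results[[cid]]$consensus)
      np <- detect_nonpaternity(tri, trio_cfg)
      results[[cid]]$upd <- upd
      results[[cid]]$nonpaternity <- np
      upd_path <- file.path(out_dir, paste0(cid, ".upd.tsv"))
      utils::write.table(as.data.frame(upd), upd_path, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      files <- c(files, upd_path)
      if (!is.null(results[[cid]]$consensus)) {
        cons <- annotate_inheritance(results[[cid]]$consensus,
                                     results[[fid]]$consensus,
                                     results[[mid]]$consensus, trio_cfg)
        poo <- rep(NA_character_, nrow(cons))
        for (j in which(cons$inheritance == "de_novo")) {
          poo[j] <- parent_of_origin(tri, cons[j, ], trio_cfg)$origin
        }
        cons$parent_of_origin <- poo
        results[[cid]]$consensus <- cons
      }
    }
  }

  # --- annotation, BED export and reports
  for (sid in names(samples)) {
    cons <- results[[sid]]$consensus
    if (!is.null(cons)) {
      for (trk in tracks) cons <- overlap_annotate(cons, trk)
      results[[sid]]$consensus <- cons
      bed_path <- file.path(out_dir, paste0(sid, ".regions.bed"))
      if (!is.null(cytobands) && nrow(cons) > 0) {
        cons$iscn <- vapply(seq_len(nrow(cons)), function(i) {
          iscn_string(cons[i, ], cytobands,
                      inheritance = cons$inheritance[i] %||% NULL)
        }, character(1))
      }
      write_bed(cons, bed_path)
      files <- c(files, bed_path)
    }
    rep <- build_report(sid, qc = results[[sid]]$qc,
                        regions = results[[sid]]$consensus,
                        ai_segments = results[[sid]]$ai_segments,
                        upd = results[[sid]]$upd,
                        nonpaternity = results[[sid]]$nonpaternity,
                        cytobands = cytobands)
    rep_path <- file.path(out_dir, paste0(sid, ".report.json"))
    write_report(rep, rep_path)
    files <- c(files, rep_path)
  }

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  rownames(manifest) <- NULL
  man_path <- file.path(out_dir, "manifest.tsv")
  utils::write.table(manifest, man_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(manifest = manifest, results = results))
}
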