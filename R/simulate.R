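# Seeded generator of probe-level SNP-array data, trios and caller
# callsets with planted truth. The dosage model is deliberately analytic:
# with a fraction p of cells carrying an event of copy number cn, the
# effective copy number is n_eff = (1-p)*2 + p*cn, LRR ~ Normal(log2(
# n_eff/2), lrr_sigma) (copy 0 floored at -5), and BAF ~ Normal(b_eff /
# n_eff, baf_sigma) clipped to [0, 1], where b_eff is the mixture B-allele
# dosage. Genotype calls are re-derived from the noiseless dosage, so a
# hemizygous deletion reads as a homozygous call, as on a real array.

#' Simulation configuration
#'
#' The default genome is desk-scale: 2 autosomes of 5,000 probes at 10 kb
#' spacing. Per-probe B-allele population frequencies are drawn from
#' Uniform(0.05, 0.95) (seeded with the config) so that
#' opposite-homozygote, trio-informative SNPs are common.
#'
#' @param n_chromosomes number of autosomes (default 2; chromosomes are
#'   named "1", "2", ...).
#' @param probes_per_chromosome probes per chromosome (default 5000).
#' @param spacing probe spacing in bp (default 1e4).
#' @param baf_sigma BAF noise SD (default 0.03).
#' @param lrr_sigma LRR noise SD (default 0.15).
#' @param nocall_rate fraction of SNPs set to NC (default 0.005).
#' @param genotype_error_rate fraction of called genotypes replaced by a
#'   random different call (default 0).
#' @param seed integer seed; fixes the probe allele frequencies and, via
#'   [simulate_sample()] etc., all draws.
#' @return object of class `sim_config` with elements `map` (a
#'   [genome_map()]), `allele_freq` (per-probe B frequency) and the noise
#'   parameters.
#' @export
sim_config <- function(n_chromosomes = 2, probes_per_chromosome = 5000,
                       spacing = 1e4, baf_sigma = 0.03, lrr_sigma = 0.15,
                       nocall_rate = 0.005, genotype_error_rate = 0,
                       seed = 1) {
  stopifnot(n_chromosomes >= 1, n_chromosomes <= 22,
            probes_per_chromosome >= 1,
            nocall_rate >= 0, nocall_rate <= 1,
            genotype_error_rate >= 0, genotype_error_rate <= 1)
  n <- n_chromosomes * probes_per_chromosome
  map <- genome_map(
    probe_id = sprintf("snp_%06d", seq_len(n)),
    chromosome = rep(as.character(seq_len(n_chromosomes)),
                     each = probes_per_chromosome),
    position = rep(seq_len(probes_per_chromosome) * spacing,
                   times = n_chromosomes),
    is_snp = TRUE
  )
  set.seed(seed)
  structure(list(map = map,
                 allele_freq = stats::runif(n, 0.05, 0.95),
                 baf_sigma = baf_sigma, lrr_sigma = lrr_sigma,
                 nocall_rate = nocall_rate,
                 genotype_error_rate = genotype_error_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Planted-event table
#'
#' @param type event type(s): "del", "dup", "mosaic_del", "mosaic_dup",
#'   "cnn_loh", "upd_iso", "upd_het".
#' @param chromosome,start,end event locus (1-based inclusive bp).
#' @param fraction cell fraction carrying the event (default 1; mosaic
#'   types use values < 1).
#' @param parent for UPD events: "paternal" or "maternal".
#' @return data.frame of planted events.
#' @export
sim_events <- function(type, chromosome, start, end, fraction = 1,
                       parent = NA_character_) {
  df <- data.frame(type = type, chromosome = as.character(chromosome),
                   start = start, end = end, fraction = fraction,
                   parent = parent, stringsAsFactors = FALSE)
  valid <- c("del", "dup", "mosaic_del", "mosaic_dup", "cnn_loh",
             "upd_iso", "upd_het")
  if (length(bad <- setdiff(df$type, valid)) > 0) {
    stop("unknown event type(s): ", paste(bad, collapse = ", "))
  }
  if (any(df$fraction < 0 | df$fraction > 1)) {
    stop("event fractions must lie in [0, 1]")
  }
  df
}

event_cn <- function(type) {
  c(del = 1, dup = 3, mosaic_del = 1, mosaic_dup = 3, cnn_loh = 2,
    upd_iso = 2, upd_het = 2)[type]
}

check_events <- function(events, map) {
  if (is.null(events) || nrow(events) == 0) return(invisible(NULL))
  for (ch in unique(events$chromosome)) {
    ev <- events[events$chromosome == ch, , drop = FALSE]
    ev <- ev[order(ev$start), , drop = FALSE]
    if (nrow(ev) > 1 && any(ev$start[-1] <= ev$end[-nrow(ev)])) {
      stop("planted events overlap on chromosome ", ch)
    }
    if (!ch %in% map$chromosome) stop("event chromosome not in map: ", ch)
  }
  invisible(NULL)
}

# Build noisy records from a pair of haplotype B-indicator vectors plus
# copy-number events. Returns genotype/baf/lrr plus the truth spans.
build_records <- function(config, h1, h2, events) {
  map <- config$map
  n <- nrow(map)
  p_frac <- rep(0, n)      # cell fraction carrying the event at each probe
  cn_ev <- rep(2, n)       # event copy number
  b_aff <- h1 + h2         # B dosage in affected cells
  truth_rows <- list()
  cn_types <- c("del", "dup", "mosaic_del", "mosaic_dup", "cnn_loh")
  if (!is.null(events) && nrow(events) > 0) {
    for (i in seq_len(nrow(events))) {
      ev <- events[i, ]
      if (!ev$type %in% cn_types) next
      idx <- probe_indices(map, ev$chromosome, ev$start, ev$end)
      if (length(idx) == 0) next
      p_frac[idx] <- ev$fraction
      cn_ev[idx] <- event_cn(ev$type)
      # which haplotype the event acts on: first one, deterministically
      b_aff[idx] <- switch(ev$type,
        del = , mosaic_del = h2[idx],            # haplotype 1 lost
        dup = , mosaic_dup = 2 * h1[idx] + h2[idx],  # haplotype 1 doubled
        cnn_loh = 2 * h1[idx]                    # haplotype 1 doubled, 2 lost
      )
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        type = ev$type, chromosome = ev$chromosome,
        start = ev$start, end = ev$end, fraction = ev$fraction,
        first_probe = idx[1], last_probe = idx[length(idx)],
        n_probes = length(idx), stringsAsFactors = FALSE
      )
    }
  }
  n_eff <- (1 - p_frac) * 2 + p_frac * cn_ev
  b_eff <- (1 - p_frac) * (h1 + h2) + p_frac * b_aff
  theta <- ifelse(n_eff > 0, b_eff / n_eff, 0.5)
  lrr_mean <- ifelse(n_eff > 0, log2(n_eff / 2), -5)
  baf <- pmin(pmax(stats::rnorm(n, theta, config$baf_sigma), 0), 1)
  lrr <- stats::rnorm(n, lrr_mean, config$lrr_sigma)
  genotype <- ifelse(theta < 0.25, "AA", ifelse(theta > 0.75, "BB", "AB"))
  if (config$genotype_error_rate > 0) {
    err <- stats::runif(n) < config$genotype_error_rate
    if (any(err)) {
      genotype[err] <- vapply(genotype[err], function(g) {
        sample(setdiff(c("AA", "AB", "BB"), g), 1)
      }, character(1))
    }
  }
  if (config$nocall_rate > 0) {
    genotype[stats::runif(n) < config$nocall_rate] <- "NC"
  }
  list(genotype = genotype, baf = baf, lrr = lrr,
       truth = if (length(truth_rows) > 0) do.call(rbind, truth_rows) else
         NULL)
}

#' Simulate one sample with planted events
#'
#' Haplotypes are drawn per probe from the config's allele frequencies
#' (Hardy-Weinberg); planted events perturb LRR/BAF through the mixture
#' dosage model described in the package overview. Fully reproducible from
#' `seed`.
#'
#' @param config a [sim_config()].
#' @param events optional [sim_events()] table (copy-number and LOH types).
#' @param sample_id sample identifier.
#' @param seed integer seed for this sample's draws.
#' @param gender "M", "F" or "unknown".
#' @return list with `sample` (a [sample_data()]) and `truth` (planted
#'   events with probe spans, NULL when none).
#' @export
simulate_sample <- function(config, events = NULL, sample_id = "sim1",
                            seed = config$seed, gender = "unknown") {
  check_events(events, config$map)
  set.seed(seed)
  n <- nrow(config$map)
  h1 <- as.integer(stats::runif(n) < config$allele_freq)
  h2 <- as.integer(stats::runif(n) < config$allele_freq)
  rec <- build_records(config, h1, h2, events)
  list(
    sample = sample_data(sample_id, config$map, rec$genotype, rec$baf,
                         rec$lrr, gender),
    truth = rec$truth,
    haplotypes = cbind(h1 = h1, h2 = h2)
  )
}

#' Simulate a father/mother/child trio
#'
#' Parents are drawn independently from the config's allele frequencies;
#' the child receives one recorded haplotype per chromosome from each
#' parent (Mendelian transmission, no recombination). Planted `upd_iso`
#' events replace both child homologs with one chosen homolog of the named
#' parent; `upd_het` events with both homologs of that parent. De novo
#' copy-number events in `child_events` are applied to the child only.
#' With `nonpaternity = TRUE` the child's paternal haplotypes come from an
#' unrelated male while the stated father's data is returned in the trio.
#'
#' @param config a [sim_config()].
#' @param child_events optional [sim_events()] table for the child
#'   (copy-number types plus `upd_iso`/`upd_het` with a `parent`).
#' @param nonpaternity simulate a non-biological stated father.
#' @param seed integer seed.
#' @return list with `trio` (a [trio()]), `truth` (child events with probe
#'   spans) and `transmission` (per-chromosome transmitted haplotype of
#'   each parent).
#' @export
simulate_trio <- function(config, child_events = NULL, nonpaternity = FALSE,
                          seed = config$seed) {
  check_events(child_events, config$map)
  set.seed(seed)
  map <- config$map
  n <- nrow(map)
  draw_hap <- function() as.integer(stats::runif(n) < config$allele_freq)
  f1 <- draw_hap(); f2 <- draw_hap()
  m1 <- draw_hap(); m2 <- draw_hap()
  bio_f1 <- f1; bio_f2 <- f2
  if (nonpaternity) {
    bio_f1 <- draw_hap(); bio_f2 <- draw_hap()
  }
  chroms <- unique(map$chromosome)
  t_f <- stats::setNames(sample(1:2, length(chroms), replace = TRUE), chroms)
  t_m <- stats::setNames(sample(1:2, length(chroms), replace = TRUE), chroms)
  ch_idx <- match(map$chromosome, chroms)
  c_pat <- ifelse(t_f[ch_idx] == 1, bio_f1, bio_f2)
  c_mat <- ifelse(t_m[ch_idx] == 1, m1, m2)

  upd_truth <- NULL
  if (!is.null(child_events) && nrow(child_events) > 0) {
    upd <- child_events[child_events$type %in% c("upd_iso", "upd_het"), ,
                        drop = FALSE]
    for (i in seq_len(nrow(upd))) {
      ev <- upd[i, ]
      if (!ev$parent %in% c("paternal", "maternal")) {
        stop("UPD events need parent 'paternal' or 'maternal'")
      }
      idx <- probe_indices(map, ev$chromosome, ev$start, ev$end)
      if (length(idx) == 0) next
      if (ev$parent == "paternal") {
        if (ev$type == "upd_iso") {
          c_pat[idx] <- f1[idx]; c_mat[idx] <- f1[idx]
        } else {
          c_pat[idx] <- f1[idx]; c_mat[idx] <- f2[idx]
        }
      } else {
        if (ev$type == "upd_iso") {
          c_pat[idx] <- m1[idx]; c_mat[idx] <- m1[idx]
        } else {
          c_pat[idx] <- m1[idx]; c_mat[idx] <- m2[idx]
        }
      }
      upd_truth <- rbind(upd_truth, data.frame(
        type = ev$type, chromosome = ev$chromosome, start = ev$start,
        end = ev$end, fraction = 1, parent = ev$parent,
        first_probe = idx[1], last_probe = idx[length(idx)],
        n_probes = length(idx), stringsAsFactors = FALSE
      ))
    }
  }
  cn_events <- if (!is.null(child_events)) {
    child_events[!child_events$type %in% c("upd_iso", "upd_het"), ,
                 drop = FALSE]
  } else NULL

  rec_f <- build_records(config, f1, f2, NULL)
  rec_m <- build_records(config, m1, m2, NULL)
  rec_c <- build_records(config, c_pat, c_mat, cn_events)
  tri <- trio(
    child = sample_data("child", map, rec_c$genotype, rec_c$baf, rec_c$lrr),
    father = sample_data("father", map, rec_f$genotype, rec_f$baf,
                         rec_f$lrr, gender = "M"),
    mother = sample_data("mother", map, rec_m$genotype, rec_m$baf,
                         rec_m$lrr, gender = "F")
  )
  truth <- rec_c$truth
  if (!is.null(upd_truth)) {
    if (is.null(truth)) {
      truth <- upd_truth
    } else {
      truth$parent <- NA_character_
      truth <- rbind(truth[, names(upd_truth)], upd_truth)
    }
  }
  list(trio = tri, truth = truth,
       transmission = list(father = t_f, mother = t_m),
       nonpaternity = nonpaternity)
}

#' Simulate per-caller callsets from planted truth
#'
#' Each full copy-number truth event (del/dup) is emitted by each caller
#' independently with that caller's sensitivity, with endpoints jittered
#' by up to `boundary_jitter_probes` probes; false calls are placed
#' uniformly on event-free territory. Deterministic per seed.
#'
#' @param truth truth table from [simulate_sample()]/[simulate_trio()]
#'   (uses types "del" and "dup").
#' @param map the [genome_map()] the truth refers to.
#' @param profiles named list per caller:
#'   `list(sensitivity =, fp_rate_per_genome =, boundary_jitter_probes =)`.
#' @param sample_id sample identifier stored on the callsets.
#' @param seed integer seed.
#' @param fp_n_probes probe span of false calls (default 5).
#' @return list of [callset()]s, one per profile entry.
#' @export
simulate_callsets <- function(truth, map, profiles, sample_id = "sim1",
                              seed = 1, fp_n_probes = 5) {
  set.seed(seed)
  events <- if (!is.null(truth)) {
    truth[truth$type %in% c("del", "dup"), , drop = FALSE]
  } else NULL
  out <- list()
  for (method in names(profiles)) {
    pr <- profiles[[method]]
    jit <- pr$boundary_jitter_probes %||% 0
    calls <- list()
    for (i in seq_len(if (is.null(events)) 0 else nrow(events))) {
      ev <- events[i, ]
      if (stats::runif(1) > pr$sensitivity) next
      rows <- which(map$chromosome == ev$chromosome)
      first <- ev$first_probe; last <- ev$last_probe
      if (jit > 0) {
        first <- first + sample(-jit:jit, 1)
        last <- last + sample(-jit:jit, 1)
      }
      first <- max(first, rows[1]); last <- min(last, rows[length(rows)])
      if (first > last) next
      calls[[length(calls) + 1]] <- data.frame(
        chromosome = ev$chromosome,
        start = map$position[first], end = map$position[last],
        copy_number = if (ev$type == "del") 1L else 3L,
        n_probes = last - first + 1L, confidence = 100,
        stringsAsFactors = FALSE
      )
    }
    n_fp <- stats::rpois(1, pr$fp_rate_per_genome %||% 0)
    if (n_fp > 0) {
      in_event <- rep(FALSE, nrow(map))
      for (i in seq_len(if (is.null(events)) 0 else nrow(events))) {
        in_event[events$first_probe[i]:events$last_probe[i]] <- TRUE
      }
      free <- which(!in_event)
      free <- free[free + fp_n_probes - 1 <= nrow(map)]
      for (k in seq_len(n_fp)) {
        first <- sample(free, 1)
        last <- first + fp_n_probes - 1L
        if (map$chromosome[first] != map$chromosome[last]) next
        if (any(in_event[first:last])) next
        calls[[length(calls) + 1]] <- data.frame(
          chromosome = map$chromosome[first],
          start = map$position[first], end = map$position[last],
          copy_number = sample(c(1L, 3L), 1),
          n_probes = fp_n_probes, confidence = 100,
          stringsAsFactors = FALSE
        )
      }
    }
    out[[method]] <- callset(
      method, sample_id,
      if (length(calls) > 0) do.call(rbind, calls) else empty_calls()
    )
  }
  out
}
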