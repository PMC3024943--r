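# Trio genotype analytics: per-SNP inheritance-model classification,
# uniparental-disomy detection with iso/hetero subtyping, non-paternity
# screening, inheritance annotation of CNVs, and parent of origin of de
# novo events.
#
# Seven transmission models are tested for every (father, mother, child)
# genotype triple: biparental (one allele from each parent), paternal and
# maternal iso-UPD (one homolog of one parent doubled), paternal and
# maternal hetero-UPD (both homologs of one parent), and maternal/paternal
# deletion (hemizygous child whose single allele — read by the array as a
# homozygous call — comes from the other parent).

TRIO_STATES <- c("CONSISTENT", "P_UPD_OR_MAT_DEL", "M_UPD_OR_PAT_DEL",
                 "P_ISO_ONLY", "M_ISO_ONLY", "DOUBLE_INCONSISTENT",
                 "UNINFORMATIVE_NC")

# B-allele count of a genotype; NC -> NA.
gt_b <- function(gt) c(AA = 0L, AB = 1L, BB = 2L, NC = NA_integer_)[gt]

classify_one <- function(f, m, c) {
  bf <- gt_b(f); bm <- gt_b(m); bc <- gt_b(c)
  if (any(is.na(c(bf, bm, bc)))) return("UNINFORMATIVE_NC")
  hasA_f <- bf <= 1L; hasB_f <- bf >= 1L
  hasA_m <- bm <= 1L; hasB_m <- bm >= 1L
  biparental <- switch(as.character(bc),
    "0" = hasA_f && hasA_m,
    "1" = (hasA_f && hasB_m) || (hasB_f && hasA_m),
    "2" = hasB_f && hasB_m
  )
  if (biparental) return("CONSISTENT")
  child_hom <- bc != 1L
  allele_in_f <- if (bc == 2L) hasB_f else hasA_f  # only used when hom
  allele_in_m <- if (bc == 2L) hasB_m else hasA_m
  p_iso <- child_hom && allele_in_f   # also the maternal-deletion signature
  p_het <- bc == bf                   # child carries both paternal homologs
  m_iso <- child_hom && allele_in_m   # also the paternal-deletion signature
  m_het <- bc == bm
  p_fit <- p_iso || p_het
  m_fit <- m_iso || m_het
  if (p_fit && !m_fit) return(if (p_het) "P_UPD_OR_MAT_DEL" else "P_ISO_ONLY")
  if (m_fit && !p_fit) return(if (m_het) "M_UPD_OR_PAT_DEL" else "M_ISO_ONLY")
  if (!p_fit && !m_fit) return("DOUBLE_INCONSISTENT")
  # both sides fitting with biparental excluded cannot occur for biallelic
  # genotypes; guard anyway
  "DOUBLE_INCONSISTENT"
}

# 4^3 lookup table (genotype order AA, AB, BB, NC), built once at load.
build_state_lookup <- function() {
  arr <- array(NA_character_, dim = c(4, 4, 4),
               dimnames = list(GENOTYPES, GENOTYPES, GENOTYPES))
  for (f in GENOTYPES) for (m in GENOTYPES) for (c in GENOTYPES) {
    arr[f, m, c] <- classify_one(f, m, c)
  }
  arr
}
.trio_state_lookup <- build_state_lookup()

#' Classify a trio genotype triple against inheritance models
#'
#' Tests the seven transmission models (see the module description) and
#' reduces the fitting set to one state: `CONSISTENT` when biparental
#' transmission can produce the child genotype; `P_UPD_OR_MAT_DEL` /
#' `M_UPD_OR_PAT_DEL` when only that parent's UPD (or the complementary
#' deletion) models fit; `P_ISO_ONLY` / `M_ISO_ONLY` when additionally the
#' hetero-UPD model is excluded; `DOUBLE_INCONSISTENT` when no model fits;
#' `UNINFORMATIVE_NC` when any genotype is NC. Vectorised.
#'
#' @param father_gt,mother_gt,child_gt genotype vectors over
#'   \{AA, AB, BB, NC\}.
#' @return character vector of states.
#' @export
classify_snp <- function(father_gt, mother_gt, child_gt) {
  gts <- c(father_gt, mother_gt, child_gt)
  if (length(bad <- setdiff(unique(gts), GENOTYPES)) > 0) {
    stop("invalid genotype token(s): ", paste(bad, collapse = ", "))
  }
  .trio_state_lookup[cbind(father_gt, mother_gt, child_gt)]
}

#' Full 27-triple classification table
#'
#' @return data.frame of all 3^3 non-NC genotype triples with their state
#'   and the comma-joined set of fitting transmission models.
#' @export
classification_table <- function() {
  gts <- c("AA", "AB", "BB")
  grid <- expand.grid(father = gts, mother = gts, child = gts,
                      stringsAsFactors = FALSE)
  grid$state <- classify_snp(grid$father, grid$mother, grid$child)
  grid$models <- vapply(seq_len(nrow(grid)), function(i) {
    paste(fitting_models(grid$father[i], grid$mother[i], grid$child[i]),
          collapse = ",")
  }, character(1))
  grid
}

# Names of the transmission models that produce the child genotype.
fitting_models <- function(f, m, c) {
  bf <- gt_b(f); bm <- gt_b(m); bc <- gt_b(c)
  hasA_f <- bf <= 1L; hasB_f <- bf >= 1L
  hasA_m <- bm <= 1L; hasB_m <- bm >= 1L
  child_hom <- bc != 1L
  allele_in_f <- if (bc == 2L) hasB_f else hasA_f
  allele_in_m <- if (bc == 2L) hasB_m else hasA_m
  models <- character(0)
  bip <- switch(as.character(bc),
    "0" = hasA_f && hasA_m,
    "1" = (hasA_f && hasB_m) || (hasB_f && hasA_m),
    "2" = hasB_f && hasB_m
  )
  if (bip) models <- c(models, "biparental")
  if (child_hom && allele_in_f) models <- c(models, "paternal_iso_upd",
                                            "maternal_deletion")
  if (bc == bf) models <- c(models, "paternal_hetero_upd")
  if (child_hom && allele_in_m) models <- c(models, "maternal_iso_upd",
                                            "paternal_deletion")
  if (bc == bm) models <- c(models, "maternal_hetero_upd")
  models
}

#' Trio container
#'
#' @param child,father,mother [sample_data()] objects on the same
#'   [genome_map()], with distinct sample ids.
#' @return object of class `trio`.
#' @export
trio <- function(child, father, mother) {
  if (!identical(child$map$probe_id, father$map$probe_id) ||
      !identical(child$map$probe_id, mother$map$probe_id)) {
    stop("trio members must share one genome map")
  }
  ids <- c(child$sample_id, father$sample_id, mother$sample_id)
  if (anyDuplicated(ids)) stop("trio members must have distinct sample ids")
  structure(list(child = child, father = father, mother = mother),
            class = "trio")
}

#' Trio analytics configuration
#'
#' @param min_run minimum informative states in a UPD run (default 10).
#' @param max_opposing_fraction tolerated fraction of opposing-direction
#'   states within a run (default 0.05).
#' @param nonpaternity_mi_rate per-chromosome paternal-exclusion rate above
#'   which a chromosome counts toward the non-paternity flag (default 0.02).
#' @param nonpaternity_min_chromosomes autosome count required for the flag
#'   (default 20; genome-wide scatter, not clustering, marks non-paternity).
#' @param poo_min_informative minimum informative SNPs for a
#'   parent-of-origin verdict (default 2).
#' @param poo_min_concordance minimum vote concordance for a verdict
#'   (default 0.9).
#' @param inheritance_reciprocal_overlap reciprocal-overlap fraction for
#'   calling a child CNV inherited (default 0.5).
#' @param lrr_del_max UPD runs with mean child LRR below this are treated
#'   as deletions and excluded (default -0.1).
#' @return object of class `trio_config`.
#' @export
trio_config <- function(min_run = 10, max_opposing_fraction = 0.05,
                        nonpaternity_mi_rate = 0.02,
                        nonpaternity_min_chromosomes = 20,
                        poo_min_informative = 2, poo_min_concordance = 0.9,
                        inheritance_reciprocal_overlap = 0.5,
                        lrr_del_max = -0.1) {
  stopifnot(min_run >= 1, max_opposing_fraction >= 0,
            max_opposing_fraction < 1, nonpaternity_mi_rate > 0,
            poo_min_informative >= 1, poo_min_concordance > 0.5,
            poo_min_concordance <= 1, inheritance_reciprocal_overlap > 0,
            inheritance_reciprocal_overlap <= 1)
  structure(list(min_run = as.integer(min_run),
                 max_opposing_fraction = max_opposing_fraction,
                 nonpaternity_mi_rate = nonpaternity_mi_rate,
                 nonpaternity_min_chromosomes =
                   as.integer(nonpaternity_min_chromosomes),
                 poo_min_informative = as.integer(poo_min_informative),
                 poo_min_concordance = poo_min_concordance,
                 inheritance_reciprocal_overlap =
                   inheritance_reciprocal_overlap,
                 lrr_del_max = lrr_del_max),
            class = "trio_config")
}

#' Per-SNP trio states for a whole trio
#'
#' @param x a [trio()].
#' @return character vector of states, one per map probe (non-SNP probes
#'   get `UNINFORMATIVE_NC`).
#' @export
classify_trio <- function(x) {
  states <- classify_snp(x$father$genotype, x$mother$genotype,
                         x$child$genotype)
  states[!x$child$map$is_snp] <- "UNINFORMATIVE_NC"
  states
}

P_STATES <- c("P_UPD_OR_MAT_DEL", "P_ISO_ONLY")
M_STATES <- c("M_UPD_OR_PAT_DEL", "M_ISO_ONLY")

#' Detect uniparental-disomy regions in a trio
#'
#' Scans each autosome for maximal runs of informative trio states of one
#' parental direction (paternal-disomy signatures `P_*`, maternal `M_*`),
#' merging across opposing states while the opposing fraction stays within
#' `max_opposing_fraction`, and keeps runs with at least `min_run`
#' informative states. Runs that look like deletions — mean child LRR below
#' `lrr_del_max`, or overlap with a supplied consensus loss region — are
#' excluded. Subtype: `isodisomy` when the child is homozygous at >= 98% of
#' the run's SNPs and no informative SNP requires heterodisomy;
#' `heterodisomy` when child heterozygosity is retained (>= 90%) at run
#' SNPs where the transmitting parent is heterozygous; otherwise `mixed`.
#' The run's p-value is the binomial tail probability of seeing that many
#' informative states in the run's SNP span given the genome-wide
#' informative rate.
#'
#' @param x a [trio()].
#' @param config a [trio_config()].
#' @param consensus optional `consensus_regions` of the child; loss regions
#'   overlapping a run veto it.
#' @return data.frame of class `upd_events`: `chromosome`, `start`, `end`,
#'   `parent`, `subtype`, `n_informative`, `n_opposing`, `p_value`.
#' @export
detect_upd <- function(x, config = trio_config(), consensus = NULL) {
  map <- x$child$map
  states <- classify_trio(x)
  autos <- map$chromosome %in% AUTOSOMES
  informative <- states %in% c(P_STATES, M_STATES)
  n_classified <- sum(autos & !states %in% "UNINFORMATIVE_NC")
  rate <- if (n_classified > 0) {
    sum(informative & autos) / n_classified
  } else 0

  out <- list()
  for (ch in intersect(unique(map$chromosome), AUTOSOMES)) {
    rows <- which(map$chromosome == ch)
    inf_rows <- rows[informative[rows]]
    if (length(inf_rows) < config$min_run) next
    dir <- ifelse(states[inf_rows] %in% P_STATES, 1L, -1L)
    for (run in direction_runs(dir, config$max_opposing_fraction)) {
      r_rows <- inf_rows[run$idx]
      n_inf <- run$n_same
      if (n_inf < config$min_run) next
      span <- rows[rows >= r_rows[1] & rows <= r_rows[length(r_rows)]]
      mean_lrr <- mean(x$child$lrr[span], na.rm = TRUE)
      if (!is.na(mean_lrr) && mean_lrr < config$lrr_del_max) next
      start <- map$position[r_rows[1]]
      end <- map$position[r_rows[length(r_rows)]]
      if (!is.null(consensus) && nrow(consensus) > 0) {
        hit <- consensus$direction == "loss" &
          consensus$chromosome == ch &
          consensus$start <= end & consensus$end >= start
        if (any(hit)) next
      }
      parent <- if (run$dir > 0) "paternal" else "maternal"
      subtype <- upd_subtype(x, span, r_rows[states[r_rows] %in%
                               (if (run$dir > 0) P_STATES else M_STATES)],
                             parent)
      n_span_cl <- sum(!states[span] %in% "UNINFORMATIVE_NC")
      p_value <- stats::pbinom(n_inf - 1, n_span_cl, max(rate, 1e-12),
                               lower.tail = FALSE)
      out[[length(out) + 1]] <- data.frame(
        chromosome = ch, start = start, end = end, parent = parent,
        subtype = subtype, n_informative = n_inf,
        n_opposing = run$n_opp, p_value = p_value,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- if (length(out) > 0) do.call(rbind, out) else data.frame(
    chromosome = character(0), start = numeric(0), end = numeric(0),
    parent = character(0), subtype = character(0),
    n_informative = integer(0), n_opposing = integer(0),
    p_value = numeric(0), stringsAsFactors = FALSE
  )
  class(res) <- c("upd_events", "data.frame")
  res
}

# Maximal same-direction runs over the informative subsequence, merged
# across opposing blocks while the opposing fraction stays within limit.
direction_runs <- function(dir, max_opposing_fraction) {
  r <- rle(dir)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- list()
  i <- 1
  while (i <= length(r$values)) {
    d <- r$values[i]
    a <- starts[i]; b <- ends[i]
    n_same <- r$lengths[i]; n_opp <- 0L
    j <- i + 1
    while (j + 1 <= length(r$values)) {
      opp <- r$lengths[j]
      nxt <- r$lengths[j + 1]
      if (r$values[j + 1] == d &&
          (n_opp + opp) / (n_same + nxt + n_opp + opp) <=
            max_opposing_fraction) {
        n_opp <- n_opp + opp
        n_same <- n_same + nxt
        b <- ends[j + 1]
        j <- j + 2
      } else break
    }
    runs[[length(runs) + 1]] <- list(dir = d, idx = a:b, n_same = n_same,
                                     n_opp = n_opp)
    i <- j
  }
  runs
}

# Iso/hetero subtype of a candidate UPD run.
# span: map row indices of all probes inside the run span;
# inf_rows: rows of run-direction informative states; parent: transmitter.
upd_subtype <- function(x, span, inf_rows, parent) {
  child <- x$child$genotype[span]
  trans <- if (parent == "paternal") x$father$genotype[span] else
    x$mother$genotype[span]
  called <- child != "NC"
  hom_frac <- if (sum(called) > 0) {
    mean(child[called] %in% c("AA", "BB"))
  } else NA_real_
  # an informative SNP with a heterozygous child can only be explained by
  # the hetero-UPD model
  hetero_required <- any(x$child$genotype[inf_rows] == "AB")
  het_parent <- called & trans == "AB"
  het_retention <- if (sum(het_parent) > 0) {
    mean(child[het_parent] == "AB")
  } else NA_real_
  if (!is.na(hom_frac) && hom_frac >= 0.98 && !hetero_required) {
    "isodisomy"
  } else if (!is.na(het_retention) && het_retention >= 0.9) {
    "heterodisomy"
  } else {
    "mixed"
  }
}

#' Screen a trio for non-paternity
#'
#' Non-paternity shows as genome-wide scatter of paternal-exclusion states
#' (`M_UPD_OR_PAT_DEL`, `M_ISO_ONLY`, `DOUBLE_INCONSISTENT`), in contrast
#' to the chromosomal clustering of segmental events. The flag is raised
#' when the paternal-exclusion rate among called SNPs exceeds
#' `nonpaternity_mi_rate` on at least `nonpaternity_min_chromosomes`
#' autosomes.
#'
#' @param x a [trio()].
#' @param config a [trio_config()].
#' @return list with `flag` (logical), `genome_rate`, and `table` (per
#'   autosome: SNPs classified, paternal-exclusion count and rate).
#' @export
detect_nonpaternity <- function(x, config = trio_config()) {
  map <- x$child$map
  states <- classify_trio(x)
  excl <- states %in% c("M_UPD_OR_PAT_DEL", "M_ISO_ONLY",
                        "DOUBLE_INCONSISTENT")
  classified <- !states %in% "UNINFORMATIVE_NC"
  tab <- do.call(rbind, lapply(
    intersect(unique(map$chromosome), AUTOSOMES),
    function(ch) {
      rows <- which(map$chromosome == ch & classified)
      data.frame(chromosome = ch, n_snps = length(rows),
                 n_pat_exclusion = sum(excl[rows]),
                 rate = if (length(rows) > 0) mean(excl[rows]) else NA_real_,
                 stringsAsFactors = FALSE)
    }
  ))
  n_over <- sum(!is.na(tab$rate) & tab$rate > config$nonpaternity_mi_rate)
  list(
    flag = n_over >= config$nonpaternity_min_chromosomes,
    genome_rate = sum(tab$n_pat_exclusion) / max(sum(tab$n_snps), 1),
    n_chromosomes_over = n_over,
    table = tab
  )
}

reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- pmin(e1, e2) - pmax(s1, s2) + 1
  ov <- pmax(ov, 0)
  pmin(ov / (e1 - s1 + 1), ov / (e2 - s2 + 1))
}

#' Annotate child CNV regions with inheritance
#'
#' A child region is inherited from a parent when a same-direction parental
#' region achieves reciprocal overlap of at least
#' `inheritance_reciprocal_overlap` (both fractions); matches in both
#' parents give "both"; no match gives "de_novo".
#'
#' @param child_regions `consensus_regions` of the child.
#' @param father_regions,mother_regions `consensus_regions` of the parents.
#' @param config a [trio_config()].
#' @return `child_regions` with an added `inheritance` column in
#'   \{paternal, maternal, both, de_novo\}.
#' @export
annotate_inheritance <- function(child_regions, father_regions,
                                 mother_regions, config = trio_config()) {
  matches_parent <- function(region, parent_regions) {
    if (is.null(parent_regions) || nrow(parent_regions) == 0) return(FALSE)
    cand <- parent_regions$chromosome == region$chromosome &
      parent_regions$direction == region$direction
    if (!any(cand)) return(FALSE)
    any(reciprocal_overlap(region$start, region$end,
                           parent_regions$start[cand],
                           parent_regions$end[cand]) >=
          config$inheritance_reciprocal_overlap)
  }
  inh <- character(nrow(child_regions))
  for (i in seq_len(nrow(child_regions))) {
    reg <- child_regions[i, ]
    p <- matches_parent(reg, father_regions)
    m <- matches_parent(reg, mother_regions)
    inh[i] <- if (p && m) "both" else if (p) "paternal" else
      if (m) "maternal" else "de_novo"
  }
  child_regions$inheritance <- inh
  child_regions
}

#' Parent of origin of a de novo CNV
#'
#' For a de novo loss, informative SNPs are in-region SNPs where the
#' parents are opposite homozygotes; the child's remaining (hemizygous,
#' read as homozygous) allele names the retained parent and the deleted
#' homolog — the returned origin — belongs to the other parent. For a de
#' novo gain, informative SNPs are opposite-homozygote SNPs where the
#' child's BAF falls in the 1/3 or 2/3 cluster (nearest of
#' \{0, 1/3, 2/3, 1\} with margin `baf_margin`); the duplicated allele's
#' parent is the origin. A verdict requires `poo_min_informative`
#' informative SNPs voting with concordance `poo_min_concordance`.
#'
#' @param x a [trio()].
#' @param region one-row region (needs `chromosome`, `start`, `end`,
#'   `direction`).
#' @param config a [trio_config()].
#' @param baf_margin assignment margin around the gain BAF clusters
#'   (default 0.08).
#' @return list with `origin` ("paternal", "maternal" or "undetermined"),
#'   `n_informative` and `concordance`.
#' @export
parent_of_origin <- function(x, region, config = trio_config(),
                             baf_margin = 0.08) {
  map <- x$child$map
  rows <- probe_indices(map, region$chromosome, region$start, region$end)
  rows <- rows[map$is_snp[rows]]
  undet <- list(origin = "undetermined", n_informative = 0L,
                concordance = NA_real_)
  if (length(rows) == 0) return(undet)
  f <- x$father$genotype[rows]
  m <- x$mother$genotype[rows]
  c_gt <- x$child$genotype[rows]
  opp <- (f == "AA" & m == "BB") | (f == "BB" & m == "AA")
  votes <- character(0)
  if (region$direction == "loss") {
    sel <- which(opp & c_gt %in% c("AA", "BB"))
    for (i in sel) {
      retained <- if (c_gt[i] == f[i]) "paternal" else
        if (c_gt[i] == m[i]) "maternal" else NA_character_
      if (is.na(retained)) next
      votes <- c(votes, if (retained == "paternal") "maternal" else "paternal")
    }
  } else {
    baf <- x$child$baf[rows]
    sel <- which(opp & !is.na(baf))
    clusters <- c(0, 1 / 3, 2 / 3, 1)
    for (i in sel) {
      d <- abs(baf[i] - clusters)
      k <- which.min(d)
      if (d[k] > baf_margin || k %in% c(1L, 4L)) next
      # k == 2: one B of three copies; k == 3: two B of three
      dup_allele <- if (k == 2L) "A" else "B"
      dup_parent <- if (f[i] == paste0(dup_allele, dup_allele)) "paternal"
        else "maternal"
      votes <- c(votes, dup_parent)
    }
  }
  if (length(votes) < config$poo_min_informative) {
    undet$n_informative <- length(votes)
    return(undet)
  }
  tab <- table(votes)
  concordance <- max(tab) / length(votes)
  if (concordance < config$poo_min_concordance) {
    return(list(origin = "undetermined", n_informative = length(votes),
                concordance = concordance))
  }
  list(origin = names(tab)[which.max(tab)], n_informative = length(votes),
       concordance = concordance)
}
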