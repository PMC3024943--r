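# Independent brute-force oracles. These deliberately share no code with
# the package implementations they check: plain loops and literal
# transmission enumeration only.

# --- consensus: per-probe voting by explicit loops -------------------------

# Direction each method assigns to one probe, by scanning every call.
oracle_probe_direction <- function(cs, chromosome, position) {
  dir <- NULL
  for (i in seq_len(nrow(cs$calls))) {
    call <- cs$calls[i, ]
    if (call$chromosome == chromosome && call$start <= position &&
        position <= call$end) {
      d <- if (call$copy_number < 2) "loss" else "gain"
      if (is.null(dir)) dir <- d else if (dir != d) return(NA_character_)
    }
  }
  if (is.null(dir)) NA_character_ else dir
}

# Full consensus by per-probe enumeration + run scan.
oracle_consensus <- function(callsets, map, min_methods = 2, min_probes = 3,
                             trusted = NULL) {
  out <- data.frame()
  for (ch in unique(map$chromosome)) {
    rows <- which(map$chromosome == ch)
    state <- character(length(rows))
    for (k in seq_along(rows)) {
      pos <- map$position[rows[k]]
      dirs <- vapply(callsets, oracle_probe_direction, "",
                     chromosome = ch, position = pos)
      n_loss <- sum(dirs == "loss", na.rm = TRUE)
      n_gain <- sum(dirs == "gain", na.rm = TRUE)
      is_loss <- n_loss >= min_methods
      is_gain <- n_gain >= min_methods
      if (!is.null(trusted)) {
        kt <- which(vapply(callsets, function(x) x$method, "") == trusted)
        if (length(kt) == 1 && !is.na(dirs[kt]) && dirs[kt] == "gain") {
          is_gain <- TRUE
        }
      }
      state[k] <- if (is_loss && !is_gain) "loss" else
        if (is_gain && !is_loss) "gain" else "none"
    }
    k <- 1
    while (k <= length(rows)) {
      if (state[k] == "none") { k <- k + 1; next }
      j <- k
      while (j < length(rows) && state[j + 1] == state[k]) j <- j + 1
      if (j - k + 1 >= min_probes) {
        out <- rbind(out, data.frame(
          chromosome = ch, start = map$position[rows[k]],
          end = map$position[rows[j]], direction = state[k],
          n_probes = j - k + 1, stringsAsFactors = FALSE
        ))
      }
      k <- j + 1
    }
  }
  out
}

# Random callset triple on a given map.
random_callsets <- function(map, n_methods = 3, max_calls = 4,
                            sample_id = "s1") {
  methods <- paste0("m", seq_len(n_methods))
  lapply(methods, function(me) {
    n_calls <- sample(0:max_calls, 1)
    calls <- NULL
    for (i in seq_len(n_calls)) {
      ch <- sample(unique(map$chromosome), 1)
      pos <- map$position[map$chromosome == ch]
      a <- sample(seq_along(pos), 1)
      b <- min(a + sample(0:14, 1), length(pos))
      calls <- rbind(calls, data.frame(
        chromosome = ch, start = pos[a], end = pos[b],
        copy_number = sample(c(0L, 1L, 3L, 4L), 1),
        n_probes = b - a + 1L, confidence = stats::runif(1, 10, 100),
        stringsAsFactors = FALSE
      ))
    }
    if (is.null(calls)) {
      callset(me, sample_id, data.frame(
        chromosome = character(0), start = numeric(0), end = numeric(0),
        copy_number = integer(0)))
    } else {
      callset(me, sample_id, calls)
    }
  })
}

# Compare region frames on the geometry columns.
region_geometry <- function(df) {
  df <- as.data.frame(df)
  class(df) <- "data.frame"
  if (nrow(df) == 0) {
    return(data.frame(chromosome = character(0), start = numeric(0),
                      end = numeric(0), direction = character(0),
                      n_probes = integer(0)))
  }
  df <- df[order(df$chromosome, df$start), c("chromosome", "start", "end",
                                             "direction", "n_probes")]
  rownames(df) <- NULL
  df$n_probes <- as.integer(df$n_probes)
  df
}

# --- trio: literal allele-transmission enumeration -------------------------

oracle_alleles <- function(gt) {
  switch(gt, AA = c("A", "A"), AB = c("A", "B"), BB = c("B", "B"))
}

oracle_gt <- function(a1, a2) paste(sort(c(a1, a2)), collapse = "")

# Enumerate every transmission model by constructing the child genotype it
# would produce, and collect the models matching the observed child.
oracle_models <- function(f, m, c) {
  fa <- oracle_alleles(f); ma <- oracle_alleles(m)
  hit <- character(0)
  for (x in fa) for (y in ma) {
    if (oracle_gt(x, y) == c) hit <- c(hit, "biparental")
  }
  for (x in fa) if (oracle_gt(x, x) == c) hit <- c(hit, "paternal_iso_upd")
  if (oracle_gt(fa[1], fa[2]) == c) hit <- c(hit, "paternal_hetero_upd")
  for (y in ma) if (oracle_gt(y, y) == c) hit <- c(hit, "maternal_iso_upd")
  if (oracle_gt(ma[1], ma[2]) == c) hit <- c(hit, "maternal_hetero_upd")
  # hemizygous child reads as homozygous: deletion of the maternal copy
  # leaves a paternal allele, and vice versa
  for (x in fa) if (oracle_gt(x, x) == c) hit <- c(hit, "maternal_deletion")
  for (y in ma) if (oracle_gt(y, y) == c) hit <- c(hit, "paternal_deletion")
  unique(hit)
}

oracle_state <- function(f, m, c) {
  if (any(c(f, m, c) == "NC")) return("UNINFORMATIVE_NC")
  models <- oracle_models(f, m, c)
  if ("biparental" %in% models) return("CONSISTENT")
  p_models <- c("paternal_iso_upd", "paternal_hetero_upd",
                "maternal_deletion")
  m_models <- c("maternal_iso_upd", "maternal_hetero_upd",
                "paternal_deletion")
  p_fit <- any(p_models %in% models)
  m_fit <- any(m_models %in% models)
  if (p_fit && !m_fit) {
    return(if ("paternal_hetero_upd" %in% models) "P_UPD_OR_MAT_DEL"
           else "P_ISO_ONLY")
  }
  if (m_fit && !p_fit) {
    return(if ("maternal_hetero_upd" %in% models) "M_UPD_OR_PAT_DEL"
           else "M_ISO_ONLY")
  }
  "DOUBLE_INCONSISTENT"
}

# --- annotation: quadratic all-pairs overlap -------------------------------

oracle_overlap_hits <- function(regions, intervals, min_frac = 0) {
  hits <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    acc <- integer(0)
    for (j in seq_len(nrow(intervals))) {
      if (regions$chromosome[i] != intervals$chromosome[j]) next
      ov <- min(regions$end[i], intervals$end[j]) -
        max(regions$start[i], intervals$start[j]) + 1
      len <- regions$end[i] - regions$start[i] + 1
      if (ov > 0 && ov >= min_frac * len) acc <- c(acc, j)
    }
    hits[[i]] <- acc
  }
  hits
}

# --- shared tiny fixtures --------------------------------------------------

tiny_map <- function(n = 10, chromosome = "1", spacing = 100) {
  genome_map(sprintf("p%s_%03d", chromosome, seq_len(n)),
             rep(chromosome, n), seq_len(n) * spacing)
}

make_callset <- function(method, chromosome, start, end, cn,
                         sample_id = "s1", confidence = 100) {
  callset(method, sample_id, data.frame(
    chromosome = chromosome, start = start, end = end, copy_number = cn,
    n_probes = NA_integer_, confidence = confidence,
    stringsAsFactors = FALSE
  ))
}

empty_callset <- function(method, sample_id = "s1") {
  callset(method, sample_id, data.frame(
    chromosome = character(0), start = numeric(0), end = numeric(0),
    copy_number = integer(0)))
}
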