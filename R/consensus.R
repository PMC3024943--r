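# Majority-vote CNV consensus across caller callsets, formalised per probe:
# a probe is a consensus probe for a direction when at least `min_methods`
# callers assign that direction to it (or, in asymmetric mode, when the
# trusted caller alone assigns a gain); consensus regions are maximal runs
# of consecutive consensus probes of one direction with at least
# `min_probes` members, delineated conservatively by the first and last
# probe of the run.

#' Consensus vote configuration
#'
#' @param min_methods minimum number of agreeing callers (default 2: the
#'   majority of three; calls seen by a single caller are discarded).
#' @param min_probes minimum run length in consecutive probes (default 3).
#' @param trusted_dup_method optional caller name whose duplication (gain)
#'   calls do not need confirmation by a second caller (asymmetric voting;
#'   default none).
#' @return object of class `vote_config`.
#' @export
vote_config <- function(min_methods = 2, min_probes = 3,
                        trusted_dup_method = NULL) {
  stopifnot(min_methods >= 1, min_probes >= 1)
  structure(list(min_methods = as.integer(min_methods),
                 min_probes = as.integer(min_probes),
                 trusted_dup_method = trusted_dup_method),
            class = "vote_config")
}

# Per-method probe direction vectors for one chromosome.
# Returns a methods x probes integer matrix: -1 loss, +1 gain, 0 none
# (a probe covered by both a loss and a gain of the same method is a
# within-method conflict and contributes no direction).
method_direction_matrix <- function(callsets, map, chromosome) {
  rows <- which(map$chromosome == chromosome)
  pos <- map$position[rows]
  dir <- matrix(0L, nrow = length(callsets), ncol = length(rows),
                dimnames = list(vapply(callsets, `[[`, "", "method"), NULL))
  for (k in seq_along(callsets)) {
    calls <- callsets[[k]]$calls
    calls <- calls[calls$chromosome == chromosome, , drop = FALSE]
    if (nrow(calls) == 0) next
    loss <- logical(length(rows)); gain <- logical(length(rows))
    for (i in seq_len(nrow(calls))) {
      lo <- findInterval(calls$start[i] - 1, pos) + 1L
      hi <- findInterval(calls$end[i], pos)
      if (lo > hi) next
      if (calls$copy_number[i] < 2) loss[lo:hi] <- TRUE else gain[lo:hi] <- TRUE
    }
    dir[k, loss & !gain] <- -1L
    dir[k, gain & !loss] <- 1L
  }
  dir
}

#' Tabulate per-probe caller directions
#'
#' Explicit per-probe view of the vote: for every map probe, the direction
#' ("loss"/"gain"/NA) each caller's filtered calls assign to it.
#'
#' @param callsets list of [callset()]s for one sample.
#' @param map a [genome_map()].
#' @return data.frame with `probe_id`, `chromosome`, `position` and one
#'   direction column per caller.
#' @export
probe_vote_table <- function(callsets, map) {
  check_same_sample(callsets)
  check_known_chromosomes(callsets, map)
  out <- data.frame(probe_id = map$probe_id, chromosome = map$chromosome,
                    position = map$position, stringsAsFactors = FALSE)
  for (cs in callsets) out[[cs$method]] <- NA_character_
  for (ch in unique(map$chromosome)) {
    rows <- which(map$chromosome == ch)
    dir <- method_direction_matrix(callsets, map, ch)
    for (k in seq_along(callsets)) {
      v <- rep(NA_character_, length(rows))
      v[dir[k, ] == -1L] <- "loss"
      v[dir[k, ] == 1L] <- "gain"
      out[[callsets[[k]]$method]][rows] <- v
    }
  }
  out
}

check_same_sample <- function(callsets) {
  if (length(callsets) == 0) stop("need at least one callset")
  ids <- unique(vapply(callsets, `[[`, "", "sample_id"))
  ids <- ids[!is.na(ids)]
  if (length(ids) > 1) {
    stop("callsets come from different samples: ", paste(ids, collapse = ", "))
  }
}

check_known_chromosomes <- function(callsets, map) {
  for (cs in callsets) {
    bad <- setdiff(unique(cs$calls$chromosome), map$chromosome)
    if (length(bad) > 0) {
      stop("callset '", cs$method, "' has call(s) on chromosome(s) not in ",
           "the map: ", paste(bad, collapse = ", "))
    }
  }
}

#' Majority-vote consensus CNV calling
#'
#' Combines the filtered callsets of several callers into a restrictive
#' consensus set: regions reported by only one caller are discarded
#' (caller-specific artefacts), agreement is on direction (loss vs gain,
#' not exact copy number), delineation is conservative (the run of probes
#' the agreeing callers jointly cover), and runs shorter than `min_probes`
#' consecutive probes are dropped. With `trusted_dup_method` set, that
#' caller's duplication calls stand without confirmation.
#'
#' @param callsets list of [callset()]s for one sample.
#' @param map a [genome_map()].
#' @param config a [vote_config()].
#' @return data.frame of class `consensus_regions`: columns `sample_id`,
#'   `chromosome`, `start`, `end` (first/last supporting probe positions),
#'   `direction`, `copy_number` (modal over supporting calls, ties resolved
#'   toward 2 then smaller), `n_probes`, `supporting_methods`
#'   (comma-joined), `vote_mode` ("majority" or "trusted_dup").
#' @export
vote_consensus <- function(callsets, map, config = vote_config()) {
  check_same_sample(callsets)
  check_known_chromosomes(callsets, map)
  sample_id <- vapply(callsets, `[[`, "", "sample_id")
  sample_id <- c(sample_id[!is.na(sample_id)], NA_character_)[1]
  methods <- vapply(callsets, `[[`, "", "method")
  trusted_k <- if (is.null(config$trusted_dup_method)) 0L else
    match(config$trusted_dup_method, methods, nomatch = 0L)

  res <- list()
  for (ch in unique(map$chromosome)) {
    rows <- which(map$chromosome == ch)
    dir <- method_direction_matrix(callsets, map, ch)
    n_loss <- colSums(dir == -1L)
    n_gain <- colSums(dir == 1L)
    cons_loss <- n_loss >= config$min_methods
    cons_gain <- n_gain >= config$min_methods
    if (trusted_k > 0L) cons_gain <- cons_gain | dir[trusted_k, ] == 1L
    state <- integer(length(rows))
    state[cons_loss & !cons_gain] <- -1L
    state[cons_gain & !cons_loss] <- 1L

    r <- rle(state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values != 0L & r$lengths >= config$min_probes)) {
      a <- starts[j]; b <- ends[j]
      d <- r$values[j]
      run_rows <- rows[a:b]
      support <- methods[apply(dir[, a:b, drop = FALSE] == d, 1, any)]
      cn <- modal_copy_number(callsets, ch, map$position[run_rows], d)
      res[[length(res) + 1]] <- data.frame(
        sample_id = sample_id, chromosome = ch,
        start = map$position[run_rows[1]],
        end = map$position[run_rows[length(run_rows)]],
        direction = if (d < 0) "loss" else "gain",
        copy_number = cn, n_probes = b - a + 1L,
        supporting_methods = paste(sort(support), collapse = ","),
        vote_mode = if (length(support) >= config$min_methods) "majority"
                    else "trusted_dup",
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(res) > 0) do.call(rbind, res) else data.frame(
    sample_id = character(0), chromosome = character(0), start = numeric(0),
    end = numeric(0), direction = character(0), copy_number = integer(0),
    n_probes = integer(0), supporting_methods = character(0),
    vote_mode = character(0), stringsAsFactors = FALSE
  )
  out <- out[order(match(out$chromosome, VALID_CHROMOSOMES), out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("consensus_regions", "data.frame")
  out
}

# Modal copy number among same-direction calls over the run's probes,
# weighted by the number of run probes each call covers; ties resolved
# toward the value closest to 2, then the smaller value.
modal_copy_number <- function(callsets, chromosome, run_positions, d) {
  weights <- numeric(0)
  cns <- integer(0)
  for (cs in callsets) {
    calls <- cs$calls
    calls <- calls[calls$chromosome == chromosome &
                     sign(calls$copy_number - 2L) == d, , drop = FALSE]
    for (i in seq_len(nrow(calls))) {
      w <- sum(run_positions >= calls$start[i] & run_positions <= calls$end[i])
      if (w > 0) {
        cns <- c(cns, calls$copy_number[i])
        weights <- c(weights, w)
      }
    }
  }
  if (length(cns) == 0) return(if (d < 0) 1L else 3L)
  tab <- tapply(weights, cns, sum)
  cand <- as.integer(names(tab)[tab == max(tab)])
  cand[order(abs(cand - 2L), cand)][1]
}
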