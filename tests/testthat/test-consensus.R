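# probes at 100..1000 step 100 on chromosome 1
cmap <- tiny_map(10)

test_that("single-caller regions are discarded", {
  a <- make_callset("A", "1", 100, 200, 1)
  b <- empty_callset("B")
  c <- empty_callset("C")
  expect_equal(nrow(vote_consensus(list(a, b, c), cmap)), 0)
})

test_that("two-caller overlap is delineated conservatively", {
  a <- make_callset("A", "1", 100, 500, 1)
  b <- make_callset("B", "1", 300, 800, 1)
  c <- empty_callset("C")
  res <- vote_consensus(list(a, b, c), cmap)
  expect_equal(nrow(res), 1)
  expect_equal(res$start, 300)
  expect_equal(res$end, 500)
  expect_equal(res$n_probes, 3L)
  expect_equal(res$supporting_methods, "A,B")
  expect_equal(res$direction, "loss")
  expect_equal(res$vote_mode, "majority")
})

test_that("runs below the 3-consecutive-probe floor are dropped", {
  a <- make_callset("A", "1", 100, 300, 1)
  b <- make_callset("B", "1", 200, 300, 1)
  res <- vote_consensus(list(a, b), cmap)
  expect_equal(nrow(res), 0)  # shared run {200, 300} is 2 probes
  # extending the second call by one probe reaches the floor
  b3 <- make_callset("B", "1", 100, 300, 1)
  expect_equal(nrow(vote_consensus(list(a, b3), cmap)), 1)
})

test_that("asymmetric voting accepts trusted duplications alone", {
  a <- make_callset("A", "1", 100, 500, 3)
  b <- empty_callset("B")
  c <- empty_callset("C")
  cfg <- vote_config(trusted_dup_method = "A")
  res <- vote_consensus(list(a, b, c), cmap, cfg)
  expect_equal(nrow(res), 1)
  expect_equal(res$vote_mode, "trusted_dup")
  expect_equal(res$direction, "gain")
  # trusted losses still need confirmation
  a2 <- make_callset("A", "1", 100, 500, 1)
  expect_equal(nrow(vote_consensus(list(a2, b, c), cmap, cfg)), 0)
  # a second supporting method upgrades the vote mode to majority
  b2 <- make_callset("B", "1", 100, 500, 3)
  res2 <- vote_consensus(list(a, b2, c), cmap, cfg)
  expect_equal(res2$vote_mode, "majority")
})

test_that("conflicting directions at a probe support neither", {
  a <- make_callset("A", "1", 100, 500, 1)
  b <- make_callset("B", "1", 100, 500, 3)
  tab <- probe_vote_table(list(a, b), cmap)
  expect_equal(tab$A[1], "loss")
  expect_equal(tab$B[1], "gain")
  expect_equal(nrow(vote_consensus(list(a, b), cmap)), 0)
})

test_that("probe vote table tabulates coverage", {
  a <- make_callset("A", "1", 100, 300, 1)
  b <- empty_callset("B")
  tab <- probe_vote_table(list(a, b), cmap)
  expect_equal(tab$A, c(rep("loss", 3), rep(NA, 7)))
  expect_true(all(is.na(tab$B)))
})

test_that("empty callsets give empty consensus", {
  res <- vote_consensus(list(empty_callset("A"), empty_callset("B")), cmap)
  expect_equal(nrow(res), 0)
})

test_that("modal copy number resolves ties toward 2 then smaller", {
  # cn 0 and cn 1 tie over the run: 1 is closer to 2
  a <- make_callset("A", "1", 100, 1000, 0L)
  b <- make_callset("B", "1", 100, 1000, 1L)
  res <- vote_consensus(list(a, b), cmap)
  expect_equal(res$copy_number, 1L)
  # cn 1 vs cn 3 cannot meet (directions differ); cn 3 vs 4: 3 wins
  c1 <- make_callset("A", "1", 100, 1000, 3L)
  c2 <- make_callset("B", "1", 100, 1000, 4L)
  expect_equal(vote_consensus(list(c1, c2), cmap)$copy_number, 3L)
})

test_that("callsets from different samples are rejected", {
  a <- make_callset("A", "1", 100, 500, 1, sample_id = "s1")
  b <- make_callset("B", "1", 100, 500, 1, sample_id = "s2")
  expect_error(vote_consensus(list(a, b), cmap), "different samples")
})

test_that("calls on chromosomes outside the map are rejected", {
  a <- make_callset("A", "9", 100, 500, 1)
  b <- make_callset("B", "9", 100, 500, 1)
  expect_error(vote_consensus(list(a, b), cmap), "not in the map")
})

test_that("interval implementation equals the per-probe oracle", {
  set.seed(101)
  map <- genome_map(
    paste0("p", 1:120),
    rep(c("1", "2"), each = 60),
    rep(sort(sample(1:1e5, 60)), 2)
  )
  for (rep_i in 1:300) {
    css <- random_callsets(map)
    trusted <- if (rep_i %% 3 == 0) "m1" else NULL
    got <- vote_consensus(css, map,
                          vote_config(trusted_dup_method = trusted))
    want <- oracle_consensus(css, map, trusted = trusted)
    expect_equal(region_geometry(got), region_geometry(want))
  }
})

test_that("consensus is invariant under callset order", {
  set.seed(55)
  map <- tiny_map(60, spacing = 1000)
  for (i in 1:25) {
    css <- random_callsets(map)
    r1 <- vote_consensus(css, map)
    r2 <- vote_consensus(rev(css), map)
    expect_equal(region_geometry(r1), region_geometry(r2))
  }
})

test_that("adding a call never removes same-direction consensus probes", {
  set.seed(77)
  map <- tiny_map(60, spacing = 1000)
  probes_of <- function(res, dir) {
    unlist(lapply(which(res$direction == dir), function(i) {
      seq(res$start[i], res$end[i], by = 1000)
    }))
  }
  for (i in 1:25) {
    css <- random_callsets(map)
    base <- vote_consensus(css, map, vote_config(min_probes = 1))
    pos <- map$position
    a <- sample(seq_along(pos), 1)
    b <- min(a + sample(0:9, 1), length(pos))
    extra <- data.frame(chromosome = "1", start = pos[a], end = pos[b],
                        copy_number = 1L)
    css2 <- css
    css2[[1]] <- callset("m1", "s1", rbind(
      css[[1]]$calls[, c("chromosome", "start", "end", "copy_number")],
      extra))
    grown <- vote_consensus(css2, map, vote_config(min_probes = 1))
    expect_true(all(probes_of(base, "loss") %in% probes_of(grown, "loss")))
  }
})

test_that("every consensus probe lies under >= 2 agreeing callers", {
  set.seed(88)
  map <- tiny_map(80, spacing = 1000)
  for (i in 1:20) {
    css <- random_callsets(map)
    res <- vote_consensus(css, map)
    tab <- probe_vote_table(css, map)
    for (j in seq_len(nrow(res))) {
      rows <- which(tab$position >= res$start[j] &
                      tab$position <= res$end[j])
      for (r in rows) {
        n_agree <- sum(tab[r, c("m1", "m2", "m3")] == res$direction[j],
                       na.rm = TRUE)
        expect_gte(n_agree, 2)
      }
    }
  }
})

test_that("raising min_probes only removes regions", {
  set.seed(99)
  map <- tiny_map(80, spacing = 1000)
  for (i in 1:20) {
    css <- random_callsets(map)
    r3 <- region_geometry(vote_consensus(css, map, vote_config(min_probes = 3)))
    r5 <- region_geometry(vote_consensus(css, map, vote_config(min_probes = 5)))
    key <- function(df) paste(df$chromosome, df$start, df$end, df$direction)
    expect_true(all(key(r5) %in% key(r3)))
    expect_true(all(r5$n_probes >= 5))
  }
})
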