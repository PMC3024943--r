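test_that("the generator is seed-deterministic", {
  cfg <- sim_config(n_chromosomes = 1, probes_per_chromosome = 300, seed = 9)
  a <- simulate_sample(cfg, seed = 42)
  b <- simulate_sample(cfg, seed = 42)
  c <- simulate_sample(cfg, seed = 43)
  expect_identical(a$sample$baf, b$sample$baf)
  expect_identical(a$sample$genotype, b$sample$genotype)
  expect_false(identical(a$sample$baf, c$sample$baf))
})

test_that("noiseless heterozygotes sit exactly at BAF 0.5", {
  cfg <- sim_config(n_chromosomes = 1, probes_per_chromosome = 500,
                    baf_sigma = 0, lrr_sigma = 0, nocall_rate = 0, seed = 10)
  sim <- simulate_sample(cfg, seed = 10)
  het <- sim$sample$genotype == "AB"
  expect_true(any(het))
  expect_true(all(sim$sample$baf[het] == 0.5))
  expect_true(all(sim$sample$lrr == 0))
})

test_that("a full deletion drops LRR to log2(1/2) and calls homozygous", {
  cfg <- sim_config(n_chromosomes = 1, probes_per_chromosome = 200,
                    baf_sigma = 0, lrr_sigma = 0, nocall_rate = 0, seed = 11)
  ev <- sim_events("del", "1", 1, 5e5)
  sim <- simulate_sample(cfg, ev, seed = 11)
  idx <- sim$truth$first_probe:sim$truth$last_probe
  expect_true(all(sim$sample$lrr[idx] == log2(1 / 2)))
  expect_true(all(sim$sample$genotype[idx] %in% c("AA", "BB")))
  expect_true(all(sim$sample$baf[idx] %in% c(0, 1)))
})

test_that("a half-fraction mosaic deletion shifts het mBAF to 2/3", {
  cfg <- sim_config(n_chromosomes = 1, probes_per_chromosome = 400,
                    baf_sigma = 0, lrr_sigma = 0, nocall_rate = 0, seed = 12)
  ev <- sim_events("mosaic_del", "1", 1, 2e6, fraction = 0.5)
  sim <- simulate_sample(cfg, ev, seed = 12)
  idx <- sim$truth$first_probe:sim$truth$last_probe
  het <- idx[sim$sample$genotype[idx] == "AB"]
  mb <- mirror_baf(sim$sample$baf[het])
  expect_true(all(abs(mb - expected_mbaf(0.5, "mosaic_deletion")) < 1e-12))
})

test_that("generated means match the dosage formulas within 3 SE", {
  cfg <- sim_config(n_chromosomes = 2, probes_per_chromosome = 5000,
                    nocall_rate = 0, seed = 13)
  sim <- simulate_sample(cfg, seed = 13)
  n <- 10000
  se_lrr <- cfg$lrr_sigma / sqrt(n)
  expect_lt(abs(mean(sim$sample$lrr) - 0), 3 * se_lrr)
  het <- sim$sample$genotype == "AB"
  se_baf <- cfg$baf_sigma / sqrt(sum(het))
  expect_lt(abs(mean(sim$sample$baf[het]) - 0.5), 3 * se_baf)
})

test_that("truth spans align to the planted probe interval", {
  cfg <- sim_config(n_chromosomes = 2, probes_per_chromosome = 300,
                    seed = 14)
  ev <- sim_events(c("del", "dup"), c("1", "2"), c(2e5, 1e6),
                   c(8e5, 2e6))
  sim <- simulate_sample(cfg, ev, seed = 14)
  expect_equal(nrow(sim$truth), 2)
  map <- cfg$map
  for (i in 1:2) {
    tr <- sim$truth[i, ]
    rows <- which(map$chromosome == tr$chromosome &
                    map$position >= tr$start & map$position <= tr$end)
    expect_equal(tr$first_probe, rows[1])
    expect_equal(tr$last_probe, rows[length(rows)])
    expect_equal(tr$n_probes, length(rows))
  }
})

test_that("overlapping planted events are rejected", {
  cfg <- sim_config(n_chromosomes = 1, probes_per_chromosome = 100,
                    seed = 15)
  ev <- sim_events(c("del", "dup"), c("1", "1"), c(100, 5e4), c(1e5, 2e5))
  expect_error(simulate_sample(cfg, ev, seed = 15), "overlap")
})

test_that("clean trios are Mendelian-consistent genome-wide", {
  cfg <- sim_config(n_chromosomes = 2, probes_per_chromosome = 600,
                    nocall_rate = 0, seed = 16)
  st <- simulate_trio(cfg, seed = 500)
  states <- classify_trio(st$trio)
  expect_true(all(states == "CONSISTENT"))
})

test_that("planted paternal isodisomy makes the child homozygous in-region", {
  cfg <- sim_config(n_chromosomes = 2, probes_per_chromosome = 600,
                    nocall_rate = 0, seed = 17)
  st <- simulate_trio(cfg, sim_events("upd_iso", "1", 1e6, 4e6,
                                      parent = "paternal"), seed = 501)
  tr <- st$truth
  idx <- tr$first_probe:tr$last_probe
  expect_true(all(st$trio$child$genotype[idx] %in% c("AA", "BB")))
  states <- classify_trio(st$trio)[idx]
  opp <- (st$trio$father$genotype[idx] == "AA" &
            st$trio$mother$genotype[idx] == "BB") |
         (st$trio$father$genotype[idx] == "BB" &
            st$trio$mother$genotype[idx] == "AA")
  # maternal-exclusion (paternal-disomy) signatures at opposite homozygotes
  expect_true(all(states[opp] %in% c("P_UPD_OR_MAT_DEL", "P_ISO_ONLY")))
  expect_gt(sum(opp), 0)
})

test_that("non-paternity raises the paternal-exclusion rate far above 2%", {
  cfg <- sim_config(n_chromosomes = 2, probes_per_chromosome = 2000,
                    nocall_rate = 0, seed = 18)
  st <- simulate_trio(cfg, nonpaternity = TRUE, seed = 502)
  states <- classify_trio(st$trio)
  excl <- mean(states %in% c("M_UPD_OR_PAT_DEL", "M_ISO_ONLY",
                             "DOUBLE_INCONSISTENT"))
  expect_gt(excl, 0.05)
})

test_that("perfect callers let the consensus recover every true event", {
  cfg <- sim_config(n_chromosomes = 2, probes_per_chromosome = 500,
                    seed = 19)
  ev <- sim_events(c("del", "dup"), c("1", "2"), c(2e5, 1e6), c(8e5, 2e6))
  sim <- simulate_sample(cfg, ev, seed = 19)
  profiles <- list(
    quantisnp = list(sensitivity = 1, fp_rate_per_genome = 0,
                     boundary_jitter_probes = 0),
    penncnv = list(sensitivity = 1, fp_rate_per_genome = 0,
                   boundary_jitter_probes = 0),
    vanillaice = list(sensitivity = 1, fp_rate_per_genome = 0,
                      boundary_jitter_probes = 0))
  css <- simulate_callsets(sim$truth, cfg$map, profiles, seed = 19)
  res <- vote_consensus(css, cfg$map)
  expect_equal(nrow(res), 2)
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    hit <- res[res$chromosome == tr$chromosome, ]
    expect_equal(hit$start, cfg$map$position[tr$first_probe])
    expect_equal(hit$end, cfg$map$position[tr$last_probe])
    expect_equal(hit$direction,
                 if (tr$type == "del") "loss" else "gain")
  }
})

test_that("a single sensitive caller cannot carry the majority vote", {
  cfg <- sim_config(n_chromosomes = 1, probes_per_chromosome = 500,
                    seed = 20)
  ev <- sim_events("del", "1", 2e5, 8e5)
  sim <- simulate_sample(cfg, ev, seed = 20)
  profiles <- list(
    a = list(sensitivity = 1, fp_rate_per_genome = 0),
    b = list(sensitivity = 0, fp_rate_per_genome = 0),
    c = list(sensitivity = 0, fp_rate_per_genome = 0))
  css <- simulate_callsets(sim$truth, cfg$map, profiles, seed = 20)
  expect_equal(nrow(vote_consensus(css, cfg$map)), 0)
})

test_that("trusted-duplication mode carries a lone trusted gain call", {
  cfg <- sim_config(n_chromosomes = 1, probes_per_chromosome = 500,
                    seed = 21)
  ev <- sim_events("dup", "1", 2e5, 8e5)
  sim <- simulate_sample(cfg, ev, seed = 21)
  profiles <- list(
    penncnv = list(sensitivity = 1, fp_rate_per_genome = 0),
    quantisnp = list(sensitivity = 0, fp_rate_per_genome = 0),
    vanillaice = list(sensitivity = 0, fp_rate_per_genome = 0))
  css <- simulate_callsets(sim$truth, cfg$map, profiles, seed = 21)
  expect_equal(nrow(vote_consensus(css, cfg$map)), 0)
  res <- vote_consensus(css, cfg$map,
                        vote_config(trusted_dup_method = "penncnv"))
  expect_equal(nrow(res), 1)
  expect_equal(res$vote_mode, "trusted_dup")
})
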