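test_that("classification matches the brute-force enumerator on all 27 triples", {
  tab <- classification_table()
  expect_equal(nrow(tab), 27)
  for (i in seq_len(nrow(tab))) {
    expect_equal(
      tab$state[i],
      oracle_state(tab$father[i], tab$mother[i], tab$child[i]),
      info = paste(tab$father[i], tab$mother[i], tab$child[i])
    )
  }
  expect_equal(sum(tab$state == "CONSISTENT"),
               sum(vapply(seq_len(nrow(tab)), function(i) {
                 "biparental" %in% oracle_models(tab$father[i], tab$mother[i],
                                                 tab$child[i])
               }, logical(1))))
})

test_that("classification is parent-swap symmetric", {
  swap <- c(CONSISTENT = "CONSISTENT",
            P_UPD_OR_MAT_DEL = "M_UPD_OR_PAT_DEL",
            M_UPD_OR_PAT_DEL = "P_UPD_OR_MAT_DEL",
            P_ISO_ONLY = "M_ISO_ONLY", M_ISO_ONLY = "P_ISO_ONLY",
            DOUBLE_INCONSISTENT = "DOUBLE_INCONSISTENT",
            UNINFORMATIVE_NC = "UNINFORMATIVE_NC")
  gts <- c("AA", "AB", "BB", "NC")
  for (f in gts) for (m in gts) for (c in gts) {
    expect_equal(classify_snp(m, f, c),
                 unname(swap[classify_snp(f, m, c)]),
                 info = paste(f, m, c))
  }
})

test_that("worked genotype triples classify as expected", {
  expect_equal(classify_snp("AA", "BB", "AB"), "CONSISTENT")
  expect_equal(classify_snp("AA", "BB", "AA"), "P_UPD_OR_MAT_DEL")
  expect_equal(classify_snp("AB", "AA", "BB"), "P_ISO_ONLY")
  expect_equal(classify_snp("AA", "AA", "BB"), "DOUBLE_INCONSISTENT")
  expect_equal(classify_snp("NC", "AB", "AA"), "UNINFORMATIVE_NC")
  expect_error(classify_snp("AA", "XY", "AB"), "invalid genotype")
})

test_that("trio container validates maps and sample ids", {
  cfg <- sim_config(n_chromosomes = 1, probes_per_chromosome = 20, seed = 1)
  a <- simulate_sample(cfg, sample_id = "a", seed = 1)$sample
  b <- simulate_sample(cfg, sample_id = "b", seed = 2)$sample
  expect_error(trio(a, b, b), "distinct sample ids")
  expect_s3_class(trio(a, b,
                       simulate_sample(cfg, sample_id = "c", seed = 3)$sample),
                  "trio")
})

trio_cfg_small <- function() sim_config(n_chromosomes = 2,
                                        probes_per_chromosome = 1200,
                                        seed = 2)

test_that("planted paternal isodisomy is detected with parent and subtype", {
  st <- simulate_trio(trio_cfg_small(),
                      sim_events("upd_iso", "1", 2e6, 7e6,
                                 parent = "paternal"), seed = 101)
  upd <- detect_upd(st$trio)
  expect_equal(nrow(upd), 1)
  expect_equal(upd$parent, "paternal")
  expect_equal(upd$subtype, "isodisomy")
  expect_equal(upd$chromosome, "1")
  expect_gte(upd$start, 2e6 - 2e5)
  expect_lte(upd$end, 7e6 + 2e5)
  expect_lt(upd$p_value, 1e-6)
})

test_that("planted maternal heterodisomy is detected with parent and subtype", {
  st <- simulate_trio(trio_cfg_small(),
                      sim_events("upd_het", "2", 2e6, 7e6,
                                 parent = "maternal"), seed = 102)
  upd <- detect_upd(st$trio)
  expect_equal(nrow(upd), 1)
  expect_equal(upd$parent, "maternal")
  expect_equal(upd$subtype, "heterodisomy")
})

test_that("normal trios yield no UPD events", {
  for (seed in 1:8) {
    st <- simulate_trio(trio_cfg_small(), seed = 200 + seed)
    expect_equal(nrow(detect_upd(st$trio)), 0)
  }
})

test_that("a deletion-like run is not reported as UPD", {
  # de novo deletion: paternal-exclusion states cluster but child LRR drops
  st <- simulate_trio(trio_cfg_small(),
                      sim_events("del", "1", 2e6, 7e6), seed = 103)
  upd <- detect_upd(st$trio)
  expect_equal(nrow(upd), 0)
})

test_that("non-paternity is flagged by genome-wide exclusion scatter", {
  cfg <- sim_config(n_chromosomes = 22, probes_per_chromosome = 250,
                    seed = 3)
  np <- simulate_trio(cfg, nonpaternity = TRUE, seed = 301)
  res <- detect_nonpaternity(np$trio)
  expect_true(res$flag)
  expect_gt(res$genome_rate, 0.02)
  expect_equal(nrow(res$table), 22)
})

test_that("true trios with genotype error stay below the flag", {
  cfg <- sim_config(n_chromosomes = 22, probes_per_chromosome = 250,
                    genotype_error_rate = 0.002, seed = 4)
  ok <- simulate_trio(cfg, seed = 302)
  expect_false(detect_nonpaternity(ok$trio)$flag)
})

test_that("a single UPD chromosome does not trigger non-paternity", {
  cfg <- sim_config(n_chromosomes = 22, probes_per_chromosome = 250,
                    seed = 5)
  st <- simulate_trio(cfg, sim_events("upd_het", "3", 1, 2.5e6,
                                      parent = "maternal"), seed = 303)
  res <- detect_nonpaternity(st$trio)
  expect_false(res$flag)
  expect_lte(res$n_chromosomes_over, 2)
})

mk_regions <- function(chromosome, start, end, direction,
                       sample_id = "s") {
  data.frame(sample_id = sample_id, chromosome = chromosome, start = start,
             end = end, direction = direction,
             copy_number = ifelse(direction == "loss", 1L, 3L),
             stringsAsFactors = FALSE)
}

test_that("inheritance annotation follows reciprocal overlap", {
  child <- mk_regions("1", 100, 200, "loss")
  exact <- annotate_inheritance(child, mk_regions("1", 100, 200, "loss"),
                                NULL)
  expect_equal(exact$inheritance, "paternal")
  # reciprocal overlaps 21/101 and 21/221 both < 0.5
  partial <- annotate_inheritance(child, mk_regions("1", 180, 400, "loss"),
                                  NULL)
  expect_equal(partial$inheritance, "de_novo")
  # direction mismatch never matches
  flip <- annotate_inheritance(child, NULL, mk_regions("1", 100, 200, "gain"))
  expect_equal(flip$inheritance, "de_novo")
  both <- annotate_inheritance(child, mk_regions("1", 90, 210, "loss"),
                               mk_regions("1", 100, 200, "loss"))
  expect_equal(both$inheritance, "both")
})

test_that("inheritance is parent-symmetric and overlap-monotone", {
  child <- mk_regions("2", 1000, 2000, "gain")
  f <- mk_regions("2", 1400, 2400, "gain")
  a <- annotate_inheritance(child, f, NULL)
  b <- annotate_inheritance(child, NULL, f)
  expect_equal(a$inheritance == "paternal", b$inheritance == "maternal")
  # raising the threshold can only push toward de_novo
  for (th in c(0.2, 0.4, 0.6, 0.8)) {
    lo <- annotate_inheritance(child, f, NULL,
                               trio_config(inheritance_reciprocal_overlap = th))
    hi <- annotate_inheritance(child, f, NULL,
                               trio_config(inheritance_reciprocal_overlap = min(th + 0.2, 1)))
    expect_false(lo$inheritance == "de_novo" && hi$inheritance != "de_novo")
  }
})

# Hand-built trio around a de novo child deletion: parents opposite
# homozygotes at 5 SNPs, child retains the paternal allele.
poo_fixture <- function(child_gt, child_baf = NULL, direction = "loss") {
  map <- tiny_map(7, "1", spacing = 1000)
  f <- sample_data("f", map, rep("AA", 7), rep(0, 7), rep(0, 7), "M")
  m <- sample_data("m", map, rep("BB", 7), rep(1, 7), rep(0, 7), "F")
  baf <- if (is.null(child_baf)) rep(0, 7) else child_baf
  c <- sample_data("c", map, child_gt, baf, rep(-0.5, 7))
  list(trio = trio(c, f, m),
       region = data.frame(chromosome = "1", start = 2000, end = 6000,
                           direction = direction,
                           stringsAsFactors = FALSE))
}

test_that("parent of origin of a de novo loss follows the retained allele", {
  fx <- poo_fixture(rep("AA", 7))  # child keeps paternal A everywhere
  res <- parent_of_origin(fx$trio, fx$region)
  expect_equal(res$origin, "maternal")  # maternal homolog was lost
  expect_equal(res$n_informative, 5L)
  expect_equal(res$concordance, 1)
  fx2 <- poo_fixture(rep("BB", 7))
  expect_equal(parent_of_origin(fx2$trio, fx2$region)$origin, "paternal")
})

test_that("parent of origin of a de novo gain reads the BAF cluster", {
  # father AA, mother BB; child BAF ~ 1/3 means two A one B: duplicated A
  # is paternal here
  fx <- poo_fixture(rep("AB", 7), child_baf = rep(1 / 3, 7),
                    direction = "gain")
  res <- parent_of_origin(fx$trio, fx$region)
  expect_equal(res$origin, "paternal")
  fx2 <- poo_fixture(rep("AB", 7), child_baf = rep(2 / 3, 7),
                     direction = "gain")
  expect_equal(parent_of_origin(fx2$trio, fx2$region)$origin, "maternal")
  # BAF far from any cluster is uninformative
  fx3 <- poo_fixture(rep("AB", 7), child_baf = rep(0.5, 7),
                     direction = "gain")
  expect_equal(parent_of_origin(fx3$trio, fx3$region)$origin, "undetermined")
})

test_that("parent of origin needs enough informative SNPs", {
  fx <- poo_fixture(rep("AA", 7))
  narrow <- data.frame(chromosome = "1", start = 2000, end = 2500,
                       direction = "loss", stringsAsFactors = FALSE)
  res <- parent_of_origin(fx$trio, narrow)  # 1 informative SNP < default 2
  expect_equal(res$origin, "undetermined")
  expect_equal(res$n_informative, 1L)
  off <- data.frame(chromosome = "1", start = 7500, end = 8000,
                    direction = "loss", stringsAsFactors = FALSE)
  expect_equal(parent_of_origin(fx$trio, off)$n_informative, 0L)
})

test_that("parent of origin is correct on simulated de novo deletions", {
  cfg <- sim_config(n_chromosomes = 1, probes_per_chromosome = 500,
                    seed = 6)
  hits <- 0
  for (seed in 1:10) {
    st <- simulate_trio(cfg, sim_events("del", "1", 1e6, 3e6), seed = 400 + seed)
    region <- data.frame(chromosome = "1", start = 1e6, end = 3e6,
                         direction = "loss", stringsAsFactors = FALSE)
    res <- parent_of_origin(st$trio, region)
    # truth: haplotype 1 (the paternal homolog) is deleted by construction
    expect_true(res$origin %in% c("paternal", "undetermined"))
    if (res$origin == "paternal") hits <- hits + 1
  }
  expect_gte(hits, 9)
})
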