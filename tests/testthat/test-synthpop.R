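test_that("founder pool follows the 1/f spectrum and is deterministic", {
  cfg <- sim_config(n_founders = 100L, n_sites = 10000L,
                    region_length = 2e6, n_proto_founders = 24L, seed = 7L)
  pool <- build_founder_pool(cfg)
  maf <- panel_freq(pool, minor = TRUE)
  poly <- maf > 0
  expect_gt(mean(maf[poly] < 0.05), mean(maf[poly] > 0.20))

  pool2 <- build_founder_pool(cfg)
  expect_identical(pool$alleles, pool2$alleles)
  expect_identical(pool$site_map, pool2$site_map)
})

test_that("two founders force every polymorphic site to frequency 0.5", {
  cfg <- sim_config(n_founders = 2L, n_sites = 500L, region_length = 1e5,
                    n_proto_founders = 2L, seed = 3L)
  pool <- build_founder_pool(cfg)
  f <- panel_freq(pool)
  expect_true(all(f[f > 0 & f < 1] == 0.5))
})

test_that("founder pool rejects an empty region", {
  expect_error(sim_config(n_sites = 0L), "n_sites")
})

test_that("mosaic copying matches its limit behaviors", {
  cfg <- small_cfg()
  founders <- build_founder_pool(cfg)
  # zero switch rate: output is one founder verbatim
  h <- sample_mosaic_haplotype(founders, switch_rate = 0, seed = 11)
  donor <- attr(h, "donor")
  expect_length(unique(donor), 1L)
  expect_identical(as.integer(h), unname(founders$alleles[donor[1], ]))
  # huge switch rate: donor changes at essentially every interval
  h2 <- sample_mosaic_haplotype(founders, switch_rate = 1e7, seed = 12)
  d2 <- attr(h2, "donor")
  expect_gt(mean(d2[-1] != d2[-length(d2)]), 0.95)
  expect_error(sample_mosaic_haplotype(founders, switch_rate = -1),
               "switch_rate")
})

test_that("mosaic boundary count matches the Poisson expectation", {
  # 10 switches/Morgan over a 100 cM map: expect ~10 boundaries
  n <- 500L
  sm <- site_map(chrom = "1", pos = seq_len(n) * 1000L,
                 id = as.character(seq_len(n)), ref = "A", alt = "C",
                 cm = seq(0, 100, length.out = n))
  founders <- hap_panel(matrix(0L, 50, n), sm)
  set.seed(99)
  counts <- replicate(500, {
    d <- attr(sample_mosaic_haplotype(founders, switch_rate = 10), "donor")
    sum(d[-1] != d[-length(d)])
  })
  se <- sqrt(10 / 500)
  expect_lt(abs(mean(counts) - 10), 3 * se + 0.15)  # + discretization slack
})

test_that("allele frequency divergence grows with drift and bottleneck", {
  divergence <- function(cfg) {
    ts <- simulate_populations(cfg)
    pg <- panel_freq(ts$global_panel)
    pl <- colMeans(ts$local_truth$alleles)
    mean(abs(pl - pg))
  }
  res <- t(sapply(1:5, function(sd) {
    c(none = divergence(small_cfg(seed = sd, drift_generations = 0L,
                                  local_founder_fraction = 1.0)),
      drifted = divergence(small_cfg(seed = sd, drift_generations = 20L,
                                     local_founder_fraction = 0.3)))
  }))
  expect_true(all(res[, "drifted"] > res[, "none"]))
})

test_that("simulated populations respect ascertainment and pairing", {
  ts <- simulate_populations(small_cfg(seed = 4L,
                                       array_ascertainment_maf = 0.1))
  maf_g <- panel_freq(ts$global_panel, minor = TRUE)
  expect_true(all(maf_g[ts$site_map$is_array] >= 0.1))
  expect_lt(sum(ts$site_map$is_array), nrow(ts$site_map))
  expect_equal(n_haps(ts$local_truth), 2L * 12L)
  expect_identical(ts$global_panel$site_map, ts$site_map)
  # determinism of the full truth set
  ts2 <- simulate_populations(small_cfg(seed = 4L,
                                        array_ascertainment_maf = 0.1))
  expect_identical(ts$local_truth$alleles, ts2$local_truth$alleles)
  expect_identical(ts$local_called$calls, ts2$local_called$calls)
})

test_that("genotype error injection matches its binomial contract", {
  cfg <- small_cfg(seed = 6L)
  ts <- simulate_populations(cfg)
  truth <- panel_genotypes(ts$local_truth)

  gm0 <- inject_genotype_errors(ts$local_truth, rate = 0, seed = 1)
  expect_identical(unname(gm0$calls), unname(truth))

  # larger panel for a tight binomial check
  big <- simulate_populations(sim_config(n_founders = 60L, n_sites = 1000L,
                                         region_length = 1e6,
                                         n_proto_founders = 12L,
                                         n_global_haps = 40L,
                                         n_local_subjects = 90L,
                                         drift_generations = 0L,
                                         drift_pool_haps = 180L, seed = 8L))
  bt <- panel_genotypes(big$local_truth)
  gm <- inject_genotype_errors(big$local_truth, rate = 0.01, seed = 2)
  n <- length(bt)
  obs <- mean(gm$calls != bt)
  se <- sqrt(0.01 * 0.99 / n)
  expect_lt(abs(obs - 0.01), 3 * se)

  # flag_prob = 1: masking GQ < 20 removes every injected error
  gm1 <- inject_genotype_errors(big$local_truth, rate = 0.01,
                                quality_model = list(flag_prob = 1,
                                                     qual_fail_fraction = 0),
                                seed = 3)
  masked <- gm1$calls
  masked[gm1$gq < 20] <- NA_integer_
  ok <- !is.na(masked)
  expect_true(all(masked[ok] == bt[ok]))
})

test_that("switch-error injection preserves genotypes and matches its rate", {
  cfg <- sim_config(n_founders = 60L, n_sites = 400L, region_length = 4e5,
                    n_proto_founders = 12L, n_global_haps = 40L,
                    n_local_subjects = 200L, drift_generations = 0L,
                    drift_pool_haps = 400L, seed = 9L)
  ts <- simulate_populations(cfg)
  expect_identical(inject_switch_errors(ts$local_truth, 0),
                   ts$local_truth)
  sw <- inject_switch_errors(ts$local_truth, 0.05, seed = 10)
  expect_identical(panel_genotypes(sw), panel_genotypes(ts$local_truth))

  # count realized phase switches per subject against binomial expectation
  subj <- unique(na.omit(sw$subject_ids))
  n_sw <- exp_sw <- numeric(length(subj))
  for (i in seq_along(subj)) {
    rows <- which(sw$subject_ids == subj[i])
    h_old <- ts$local_truth$alleles[rows[1], ]
    h_new <- sw$alleles[rows[1], ]
    het <- which(ts$local_truth$alleles[rows[1], ] !=
                   ts$local_truth$alleles[rows[2], ])
    if (length(het) < 2) { n_sw[i] <- NA; next }
    state <- h_new[het] != h_old[het]
    n_sw[i] <- sum(diff(state) != 0)
    exp_sw[i] <- 0.05 * (length(het) - 1)
  }
  ok <- !is.na(n_sw)
  se <- sqrt(sum(0.05 * 0.95 * (exp_sw[ok] / 0.05))) / sum(ok)
  expect_lt(abs(mean(n_sw[ok]) - mean(exp_sw[ok])), 3 * se)
})

test_that("array sites are a strict subset and indels are flagged non-SNV", {
  ts <- simulate_populations(small_cfg(seed = 5L))
  expect_true(all(which(ts$site_map$is_array) %in% seq_len(nrow(ts$site_map))))
  expect_true(any(!is_snv(ts$site_map)))
  expect_true(all(is_snv(ts$site_map)[ts$site_map$is_array]))
})
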