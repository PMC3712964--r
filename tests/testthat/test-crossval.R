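test_that("leave-one-out removes exactly one subject's haplotype pair", {
  ts <- simulate_populations(small_cfg(seed = 31L))
  panel <- ts$local_truth
  s <- unique(na.omit(panel$subject_ids))[3]
  loo <- leave_one_out_panel(panel, s)
  expect_equal(n_haps(loo), n_haps(panel) - 2L)
  expect_false(s %in% loo$subject_ids)
  # removing then re-adding restores the panel up to haplotype order
  rows <- which(panel$subject_ids == s)
  restored <- hap_panel(rbind(loo$alleles, panel$alleles[rows, ]),
                        panel$site_map,
                        c(loo$hap_ids, panel$hap_ids[rows]),
                        c(loo$subject_ids, panel$subject_ids[rows]))
  ord <- match(panel$hap_ids, restored$hap_ids)
  expect_identical(restored$alleles[ord, ], panel$alleles)
  expect_error(leave_one_out_panel(panel, "nobody"), "unknown")
})

test_that("a 91-subject local panel leaves 180 haplotypes per imputation", {
  sm <- make_site_map_n(3)
  subj <- sprintf("S%03d", 1:91)
  panel <- hap_panel(matrix(0L, 182, 3), sm,
                     hap_ids = paste0(rep(subj, each = 2), c("a", "b")),
                     subject_ids = rep(subj, each = 2))
  expect_equal(n_haps(leave_one_out_panel(panel, "S001")), 180L)
})

test_that("snp_r2 matches the textbook formula and its invariances", {
  truth <- c(0, 1, 2, 1)
  dos <- c(0.1, 0.9, 1.7, 1.3)
  expect_equal(snp_r2(dos, truth), r2_formula_oracle(dos, truth))
  expect_equal(snp_r2(truth, truth), 1)
  expect_equal(snp_r2(2 - truth, truth), 1)  # affine invariance
  expect_true(is.na(snp_r2(c(1, 1, 1), c(0, 1, 2))))   # zero variance
  expect_true(is.na(snp_r2(c(1, NA), c(0, 1))))        # < 2 complete pairs
  expect_equal(snp_r2(c(dos, 5), c(truth, NA)),        # complete-case
               snp_r2(dos, truth))
  expect_error(snp_r2(1:3, 1:4), "length")
})

test_that("MAF bins follow the sqrt-10 boundaries", {
  expect_equal(as.character(assign_maf_bin(0.05)), "3.2-10%")
  expect_equal(as.character(assign_maf_bin(0.01)), "1-3.2%")
  expect_equal(as.character(assign_maf_bin(0.5)), ">32%")
  expect_equal(as.character(assign_maf_bin(0.0099)), "<1%")
  expect_equal(as.character(assign_maf_bin(10^-1.5)), "3.2-10%")
  expect_error(assign_maf_bin(0), "MAF")
  expect_error(assign_maf_bin(0.6), "MAF")
  expect_equal(as.character(assign_global_band(c(0.005, 0.02, 0.2))),
               c("<1%", "1-3.2%", ">3.2%"))
})

test_that("bin summaries compute increase statistics correctly", {
  tab <- data.frame(id = c("a", "b"), pos = 1:2,
                    maf_local = c(0.02, 0.02), maf_global = c(0.02, 0.02),
                    r2_one_panel = c(0.5, NA), r2_two_panel = c(0.7, 0.2),
                    n_subjects_used = c(10L, 10L))
  s <- summarize_bins(tab)
  row <- s[s$bin == "1-3.2%", ]
  expect_equal(row$n_snps, 1L)
  expect_equal(row$mean_increase, 0.2)
  expect_true(is.na(row$sd_increase))
  expect_equal(attr(s, "n_undefined"), 1L)
  expect_equal(s$n_snps[s$bin == ">32%"], 0L)
})

test_that("standard errors agree with a bootstrap oracle", {
  set.seed(88)
  n <- 1000L
  inc <- rnorm(n, 0.1, 0.05)
  tab <- data.frame(id = as.character(seq_len(n)), pos = seq_len(n),
                    maf_local = rep(0.02, n), maf_global = rep(0.02, n),
                    r2_one_panel = rep(0.5, n),
                    r2_two_panel = 0.5 + inc,
                    n_subjects_used = rep(90L, n))
  s <- summarize_bins(tab)
  se <- s$se_increase[s$bin == "1-3.2%"]
  boot <- replicate(400, mean(sample(inc, n, replace = TRUE)))
  expect_lt(abs(se - 0.05 / sqrt(n)), 3 * sd(boot))
  expect_lt(abs(se - sd(boot)), 3 * sd(boot))
  expect_lt(s$t_p_vs_zero[s$bin == "1-3.2%"], 1e-10)
})

test_that("effective sample size conversion reproduces printed cells", {
  expect_equal(round(ess_increase(0.504, 0.697)), 38)
  expect_equal(round(ess_increase(0.586, 0.753)), 28)
  expect_equal(ess_increase(0.42, 0.42), 0)
  expect_error(ess_increase(0, 0.5), "> 0")
})

test_that("poor-to-well crosstab fractions match fixture arithmetic", {
  n <- 100L
  r2_one <- rep(0.9, n); r2_one[1:10] <- 0.1
  r2_two <- rep(0.95, n); r2_two[1:10] <- 0.1; r2_two[1:2] <- 0.9
  tab <- data.frame(id = as.character(1:n), pos = 1:n,
                    maf_local = 0.1, maf_global = 0.1,
                    r2_one_panel = r2_one, r2_two_panel = r2_two,
                    n_subjects_used = 90L)
  ct <- poor_to_well_crosstab(tab)
  expect_equal(ct$frac_poor, 0.10)
  expect_equal(ct$frac_poor_to_well, 0.20)
  all_good <- tab
  all_good$r2_one_panel <- 1; all_good$r2_two_panel <- 1
  ct2 <- poor_to_well_crosstab(all_good)
  expect_equal(ct2$frac_poor, 0)
  expect_true(is.na(ct2$frac_poor_to_well))
  expect_error(poor_to_well_crosstab(tab, poor = 0.5, well = 0.5),
               "thresholds")
})

test_that("improvement grid reproduces planted cell structure", {
  tab <- data.frame(
    id = as.character(1:40), pos = 1:40,
    maf_local = rep(c(0.02, 0.05), each = 20),
    maf_global = rep(c(0.005, 0.2), 20),
    r2_one_panel = 0.4,
    r2_two_panel = 0.4 + rep(c(0.3, 0.1), 20),  # global-rare cells gain more
    n_subjects_used = 90L
  )
  g <- improvement_grid(tab)
  expect_equal(g$count["1-3.2%", "<1%"], 10)
  expect_equal(g$mean_increase["1-3.2%", "<1%"], 0.3)
  expect_equal(g$mean_increase["1-3.2%", "10-32%"], 0.1)
  expect_true(all(is.na(g$mean_increase[g$count == 0])))
  one <- improvement_grid(tab[tab$maf_local == 0.02 &
                                tab$maf_global == 0.005, ])
  pop <- which(one$count > 0)
  expect_length(pop, 1)
  expect_equal(one$mean_increase[pop], 0.3)
})

test_that("cross-validation scores a small truth set end to end", {
  ts <- simulate_populations(small_cfg(seed = 33L))
  tab <- run_crossval(ts)
  expect_s3_class(tab, "accuracy_table")
  def <- tab[!is.na(tab$r2_one_panel), ]
  expect_gt(nrow(def), 0)
  expect_true(all(def$r2_one_panel >= 0 & def$r2_one_panel <= 1))
  expect_true(all(def$r2_two_panel >= 0 & def$r2_two_panel <= 1))
  expect_true(all(tab$n_subjects_used <= 12L))
  # determinism
  tab2 <- run_crossval(simulate_populations(small_cfg(seed = 33L)))
  expect_equal(tab, tab2)
  # a truth set with too few subjects errors
  tiny <- simulate_populations(small_cfg(seed = 34L, n_local_subjects = 2L,
                                         drift_pool_haps = 72L))
  expect_error(run_crossval(tiny), "3 sequenced")
})

test_that("perfect dosages give r2 = 1 and monomorphic sites undefined", {
  ts <- simulate_populations(small_cfg(seed = 35L, genotype_error_rate = 0))
  truth <- panel_genotypes(ts$local_truth)
  poly <- which(apply(truth, 2, var) > 0)
  mono <- which(apply(truth, 2, var) == 0)
  expect_equal(snp_r2(truth[, poly[1]], truth[, poly[1]]), 1)
  if (length(mono) > 0)
    expect_true(is.na(snp_r2(truth[, mono[1]] + 0.0, truth[, mono[1]])))
})
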