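random_hmm_instance <- function(H, L, miss_frac = 0.1) {
  alleles <- matrix(sample(c(0L, 1L), H * L, replace = TRUE), H, L)
  alleles[sample(length(alleles), round(miss_frac * length(alleles)))] <-
    NA_integer_
  obs <- sample(c(0L, 1L, NA), L, replace = TRUE)
  ns <- runif(L - 1, 0.2, 1)
  lambda <- runif(1, 0.01, 0.3)
  sm <- make_site_map_n(L)
  list(panel = hap_panel(alleles, sm), obs = obs, ns = ns, lambda = lambda)
}

fb_via_package <- function(inst) {
  # drive the exported interface with the instance's exact transition
  # probabilities by inverting the genetic-distance formula
  params <- hmm_params(Ne = 20000, lambda = inst$lambda)
  H <- n_haps(inst$panel)
  d_cm <- -log(inst$ns) * 100 * H / (4 * params$Ne)
  sm <- inst$panel$site_map
  sm$cm <- cumsum(c(0, d_cm))
  panel <- hap_panel(inst$panel$alleles, sm, inst$panel$hap_ids)
  forward_backward(inst$obs, panel, params)
}

test_that("lambda follows the Watterson-style closed form", {
  expect_equal(compute_lambda(2), 1 / 6)
  expect_equal(compute_lambda(4), 0.06)
  lam <- vapply(2:1000, compute_lambda, numeric(1))
  expect_true(all(diff(lam) < 0))
  expect_true(all(lam > 0 & lam <= 0.25))
  expect_error(compute_lambda(1), "at least 2")
})

test_that("no-switch probability has the right form and monotonicity", {
  expect_equal(no_switch_prob(0, 20000, 100), 1)
  expect_equal(no_switch_prob(0.01, 20000, 200), exp(-0.04))
  expect_true(no_switch_prob(0.2, 20000, 100) <
                no_switch_prob(0.1, 20000, 100))
  expect_true(no_switch_prob(0.1, 40000, 100) <
                no_switch_prob(0.1, 20000, 100))
  expect_true(no_switch_prob(0.1, 20000, 200) >
                no_switch_prob(0.1, 20000, 100))
  expect_error(no_switch_prob(-1, 20000, 100), ">= 0")
})

test_that("single-haplotype panel pins the posterior", {
  sm <- make_site_map_n(5)
  panel <- hap_panel(matrix(c(0L, 1L, 0L, 1L, 0L), 1, 5), sm)
  g <- forward_backward(c(0L, NA, 0L, NA, 0L), panel, hmm_params())
  expect_equal(unname(g), matrix(1, 1, 5))
})

test_that("posterior splits evenly over perfectly matching haplotypes", {
  sm <- make_site_map_n(4, cm = rep(0, 4))  # zero distances: no switching
  alleles <- rbind(c(0L, 1L, 0L, 1L),
                   c(0L, 1L, 0L, 1L),
                   c(1L, 0L, 1L, 0L),
                   c(1L, 1L, 1L, 1L),
                   c(0L, 0L, 0L, 0L))
  panel <- hap_panel(alleles, sm)
  g <- forward_backward(c(0L, 1L, 0L, 1L), panel,
                        hmm_params(lambda = 1e-12))
  expect_equal(unname(g[1, ]), rep(0.5, 4), tolerance = 1e-6)
  expect_equal(unname(g[2, ]), rep(0.5, 4), tolerance = 1e-6)
  expect_lt(max(g[3:5, ]), 1e-6)
})

test_that("forward-backward equals the path-enumeration oracle", {
  set.seed(2024)
  for (i in 1:30) {
    H <- sample(2:4, 1)
    L <- sample(3:6, 1)
    inst <- random_hmm_instance(H, L)
    if (all(is.na(inst$obs))) inst$obs[1] <- 0L
    got <- fb_via_package(inst)
    want <- fb_enum_oracle(inst$panel$alleles, inst$obs, inst$ns,
                           inst$lambda)
    expect_lt(max(abs(got - want)), 1e-9)
    expect_equal(unname(colSums(got)), rep(1, L), tolerance = 1e-9)
  }
})

test_that("reversing sites reverses the posteriors", {
  set.seed(77)
  inst <- random_hmm_instance(4, 6)
  inst$obs[1] <- 1L
  got <- fb_via_package(inst)
  rev_inst <- list(panel = hap_panel(inst$panel$alleles[, 6:1],
                                     inst$panel$site_map),
                   obs = inst$obs[6:1], ns = rev(inst$ns),
                   lambda = inst$lambda)
  got_rev <- fb_via_package(rev_inst)
  expect_lt(max(abs(got - got_rev[, 6:1])), 1e-9)
})

test_that("all-missing observations warn and return uniform posteriors", {
  sm <- make_site_map_n(3)
  panel <- hap_panel(matrix(c(0L, 1L), 2, 3), sm)
  expect_warning(g <- forward_backward(rep(NA_integer_, 3), panel),
                 "missing")
  expect_equal(unname(g), matrix(0.5, 2, 3))
})

test_that("subset observations are validated against the grid", {
  sm <- make_site_map_n(5)
  panel <- hap_panel(matrix(0L, 2, 5), sm)
  expect_error(forward_backward(c(0L, 1L), panel, obs_sites = c(2L, 9L)),
               "outside")
  expect_error(forward_backward(c(0L, 1L, 0L), panel), "match grid|match")
})

test_that("dosage reproduces truth when the panel contains the donors", {
  cfg <- sim_config(n_founders = 60L, n_sites = 800L, region_length = 8e5,
                    map_length = 0.8, n_proto_founders = 12L,
                    n_global_haps = 80L, n_local_subjects = 40L,
                    drift_generations = 0L, local_founder_fraction = 1,
                    drift_pool_haps = 80L, genotype_error_rate = 0,
                    seed = 21L)
  ts <- simulate_populations(cfg)
  truth <- panel_genotypes(ts$local_truth)
  typed <- ts$site_map$is_array
  # panel deliberately includes the subject's own haplotypes (no LOO here)
  panel <- hap_panel(rbind(ts$global_panel$alleles, ts$local_truth$alleles),
                     ts$site_map)
  acc <- sapply(1:10, function(i) {
    rows <- which(ts$local_truth$subject_ids ==
                    rownames(truth)[i])
    d <- impute_dosage(ts$local_truth$alleles[rows, ], panel,
                       typed = typed)
    mean(round(d) == truth[i, ])
  })
  expect_gte(mean(acc), 0.99)
})

test_that("noiseless typed sites reproduce observed genotypes as lambda -> 0", {
  ts <- simulate_populations(small_cfg(seed = 22L))
  typed <- ts$site_map$is_array
  s <- unique(na.omit(ts$local_truth$subject_ids))[1]
  rows <- which(ts$local_truth$subject_ids == s)
  haps <- ts$local_truth$alleles[rows, ]
  d <- impute_dosage(haps, ts$global_panel,
                     hmm_params(lambda = 1e-9), typed = typed)
  expect_equal(d[typed], unname(colSums(haps))[typed], tolerance = 1e-5)
})

test_that("duplicating the panel leaves dosages unchanged at fixed lambda", {
  ts <- simulate_populations(small_cfg(seed = 23L))
  typed <- ts$site_map$is_array
  s <- unique(na.omit(ts$local_truth$subject_ids))[2]
  rows <- which(ts$local_truth$subject_ids == s)
  haps <- ts$local_truth$alleles[rows, ]
  d1 <- impute_dosage(haps, ts$global_panel,
                      hmm_params(Ne = 20000, lambda = 0.01), typed = typed)
  dup <- hap_panel(ts$global_panel$alleles, ts$site_map,
                   hap_ids = paste0("dup", seq_len(n_haps(ts$global_panel))))
  # doubling H halves the per-state switch exponent, so hold 4*Ne/H fixed
  d2 <- impute_dosage(haps, list(ts$global_panel, dup),
                      hmm_params(Ne = 40000, lambda = 0.01), typed = typed)
  expect_equal(d1, d2, tolerance = 1e-8)
})

test_that("dosages stay within [0, 2] and the leave-one-out guard fires", {
  ts <- simulate_populations(small_cfg(seed = 24L))
  typed <- ts$site_map$is_array
  s <- unique(na.omit(ts$local_truth$subject_ids))[1]
  rows <- which(ts$local_truth$subject_ids == s)
  haps <- ts$local_truth$alleles[rows, ]
  d <- impute_dosage(haps, list(ts$global_panel,
                                leave_one_out_panel(ts$local_truth, s)),
                     typed = typed, subject_id = s)
  expect_true(all(d >= 0 & d <= 2))
  expect_error(
    impute_dosage(haps, list(ts$global_panel, ts$local_truth),
                  typed = typed, subject_id = s),
    "leave-one-out"
  )
})

test_that("two-panel combination aligns local sites onto the global grid", {
  sm <- make_site_map_n(4)
  g <- hap_panel(matrix(0L, 2, 4), sm, hap_ids = c("g1", "g2"))
  sm_local <- sm[c(1, 3), ]
  class(sm_local) <- c("site_map", "data.frame")
  l <- hap_panel(matrix(1L, 2, 2), sm_local, hap_ids = c("l1", "l2"))
  comb <- combine_panels(g, l)
  expect_equal(n_haps(comb), 4)
  expect_equal(unname(comb$alleles[3, ]), c(1L, NA, 1L, NA))
})
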