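# Small, fast simulation configs and hand-built QC fixtures.

small_cfg <- function(seed = 1L, ...) {
  defaults <- list(n_founders = 40L, n_sites = 160L, region_length = 4e5,
                   map_length = 0.4, n_proto_founders = 8L,
                   n_global_haps = 60L, n_local_subjects = 12L,
                   local_founder_fraction = 0.3, drift_generations = 5L,
                   drift_pool_haps = 72L, seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

make_site_map_n <- function(n, pos = seq_len(n) * 100L,
                            cm = pos / 1e5) {
  site_map(chrom = "chr1", pos = pos, id = sprintf("s%03d", seq_len(n)),
           ref = rep("A", n), alt = rep("G", n), cm = cm)
}

# QC cascade fixture: 20 sites, 10 subjects; plants 3 low-QUAL sites,
# 2 low-call-rate sites and 1 site monomorphic after GQ masking.
qc_cascade_fixture <- function() {
  n_sub <- 10L
  n_site <- 20L
  set.seed(42)
  # clean background: HWE-balanced genotypes at freq ~0.5
  calls <- matrix(sample(0:2, n_sub * n_site, replace = TRUE,
                         prob = c(0.25, 0.5, 0.25)), n_sub, n_site)
  gq <- matrix(60, n_sub, n_site)
  qual <- rep(100, n_site)
  qual[1:3] <- 30                      # fail site QUAL >= 40
  for (j in 4:5) calls[1:6, j] <- NA   # call rate 0.4 < 0.5
  calls[, 6] <- 0L                     # monomorphic except 2 het calls ...
  calls[1:2, 6] <- 1L
  gq[1:2, 6] <- 10                     # ... which GQ-masking removes
  gm <- geno_matrix(calls, make_site_map_n(n_site), gq, qual,
                    subjects = sprintf("P%02d", seq_len(n_sub)))
  gm
}

# Array/sequence merge fixture straddling the 50/30 mismatch thresholds:
# subject 1 gets 51 mismatches (excluded), subject 2 exactly 50 (kept);
# variant 1 gets 31 mismatches (excluded), variant 2 exactly 30 (kept).
merge_threshold_fixture <- function() {
  n_sub <- 35L
  n_site <- 60L
  sm <- make_site_map_n(n_site)
  subj <- sprintf("P%02d", seq_len(n_sub))
  seq_calls <- matrix(1L, n_sub, n_site)
  arr_calls <- seq_calls
  arr_calls[2:32, 1] <- 0L             # variant 1: 31 mismatches
  arr_calls[2:31, 2] <- 0L             # variant 2: 30 mismatches
  arr_calls[1, 3:53] <- 0L             # subject 1: 51 mismatches
  arr_calls[2, 3:50] <- 0L             # subject 2: 48 + 2 above = 50
  list(
    array = geno_matrix(arr_calls, sm, subjects = subj),
    seq = geno_matrix(seq_calls, sm, subjects = subj)
  )
}

# shared cache for the acceptance-scale cross-validation runs
.acceptance_cache <- new.env(parent = emptyenv())

reference_experiments <- function() {
  if (is.null(.acceptance_cache$runs)) {
    .acceptance_cache$runs <- lapply(1:5, function(sd) {
      list(ref = augmentation_experiment(sd),
           strong = augmentation_experiment(sd, drift_generations = 40L))
    })
  }
  .acceptance_cache$runs
}
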