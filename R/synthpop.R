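## Synthetic structured-population generator.
##
## LD is produced by founder-mosaic copying rather than a coalescent: every
## simulated haplotype is an imperfect mosaic of an ancestral founder pool,
## with copying switches placed by a Poisson process on the genetic map.
## Population drift is iterated re-mosaicking of the local haplotype pool
## over a founder subset, which shifts allele frequencies while preserving
## haplotype block structure -- exactly the situation in which a local
## reference panel should help a haplotype-copying imputation model.

make_site_map <- function(cfg) {
  if (cfg$region_length < cfg$n_sites)
    stop("region_length smaller than n_sites")
  if (cfg$n_sites == 0L) stop("empty region: n_sites must be >= 1")
  pos <- sort(sample.int(cfg$region_length, cfg$n_sites))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, cfg$n_sites, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  is_indel <- stats::runif(cfg$n_sites) < cfg$indel_fraction
  # short insertions: ALT gains one base, which marks the record non-SNV
  alt[is_indel] <- paste0(alt[is_indel],
                          sample(bases, sum(is_indel), replace = TRUE))
  site_map(
    chrom = "chr1",
    pos = pos,
    id = sprintf("var%06d", seq_len(cfg$n_sites)),
    ref = ref,
    alt = alt,
    cm = pos / cfg$region_length * cfg$map_length,
    is_exomic = stats::runif(cfg$n_sites) < cfg$exome_fraction,
    is_array = FALSE,
    is_multimap = stats::runif(cfg$n_sites) < cfg$multimap_fraction
  )
}

draw_founder_freqs <- function(n_sites, n_founders, alpha) {
  fmin <- 1 / (2 * n_founders)
  u <- stats::runif(n_sites)
  if (abs(alpha - 1) < 1e-12) {
    fmin * (0.5 / fmin)^u
  } else {
    a <- 1 - alpha
    (fmin^a + u * (0.5^a - fmin^a))^(1 / a)
  }
}

.founder_pool <- function(cfg, sm) {
  L <- cfg$n_sites
  nf <- cfg$n_founders
  np <- min(cfg$n_proto_founders, nf)
  f <- draw_founder_freqs(L, nf, cfg$freq_spectrum_alpha)

  # old (common) variants segregate among the proto backgrounds; founders
  # are mosaics of those backgrounds
  proto <- matrix(as.integer(stats::runif(np * L) < rep(f, each = np)),
                  nrow = np)
  p_sw <- interval_switch_prob(sm$cm, cfg$founder_block_rate)
  alleles <- mosaic_matrix(proto, p_sw, nf)

  # young (rare) variants are mutations on individual founders: other
  # founders carry the same background without the allele
  young <- f < 1 / np
  if (any(young)) {
    ny <- sum(young)
    alleles[, young] <- matrix(
      as.integer(stats::runif(nf * ny) < rep(f[young], each = nf)),
      nrow = nf)
  }
  hap_panel(alleles, sm, hap_ids = sprintf("FND%04d", seq_len(nf)))
}

#' Build the ancestral founder haplotype pool
#'
#' Draws per-site founder allele frequencies from a truncated power-law
#' site-frequency spectrum with density proportional to `f^(-alpha)` on
#' `[1/(2 n_founders), 0.5]` and samples founder alleles independently from
#' those frequencies. With `alpha = 1` rare variants dominate the pool, as
#' in neutral sequence data.
#'
#' @param cfg a [sim_config()]; uses `n_founders`, `n_sites`,
#'   `freq_spectrum_alpha` and `seed`.
#' @return A [hap_panel] of `n_founders` haplotypes over a freshly drawn
#'   site map. Deterministic given `cfg$seed`.
#' @export
build_founder_pool <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  sm <- make_site_map(cfg)
  .founder_pool(cfg, sm)
}

interval_switch_prob <- function(cm, rate_per_morgan) {
  1 - exp(-rate_per_morgan * diff(cm) / 100)
}

mosaic_one <- function(alleles, p_switch) {
  L <- ncol(alleles)
  H <- nrow(alleles)
  if (H == 1L) {
    out <- alleles[1L, ]
    attr(out, "donor") <- rep(1L, L)
    return(out)
  }
  sw <- which(stats::runif(L - 1) < p_switch)
  donors <- integer(length(sw) + 1L)
  donors[1L] <- sample.int(H, 1L)
  if (length(sw) > 0) {
    for (j in seq_along(sw)) {
      # switch always moves to a *different* donor haplotype
      d <- sample.int(H - 1L, 1L)
      donors[j + 1L] <- if (d >= donors[j]) d + 1L else d
    }
  }
  donor_per_site <- donors[findInterval(seq_len(L) - 1L, sw) + 1L]
  out <- alleles[cbind(donor_per_site, seq_len(L))]
  attr(out, "donor") <- donor_per_site
  out
}

#' Sample one mosaic haplotype from a donor panel
#'
#' The copied donor haplotype changes between adjacent sites with
#' probability `1 - exp(-switch_rate * d)` where `d` is the inter-site
#' genetic distance in Morgans; at a switch the new donor is drawn uniformly
#' from the other haplotypes. The realized donor index per site is attached
#' as attribute `"donor"`.
#'
#' @param founders a [hap_panel] of donor haplotypes.
#' @param sm site map supplying genetic positions (defaults to the panel's).
#' @param switch_rate copying switch rate per Morgan, `>= 0`.
#' @param seed optional integer seed for a standalone reproducible draw.
#' @return Integer allele vector over the panel's sites.
#' @export
sample_mosaic_haplotype <- function(founders, sm = founders$site_map,
                                    switch_rate, seed = NULL) {
  if (switch_rate < 0) stop("switch_rate must be >= 0")
  if (n_haps(founders) < 1) stop("founder panel is empty")
  if (!is.null(seed)) set.seed(seed)
  p <- interval_switch_prob(sm$cm, switch_rate)
  mosaic_one(founders$alleles, p)
}

mosaic_matrix <- function(alleles, p_switch, n_out) {
  out <- matrix(0L, n_out, ncol(alleles))
  for (i in seq_len(n_out)) out[i, ] <- mosaic_one(alleles, p_switch)
  out
}

.inject_errors <- function(panel, rate, qm) {
  g <- panel_genotypes(panel)
  n <- nrow(g); L <- ncol(g)
  err <- matrix(stats::runif(n * L) < rate, n, L)
  calls <- g
  flip_up <- matrix(stats::runif(n * L) < 0.5, n, L)
  calls[err & g == 0L] <- 1L
  calls[err & g == 2L] <- 1L
  calls[err & g == 1L & flip_up] <- 2L
  calls[err & g == 1L & !flip_up] <- 0L
  gq <- matrix(stats::runif(n * L, 30, 99), n, L)
  flagged <- err & matrix(stats::runif(n * L) < qm$flag_prob, n, L)
  gq[flagged] <- stats::runif(sum(flagged), 2, 19)
  fail_site <- stats::runif(L) < qm$qual_fail_fraction
  sq <- ifelse(fail_site, stats::runif(L, 10, 39.5), stats::runif(L, 40, 200))
  geno_matrix(calls, panel$site_map, gq = round(gq, 1),
              site_qual = round(sq, 1),
              subjects = unique(stats::na.omit(panel$subject_ids)))
}

#' Derive error-injected genotype calls from truth haplotypes
#'
#' Forms diploid genotypes from each subject's haplotype pair and perturbs
#' each call independently with probability `rate` (adjacent-state moves:
#' hom to het, het to either hom). Erroneous calls receive a low
#' (GQ < 20) phred genotype quality with probability
#' `quality_model$flag_prob`, so GQ masking catches a tunable share of the
#' injected errors; correct calls always have GQ >= 30. Per-site QUAL is
#' drawn so that about `quality_model$qual_fail_fraction` of sites fall
#' below the 40 threshold.
#'
#' @param panel a subject-paired [hap_panel] of truth haplotypes.
#' @param rate per-call error probability in `[0, 1)`.
#' @param quality_model list with `flag_prob` and `qual_fail_fraction`.
#' @param seed optional integer seed.
#' @return A [geno_matrix].
#' @export
inject_genotype_errors <- function(panel, rate,
                                   quality_model = list(
                                     flag_prob = 0.5,
                                     qual_fail_fraction = 0.02),
                                   seed = NULL) {
  if (rate < 0 || rate >= 1) stop("error rate must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  .inject_errors(panel, rate, quality_model)
}

.inject_switch <- function(panel, rate) {
  a <- panel$alleles
  subjects <- unique(stats::na.omit(panel$subject_ids))
  for (s in subjects) {
    rows <- which(panel$subject_ids == s)
    h1 <- a[rows[1], ]; h2 <- a[rows[2], ]
    het <- which(!is.na(h1) & !is.na(h2) & h1 != h2)
    if (length(het) < 2) next
    tog <- stats::runif(length(het) - 1) < rate
    swapped <- c(FALSE, cumsum(tog) %% 2 == 1)
    sw <- het[swapped]
    if (length(sw) > 0) {
      tmp <- h1[sw]; h1[sw] <- h2[sw]; h2[sw] <- tmp
      a[rows[1], ] <- h1; a[rows[2], ] <- h2
    }
  }
  hap_panel(a, panel$site_map, panel$hap_ids, panel$subject_ids)
}

#' Inject phase switch errors into subject haplotype pairs
#'
#' Between consecutive heterozygous sites the phase state flips with
#' probability `rate`; from a flip onward the two haplotypes' alleles are
#' exchanged at heterozygous sites. Diploid genotypes are unchanged by
#' construction. Emulates imperfect statistical phasing of the local
#' reference panel.
#'
#' @param panel a subject-paired [hap_panel].
#' @param rate per-interval switch probability in `[0, 1)`.
#' @param seed optional integer seed.
#' @return A [hap_panel] with the same genotypes and perturbed phase.
#' @export
inject_switch_errors <- function(panel, rate, seed = NULL) {
  if (rate < 0 || rate >= 1) stop("switch rate must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  if (rate == 0) return(panel)
  .inject_switch(panel, rate)
}

#' Simulate a global reference panel and a drifted local cohort
#'
#' Runs the full generator: ancestral founder pool, global panel of mosaics
#' over all founders, a local isolate founded by a random subset of
#' `ceiling(local_founder_fraction * n_founders)` founders and drifted by
#' `drift_generations` rounds of re-mosaicking, array-site ascertainment on
#' global-panel MAF, and error-injected sequence and array genotype calls
#' for the local subjects.
#'
#' @param cfg a [sim_config()].
#' @return A list of class `truth_set` with elements:
#' \describe{
#'   \item{global_panel}{[hap_panel] of `n_global_haps` haplotypes.}
#'   \item{local_truth}{subject-paired [hap_panel], 2 haplotypes per local
#'     subject (the gold-standard phase).}
#'   \item{local_panel}{`local_truth` after optional phase-switch-error
#'     injection; what the imputation stage uses as the local reference.}
#'   \item{local_called}{[geno_matrix] of error-injected sequence calls
#'     with GQ/QUAL (the "called" exome data).}
#'   \item{local_array_called}{[geno_matrix] of array genotypes at array
#'     sites only.}
#'   \item{site_map}{shared [site_map] with `is_array` filled in.}
#'   \item{founder_subset}{indices of founders ancestral to the isolate.}
#'   \item{config}{the input configuration.}
#' }
#' @export
simulate_populations <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  sm <- make_site_map(cfg)
  founders <- .founder_pool(cfg, sm)
  p_switch <- interval_switch_prob(sm$cm, cfg$mosaic_switch_rate)

  global_alleles <- mosaic_matrix(founders$alleles, p_switch,
                                  cfg$n_global_haps)

  n_sub <- ceiling(cfg$local_founder_fraction * cfg$n_founders)
  founder_subset <- sort(sample.int(cfg$n_founders, n_sub))
  if (length(founder_subset) == 0) stop("local founder subset is empty")
  pool <- founders$alleles[founder_subset, , drop = FALSE]
  n_local_haps <- 2L * cfg$n_local_subjects
  pool <- mosaic_matrix(pool, p_switch, cfg$drift_pool_haps)  # bottleneck
  # one drift generation = one meiosis: re-mosaic at the meiotic rate
  p_meiosis <- interval_switch_prob(sm$cm, cfg$drift_switch_rate)
  for (g in seq_len(cfg$drift_generations))
    pool <- mosaic_matrix(pool, p_meiosis, cfg$drift_pool_haps)
  # the sequenced cohort is a sample of the isolate's breeding pool
  cohort <- pool[sample.int(nrow(pool), n_local_haps), , drop = FALSE]

  subj <- sprintf("LOC%03d", seq_len(cfg$n_local_subjects))
  local_truth <- hap_panel(
    cohort, sm,
    hap_ids = paste0(rep(subj, each = 2), c("_h1", "_h2")),
    subject_ids = rep(subj, each = 2)
  )
  global_panel <- hap_panel(global_alleles, sm,
                            hap_ids = sprintf("GLB%04d",
                                              seq_len(cfg$n_global_haps)))

  maf_global <- panel_freq(global_panel, minor = TRUE)
  ascertainable <- is_snv(sm) & !sm$is_multimap &
    maf_global >= cfg$array_ascertainment_maf
  # arrays tag a subset of common variation, not all of it
  on_array <- stats::runif(nrow(sm)) < cfg$array_fraction
  sm$is_array <- ascertainable & on_array
  global_panel$site_map <- sm
  local_truth$site_map <- sm

  local_called <- .inject_errors(local_truth, cfg$genotype_error_rate,
                                 cfg$quality_model)
  local_panel <- if (cfg$phase_switch_rate > 0)
    .inject_switch(local_truth, cfg$phase_switch_rate) else local_truth

  array_sites <- which(sm$is_array)
  truth_array <- subset_panel(local_truth, sites = array_sites)
  array_called <- .inject_errors(
    truth_array, cfg$array_error_rate,
    list(flag_prob = 0, qual_fail_fraction = 0)
  )

  structure(
    list(global_panel = global_panel,
         local_truth = local_truth,
         local_panel = local_panel,
         local_called = local_called,
         local_array_called = array_called,
         site_map = sm,
         founder_subset = founder_subset,
         config = cfg),
    class = "truth_set"
  )
}

#' @export
print.truth_set <- function(x, ...) {
  cat("truth_set\n  ")
  print(x$site_map)
  cat("  global: ", n_haps(x$global_panel), " haplotypes; local: ",
      length(unique(stats::na.omit(x$local_truth$subject_ids))),
      " subjects\n", sep = "")
  invisible(x)
}
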