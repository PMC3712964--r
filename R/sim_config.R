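#' Simulation configuration
#'
#' Bundles every knob of the synthetic-population generator. The defaults
#' are the reference study conditions used throughout the package: a 3 Mb /
#' 3 cM exomic window, a 500-haplotype global reference panel, and a local
#' cohort of 90 diploid subjects sampled from a drifted isolate founded by
#' 15% of the ancestral founder pool and drifted for 20 generations at an
#' effective size of 540 diploids.
#'
#' @param n_founders ancestral founder haplotypes the mosaics copy from.
#' @param n_sites biallelic variant sites in the window.
#' @param region_length window length in base pairs.
#' @param map_length window length in centiMorgans.
#' @param freq_spectrum_alpha exponent of the site-frequency spectrum;
#'   founder allele frequencies are drawn with density proportional to
#'   `f^(-alpha)` on `[1/(2 n_founders), 0.5]`, so `alpha = 1` gives the
#'   neutral-like 1/f spectrum in which rare variants dominate.
#' @param n_proto_founders number of deep ancestral ("proto") haplotype
#'   backgrounds. Common (old) variants live at this level, so several
#'   founders share each local background; rare (young) variants are
#'   overlaid on individual founders, so a rare allele rides a background
#'   that other founders carry without it -- the reason array data alone
#'   identify the background but not the rare allele.
#' @param founder_block_rate switch rate per Morgan of the founder-level
#'   mosaic over proto backgrounds; sets the background block scale.
#' @param n_global_haps haplotypes in the global reference panel.
#' @param n_local_subjects diploid subjects in the local cohort.
#' @param local_founder_fraction fraction of founders ancestral to the local
#'   isolate, in (0, 1]. Smaller values mean a narrower bottleneck.
#' @param drift_generations generations of re-mosaicking drift applied to
#'   the local haplotype pool after the bottleneck.
#' @param drift_pool_haps size (haplotypes) of the isolate's breeding pool
#'   carried through the drift generations; the sequenced cohort is drawn
#'   from this pool, which is larger than the cohort itself (an isolate's
#'   effective size exceeds its sequenced sample).
#' @param mosaic_switch_rate haplotype-copying switch rate per Morgan used
#'   when drawing present-day haplotypes from the ancestral founder pool;
#'   it compresses many generations of ancestral recombination into one
#'   mosaic draw and sets the background LD block scale.
#' @param drift_switch_rate copying switch rate per Morgan per drift
#'   generation; one generation is one meiosis, so the default is the
#'   meiotic crossover rate of 1 per Morgan. Frequency drift itself comes
#'   from resampling the finite local haplotype pool each generation.
#' @param genotype_error_rate per-call probability that a sequence genotype
#'   call is perturbed to an adjacent genotype.
#' @param phase_switch_rate per-interval probability of a phase switch
#'   error between consecutive heterozygous sites in the local panel
#'   haplotypes (0 = perfect phase).
#' @param array_ascertainment_maf minimum global-panel MAF for a SNV to be
#'   placed on the genotyping array (commercial arrays are ascertained on
#'   globally common variation).
#' @param array_fraction fraction of ascertainable (globally common) SNVs
#'   actually placed on the array; arrays tag a subset of common variation
#'   rather than all of it, which leaves common off-array variants to be
#'   imputed.
#' @param exome_fraction fraction of sites flagged exomic (sequence
#'   coverage); the default 1 treats the whole window as an exomic target.
#' @param indel_fraction fraction of sites emitted as short indels rather
#'   than single-base substitutions.
#' @param multimap_fraction fraction of sites flagged as mapping to more
#'   than one homologous region.
#' @param array_error_rate per-call error rate of the array genotypes
#'   produced for the local subjects (used by the array-sequence merge).
#' @param quality_model list controlling simulated qualities:
#'   `flag_prob` is the probability an erroneous sequence call receives a
#'   low (GQ < 20) genotype quality, `qual_fail_fraction` the fraction of
#'   sites drawn with site QUAL below 40.
#' @param seed integer seed; identical configs give bit-identical output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 400L,
                       n_sites = 1500L,
                       region_length = 3e6,
                       map_length = 3,
                       freq_spectrum_alpha = 1,
                       n_proto_founders = 24L,
                       founder_block_rate = 200,
                       n_global_haps = 500L,
                       n_local_subjects = 90L,
                       local_founder_fraction = 0.15,
                       drift_generations = 20L,
                       drift_pool_haps = 1080L,
                       mosaic_switch_rate = 120,
                       drift_switch_rate = 1,
                       genotype_error_rate = 0.001,
                       phase_switch_rate = 0,
                       array_ascertainment_maf = 0.05,
                       array_fraction = 0.5,
                       exome_fraction = 1,
                       indel_fraction = 0.02,
                       multimap_fraction = 0.01,
                       array_error_rate = 0.001,
                       quality_model = list(flag_prob = 0.5,
                                            qual_fail_fraction = 0.02),
                       seed = 1L) {
  cfg <- list(
    n_founders = as.integer(n_founders),
    n_sites = as.integer(n_sites),
    region_length = as.numeric(region_length),
    map_length = as.numeric(map_length),
    freq_spectrum_alpha = as.numeric(freq_spectrum_alpha),
    n_proto_founders = as.integer(n_proto_founders),
    founder_block_rate = as.numeric(founder_block_rate),
    n_global_haps = as.integer(n_global_haps),
    n_local_subjects = as.integer(n_local_subjects),
    local_founder_fraction = as.numeric(local_founder_fraction),
    drift_generations = as.integer(drift_generations),
    drift_pool_haps = as.integer(drift_pool_haps),
    mosaic_switch_rate = as.numeric(mosaic_switch_rate),
    drift_switch_rate = as.numeric(drift_switch_rate),
    genotype_error_rate = as.numeric(genotype_error_rate),
    phase_switch_rate = as.numeric(phase_switch_rate),
    array_ascertainment_maf = as.numeric(array_ascertainment_maf),
    array_fraction = as.numeric(array_fraction),
    exome_fraction = as.numeric(exome_fraction),
    indel_fraction = as.numeric(indel_fraction),
    multimap_fraction = as.numeric(multimap_fraction),
    array_error_rate = as.numeric(array_error_rate),
    quality_model = quality_model,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c("n_founders", "n_sites", "n_global_haps", "n_local_subjects")
  for (f in counts)
    if (cfg[[f]] < 1L) stop(f, " must be >= 1")
  if (cfg$n_founders < 2L) stop("n_founders must be >= 2")
  if (cfg$map_length <= 0) stop("map_length must be > 0")
  if (cfg$mosaic_switch_rate < 0) stop("mosaic_switch_rate must be >= 0")
  if (cfg$drift_switch_rate < 0) stop("drift_switch_rate must be >= 0")
  if (cfg$n_proto_founders < 2L) stop("n_proto_founders must be >= 2")
  if (cfg$founder_block_rate < 0) stop("founder_block_rate must be >= 0")
  fracs <- c("local_founder_fraction", "genotype_error_rate",
             "phase_switch_rate", "array_ascertainment_maf",
             "array_fraction",
             "exome_fraction", "indel_fraction", "multimap_fraction",
             "array_error_rate")
  for (f in fracs)
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  if (cfg$local_founder_fraction <= 0)
    stop("local_founder_fraction must be > 0")
  if (cfg$genotype_error_rate >= 1) stop("genotype_error_rate must be < 1")
  if (cfg$drift_generations < 0L) stop("drift_generations must be >= 0")
  if (cfg$drift_pool_haps < 2L * cfg$n_local_subjects)
    stop("drift_pool_haps must be at least twice n_local_subjects")
  if (ceiling(cfg$local_founder_fraction * cfg$n_founders) < 1)
    stop("local founder subset is empty")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "sim_config: %d sites / %.1f Mb / %.1f cM; %d founders\n",
    "  global panel %d haplotypes; local cohort %d subjects ",
    "(founder fraction %.2f, %d drift generations)\n  seed %d\n"),
    x$n_sites, x$region_length / 1e6, x$map_length, x$n_founders,
    x$n_global_haps, x$n_local_subjects, x$local_founder_fraction,
    x$drift_generations, x$seed))
  invisible(x)
}
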