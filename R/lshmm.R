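## Haploid Li-Stephens haplotype-copying imputation engine.
##
## A target haplotype is modeled as an imperfect mosaic copy of the
## reference haplotypes: a hidden Markov chain over donor haplotypes with
## recombination-driven switching (rate scaled by effective population size
## and panel size) and mutation-driven miscopying. Posterior donor
## probabilities at every site -- typed or not -- convert directly into
## expected alternate-allele dosages.

#' HMM parameters for the haplotype-copying model
#'
#' @param Ne effective population size scaling the switch rate; the default
#'   20,000 is the value used for human imputation with IMPUTE-family
#'   settings.
#' @param lambda miscopy (mutation) probability; `NULL` derives it from the
#'   reference panel size via [compute_lambda()].
#' @param min_no_switch numerical floor on the per-interval no-switch
#'   probability.
#' @return A list of class `hmm_params`.
#' @export
hmm_params <- function(Ne = 20000, lambda = NULL, min_no_switch = 1e-12) {
  if (Ne < 1) stop("Ne must be >= 1")
  if (!is.null(lambda) && (lambda < 0 || lambda >= 0.5))
    stop("lambda must lie in [0, 0.5)")
  structure(list(Ne = as.numeric(Ne), lambda = lambda,
                 min_no_switch = as.numeric(min_no_switch)),
            class = "hmm_params")
}

#' Panel-size-derived miscopy probability
#'
#' Watterson-style mutation parameter `theta = 1 / sum_{i<H} 1/i` converted
#' to the per-site miscopy probability `lambda = theta / (2 (H + theta))`.
#' Strictly decreasing in the panel size `H`.
#'
#' @param H number of reference haplotypes, `>= 2`.
#' @return Miscopy probability in `(0, 0.25]`.
#' @examples
#' compute_lambda(2)   # 1/6
#' compute_lambda(4)   # 0.06
#' @export
compute_lambda <- function(H) {
  if (H < 2) stop("panel must contain at least 2 haplotypes")
  theta <- 1 / sum(1 / seq_len(H - 1))
  theta / (2 * (H + theta))
}

#' Per-interval probability of not switching copy donor
#'
#' The standard copying-model transition: over genetic distance `d` (in
#' centiMorgans) the donor is retained with probability
#' `exp(-4 Ne (d/100) / H)`; the complementary switch mass is spread
#' uniformly over all `H` donors (including the current one).
#'
#' @param d_cm genetic distance in centiMorgans, `>= 0` (vectorized).
#' @param Ne effective population size.
#' @param H reference panel haplotype count.
#' @return No-switch probabilities in `(0, 1]`.
#' @export
no_switch_prob <- function(d_cm, Ne, H) {
  if (any(d_cm < 0)) stop("genetic distance must be >= 0")
  exp(-4 * Ne * (d_cm / 100) / H)
}

panel_no_switch <- function(sm, params, H) {
  if (nrow(sm) < 2) return(numeric(0))
  pmax(no_switch_prob(diff(sm$cm), params$Ne, H), params$min_no_switch)
}

#' Posterior donor probabilities for one haploid observation
#'
#' Runs the scaled forward-backward recursion over the full site grid.
#' Untyped sites (observation `NA`) emit probability 1 for every donor;
#' typed sites emit `1 - lambda` on allele match and `lambda` on mismatch;
#' missing panel alleles emit 0.5.
#'
#' @param obs integer vector of haploid alleles (0/1/`NA`) over the full
#'   grid, or -- with `obs_sites` -- over a typed subset.
#' @param panel a [hap_panel] covering the full grid.
#' @param params an [hmm_params()].
#' @param obs_sites optional integer site indices for a subset observation;
#'   indices outside the grid are an error.
#' @return `H x L` matrix of posterior donor probabilities; every column
#'   sums to 1.
#' @export
forward_backward <- function(obs, panel, params = hmm_params(),
                             obs_sites = NULL) {
  L <- ncol(panel$alleles)
  H <- n_haps(panel)
  if (!is.null(obs_sites)) {
    if (length(obs_sites) != length(obs))
      stop("obs and obs_sites lengths differ")
    if (any(obs_sites < 1 | obs_sites > L))
      stop("observation site outside the panel site grid")
    full <- rep(NA_integer_, L)
    full[obs_sites] <- obs
    obs <- full
  }
  if (length(obs) != L)
    stop("observation length ", length(obs), " does not match grid of ", L)
  obs <- as.integer(obs)
  if (all(is.na(obs)))
    warning("all observations missing; returning uniform posteriors")
  lambda <- if (is.null(params$lambda) && H >= 2) compute_lambda(H)
            else if (is.null(params$lambda)) 0.01 else params$lambda
  g <- .ls_forward_backward(panel$alleles, obs, panel_no_switch(
    panel$site_map, params, H), lambda)
  rownames(g) <- panel$hap_ids
  g
}

#' Combine a global and a local reference panel
#'
#' Haplotype concatenation over the global panel's site grid (no cross-panel
#' re-imputation): local-panel sites are aligned to the global grid by
#' (position, ref, alt); global sites absent from the local panel carry
#' missing alleles there, which the HMM emission treats as uninformative.
#'
#' @param global a [hap_panel] defining the site grid.
#' @param local optional second [hap_panel]; `NULL` returns `global`.
#' @return A [hap_panel] with `H_global + H_local` haplotypes.
#' @export
combine_panels <- function(global, local = NULL) {
  if (is.null(local)) return(global)
  idx <- match(site_key(global$site_map), site_key(local$site_map))
  la <- matrix(NA_integer_, n_haps(local), ncol(global$alleles))
  hit <- !is.na(idx)
  la[, hit] <- local$alleles[, idx[hit], drop = FALSE]
  hap_panel(rbind(global$alleles, la), global$site_map,
            hap_ids = make.unique(c(global$hap_ids, local$hap_ids)),
            subject_ids = c(global$subject_ids, local$subject_ids))
}

#' Impute allele dosages for one phased subject
#'
#' Runs the copying HMM once per haplotype of the subject against the
#' (combined) reference panel and converts posterior donor probabilities
#' into the expected alternate-allele count: per haplotype and site,
#' `P(allele = 1) = sum_k gamma_k * (lambda + (1 - 2 lambda) a_k)` with
#' missing panel alleles contributing 0.5; the diploid dosage is the sum
#' over the two haplotypes.
#'
#' @param haps `2 x L` integer matrix: the subject's phased haplotypes over
#'   the full site grid.
#' @param panels a [hap_panel] or a list of one or two panels
#'   (global first); two panels are combined with [combine_panels()] and
#'   `lambda` is derived from the combined haplotype count.
#' @param params an [hmm_params()].
#' @param typed logical mask (length L) of typed sites; defaults to the
#'   panel site map's `is_array` flag. Untyped entries of `haps` are
#'   ignored.
#' @param subject_id optional subject identifier; if any panel haplotype
#'   carries this subject id the call errors (leave-one-out guard against
#'   imputing a subject from their own haplotypes).
#' @return Numeric dosage vector of length L, in `[0, 2]`.
#' @export
impute_dosage <- function(haps, panels, params = hmm_params(),
                          typed = NULL, subject_id = NULL) {
  if (inherits(panels, "hap_panel")) panels <- list(panels)
  if (length(panels) < 1 || length(panels) > 2)
    stop("provide one or two reference panels")
  comb <- if (length(panels) == 2) combine_panels(panels[[1]], panels[[2]])
          else panels[[1]]
  if (!is.null(subject_id) && subject_id %in% comb$subject_ids)
    stop("leave-one-out violation: subject ", subject_id,
         " is present in the reference panel")
  L <- ncol(comb$alleles)
  haps <- as.matrix(haps)
  if (nrow(haps) != 2 || ncol(haps) != L)
    stop("haps must be a 2 x L matrix on the panel site grid")
  if (is.null(typed)) typed <- comb$site_map$is_array
  if (length(typed) != L) stop("typed mask length mismatch")

  H <- n_haps(comb)
  lambda <- if (is.null(params$lambda)) compute_lambda(H) else params$lambda
  pr <- hmm_params(params$Ne, lambda, params$min_no_switch)
  w <- lambda + (1 - 2 * lambda) * comb$alleles
  w[is.na(w)] <- 0.5

  p1 <- vapply(1:2, function(i) {
    obs <- ifelse(typed, haps[i, ], NA_integer_)
    g <- forward_backward(obs, comb, pr)
    colSums(g * w)
  }, numeric(L))
  pmin(pmax(rowSums(p1), 0), 2)
}
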