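## Drop-one-out cross-validation of imputation accuracy.
##
## Every sequenced subject is imputed from their phased array-site alleles
## twice -- against the global panel alone and against the global panel plus
## the local panel with that subject's own haplotypes removed -- and the
## imputed dosages are scored per SNP against the gold-standard sequence
## genotypes across subjects.

#' Remove one subject's haplotypes from a panel
#'
#' @param panel a subject-paired [hap_panel].
#' @param subject_id subject to remove; must own exactly 2 haplotypes.
#' @return A [hap_panel] with `H - 2` haplotypes.
#' @export
leave_one_out_panel <- function(panel, subject_id) {
  rows <- which(panel$subject_ids == subject_id)
  if (length(rows) == 0) stop("unknown subject: ", subject_id)
  if (length(rows) != 2)
    stop("subject ", subject_id, " owns ", length(rows),
         " haplotypes, expected 2")
  subset_panel(panel, haps = -rows)
}

#' Squared Pearson correlation between dosage and truth
#'
#' Complete-case squared correlation; undefined (`NA`) when fewer than two
#' complete pairs remain or either vector is constant.
#'
#' @param dosage numeric vector of imputed dosages.
#' @param truth_genotypes numeric vector of gold-standard genotypes
#'   (0/1/2, `NA` allowed).
#' @return Squared correlation in `[0, 1]`, or `NA`.
#' @export
snp_r2 <- function(dosage, truth_genotypes) {
  if (length(dosage) != length(truth_genotypes))
    stop("dosage and truth vectors differ in length")
  ok <- !is.na(dosage) & !is.na(truth_genotypes)
  if (sum(ok) < 2) return(NA_real_)
  x <- dosage[ok]; y <- truth_genotypes[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

maf_bin_breaks <- 10^c(-2, -1.5, -1, -0.5)
maf_bin_labels <- c("1-3.2%", "3.2-10%", "10-32%", ">32%")

#' Assign a minor allele frequency to its exponential bin
#'
#' Bins increase by factors of `sqrt(10)`: boundaries at `10^-2`,
#' `10^-1.5`, `10^-1`, `10^-0.5`, half-open and lower-inclusive, with the
#' top bin closed at 0.5. Frequencies below 1% fall in a "<1%" band that
#' per-bin summaries exclude.
#'
#' @param maf minor allele frequencies in `(0, 0.5]` (vectorized).
#' @return Factor with levels `<1%`, `1-3.2%`, `3.2-10%`, `10-32%`,
#'   `>32%`.
#' @export
assign_maf_bin <- function(maf) {
  if (any(is.na(maf)) || any(maf <= 0 | maf > 0.5 + 1e-12))
    stop("MAF must lie in (0, 0.5]")
  idx <- findInterval(maf, maf_bin_breaks)  # 0 = below 1%
  factor(c("<1%", maf_bin_labels)[idx + 1L],
         levels = c("<1%", maf_bin_labels))
}

global_band_labels <- c("<1%", "1-3.2%", ">3.2%")

#' Assign a global-panel MAF to the coarse stratification bands
#'
#' @param maf minor allele frequencies in `(0, 0.5]`.
#' @return Factor with levels `<1%`, `1-3.2%`, `>3.2%`.
#' @export
assign_global_band <- function(maf) {
  if (any(is.na(maf)) || any(maf <= 0 | maf > 0.5 + 1e-12))
    stop("MAF must lie in (0, 0.5]")
  idx <- findInterval(maf, c(0.01, 10^-1.5))
  factor(global_band_labels[idx + 1L], levels = global_band_labels)
}

default_target_sites <- function(ts) {
  sm <- ts$site_map
  fg <- panel_freq(ts$global_panel)
  which(sm$is_exomic & !sm$is_array & is_snv(sm) & !sm$is_multimap &
          fg > 0 & fg < 1)
}

#' Run the drop-one-out cross-validation experiment
#'
#' For every local subject, imputes the exomic non-array target sites from
#' the subject's phased array-site alleles, once with the global panel
#' alone and once with the global panel plus the leave-one-out local panel,
#' then computes per-SNP dosage r-squared across subjects under each
#' configuration.
#'
#' @param ts a `truth_set` from [simulate_populations()].
#' @param params an [hmm_params()].
#' @param target_sites integer site indices to score; default: exomic,
#'   non-array, single-nucleotide, uniquely mapping sites polymorphic in
#'   the global panel (cohort-private variants are excluded).
#' @param array_sites integer indices of typed sites; default: the site
#'   map's array flag.
#' @param gold `"called"` scores against the error-injected sequence calls
#'   with GQ < 20 masked (the realistic gold standard); `"truth"` scores
#'   against the noiseless simulated genotypes.
#' @return A `data.frame` of class `accuracy_table`: one row per target
#'   SNP with local and global MAF, `r2_one_panel`, `r2_two_panel` and the
#'   number of subjects used.
#' @export
run_crossval <- function(ts, params = hmm_params(), target_sites = NULL,
                         array_sites = NULL, gold = c("called", "truth")) {
  gold <- match.arg(gold)
  sm <- ts$site_map
  L <- nrow(sm)
  subjects <- unique(stats::na.omit(ts$local_panel$subject_ids))
  if (length(subjects) < 3) stop("need at least 3 sequenced subjects")
  if (is.null(array_sites)) array_sites <- which(sm$is_array)
  if (is.null(target_sites)) target_sites <- default_target_sites(ts)
  typed <- seq_len(L) %in% array_sites

  gold_gm <- if (gold == "called") {
    calls <- ts$local_called$calls
    calls[ts$local_called$gq < 20] <- NA_integer_
    calls
  } else {
    panel_genotypes(ts$local_truth)
  }
  gold_gm <- gold_gm[subjects, target_sites, drop = FALSE]

  n <- length(subjects)
  t_len <- length(target_sites)
  dos_one <- matrix(NA_real_, n, t_len, dimnames = list(subjects, NULL))
  dos_two <- dos_one
  for (i in seq_len(n)) {
    s <- subjects[i]
    rows <- which(ts$local_panel$subject_ids == s)
    haps <- ts$local_panel$alleles[rows, , drop = FALSE]
    loo <- leave_one_out_panel(ts$local_panel, s)
    d1 <- impute_dosage(haps, ts$global_panel, params, typed = typed,
                        subject_id = s)
    d2 <- impute_dosage(haps, list(ts$global_panel, loo), params,
                        typed = typed, subject_id = s)
    dos_one[i, ] <- d1[target_sites]
    dos_two[i, ] <- d2[target_sites]
  }

  f_local <- colMeans(gold_gm, na.rm = TRUE) / 2
  f_global <- panel_freq(ts$global_panel)[target_sites]
  res <- data.frame(
    id = sm$id[target_sites],
    pos = sm$pos[target_sites],
    maf_local = pmin(f_local, 1 - f_local),
    maf_global = pmin(f_global, 1 - f_global),
    r2_one_panel = vapply(seq_len(t_len), function(j)
      snp_r2(dos_one[, j], gold_gm[, j]), numeric(1)),
    r2_two_panel = vapply(seq_len(t_len), function(j)
      snp_r2(dos_two[, j], gold_gm[, j]), numeric(1)),
    n_subjects_used = colSums(!is.na(gold_gm)),
    stringsAsFactors = FALSE
  )
  class(res) <- c("accuracy_table", "data.frame")
  res
}

#' Effective-sample-size increase implied by an accuracy gain
#'
#' A proportionate increase in imputation r-squared acts on association
#' power like the same proportionate increase in study sample size, so the
#' gain is reported as `100 * (r2_two / r2_one - 1)` percent.
#'
#' @param mean_r2_one,mean_r2_two mean per-bin r-squared under the
#'   one-panel and two-panel configurations; the baseline must be positive.
#' @return Percentage increase (not rounded).
#' @examples
#' ess_increase(0.504, 0.697)  # ~38%
#' @export
ess_increase <- function(mean_r2_one, mean_r2_two) {
  if (any(mean_r2_one <= 0)) stop("baseline mean r2 must be > 0")
  100 * (mean_r2_two / mean_r2_one - 1)
}

defined_records <- function(tab) {
  tab[!is.na(tab$r2_one_panel) & !is.na(tab$r2_two_panel), , drop = FALSE]
}

#' Summarize accuracy records by MAF bin
#'
#' Per-bin mean and median r-squared under each panel configuration, the
#' mean, SD and SE of the per-SNP increase, the effective-sample-size
#' increase (whole percent), and a two-sided t-test of the increase against
#' zero. Welch tests between adjacent bins are attached as attribute
#' `"adjacent_tests"`. Records with undefined r-squared are excluded (and
#' counted in attribute `"n_undefined"`); for local binning, SNPs with
#' MAF below 1% are excluded from the table.
#'
#' @param tab an `accuracy_table` from [run_crossval()].
#' @param bin_by `"local"` (exponential sqrt-10 bins on gold-standard
#'   local MAF) or `"global"` (coarse global-panel bands).
#' @return A `data.frame`, one row per bin.
#' @export
summarize_bins <- function(tab, bin_by = c("local", "global")) {
  bin_by <- match.arg(bin_by)
  def <- defined_records(tab)
  if (bin_by == "local") {
    def <- def[def$maf_local > 0, , drop = FALSE]
    bins <- assign_maf_bin(def$maf_local)
    keep <- bins != "<1%"
    def <- def[keep, , drop = FALSE]
    bins <- droplevels(bins[keep])
    bins <- factor(bins, levels = maf_bin_labels)
  } else {
    def <- def[def$maf_global > 0, , drop = FALSE]
    bins <- assign_global_band(def$maf_global)
  }
  inc <- def$r2_two_panel - def$r2_one_panel
  lv <- levels(bins)
  rows <- lapply(lv, function(b) {
    sel <- bins == b
    n <- sum(sel)
    if (n == 0) {
      return(data.frame(bin = b, n_snps = 0L, mean_r2_one = NA_real_,
                        mean_r2_two = NA_real_, mean_increase = NA_real_,
                        sd_increase = NA_real_, se_increase = NA_real_,
                        ess_increase_pct = NA_real_, t_p_vs_zero = NA_real_,
                        median_r2_one = NA_real_, median_r2_two = NA_real_))
    }
    m1 <- mean(def$r2_one_panel[sel])
    m2 <- mean(def$r2_two_panel[sel])
    di <- inc[sel]
    sdv <- if (n > 1) stats::sd(di) else NA_real_
    pt <- if (n > 1 && isTRUE(sdv > 0))
      stats::t.test(di, mu = 0)$p.value else NA_real_
    data.frame(
      bin = b, n_snps = n, mean_r2_one = m1, mean_r2_two = m2,
      mean_increase = m2 - m1, sd_increase = sdv,
      se_increase = if (n > 1) sdv / sqrt(n) else NA_real_,
      ess_increase_pct = if (m1 > 0) round(ess_increase(m1, m2)) else NA_real_,
      t_p_vs_zero = pt,
      median_r2_one = stats::median(def$r2_one_panel[sel]),
      median_r2_two = stats::median(def$r2_two_panel[sel])
    )
  })
  out <- do.call(rbind, rows)
  adj <- lapply(seq_len(length(lv) - 1), function(i) {
    a <- inc[bins == lv[i]]; b <- inc[bins == lv[i + 1]]
    p <- if (length(a) > 1 && length(b) > 1 &&
             (stats::sd(a) > 0 || stats::sd(b) > 0))
      stats::t.test(a, b)$p.value else NA_real_
    data.frame(bin_a = lv[i], bin_b = lv[i + 1], p_welch = p)
  })
  attr(out, "adjacent_tests") <- do.call(rbind, adj)
  attr(out, "n_undefined") <- nrow(tab) - nrow(defined_records(tab))
  out
}

#' Fraction of poorly imputed SNPs rescued by the local panel
#'
#' @param tab an `accuracy_table`.
#' @param poor,well r-squared thresholds, `0 < poor < well < 1`.
#' @return List with `frac_poor` (share of defined SNPs with one-panel
#'   r-squared below `poor`), `frac_poor_to_well` (among those, share with
#'   two-panel r-squared above `well`; `NA` if none are poor), and counts.
#' @export
poor_to_well_crosstab <- function(tab, poor = 0.2, well = 0.8) {
  if (poor <= 0 || well >= 1 || poor >= well)
    stop("thresholds must satisfy 0 < poor < well < 1")
  def <- defined_records(tab)
  is_poor <- def$r2_one_panel < poor
  list(
    frac_poor = if (nrow(def) > 0) mean(is_poor) else NA_real_,
    frac_poor_to_well = if (any(is_poor))
      mean(def$r2_two_panel[is_poor] > well) else NA_real_,
    n_poor = sum(is_poor),
    n_total = nrow(def)
  )
}

#' Mean accuracy improvement on a local-by-global MAF grid
#'
#' 2-D binning of the per-SNP r-squared increase: rows are local-sequence
#' MAF bins, columns are global-panel MAF bins including a below-1% band.
#' Cells with no SNPs carry `NA` means and zero counts.
#'
#' @param tab an `accuracy_table`.
#' @param local_bins local-MAF bin labels to keep as rows (default: the
#'   four exponential bins).
#' @return List of two aligned matrices, `mean_increase` and `count`.
#' @export
improvement_grid <- function(tab, local_bins = maf_bin_labels) {
  def <- defined_records(tab)
  def <- def[def$maf_local > 0 & def$maf_global > 0, , drop = FALSE]
  lb <- assign_maf_bin(def$maf_local)
  gb <- assign_maf_bin(def$maf_global)  # includes the "<1%" band
  keep <- lb %in% local_bins
  lb <- factor(lb[keep], levels = local_bins)
  gb <- droplevels(gb[keep])
  gb <- factor(gb, levels = c("<1%", maf_bin_labels))
  inc <- def$r2_two_panel[keep] - def$r2_one_panel[keep]
  cnt <- table(lb, gb)
  mu <- tapply(inc, list(lb, gb), mean)
  mu[cnt == 0] <- NA
  list(mean_increase = unclass(mu), count = unclass(as.matrix(cnt)))
}

#' Run the full augmentation experiment for one seed
#'
#' Convenience wrapper: simulate the reference study conditions, run the
#' drop-one-out cross-validation and return the accuracy records.
#'
#' @param seed integer seed.
#' @param drift_generations drift generations for the local isolate
#'   (default: the reference 20; 40 gives the strongly drifted contrast).
#' @param params an [hmm_params()].
#' @param ... further overrides passed to [sim_config()].
#' @return An `accuracy_table`.
#' @export
augmentation_experiment <- function(seed, drift_generations = 20L,
                                    params = hmm_params(), ...) {
  cfg <- sim_config(seed = seed, drift_generations = drift_generations, ...)
  run_crossval(simulate_populations(cfg), params)
}
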