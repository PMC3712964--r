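## Sequence-data quality-control cascade and array-sequence merging.
##
## Filter order matters and is logged: site QUAL, GQ masking, call rate,
## MAF, exact HWE, multi-mapping exclusion, SNV-only. Filters only mask or
## drop -- no retained call is ever altered.

new_qc_report <- function() {
  data.frame(stage = character(), unit = character(),
             n_removed = integer(), n_retained = integer(),
             stringsAsFactors = FALSE)
}

add_stage <- function(rep, stage, unit, n_removed, n_retained) {
  rbind(rep, data.frame(stage = stage, unit = unit,
                        n_removed = as.integer(n_removed),
                        n_retained = as.integer(n_retained),
                        stringsAsFactors = FALSE))
}

#' Default sequence-QC thresholds
#'
#' Site QUAL at least 40; calls with GQ below 20 set missing; site call
#' rate at least 50%; MAF at least 0.75% of non-missing calls (at ~100
#' subjects this requires at least two minor alleles); exact HWE p-value
#' at least 1e-4; multi-mapping and non-SNV sites excluded.
#'
#' @param site_qual,call_gq,call_rate,maf,hwe_p,drop_multimap,snv_only
#'   individual thresholds/switches.
#' @return Named list of thresholds.
#' @export
qc_thresholds <- function(site_qual = 40, call_gq = 20, call_rate = 0.5,
                          maf = 0.0075, hwe_p = 1e-4,
                          drop_multimap = TRUE, snv_only = TRUE) {
  list(site_qual = site_qual, call_gq = call_gq, call_rate = call_rate,
       maf = maf, hwe_p = hwe_p, drop_multimap = drop_multimap,
       snv_only = snv_only)
}

site_minor_freq <- function(calls) {
  f <- colMeans(calls, na.rm = TRUE) / 2
  f[is.nan(f)] <- 0
  pmin(f, 1 - f)
}

#' Apply the sequence-data QC cascade
#'
#' Filters are applied in a fixed, logged order: (1) sites with phred QUAL
#' below threshold removed; (2) calls with GQ below threshold masked to
#' missing; (3) sites called in fewer than the required fraction of
#' subjects removed; (4) sites with minor allele frequency (over
#' non-missing calls) below threshold removed -- this also removes sites
#' monomorphic after masking; (5) sites failing the exact
#' Hardy-Weinberg test removed; (6) multi-mapping sites removed; (7)
#' non-SNV (indel) sites removed. Re-running the cascade on its own output
#' removes nothing.
#'
#' @param gm a [geno_matrix].
#' @param thresholds a [qc_thresholds()] list.
#' @return List with `gm` (filtered matrix, possibly with zero sites) and
#'   `report` (one row per stage: stage, unit, n_removed, n_retained).
#' @export
apply_sequence_qc <- function(gm, thresholds = qc_thresholds()) {
  if (!inherits(gm, "geno_matrix") || ncol(gm$calls) == 0)
    stop("empty or invalid genotype matrix")
  th <- thresholds
  rep <- new_qc_report()

  keep <- gm$site_qual >= th$site_qual
  rep <- add_stage(rep, "site_qual", "sites", sum(!keep), sum(keep))
  gm <- subset_geno(gm, sites = which(keep))

  mask <- !is.na(gm$calls) & gm$gq < th$call_gq
  gm$calls[mask] <- NA_integer_
  rep <- add_stage(rep, "gq_mask", "calls", sum(mask), ncol(gm$calls))

  cr <- colMeans(!is.na(gm$calls))
  keep <- cr >= th$call_rate
  rep <- add_stage(rep, "call_rate", "sites", sum(!keep), sum(keep))
  gm <- subset_geno(gm, sites = which(keep))

  keep <- site_minor_freq(gm$calls) >= th$maf
  rep <- add_stage(rep, "maf", "sites", sum(!keep), sum(keep))
  gm <- subset_geno(gm, sites = which(keep))

  if (ncol(gm$calls) > 0) {
    naa <- colSums(gm$calls == 0L, na.rm = TRUE)
    nab <- colSums(gm$calls == 1L, na.rm = TRUE)
    nbb <- colSums(gm$calls == 2L, na.rm = TRUE)
    keep <- hwe_exact_test(naa, nab, nbb) >= th$hwe_p
  } else keep <- logical(0)
  rep <- add_stage(rep, "hwe", "sites", sum(!keep), sum(keep))
  gm <- subset_geno(gm, sites = which(keep))

  if (th$drop_multimap) {
    keep <- !gm$site_map$is_multimap
    rep <- add_stage(rep, "multimap", "sites", sum(!keep), sum(keep))
    gm <- subset_geno(gm, sites = which(keep))
  }
  if (th$snv_only) {
    keep <- is_snv(gm$site_map)
    rep <- add_stage(rep, "snv_only", "sites", sum(!keep), sum(keep))
    gm <- subset_geno(gm, sites = which(keep))
  }
  list(gm = gm, report = rep)
}

#' Merge array and sequence genotype matrices with concordance QC
#'
#' Restricts to subjects present in both matrices, counts mismatching
#' calls (both non-missing, different genotype) per subject and per
#' overlapping variant before any exclusion, then drops subjects with more
#' than `max_subject_mismatch` and variants with more than
#' `max_variant_mismatch` mismatches (values at the threshold are
#' retained). The merged matrix is the union of the two site sets; at
#' retained overlapping sites the sequence call wins where present, array
#' calls fill sequence gaps.
#'
#' @param array_gm,seq_gm [geno_matrix] objects sharing at least one
#'   subject.
#' @param max_subject_mismatch,max_variant_mismatch strict exclusion
#'   thresholds (defaults 50 and 30).
#' @return List with `gm`, `report`, and `concordance` (overall plus
#'   per-MAF-band minor-allele concordance; the minor-allele denominator is
#'   call pairs in which either source carries at least one minor allele).
#' @export
merge_array_sequence <- function(array_gm, seq_gm,
                                 max_subject_mismatch = 50,
                                 max_variant_mismatch = 30) {
  subj <- intersect(array_gm$subjects, seq_gm$subjects)
  if (length(subj) == 0) stop("array and sequence data share no subjects")
  a <- subset_geno(array_gm, subjects = match(subj, array_gm$subjects))
  s <- subset_geno(seq_gm, subjects = match(subj, seq_gm$subjects))

  ka <- site_key(a$site_map); ks <- site_key(s$site_map)
  ov_a <- which(ka %in% ks)
  ov_s <- match(ka[ov_a], ks)
  ac <- a$calls[, ov_a, drop = FALSE]
  sc <- s$calls[, ov_s, drop = FALSE]
  both <- !is.na(ac) & !is.na(sc)
  mism <- both & ac != sc

  subj_mism <- rowSums(mism)
  var_mism <- colSums(mism)
  bad_subj <- subj_mism > max_subject_mismatch
  bad_var_keys <- ka[ov_a][var_mism > max_variant_mismatch]

  rep <- new_qc_report()
  rep <- add_stage(rep, "mismatch_subjects", "subjects",
                   sum(bad_subj), sum(!bad_subj))
  rep <- add_stage(rep, "mismatch_variants", "variants",
                   length(bad_var_keys),
                   length(ov_a) - length(bad_var_keys))

  n_comp <- sum(both)
  overall <- if (n_comp > 0) 1 - sum(mism) / n_comp else NA_real_
  # minor-allele concordance: pairs where either source shows the minor
  # allele, banded by sequence MAF
  fs <- colMeans(sc, na.rm = TRUE) / 2
  fs[is.nan(fs)] <- 0
  minor_is_alt <- fs <= 0.5
  maf_s <- pmin(fs, 1 - fs)
  carries <- function(x, alt_minor)
    ifelse(alt_minor, x >= 1, x <= 1) & !is.na(x)
  minor_any <- both &
    (carries(ac, rep(minor_is_alt, each = nrow(ac))) |
     carries(sc, rep(minor_is_alt, each = nrow(sc))))
  band <- rep("monomorphic", length(maf_s))
  pm <- maf_s > 0
  band[pm] <- as.character(assign_maf_bin(maf_s[pm]))
  minor_by_band <- lapply(unique(band), function(b) {
    cols <- band == b
    sel <- minor_any[, cols, drop = FALSE]
    n <- sum(sel)
    agree <- sum(sel & ac[, cols, drop = FALSE] == sc[, cols, drop = FALSE])
    data.frame(band = b, n_pairs = n,
               concordance = if (n > 0) agree / n else NA_real_)
  })
  concordance <- list(
    overall = overall, n_compared = n_comp,
    per_subject_mismatch = stats::setNames(subj_mism, subj),
    per_variant_mismatch = stats::setNames(var_mism, ka[ov_a]),
    minor_allele = do.call(rbind, minor_by_band)
  )

  keep_subj <- which(!bad_subj)
  a <- subset_geno(a, subjects = keep_subj)
  s <- subset_geno(s, subjects = keep_subj)
  drop_a <- ka[ov_a] %in% bad_var_keys
  drop_s <- ks %in% bad_var_keys
  a <- subset_geno(a, sites = setdiff(seq_along(ka), c(ov_a[drop_a])))
  s <- subset_geno(s, sites = which(!drop_s))

  # union site set ordered by position; sequence call wins on overlap
  ka <- site_key(a$site_map); ks <- site_key(s$site_map)
  extra_a <- which(!(ka %in% ks))
  sm_merge <- rbind(as.data.frame(s$site_map),
                    as.data.frame(a$site_map[extra_a, , drop = FALSE]))
  ord <- order(sm_merge$pos)
  sm_merge <- sm_merge[ord, , drop = FALSE]
  class(sm_merge) <- c("site_map", "data.frame")
  rownames(sm_merge) <- NULL

  nsub <- length(keep_subj)
  nsite <- nrow(sm_merge)
  calls <- matrix(NA_integer_, nsub, nsite)
  gq <- matrix(0, nsub, nsite)
  sq <- numeric(nsite)
  km <- site_key(sm_merge)
  is_ <- match(km, ks); ia <- match(km, ka)
  for (j in seq_len(nsite)) {
    if (!is.na(is_[j])) {
      calls[, j] <- s$calls[, is_[j]]
      gq[, j] <- s$gq[, is_[j]]
      sq[j] <- s$site_qual[is_[j]]
      if (!is.na(ia[j])) {  # array fills sequence gaps
        gap <- is.na(calls[, j])
        calls[gap, j] <- a$calls[gap, ia[j]]
        gq[gap, j] <- a$gq[gap, ia[j]]
      }
    } else {
      calls[, j] <- a$calls[, ia[j]]
      gq[, j] <- a$gq[, ia[j]]
      sq[j] <- a$site_qual[ia[j]]
    }
  }
  gm <- geno_matrix(calls, sm_merge, gq, sq, subjects = s$subjects)
  list(gm = gm, report = rep, concordance = concordance)
}

#' Restrict a genotype matrix to sites present in a reference panel
#'
#' Sites are matched on (position, ref, alt). Sites whose position exists
#' in the panel but with different allele codes are excluded and logged
#' separately from sites absent altogether (cohort-private variants).
#'
#' @param gm a [geno_matrix].
#' @param panel a [hap_panel].
#' @return List with `gm` and `report`.
#' @export
restrict_to_global_panel <- function(gm, panel) {
  kg <- site_key(gm$site_map)
  kp <- site_key(panel$site_map)
  in_panel <- kg %in% kp
  pos_hit <- gm$site_map$pos %in% panel$site_map$pos
  code_mismatch <- !in_panel & pos_hit
  absent <- !in_panel & !pos_hit
  rep <- new_qc_report()
  rep <- add_stage(rep, "absent_from_panel", "sites", sum(absent),
                   sum(!absent))
  rep <- add_stage(rep, "allele_code_mismatch", "sites",
                   sum(code_mismatch), sum(in_panel))
  list(gm = subset_geno(gm, sites = which(in_panel)), report = rep)
}

#' Exclude subjects with low combined call rate
#'
#' Subjects called at fewer than `min_rate` of sites are removed; a
#' subject exactly at the threshold is retained.
#'
#' @param gm a [geno_matrix].
#' @param min_rate minimum non-missing fraction, in (0, 1].
#' @return List with `gm` and `report`.
#' @export
filter_subject_call_rate <- function(gm, min_rate = 0.8) {
  if (min_rate <= 0 || min_rate > 1) stop("min_rate must lie in (0, 1]")
  cr <- rowMeans(!is.na(gm$calls))
  keep <- cr >= min_rate
  rep <- new_qc_report()
  rep <- add_stage(rep, "subject_call_rate", "subjects", sum(!keep),
                   sum(keep))
  list(gm = subset_geno(gm, subjects = which(keep)), report = rep)
}
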