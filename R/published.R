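#' Published mean per-bin imputation accuracies from two isolate cohorts
#'
#' Mean per-SNP dosage r-squared reported by a published exome-imputation
#' study of two European population isolates (an Adriatic island cohort,
#' `A`, and a Northern Isles cohort, `B`), under imputation from a global
#' reference panel alone (`mean_r2_one`) and with a ~90-subject local
#' exome panel added (`mean_r2_two`), by minor-allele-frequency bin.
#' These printed per-panel means are the inputs from which the derived
#' cells -- the per-bin accuracy increase and the effective-sample-size
#' increase -- are recomputed with [ess_increase()].
#'
#' @return A `data.frame` with columns `cohort`, `bin`, `mean_r2_one`,
#'   `mean_r2_two`.
#' @examples
#' ref <- reference_accuracy_means()
#' round(ess_increase(ref$mean_r2_one, ref$mean_r2_two))
#' @export
reference_accuracy_means <- function() {
  data.frame(
    cohort = rep(c("A", "B"), each = 4),
    bin = factor(rep(maf_bin_labels, 2), levels = maf_bin_labels),
    mean_r2_one = c(0.504, 0.729, 0.868, 0.894,
                    0.586, 0.778, 0.894, 0.913),
    mean_r2_two = c(0.697, 0.841, 0.916, 0.934,
                    0.753, 0.867, 0.931, 0.944),
    stringsAsFactors = FALSE
  )
}
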