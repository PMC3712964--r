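# panelaug

Quantifying how much a small population-specific ("local") reference
panel of phased haplotypes improves genotype imputation when added to a
large global panel — the design question faced by any genome-wide
association study of an isolated or drifted population that can afford to
sequence a subset of its own cohort.

## Who this is for

Statistical geneticists evaluating reference-panel strategies for
imputing less common variants (minor allele frequency 1–10%), and anyone
who needs a fully synthetic, seedable test bed for haplotype-copying
imputation: no external data are downloaded or required.

## What it computes

The core model is the haploid Li–Stephens haplotype-copying hidden Markov
model. A target haplotype is an imperfect mosaic of the `H` reference
haplotypes: between sites at genetic distance `d` cM the copied donor is
retained with probability `exp(-4·Ne·(d/100)/H)` (default
`Ne = 20,000`), and emission allows miscopying with probability
`λ = θ/(2(H+θ))`, `θ = 1/Σ_{i<H} 1/i`. Posterior donor probabilities from
the scaled forward–backward recursion (Rcpp, `O(H·L)`) convert into
expected allele dosages in `[0, 2]`, with one- or two-panel reference
support (two panels are concatenated, never merged).

Around the engine the package implements the full evaluation loop:

* `simulate_populations()` — structured synthetic populations: a
  two-level founder ancestry (common variants on shared proto-founder
  backgrounds, rare variants private to individual founders), a global
  panel, and a bottlenecked, drifted isolate cohort with error-injected
  sequence and array genotype calls.
* `apply_sequence_qc()`, `merge_array_sequence()`,
  `restrict_to_global_panel()`, `filter_subject_call_rate()` — the QC
  cascade (phred site/call filters, call rate, minor allele count, exact
  Hardy–Weinberg test via `hwe_exact_test()`, array–sequence concordance
  with 50/30 mismatch exclusions).
* `run_crossval()` — drop-one-out cross-validation: each subject is
  imputed with their own haplotypes removed from the local panel, and
  per-SNP dosage r² is scored against the gold-standard sequence calls.
* `summarize_bins()`, `ess_increase()`, `poor_to_well_crosstab()`,
  `improvement_grid()` — MAF-binned accuracy tables (bins grow by
  factors of √10), effective-sample-size conversion, and the
  rescued-SNP and local-by-global MAF analyses.
* `run_pipeline()` — all stages end to end with provenance-stamped TSV
  reports; `analysis/01_simulate.R` … `analysis/04_drift_contrast.R` are
  the narrative drivers that write `results/`.

## Worked example

```r
library(panelaug)

tab <- augmentation_experiment(seed = 1)   # simulate + cross-validate
summarize_bins(tab)[, c("bin", "n_snps", "mean_r2_one", "mean_r2_two",
                        "mean_increase", "ess_increase_pct")]
```

```
      bin n_snps mean_r2_one mean_r2_two mean_increase ess_increase_pct
1  1-3.2%    101   0.5935744   0.8974731     0.3038986               51
2 3.2-10%    191   0.7227402   0.9686169     0.2458766               34
3  10-32%    126   0.8558470   0.9824077     0.1265607               15
4    >32%     60   0.9242195   0.9887324     0.0645129                7
```

Reading the rows: from the global panel alone, SNPs at local MAF 1–3.2%
impute with mean r² 0.59; adding the 89-subject leave-one-out local panel
raises that to 0.90 — an accuracy gain of 0.30, equivalent to a 51%
larger study for association power. The gain shrinks monotonically with
MAF: common variants already impute well globally, so the local panel
adds little there. That ordering — large gains for less common variants,
small ones above 32% — is the pattern the package exists to demonstrate,
and the property suite asserts it across five seeds, together with the
distance effect (doubling the isolate's drift enlarges the rare-bin
gain, paired by seed) and the stratification by global-panel MAF (SNPs
under-represented in the global panel gain the most).

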