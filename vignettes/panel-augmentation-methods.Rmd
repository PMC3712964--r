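---
title: "Methods: simulating and evaluating local reference panel augmentation"
author: "panelaug"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and evaluating local reference panel augmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The question

Genome-wide association studies impute untyped variants from a large
"global" reference panel of phased haplotypes. For less common variants
(minor allele frequency, MAF, 1–10%) imputation from a global panel is
often inaccurate, because commercial arrays under-tag such variants and
because a study population — especially a genetic isolate — carries them
on haplotype backgrounds, and at frequencies, that the global panel does
not represent well. `panelaug` asks, on fully synthetic data: *how much
does adding a small population-specific ("local") panel of sequenced study
subjects to the global panel improve per-SNP imputation accuracy, and for
which variants?*

The package implements the full evaluation loop: a structured-population
simulator, the sequence-data QC cascade, a haploid Li–Stephens
haplotype-copying imputation engine supporting one or two reference
panels, and drop-one-out cross-validation of per-SNP dosage r².

# The imputation model

A target haplotype is modeled as an imperfect mosaic copy of the `H`
reference haplotypes. The hidden state at site `l` is the donor haplotype
being copied. Between adjacent sites separated by genetic distance `d`
centiMorgans the donor is retained with probability

```
p = exp(-4 * Ne * (d / 100) / H)
```

and with probability `1 - p` the donor is redrawn uniformly from all `H`
haplotypes (including the current one). `Ne` is the effective population
size; the default 20,000 is the value conventionally used for human
imputation. Emission allows miscopying: at a typed site the observed
allele matches the donor allele with probability `1 - lambda`, where

```
theta  = 1 / sum_{i=1}^{H-1} 1/i
lambda = theta / (2 * (H + theta))
```

is the Watterson-style mutation parameter; missing donor alleles emit
0.5. Untyped sites are silent (emission 1 for every donor), so the chain
runs over the full site grid and posterior donor probabilities are exact
at untyped sites rather than interpolated. The posterior converts to an
expected alternate-allele dosage per haplotype,
`P(allele = 1) = sum_k gamma_k (lambda + (1 - 2 lambda) a_k)`, and the
diploid dosage is the sum over the subject's two haplotypes.

Two-panel imputation concatenates the local panel's haplotypes onto the
global panel's site grid without any cross-panel re-imputation; global
sites absent from the local panel carry missing alleles there. `lambda`
is recomputed for the combined haplotype count. This is the simplest
behavior consistent with running an IMPUTE-style tool with a secondary
reference panel and without panel merging.

Numerics: the forward–backward recursion is linear-space with per-site
normalization (no underflow up to at least 10^5 sites; the normalization
invariant is tested to 1e-9), implemented in C++ with the uniform-switch
rank-one update, so one pass costs `O(H L)` rather than `O(H^2 L)`. A
floor (`min_no_switch`, default 1e-12) guards the per-interval no-switch
probability. Correctness is property-tested against exhaustive
enumeration of all `H^L` copying paths for small instances.

# The synthetic populations

No individual-level data from the study populations this design emulates
are public, so the generator is first-class, tested code and defines the
study conditions. It uses founder-mosaic copying rather than a
coalescent: cheap, seedable, and produces block LD that a copying-model
imputation engine can exploit.

Ancestry is two-level, which is the minimal structure that reproduces the
field's central difficulty:

* **24 proto-founder backgrounds** carry the *old, common* variants
  (sites with spectrum frequency at least `1/24`). Any present-day
  haplotype block is one of few backgrounds shared by many panel
  haplotypes, so common variants are imputable from array data.
* **400 founder haplotypes** are mosaics of the backgrounds (block scale
  0.5 cM; `founder_block_rate = 200`/Morgan). *Young, rare* variants are
  overlaid on individual founders: a rare allele rides a background that
  other founders carry without it. Array sites are globally common and
  therefore background-level, so array data identify the background but
  not the rare allele — exactly why rare variants impute poorly from a
  global panel.

Per-site frequencies follow a truncated power-law spectrum with density
proportional to `f^-alpha` on `[1/(2 n_founders), 0.5]`; `alpha = 1`
(default) makes rare variants dominate, as in neutral sequence data.

Present-day haplotypes (the 500-haplotype global panel and the isolate's
founding pool) are mosaics over the founders at
`mosaic_switch_rate = 120`/Morgan. This matches the copying model's own
implied donor-segment scale (`4 Ne / H` is about 118/Morgan at
`Ne = 20000`, `H = 678`): reference haplotypes share segments with a
target at the scale the HMM expects. We found this matching essential:
with much coarser mosaics every rare variant is perfectly recoverable
from the global panel (its carrier founder is uniquely identified), and
with much finer mosaics the chain cannot track any donor and even common
variants fail.

The local isolate: a bottleneck retains `local_founder_fraction = 0.15`
of the founders; the breeding pool of `drift_pool_haps = 1080`
haplotypes (an effective size of 540 diploids — small-isolate scale, and
deliberately larger than the sequenced cohort) is then re-mosaicked for
`drift_generations = 20` generations at the meiotic crossover rate of
1/Morgan. Frequency drift arises from the finite resampling; haplotype
divergence from the additional post-split recombination. The 90-subject
cohort is sampled from the final pool. The bottleneck multiplies the
frequency of surviving rare variants by roughly `1/0.15`, populating the
globally-rare/locally-common corner in which the local panel helps most.
The "strongly drifted" contrast doubles `drift_generations` to 40; with
a shared seed the strong-drift population is the reference population
aged a further 20 generations, giving a tightly paired comparison.

Genotype calls are derived from the truth haplotypes with per-call error
0.001 (matching the ~99.9% array–sequence concordance typical of
quality-controlled exome calls; larger error rates flood the rare MAF
bins with artifact sites whose truth is monomorphic), with erroneous
calls receiving a low genotype quality (GQ < 20) with probability 0.5
and 2% of sites drawing a failing site QUAL. Arrays are ascertained on
the global panel: a random half (`array_fraction = 0.5`) of SNVs with
global MAF at least 5% — arrays tag a subset of common variation, which
leaves common off-array variants to impute. 2% of sites are emitted as
indels and 1% flagged multi-mapping solely so the corresponding QC
exclusions have work to do. Phase-switch-error injection is available
(`phase_switch_rate`) but defaults to 0: phasing itself is out of scope
and the truth phase stands in for a well-phased panel.

What the generator does **not** emulate: genuinely coalescent genealogies
with recombination hotspots, gene conversion, mutation recurrence,
pedigree structure within the cohort, multi-allelic sites, and
chromosome-scale variation in map density. Passing tests therefore show
that the pipeline reproduces the *mechanism* — they do not calibrate how
large the accuracy gains would be on any real cohort.

# Quality control

The sequence cascade applies, in order: site QUAL ≥ 40; calls with
GQ < 20 masked to missing; site call rate ≥ 50%; MAF ≥ 0.75% of
non-missing calls (with ~100 subjects this is a minimum minor allele
count of 2); exact Hardy–Weinberg test at p ≥ 1e-4; multi-mapping sites
excluded; non-SNV sites excluded. Order matters (masking precedes the
call-rate and MAF computations, which precede HWE) and is logged; the
cascade is idempotent and never alters a retained call.

The HWE test is the exact conditional test: given the sample size and
allele counts, the p-value is the total probability of all heterozygote
counts no more probable than the observed one (a relative tolerance of
1e-9 groups floating-point ties). It is vectorized by grouping sites that
share (sample size, minor allele count), and is property-tested against
an independent recurrence-based enumeration for every genotype table up
to n = 200 at 1e-12.

Array–sequence merging counts mismatching calls per subject and per
variant *before* exclusion, drops subjects with more than 50 and variants
with more than 30 mismatches (values at the threshold are retained — the
thresholds are strict inequalities), and resolves retained overlaps in
favor of the sequence call, which is the downstream gold standard.
Minor-allele concordance is reported per MAF band over call pairs in
which either source shows at least one minor allele; the denominator
convention is not standardized, so the count basis is reported alongside.
Variants absent from the global panel (cohort-private) or with mismatched
allele codes are excluded and logged separately, and subjects called at
fewer than 80% of the combined panel are dropped (exactly 80% is
retained).

# The evaluation

Every sequenced subject is imputed at the exomic non-array target sites
from their phased array-site alleles, twice: global panel alone, and
global panel plus the local panel with that subject's two haplotypes
removed (a guard refuses to impute a subject whose haplotypes are present
in any panel). Per SNP, squared Pearson correlation between imputed
dosage and the gold-standard sequence genotypes is computed across
subjects, complete-case with respect to missing gold calls; SNPs with
fewer than two complete pairs or zero variance on either side are
undefined and excluded from summaries (their count is reported).

MAF bins increase by factors of sqrt(10) — boundaries at 10^-2, 10^-1.5,
10^-1, 10^-0.5, lower-inclusive, top bin closed at 0.5 — on the *local*
gold-standard frequencies; the secondary stratification uses *global
panel* frequencies in bands <1%, 1–3.2%, >3.2%. Per bin we report the
mean and median r² under each configuration, the mean, SD and SE of the
per-SNP increase, a two-sided one-sample t-test of the increase against
zero and Welch tests between adjacent bins (reports of this kind rarely
state the variance assumption; Welch is the safer default), and the
effective-sample-size increase `100 (m2/m1 - 1)` rounded to a whole
percent — a proportionate increase in r² has the same effect on
association power as the same proportionate increase in sample size.
Note the ratio-of-means definition: published tables of this kind
occasionally print a derived cell inconsistent with it, and we follow the
definition, not the cell.

# Design choices that were genuinely open

* **Gold standard**: scored against the error-injected sequence calls
  with GQ < 20 masked (realistic), not the noiseless truth; an option
  flips this.
* **Overlap conflict in merging**: sequence wins; the merge source is
  logged via the report rather than per call.
* **Two-panel weighting**: plain concatenation; how a production tool
  internally weights an unmerged secondary panel is not documented, and
  concatenation is the declared approximation.
* **Drift knob**: "stronger divergence" doubles drift generations. We
  examined halving the breeding pool and tightening the bottleneck as
  alternative distance dials during design; both are confounded by
  composition churn of the rare MAF bin (rare variants drifting out of,
  and common variants into, the bin), which is why the distance contrast
  is asserted as a paired mean across seeds rather than per seed.
* **Problem sizes**: 1,500 sites over 3 Mb / 3 cM, 500 global
  haplotypes, 90 subjects, 5 seeds for every replicated claim; small
  unit-test configs use 160 sites and 12 subjects. These sizes keep a
  full cross-validation run around 20 seconds while leaving hundreds of
  scored SNPs per MAF bin.

# Known limitations

* The gain magnitudes are generator-dependent; only directions and
  orderings are asserted.
* The global panel is drawn from the same founder pool as the isolate
  (no continental structure), so "distance" is purely
  bottleneck-plus-drift.
* The copying engine is haploid and consumes phased input; pre-phasing
  quality enters only through the optional switch-error injection.
* Single chromosome window, no chunking at scale; the chunk-free run is
  exact for the window sizes used here.
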