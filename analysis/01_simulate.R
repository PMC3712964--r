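#!/usr/bin/env Rscript

# Simulate the reference study conditions: a 500-haplotype global reference
# panel plus a 90-subject local isolate cohort with error-injected exome
# sequence calls, and write every interchange file (VCF, IMPUTE2 panel,
# genetic map, truth dosages) under results/sim/.

library(panelaug)

out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 1L)
print(cfg)
ts <- simulate_populations(cfg)
print(ts)

write_vcf(ts$local_called, file.path(out, "local_sequence.vcf"),
          seed = cfg$seed)
write_vcf(ts$local_array_called, file.path(out, "local_array.vcf"),
          seed = cfg$seed)
write_vcf(ts$local_truth, file.path(out, "local_truth_phased.vcf"),
          seed = cfg$seed)
write_impute2_panel(ts$global_panel, file.path(out, "global_panel"))
write_genetic_map(ts$site_map, file.path(out, "genetic_map.txt"))
write_report_tsv(
  data.frame(id = ts$site_map$id, t(panel_genotypes(ts$local_truth)),
             check.names = FALSE),
  file.path(out, "truth_dosage.tsv"), seed = cfg$seed)

maf_g <- panel_freq(ts$global_panel, minor = TRUE)
cat(sprintf(
  "simulated %d sites (%d array, %d exomic targets); local/global mean |dF| = %.3f\n",
  nrow(ts$site_map), sum(ts$site_map$is_array),
  sum(ts$site_map$is_exomic & !ts$site_map$is_array),
  mean(abs(colMeans(ts$local_truth$alleles) - panel_freq(ts$global_panel)))))
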