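#!/usr/bin/env Rscript

# Run the sequence QC cascade and the array-sequence merge on the simulated
# cohort, then restrict to global-panel sites and filter low-call-rate
# subjects. Writes results/qc/qc_report.tsv and the filtered call set.

library(panelaug)

dir.create("results/qc", showWarnings = FALSE, recursive = TRUE)

ts <- simulate_populations(sim_config(seed = 1L))

seq_qc <- apply_sequence_qc(ts$local_called)
cat("sequence QC:\n"); print(seq_qc$report)

merged <- merge_array_sequence(ts$local_array_called, seq_qc$gm)
cat(sprintf("array/sequence concordance: %.4f over %d calls\n",
            merged$concordance$overall, merged$concordance$n_compared))
print(merged$concordance$minor_allele)

restricted <- restrict_to_global_panel(merged$gm, ts$global_panel)
final <- filter_subject_call_rate(restricted$gm)

report <- rbind(seq_qc$report, merged$report, restricted$report,
                final$report)
write_report_tsv(report, "results/qc/qc_report.tsv", seed = 1)
write_vcf(final$gm, "results/qc/merged_filtered.vcf", seed = 1)
cat(sprintf("final call set: %d subjects x %d variants\n",
            nrow(final$gm$calls), ncol(final$gm$calls)))
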