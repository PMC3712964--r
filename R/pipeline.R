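## Pipeline orchestration: simulate -> QC -> impute/cross-validate ->
## report, with a manifest and provenance headers on every output file.

#' Assemble a full pipeline configuration
#'
#' @param sim a [sim_config()].
#' @param qc a [qc_thresholds()] list.
#' @param hmm an [hmm_params()].
#' @param out_dir output directory (created if absent).
#' @param gold gold standard for scoring, `"called"` or `"truth"`.
#' @param seed master seed; defaults to the simulation seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), qc = qc_thresholds(),
                       hmm = hmm_params(), out_dir = tempfile("panelaug_"),
                       gold = "called", seed = sim$seed) {
  structure(list(sim = sim, qc = qc, hmm = hmm, out_dir = out_dir,
                 gold = gold, seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  writeLines(deparse(config[setdiff(names(config), "out_dir")]), tmp)
  unname(tools::md5sum(tmp))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the complete analysis pipeline
#'
#' Executes simulate, QC (sequence cascade, array-sequence merge,
#' global-panel restriction, subject call rate), drop-one-out
#' cross-validation and reporting, writing every table under
#' `config$out_dir` with a provenance header (package version, seed,
#' config hash). A failing stage aborts with a stage-tagged error; outputs
#' of completed stages are retained.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the truth set, QC outputs, accuracy
#'   records, bin summaries and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  seed <- config$seed
  outfile <- function(name) file.path(config$out_dir, name)
  manifest <- list()
  note <- function(stage, files)
    manifest[[length(manifest) + 1]] <<- data.frame(
      stage = stage, output = files, seed = seed, config = hash,
      stringsAsFactors = FALSE)

  ts <- run_stage("simulate", {
    cfg <- config$sim
    cfg$seed <- seed
    simulate_populations(cfg)
  })
  run_stage("simulate", {
    write_vcf(ts$local_called, outfile("local_sequence.vcf"),
              seed = seed, config_hash = hash)
    write_vcf(ts$local_array_called, outfile("local_array.vcf"),
              seed = seed, config_hash = hash)
    write_impute2_panel(ts$global_panel, outfile("global_panel"))
    write_genetic_map(ts$site_map, outfile("genetic_map.txt"))
    write_report_tsv(
      data.frame(id = ts$site_map$id,
                 t(panel_genotypes(ts$local_truth)),
                 check.names = FALSE),
      outfile("truth_dosage.tsv"), seed, hash)
  })
  note("simulate", c("local_sequence.vcf", "local_array.vcf",
                     "global_panel.hap", "genetic_map.txt",
                     "truth_dosage.tsv"))

  qc_out <- run_stage("qc", {
    seq_qc <- apply_sequence_qc(ts$local_called, config$qc)
    merged <- merge_array_sequence(ts$local_array_called, seq_qc$gm)
    restricted <- restrict_to_global_panel(merged$gm, ts$global_panel)
    final <- filter_subject_call_rate(restricted$gm)
    report <- rbind(seq_qc$report, merged$report, restricted$report,
                    final$report)
    write_report_tsv(report, outfile("qc_report.tsv"), seed, hash)
    list(gm = final$gm, report = report, concordance = merged$concordance)
  })
  note("qc", "qc_report.tsv")

  records <- run_stage("crossval", {
    retained <- site_key(ts$site_map) %in% site_key(qc_out$gm$site_map)
    targets <- intersect(default_target_sites(ts), which(retained))
    if (length(targets) == 0) stop("no target sites survived QC")
    run_crossval(ts, config$hmm, target_sites = targets,
                 gold = config$gold)
  })
  run_stage("crossval",
    write_report_tsv(records, outfile("accuracy_records.tsv"), seed, hash))
  note("crossval", "accuracy_records.tsv")

  reports <- run_stage("report", {
    table1 <- summarize_bins(records, "local")
    strat <- summarize_bins(records, "global")
    ct <- poor_to_well_crosstab(records)
    grid <- improvement_grid(records)
    write_report_tsv(table1, outfile("table1.tsv"), seed, hash)
    write_report_tsv(strat, outfile("strat_global.tsv"), seed, hash)
    write_report_tsv(
      data.frame(frac_poor = ct$frac_poor,
                 frac_poor_to_well = ct$frac_poor_to_well,
                 n_poor = ct$n_poor, n_total = ct$n_total),
      outfile("crosstab.tsv"), seed, hash)
    gm_df <- data.frame(local_bin = rownames(grid$mean_increase),
                        grid$mean_increase, check.names = FALSE)
    gc_df <- data.frame(local_bin = rownames(grid$count),
                        grid$count, check.names = FALSE)
    write_report_tsv(gm_df, outfile("grid_mean.tsv"), seed, hash)
    write_report_tsv(gc_df, outfile("grid_counts.tsv"), seed, hash)
    list(table1 = table1, strat_global = strat, crosstab = ct, grid = grid)
  })
  note("report", c("table1.tsv", "strat_global.tsv", "crosstab.tsv",
                   "grid_mean.tsv", "grid_counts.tsv"))

  manifest <- do.call(rbind, manifest)
  write_report_tsv(manifest, outfile("manifest.tsv"), seed, hash)
  invisible(list(truth = ts, qc = qc_out, records = records,
                 table1 = reports$table1,
                 strat_global = reports$strat_global,
                 crosstab = reports$crosstab, grid = reports$grid,
                 manifest = manifest, out_dir = config$out_dir))
}
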