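# End-to-end pipelines behind the command-line entry point
# (inst/cli/cqbatch.R): correct / tune / simulate / evaluate, each writing
# files plus a machine-readable provenance record.

.write_provenance <- function(out_dir, record) {
  record$r_version <- as.character(getRversion())
  record$package_version <- as.character(utils::packageVersion("cqbatch"))
  jsonlite::write_json(record, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run a correction (or tuned correction) end to end
#'
#' Reads counts and metadata, corrects, and writes the corrected table
#' plus a provenance record (`provenance.json`) and, when tuning, the full
#' R2 report grid (`tuning_report.tsv`). Reruns with the same inputs and
#' seeds are bit-identical.
#'
#' @param counts,metadata input file paths ([read_count_table()],
#'   [read_metadata()]).
#' @param batch_col,key_cols,covariate_cols metadata column roles.
#' @param out_dir output directory (created if needed).
#' @param ref_batch reference batch; ignored when `tune = TRUE` and
#'   `tune_refs` is given.
#' @param mode `"default"` or `"libsize"`.
#' @param taus quantile grid. @param seed master seed.
#' @param tune logical; run two-layer tuning instead of a single fit.
#' @param tune_refs,tune_strategies tuning grid (defaults: all batches,
#'   [default_strategies()]).
#' @param threads taxon-level parallelism.
#' @return invisibly, the corrected [count_table()].
#' @export
run_correct <- function(counts, metadata, batch_col, key_cols,
                        covariate_cols = character(), out_dir = ".",
                        ref_batch = NULL, mode = "default",
                        taus = default_taus(), seed = 1L, tune = FALSE,
                        tune_refs = NULL, tune_strategies = NULL,
                        threads = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- read_count_table(counts)
  meta <- read_metadata(metadata, batch_col, key_cols, covariate_cols)
  al <- align_samples(tab, meta)
  if (tune) {
    strategies <- tune_strategies %||% default_strategies(taus)
    res <- tune_correction(al$table, al$meta,
                           candidate_refs = tune_refs,
                           strategies = strategies, mode = mode,
                           jitter_seed = seed, threads = threads)
    corrected <- res$table
    write.table(res$report, file.path(out_dir, "tuning_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    chosen <- list(ref_batch = res$ref_batch,
                   strategy_map = as.list(res$strategy_map),
                   r2_batch = res$r2_batch)
  } else {
    cfg <- correction_config(ref_batch = ref_batch,
                             strategy = fit_strategy(taus = taus),
                             mode = mode, jitter_seed = seed,
                             threads = threads)
    corrected <- correct_counts(al$table, al$meta, cfg)
    chosen <- list(ref_batch = attr(corrected, "ref_batch"),
                   strategy = "standard")
  }
  write_count_table(corrected, file.path(out_dir, "corrected_counts.tsv"))
  .write_provenance(out_dir, list(
    subcommand = if (tune) "tune" else "correct", counts = counts,
    metadata = metadata, batch_col = batch_col, key_cols = key_cols,
    covariate_cols = covariate_cols, mode = mode, seed = seed,
    taus = range(taus), n_taus = length(taus), chosen = chosen))
  invisible(corrected)
}

#' Simulate a dataset to files
#'
#' Writes counts TSV, metadata TSV (condition, batch, libsize) and a truth
#' JSON holding the DA/batch taxon sets, directions and scenario
#' parameters.
#'
#' @param out_dir output directory. @param scenario a
#'   [simulation_scenario()] or preset letter. @param seed master seed.
#' @param n_samples,n_taxa,sparsity_target starting-table shape, passed to
#'   [synth_starting_data()].
#' @return invisibly, the [simulate_dataset()] result.
#' @export
run_simulate <- function(out_dir = ".", scenario = "A", seed = 1L,
                         n_samples = 270L, n_taxa = 233L,
                         sparsity_target = 0.7) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(scenario)) scenario <- scenario_preset(scenario)
  starting <- synth_starting_data(n_samples, n_taxa, sparsity_target,
                                  seed = seed)
  sim <- simulate_dataset(starting, scenario, seed = seed)
  write_count_table(sim$table, file.path(out_dir, "counts.tsv"))
  meta <- data.frame(sample_id = sim$table$sample_ids,
                     condition = sim$condition, batch = sim$batch,
                     libsize = sim$table$libsize)
  write.table(meta, file.path(out_dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(da_taxa = sim$da_taxa, da_dir = sim$da_dir,
         batch_dir = sim$batch_dir,
         scenario = unclass(sim$scenario)),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  .write_provenance(out_dir, list(subcommand = "simulate", seed = seed,
                                  scenario = unclass(scenario),
                                  n_samples = n_samples, n_taxa = n_taxa))
  invisible(sim)
}

#' Evaluate a correction before/after
#'
#' Emits PERMANOVA R2 for batch and the key variable under Bray-Curtis and
#' Aitchison dissimilarity for both tables, the cross-validated
#' random-forest prediction metric, and - when a truth JSON from
#' [run_simulate()] is given - observed FDR and sensitivity of BH-adjusted
#' per-taxon association testing. Without truth the FDR rows are omitted,
#' not zero-filled.
#'
#' @param before,after count table paths. @param metadata metadata path.
#' @param batch_col,key_cols metadata roles. @param truth optional truth
#'   JSON path. @param out_dir output directory. @param seed CV seed.
#' @param alpha BH level.
#' @return invisibly, the report data.frame (also written as
#'   `evaluation.tsv`).
#' @export
run_evaluate <- function(before, after, metadata, batch_col, key_cols,
                         truth = NULL, out_dir = ".", seed = 1L,
                         alpha = 0.05) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- read_metadata(metadata, batch_col, key_cols)
  rows <- NULL
  truth_idx <- NULL
  if (!is.null(truth))
    truth_idx <- jsonlite::read_json(truth,
                                     simplifyVector = TRUE)$da_taxa
  for (tag in c("before", "after")) {
    tab <- read_count_table(if (tag == "before") before else after)
    al <- align_samples(tab, meta)
    if (!identical(sort(tab$sample_ids), sort(meta$sample_ids)))
      stop("sample IDs of ", tag, " table do not match the metadata")
    key <- al$meta$key_cols[1L]
    for (metric in c("bray_curtis", "aitchison")) {
      d <- if (metric == "bray_curtis") bray_curtis_matrix(al$table)
           else aitchison_matrix(al$table)
      rows <- rbind(rows,
        data.frame(dataset = tag, metric = paste0("r2_batch_", metric),
                   value = permanova_r2(d, al$meta$batch)),
        data.frame(dataset = tag, metric = paste0("r2_key_", metric),
                   value = permanova_r2(d, al$meta$data[[key]])))
    }
    cv <- predict_key_cv(al$table, al$meta, key = key, seed = seed)
    rows <- rbind(rows, data.frame(dataset = tag,
                                   metric = paste0("cv_", cv$metric),
                                   value = cv$value))
    if (!is.null(truth_idx)) {
      fdr <- association_fdr(al$table, al$meta, key = key, alpha = alpha,
                             truth = truth_idx)
      rows <- rbind(rows,
        data.frame(dataset = tag, metric = "observed_fdr",
                   value = fdr$observed_fdr),
        data.frame(dataset = tag, metric = "sensitivity",
                   value = fdr$sensitivity))
    }
  }
  write.table(rows, file.path(out_dir, "evaluation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  .write_provenance(out_dir, list(subcommand = "evaluate", before = before,
                                  after = after, metadata = metadata,
                                  seed = seed, alpha = alpha))
  invisible(rows)
}
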