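# Two-layer tuning: per-prevalence-bin fitting strategy (inner layer) and
# reference batch (outer layer), minimizing PERMANOVA R2 explained by
# batch.

#' Partition taxa into prevalence bins
#'
#' Taxon `j` goes to the first bin whose cutoff its prevalence (fraction
#' of samples with a positive count) exceeds; the last bin collects
#' everything at or below the smallest cutoff. Bins are disjoint and
#' exhaustive; empty bins are kept (and skipped downstream).
#'
#' @param table a [count_table()].
#' @param cutoffs strictly decreasing thresholds in (0, 1); default 0.9,
#'   0.8, ..., 0.1.
#' @return named list of taxon index vectors.
#' @export
prevalence_bins <- function(table, cutoffs = seq(0.9, 0.1, by = -0.1)) {
  stopifnot(inherits(table, "count_table"))
  if (any(cutoffs <= 0) || any(cutoffs >= 1) ||
      is.unsorted(rev(cutoffs), strictly = TRUE))
    stop("cutoffs must be strictly decreasing values in (0, 1)")
  prev <- colMeans(table$counts > 0)
  # bin b = 1 + number of cutoffs at or above the prevalence; a prevalence
  # exactly at a cutoff belongs to the lower bin (cutoffs must be exceeded)
  assigned <- vapply(prev, function(p) 1L + sum(p <= cutoffs), integer(1))
  out <- lapply(seq_len(length(cutoffs) + 1L),
                function(b) which(assigned == b))
  names(out) <- c(paste0("prev_gt_", cutoffs),
                  paste0("prev_le_", cutoffs[length(cutoffs)]))
  out
}

#' Choose the best fitting strategy per prevalence bin
#'
#' For a fixed reference batch, corrects each prevalence sub-table under
#' every candidate strategy, scores the corrected sub-table by PERMANOVA
#' R2 explained by batch, and keeps the argmin (ties: first candidate in
#' the given order). The optimally corrected sub-tables are concatenated
#' back into a full table.
#'
#' @param table a [count_table()]. @param meta aligned metadata.
#' @param ref_batch reference batch level.
#' @param strategies named list of [fit_strategy()] candidates.
#' @param cutoffs prevalence cutoffs for [prevalence_bins()].
#' @param mode,jitter_seed,eval_grid_size,threads see
#'   [correction_config()].
#' @param distance `"bray_curtis"` (default) or `"aitchison"` tuning
#'   metric.
#' @return list: `table` (corrected), `strategy_map` (bin -> strategy
#'   name), `report` (data.frame of every bin x strategy R2).
#' @export
select_strategy_per_bin <- function(table, meta, ref_batch = NULL,
                                    strategies = default_strategies(),
                                    cutoffs = seq(0.9, 0.1, by = -0.1),
                                    mode = "default", jitter_seed = 1L,
                                    eval_grid_size = 199L, threads = 1L,
                                    distance = c("bray_curtis",
                                                 "aitchison")) {
  distance <- match.arg(distance)
  if (!length(strategies)) stop("need at least one candidate strategy")
  if (is.null(names(strategies)))
    names(strategies) <- paste0("strategy", seq_along(strategies))
  if (!identical(table$sample_ids, meta$sample_ids)) {
    al <- align_samples(table, meta)
    table <- al$table
    meta <- al$meta
  }
  bins <- prevalence_bins(table, cutoffs)
  corrected <- table$counts
  batch <- meta$batch
  report <- NULL
  strategy_map <- setNames(rep(NA_character_, length(bins)), names(bins))
  dist_fun <- if (distance == "bray_curtis") bray_curtis_matrix
              else aitchison_matrix
  for (b in seq_along(bins)) {
    idx <- bins[[b]]
    if (!length(idx)) {  # empty bin: keep the bookkeeping, skip the work
      report <- rbind(report,
                      data.frame(bin = names(bins)[b],
                                 strategy = names(strategies),
                                 r2_batch = NA_real_,
                                 stringsAsFactors = FALSE))
      next
    }
    sub <- count_table(table$counts[, idx, drop = FALSE])
    best <- NULL
    for (s in seq_along(strategies)) {
      cfg <- correction_config(ref_batch = ref_batch,
                               strategy = strategies[[s]], mode = mode,
                               jitter_seed = jitter_seed,
                               eval_grid_size = eval_grid_size,
                               threads = threads)
      corr <- correct_counts(sub, meta, cfg)
      r2 <- if (all(corr$libsize == 0)) 1
            else permanova_r2(dist_fun(corr), batch)
      report <- rbind(report,
                      data.frame(bin = names(bins)[b],
                                 strategy = names(strategies)[s],
                                 r2_batch = r2,
                                 stringsAsFactors = FALSE))
      if (is.null(best) || r2 < best$r2 - 1e-12) {
        best <- list(r2 = r2, counts = corr$counts,
                     name = names(strategies)[s])
      }
    }
    corrected[, idx] <- best$counts
    strategy_map[b] <- best$name
  }
  list(table = count_table(corrected), strategy_map = strategy_map,
       report = report)
}

#' Two-layer tuning of reference batch and fitting strategies
#'
#' Outer loop over candidate reference batches, inner per-bin strategy
#' selection; the corrected table with the lowest PERMANOVA R2 explained
#' by batch wins. Only per-bin local optima are sought, which keeps the
#' search affordable; the same reference batch is used for all taxa of
#' one corrected table, since mixing references would distort the overall
#' community structure.
#'
#' @inheritParams select_strategy_per_bin
#' @param candidate_refs batch levels to try (default: all observed).
#' @return list: `table` (final corrected), `ref_batch`, `strategy_map`,
#'   `r2_batch` (of the winner), `report` (every ref x bin x strategy R2).
#' @export
tune_correction <- function(table, meta, candidate_refs = NULL,
                            strategies = default_strategies(),
                            cutoffs = seq(0.9, 0.1, by = -0.1),
                            mode = "default", jitter_seed = 1L,
                            eval_grid_size = 199L, threads = 1L,
                            distance = c("bray_curtis", "aitchison")) {
  distance <- match.arg(distance)
  if (!identical(table$sample_ids, meta$sample_ids)) {
    al <- align_samples(table, meta)
    table <- al$table
    meta <- al$meta
  }
  candidate_refs <- as.character(candidate_refs %||% levels(meta$batch))
  bad <- setdiff(candidate_refs, levels(meta$batch))
  if (length(bad))
    stop("candidate refs not observed: ", paste(bad, collapse = ", "))
  dist_fun <- if (distance == "bray_curtis") bray_curtis_matrix
              else aitchison_matrix
  best <- NULL
  report <- NULL
  for (ref in candidate_refs) {
    sel <- select_strategy_per_bin(table, meta, ref_batch = ref,
                                   strategies = strategies,
                                   cutoffs = cutoffs, mode = mode,
                                   jitter_seed = jitter_seed,
                                   eval_grid_size = eval_grid_size,
                                   threads = threads, distance = distance)
    r2 <- permanova_r2(dist_fun(sel$table), meta$batch)
    report <- rbind(report, cbind(ref_batch = ref, sel$report,
                                  stringsAsFactors = FALSE))
    if (is.null(best) || r2 < best$r2_batch - 1e-12)
      best <- list(table = sel$table, ref_batch = ref,
                   strategy_map = sel$strategy_map, r2_batch = r2)
  }
  c(best, list(report = report))
}
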