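# The matching-step: transport every observed count through its percentile
# in the original conditional distribution to the batch-free one, with tie
# smoothing and the left-continuous fallback; orchestration over taxa.

#' Configuration for a correction run
#'
#' @param ref_batch batch level all other batches are aligned to; its
#'   samples are returned unchanged. Default: first batch level.
#' @param strategy a [fit_strategy()] applied to every taxon.
#' @param mode `"default"` removes between-batch library-size differences
#'   along with the rest of the batch effect; `"libsize"` keeps library
#'   size in the model (standardized libsize in the presence part, log
#'   libsize offset in the quantile part) so its variability is preserved.
#' @param jitter_seed master seed; per-taxon jitter streams are derived
#'   from it so taxon-parallel runs are reproducible.
#' @param jitter_reps number of independent jitter draws to average over
#'   (default 1, the standard single-draw usage; higher values smooth the
#'   jitter noise of the corrected counts at proportional cost).
#' @param eval_grid_size resolution of the shared percentile grid used for
#'   assembly and matching.
#' @param force_zero_batch validation hook: zero all fitted batch
#'   coefficients, making the batch-free distribution identical to the
#'   original one (output must then equal input).
#' @param threads taxa are corrected independently; values > 1 use
#'   `parallel::mclapply` with deterministic result assembly.
#' @export
correction_config <- function(ref_batch = NULL,
                              strategy = fit_strategy(),
                              mode = c("default", "libsize"),
                              jitter_seed = 1L,
                              jitter_reps = 1L,
                              eval_grid_size = 199L,
                              force_zero_batch = FALSE,
                              threads = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(strategy, "fit_strategy"), jitter_reps >= 1)
  structure(list(ref_batch = ref_batch, strategy = strategy, mode = mode,
                 jitter_seed = as.integer(jitter_seed),
                 jitter_reps = as.integer(jitter_reps),
                 eval_grid = default_eval_grid(eval_grid_size),
                 force_zero_batch = isTRUE(force_zero_batch),
                 threads = as.integer(threads)),
            class = "correction_config")
}

# Transport one observation between two quantile functions evaluated on a
# shared grid. Identity transport (elementwise-equal functions, e.g. a
# reference-batch sample) returns the observation unchanged. Ties: rounded
# (half-up) average over all matched grid values of the batch-free
# function. No match: left-continuous fallback to the largest grid
# percentile whose original value lies below the observation.
.match_value <- function(vals_o, vals_c, y) {
  if (identical(vals_o, vals_c)) return(y)
  m <- vals_o == y
  if (any(m)) return(round_half_up(mean(vals_c[m])))
  below <- which(vals_o < y)
  if (length(below)) vals_c[max(below)] else vals_c[1L]
}

#' Match one observation between two conditional quantile functions
#'
#' Locates `y_obs` in the original function `q_o` and returns the value of
#' the batch-free function `q_c` at the same percentile(s): the rounded
#' average over all matched grid percentiles, or, when the observation is
#' absent from the grid, the value of `q_c` at the largest percentile where
#' `q_o` stays below `y_obs` (quantile functions are left-continuous).
#' When the two functions coincide the observation is returned unchanged.
#'
#' @param q_o,q_c [predict_cqf()] objects on the same evaluation grid.
#' @param y_obs observed count (integer, >= 0).
#' @return corrected integer count.
#' @export
match_and_correct <- function(q_o, q_c, y_obs) {
  stopifnot(inherits(q_o, "cqf"), inherits(q_c, "cqf"),
            length(q_o$values) == length(q_c$values))
  if (y_obs < 0) stop("y_obs must be a non-negative count")
  as.integer(.match_value(q_o$values, q_c$values, y_obs))
}

# Fit, assemble and match a single taxon column. Returns the corrected
# column with a "note" attribute describing degenerate handling.
correct_taxon_impl <- function(y, design, config, taxon_index = 1L) {
  n <- length(y)
  pos <- y > 0
  n_pos <- sum(pos)
  note <- NULL
  if (all(y == 0))
    return(structure(y, note = "all_zero"))
  if (n_pos < 2L)
    return(structure(y, note = "fewer_than_two_positive"))

  strategy <- config$strategy
  mode <- config$mode
  pres <- fit_presence(design, pos, strategy, mode = mode)
  sub <- subset_design(design, pos)
  if (config$force_zero_batch && !pres$degenerate &&
      length(pres$b_cols)) {
    pres$coef[pres$b_cols] <- 0
    pres$gamma[] <- 0
  }
  pi_o <- predict_presence(pres, design, remove_batch = FALSE)
  pi_c <- predict_presence(pres, design, remove_batch = TRUE)
  grid <- config$eval_grid
  is_ref <- as.integer(design$batch) == 1L  # relevel put ref first

  single_draw <- function(rep) {
    seed_j <- substream_seed(config$jitter_seed, "jitter",
                             taxon_index + (rep - 1L) * 7919L)
    w <- jitter_counts(y[pos], seed_j)
    if (mode == "libsize") w <- log(w) - log(design$libsize[pos])
    qfit <- fit_positive_quantiles(sub, w, strategy)
    if (config$force_zero_batch && length(qfit$b_cols))
      qfit$coef[, qfit$b_cols] <- 0
    W_o <- predict_positive_quantiles(qfit, design, remove_batch = FALSE)
    W_c <- predict_positive_quantiles(qfit, design, remove_batch = TRUE)
    taus <- qfit$tau
    out <- integer(n)
    for (i in seq_len(n)) {
      if (is_ref[i] && !config$force_zero_batch) { out[i] <- y[i]; next }
      wo <- monotone_rearrange(W_o[i, ])
      wc <- monotone_rearrange(W_c[i, ])
      if (mode == "libsize") {
        off <- log(design$libsize[i])
        wo <- exp(wo + off)
        wc <- exp(wc + off)
      }
      qo <- dejitter_quantiles(wo)
      qc <- dejitter_quantiles(wc)
      vo <- .cqf_eval(1 - pi_o[i], qo, taus, grid)
      vc <- .cqf_eval(1 - pi_c[i], qc, taus, grid)
      out[i] <- .match_value(vo, vc, y[i])
    }
    out
  }
  reps <- config$jitter_reps %||% 1L
  out <- if (reps == 1L) single_draw(1L)
         else round_half_up(rowMeans(vapply(seq_len(reps),
                                            function(r)
                                              as.numeric(single_draw(r)),
                                            numeric(n))))
  structure(as.integer(out), note = note)
}

# Row subset of a design_matrix, keeping bookkeeping intact.
subset_design <- function(design, keep) {
  out <- design
  out$X <- design$X[keep, , drop = FALSE]
  out$batch <- design$batch[keep]
  out$sample_ids <- design$sample_ids[keep]
  if (!is.null(design$libsize)) out$libsize <- design$libsize[keep]
  if (!is.null(design$libsize_s)) out$libsize_s <- design$libsize_s[keep]
  out
}

#' Correct a single taxon column
#'
#' Fits the two-part model on all samples, assembles each sample's original
#' and batch-free conditional quantile functions and transports the
#' observed counts. Degenerate taxa (all zero, or fewer than two positive
#' counts) are passed through unchanged; a taxon present in every sample is
#' corrected with the presence part pinned at one, since only its positive
#' part carries information.
#'
#' @param counts_j integer column aligned with the design rows.
#' @param design a [build_design()] result.
#' @param config a [correction_config()].
#' @param taxon_index index used to derive the taxon's jitter stream.
#' @return corrected integer vector (attribute `note` records degenerate
#'   handling).
#' @export
correct_taxon <- function(counts_j, design, config = correction_config(),
                          taxon_index = 1L) {
  correct_taxon_impl(as.integer(counts_j), design, config, taxon_index)
}

#' Remove batch effects from a count table
#'
#' Applies the two-step (regression + matching) correction to every taxon,
#' aligning all batches to the reference batch. Output preserves shape,
#' identifiers and integer type; reference-batch samples are returned
#' exactly unchanged.
#'
#' @param table a [count_table()].
#' @param meta a [sample_metadata()] aligned with the table (shared sample
#'   IDs are intersected otherwise).
#' @param config a [correction_config()].
#' @return corrected [count_table()]; attribute `correction_log` holds
#'   per-taxon notes, and `config`/`ref_batch` record the run.
#' @export
correct_counts <- function(table, meta, config = correction_config()) {
  stopifnot(inherits(table, "count_table"),
            inherits(meta, "sample_metadata"))
  if (!identical(table$sample_ids, meta$sample_ids)) {
    al <- align_samples(table, meta)
    table <- al$table
    meta <- al$meta
  }
  design <- build_design(meta, ref_batch = config$ref_batch,
                         with_libsize = config$mode == "libsize",
                         libsize = table$libsize)
  J <- ncol(table$counts)
  worker <- function(j)
    correct_taxon_impl(table$counts[, j], design, config,
                       taxon_index = taxon_stream_index(table$taxon_ids[j]))
  cols <- if (config$threads > 1L)
    parallel::mclapply(seq_len(J), worker, mc.cores = config$threads)
  else lapply(seq_len(J), worker)
  corrected <- do.call(cbind, lapply(cols, as.integer))
  dimnames(corrected) <- dimnames(table$counts)
  notes <- vapply(cols, function(x) attr(x, "note") %||% "", character(1))
  out <- count_table(corrected)
  attr(out, "correction_log") <-
    data.frame(taxon = table$taxon_ids, note = notes,
               stringsAsFactors = FALSE)
  attr(out, "ref_batch") <- design$ref_batch
  attr(out, "config") <- config
  out
}
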