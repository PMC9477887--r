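# Simulation framework: a zero-inflated over-dispersed starting table
# emulating a vaginal-microbiome genus profile, confounded condition/batch
# assignment, Dirichlet count resampling, and library-size preserving
# fold-change injection for differentially abundant and batch-affected
# taxa.

#' Synthetic starting data
#'
#' A stand-in for a real 16S genus-level starting table: gamma-Poisson
#' (negative-binomial-like) counts whose taxon means follow a fixed
#' geometric profile spanning four orders of magnitude, lognormal library
#' sizes, and extra sampling zeros injected to reach a target overall zero
#' fraction. The taxon mean profile is deterministic, so abundance ranks
#' are stable across seeds. A real table exported to TSV can be used in
#' its place via [read_count_table()].
#'
#' @param n_samples,n_taxa table dimensions (defaults 270 x 233).
#' @param sparsity_target overall zero fraction aimed for (default 0.7,
#'   typical of sparse genus-level 16S tables).
#' @param seed RNG seed.
#' @param mean_libsize median library size of the lognormal depth model.
#' @param dispersion gamma-Poisson overdispersion (gamma shape; smaller =
#'   more overdispersed).
#' @return a [count_table()] with attribute `realized_sparsity`.
#' @export
synth_starting_data <- function(n_samples = 270L, n_taxa = 233L,
                                sparsity_target = 0.7, seed = 1L,
                                mean_libsize = 1e4, dispersion = 0.5) {
  rel <- 10^seq(0, -4, length.out = n_taxa)
  rel <- rel / sum(rel)
  counts <- with_seed(substream_seed(seed, "simulate"), {
    libsize <- rlnorm(n_samples, log(mean_libsize), 0.5)
    mu <- outer(libsize, rel)
    g <- matrix(rgamma(n_samples * n_taxa, shape = dispersion,
                       rate = dispersion), n_samples, n_taxa)
    matrix(rpois(n_samples * n_taxa, mu * g), n_samples, n_taxa)
  })
  f0 <- mean(counts == 0)
  if (f0 < sparsity_target) {
    # inject sampling zeros, preferentially into low counts
    nonzero <- which(counts > 0)
    n_extra <- round((sparsity_target - f0) * length(counts))
    pick <- with_seed(substream_seed(seed, "zeros"),
      sample(nonzero, min(n_extra, length(nonzero)),
             prob = 1 / (1 + counts[nonzero])))
    counts[pick] <- 0L
  }
  rownames(counts) <- paste0("sample", seq_len(n_samples))
  colnames(counts) <- paste0("taxon", seq_len(n_taxa))
  out <- count_table(counts)
  attr(out, "realized_sparsity") <- mean(counts == 0)
  out
}

#' Define a simulation scenario
#'
#' Condition and batch fold changes with confounded assignment: condition
#' and batch are drawn jointly Bernoulli with the given marginals and odds
#' ratio. In the library-size-linked variant the batch probability is
#' `plogis(standardized libsize)`, tying batch membership to sequencing
#' depth.
#'
#' @param condition_fc,batch_fc fold changes (>= 1) injected for the key
#'   variable and the batch.
#' @param odds_ratio condition-batch odds ratio (default 1.25).
#' @param p_condition,p_batch marginal probabilities (default 0.5 each).
#' @param libsize_linked logical; link batch membership to library size.
#' @param n_da number of differentially abundant taxa (default 20).
#' @export
simulation_scenario <- function(condition_fc = 1, batch_fc = 1,
                                odds_ratio = 1.25, p_condition = 0.5,
                                p_batch = 0.5, libsize_linked = FALSE,
                                n_da = 20L) {
  stopifnot(condition_fc >= 1, batch_fc >= 1, odds_ratio > 0,
            p_condition > 0, p_condition < 1, p_batch > 0, p_batch < 1)
  structure(list(condition_fc = condition_fc, batch_fc = batch_fc,
                 odds_ratio = odds_ratio, p_condition = p_condition,
                 p_batch = p_batch, libsize_linked = isTRUE(libsize_linked),
                 n_da = as.integer(n_da)),
            class = "simulation_scenario")
}

#' Preset scenarios
#'
#' `"A"` condition FC 16 / batch FC 1 (null batch effect), `"B"` 64 / 4
#' (condition > batch), `"C"` 4 / 64 (condition < batch); `"D"`, `"E"`,
#' `"F"` repeat them with batch membership linked to library size.
#'
#' @param name scenario letter.
#' @export
scenario_preset <- function(name = c("A", "B", "C", "D", "E", "F")) {
  name <- match.arg(name)
  fc <- switch(name, A = , D = c(16, 1), B = , E = c(64, 4),
               C = , F = c(4, 64))
  simulation_scenario(condition_fc = fc[1L], batch_fc = fc[2L],
                      libsize_linked = name %in% c("D", "E", "F"))
}

# Joint-Bernoulli cell probability P(X=1, Y=1) for given marginals and
# odds ratio (Plackett construction: the root of the cross-product-ratio
# quadratic lying in the Frechet interval).
plackett_p11 <- function(p1, p2, psi) {
  lo <- max(0, p1 + p2 - 1)
  hi <- min(p1, p2)
  if (abs(psi - 1) < 1e-12) {
    p11 <- p1 * p2
  } else {
    s <- 1 + (p1 + p2) * (psi - 1)
    disc <- s^2 - 4 * psi * (psi - 1) * p1 * p2
    if (disc < 0) stop("no joint distribution with these margins and OR")
    p11 <- (s - sqrt(disc)) / (2 * (psi - 1))
  }
  if (p11 < lo - 1e-12 || p11 > hi + 1e-12)
    stop("no joint distribution with these margins and OR")
  min(max(p11, lo), hi)
}

#' Draw confounded condition and batch labels
#'
#' Standard mode: `(condition, batch)` pairs from the joint Bernoulli
#' distribution with the scenario's marginals and odds ratio. Library-size
#' linked mode: each sample's batch probability is
#' `plogis(standardized libsize)`; condition is then drawn given batch so
#' that the marginal condition probability and the condition-batch odds
#' ratio are preserved.
#'
#' @param n number of samples.
#' @param scenario a [simulation_scenario()].
#' @param libsize per-sample library sizes (required when the scenario is
#'   libsize-linked).
#' @param seed RNG seed.
#' @return list with integer 0/1 vectors `condition` and `batch`.
#' @export
draw_condition_batch <- function(n, scenario, libsize = NULL, seed = 1L) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  with_seed(substream_seed(seed, "assign"), {
    if (!scenario$libsize_linked) {
      p11 <- plackett_p11(scenario$p_condition, scenario$p_batch,
                          scenario$odds_ratio)
      probs <- c(p11,
                 scenario$p_condition - p11,
                 scenario$p_batch - p11,
                 1 - scenario$p_condition - scenario$p_batch + p11)
      cell <- sample.int(4L, n, replace = TRUE, prob = probs)
      list(condition = as.integer(cell %in% c(1L, 2L)),
           batch = as.integer(cell %in% c(1L, 3L)))
    } else {
      if (is.null(libsize)) stop("libsize-linked mode requires libsize")
      pb <- plogis(as.numeric(scale(libsize)))
      batch <- rbinom(n, 1L, pb)
      pbar <- mean(pb)
      p11 <- plackett_p11(scenario$p_condition, pbar, scenario$odds_ratio)
      p_c_given_b1 <- p11 / pbar
      p_c_given_b0 <- (scenario$p_condition - p11) / (1 - pbar)
      condition <- rbinom(n, 1L,
                          ifelse(batch == 1L, p_c_given_b1, p_c_given_b0))
      list(condition = condition, batch = batch)
    }
  })
}

#' Select differentially abundant and batch-affected taxa
#'
#' DA taxa sit at evenly spaced abundance ranks from the most to the least
#' abundant taxon, with association direction alternating along the rank
#' order. Batch effects touch the whole profile: every taxon is assigned
#' to an increased or decreased half (random split, sizes differing by at
#' most one).
#'
#' @param starting a [count_table()] whose taxon means define abundance
#'   ranks.
#' @param n_da number of DA taxa.
#' @param seed RNG seed for the batch-direction split.
#' @return list: `da_taxa`, `da_dir` (+1/-1), `batch_taxa` (all taxa),
#'   `batch_dir`.
#' @export
pick_da_taxa <- function(starting, n_da = 20L, seed = 1L) {
  stopifnot(inherits(starting, "count_table"))
  J <- ncol(starting$counts)
  if (n_da > J) stop("n_da exceeds the number of taxa")
  by_abundance <- order(colMeans(starting$counts), decreasing = TRUE)
  ranks <- unique(round(seq(1, J, length.out = n_da)))
  da <- by_abundance[ranks]
  da_dir <- rep_len(c(1L, -1L), length(da))
  up <- with_seed(substream_seed(seed, "split"),
                  sample.int(J, ceiling(J / 2)))
  batch_dir <- rep(-1L, J)
  batch_dir[up] <- 1L
  list(da_taxa = da, da_dir = da_dir, batch_taxa = seq_len(J),
       batch_dir = batch_dir)
}

#' Library-size preserving fold multiplier
#'
#' When decreased taxa are divided by `fc`, the increased taxa are
#' multiplied by `FC' = (S - O - D/fc) / P` (S total, O unaffected sum, D
#' decreased sum, P increased sum) so that the sample's total count is
#' maintained.
#'
#' @param counts_i one sample's count vector (pre-fold).
#' @param increased,decreased taxon index sets.
#' @param fc fold change (>= 1).
#' @export
fc_prime <- function(counts_i, increased, decreased, fc) {
  P <- sum(counts_i[increased])
  if (P == 0) stop("increased set has zero total count")
  D <- sum(counts_i[decreased])
  S <- sum(counts_i)
  O <- S - D - P
  (S - O - D / fc) / P
}

# Apply a fold change in place: decreased / fc, increased * FC'(sample).
.apply_fold <- function(x, increased, decreased, fc) {
  if (fc == 1) return(x)
  if (sum(x[increased]) == 0) {
    x[decreased] <- x[decreased] / fc  # nothing to rescale against
    return(x)
  }
  mult <- fc_prime(x, increased, decreased, fc)
  x[decreased] <- x[decreased] / fc
  x[increased] <- x[increased] * mult
  x
}

#' Simulate a two-batch dataset with injected effects
#'
#' Per sample: relative abundances are drawn from a Dirichlet distribution
#' with parameter `starting counts + 0.5` and scaled by the sample's
#' library size to give initial counts; condition folds are applied to the
#' DA taxa of condition-1 samples (negative taxa divided by the fold,
#' positive taxa multiplied by the library-size preserving `FC'`); batch
#' folds are applied analogously to the batch-affected halves of batch-1
#' samples; counts are rounded half-up to integers.
#'
#' @param starting a [count_table()] (see [synth_starting_data()]).
#' @param scenario a [simulation_scenario()].
#' @param seed RNG seed; sub-streams drive the label draw, taxon split and
#'   Dirichlet resampling.
#' @return class `simulated_dataset`: `table`, `condition`, `batch`,
#'   `da_taxa`, `da_dir`, `batch_taxa`, `batch_dir`, `scenario`.
#' @export
simulate_dataset <- function(starting, scenario = simulation_scenario(),
                             seed = 1L) {
  stopifnot(inherits(starting, "count_table"),
            inherits(scenario, "simulation_scenario"))
  n <- nrow(starting$counts)
  J <- ncol(starting$counts)
  libsize <- starting$libsize
  labels <- draw_condition_batch(n, scenario, libsize = libsize,
                                 seed = seed)
  sets <- pick_da_taxa(starting, scenario$n_da, seed = seed)
  counts <- with_seed(substream_seed(seed, "simulate"), {
    out <- matrix(0, n, J)
    for (i in seq_len(n)) {
      g <- rgamma(J, shape = starting$counts[i, ] + 0.5)
      x <- g / sum(g) * libsize[i]
      if (labels$condition[i] == 1L)
        x <- .apply_fold(x, sets$da_taxa[sets$da_dir > 0],
                         sets$da_taxa[sets$da_dir < 0],
                         scenario$condition_fc)
      if (labels$batch[i] == 1L)
        x <- .apply_fold(x, sets$batch_taxa[sets$batch_dir > 0],
                         sets$batch_taxa[sets$batch_dir < 0],
                         scenario$batch_fc)
      out[i, ] <- x
    }
    out
  })
  counts <- round_half_up(counts)
  dimnames(counts) <- dimnames(starting$counts)
  structure(list(table = count_table(counts),
                 condition = labels$condition, batch = labels$batch,
                 da_taxa = sets$da_taxa, da_dir = sets$da_dir,
                 batch_taxa = sets$batch_taxa, batch_dir = sets$batch_dir,
                 scenario = scenario),
            class = "simulated_dataset")
}

#' Metadata frame of a simulated dataset
#'
#' @param sim a [simulate_dataset()] result.
#' @return a [sample_metadata()] with `batch` as batch column and
#'   `condition` as the key variable.
#' @export
simulated_metadata <- function(sim) {
  stopifnot(inherits(sim, "simulated_dataset"))
  df <- data.frame(condition = sim$condition, batch = sim$batch,
                   row.names = sim$table$sample_ids)
  sample_metadata(df, batch_col = "batch", key_cols = "condition")
}
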