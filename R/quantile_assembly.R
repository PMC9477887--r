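# Assembly of per-sample zero-inflated conditional quantile functions from
# the two fitted parts, on a shared evaluation grid.

#' Invert the jitter on fitted quantiles
#'
#' Maps a jittered-count quantile `q` back to the count scale via
#' `max(ceiling(q) - 1, 0)`. At exact integers `ceiling(q) - 1 = q - 1`,
#' the left-continuity convention for quantile functions.
#'
#' @param w_quantiles numeric vector.
#' @export
dejitter_quantiles <- function(w_quantiles) {
  pmax(ceiling(w_quantiles) - 1, 0)
}

#' Repair quantile crossing by monotone rearrangement
#'
#' Estimated conditional quantiles at neighbouring levels may cross in
#' finite samples; sorting restores a valid (non-decreasing) quantile
#' function while preserving the set of fitted marginal values. Idempotent
#' and a no-op on monotone input.
#'
#' @param values per-level quantile estimates, indexed by increasing tau.
#' @export
monotone_rearrange <- function(values) sort(values)

#' Default evaluation grid for conditional quantile functions
#'
#' The shared percentile grid on which quantile functions are evaluated and
#' matched; finer grids shrink the discretization error of the
#' matching-step.
#'
#' @param size number of grid points (default 199: 0.005 to 0.995).
#' @export
default_eval_grid <- function(size = 199L) seq_len(size) / (size + 1)

# Evaluate a zero-inflated quantile function on a percentile grid.
# zero_mass occupies [0, 1 - pi]; the positive-part fitted grid (pos_tau,
# sorted integer values pos_q) is squeezed into (1 - pi, 1] by linear tau
# rescaling with left-continuous step interpolation.
.cqf_eval <- function(zero_mass, pos_q, pos_tau, at) {
  out <- numeric(length(at))
  up <- at > zero_mass
  if (any(up)) {
    tp <- (at[up] - zero_mass) / (1 - zero_mass)
    idx <- findInterval(tp - 1e-9, pos_tau) + 1L
    idx[idx > length(pos_q)] <- length(pos_q)
    out[up] <- pos_q[idx]
  }
  out
}

#' Assemble a sample's conditional quantile function
#'
#' Combines the presence fit and the positive-part quantile fit into the
#' sample's zero-inflated conditional quantile function: percentiles up to
#' `1 - pi-hat` are zero, and the fitted positive-count quantiles (monotone
#' rearranged, then mapped back to the count scale) are squeezed into the
#' remaining `(1 - pi-hat, 1]` stretch. With `remove_batch = TRUE` the
#' batch contributions are zeroed in both parts, yielding the batch-free
#' function; for a reference-batch sample the two coincide.
#'
#' @param presence_fit a [fit_presence()] result.
#' @param quantile_fit a [fit_positive_quantiles()] result.
#' @param design a [build_design()] result (its rows are the samples to
#'   evaluate; pass a one-row design for a single sample).
#' @param remove_batch logical; zero the batch effects.
#' @param mode `"default"` (counts were jittered) or `"libsize"` (the fit
#'   is on the log relative scale; quantiles are shifted back by the log
#'   library-size offset and exponentiated before de-jittering).
#' @param libsize per-sample library sizes (libsize mode only).
#' @param eval_grid percentile grid from [default_eval_grid()].
#' @param row which design row to assemble (default 1).
#' @return class `cqf`: `zero_mass`, `pos_tau`, `pos_q` (integer counts),
#'   `eval_tau`, `values`.
#' @export
predict_cqf <- function(presence_fit, quantile_fit, design,
                        remove_batch = FALSE,
                        mode = c("default", "libsize"), libsize = NULL,
                        eval_grid = default_eval_grid(), row = 1L) {
  mode <- match.arg(mode)
  pi_hat <- predict_presence(presence_fit, design,
                             remove_batch = remove_batch)[row]
  W <- predict_positive_quantiles(quantile_fit, design,
                                  remove_batch = remove_batch)[row, ]
  w <- monotone_rearrange(as.numeric(W))
  if (mode == "libsize") {
    ls <- libsize %||% design$libsize
    w <- exp(w + log(ls[row]))
  }
  q <- dejitter_quantiles(w)
  zm <- 1 - pi_hat
  structure(list(zero_mass = zm, pos_tau = quantile_fit$tau, pos_q = q,
                 eval_tau = eval_grid,
                 values = .cqf_eval(zm, q, quantile_fit$tau, eval_grid)),
            class = "cqf")
}

#' Evaluate a conditional quantile function at arbitrary percentiles
#'
#' @param cqf a [predict_cqf()] object. @param tau percentiles in (0, 1).
#' @export
eval_cqf <- function(cqf, tau) {
  .cqf_eval(cqf$zero_mass, cqf$pos_q, cqf$pos_tau, tau)
}

#' @export
print.cqf <- function(x, ...) {
  cat("conditional quantile function: zero mass",
      round(x$zero_mass, 3), "| positive quantiles",
      paste(range(x$pos_q), collapse = "-"), "\n")
  invisible(x)
}
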