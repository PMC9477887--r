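# Check-loss minimization. The numerical core is a Frisch-Newton
# primal-dual interior-point solver (src/qrip.cpp) that accepts a
# per-observation quantile level; L1 penalties and composite (shared-slope)
# fits are reduced to that primitive by row augmentation and stacking.

#' Quantile-regression check loss
#'
#' `sum(rho_tau(y - X b))` with `rho_tau(u) = u * (tau - 1(u < 0))`.
#'
#' @param X design matrix, `y` response, `b` coefficients, `tau` quantile
#'   level (scalar or per-observation vector).
#' @export
check_loss <- function(X, y, b, tau) {
  r <- as.numeric(y - X %*% b)
  sum(r * (tau - (r < 0)))
}

# Solve min_b sum_i rho_{tau_i}(y_i - x_i'b). `penalty` is a per-column
# vector of L1 weights (0 = unpenalized); each penalized coefficient j
# contributes lambda_j * |b_j|, implemented as an extra pseudo-observation
# (y = 0, x = 2 lambda_j e_j, tau = 1/2) since rho_{1/2}(-2 lambda b) =
# lambda |b|.
qr_solve <- function(X, y, tau, penalty = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  tau_vec <- if (length(tau) == 1L) rep(tau, n) else as.numeric(tau)
  if (!is.null(penalty) && any(penalty > 0)) {
    jj <- which(penalty > 0)
    aug <- matrix(0, length(jj), ncol(X))
    aug[cbind(seq_along(jj), jj)] <- 2 * penalty[jj]
    X <- rbind(X, aug)
    y <- c(y, rep(0, length(jj)))
    tau_vec <- c(tau_vec, rep(0.5, length(jj)))
  }
  fit <- qr_fit_ip(X, as.numeric(y), tau_vec)
  list(coefficients = as.numeric(fit$coefficients),
       objective = fit$objective, iterations = fit$iterations)
}

# Composite fit over a tau grid: per-tau intercepts, slopes shared across
# all levels. Solved as one pooled check-loss problem on the stacked design
# [I_k (x) 1 | 1_k (x) X[, -1]] with the row-level tau equal to the level
# of its block.
qr_solve_composite <- function(X, y, taus, penalty_slopes = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  k <- length(taus)
  p <- ncol(X)
  ints <- matrix(0, n * k, k)
  for (j in seq_len(k)) ints[(j - 1L) * n + seq_len(n), j] <- 1
  Xs <- cbind(ints, do.call(rbind, rep(list(X[, -1L, drop = FALSE]), k)))
  ys <- rep(as.numeric(y), k)
  tv <- rep(taus, each = n)
  pen <- NULL
  if (!is.null(penalty_slopes) && any(penalty_slopes > 0))
    pen <- c(rep(0, k), penalty_slopes)
  fit <- qr_solve(Xs, ys, tv, penalty = pen)
  b <- fit$coefficients
  slopes <- if (p > 1L) b[k + seq_len(p - 1L)] else numeric(0)
  coefs <- cbind(b[seq_len(k)],
                 matrix(slopes, k, p - 1L, byrow = TRUE))
  colnames(coefs) <- colnames(X)
  list(coefficients = coefs, objective = fit$objective)
}
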