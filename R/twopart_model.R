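# Two-part conditional model for one taxon: logistic presence-absence and
# quantile regression on jittered positive counts over a tau grid.

#' Default quantile-level grid
#'
#' `tau = (1/(k+1), ..., k/(k+1))`. `k = 199` gives the fine default grid
#' 0.005, 0.010, ..., 0.995; `k = 19` is the fast preset (5th to 95th
#' percentiles in steps of 5).
#'
#' @param k number of levels.
#' @export
default_taus <- function(k = 199L) seq_len(k) / (k + 1)

#' Define a fitting strategy for the two-part model
#'
#' @param logistic one of `"standard"` (maximum likelihood), `"lasso"`
#'   (L1-penalized) or `"batch_only"`.
#' @param quantile one of `"standard"`, `"lasso"`, `"composite"`
#'   (per-level intercepts, shared slopes) or `"batch_only"`.
#' @param penalty `"over_n"` for `lambda = 2p/n+` or `"over_log_n"` for
#'   `2p/log(n+)` where `n+` is the number of positive observations
#'   (natural log).
#' @param taus quantile-level grid, strictly increasing in (0, 1).
#' @details `batch_only` drops the key variables and covariates from *both*
#'   parts (simple quantile-quantile matching between batches), so asking
#'   for it in only one part is an error.
#' @export
fit_strategy <- function(logistic = c("standard", "lasso", "batch_only"),
                         quantile = c("standard", "lasso", "composite",
                                      "batch_only"),
                         penalty = c("over_n", "over_log_n"),
                         taus = default_taus()) {
  logistic <- match.arg(logistic)
  quantile <- match.arg(quantile)
  penalty <- match.arg(penalty)
  if (xor(logistic == "batch_only", quantile == "batch_only"))
    stop("batch_only must be used for both model parts")
  taus <- as.numeric(taus)
  if (any(taus <= 0) || any(taus >= 1) || is.unsorted(taus, strictly = TRUE))
    stop("taus must be strictly increasing values in (0, 1)")
  structure(list(logistic = logistic, quantile = quantile,
                 penalty = penalty, taus = taus),
            class = "fit_strategy")
}

#' Preset strategies used by the tuning layer
#'
#' `standard`, `lasso` (penalized quantile part) and `batch_only` (simple
#' quantile-quantile matching). The composite fit is available through
#' [fit_strategy()] but excluded from the default pool because of its cost
#' and strong shared-slope assumption.
#'
#' @param taus quantile grid passed to each preset.
#' @return named list of [fit_strategy()] objects.
#' @export
default_strategies <- function(taus = default_taus()) {
  list(standard = fit_strategy("standard", "standard", taus = taus),
       lasso = fit_strategy("standard", "lasso", taus = taus),
       batch_only = fit_strategy("batch_only", "batch_only", taus = taus))
}

#' Jitter positive counts
#'
#' Adds i.i.d. Uniform(0, 1) noise to positive integer counts so that
#' quantile regression is well defined; inverted on the integers by
#' [dejitter_quantiles()] (ceiling minus one).
#'
#' @param y_pos positive integer counts.
#' @param seed integer; the draw is reproducible given the seed and does
#'   not disturb the caller's RNG stream.
#' @export
jitter_counts <- function(y_pos, seed) {
  if (any(y_pos <= 0)) stop("jitter_counts expects positive counts")
  y_pos + with_seed(seed, runif(length(y_pos)))
}

#' Sparsity-proportional L1 penalty
#'
#' `lambda = 2p/n+` or `2p/log(n+)` (natural log), where `p` is the design
#' width (intercept included) and `n+` the number of positive observations
#' for the taxon.
#'
#' @param p design width. @param n_pos positive-observation count.
#' @param mode `"over_n"` or `"over_log_n"`.
#' @export
penalty_lambda <- function(p, n_pos, mode = c("over_n", "over_log_n")) {
  mode <- match.arg(mode)
  if (n_pos < 2) stop("need at least two positive observations")
  if (mode == "over_n") 2 * p / n_pos else 2 * p / log(n_pos)
}

# Columns of the fitting design actually used by a strategy part.
.design_cols <- function(design, part_mode, libsize_mode = FALSE) {
  X <- design$X
  use <- if (part_mode == "batch_only") c(1L, design$b_idx)
         else seq_len(ncol(X))
  Xu <- X[, use, drop = FALSE]
  b_cols <- match(design$b_idx, use)
  b_cols <- b_cols[!is.na(b_cols)]
  if (libsize_mode) {
    if (is.null(design$libsize_s))
      stop("libsize mode requires a design built with with_libsize = TRUE")
    Xu <- cbind(Xu, libsize_s = design$libsize_s)
  }
  list(X = Xu, b_cols = b_cols, use = use)
}

#' Fit the presence-absence part
#'
#' Logistic regression of the presence indicator on the design, by maximum
#' likelihood, L1-penalized fit, or with batch dummies only. In the
#' library-size preserving mode the standardized library size enters as an
#' additional predictor. Complete (or quasi-complete) separation is
#' detected and the fit falls back to the penalized path with a warning.
#' Fitted probabilities are later truncated to `[1/(4n), 1 - 1/(4n)]` when
#' the conditional distributions are assembled.
#'
#' @param design a [build_design()] result.
#' @param present binary vector, `1` where the taxon count is positive.
#' @param strategy a [fit_strategy()].
#' @param mode `"default"` or `"libsize"`.
#' @return class `presence_fit`: coefficients split into `zeta` (Z block),
#'   `gamma` (batch block) and `psi` (library size, libsize mode), plus the
#'   column bookkeeping needed for prediction; or a degenerate marker when
#'   `present` is constant.
#' @export
fit_presence <- function(design, present, strategy = fit_strategy(),
                         mode = c("default", "libsize")) {
  mode <- match.arg(mode)
  present <- as.numeric(present > 0)
  if (all(present == 1) || all(present == 0))
    return(structure(list(degenerate = TRUE,
                          reason = if (all(present == 1)) "all_present"
                                   else "all_absent"),
                     class = "presence_fit"))
  dc <- .design_cols(design, strategy$logistic, mode == "libsize")
  X <- dc$X
  n <- nrow(X)
  method <- strategy$logistic
  fit_glm <- function()
    tryCatch(suppressWarnings(glm.fit(X, present, family = binomial())),
             error = function(e) NULL)
  coefs <- NULL
  if (method %in% c("standard", "batch_only")) {
    g <- fit_glm()
    sep <- is.null(g) || !g$converged || any(abs(g$coefficients) > 15) ||
      anyNA(g$coefficients)
    if (!sep) coefs <- g$coefficients
    else if (method == "standard") {
      warning("separation in logistic fit; falling back to L1 penalty")
      method <- "lasso"
    } else {
      # batch-only separation: a batch with constant presence. Clamp by
      # refitting with a weak ridge-like L1 on batch dummies.
      coefs <- .logistic_lasso(X, present, dc$b_cols, strategy$penalty,
                               penalize_batch = TRUE)
    }
  }
  if (method == "lasso" && is.null(coefs))
    coefs <- .logistic_lasso(X, present, dc$b_cols, strategy$penalty)
  names(coefs) <- colnames(X)
  psi <- if (mode == "libsize") coefs[length(coefs)] else NULL
  ncoef <- if (mode == "libsize") length(coefs) - 1L else length(coefs)
  b_cols <- dc$b_cols
  z_cols <- setdiff(seq_len(ncoef), b_cols)
  structure(list(degenerate = FALSE, coef = coefs, use = dc$use,
                 b_cols = b_cols, zeta = coefs[z_cols],
                 gamma = coefs[b_cols], psi = psi, n = n,
                 mode = mode, method = method),
            class = "presence_fit")
}

# L1-penalized logistic fit; batch dummies (and intercept) are excluded
# from shrinkage by default so the batch effects being removed stay
# estimable.
.logistic_lasso <- function(X, present, b_cols, penalty_mode,
                            penalize_batch = FALSE) {
  p <- ncol(X)
  if (min(table(present)) < 2) {
    # too few observations in one class for a penalized path; take the
    # (possibly separated) ML fit with clamped coefficients - the fitted
    # probabilities are truncated downstream anyway
    g <- tryCatch(suppressWarnings(glm.fit(X, present,
                                           family = binomial())),
                  error = function(e) NULL)
    cf <- if (is.null(g)) rep(0, p) else g$coefficients
    cf[is.na(cf)] <- 0
    return(pmin(pmax(cf, -15), 15))
  }
  lam <- penalty_lambda(p, length(present), penalty_mode) / length(present)
  x <- X[, -1L, drop = FALSE]
  if (ncol(x) < 2L) {  # glmnet needs >= 2 predictors; pad with a null column
    x <- cbind(x, .pad = 0)
  }
  pf <- rep(1, ncol(x))
  if (!penalize_batch && length(b_cols))
    pf[b_cols - 1L] <- 0
  g <- glmnet::glmnet(x, present, family = "binomial", alpha = 1,
                      lambda = lam, penalty.factor = pf,
                      standardize = FALSE)
  cf <- as.numeric(coef(g, s = lam))
  cf <- cf[seq_len(p)]  # drop padding if added
  cf
}

# Fitted presence probability for given rows, optionally with the batch
# contribution removed, truncated away from 0 and 1.
predict_presence <- function(fit, design, remove_batch = FALSE,
                             libsize_s = NULL) {
  if (fit$degenerate)
    return(rep(if (fit$reason == "all_present") 1 else 0, nrow(design$X)))
  X <- design$X[, fit$use, drop = FALSE]
  cf <- fit$coef
  eta <- if (fit$mode == "libsize") {
    ls <- libsize_s %||% design$libsize_s
    as.numeric(X %*% cf[seq_len(ncol(X))]) + fit$psi * ls
  } else as.numeric(X %*% cf)
  if (remove_batch && length(fit$b_cols))
    eta <- eta - as.numeric(X[, fit$b_cols, drop = FALSE] %*% fit$gamma)
  lo <- 1 / (4 * fit$n)
  pmin(pmax(plogis(eta), lo), 1 - lo)
}

#' Fit the positive-count quantile part
#'
#' Linear quantile regression of the jittered positive counts (or, in the
#' library-size preserving mode, of log jittered counts with log library
#' size subtracted as a fixed offset) on the design, at every level of the
#' tau grid. Strategies: per-level check-loss minimization (`standard`),
#' L1-penalized fit with the sparsity-proportional penalty (`lasso`;
#' intercept and batch dummies unpenalized), per-level intercepts with
#' shared slopes (`composite`), or batch dummies only (`batch_only`). When
#' there are fewer positive rows than design columns the standard fit
#' automatically switches to the penalized one.
#'
#' @param design_pos design restricted to rows with positive counts.
#' @param w jittered positive counts (default mode) or log jittered counts
#'   minus the log library-size offset (libsize mode).
#' @param strategy a [fit_strategy()].
#' @return class `quantile_fit`: `tau`, coefficient matrix `coef`
#'   (`k x p_used`), used-column map and batch-column indices.
#' @export
fit_positive_quantiles <- function(design_pos, w,
                                   strategy = fit_strategy()) {
  dc <- .design_cols(design_pos, strategy$quantile, FALSE)
  X <- dc$X
  n <- nrow(X)
  if (n < 2) stop("need at least two positive observations")
  taus <- strategy$taus
  method <- strategy$quantile
  if (method == "standard" && n < ncol(X)) {
    message("fewer positive rows than design columns; switching to lasso")
    method <- "lasso"
  }
  pen <- NULL
  if (method == "lasso") {
    lam <- penalty_lambda(ncol(X), n, strategy$penalty)
    pen <- rep(lam, ncol(X))
    pen[1L] <- 0
    pen[dc$b_cols] <- 0
  }
  coefs <- if (method == "composite") {
    qr_solve_composite(X, w, taus)$coefficients
  } else {
    t(vapply(taus, function(tt)
      qr_solve(X, w, tt, penalty = pen)$coefficients,
      numeric(ncol(X))))
  }
  colnames(coefs) <- colnames(X)
  structure(list(tau = taus, coef = coefs, use = dc$use,
                 b_cols = dc$b_cols, method = method),
            class = "quantile_fit")
}

# Fitted positive-part quantiles (jittered-count scale, before monotone
# rearrangement) for all rows of a design: an n x k matrix.
predict_positive_quantiles <- function(fit, design, remove_batch = FALSE) {
  X <- design$X[, fit$use, drop = FALSE]
  cf <- fit$coef
  Q <- X %*% t(cf)
  if (remove_batch && length(fit$b_cols)) {
    Xb <- X[, fit$b_cols, drop = FALSE]
    Q <- Q - Xb %*% t(cf[, fit$b_cols, drop = FALSE])
  }
  Q
}
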