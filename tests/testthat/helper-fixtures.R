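# Fixture builders and independent oracles shared across test files.
# Everything is generated in code; no binary fixtures.

# Small two-batch dataset with a known multiplicative batch effect on a
# subset of taxa and a binary key variable.
make_batch_dataset <- function(n = 120, J = 12, batch_mult = 3,
                               affected = seq_len(J %/% 2), seed = 1) {
  withr_seed <- function(s, code) cqbatch:::with_seed(s, code)
  withr_seed(seed, {
    batch <- rep(c(0L, 1L), length.out = n)
    key <- rbinom(n, 1, 0.5)
    mu <- 10^seq(2, 0, length.out = J)
    counts <- sapply(seq_len(J), function(j) {
      m <- mu[j] * (1 + 0.5 * key) *
        ifelse(batch == 1L & j %in% affected, batch_mult, 1)
      rpois(n, m * rgamma(n, 2, 2))
    })
    rownames(counts) <- paste0("s", seq_len(n))
    colnames(counts) <- paste0("t", seq_len(J))
    meta <- sample_metadata(
      data.frame(batch = batch, key = key,
                 row.names = rownames(counts)),
      batch_col = "batch", key_cols = "key")
    list(table = count_table(counts), meta = meta, batch = batch,
         key = key)
  })
}

# Brute-force check-loss oracle: the optimum of a piecewise-linear LP is
# attained at an exact interpolation of p observations; enumerate them.
brute_force_check_loss <- function(X, y, tau) {
  n <- nrow(X)
  p <- ncol(X)
  tv <- if (length(tau) == 1L) rep(tau, n) else tau
  loss <- function(b) {
    r <- y - as.numeric(X %*% b)
    sum(r * (tv - (r < 0)))
  }
  best <- Inf
  for (idx in combn(n, p, simplify = FALSE)) {
    Xs <- X[idx, , drop = FALSE]
    if (abs(det(Xs)) < 1e-9) next
    best <- min(best, loss(solve(Xs, y[idx])))
  }
  best
}

# Step-up BH oracle from the definition: largest k with p_(k) <= k a / m.
bh_reject_oracle <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * alpha / m)
  if (!length(k)) return(integer(0))
  sort(o[seq_len(max(k))])
}

# Hand-rolled zero-inflated quantile function object for matching tests.
make_cqf <- function(values, eval_tau = seq_along(values) / 10,
                     zero_mass = mean(values == 0)) {
  structure(list(zero_mass = zero_mass, pos_tau = eval_tau,
                 pos_q = values[values > 0] %||% integer(0),
                 eval_tau = eval_tau, values = values),
            class = "cqf")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
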