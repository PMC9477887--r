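test_that("synthetic starting data hit the requested shape and sparsity", {
  tab <- synth_starting_data(90, 60, sparsity_target = 0.7, seed = 2)
  expect_equal(dim(tab$counts), c(90, 60))
  expect_gte(attr(tab, "realized_sparsity"), 0.65)
  expect_lte(attr(tab, "realized_sparsity"), 0.75)
  # reproducible
  tab2 <- synth_starting_data(90, 60, sparsity_target = 0.7, seed = 2)
  expect_identical(tab$counts, tab2$counts)
  # taxon abundance ranks stable across seeds
  tab3 <- synth_starting_data(90, 60, sparsity_target = 0.7, seed = 77)
  rho <- cor(colMeans(tab$counts), colMeans(tab3$counts),
             method = "spearman")
  expect_gt(rho, 0.9)
  # different sparsity regime
  sparse <- synth_starting_data(60, 40, sparsity_target = 0.85, seed = 3)
  expect_gt(attr(sparse, "realized_sparsity"), 0.8)
})

test_that("the joint-Bernoulli cell matches the closed form and a
           root-finding oracle", {
  # independence
  expect_equal(cqbatch:::plackett_p11(0.5, 0.5, 1), 0.25)
  # OR = 1.25 with 0.5/0.5 margins: p11 = 0.5 sqrt(1.25)/(1 + sqrt(1.25))
  expect_equal(cqbatch:::plackett_p11(0.5, 0.5, 1.25),
               0.5 * sqrt(1.25) / (1 + sqrt(1.25)), tolerance = 1e-12)
  # numeric oracle across margins and ORs
  for (p1 in c(0.3, 0.5, 0.7)) for (psi in c(0.5, 1.25, 4)) {
    f <- function(x) x * (1 - p1 - 0.5 + x) / ((p1 - x) * (0.5 - x)) - psi
    root <- uniroot(f, c(max(0, p1 - 0.5) + 1e-9, min(p1, 0.5) - 1e-9),
                    tol = 1e-14)$root
    expect_equal(cqbatch:::plackett_p11(p1, 0.5, psi), root,
                 tolerance = 1e-10)
  }
  expect_error(cqbatch:::plackett_p11(0.5, 0.5, -1))
})

test_that("label draws respect the odds ratio and the libsize link", {
  sc <- simulation_scenario(16, 1)
  lab <- draw_condition_batch(10000, sc, seed = 5)
  tabct <- table(lab$condition, lab$batch)
  emp_or <- tabct[2, 2] * tabct[1, 1] / (tabct[2, 1] * tabct[1, 2])
  expect_lt(abs(emp_or - 1.25) / 1.25, 0.10)
  expect_lt(abs(mean(lab$condition) - 0.5), 0.02)

  sc2 <- simulation_scenario(16, 1, libsize_linked = TRUE)
  libsize <- exp(rnorm(10000, 9, 0.5))
  lab2 <- draw_condition_batch(10000, sc2, libsize = libsize, seed = 6)
  qs <- cut(libsize, quantile(libsize, 0:4 / 4), include.lowest = TRUE)
  pb_by_q <- tapply(lab2$batch, qs, mean)
  expect_false(is.unsorted(pb_by_q))  # monotone in depth
  expect_error(draw_condition_batch(10, sc2, seed = 1), "libsize")
})

test_that("DA taxa span the abundance range with alternating directions
           and the batch split is balanced", {
  tab <- synth_starting_data(60, 50, seed = 4)
  sets <- pick_da_taxa(tab, n_da = 10, seed = 4)
  expect_length(sets$da_taxa, 10)
  ranks <- match(sets$da_taxa, order(colMeans(tab$counts),
                                     decreasing = TRUE))
  expect_equal(ranks, sort(ranks))
  expect_lte(max(diff(ranks)), 10)  # roughly evenly spaced
  expect_equal(sets$da_dir, rep_len(c(1L, -1L), 10))
  expect_lte(abs(sum(sets$batch_dir == 1) - sum(sets$batch_dir == -1)), 1)
  expect_error(pick_da_taxa(tab, n_da = 51), "exceeds")
})

test_that("the fold multiplier preserves the sample total", {
  counts <- c(rep(70, 10), rep(10, 10), rep(20, 10))  # S = 1000
  inc <- 21:30
  dec <- 11:20
  m <- fc_prime(counts, inc, dec, fc = 4)
  expect_equal(m, 1.375)
  adjusted <- counts
  adjusted[dec] <- adjusted[dec] / 4
  adjusted[inc] <- adjusted[inc] * m
  expect_equal(sum(adjusted), sum(counts))
  expect_equal(fc_prime(counts, inc, dec, fc = 1), 1)
  expect_error(fc_prime(c(0, 0, 1), 1:2, 3, 2), "zero total")
})

test_that("simulated datasets carry the injected structure", {
  start <- synth_starting_data(150, 60, seed = 10)
  # identity folds: a pure Dirichlet resample keeps the mean profile
  null_sim <- simulate_dataset(start, simulation_scenario(1, 1), seed = 20)
  rel_start <- colMeans(start$counts / pmax(start$libsize, 1))
  rel_sim <- colMeans(null_sim$table$counts /
                        pmax(null_sim$table$libsize, 1))
  expect_gt(cor(rel_start, rel_sim), 0.99)
  # library size maintained within rounding under condition folds only
  cond_sim <- simulate_dataset(start, simulation_scenario(16, 1),
                               seed = 21)
  expect_lt(max(abs(cond_sim$table$libsize - start$libsize)),
            60 * 0.5 + 1)
  # injected DA direction shows in condition-wise means
  big <- simulate_dataset(start, simulation_scenario(64, 4), seed = 22)
  rel <- big$table$counts / pmax(big$table$libsize, 1)
  up <- big$da_taxa[big$da_dir > 0]
  dn <- big$da_taxa[big$da_dir < 0]
  ratio <- function(j) mean(rel[big$condition == 1, j]) /
    max(mean(rel[big$condition == 0, j]), 1e-12)
  # positive taxa rise (capped by the libsize-preserving multiplier),
  # negative taxa are divided by the full fold change
  expect_gt(median(sapply(up, ratio)), 1.3)
  expect_lt(max(sapply(dn, ratio)), 0.1)
  expect_identical(dim(big$table$counts), dim(start$counts))
})
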