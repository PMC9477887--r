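grid9 <- (1:9) / 10
cqf_from_values <- function(v)
  structure(list(zero_mass = mean(v == 0), pos_tau = grid9,
                 pos_q = v[v > 0], eval_tau = grid9, values = v),
            class = "cqf")

test_that("matching transports ties by rounded average and falls back
           left-continuously", {
  q_o <- cqf_from_values(c(0, 0, 0, 0, 1, 1, 2, 3, 5))
  q_c <- cqf_from_values(c(0, 0, 1, 1, 2, 2, 3, 4, 6))
  # y = 1 matches tau 0.5, 0.6 -> mean(2, 2) = 2
  expect_equal(match_and_correct(q_o, q_c, 1), 2L)
  # y = 4 is absent; largest tau with value below is 0.8 -> q_c = 4
  expect_equal(match_and_correct(q_o, q_c, 4), 4L)
  # y = 0 matches tau 0.1..0.4 -> mean(0, 0, 1, 1) = 0.5, half-up -> 1
  expect_equal(match_and_correct(q_o, q_c, 0), 1L)
  expect_error(match_and_correct(q_o, q_c, -1), "non-negative")
})

test_that("identity transport returns every observation unchanged", {
  q <- cqf_from_values(c(0, 0, 0, 1, 1, 2, 3, 5, 9))
  for (y in c(0L, 1L, 2L, 3L, 4L, 5L, 9L, 12L))
    expect_equal(match_and_correct(q, q, y), y)
})

test_that("degenerate taxa pass through unchanged", {
  dat <- make_batch_dataset(n = 40, J = 4, seed = 5)
  design <- build_design(dat$meta, ref_batch = "0")
  cfg <- correction_config(ref_batch = "0",
                           strategy = fit_strategy(taus = (1:9) / 10))
  zero_col <- rep(0L, 40)
  expect_equal(as.integer(correct_taxon(zero_col, design, cfg)), zero_col)
  one_pos <- c(7L, rep(0L, 39))
  expect_equal(as.integer(correct_taxon(one_pos, design, cfg)), one_pos)
})

test_that("correcting a doubled batch pulls its mean to the reference", {
  set.seed(41)
  n <- 500
  batch <- rep(c(0L, 1L), each = n / 2)
  key <- rbinom(n, 1, 0.5)
  base <- rpois(n, 40 + 10 * key)
  y <- ifelse(batch == 1L, rbinom(n, base, 1) + rpois(n, base), base)
  meta <- sample_metadata(data.frame(batch = batch, key = key),
                          "batch", "key")
  design <- build_design(meta, ref_batch = "0")
  gap_before <- abs(mean(y[batch == 1]) / mean(y[batch == 0]) - 1)
  expect_gt(gap_before, 0.7)
  corr <- correct_taxon(y, design,
                        correction_config(ref_batch = "0",
                                          strategy = fit_strategy(
                                            taus = (1:19) / 20)))
  gap_after <- abs(mean(corr[batch == 1]) / mean(corr[batch == 0]) - 1)
  expect_lt(gap_after, 0.15)
  expect_identical(corr[batch == 0L], as.integer(y[batch == 0L]))
})

test_that("table-wide correction preserves shape, IDs, integrality and the
           reference batch", {
  dat <- make_batch_dataset(n = 80, J = 10, batch_mult = 4, seed = 6)
  cfg <- correction_config(ref_batch = "0",
                           strategy = fit_strategy(taus = (1:9) / 10))
  corr <- correct_counts(dat$table, dat$meta, cfg)
  expect_identical(dim(corr$counts), dim(dat$table$counts))
  expect_identical(dimnames(corr$counts), dimnames(dat$table$counts))
  expect_true(all(corr$counts >= 0))
  expect_identical(storage.mode(corr$counts), "integer")
  ref <- dat$batch == 0
  expect_identical(corr$counts[ref, ], dat$table$counts[ref, ])
  expect_false(identical(corr$counts, dat$table$counts))
})

test_that("averaging over jitter replicates stays integer-valued, keeps
           the reference batch, and tracks the single draw", {
  dat <- make_batch_dataset(n = 60, J = 6, batch_mult = 3, seed = 17)
  cfg1 <- correction_config(ref_batch = "0",
                            strategy = fit_strategy(taus = (1:9) / 10))
  cfg3 <- correction_config(ref_batch = "0",
                            strategy = fit_strategy(taus = (1:9) / 10),
                            jitter_reps = 3)
  c1 <- correct_counts(dat$table, dat$meta, cfg1)
  c3 <- correct_counts(dat$table, dat$meta, cfg3)
  expect_identical(storage.mode(c3$counts), "integer")
  ref <- dat$batch == 0
  expect_identical(c3$counts[ref, ], dat$table$counts[ref, ])
  # the averaged correction stays close to the single-draw one
  expect_lt(mean(abs(c3$counts - c1$counts) /
                   pmax(dat$table$counts, 1)), 0.2)
})

test_that("forcing zero batch coefficients reproduces the input exactly", {
  dat <- make_batch_dataset(n = 60, J = 8, batch_mult = 5, seed = 7)
  cfg <- correction_config(ref_batch = "0",
                           strategy = fit_strategy(taus = (1:9) / 10),
                           force_zero_batch = TRUE)
  corr <- correct_counts(dat$table, dat$meta, cfg)
  expect_identical(corr$counts, dat$table$counts)
})

test_that("correction shrinks batch-wise library-size gaps and is nearly
           idempotent in distribution", {
  start <- synth_starting_data(120, 50, seed = 8)
  # libsize-linked batch assignment induces a batch-wise library-size gap
  sim <- simulate_dataset(start,
                          simulation_scenario(4, 16, libsize_linked = TRUE),
                          seed = 88)
  meta <- simulated_metadata(sim)
  cfg <- correction_config(ref_batch = "0",
                           strategy = fit_strategy(taus = (1:19) / 20),
                           jitter_seed = 3)
  corr <- correct_counts(sim$table, meta, cfg)
  ref <- sim$batch == 0
  gap0 <- abs(mean(sim$table$libsize[!ref]) - mean(sim$table$libsize[ref]))
  gap1 <- abs(mean(corr$libsize[!ref]) - mean(corr$libsize[ref]))
  expect_lt(gap1, gap0)
  r2_once <- permanova_r2(bray_curtis_matrix(corr), meta$batch)
  corr2 <- correct_counts(corr, meta, cfg)
  r2_twice <- permanova_r2(bray_curtis_matrix(corr2), meta$batch)
  expect_lt(abs(r2_twice - r2_once), 0.01)
})

test_that("library-size preserving mode keeps depth variability while
           reducing batch structure", {
  start <- synth_starting_data(120, 40, seed = 9)
  sim <- simulate_dataset(start,
                          simulation_scenario(4, 16, libsize_linked = TRUE),
                          seed = 99)
  meta <- simulated_metadata(sim)
  cfg <- correction_config(ref_batch = "0",
                           strategy = fit_strategy(taus = (1:19) / 20),
                           mode = "libsize", jitter_seed = 4)
  corr <- correct_counts(sim$table, meta, cfg)
  expect_identical(dim(corr$counts), dim(sim$table$counts))
  ref <- sim$batch == 0
  expect_identical(corr$counts[ref, ], sim$table$counts[ref, ])
  r2_before <- permanova_r2(bray_curtis_matrix(sim$table), meta$batch)
  r2_after <- permanova_r2(bray_curtis_matrix(corr), meta$batch)
  expect_lt(r2_after, r2_before)
  # library sizes keep spread: corrected depth still correlates with input
  expect_gt(cor(corr$libsize, sim$table$libsize), 0.5)
})
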