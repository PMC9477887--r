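test_that("Bray-Curtis distances follow the min-overlap formula", {
  tab <- count_table(matrix(c(1L, 0L, 2L, 2L, 0L, 4L), 2, 3,
                            dimnames = list(c("a", "b"), NULL)))
  d <- bray_curtis_matrix(tab)
  expect_equal(d["a", "b"], 1 - 2 * 2 / 9)      # (1,2,0) vs (0,2,4)
  expect_equal(diag(d), c(a = 0, b = 0))
  same <- count_table(matrix(c(3L, 3L, 1L, 1L), 2, 2))
  expect_equal(bray_curtis_matrix(same)[1, 2], 0)
  disjoint <- count_table(matrix(c(5L, 0L, 0L, 7L), 2, 2))
  expect_equal(bray_curtis_matrix(disjoint)[1, 2], 1)
})

test_that("Aitchison distance is CLR-Euclidean and scale-free in the
           small-pseudocount limit", {
  tab <- count_table(matrix(c(2L, 4L, 5L, 10L, 1L, 2L), 2, 3))
  # proportional rows: distance vanishes as the pseudocount vanishes
  expect_lt(aitchison_matrix(tab, pseudocount = 1e-9)[1, 2], 1e-6)
  # hand computation on a 3-taxon pair
  x <- c(1, 3, 6) + 0.5
  y <- c(2, 2, 2) + 0.5
  clr <- function(v) log(v / sum(v)) - mean(log(v / sum(v)))
  hand <- sqrt(sum((clr(x) - clr(y))^2))
  tab2 <- count_table(matrix(as.integer(c(1, 2, 3, 2, 6, 2)), 2, 3))
  expect_equal(aitchison_matrix(tab2, 0.5)[1, 2], hand, tolerance = 1e-10)
  # CLR of a uniform composition is the zero vector: distance 0 to itself
  expect_equal(aitchison_matrix(count_table(matrix(c(2L, 2L, 2L, 2L),
                                                   2, 2)))[1, 2], 0)
})

test_that("PERMANOVA R2 reproduces the hand sum-of-squares decomposition
           and the vegan reference", {
  pts <- c(0, 1, 3, 5)
  grp <- factor(c("a", "a", "b", "b"))
  d <- as.matrix(dist(pts))
  expect_equal(permanova_r2(d, grp), 12.25 / 14.75, tolerance = 1e-10)
  # perfectly separated identical points
  d2 <- as.matrix(dist(c(0, 0, 9, 9)))
  expect_equal(permanova_r2(d2, grp), 1)
  expect_error(permanova_r2(d, factor(rep("a", 4))), "single level")
  # independent reference: vegan's adonis2 on a random dataset
  set.seed(51)
  tab <- count_table(matrix(rpois(200, 10), 20, 10))
  g <- factor(rep(c("x", "y"), 10))
  dd <- bray_curtis_matrix(tab)
  ref <- vegan::adonis2(as.dist(dd) ~ g, permutations = 2)$R2[1]
  expect_equal(permanova_r2(dd, g), ref, tolerance = 1e-10)
  # numeric covariate route against adonis2 as well
  z <- rnorm(20)
  refz <- vegan::adonis2(as.dist(dd) ~ z, permutations = 2)$R2[1]
  expect_equal(permanova_r2(dd, z), refz, tolerance = 1e-10)
})

test_that("null PERMANOVA R2 concentrates near (g-1)/(n-1)", {
  set.seed(52)
  n <- 100
  tab <- count_table(matrix(rpois(n * 20, 8), n, 20))
  d <- bray_curtis_matrix(tab)
  r2 <- replicate(60, permanova_r2(d, factor(sample(rep(1:2, n / 2)))))
  expect_lt(abs(mean(r2) - 1 / (n - 1)), 0.005)
})

test_that("BH adjustment and FDR bookkeeping match the hand example", {
  p <- c(0.01, 0.02, 0.2, 0.9)
  expect_equal(p.adjust(p, "BH"),
               c(0.04, 0.04, 4 * 0.2 / 3, 0.9))
  set.seed(53)
  n <- 60
  key <- rbinom(n, 1, 0.5)
  counts <- cbind(rpois(n, 30 * (1 + 3 * key)),
                  rpois(n, 30 * (1 + 3 * key)),
                  matrix(rpois(n * 6, 30), n),
                  0L)  # constant taxon
  tab <- count_table(counts)
  meta <- sample_metadata(data.frame(batch = rep(0:1, n / 2), key = key),
                          "batch", "key")
  res <- association_fdr(tab, meta, key = "key", truth = c(1L, 2L))
  expect_true(all(c(1L, 2L) %in% res$discoveries))
  expect_equal(unname(res$pvalues[9]), 1)  # constant taxon assigned p = 1
  if (setequal(res$discoveries, c(1L, 2L))) {
    expect_equal(res$observed_fdr, 0)
    expect_equal(res$sensitivity, 1)
  }
  # zero discoveries on pure-noise data: FDR defined as 0 / max(0, 1)
  noise <- count_table(matrix(rpois(60 * 8, 30), 60, 8))
  none <- association_fdr(noise, meta, key = "key", alpha = 1e-6,
                          truth = c(1L, 2L))
  expect_length(none$discoveries, 0)
  expect_equal(none$observed_fdr, 0)
})

test_that("random-forest CV separates a determined key and stays at chance
           on permuted labels", {
  set.seed(54)
  n <- 120
  key <- rbinom(n, 1, 0.5)
  driver <- rpois(n, 200 * (1 + 9 * key))
  counts <- cbind(driver, matrix(rpois(n * 9, 50), n))
  colnames(counts) <- NULL
  tab <- count_table(counts)
  meta <- sample_metadata(data.frame(batch = rep(0:1, n / 2), key = key),
                          "batch", "key")
  res <- predict_key_cv(tab, meta, key = "key", seed = 2)
  expect_equal(res$metric, "auc")
  expect_gte(res$value, 0.99)

  meta_perm <- sample_metadata(
    data.frame(batch = rep(0:1, n / 2), key = sample(key)),
    "batch", "key")
  null_res <- predict_key_cv(tab, meta_perm, key = "key", seed = 3)
  expect_lt(abs(null_res$value - 0.5), 0.12)

  # continuous key: signal beats the intercept-only baseline
  meta_num <- sample_metadata(
    data.frame(batch = rep(0:1, n / 2),
               key = as.numeric(scale(driver)) + rnorm(n, sd = 0.4)),
    "batch", "key")
  num_res <- predict_key_cv(tab, meta_num, key = "key", seed = 4)
  expect_equal(num_res$metric, "rmse")
  expect_lt(num_res$value, sd(meta_num$data$key))
})
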