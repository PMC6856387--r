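test_that("Welch t from summaries matches t.test on the raw data", {
  set.seed(55)
  for (i in 1:15) {
    x <- rnorm(sample(3:12, 1), mean = runif(1, -5, 5), sd = runif(1, .5, 3))
    y <- rnorm(sample(3:12, 1), mean = runif(1, -5, 5), sd = runif(1, .5, 3))
    got <- welch_t_from_summary(summarize_group(x), summarize_group(y))
    ref <- t.test(x, y, var.equal = FALSE)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-9)
    expect_equal(got$p, ref$p.value, tolerance = 1e-9)

    pooled <- welch_t_from_summary(summarize_group(x), summarize_group(y),
                                   pooled = TRUE)
    refp <- t.test(x, y, var.equal = TRUE)
    expect_equal(pooled$t, unname(refp$statistic), tolerance = 1e-9)
    expect_equal(pooled$p, refp$p.value, tolerance = 1e-9)
  }
})

test_that("Welch t handles identical and degenerate groups", {
  g <- group_summary(5, 1, 4)
  same <- welch_t_from_summary(g, g)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  z1 <- group_summary(5, 0, 4); z2 <- group_summary(6, 0, 4)
  expect_equal(welch_t_from_summary(z1, z1)$p, 1)
  expect_equal(welch_t_from_summary(z1, z2)$p, 0)
})

test_that("Welch t agrees with a permutation test on small raw groups", {
  set.seed(77)
  x <- rnorm(6, 1.2, 1); y <- rnorm(5, 0, 1)
  obs <- abs(welch_t_from_summary(summarize_group(x), summarize_group(y))$t)
  pool <- c(x, y)
  perm_t <- replicate(4000, {
    idx <- sample(length(pool), length(x))
    a <- pool[idx]; b <- pool[-idx]
    abs((mean(a) - mean(b)) /
          sqrt(var(a) / length(a) + var(b) / length(b)))
  })
  p_perm <- mean(perm_t >= obs)
  p_t <- welch_t_from_summary(summarize_group(x), summarize_group(y))$p
  expect_lt(abs(p_perm - p_t), 0.06)
})

test_that("one-sample t from summaries matches t.test on raw data", {
  set.seed(66)
  for (i in 1:10) {
    x <- rnorm(sample(4:15, 1), mean = 2)
    mu0 <- runif(1, -1, 4)
    got <- one_sample_t_from_summary(summarize_group(x), mu0)
    ref <- t.test(x, mu = mu0)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(got$df, unname(ref$parameter))
    expect_equal(got$p, ref$p.value, tolerance = 1e-9)
  }
  expect_equal(one_sample_t_from_summary(group_summary(3, 1, 5), 3)$p, 1)
  # sign symmetry
  g <- group_summary(10, 2, 6)
  expect_equal(one_sample_t_from_summary(g, 12)$p,
               one_sample_t_from_summary(g, 8)$p)
})

test_that("Pearson correlation matches cor.test and handles exact lines", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  set.seed(88)
  for (i in 1:10) {
    a <- rnorm(sample(4:20, 1)); b <- rnorm(length(a)) + 0.5 * a
    got <- pearson_r(a, b)
    ref <- cor.test(a, b)
    expect_equal(got$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("a correlation of 0.90 over 6 samples is significant below 0.015", {
  # construct a 6-point data set with r = 0.90 exactly
  x <- c(-1.290994, -0.774597, -0.258199, 0.258199, 0.774597, 1.290994)
  e <- c(1, -1, 1, -1, 1, -1)
  e <- resid(lm(e ~ x)); e <- e / sqrt(sum(e^2))
  xs <- (x - mean(x)) / sqrt(sum((x - mean(x))^2))
  y <- 0.90 * xs + sqrt(1 - 0.81) * e
  got <- pearson_r(x, y)
  expect_equal(got$r, 0.90, tolerance = 1e-6)
  # frozen from 2 * pt(-0.9 * sqrt(4 / 0.19), df = 4)
  expect_equal(got$p, 0.014500, tolerance = 1e-4)
  expect_lt(got$p, 0.015)
})

test_that("paired bootstrap is deterministic and bounded as expected", {
  set.seed(3)
  before <- rnorm(30, 10, 1)
  after <- before + abs(rnorm(30, 2, 0.5))  # all differences positive
  p <- paired_bootstrap_increase(before, after, B = 10000L, seed = 9L)
  expect_lte(p, 0.005)
  expect_identical(p, paired_bootstrap_increase(before, after, B = 10000L,
                                                seed = 9L))
  expect_equal(paired_bootstrap_increase(before, before, B = 2000L, seed = 1L),
               1, tolerance = 1e-3)
  expect_error(paired_bootstrap_increase(numeric(0), numeric(0)), "pair")
})

test_that("bootstrap p converges to the exhaustive enumeration at n = 3", {
  d <- c(-1, 0.4, 2.5)
  # all 27 equally likely resamples of the 3 differences
  grid <- expand.grid(1:3, 1:3, 1:3)
  exact <- mean(apply(grid, 1, function(ix) mean(d[ix]) <= 0))
  B <- 40000L
  p <- paired_bootstrap_increase(rep(0, 3), d, B = B, seed = 5L)
  expected <- (1 + B * exact) / (B + 1)
  mc_sd <- sqrt(exact * (1 - exact) / B)
  expect_lt(abs(p - expected), 5 * mc_sd)
})

test_that("the Hellinger transform yields unit-norm square-rooted abundances", {
  expect_equal(hellinger(c(1, 1, 1, 1)), rep(0.5, 4))
  expect_equal(hellinger(c(9, 16)), c(0.6, 0.8))
  set.seed(10)
  for (i in 1:10) {
    v <- rgamma(sample(2:30, 1), 1)
    h <- hellinger(v)
    expect_equal(sum(h^2), 1, tolerance = 1e-12)
  }
  expect_error(hellinger(c(0, 0)), "all-zero")
  expect_error(hellinger(c(-1, 2)), "nonnegative")
})

test_that("Hellinger agrees with vegan::decostand", {
  skip_if_not_installed("vegan")
  set.seed(12)
  m <- matrix(rpois(40, 20), nrow = 4)
  ref <- as.matrix(vegan::decostand(m, "hellinger"))
  got <- t(apply(m, 1, hellinger))
  expect_equal(got, ref, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("PCA explains collinear data with one component and reconstructs exactly", {
  line <- cbind(1:10, 2 * (1:10) + 3)
  fit <- pca_decompose(line)
  expect_equal(fit$explained_variance_ratios[1], 1.0)

  set.seed(14)
  m <- matrix(rnorm(60), nrow = 10)
  fit <- pca_decompose(m)
  recon <- fit$scores %*% t(fit$components)
  centered <- sweep(m, 2, colMeans(m))
  expect_equal(recon, centered, ignore_attr = TRUE, tolerance = 1e-9)
  expect_true(all(diff(fit$explained_variance_ratios) <= 1e-12))
  expect_lte(sum(fit$explained_variance_ratios), 1 + 1e-9)
  # sign convention: the largest loading of each component is positive
  expect_true(all(apply(fit$components, 2,
                        function(v) v[which.max(abs(v))] > 0)))
  expect_error(pca_decompose(matrix(1:3, nrow = 1)), "2 samples")
})

test_that("an isotropic 2-D Gaussian splits variance evenly", {
  set.seed(99)
  m <- matrix(rnorm(2e4), ncol = 2)
  r <- pca_decompose(m)$explained_variance_ratios
  expect_equal(r[1], 0.5, tolerance = 0.02)
  expect_equal(r[2], 0.5, tolerance = 0.02)
})

test_that("consensus selection requires both models in at least half the rarefactions", {
  rec <- function(rid, model, feats)
    data.frame(rarefaction_id = rid, model_id = model, feature = feats,
               stringsAsFactors = FALSE)
  records <- do.call(rbind, c(
    lapply(1:10, function(r) rec(r, "SVC", c("always", "svconly"))),
    lapply(1:10, function(r) rec(r, "LR", "always")),
    lapply(1:5, function(r) rec(r, "SVC", "boundary")),
    lapply(1:5, function(r) rec(r, "LR", "boundary")),
    lapply(1:4, function(r) rec(r, "SVC", "below")),
    lapply(1:4, function(r) rec(r, "LR", "below"))
  ))
  sel <- consensus_select(records, n_rarefactions = 10)
  expect_true("always" %in% sel)       # both models, all rarefactions
  expect_false("svconly" %in% sel)     # one model only
  expect_true("boundary" %in% sel)     # exactly half: inclusive
  expect_false("below" %in% sel)       # 4 of 10

  expect_error(consensus_select(rbind(records, rec(1, "RF", "x")), 10),
               "unknown model tags")

  # monotone: new records never remove a selected feature
  more <- rbind(records, rec(6, "SVC", "below"), rec(6, "LR", "below"))
  expect_true(all(sel %in% consensus_select(more, 10)))
})
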