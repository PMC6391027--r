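test_that("thresholds are inverse-normal cumulative proportions", {
  x <- rep(1:3, times = c(50, 30, 20))
  expect_equal(estimate_thresholds(x),
               stats::qnorm(c(0.5, 0.8)), tolerance = 1e-12)
  expect_equal(estimate_thresholds(x)[1], 0)
  x2 <- rep(1:3, times = c(40, 40, 40))
  expect_equal(estimate_thresholds(x2),
               c(-1, 1) * stats::qnorm(2 / 3), tolerance = 1e-12)
  expect_equal(round(estimate_thresholds(x2), 4), c(-0.4307, 0.4307))
  expect_error(estimate_thresholds(rep(3, 100), item = "foo"),
               "degenerate margin for foo")
})

test_that("polychoric estimate equals a brute-force grid search of the likelihood", {
  tab <- matrix(c(20, 10, 5, 10, 20, 10, 5, 10, 20), 3, 3, byrow = TRUE)
  x <- rep(rep(1:3, each = 3), times = as.vector(t(tab)))
  y <- rep(rep(1:3, times = 3), times = as.vector(t(tab)))
  est <- pairwise_correlation(x, y)
  # oracle: dense grid over the correlation at step 1e-4
  tau_x <- estimate_thresholds(x)
  tau_y <- estimate_thresholds(y)
  txy <- table(factor(x, 1:3), factor(y, 1:3))
  grid <- seq(-0.999, 0.999, by = 1e-4)
  ll <- vapply(grid, function(r)
    sum(txy * log(pmax(dualfactor:::bvn_cell_probs(tau_x, tau_y, r),
                       1e-300))), 0)
  expect_lt(abs(est$rho - grid[which.max(ll)]), 1e-3)
})

test_that("identical discretisations of one latent draw hit the boundary", {
  set.seed(3)
  z <- stats::rnorm(2000)
  x <- findInterval(z, stats::qnorm(c(.55, .9))) + 1L
  expect_warning(est <- pairwise_correlation(x, x), "boundary")
  expect_gte(est$rho, 0.99)
  expect_true(est$boundary)
})

test_that("polychoric estimation is consistent across the correlation range", {
  for (rho in c(-0.6, 0, 0.3, 0.8)) {
    est <- vapply(1:20, function(s) {
      d <- simulate_polychoric_pair(5000, rho, seed = 100 * rho + s)
      pairwise_correlation(d$x, d$y)$rho
    }, 0)
    expect_lt(abs(mean(est) - rho), 0.02)
  }
})

test_that("pairwise correlations are symmetric in their arguments", {
  d <- simulate_mh(mixed4_config(n = 800), seed = 4)
  expect_equal(pairwise_correlation(d$o1, d$o2)$rho,
               pairwise_correlation(d$o2, d$o1)$rho)
  expect_equal(
    pairwise_correlation(d$o1, d$c1, "ordinal", "continuous")$rho,
    pairwise_correlation(d$c1, d$o1, "continuous", "ordinal")$rho)
})

test_that("the continuous-continuous path is the textbook Pearson correlation", {
  d <- simulate_mh(mixed4_config(n = 500), seed = 8)
  est <- pairwise_correlation(d$c1, d$c2, "continuous", "continuous")
  expect_equal(est$rho,
               stats::cor(d$c1, d$c2, use = "pairwise.complete.obs"),
               tolerance = 1e-12)
})

test_that("too few pairwise-complete observations fail loudly", {
  x <- c(1:3, rep(NA, 20)); y <- c(rep(NA, 20), 1:3)
  expect_error(pairwise_correlation(x, y), "pairwise-complete")
})

test_that("the full matrix is symmetric with unit diagonal and PSD Gamma", {
  d <- simulate_mh(mixed4_config(n = 1500), seed = 12)
  mm <- mixed_moments(d)
  expect_equal(mm$R, t(mm$R))
  expect_equal(diag(mm$R), rep(1, 4), ignore_attr = TRUE)
  expect_true(all(abs(mm$R) <= 1))
  ev <- eigen(mm$gamma, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
  expect_equal(mm$gamma, t(mm$gamma))
})

test_that("influence-function Gamma agrees with a bootstrap oracle", {
  d <- simulate_mh(mixed4_config(n = 2000), seed = 9)
  mi <- mixed_moments(d, gamma = "influence")
  mb <- mixed_moments(d, gamma = "bootstrap", boot_reps = 500, boot_seed = 5)
  ratio <- diag(mi$gamma) / diag(mb$gamma)
  expect_true(all(abs(ratio - 1) < 0.25))
})

test_that("statistic covariances shrink as 1/n", {
  cfg <- mixed4_config
  g1 <- mixed_moments(simulate_mh(cfg(2000), seed = 9))$gamma
  g2 <- mixed_moments(simulate_mh(cfg(8000), seed = 10))$gamma
  # cov(s) = Gamma / n, so the n = 8000 diagonal should be ~ a quarter of
  # the n = 2000 one
  ratio <- (diag(g2) / 8000) / (diag(g1) / 2000)
  expect_true(all(ratio > 0.25 * 0.7 & ratio < 0.25 * 1.3))
})

test_that("mislabelled scale types are rejected with the item named", {
  d <- simulate_mh(default_mh_config(n = 300), seed = 2)
  info <- item_info(d)
  info$type[info$name == "int1"] <- "continuous"
  expect_error(mixed_moments(d, info), "int1.*mislabelled")
  info <- item_info(d)
  info$type[info$name == "wb1"] <- "ordinal"
  expect_error(mixed_moments(d, info), "wb1")
})

test_that("Cronbach's alpha matches closed forms", {
  S <- matrix(c(1, .5, .5, 1), 2)
  X <- MASS::mvrnorm(200, c(0, 0), S, empirical = TRUE)
  d <- data.frame(a = X[, 1], b = X[, 2])
  rel <- scale_reliability(d, c("a", "b"))
  expect_equal(rel$alpha, 2 * (1 - 2 / 3), tolerance = 1e-10)
  # uncorrelated items: alpha 0
  X0 <- MASS::mvrnorm(200, c(0, 0, 0), diag(3), empirical = TRUE)
  d0 <- data.frame(a = X0[, 1], b = X0[, 2], c = X0[, 3])
  expect_equal(scale_reliability(d0, c("a", "b", "c"))$alpha, 0,
               tolerance = 1e-10)
  # perfectly correlated items: alpha 1
  dp <- data.frame(a = X[, 1], b = X[, 1], c = X[, 1])
  expect_equal(scale_reliability(dp, c("a", "b", "c"))$alpha, 1,
               tolerance = 1e-10)
  expect_error(scale_reliability(dp, "a"), "two items")
  dz <- data.frame(a = rep(1, 50), b = rep(1, 50))
  expect_error(scale_reliability(dz, c("a", "b")), "variance")
})

test_that("item-total correlations use the rest-of-scale sum", {
  d <- simulate_mh(default_mh_config(n = 2000), seed = 6)
  rel <- scale_reliability(d, paste0("int", 1:9))
  X <- stats::na.omit(as.matrix(d[paste0("int", 1:9)]))
  expect_equal(unname(rel$item_total["int1"]),
               stats::cor(X[, 1], rowSums(X[, -1])), tolerance = 1e-12)
  expect_true(all(abs(rel$item_total) <= 1))
  expect_lte(rel$alpha, 1)
})

test_that("intraclass correlation recovers designed variance shares", {
  # constant within clusters, different between: ICC = 1
  v <- rep(1:10, each = 5)
  expect_equal(intraclass_correlation(v + 0.0, rep(1:10, each = 5)), 1)
  # random labels: ICC ~ 0
  set.seed(2)
  expect_lt(intraclass_correlation(stats::rnorm(20000),
                                   sample(1:50, 20000, TRUE)), 0.01)
  # between-variance .05, within .95 (enough clusters that the cluster
  # draw itself does not dominate the error)
  set.seed(3)
  cl <- sample(1:500, 20000, TRUE)
  b <- stats::rnorm(500, 0, sqrt(0.05))
  y <- b[cl] + stats::rnorm(20000, 0, sqrt(0.95))
  expect_lt(abs(intraclass_correlation(y, cl) - 0.05), 0.01)
  expect_error(intraclass_correlation(stats::rnorm(10), rep(1, 10)),
               "two clusters")
})
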