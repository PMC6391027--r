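test_that("identical groups yield full invariance and matching configural estimates", {
  cfg <- toy_config(n = 1200)
  d <- simulate_mh(cfg, seed = 31)
  # duplicated rows as the two "groups": configural estimates must agree
  d2 <- rbind(d, d)
  d2$gender <- rep(0:1, each = nrow(d))
  attr(d2, "items") <- cfg$items
  spec <- cfa_model("correlated", cfg$items)
  inv <- invariance_sequence(spec, d2, "gender")
  expect_equal(inv$verdict, "full")
  pt <- inv$configural$ptab
  for (ty in c("lambda", "tau", "phi")) {
    g1 <- pt$value[pt$group == 1 & pt$type == ty]
    g2 <- pt$value[pt$group == 2 & pt$type == ty]
    expect_equal(g1, g2, tolerance = 1e-5)
  }
  # configural df is the sum of the single-group dfs
  expect_equal(inv$configural$df,
               inv$baseline[[1]]$df + inv$baseline[[2]]$df)
  # scalar nested in configural with nonnegative difference
  expect_gt(inv$scalar$df, inv$configural$df)
  expect_gte(inv$test$stat, 0)
})

test_that("a planted threshold shift is detected and the right item freed", {
  cfg <- toy_config(n = 2000)
  spec <- cfa_model("correlated", cfg$items)
  hits <- 0
  for (r in 1:10) {
    d1 <- simulate_mh(cfg, seed = 300 + r)
    cfg2 <- cfg
    cfg2$thresholds["y3", ] <- cfg2$thresholds["y3", ] + 0.5
    d2 <- simulate_mh(cfg2, seed = 600 + r)
    d1$gender <- 0; d2$gender <- 1
    d <- rbind(d1, d2)
    attr(d, "items") <- cfg$items
    inv <- invariance_sequence(spec, d, "gender")
    if (inv$verdict == "partial" && identical(inv$freed, "y3"))
      hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("group handling validates its inputs", {
  cfg <- toy_config(n = 400)
  d <- simulate_mh(cfg, seed = 2)
  spec <- cfa_model("correlated", cfg$items)
  expect_error(invariance_sequence(spec, d, "nosuch"), "not found")
  d$three <- sample(0:2, nrow(d), TRUE)
  expect_error(invariance_sequence(spec, d, "three"), "binary")
  expect_error(invariance_sequence(spec, d, "gender", min_group_n = 5000),
               "fewer than")
})

test_that("the negative residual-variance policy fixes, passes through or fails", {
  cfg <- mixed4_config(n = 1500)
  d <- simulate_mh(cfg, seed = 44)
  spec <- cfa_model("correlated", cfg$items)   # mixed items: DWLS path
  fit <- dwls_fit(spec, data = d)
  # no negative variances: unchanged passthrough
  expect_identical(fix_negative_residual(fit), fit)
  # non-significant negative estimate: refit with the variance pinned at 0
  fit_neg <- fit
  fit_neg$negative_resid <- data.frame(item = "c1", group = 1,
                                       value = -0.14, se = 0.7, p = 0.84)
  fixed <- fix_negative_residual(fit_neg)
  pt <- fixed$ptab
  row <- pt[pt$type == "psi" & pt$item == "c1", ]
  expect_false(row$free)
  expect_equal(row$value, 0)
  fixes <- attr(fixed, "applied_fixes")
  expect_equal(fixes[[1]]$item, "c1")
  expect_equal(fixes[[1]]$fixed, 0)
  # significant negative estimate: loud failure
  fit_sig <- fit
  fit_sig$negative_resid <- data.frame(item = "c1", group = 1,
                                       value = -0.3, se = 0.05, p = 0.001)
  expect_error(fix_negative_residual(fit_sig), "misspecification")
})

test_that("covariate associations recover null and planted effects", {
  # null: all coefficients near zero
  cfg0 <- toy_config(n = 2000)
  spec <- cfa_model("correlated", cfg0$items)
  est <- sapply(1:10, function(s) {
    d <- simulate_mh(cfg0, seed = 50 + s)
    covariate_association(spec, d, "gender")$estimate
  })
  expect_lt(max(abs(rowMeans(est))), 0.05)
  # planted: gender shifts factor b by -.6 SD
  cfg1 <- toy_config(n = 2000,
                     effects = list(gender = c(a = 0, b = -0.6),
                                    income = c(a = 0, b = 0)))
  est1 <- sapply(1:3, function(s) {
    d <- simulate_mh(cfg1, seed = 80 + s)
    ca <- covariate_association(spec, d, "gender")
    ca$estimate[ca$factor == "b"]
  })
  expect_lt(abs(mean(est1) - (-0.6)), 0.1)
  # constant covariates are rejected
  d <- simulate_mh(cfg0, seed = 1)
  d$gender <- 1
  expect_error(covariate_association(spec, d, "gender"), "constant")
})
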