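test_that("fitting the generating model to exact population moments is a zero-residual fixed point", {
  cfg <- default_mh_config()
  spec <- cfa_model("correlated", cfg$items, cfg$resid_pairs[c("a", "b")])
  vals <- dualfactor:::config_values(cfg)
  im <- model_implied_moments(spec, vals)
  mm0 <- moments_from_blocks(cfg$items, im$thresholds, im$means, im$vars,
                             im$R, n = 1982)
  fit <- dwls_fit(spec, moments = mm0)
  expect_lt(fit$Fmin, 1e-8)
  expect_equal(fit$chisq, 0)
  Phi <- factor_correlations(fit)
  expect_equal(Phi["internalising", "externalising"], 0.58, tolerance = 1e-4)
  expect_equal(Phi["internalising", "wellbeing"], -0.58, tolerance = 1e-4)
  L <- standardized_loadings(fit)
  expect_lt(max(abs(L[cfg$lambda != 0] - cfg$lambda[cfg$lambda != 0])), 1e-4)
})

test_that("a just-identified model has zero chi-square", {
  cfg <- toy_config(n = 1500, domains = rep("a", 3))
  d <- simulate_mh(cfg, seed = 17)
  fit <- dwls_fit(cfa_model("correlated", cfg$items), data = d)
  expect_equal(fit$df, 0)
  expect_lt(fit$Fmin, 1e-9)
  expect_equal(fit$chisq, 0)
})

test_that("loadings are recovered from simulated data", {
  cfg <- default_mh_config()
  spec <- cfa_model("correlated", cfg$items, cfg$resid_pairs[c("a", "b")])
  maes <- vapply(1:2, function(s) {
    d <- simulate_mh(cfg, seed = s)
    fit <- dwls_fit(spec, data = d)
    L <- standardized_loadings(fit)
    mean(abs(L[cfg$lambda != 0] - cfg$lambda[cfg$lambda != 0]))
  }, 0)
  expect_lt(mean(maes), 0.05)
})

test_that("the fit is invariant to item ordering", {
  cfg <- toy_config(n = 1200)
  d <- simulate_mh(cfg, seed = 19)
  info <- item_info(d)
  fit1 <- dwls_fit(cfa_model("correlated", info), data = d)
  perm <- c(4, 1, 6, 2, 5, 3)
  info2 <- info[perm, ]
  fit2 <- dwls_fit(cfa_model("correlated", info2),
                   moments = mixed_moments(d, info2))
  expect_equal(fit1$chisq, fit2$chisq, tolerance = 1e-4)
  expect_equal(fit1$df, fit2$df)
  expect_equal(fit1$fit_indices$rmsea, fit2$fit_indices$rmsea,
               tolerance = 1e-5)
})

test_that("fit indices match hand-computed closed forms", {
  cases <- list(
    #      chi2  df  chi2_b df_b  n     rmsea      cfi        tli
    list(c(100, 50, 500, 60, 500), c(0.0447661, 0.8863636, 0.8636364)),
    list(c(50, 50, 200, 40, 300), c(0, 1, 1)),
    list(c(30, 40, 100, 45, 150), c(0, 1, 1.2045455)),
    list(c(600, 100, 650, 120, 1000), c(0.0707461, 0.0566038, -0.1320755)),
    list(c(82.5, 60, 900, 66, 750), c(0.0223756, 0.9730216, 0.9703237)))
  for (cs in cases) {
    v <- cs[[1]]
    fi <- fit_indices(v[1], v[2], v[3], v[4], v[5])
    expect_equal(c(fi$rmsea, fi$cfi, fi$tli), cs[[2]], tolerance = 1e-6)
  }
  # chi2 = df: perfect fit
  fi <- fit_indices(60, 60, 300, 45, 400)
  expect_equal(fi$rmsea, 0)
  expect_equal(fi$cfi, 1)
  # RMSEA confidence bounds invert the noncentral chi-square distribution
  fi <- fit_indices(410.931, 145, 5000, 171, 1982)
  ncp_lo <- fi$rmsea_ci[1]^2 * 145 * 1981
  ncp_hi <- fi$rmsea_ci[2]^2 * 145 * 1981
  expect_equal(stats::pchisq(410.931, 145, ncp = ncp_lo), 0.95,
               tolerance = 1e-6)
  expect_equal(stats::pchisq(410.931, 145, ncp = ncp_hi), 0.05,
               tolerance = 1e-6)
})

test_that("modification indices are nonnegative and calibrated under the null", {
  cfg <- toy_config(n = 2000)
  spec <- cfa_model("correlated", cfg$items)
  all_mi <- unlist(lapply(1:10, function(s) {
    d <- simulate_mh(cfg, seed = 40 + s)
    fit <- dwls_fit(spec, data = d)
    modification_indices(fit)$mi
  }))
  expect_true(all(all_mi >= 0))
  # pooled across seeds and candidates the indices should look like
  # chi-square(1) draws: no gross anticonservativeness at the .99 quantile
  # and a median near the chi-square(1) median (.455)
  rate <- mean(all_mi > stats::qchisq(0.99, 1))
  expect_lt(rate, 0.035)
  expect_gt(stats::median(all_mi), 0.1)
  expect_lt(stats::median(all_mi), 1.5)
})

test_that("a scaled difference test of a model against itself is zero", {
  cfg <- toy_config(n = 800)
  d <- simulate_mh(cfg, seed = 3)
  fit <- dwls_fit(cfa_model("correlated", cfg$items), data = d)
  dt <- scaled_difference(fit, fit)
  expect_equal(dt$stat, 0)
  expect_equal(dt$df, 0L)
})

test_that("the scaled difference test holds its size under the null", {
  cfg <- toy_config(n = 1000, domains = rep("a", 6))
  spec0 <- cfa_model("correlated", cfg$items)
  spec1 <- cfa_model("correlated", cfg$items,
                     data.frame(a = "y1", b = "y2"))
  rej <- 0
  for (r in 1:200) {
    d <- simulate_mh(cfg, seed = 10000 + r)
    mm <- mixed_moments(d)
    dt <- scaled_difference(dwls_fit(spec0, moments = mm),
                            dwls_fit(spec1, moments = mm))
    if (!is.na(dt$p) && dt$p < 0.05) rej <- rej + 1
  }
  expect_gte(rej / 200, 0.01)
  expect_lte(rej / 200, 0.10)
})

test_that("restricted models must have larger df", {
  cfg <- toy_config(n = 800)
  d <- simulate_mh(cfg, seed = 3)
  mm <- mixed_moments(d)
  f0 <- dwls_fit(cfa_model("correlated", cfg$items), moments = mm)
  f1 <- dwls_fit(cfa_model("correlated", cfg$items,
                           data.frame(a = "y1", b = "y2")), moments = mm)
  expect_error(scaled_difference(f1, f0), "larger df")
  dt <- scaled_difference(f0, f1)
  expect_equal(dt$df, 1L)
  expect_gte(dt$stat, 0)
})

test_that("the continuous-only path fits by normal-theory ML with the stated df", {
  cfg <- default_mh_config(n = 2000)
  d <- simulate_mh(cfg, seed = 23)
  info <- item_info(d)
  wb <- info[info$domain == "wellbeing", ]
  fit0 <- dwls_fit(cfa_model("instrument", wb), data = d)
  expect_equal(fit0$method, "ml")
  expect_equal(fit0$df, 2L)
  fit1 <- dwls_fit(cfa_model("instrument", wb,
                             data.frame(a = "wb1", b = "wb3")), data = d)
  expect_equal(fit1$df, 1L)
  # the generating residual pair improves fit and is recovered positive
  expect_lt(fit1$chisq, fit0$chisq)
  expect_gt(unname(stats::coef(fit1)["rcov.wb1.wb3"]), 0)
  # standardised loadings live in the correlation metric
  L <- standardized_loadings(fit1)
  expect_true(all(abs(L) <= 1))
})
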