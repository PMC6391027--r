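test_that("the default configuration encodes the study design", {
  cfg <- default_mh_config()
  expect_equal(as.integer(table(cfg$items$domain)[
    c("internalising", "externalising", "wellbeing")]), c(9, 6, 4))
  expect_equal(sum(cfg$items$type == "ordinal"), 15)
  expect_equal(cfg$phi["internalising", "externalising"], 0.58)
  expect_equal(cfg$phi["internalising", "wellbeing"], -0.58)
  expect_equal(cfg$phi["externalising", "wellbeing"], -0.42)
  lams <- cfg$lambda[cfg$lambda != 0]
  expect_true(all(lams >= 0.43 & lams <= 0.80))
  wb_pair <- cfg$resid_pairs[cfg$resid_pairs$a == "wb1", ]
  expect_equal(wb_pair$b, "wb3")
  expect_equal(wb_pair$value, 0.26)
  expect_true(all(cfg$missing >= 0.006 & cfg$missing <= 0.026))
  # floor-effect thresholds: first category is the modal one for symptoms
  expect_true(all(stats::pnorm(cfg$thresholds[
    setdiff(rownames(cfg$thresholds), "ext6"), 1]) > 0.5))
})

test_that("generation is reproducible and seed-sensitive", {
  cfg <- default_mh_config(n = 300)
  d1 <- simulate_mh(cfg, seed = 7)
  d2 <- simulate_mh(cfg, seed = 7)
  d3 <- simulate_mh(cfg, seed = 8)
  expect_identical(d1, d2)
  expect_false(identical(d1, d3))
})

test_that("configuration invariants are enforced", {
  cfg <- default_mh_config()
  bad <- cfg; bad$phi[1, 2] <- 2
  expect_error(simulate_mh(bad), "positive-definite")
  bad <- cfg; bad$thresholds["int1", ] <- c(1, 0)
  expect_error(simulate_mh(bad), "increasing")
  bad <- cfg; bad$missing["int1"] <- 1
  expect_error(simulate_mh(bad), "missingness")
  bad <- cfg; bad$resid_pairs$b[1] <- bad$resid_pairs$a[1]
  expect_error(simulate_mh(bad), "distinct")
  # an over-strong residual pair breaks positive-definiteness
  bad <- cfg; bad$resid_pairs$value[1] <- 0.95
  expect_error(simulate_mh(bad), "positive definite")
})

test_that("ordinal margins match the closed-form orthant probabilities", {
  cfg <- default_mh_config(n = 50000)
  d <- simulate_mh(cfg, seed = 99)
  pr <- cfg$covariates$prob
  eff <- cfg$covariates$effects
  for (nm in c("int1", "int5", "ext2", "ext6")) {
    lam <- cfg$lambda[nm, ]
    tau <- cfg$thresholds[nm, ]
    # mixture over the four covariate combinations of the latent-normal
    # orthant probabilities (covariates shift the factor means)
    cum <- c(0, 0)
    for (g in 0:1) for (i in 0:1) {
      w <- stats::dbinom(g, 1, pr[["gender"]]) *
        stats::dbinom(i, 1, pr[["income"]])
      shift <- sum(lam * (g * eff$gender[names(lam)] +
                            i * eff$income[names(lam)]))
      cum <- cum + w * stats::pnorm(tau - shift)
    }
    obs <- cumsum(prop.table(table(d[[nm]])))[1:2]
    expect_lt(max(abs(unname(obs) - unname(cum))), 0.01)
  }
})

test_that("realised missingness matches the configured rates", {
  cfg <- default_mh_config(n = 50000)
  d <- simulate_mh(cfg, seed = 99)
  for (nm in c("int1", "ext3", "wb4")) {
    rate <- cfg$missing[[nm]]
    se <- sqrt(rate * (1 - rate) / nrow(d))
    expect_lt(abs(mean(is.na(d[[nm]])) - rate), 3 * se)
  }
})

test_that("the sample mixed correlation matrix matches the model-implied moments", {
  cfg <- default_mh_config(n = 50000, covariate_effects = FALSE, icc = 0)
  d <- simulate_mh(cfg, seed = 5)
  mm <- mixed_moments(d, gamma = "none")
  spec <- cfa_model("correlated", cfg$items, cfg$resid_pairs[c("a", "b")])
  im <- model_implied_moments(spec, dualfactor:::config_values(cfg))
  expect_lt(max(abs(mm$R - im$R)), 0.02)
  for (nm in names(mm$thresholds))
    expect_lt(max(abs(mm$thresholds[[nm]] - im$thresholds[[nm]])), 0.03)
})

test_that("cluster share of a near-saturated item hits the ICC target", {
  items <- data.frame(name = "c1", type = "continuous", domain = "a",
                      reverse = FALSE, stringsAsFactors = FALSE)
  cfg <- mh_config(
    items = items,
    lambda = matrix(sqrt(0.999), 1, 1, dimnames = list("c1", "a")),
    phi = matrix(1, 1, 1, dimnames = list("a", "a")),
    thresholds = matrix(numeric(0), 0, 2),
    continuous = data.frame(name = "c1", intercept = 5, sd = 1),
    resid_pairs = data.frame(a = character(0), b = character(0),
                             value = numeric(0)),
    covariates = list(prob = c(gender = .5, income = .4),
                      effects = zero_effects("a")),
    missing = c(c1 = 0), n = 20000, n_clusters = 400, icc = 0.05)
  d <- simulate_mh(cfg, seed = 21)
  expect_lt(abs(intraclass_correlation(d$c1, d$cluster) - 0.05), 0.01)
})

test_that("zero loadings produce independent items", {
  cfg <- toy_config(n = 50000, domains = rep("a", 4), lambda = rep(0, 4))
  d <- simulate_mh(cfg, seed = 13)
  mm <- mixed_moments(d, gamma = "none")
  expect_lt(max(abs(mm$R[upper.tri(mm$R)])), 0.02)
})

test_that("CSV round trip preserves data and metadata", {
  cfg <- default_mh_config(n = 120)
  d <- simulate_mh(cfg, seed = 2)
  path <- tempfile(fileext = ".csv")
  write_mh_data(d, path)
  d2 <- read_mh_data(path)
  expect_equal(item_info(d2), item_info(d))
  expect_equal(as.data.frame(d2), as.data.frame(d), tolerance = 1e-12)
})
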