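test_that("degrees of freedom reproduce the printed single-group accounting", {
  cfg <- default_mh_config()
  rp <- cfg$resid_pairs[c("a", "b")]
  expect_equal(model_df(cfa_model("correlated", cfg$items, rp))$df, 145)
  expect_equal(model_df(cfa_model("bifactor", cfg$items, rp))$df, 129)
  expect_equal(model_df(cfa_model("s1", cfg$items, rp,
                                  reference = "wellbeing"))$df, 133)
  expect_equal(model_df(cfa_model("s1", cfg$items, rp,
                                  reference = "internalising"))$df, 138)
})

test_that("dropping items updates the accounting and prunes residual pairs", {
  cfg <- default_mh_config()
  rp <- cfg$resid_pairs[c("a", "b")]
  m1 <- cfa_model("correlated", cfg$items, rp)
  m1r <- drop_items(m1, c("int4", "wb3"))
  expect_equal(model_df(m1r)$df, 113)
  expect_equal(nrow(m1r$resid_pairs), 3)   # the wellbeing pair is gone
  m4 <- cfa_model("s1", cfg$items, rp, reference = "internalising")
  m4r <- drop_items(m4, "int4")
  expect_equal(model_df(m4r)$df, 121)
  expect_equal(nrow(m4r$resid_pairs), 4)
  expect_error(drop_items(m1, "nonexistent"), "unknown items")
  expect_error(drop_items(m1, paste0("wb", 1:3)), "fewer than two items")
})

test_that("a three-item one-factor model is just identified", {
  items <- data.frame(name = paste0("y", 1:3), type = "ordinal",
                      domain = "a", reverse = FALSE)
  m <- cfa_model("correlated", items)
  d <- model_df(m)
  expect_equal(d$statistics, 9)   # 6 thresholds + 3 correlations
  expect_equal(d$df, 0)
})

test_that("builders produce the stated loading patterns", {
  cfg <- default_mh_config()
  m1 <- cfa_model("correlated", cfg$items)
  expect_equal(nrow(m1$factors), 3)
  expect_equal(sum(m1$phi_free[upper.tri(m1$phi_free)]), 3)
  expect_true(all(rowSums(m1$lambda) == 1))

  m2 <- cfa_model("bifactor", cfg$items)
  expect_equal(nrow(m2$factors), 4)
  expect_true(all(rowSums(m2$lambda) == 2))
  expect_false(any(m2$phi_free))

  m3 <- cfa_model("s1", cfg$items, reference = "internalising")
  expect_equal(sort(m3$factors$name),
               sort(c("general", "spec_externalising", "spec_wellbeing")))
  int_items <- cfg$items$name[cfg$items$domain == "internalising"]
  expect_true(all(rowSums(m3$lambda[int_items, , drop = FALSE]) == 1))
  expect_true(all(m3$lambda[int_items, "general"]))
  expect_error(cfa_model("s1", cfg$items, reference = "somatic"),
               "reference domain absent")
  expect_error(cfa_model("correlated", cfg$items,
                         data.frame(a = "int1", b = "zzz")),
               "unknown items")
})

test_that("builders are idempotent and models serialise losslessly", {
  cfg <- default_mh_config()
  rp <- cfg$resid_pairs[c("a", "b")]
  m_a <- cfa_model("s1", cfg$items, rp, reference = "wellbeing")
  m_b <- cfa_model("s1", cfg$items, rp, reference = "wellbeing")
  expect_identical(m_a, m_b)
  path <- tempfile(fileext = ".yaml")
  write_model(m_a, path)
  m_c <- read_model(path)
  expect_equal(m_c$lambda, m_a$lambda)
  expect_equal(m_c$phi_free, m_a$phi_free)
  expect_equal(m_c$resid_pairs$a, m_a$resid_pairs$a)
  expect_equal(m_c$resid_pairs$b, m_a$resid_pairs$b)
  expect_equal(model_df(m_c), model_df(m_a))
})

test_that("implied moments follow the factor algebra", {
  items <- data.frame(name = c("y1", "y2"), type = "ordinal", domain = "a",
                      reverse = FALSE)
  m <- cfa_model("correlated", items)
  vals <- list(lambda = matrix(c(.6, .6), 2, 1, dimnames = list(items$name, "a")),
               tau = matrix(c(0, 0, 1, 1), 2, 2,
                            dimnames = list(items$name, NULL)))
  im <- model_implied_moments(m, vals)
  expect_equal(im$R[1, 2], 0.36)
  # zero loadings give the identity
  vals0 <- vals; vals0$lambda[] <- 0
  expect_equal(model_implied_moments(m, vals0)$R, diag(2),
               ignore_attr = TRUE)
  # residual correlations add to the implied entry exactly
  m2 <- cfa_model("correlated", items, data.frame(a = "y1", b = "y2"))
  im2 <- model_implied_moments(m2, c(vals, list(rcov = 0.26)))
  expect_equal(im2$R[1, 2], 0.36 + 0.26)
  # Heywood detection names the item
  valsH <- vals; valsH$lambda[1, 1] <- 1.2
  expect_error(model_implied_moments(m, valsH), "y1.*Heywood")
})

test_that("implied moments at generating values equal the generator's population moments", {
  cfg <- default_mh_config()
  spec <- cfa_model("correlated", cfg$items, cfg$resid_pairs[c("a", "b")])
  im <- model_implied_moments(spec, dualfactor:::config_values(cfg))
  lam <- cfg$lambda
  common <- lam %*% cfg$phi %*% t(lam)
  Rpop <- common
  diag(Rpop) <- 1
  for (q in seq_len(nrow(cfg$resid_pairs))) {
    a <- cfg$resid_pairs$a[q]; b <- cfg$resid_pairs$b[q]
    Rpop[a, b] <- Rpop[b, a] <- common[a, b] + cfg$resid_pairs$value[q]
  }
  expect_equal(im$R, Rpop, tolerance = 1e-12)
  expect_equal(unname(im$means), rep(7, 4))
  expect_equal(unname(im$vars), rep(2.25, 4))
})

test_that("multigroup accounting nests configural within scalar", {
  cfg <- default_mh_config()
  spec <- cfa_model("correlated", cfg$items, cfg$resid_pairs[c("a", "b")])
  single <- model_df(spec)$df
  conf <- model_df(spec, groups = list(level = "configural",
                                       freed = character(0)))
  scal <- model_df(spec, groups = list(level = "scalar",
                                       freed = character(0)))
  expect_equal(conf$df, 2 * single)
  expect_gt(scal$df, conf$df)
  # freeing an ordinal item returns 2 df (3 deviations - 1 fixed scale),
  # a continuous item 2 df (loading + intercept)
  scal_f <- model_df(spec, groups = list(level = "scalar",
                                         freed = c("int4", "wb3")))
  expect_equal(scal$df - scal_f$df, 4)
})

test_that("moments and fit objects serialise for audit and re-fitting", {
  cfg <- mixed4_config(n = 1200)
  d <- simulate_mh(cfg, seed = 61)
  mm <- mixed_moments(d)
  p1 <- tempfile(fileext = ".json")
  write_moments(mm, p1)
  mm2 <- read_moments(p1)
  expect_equal(mm2$R, mm$R, tolerance = 1e-12)
  expect_equal(mm2$gamma, mm$gamma, tolerance = 1e-12, ignore_attr = TRUE)
  spec <- cfa_model("correlated", cfg$items)
  f1 <- dwls_fit(spec, moments = mm)
  f2 <- dwls_fit(spec, moments = mm2)
  expect_equal(f1$estimates, f2$estimates, tolerance = 1e-8)
  p2 <- tempfile(fileext = ".json")
  write_fit(f1, p2, mi = modification_indices(f1))
  rec <- read_fit(p2)
  expect_equal(rec$fit$chisq, f1$chisq, tolerance = 1e-10)
  expect_equal(rec$parameters$estimate, unname(f1$estimates),
               tolerance = 1e-12)
  expect_true(all(rec$modification_indices$mi >= 0))
})
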