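# Diagonally weighted least squares estimation (WLSMV-style): minimise
#   F(theta) = (s - sigma(theta))' diag(Gamma)^-1 (s - sigma(theta))
# over the free parameters, with sandwich standard errors using the full
# asymptotic covariance Gamma and a scaled-and-shifted (mean-and-variance
# adjusted) test statistic
#   T* = a n F + b,  a = sqrt(df / tr[(U Gamma)^2]),  b = df - a tr(U Gamma),
# where U is the DWLS residual projector.  Continuous-only specifications
# are fitted by normal-theory maximum likelihood instead.

par_bounds <- function(ptab) {
  lo <- c(lambda = -10, phi = -0.995, rcov = -3, psi = -5, nu = -100,
          tau = -6, kappa = -3, scale = 0.05, gamma = -5, cov_mean = -100,
          cov_var = 1e-6)
  hi <- c(lambda = 10, phi = 0.995, rcov = 3, psi = 100, nu = 100,
          tau = 6, kappa = 3, scale = 5, gamma = 5, cov_mean = 100,
          cov_var = 100)
  free <- ptab[ptab$free, ]
  agg <- function(v) tapply(v, free$par, mean)
  list(lower = as.numeric(agg(lo[free$type])),
       upper = as.numeric(agg(hi[free$type])))
}

# Data-driven start values: thresholds/means/variances at their sample
# estimates, loadings .5 (general/domain) or .3 (specific) scaled by the
# item sd, zero correlations.
start_values <- function(spec, ptab, mm_list) {
  it <- spec$items
  for (r in seq_len(nrow(ptab))) {
    if (!ptab$free[r]) next
    g <- ptab$group[r]
    mm <- mm_list[[min(g, length(mm_list))]]
    ty <- ptab$type[r]; nm <- ptab$item[r]
    if (ty == "tau") {
      ptab$value[r] <- mm$thresholds[[nm]][as.integer(ptab$fac[r])]
    } else if (ty == "nu" || ty == "cov_mean") {
      ptab$value[r] <- mm$means[[nm]]
    } else if (ty == "psi") {
      ptab$value[r] <- 0.5 * mm$vars[[nm]]
    } else if (ty == "cov_var") {
      ptab$value[r] <- mm$vars[[nm]]
    } else if (ty == "lambda" &&
               it$type[match(nm, it$name)] == "continuous") {
      ptab$value[r] <- ptab$value[r] * sqrt(mm$vars[[nm]])
    }
  }
  ptab
}

theta_start <- function(ptab) {
  free <- ptab[ptab$free, ]
  as.numeric(tapply(free$value, free$par, mean))
}

set_theta <- function(ptab, theta) {
  idx <- which(ptab$free)
  ptab$value[idx] <- theta[ptab$par[idx]]
  ptab
}

#' Construct a moments object from explicit blocks
#'
#' Builds the \code{mixed_moments} container from user-supplied thresholds,
#' means, variances and a correlation matrix (e.g. population values or a
#' published matrix), so that models can be fitted without raw data.  When
#' \code{gamma} is omitted the identity weight is used, making the DWLS
#' discrepancy an unweighted least-squares criterion.
#'
#' @param items Item metadata data frame.
#' @param thresholds Named list of threshold vectors (ordinal items).
#' @param means,vars Named vectors (continuous items).
#' @param R Correlation matrix over all items (dimnames = item names).
#' @param n Nominal sample size.
#' @param gamma Optional asymptotic covariance of the stacked statistics.
#' @return A \code{mixed_moments} object.
#' @export
moments_from_blocks <- function(items, thresholds, means, vars, R, n,
                                gamma = NULL) {
  nm <- items$name
  s <- numeric(0)
  index <- data.frame(type = character(0), item1 = character(0),
                      item2 = character(0))
  for (j in seq_len(nrow(items))) {
    if (items$type[j] == "ordinal") {
      s <- c(s, thresholds[[nm[j]]])
      index <- rbind(index, data.frame(type = c("tau1", "tau2"),
                                       item1 = nm[j], item2 = NA))
    } else {
      s <- c(s, means[[nm[j]]], vars[[nm[j]]])
      index <- rbind(index, data.frame(type = c("mean", "var"),
                                       item1 = nm[j], item2 = NA))
    }
  }
  pairsm <- utils::combn(nrow(items), 2)
  s <- c(s, R[cbind(pairsm[1, ], pairsm[2, ])])
  index <- rbind(index, data.frame(type = "cor", item1 = nm[pairsm[1, ]],
                                   item2 = nm[pairsm[2, ]]))
  if (is.null(gamma)) gamma <- diag(length(s))
  structure(list(items = items, thresholds = thresholds, means = means,
                 vars = vars, R = R, npair = matrix(n, nrow(items), nrow(items)),
                 statistics = s, index = index, n = n,
                 boundary_pairs = character(0), gamma = gamma),
            class = "mixed_moments")
}

#' Fit a factor model by diagonally weighted least squares
#'
#' Minimises the diagonally weighted quadratic form in the difference
#' between the sample statistic vector (thresholds, means, variances,
#' polychoric/polyserial/Pearson correlations) and the model-implied vector,
#' computes sandwich standard errors from the full asymptotic covariance,
#' and the mean-and-variance adjusted (scaled-and-shifted) test statistic
#' with baseline-model fit indices.  Specifications whose items are all
#' continuous are fitted by normal-theory maximum likelihood.
#'
#' @param spec A \code{dualfactor_model}.
#' @param moments A \code{mixed_moments} object (single group), or
#'   \code{NULL} to compute it from \code{data}.
#' @param data Item-response data frame (used when \code{moments} is NULL,
#'   and for the ML path).
#' @param group_moments List of two \code{mixed_moments} objects for a
#'   two-group fit.
#' @param groups Two-group structure: \code{list(level =
#'   "configural"|"scalar", freed = <character>)}.
#' @param constraints Optional list of \code{list(type, item, group, value)}
#'   fixing individual parameters (e.g. a residual variance at zero).
#' @param adjust \code{"scaled_shifted"} (default, mean-and-variance
#'   adjusted) or \code{"mean"} (mean-only scaling) for the test statistic.
#' @param restarts Maximum number of jittered restarts on non-convergence.
#' @param start Optional named start vector (matched by parameter name).
#' @return An object of class \code{dualfactor_fit}.
#' @export
dwls_fit <- function(spec, moments = NULL, data = NULL, group_moments = NULL,
                     groups = NULL, constraints = NULL,
                     adjust = c("scaled_shifted", "mean"), restarts = 3L,
                     start = NULL) {
  adjust <- match.arg(adjust)
  if (all(spec$items$type == "continuous") && is.null(groups) &&
      length(spec$covariates) == 0) {
    if (is.null(data)) stop("the ML path for continuous-only models needs data")
    return(ml_fit(spec, data))
  }
  if (is.null(group_moments)) {
    if (is.null(moments)) {
      if (is.null(data)) stop("supply moments or data")
      meta <- attr(data, "items")
      vars <- c(spec$items$name, spec$covariates)
      info <- meta[match(spec$items$name, meta$name), ]
      if (length(spec$covariates))
        info <- rbind(info, data.frame(name = spec$covariates,
                                       type = "continuous", domain = "covariate",
                                       reverse = FALSE))
      moments <- mixed_moments(data, info)
    }
    mm_list <- list(moments)
  } else mm_list <- group_moments
  ngroups <- length(mm_list)
  if (ngroups == 2 && is.null(groups))
    stop("two-group fits need a `groups` structure")

  ptab <- param_table(spec, groups)
  if (!is.null(constraints)) {
    for (cn in constraints) {
      sel <- ptab$type == cn$type & ptab$group == cn$group &
        (!is.na(ptab$item) & ptab$item == cn$item)
      if (!any(sel)) stop("constraint matches no parameter")
      ptab$free[sel] <- FALSE
      ptab$value[sel] <- cn$value
      ptab$eq[sel] <- NA
    }
    # re-assign parameter ids after fixing
    ptab$par <- NA_integer_
    free_rows <- which(ptab$free)
    labels <- ifelse(is.na(ptab$eq[free_rows]),
                     paste0(".row", free_rows), ptab$eq[free_rows])
    ptab$par[free_rows] <- as.integer(factor(labels, levels = unique(labels)))
  }
  ptab <- start_values(spec, ptab, mm_list)

  s <- unlist(lapply(mm_list, function(m) m$statistics), use.names = FALSE)
  n <- sum(vapply(mm_list, function(m) m$n, 0))
  Gam <- as.matrix(Matrix_bdiag(lapply(seq_len(ngroups), function(g)
    mm_list[[g]]$gamma * (n / mm_list[[g]]$n))))
  wi <- 1 / pmax(diag(Gam), 1e-12)
  nstat <- length(s)

  theta0 <- theta_start(ptab)
  npar <- length(theta0)
  pname <- vapply(split(ptab$name[ptab$free], ptab$par[ptab$free]),
                  `[`, "", 1L)
  if (!is.null(start)) {
    hit <- match(names(start), pname)
    theta0[stats::na.omit(hit)] <- start[!is.na(hit)]
  }
  bounds <- par_bounds(ptab)

  implied_fn <- compile_implied(spec, ptab)
  free_idx <- which(ptab$free)
  free_par <- ptab$par[free_idx]
  base_values <- ptab$value
  stacked_sigma <- function(theta) {
    values <- base_values
    values[free_idx] <- theta[free_par]
    out <- vector("list", ngroups)
    for (g in seq_len(ngroups)) {
      res <- implied_fn(values, g)
      if (is.null(res$stats)) return(NULL)
      out[[g]] <- res
    }
    out
  }
  # Two small regularisers stabilise empirically under-identified regions:
  # a smooth penalty keeps the search inside the admissible region (ordinal
  # residual variances positive), and a tiny ridge on specific-factor
  # loadings selects the minimum-norm point along the flat ridges that
  # arise when a specific factor's loadings are truly near zero (otherwise
  # one loading drifts to the admissibility boundary while its siblings
  # collapse).  For identified specific loadings the ridge shifts estimates
  # by O(1e-4), far below reported precision; no other parameter is
  # penalised.
  spec_facs <- spec$factors$name[spec$factors$kind == "specific"]
  ridge_pars <- unique(ptab$par[ptab$free & ptab$type == "lambda" &
                                  ptab$fac %in% spec_facs])
  obj <- function(theta) {
    impl <- stacked_sigma(theta)
    if (is.null(impl)) return(1e12)
    sig <- unlist(lapply(impl, function(x) x$stats), use.names = FALSE)
    e <- s - sig
    viol <- sum(vapply(impl, function(x) x$viol, 0))
    sum(wi * e * e) + 100 * viol + 1e-3 * sum(theta[ridge_pars]^2)
  }

  ctrl <- list(iter.max = 1000, eval.max = 4000, rel.tol = 1e-12,
               x.tol = 1e-10)
  num_grad <- function(theta) {
    vapply(seq_along(theta), function(k) {
      h <- 1e-5 * (1 + abs(theta[k]))
      tp <- theta; tm <- theta
      tp[k] <- tp[k] + h; tm[k] <- tm[k] - h
      (obj(tp) - obj(tm)) / (2 * h)
    }, 0)
  }
  # interior points only: at a bound the gradient need not vanish
  grad_ok <- function(res) {
    interior <- res$par > bounds$lower + 1e-8 & res$par < bounds$upper - 1e-8
    max(abs(num_grad(res$par)[interior]), 0) < 1e-3
  }
  fit0 <- stats::nlminb(theta0, obj, lower = bounds$lower,
                        upper = bounds$upper, control = ctrl)
  # polish: a warm restart escapes shallow plateaus of the quadratic form
  fit0b <- stats::nlminb(fit0$par, obj, lower = bounds$lower,
                         upper = bounds$upper, control = ctrl)
  if (fit0b$objective <= fit0$objective) fit0 <- fit0b
  best <- fit0
  ok <- best$convergence == 0 || grad_ok(best)
  attempts <- 0L
  while (!ok && attempts < restarts) {
    attempts <- attempts + 1L
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(1000L + attempts)
    jit <- theta0 + stats::runif(npar, -0.05, 0.05)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
    jit <- pmin(pmax(jit, bounds$lower), bounds$upper)
    cand <- stats::nlminb(jit, obj, lower = bounds$lower,
                          upper = bounds$upper, control = ctrl)
    if (cand$objective < best$objective) best <- cand
    ok <- best$convergence == 0 || grad_ok(best)
  }
  theta <- best$par
  pt <- set_theta(ptab, theta)
  impl <- stacked_sigma(theta)
  if (is.null(impl))
    stop("non-convergence: implied covariance degenerate at the optimum")
  sig <- unlist(lapply(impl, function(x) x$stats), use.names = FALSE)
  heywood <- unlist(lapply(impl, function(x) if (!x$ok) x$bad else NULL))
  e <- s - sig
  Fmin <- sum(wi * e * e)

  # Jacobian of sigma wrt theta (central differences)
  Delta <- matrix(0, nstat, npar)
  for (k in seq_len(npar)) {
    h <- 1e-5 * (1 + abs(theta[k]))
    tp <- theta; tm <- theta
    tp[k] <- tp[k] + h; tm[k] <- tm[k] - h
    sp <- stacked_sigma(tp)
    sm <- stacked_sigma(tm)
    Delta[, k] <- (unlist(lapply(sp, function(x) x$stats)) -
                     unlist(lapply(sm, function(x) x$stats))) / (2 * h)
  }
  converged <- ok
  if (!converged)
    warning("DWLS fit did not converge after ", attempts, " restarts",
            call. = FALSE)

  WD <- wi * Delta                         # W^-1 Delta
  B <- crossprod(Delta, WD)                # Delta' W^-1 Delta
  Bi <- solve(B + diag(1e-10 * mean(diag(B)), npar))
  DG <- crossprod(WD, Gam)                 # Delta' W^-1 Gamma
  UG <- wi * Gam - WD %*% (Bi %*% DG)      # U Gamma
  df <- nstat - npar
  Traw <- n * Fmin
  adj <- adjust_statistic(Traw, df, UG, adjust)
  vc <- Bi %*% (DG %*% WD) %*% Bi / n
  se <- sqrt(pmax(diag(vc), 0))

  base <- baseline_stats(mm_list, s, wi, Gam, n, adjust)
  fi <- if (df > 0) fit_indices(adj$stat, df, base$chisq, base$df, n)
  else list(rmsea = 0, rmsea_ci = c(0, 0), cfi = 1, tli = 1)

  # negative continuous residual variances (policy handled downstream)
  nr <- NULL
  psi_rows <- which(ptab$type == "psi" & ptab$free)
  for (r in psi_rows) {
    k <- ptab$par[r]
    if (theta[k] < 0) {
      z <- theta[k] / se[k]
      nr <- rbind(nr, data.frame(item = ptab$item[r], group = ptab$group[r],
                                 value = theta[k], se = se[k],
                                 p = 2 * stats::pnorm(-abs(z))))
    }
  }

  structure(list(
    spec = spec, method = "dwls", groups = groups, ngroups = ngroups,
    estimates = stats::setNames(theta, pname), se = stats::setNames(se, pname),
    vcov = vc, ptab = pt, n = n, statistics = s, implied = sig,
    residuals = e, gamma = Gam, wi = wi, Delta = Delta, Bi = Bi, UG = UG,
    nstat = nstat, npar = npar, df = df, Fmin = Fmin, Traw = Traw,
    chisq = adj$stat, scaling = adj, pvalue = stats::pchisq(adj$stat, df,
                                                            lower.tail = FALSE),
    baseline = base, fit_indices = fi, converged = converged,
    restarts = attempts, heywood = heywood, negative_resid = nr,
    moments = mm_list), class = "dualfactor_fit")
}

# block-diagonal without depending on Matrix
Matrix_bdiag <- function(mats) {
  sizes <- vapply(mats, nrow, 0L)
  out <- matrix(0, sum(sizes), sum(sizes))
  at <- 0L
  for (M in mats) {
    idx <- at + seq_len(nrow(M))
    out[idx, idx] <- M
    at <- at + nrow(M)
  }
  out
}

adjust_statistic <- function(Traw, df, UG, adjust) {
  if (df <= 0)
    return(list(stat = 0, a = 1, b = 0, tr1 = 0, tr2 = 0, method = adjust))
  tr1 <- sum(diag(UG))
  tr2 <- sum(UG * t(UG))
  if (adjust == "mean") {
    stat <- Traw / (tr1 / df)
    return(list(stat = max(stat, 0), a = df / tr1, b = 0, tr1 = tr1,
                tr2 = tr2, method = adjust))
  }
  a <- sqrt(df / max(tr2, 1e-12))
  b <- df - a * tr1
  list(stat = max(a * Traw + b, 0), a = a, b = b, tr1 = tr1, tr2 = tr2,
       method = adjust)
}

# Independence baseline (zero correlations, free thresholds/means/variances):
# closed form -- the saturated coordinates fit exactly and the residual
# projector reduces to the correlation block of the diagonal weight.
baseline_stats <- function(mm_list, s, wi, Gam, n, adjust) {
  corr_idx <- unlist(lapply(mm_list, function(m) m$index$type == "cor"))
  e <- s * corr_idx
  Fb <- sum(wi * e * e)
  df_b <- sum(corr_idx)
  sel <- which(corr_idx)
  UGb <- matrix(0, length(s), length(s))
  UGb[sel, ] <- (wi[sel]) * Gam[sel, , drop = FALSE]
  adj <- adjust_statistic(n * Fb, df_b, UGb, adjust)
  list(chisq = adj$stat, df = df_b, Fmin = Fb)
}

#' Chi-square based fit indices
#'
#' RMSEA with its 90 percent confidence interval (noncentral chi-square
#' inversion), CFI and TLI, from the test statistic of the target and
#' independence-baseline models.
#'
#' @param chi2,df Target-model statistic and degrees of freedom.
#' @param baseline_chi2,baseline_df Baseline-model statistic and df.
#' @param n Sample size.
#' @return List with \code{rmsea}, \code{rmsea_ci} (length 2), \code{cfi},
#'   \code{tli}.
#' @examples
#' fit_indices(410.931, 145, 5000, 171, 1982)$rmsea   # 0.030 at 3 dp
#' @export
fit_indices <- function(chi2, df, baseline_chi2, baseline_df, n) {
  stopifnot(df > 0, baseline_df > 0)
  rmsea <- sqrt(max(0, chi2 - df) / (df * (n - 1)))
  ci <- rmsea_ci(chi2, df, n)
  num <- max(chi2 - df, 0)
  den <- max(baseline_chi2 - baseline_df, chi2 - df, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  rb <- baseline_chi2 / baseline_df
  tli <- if (rb - 1 == 0) 1 else (rb - chi2 / df) / (rb - 1)
  list(rmsea = rmsea, rmsea_ci = ci, cfi = min(max(cfi, 0), 1), tli = tli)
}

rmsea_ci <- function(chi2, df, n, level = 0.90) {
  pl <- (1 + level) / 2; pu <- (1 - level) / 2
  bound <- function(prob) {
    if (stats::pchisq(chi2, df, ncp = 0) < prob) return(0)
    up <- max(chi2 * 2, df + 10)
    while (stats::pchisq(chi2, df, ncp = up) > prob && up < 1e7) up <- up * 2
    stats::uniroot(function(l) stats::pchisq(chi2, df, ncp = l) - prob,
                   c(0, up), tol = 1e-8)$root
  }
  lo <- bound(pl); hi <- bound(pu)
  sqrt(c(lo, hi) / (df * (n - 1)))
}

# Robust univariate score test for adding Jacobian column(s) dcol to a fit.
score_test <- function(fit, dcol) {
  dcol <- as.matrix(dcol)
  gk <- crossprod(dcol, fit$wi * fit$residuals)
  A <- t(fit$wi * dcol) -
    (crossprod(dcol, fit$wi * fit$Delta) %*% fit$Bi) %*% t(fit$wi * fit$Delta)
  Vg <- A %*% fit$gamma %*% t(A)
  k <- ncol(dcol)
  if (k == 1) {
    if (Vg[1, 1] < 1e-12) return(NULL)
    mi <- fit$n * gk[1]^2 / Vg[1, 1]
    schur <- crossprod(dcol, fit$wi * dcol) -
      (crossprod(dcol, fit$wi * fit$Delta) %*% fit$Bi) %*%
      crossprod(fit$Delta, fit$wi * dcol)
    epc <- if (schur[1, 1] > 1e-12) gk[1] / schur[1, 1] else NA_real_
    list(mi = as.numeric(mi), df = 1L, epc = as.numeric(epc))
  } else {
    # the block may be rank-deficient (e.g. one deviation direction already
    # spanned by a free scale parameter); use the pseudo-inverse on the
    # identified subspace
    ev <- eigen(Vg, symmetric = TRUE)
    keep <- ev$values > 1e-10 * max(ev$values, 0)
    if (!any(keep)) return(NULL)
    gz <- crossprod(ev$vectors[, keep, drop = FALSE], gk)
    list(mi = as.numeric(fit$n * sum(gz^2 / ev$values[keep])),
         df = sum(keep), epc = NA_real_)
  }
}

#' Modification indices for fixed residual correlations
#'
#' Univariate robust score-test statistics (1 df) for freeing each
#' currently-fixed residual correlation, with the expected parameter
#' change, ranked in decreasing order.
#'
#' @param fit A converged \code{dualfactor_fit} (DWLS path).
#' @param candidates Optional data frame (\code{a}, \code{b}) of item pairs;
#'   defaults to every pair without a free residual correlation.
#' @return Data frame \code{a}, \code{b}, \code{mi}, \code{epc}, ranked;
#'   candidates with singular information are skipped (attribute
#'   \code{"skipped"}).
#' @export
modification_indices <- function(fit, candidates = NULL) {
  if (fit$method != "dwls") stop("modification indices require a DWLS fit")
  spec <- fit$spec
  it <- spec$items
  if (is.null(candidates)) {
    pairsm <- utils::combn(nrow(it), 2)
    candidates <- data.frame(a = it$name[pairsm[1, ]],
                             b = it$name[pairsm[2, ]])
    inpair <- paste(spec$resid_pairs$a, spec$resid_pairs$b)
    candidates <- candidates[!(paste(candidates$a, candidates$b) %in% inpair) &
                               !(paste(candidates$b, candidates$a) %in% inpair), ]
  }
  # implied total variances per group, for the d corr / d theta_ij columns
  vtot <- implied_total_vars(fit)
  nv <- nrow(it) + length(spec$covariates)
  npairs <- nv * (nv - 1) / 2
  per_group <- fit$nstat / fit$ngroups
  pairsm <- utils::combn(nv, 2)
  pair_pos <- function(i, j) which(pairsm[1, ] == min(i, j) &
                                     pairsm[2, ] == max(i, j))
  out <- NULL; skipped <- character(0)
  for (q in seq_len(nrow(candidates))) {
    i <- match(candidates$a[q], it$name)
    j <- match(candidates$b[q], it$name)
    dcol <- numeric(fit$nstat)
    for (g in seq_len(fit$ngroups)) {
      pos <- (g - 1) * per_group + (per_group - npairs) + pair_pos(i, j)
      dcol[pos] <- 1 / sqrt(vtot[[g]][i] * vtot[[g]][j])
    }
    st <- score_test(fit, dcol)
    if (is.null(st)) {
      skipped <- c(skipped, paste(candidates$a[q], candidates$b[q]))
      next
    }
    out <- rbind(out, data.frame(a = candidates$a[q], b = candidates$b[q],
                                 mi = st$mi, epc = st$epc))
  }
  out <- out[order(-out$mi), ]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

implied_total_vars <- function(fit) {
  spec <- fit$spec
  it <- spec$items
  lapply(seq_len(fit$ngroups), function(g) {
    pg <- fit$ptab[fit$ptab$group == g, ]
    v <- rep(1, nrow(it))
    srows <- pg[pg$type == "scale", ]
    if (nrow(srows)) v[match(srows$item, it$name)] <- srows$value^2
    # continuous: read implied variance from the implied statistic vector
    per_group <- fit$nstat / fit$ngroups
    idx_types <- fit$moments[[min(g, length(fit$moments))]]$index
    sig_g <- fit$implied[(g - 1) * per_group + seq_len(per_group)]
    for (j in which(it$type == "continuous")) {
      k <- which(idx_types$type == "var" & idx_types$item1 == it$name[j])
      v[j] <- sig_g[k]
    }
    v
  })
}

#' Scaled chi-square difference test for nested DWLS fits
#'
#' Second-order (mean-and-variance adjusted) difference statistic for two
#' nested models fitted to the same statistics: the raw difference in
#' n-scaled discrepancies is rescaled using the traces of the difference of
#' the two residual-projector products, and referred to a chi-square with
#' \code{df_restricted - df_full} degrees of freedom.  A negative scaled
#' difference (a known pathology) is reported as 0 with a warning.
#'
#' @param fit_restricted,fit_full Nested \code{dualfactor_fit} objects on
#'   identical statistics.
#' @return List with \code{stat}, \code{df}, \code{p}.
#' @export
scaled_difference <- function(fit_restricted, fit_full) {
  f0 <- fit_restricted; f1 <- fit_full
  if (f0$nstat != f1$nstat || f0$n != f1$n)
    stop("fits are not on the same statistics")
  ddf <- f0$df - f1$df
  if (ddf == 0) return(list(stat = 0, df = 0L, p = NA_real_))
  if (ddf < 0) stop("restricted model must have larger df")
  M <- f0$UG - f1$UG
  tr1 <- sum(diag(M))
  tr2 <- sum(M * t(M))
  raw <- f0$Traw - f1$Traw
  if (tr2 > 1e-12) {
    a <- sqrt(ddf / tr2)
    stat <- a * raw + (ddf - a * tr1)
  } else {
    stat <- raw / max(tr1 / ddf, 1e-12)
  }
  if (stat < 0) {
    warning("negative scaled difference reported as 0", call. = FALSE)
    stat <- 0
  }
  list(stat = stat, df = as.integer(ddf),
       p = stats::pchisq(stat, ddf, lower.tail = FALSE))
}

# ---- normal-theory ML for continuous-only specifications --------------------

ml_fit <- function(spec, data) {
  it <- spec$items
  X <- stats::na.omit(as.matrix(data[it$name]))
  n <- nrow(X)
  p <- ncol(X)
  S <- stats::cov(X) * (n - 1) / n
  mbar <- colMeans(X)
  fnames <- colnames(spec$lambda)
  m <- length(fnames)
  rp <- spec$resid_pairs
  nl <- sum(spec$lambda)
  nphi <- sum(spec$phi_free[upper.tri(spec$phi_free)])
  npar <- nl + nphi + p + nrow(rp)     # loadings, factor corr, psi, rcov
  build_sigma <- function(theta) {
    L <- matrix(0, p, m, dimnames = dimnames(spec$lambda))
    L[spec$lambda] <- theta[seq_len(nl)]
    Phi <- diag(1, m)
    if (nphi) {
      ut <- which(upper.tri(Phi) & spec$phi_free, arr.ind = TRUE)
      Phi[ut] <- theta[nl + seq_len(nphi)]
      Phi[ut[, c(2, 1), drop = FALSE]] <- theta[nl + seq_len(nphi)]
    }
    psi <- theta[nl + nphi + seq_len(p)]
    Sig <- L %*% Phi %*% t(L) + diag(psi, p)
    for (q in seq_len(nrow(rp))) {
      ia <- match(rp$a[q], it$name); ib <- match(rp$b[q], it$name)
      Sig[ia, ib] <- Sig[ia, ib] + theta[nl + nphi + p + q]
      Sig[ib, ia] <- Sig[ia, ib]
    }
    Sig
  }
  logdetS <- determinant(S, logarithm = TRUE)$modulus
  fml <- function(theta) {
    Sig <- build_sigma(theta)
    ev <- eigen(Sig, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-10) return(1e12)
    as.numeric(determinant(Sig, logarithm = TRUE)$modulus +
                 sum(diag(solve(Sig, S))) - logdetS - p)
  }
  theta0 <- c(rep(0.5 * sqrt(mean(diag(S))), nl), rep(0, nphi),
              0.5 * diag(S), rep(0, nrow(rp)))
  lo <- c(rep(-10, nl), rep(-0.995, nphi), rep(1e-6, p), rep(-3, nrow(rp)))
  hi <- c(rep(10, nl), rep(0.995, nphi), rep(100, p), rep(3, nrow(rp)))
  opt <- stats::nlminb(theta0, fml, lower = lo, upper = hi,
                       control = list(iter.max = 1000))
  theta <- opt$par
  chisq <- (n - 1) * opt$objective
  stats_n <- p * (p + 3) / 2
  df <- as.integer(stats_n - npar - p)      # p saturated means
  Fb <- as.numeric(sum(log(diag(S))) - logdetS)
  chisq_b <- (n - 1) * Fb
  df_b <- as.integer(p * (p - 1) / 2)
  fi <- fit_indices(chisq, max(df, 1), chisq_b, df_b, n)
  if (df == 0) fi <- list(rmsea = 0, rmsea_ci = c(0, 0), cfi = 1, tli = 1)
  # observed-information standard errors
  H <- stats::optimHess(theta, function(t) (n - 1) / 2 * fml(t))
  vc <- tryCatch(solve(H), error = function(e) diag(NA_real_, npar))
  pname <- c(paste0("lambda.", rep(it$name, times = rowSums(spec$lambda))),
             if (nphi) paste0("phi.", seq_len(nphi)),
             paste0("psi.", it$name),
             if (nrow(rp)) paste0("rcov.", rp$a, ".", rp$b))
  structure(list(
    spec = spec, method = "ml", ngroups = 1L,
    estimates = stats::setNames(theta, pname),
    se = stats::setNames(sqrt(pmax(diag(vc), 0)), pname), vcov = vc,
    n = n, S = S, means = mbar, df = df, npar = npar, Fmin = opt$objective,
    Traw = chisq, chisq = chisq,
    pvalue = if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE) else NA,
    baseline = list(chisq = chisq_b, df = df_b), fit_indices = fi,
    converged = opt$convergence == 0, build_sigma = build_sigma,
    fml = fml), class = "dualfactor_fit")
}

# Score-test modification indices for the ML path (numeric derivatives of
# the ML discrepancy in the candidate residual covariance).
ml_modification_indices <- function(fit, candidates = NULL) {
  spec <- fit$spec
  it <- spec$items
  p <- nrow(it)
  if (is.null(candidates)) {
    pairsm <- utils::combn(p, 2)
    candidates <- data.frame(a = it$name[pairsm[1, ]], b = it$name[pairsm[2, ]])
    inpair <- paste(spec$resid_pairs$a, spec$resid_pairs$b)
    candidates <- candidates[!(paste(candidates$a, candidates$b) %in% inpair), ]
  }
  out <- NULL
  for (q in seq_len(nrow(candidates))) {
    spec2 <- spec
    spec2$resid_pairs <- rbind(spec$resid_pairs,
                               data.frame(a = candidates$a[q],
                                          b = candidates$b[q]))
    # score test via the augmented discrepancy at gamma = 0
    theta_aug <- c(fit$estimates, 0)
    nn <- length(theta_aug)
    f2 <- ml_discrepancy_factory(spec2, fit$S)
    h <- 1e-5
    g <- numeric(nn); Hd <- matrix(0, nn, nn)
    for (k in seq_len(nn)) {
      tp <- theta_aug; tm <- theta_aug
      tp[k] <- tp[k] + h; tm[k] <- tm[k] - h
      g[k] <- (f2(tp) - f2(tm)) / (2 * h)
    }
    for (k in seq_len(nn)) for (l in k:nn) {
      tpp <- theta_aug; tpm <- theta_aug; tmp <- theta_aug; tmm <- theta_aug
      tpp[c(k, l)] <- tpp[c(k, l)] + h
      tmm[c(k, l)] <- tmm[c(k, l)] - h
      tpm[k] <- tpm[k] + h; tpm[l] <- tpm[l] - h
      tmp[k] <- tmp[k] - h; tmp[l] <- tmp[l] + h
      Hd[k, l] <- Hd[l, k] <- (f2(tpp) - f2(tpm) - f2(tmp) + f2(tmm)) / (4 * h^2)
    }
    sc <- -(fit$n - 1) / 2 * g
    Iinf <- (fit$n - 1) / 2 * Hd
    mi <- tryCatch(as.numeric(crossprod(sc, solve(Iinf, sc))),
                   error = function(e) NA_real_)
    out <- rbind(out, data.frame(a = candidates$a[q], b = candidates$b[q],
                                 mi = mi, epc = NA_real_))
  }
  out <- out[order(-out$mi), ]
  rownames(out) <- NULL
  out
}

ml_discrepancy_factory <- function(spec, S) {
  it <- spec$items
  p <- nrow(it)
  fnames <- colnames(spec$lambda)
  m <- length(fnames)
  rp <- spec$resid_pairs
  nl <- sum(spec$lambda)
  nphi <- sum(spec$phi_free[upper.tri(spec$phi_free)])
  logdetS <- determinant(S, logarithm = TRUE)$modulus
  function(theta) {
    L <- matrix(0, p, m)
    L[spec$lambda] <- theta[seq_len(nl)]
    Phi <- diag(1, m)
    if (nphi) {
      ut <- which(upper.tri(Phi) & spec$phi_free, arr.ind = TRUE)
      Phi[ut] <- theta[nl + seq_len(nphi)]
      Phi[ut[, c(2, 1), drop = FALSE]] <- theta[nl + seq_len(nphi)]
    }
    psi <- theta[nl + nphi + seq_len(p)]
    Sig <- L %*% Phi %*% t(L) + diag(psi, p)
    for (q in seq_len(nrow(rp))) {
      ia <- match(rp$a[q], it$name); ib <- match(rp$b[q], it$name)
      Sig[ia, ib] <- Sig[ia, ib] + theta[nl + nphi + p + q]
      Sig[ib, ia] <- Sig[ia, ib]
    }
    ev <- eigen(Sig, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-10) return(1e12)
    as.numeric(determinant(Sig, logarithm = TRUE)$modulus +
                 sum(diag(solve(Sig, S))) - logdetS - p)
  }
}
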