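# Limited-information sample statistics for mixed ordinal/continuous item
# tables: thresholds, means/variances, polychoric / polyserial / Pearson
# correlations, and the asymptotic covariance (Gamma) of the stacked
# statistic vector, estimated from per-observation influence functions.

#' Estimate latent-normal thresholds of an ordinal item
#'
#' Inverse standard-normal transforms of the cumulative category
#' proportions (all categories except the last).
#'
#' @param x Integer/numeric vector of ordinal responses (NA allowed).
#' @param levels Number of scale categories (default 3; categories are
#'   \code{1:levels}).
#' @param item Item name used in error messages.
#' @return Numeric vector of \code{levels - 1} strictly increasing
#'   thresholds.
#' @export
estimate_thresholds <- function(x, levels = 3L, item = "item") {
  x <- x[!is.na(x)]
  if (length(x) == 0) stop("no observed responses for ", item)
  counts <- tabulate(factor(x, levels = seq_len(levels)), nbins = levels)
  cum <- cumsum(counts)[-levels] / length(x)
  if (any(cum <= 0) || any(cum >= 1))
    stop("degenerate margin for ", item,
         ": a cumulative category proportion is 0 or 1")
  stats::qnorm(cum)
}

# Two-step polychoric: thresholds fixed at the marginal estimates, rho
# maximises the bivariate-normal contingency-table likelihood.
polychoric_rho <- function(tab, tau_x, tau_y, bound = 0.999, tol = 1e-8) {
  negll <- function(r) -sum(tab * log(pmax(bvn_cell_probs(tau_x, tau_y, r),
                                           1e-300)))
  opt <- stats::optimize(negll, c(-bound, bound), tol = tol)
  rho <- opt$minimum
  boundary <- FALSE
  # optimize() never returns the exact interval ends; snap and flag
  if (abs(rho) > bound - 1e-4) {
    if (negll(sign(rho) * bound) <= opt$objective) rho <- sign(rho) * bound
    boundary <- TRUE
    warning("polychoric estimate at boundary |rho| >= ", bound,
            call. = FALSE)
  }
  list(rho = rho, boundary = boundary)
}

# Conditional log-likelihood of an ordinal response given a standardised
# continuous score, as a function of the latent correlation (two-step
# polyserial); vectorised over observations.
polyserial_ll <- function(rho, cat, w, tau) {
  q <- sqrt(max(1 - rho^2, 1e-12))
  cuts <- c(-Inf, tau, Inf)
  upper <- stats::pnorm((cuts[cat + 1L] - rho * w) / q)
  lower <- stats::pnorm((cuts[cat] - rho * w) / q)
  sum(log(pmax(upper - lower, 1e-300)))
}

polyserial_rho <- function(cat, w, tau, bound = 0.999, tol = 1e-8) {
  opt <- stats::optimize(function(r) -polyserial_ll(r, cat, w, tau),
                         c(-bound, bound), tol = tol)
  rho <- opt$minimum
  boundary <- abs(rho) > bound - 1e-4
  if (boundary)
    warning("polyserial estimate at boundary |rho| >= ", bound, call. = FALSE)
  list(rho = rho, boundary = boundary)
}

#' Correlation between two items of arbitrary scale type
#'
#' Dispatches on the scale-type pair: ordinal--ordinal gives the two-step
#' polychoric correlation (marginal thresholds fixed, latent correlation
#' maximising the bivariate-normal table likelihood), ordinal--continuous
#' the two-step polyserial, continuous--continuous the Pearson correlation.
#' Pairwise-complete observations are used throughout. Estimates with
#' \code{|rho| >= 0.999} are clamped and flagged.
#'
#' @param x,y Response vectors.
#' @param x_type,y_type \code{"ordinal"} or \code{"continuous"}.
#' @param min_n Minimum number of pairwise-complete observations.
#' @return List with \code{rho}, \code{n} and logical \code{boundary}.
#' @export
pairwise_correlation <- function(x, y, x_type = "ordinal",
                                 y_type = "ordinal", min_n = 10L) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_n)
    stop("fewer than ", min_n, " pairwise-complete observations")
  xs <- x[ok]; ys <- y[ok]
  boundary <- FALSE
  if (x_type == "ordinal" && y_type == "ordinal") {
    tau_x <- estimate_thresholds(x)
    tau_y <- estimate_thresholds(y)
    tab <- table(factor(xs, 1:3), factor(ys, 1:3))
    est <- polychoric_rho(tab, tau_x, tau_y)
    rho <- est$rho; boundary <- est$boundary
  } else if (x_type == "continuous" && y_type == "continuous") {
    rho <- stats::cor(xs, ys)
  } else {
    if (x_type == "continuous") {   # make x the ordinal member
      tmp <- x; x <- y; y <- tmp
      xs <- x[ok]; ys <- y[ok]
    }
    tau <- estimate_thresholds(x)
    mu <- mean(y, na.rm = TRUE)
    s <- sqrt(mean((y - mu)^2, na.rm = TRUE))
    est <- polyserial_rho(xs, (ys - mu) / s, tau)
    rho <- est$rho; boundary <- est$boundary
  }
  list(rho = rho, n = sum(ok), boundary = boundary)
}

# ---- influence-function machinery ------------------------------------------

# Scaled threshold influence columns for one ordinal item: matrix n x (K-1);
# rows with missing response are zero, observed rows are multiplied by
# n/n_obs so that Gamma = crossprod(IF)/n.
threshold_influence <- function(x, tau) {
  n <- length(x)
  obs <- !is.na(x)
  scale <- n / sum(obs)
  out <- matrix(0, n, length(tau))
  for (c in seq_along(tau)) {
    p <- stats::pnorm(tau[c])
    out[obs, c] <- ((x[obs] <= c) - p) / stats::dnorm(tau[c]) * scale
  }
  out
}

# Mean polychoric score over the observed table at (rho, tau): the
# estimating function whose root is the two-step estimator.
polychoric_mean_score <- function(tab, tau_x, tau_y, rho) {
  P <- pmax(bvn_cell_probs(tau_x, tau_y, rho), 1e-300)
  dP <- bvn_cell_dprobs(tau_x, tau_y, rho)
  sum(tab * dP / P) / sum(tab)
}

# Influence column (scaled) for a two-step polychoric correlation, plus the
# two items' threshold influence columns it corrects for.
polychoric_influence <- function(x, y, tau_x, tau_y, rho, if_tx, if_ty,
                                 eps = 1e-4) {
  n <- length(x)
  ok <- !is.na(x) & !is.na(y)
  tab <- table(factor(x[ok], 1:3), factor(y[ok], 1:3))
  P <- pmax(bvn_cell_probs(tau_x, tau_y, rho), 1e-300)
  dP <- bvn_cell_dprobs(tau_x, tau_y, rho)
  u_cell <- dP / P
  h <- -(polychoric_mean_score(tab, tau_x, tau_y, rho + eps) -
           polychoric_mean_score(tab, tau_x, tau_y, rho - eps)) / (2 * eps)
  taus <- list(tx1 = 1, tx2 = 2, ty1 = 1, ty2 = 2)
  J <- numeric(4)
  for (k in 1:4) {
    txp <- tau_x; txm <- tau_x; typ <- tau_y; tym <- tau_y
    if (k <= 2) { txp[k] <- txp[k] + eps; txm[k] <- txm[k] - eps }
    else { typ[k - 2] <- typ[k - 2] + eps; tym[k - 2] <- tym[k - 2] - eps }
    J[k] <- (polychoric_mean_score(tab, txp, typ, rho) -
               polychoric_mean_score(tab, txm, tym, rho)) / (2 * eps)
  }
  psi <- numeric(n)
  psi[ok] <- u_cell[cbind(x[ok], y[ok])] * (n / sum(ok))
  nuis <- if_tx %*% J[1:2] + if_ty %*% J[3:4]
  (psi + as.vector(nuis)) / h
}

polyserial_mean_score <- function(cat, w, tau, rho, eps = 1e-4) {
  (polyserial_ll(rho + eps, cat, w, tau) -
     polyserial_ll(rho - eps, cat, w, tau)) / (2 * eps) / length(cat)
}

polyserial_influence <- function(x, z, tau, mu, s, rho, if_tx, if_mu, if_s,
                                 eps = 1e-4) {
  n <- length(x)
  ok <- !is.na(x) & !is.na(z)
  cat <- x[ok]; w <- (z[ok] - mu) / s
  # per-observation score in rho (central difference of the cond. loglik)
  q <- function(r) sqrt(max(1 - r^2, 1e-12))
  cuts <- c(-Inf, tau, Inf)
  obs_ll <- function(r, w_, tau_) {
    cc <- c(-Inf, tau_, Inf)
    log(pmax(stats::pnorm((cc[cat + 1L] - r * w_) / q(r)) -
               stats::pnorm((cc[cat] - r * w_) / q(r)), 1e-300))
  }
  psi_obs <- (obs_ll(rho + eps, w, tau) - obs_ll(rho - eps, w, tau)) / (2 * eps)
  h <- -(mean((obs_ll(rho + 2 * eps, w, tau) - obs_ll(rho, w, tau)) / (2 * eps)) -
           mean((obs_ll(rho, w, tau) - obs_ll(rho - 2 * eps, w, tau)) / (2 * eps))) / (2 * eps)
  # Jacobians wrt tau1, tau2, mu, s (numeric, on the mean score)
  ms <- function(w_, tau_) mean((obs_ll(rho + eps, w_, tau_) -
                                   obs_ll(rho - eps, w_, tau_)) / (2 * eps))
  J_tau <- numeric(2)
  for (k in 1:2) {
    tp <- tau; tm <- tau
    tp[k] <- tp[k] + eps; tm[k] <- tm[k] - eps
    J_tau[k] <- (ms(w, tp) - ms(w, tm)) / (2 * eps)
  }
  J_mu <- (ms((z[ok] - mu - eps) / s, tau) - ms((z[ok] - mu + eps) / s, tau)) / (2 * eps)
  J_s <- (ms((z[ok] - mu) / (s + eps), tau) - ms((z[ok] - mu) / (s - eps), tau)) / (2 * eps)
  psi <- numeric(n)
  psi[ok] <- psi_obs * (n / sum(ok))
  nuis <- if_tx %*% J_tau + if_mu * J_mu + if_s * J_s
  (psi + as.vector(nuis)) / h
}

pearson_influence <- function(x, y, r) {
  n <- length(x)
  ok <- !is.na(x) & !is.na(y)
  mx <- mean(x[ok]); my <- mean(y[ok])
  sx <- sqrt(mean((x[ok] - mx)^2)); sy <- sqrt(mean((y[ok] - my)^2))
  zx <- (x[ok] - mx) / sx; zy <- (y[ok] - my) / sy
  out <- numeric(n)
  out[ok] <- (zx * zy - (r / 2) * (zx^2 + zy^2)) * (n / sum(ok))
  out
}

# ---- statistic assembly -----------------------------------------------------

#' Mixed correlation matrix with asymptotic covariance
#'
#' Assembles the full limited-information statistic vector of an
#' item-response table: two latent-normal thresholds per ordinal item, mean
#' and variance per continuous item, and all pairwise polychoric /
#' polyserial / Pearson correlations, together with the asymptotic
#' covariance matrix Gamma of the stacked statistics (scaled so that
#' \code{cov(s) = Gamma / n}).  Gamma is estimated from per-observation
#' influence functions of the two-step estimating equations (with threshold
#' and standardisation nuisance corrections); a seeded nonparametric
#' bootstrap is available for validation.
#'
#' @param data Item-response data frame.
#' @param items Item metadata (defaults to \code{attr(data, "items")});
#'   binary covariates may be included as \code{"continuous"} rows.
#' @param gamma \code{"influence"} (default), \code{"bootstrap"} or
#'   \code{"none"}.
#' @param boot_reps,boot_seed Bootstrap replicates and seed when
#'   \code{gamma = "bootstrap"}.
#' @param min_n Minimum pairwise-complete observations per correlation.
#' @return An object of class \code{mixed_moments}: thresholds, means,
#'   variances, correlation matrix \code{R}, per-pair n, \code{gamma}, the
#'   statistic ordering \code{index}, and \code{n}.
#' @export
mixed_moments <- function(data, items = attr(data, "items"),
                          gamma = c("influence", "bootstrap", "none"),
                          boot_reps = 500L, boot_seed = 1L, min_n = 10L) {
  gamma <- match.arg(gamma)
  if (is.null(items)) stop("item metadata required")
  miss <- setdiff(items$name, names(data))
  if (length(miss)) stop("items absent from data: ", paste(miss, collapse = ", "))
  p <- nrow(items)
  nm <- items$name
  type <- items$type
  n <- nrow(data)
  X <- data[nm]

  # validate scale types
  for (j in seq_len(p)) {
    v <- X[[j]][!is.na(X[[j]])]
    if (type[j] == "ordinal" && !all(v %in% 1:3))
      stop("item ", nm[j], " labelled ordinal but has values outside {1,2,3}")
    if (type[j] == "continuous" && length(v) && all(v %in% 1:3))
      stop("item ", nm[j],
           " labelled continuous but its values lie in {1,2,3}: ",
           "scale type looks mislabelled")
  }

  thresholds <- list()
  means <- vars <- stats::setNames(numeric(0), NULL)
  index <- data.frame(type = character(0), item1 = character(0),
                      item2 = character(0), stringsAsFactors = FALSE)
  s <- numeric(0)
  for (j in seq_len(p)) {
    if (type[j] == "ordinal") {
      tau <- estimate_thresholds(X[[j]], item = nm[j])
      thresholds[[nm[j]]] <- tau
      s <- c(s, tau)
      index <- rbind(index, data.frame(type = c("tau1", "tau2"),
                                       item1 = nm[j], item2 = NA))
    } else {
      v <- X[[j]]
      mu <- mean(v, na.rm = TRUE)
      s2 <- mean((v - mu)^2, na.rm = TRUE)
      means[nm[j]] <- mu
      vars[nm[j]] <- s2
      s <- c(s, mu, s2)
      index <- rbind(index, data.frame(type = c("mean", "var"),
                                       item1 = nm[j], item2 = NA))
    }
  }
  R <- diag(1, p); dimnames(R) <- list(nm, nm)
  npair <- matrix(n, p, p, dimnames = list(nm, nm))
  bound_flags <- character(0)
  pairs <- utils::combn(p, 2)
  for (q in seq_len(ncol(pairs))) {
    i <- pairs[1, q]; j <- pairs[2, q]
    est <- tryCatch(
      pairwise_correlation(X[[i]], X[[j]], type[i], type[j], min_n = min_n),
      error = function(e) stop("pair (", nm[i], ", ", nm[j], "): ",
                               conditionMessage(e), call. = FALSE))
    R[i, j] <- R[j, i] <- est$rho
    npair[i, j] <- npair[j, i] <- est$n
    if (est$boundary) bound_flags <- c(bound_flags, paste(nm[i], nm[j]))
    s <- c(s, est$rho)
    index <- rbind(index, data.frame(type = "cor", item1 = nm[i],
                                     item2 = nm[j]))
  }
  names(s) <- paste0(index$type, ".", index$item1,
                     ifelse(is.na(index$item2), "", paste0(".", index$item2)))

  out <- structure(
    list(items = items, thresholds = thresholds, means = means, vars = vars,
         R = R, npair = npair, statistics = s, index = index, n = n,
         boundary_pairs = bound_flags, gamma = NULL),
    class = "mixed_moments")

  if (gamma == "influence") {
    out$gamma <- gamma_influence(X, items, out)
  } else if (gamma == "bootstrap") {
    out$gamma <- gamma_bootstrap(data, items, reps = boot_reps,
                                 seed = boot_seed, min_n = min_n)
  }
  out
}

#' @export
print.mixed_moments <- function(x, ...) {
  cat("Mixed correlation statistics:", nrow(x$items), "items, n =", x$n,
      "(", length(x$statistics), "statistics )\n")
  invisible(x)
}

# Influence-function estimate of Gamma for an assembled statistic vector.
gamma_influence <- function(X, items, mm) {
  n <- mm$n
  p <- nrow(items)
  nm <- items$name
  type <- items$type
  nstat <- length(mm$statistics)
  IF <- matrix(0, n, nstat)
  # marginal columns, kept for reuse by the pair columns
  marg <- vector("list", p)
  col <- 1L
  for (j in seq_len(p)) {
    if (type[j] == "ordinal") {
      tc <- threshold_influence(X[[j]], mm$thresholds[[nm[j]]])
      IF[, col] <- tc[, 1]; IF[, col + 1L] <- tc[, 2]
      marg[[j]] <- list(tau = tc)
      col <- col + 2L
    } else {
      v <- X[[j]]
      obs <- !is.na(v)
      sc <- n / sum(obs)
      mu <- mm$means[nm[j]]; s2 <- mm$vars[nm[j]]
      ifm <- numeric(n); ifv <- numeric(n)
      ifm[obs] <- (v[obs] - mu) * sc
      ifv[obs] <- ((v[obs] - mu)^2 - s2) * sc
      IF[, col] <- ifm; IF[, col + 1L] <- ifv
      marg[[j]] <- list(mu = ifm, s = ifv / (2 * sqrt(s2)))
      col <- col + 2L
    }
  }
  pairs <- utils::combn(p, 2)
  for (q in seq_len(ncol(pairs))) {
    i <- pairs[1, q]; j <- pairs[2, q]
    rho <- mm$R[i, j]
    if (type[i] == "ordinal" && type[j] == "ordinal") {
      IF[, col] <- polychoric_influence(
        X[[i]], X[[j]], mm$thresholds[[nm[i]]], mm$thresholds[[nm[j]]], rho,
        marg[[i]]$tau, marg[[j]]$tau)
    } else if (type[i] == "continuous" && type[j] == "continuous") {
      IF[, col] <- pearson_influence(X[[i]], X[[j]], rho)
    } else {
      oi <- if (type[i] == "ordinal") i else j
      ci <- if (type[i] == "ordinal") j else i
      mu <- mm$means[nm[ci]]
      IF[, col] <- polyserial_influence(
        X[[oi]], X[[ci]], mm$thresholds[[nm[oi]]], mu,
        sqrt(mm$vars[nm[ci]]), rho,
        marg[[oi]]$tau, marg[[ci]]$mu, marg[[ci]]$s)
    }
    col <- col + 1L
  }
  G <- crossprod(IF) / n
  dimnames(G) <- list(names(mm$statistics), names(mm$statistics))
  G
}

# Nonparametric bootstrap estimate of Gamma (validation oracle).
gamma_bootstrap <- function(data, items, reps = 500L, seed = 1L,
                            min_n = 10L) {
  set.seed(as.integer(seed))
  n <- nrow(data)
  reps_s <- vapply(seq_len(reps), function(b) {
    d <- data[sample.int(n, n, replace = TRUE), , drop = FALSE]
    mm <- mixed_moments(d, items, gamma = "none", min_n = min_n)
    mm$statistics
  }, FUN.VALUE = numeric(length(mixed_moments(data, items,
                                              gamma = "none")$statistics)))
  n * stats::cov(t(reps_s))
}

# ---- descriptive statistics -------------------------------------------------

#' Scale reliability (Cronbach's alpha and item-total statistics)
#'
#' Computed on listwise-complete rows of the selected items.
#'
#' @param data Item-response data frame.
#' @param items Character vector of item names forming the scale.
#' @return List with \code{alpha}, \code{item_total} (correlation of each
#'   item with the sum of the remaining items) and \code{alpha_if_deleted}.
#' @export
scale_reliability <- function(data, items) {
  if (length(items) < 2) stop("need at least two items")
  X <- stats::na.omit(as.matrix(data[items]))
  if (nrow(X) < 3) stop("too few listwise-complete rows")
  k <- ncol(X)
  tot <- rowSums(X)
  vt <- stats::var(tot)
  if (vt <= 0) stop("zero total-score variance")
  alpha <- (k / (k - 1)) * (1 - sum(apply(X, 2, stats::var)) / vt)
  it <- numeric(k); aid <- numeric(k)
  for (j in seq_len(k)) {
    rest <- tot - X[, j]
    it[j] <- if (stats::var(rest) > 0 && stats::var(X[, j]) > 0)
      stats::cor(X[, j], rest) else NA_real_
    if (k > 2) {
      Xr <- X[, -j, drop = FALSE]
      vr <- stats::var(rowSums(Xr))
      aid[j] <- ((k - 1) / (k - 2)) *
        (1 - sum(apply(Xr, 2, stats::var)) / vr)
    } else aid[j] <- NA_real_
  }
  list(alpha = alpha,
       item_total = stats::setNames(it, items),
       alpha_if_deleted = stats::setNames(aid, items))
}

#' One-way random-effects intraclass correlation
#'
#' ANOVA estimator with the unbalanced-design cluster-size correction,
#' truncated below at zero.
#'
#' @param values Numeric vector (NA dropped).
#' @param cluster Cluster labels, same length.
#' @return ICC estimate in [0, 1].
#' @export
intraclass_correlation <- function(values, cluster) {
  ok <- !is.na(values) & !is.na(cluster)
  values <- values[ok]; cluster <- factor(cluster[ok])
  sizes <- table(cluster)
  if (nlevels(cluster) < 2) stop("need at least two clusters")
  if (sum(sizes >= 2) < 2) stop("need at least two clusters with >= 2 members")
  N <- length(values); J <- nlevels(cluster)
  gm <- mean(values)
  cm <- tapply(values, cluster, mean)
  ssb <- sum(sizes * (cm - gm)^2)
  ssw <- sum((values - cm[cluster])^2)
  msb <- ssb / (J - 1)
  msw <- ssw / (N - J)
  k0 <- (N - sum(sizes^2) / N) / (J - 1)
  icc <- (msb - msw) / (msb + (k0 - 1) * msw)
  max(icc, 0)
}
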