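# Bivariate standard-normal probabilities, vectorised over the upper limits.
#
# The polychoric likelihood evaluates Phi2 at every cell corner of a 3x3
# contingency table for many trial correlations, so the kernel must be
# vectorised.  We use the single-integral representation with the sine
# substitution r = sin(theta), which removes the 1/sqrt(1-r^2) endpoint
# singularity and makes fixed-order Gauss-Legendre quadrature accurate to
# near machine precision for |rho| <= .999:
#
#   Phi2(h, k; rho) = Phi(h) Phi(k) +
#     (1/2pi) * Int_0^asin(rho) exp(-(h^2 + k^2 - 2 h k sin t)/(2 cos^2 t)) dt

# Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch eigenvalue
# method (symmetric tridiagonal Jacobi matrix).
gauss_legendre <- function(n) {
  if (n == 1L) return(list(nodes = 0, weights = 2))
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = 2 * e$vectors[1, ord]^2)
}

.gl48 <- gauss_legendre(48L)

#' Bivariate standard-normal distribution function
#'
#' \code{P(X <= h, Y <= k)} for a standard bivariate normal with correlation
#' \code{rho}, vectorised over \code{h} and \code{k} (recycled), scalar
#' \code{rho}.  Infinite limits are allowed.
#'
#' @param h,k Upper limits (numeric vectors, recycled to common length).
#' @param rho Correlation, a single value in \code{[-1, 1]} (clamped to
#'   \code{+/- 0.9999} internally for numerical stability).
#' @return Numeric vector of probabilities.
#' @examples
#' pbvnorm(0, 0, 0.5)      # 1/4 + asin(0.5)/(2*pi)
#' @export
pbvnorm <- function(h, k, rho) {
  stopifnot(length(rho) == 1L, is.finite(rho) || abs(rho) <= 1)
  m <- max(length(h), length(k))
  h <- rep_len(as.numeric(h), m)
  k <- rep_len(as.numeric(k), m)
  rho <- max(-0.9999, min(0.9999, rho))
  out <- stats::pnorm(h) * stats::pnorm(k)
  if (rho == 0) return(out)
  # cap infinities: the integrand vanishes when either limit is +/-Inf,
  # but we keep finite arithmetic
  hb <- pmax(pmin(h, 8.5), -8.5)
  kb <- pmax(pmin(k, 8.5), -8.5)
  upper <- asin(rho)
  theta <- 0.5 * upper * (.gl48$nodes + 1)     # map [-1,1] -> [0, asin(rho)]
  w <- 0.5 * upper * .gl48$weights
  acc <- numeric(m)
  hk <- hb * kb
  hk2 <- hb^2 + kb^2
  for (j in seq_along(theta)) {
    st <- sin(theta[j]); ct2 <- cos(theta[j])^2
    acc <- acc + w[j] * exp(-(hk2 - 2 * hk * st) / (2 * ct2))
  }
  fin <- is.finite(h) & is.finite(k)
  out[fin] <- out[fin] + acc[fin] / (2 * pi)
  pmin(pmax(out, 0), 1)
}

# Bivariate standard-normal density at (h, k) with correlation rho;
# vectorised over h, k.  Returns 0 where either argument is infinite
# (needed when differentiating rectangle probabilities at open cell edges).
dbvnorm <- function(h, k, rho) {
  m <- max(length(h), length(k))
  h <- rep_len(as.numeric(h), m)
  k <- rep_len(as.numeric(k), m)
  out <- numeric(m)
  fin <- is.finite(h) & is.finite(k)
  if (any(fin)) {
    q <- 1 - rho^2
    z <- (h[fin]^2 - 2 * rho * h[fin] * k[fin] + k[fin]^2) / q
    out[fin] <- exp(-z / 2) / (2 * pi * sqrt(q))
  }
  out
}

# Cell probabilities of the 3x3 (or general) table induced by discretising a
# standard bivariate normal at thresholds tau_x, tau_y (each strictly
# increasing).  Returns a (K_x x K_y) matrix of probabilities.
bvn_cell_probs <- function(tau_x, tau_y, rho) {
  cx <- c(-Inf, tau_x, Inf)
  cy <- c(-Inf, tau_y, Inf)
  nx <- length(cx); ny <- length(cy)
  grid <- pbvnorm(rep(cx, times = ny), rep(cy, each = nx), rho)
  G <- matrix(grid, nx, ny)
  P <- G[-1, -1, drop = FALSE] - G[-nx, -1, drop = FALSE] -
    G[-1, -ny, drop = FALSE] + G[-nx, -ny, drop = FALSE]
  pmax(P, 0)
}

# d/d rho of the cell probabilities (analytic: dPhi2/drho = phi2).
bvn_cell_dprobs <- function(tau_x, tau_y, rho) {
  cx <- c(-Inf, tau_x, Inf)
  cy <- c(-Inf, tau_y, Inf)
  nx <- length(cx); ny <- length(cy)
  grid <- dbvnorm(rep(cx, times = ny), rep(cy, each = nx), rho)
  G <- matrix(grid, nx, ny)
  G[-1, -1, drop = FALSE] - G[-nx, -1, drop = FALSE] -
    G[-1, -ny, drop = FALSE] + G[-nx, -ny, drop = FALSE]
}
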