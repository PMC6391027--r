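# Shared fixtures, built in code.  Expensive objects are memoised per test
# session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (!exists(name, envir = .fixtures)) assign(name, fn(), envir = .fixtures)
  get(name, envir = .fixtures)
}

zero_effects <- function(factor_names) {
  list(gender = stats::setNames(rep(0, length(factor_names)), factor_names),
       income = stats::setNames(rep(0, length(factor_names)), factor_names))
}

# Small ordinal-only configuration: one or two domains, no clustering,
# no missingness, covariates present but inert unless effects are given.
toy_config <- function(n = 1000, domains = c("a", "a", "a", "b", "b", "b"),
                       lambda = rep(.6, length(domains)), phi_ab = .4,
                       resid = NULL, thr = c(.55, .90), effects = NULL) {
  p <- length(domains)
  items <- data.frame(name = paste0("y", seq_len(p)), type = "ordinal",
                      domain = domains, reverse = FALSE,
                      stringsAsFactors = FALSE)
  dn <- unique(domains)
  L <- matrix(0, p, length(dn), dimnames = list(items$name, dn))
  for (j in seq_len(p)) L[j, domains[j]] <- lambda[j]
  Phi <- diag(1, length(dn)); dimnames(Phi) <- list(dn, dn)
  if (length(dn) == 2) Phi[1, 2] <- Phi[2, 1] <- phi_ab
  thrm <- matrix(rep(stats::qnorm(thr), each = p), p, 2,
                 dimnames = list(items$name, c("t1", "t2")))
  rp <- if (is.null(resid))
    data.frame(a = character(0), b = character(0), value = numeric(0))
  else resid
  mh_config(items = items, lambda = L, phi = Phi, thresholds = thrm,
            continuous = data.frame(name = character(0),
                                    intercept = numeric(0), sd = numeric(0)),
            resid_pairs = rp,
            covariates = list(prob = c(gender = .5, income = .4),
                              effects = if (is.null(effects))
                                zero_effects(dn) else effects),
            missing = stats::setNames(rep(0, p), items$name), n = n,
            n_clusters = 10, icc = 0)
}

# Mixed 4-item configuration (2 ordinal + 2 continuous, one factor).
mixed4_config <- function(n = 2000, missing = 0.01) {
  items <- data.frame(name = c("o1", "o2", "c1", "c2"),
                      type = c("ordinal", "ordinal", "continuous",
                               "continuous"),
                      domain = "a", reverse = FALSE, stringsAsFactors = FALSE)
  L <- matrix(c(.7, .6, .65, .55), 4, 1, dimnames = list(items$name, "a"))
  mh_config(items = items, lambda = L,
            phi = matrix(1, 1, 1, dimnames = list("a", "a")),
            thresholds = matrix(rep(stats::qnorm(c(.55, .9)), each = 2), 2, 2,
                                dimnames = list(c("o1", "o2"), NULL)),
            continuous = data.frame(name = c("c1", "c2"), intercept = 7,
                                    sd = 1.5),
            resid_pairs = data.frame(a = character(0), b = character(0),
                                     value = numeric(0)),
            covariates = list(prob = c(gender = .5, income = .4),
                              effects = zero_effects("a")),
            missing = stats::setNames(rep(missing, 4), items$name), n = n,
            n_clusters = 10, icc = 0)
}

# Pure one-factor configuration carrying three nominal domains (so a
# bifactor model can be specified on it).
onefactor_config <- function(n = 5000) {
  items <- data.frame(name = paste0("y", 1:12), type = "ordinal",
                      domain = rep(c("a", "b", "c"), each = 4),
                      reverse = FALSE, stringsAsFactors = FALSE)
  L <- matrix(.6, 12, 1, dimnames = list(items$name, "g"))
  thr <- matrix(rep(stats::qnorm(c(.55, .9)), each = 12), 12, 2,
                dimnames = list(items$name, NULL))
  mh_config(items = items, lambda = L,
            phi = matrix(1, 1, 1, dimnames = list("g", "g")),
            thresholds = thr,
            continuous = data.frame(name = character(0),
                                    intercept = numeric(0), sd = numeric(0)),
            resid_pairs = data.frame(a = character(0), b = character(0),
                                     value = numeric(0)),
            covariates = list(prob = c(gender = .5, income = .4),
                              effects = zero_effects("g")),
            missing = stats::setNames(rep(0, 12), items$name), n = n,
            n_clusters = 10, icc = 0)
}

default_spec <- function(kind = "correlated", reference = NULL,
                         config = default_mh_config()) {
  cfa_model(kind, config$items, config$resid_pairs[c("a", "b")],
            reference = reference)
}

# simulate ordinal pairs from a known latent correlation
simulate_polychoric_pair <- function(n, rho, thr = stats::qnorm(c(.55, .9)),
                                     seed = 1) {
  set.seed(seed)
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  list(x = findInterval(z1, thr) + 1L, y = findInterval(z2, thr) + 1L)
}
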