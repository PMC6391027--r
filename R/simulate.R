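# Synthetic item-response generator emulating a two-instrument early
# adolescent mental-health survey: a 15-item symptom questionnaire (9
# internalising + 6 externalising three-category items, one reverse-coded)
# and a 4-item continuous wellbeing scale on 0-10, with school clustering,
# binary gender/income covariates and item-level MCAR missingness.

#' Default simulation configuration
#'
#' Builds the packaged default \code{mh_config}: 9 internalising and 6
#' externalising three-category ordinal items plus 4 continuous wellbeing
#' items (0--10 scale), three correlated latent factors
#' (internalising--externalising +.58, internalising--wellbeing -.58,
#' externalising--wellbeing -.42), standardised loadings in [.43, .80],
#' four residual-correlation pairs (the wellbeing pair at .26), right-skewed
#' symptom thresholds, per-item missingness rates in [.006, .026], school
#' clustering, and small gender/income shifts of the factor means.
#'
#' Loadings, thresholds, covariate effect sizes and the cluster share are
#' package assumptions chosen to be realistic for population screening data
#' (the study design being emulated prints only constraints, not values);
#' see the methods vignette.
#'
#' @param n Sample size (default 2000).
#' @param n_clusters Number of school clusters (default 59).
#' @param icc Intraclass correlation of each latent factor attributable to
#'   cluster membership (default 0.03; item-level ICCs are the squared
#'   loading times roughly this).
#' @param covariate_effects If \code{FALSE}, gender/income effects on the
#'   factor means are zeroed (for null-calibration experiments).
#' @return An object of class \code{mh_config}.
#' @seealso [simulate_mh()], [mh_config()]
#' @export
default_mh_config <- function(n = 2000, n_clusters = 59, icc = 0.03,
                              covariate_effects = TRUE) {
  items <- data.frame(
    name = c(paste0("int", 1:9), paste0("ext", 1:6), paste0("wb", 1:4)),
    type = c(rep("ordinal", 15), rep("continuous", 4)),
    domain = c(rep("internalising", 9), rep("externalising", 6),
               rep("wellbeing", 4)),
    reverse = FALSE,
    stringsAsFactors = FALSE
  )
  items$reverse[items$name == "ext6"] <- TRUE   # "I am calm" style item

  lambda <- matrix(0, nrow(items), 3,
                   dimnames = list(items$name,
                                   c("internalising", "externalising",
                                     "wellbeing")))
  lambda[1:9, 1] <- c(.65, .60, .55, .70, .62, .58, .52, .47, .66)
  lambda[10:15, 2] <- c(.63, .57, .52, .68, .45, .50)
  lambda[16:19, 3] <- c(.67, .73, .60, .70)

  phi <- matrix(c(1, .58, -.58,
                  .58, 1, -.42,
                  -.58, -.42, 1), 3, 3,
                dimnames = list(colnames(lambda), colnames(lambda)))

  # floor-effect thresholds (cumulative .55/.90) for symptom items; the
  # reverse-coded item is emitted re-reversed with a symmetric margin
  thr <- matrix(rep(stats::qnorm(c(.55, .90)), each = 15), 15, 2,
                dimnames = list(items$name[1:15], c("t1", "t2")))
  thr["ext6", ] <- stats::qnorm(c(.25, .75))

  continuous <- data.frame(
    name = items$name[16:19],
    intercept = 7.0,          # 0-10 scale, right-skewed towards the top
    sd = 1.5,                 # total sd; residual sd follows from loadings
    stringsAsFactors = FALSE
  )

  resid_pairs <- data.frame(
    a = c("int1", "int5", "int7", "wb1"),
    b = c("int3", "int6", "int8", "wb3"),
    value = c(.20, .25, .20, .26),
    stringsAsFactors = FALSE
  )

  eff <- if (covariate_effects) {
    # gender: 0 = boy, 1 = girl; income: 0 = never FSM, 1 = ever FSM
    list(gender = c(internalising = .19, externalising = -.38, wellbeing = 0),
         income = c(internalising = .08, externalising = .36,
                    wellbeing = -.08))
  } else {
    list(gender = c(internalising = 0, externalising = 0, wellbeing = 0),
         income = c(internalising = 0, externalising = 0, wellbeing = 0))
  }

  mh_config(
    items = items, lambda = lambda, phi = phi, thresholds = thr,
    continuous = continuous, resid_pairs = resid_pairs,
    covariates = list(prob = c(gender = .47, income = .43), effects = eff),
    missing = stats::setNames(seq(.006, .026, length.out = nrow(items)),
                              items$name),
    n = n, n_clusters = n_clusters, icc = icc
  )
}

#' Construct and validate a simulation configuration
#'
#' Low-level constructor; most users want [default_mh_config()].
#'
#' @param items Data frame with columns \code{name}, \code{type}
#'   (\code{"ordinal"} or \code{"continuous"}), \code{domain},
#'   \code{reverse}.
#' @param lambda Standardised loading matrix (items x factors).
#' @param phi Factor correlation matrix (unit diagonal, positive definite).
#' @param thresholds Matrix of two increasing latent-normal thresholds per
#'   ordinal item (rows named by item).
#' @param continuous Data frame \code{name}, \code{intercept}, \code{sd}
#'   giving the 0--10-scale location/scale of each continuous item.
#' @param resid_pairs Data frame \code{a}, \code{b}, \code{value} of residual
#'   correlations on the standardised latent-response scale.
#' @param covariates List with \code{prob} (Bernoulli rates of the binary
#'   covariates) and \code{effects} (per-covariate factor-mean shifts).
#' @param missing Named vector of per-item MCAR missingness rates in [0, 1).
#' @param n Sample size.
#' @param n_clusters Number of clusters.
#' @param icc Factor-level intraclass correlation in [0, 1).
#' @return An object of class \code{mh_config}.
#' @export
mh_config <- function(items, lambda, phi, thresholds, continuous,
                      resid_pairs, covariates, missing, n = 2000,
                      n_clusters = 59, icc = 0.03) {
  cfg <- structure(
    list(items = items, lambda = lambda, phi = phi, thresholds = thresholds,
         continuous = continuous, resid_pairs = resid_pairs,
         covariates = covariates, missing = missing, n = as.integer(n),
         n_clusters = as.integer(n_clusters), icc = icc),
    class = "mh_config")
  validate_mh_config(cfg)
  cfg
}

validate_mh_config <- function(cfg) {
  it <- cfg$items
  stopifnot(all(c("name", "type", "domain") %in% names(it)),
            !anyDuplicated(it$name),
            all(it$type %in% c("ordinal", "continuous")))
  if (!isTRUE(all.equal(cfg$phi, t(cfg$phi))) ||
      any(diag(cfg$phi) != 1) ||
      any(eigen(cfg$phi, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("factor covariance matrix 'phi' must be symmetric positive-definite with unit diagonal")
  # zero loading *values* are allowed (pure-noise items for calibration
  # experiments); the model builders enforce the loading pattern instead
  ord <- it$name[it$type == "ordinal"]
  if (length(ord)) {
    thr <- cfg$thresholds
    if (!all(ord %in% rownames(thr)) || any(thr[ord, 1] >= thr[ord, 2]))
      stop("each ordinal item needs two strictly increasing thresholds")
  }
  if (any(cfg$missing < 0 | cfg$missing >= 1))
    stop("missingness rates must lie in [0, 1)")
  rp <- cfg$resid_pairs
  if (nrow(rp) > 0) {
    if (any(rp$a == rp$b) ||
        !all(c(rp$a, rp$b) %in% it$name))
      stop("residual-correlation pairs must reference distinct existing items")
  }
  if (cfg$icc < 0 || cfg$icc >= 1) stop("icc must lie in [0, 1)")
  for (ef in cfg$covariates$effects)
    if (!all(colnames(cfg$lambda) %in% names(ef)))
      stop("covariate effects must be named for every factor")
  invisible(cfg)
}

#' @export
print.mh_config <- function(x, ...) {
  cat("Simulation configuration:", nrow(x$items), "items (",
      sum(x$items$type == "ordinal"), "ordinal /",
      sum(x$items$type == "continuous"), "continuous ),",
      ncol(x$lambda), "factors, n =", x$n, "\n")
  invisible(x)
}

# Population residual covariance matrix on the standardised latent-response
# scale implied by a configuration (diagonal completes items to unit
# communality; pairs add their stated correlation).
config_resid_cov <- function(cfg) {
  p <- nrow(cfg$items)
  comm <- rowSums((cfg$lambda %*% cfg$phi) * cfg$lambda)
  if (any(comm >= 1))
    stop("item communality >= 1 in block 'loadings': ",
         paste(cfg$items$name[comm >= 1], collapse = ", "))
  Theta <- diag(1 - comm, p)
  dimnames(Theta) <- list(cfg$items$name, cfg$items$name)
  rp <- cfg$resid_pairs
  for (i in seq_len(nrow(rp))) {
    Theta[rp$a[i], rp$b[i]] <- Theta[rp$b[i], rp$a[i]] <- rp$value[i]
  }
  Theta
}

#' Simulate an item-response table
#'
#' Draws a data set from the latent-response model of a configuration:
#' cluster effects (share \code{icc} of each factor's variance), binary
#' covariates shifting the factor means, multivariate-normal factor scores
#' and residuals (with the configured residual-correlation pairs), ordinal
#' items discretised at the configured thresholds into \{1, 2, 3\} (the
#' reverse-coded item is emitted already re-reversed), continuous items
#' rescaled to the 0--10 range and clipped, and per-item MCAR missingness.
#' Deterministic given \code{(config, seed)}.
#'
#' @param config An \code{mh_config}.
#' @param seed Integer seed.
#' @return A data frame with columns \code{id}, \code{cluster},
#'   \code{gender}, \code{income} and one column per item, carrying the item
#'   metadata in \code{attr(, "items")}.
#' @export
simulate_mh <- function(config = default_mh_config(), seed = 1L) {
  validate_mh_config(config)
  set.seed(as.integer(seed))
  n <- config$n
  it <- config$items
  p <- nrow(it)
  m <- ncol(config$lambda)

  Theta <- config_resid_cov(config)
  Rchol <- tryCatch(chol(Theta), error = function(e)
    stop("implied residual covariance is not positive definite ",
         "(block 'residual pairs')"))
  Pchol <- chol(config$phi)

  cluster <- sample.int(config$n_clusters, n, replace = TRUE)
  ce <- matrix(stats::rnorm(config$n_clusters * m), config$n_clusters) %*% Pchol
  u <- matrix(stats::rnorm(n * m), n) %*% Pchol
  eta <- sqrt(config$icc) * ce[cluster, , drop = FALSE] +
    sqrt(1 - config$icc) * u

  pr <- config$covariates$prob
  eff <- config$covariates$effects
  gender <- stats::rbinom(n, 1, pr[["gender"]])
  income <- stats::rbinom(n, 1, pr[["income"]])
  eta <- eta + outer(gender, eff$gender[colnames(config$lambda)]) +
    outer(income, eff$income[colnames(config$lambda)])

  eps <- matrix(stats::rnorm(n * p), n) %*% Rchol
  ystar <- eta %*% t(config$lambda) + eps
  colnames(ystar) <- it$name

  out <- data.frame(id = seq_len(n), cluster = cluster,
                    gender = gender, income = income)
  for (j in seq_len(p)) {
    nm <- it$name[j]
    if (it$type[j] == "ordinal") {
      thr <- config$thresholds[nm, ]
      out[[nm]] <- findInterval(ystar[, j], thr) + 1L
    } else {
      cc <- config$continuous[config$continuous$name == nm, ]
      out[[nm]] <- pmin(pmax(cc$intercept + cc$sd * ystar[, j], 0), 10)
    }
  }
  for (nm in it$name) {
    rate <- config$missing[[nm]]
    if (rate > 0) out[[nm]][stats::runif(n) < rate] <- NA
  }
  attr(out, "items") <- it
  out
}

#' Item metadata of a simulated (or read) table
#'
#' @param data A data frame produced by [simulate_mh()] or [read_mh_data()].
#' @return The item metadata data frame (\code{name}, \code{type},
#'   \code{domain}, \code{reverse}).
#' @export
item_info <- function(data) {
  info <- attr(data, "items")
  if (is.null(info)) stop("no item metadata attached; use read_mh_data()")
  info
}

#' Write / read an item-response table
#'
#' The table is stored as plain CSV (missing cells empty) with a YAML
#' sidecar (\code{<path>.meta.yaml}) recording item scale types, domains and
#' reverse-coding flags.
#'
#' @param data Item-response data frame with attached item metadata.
#' @param path CSV file path.
#' @return \code{write_mh_data} returns \code{path} invisibly;
#'   \code{read_mh_data} returns the data frame with metadata re-attached.
#' @export
write_mh_data <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, na = "")
  yaml::write_yaml(lapply(split(item_info(data), seq_len(nrow(item_info(data)))),
                          as.list),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_mh_data
#' @export
read_mh_data <- function(path) {
  out <- utils::read.csv(path, na.strings = "")
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  info <- do.call(rbind, lapply(meta, function(r)
    data.frame(name = r$name, type = r$type, domain = r$domain,
               reverse = isTRUE(r$reverse), stringsAsFactors = FALSE)))
  rownames(info) <- NULL
  attr(out, "items") <- info
  out
}
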