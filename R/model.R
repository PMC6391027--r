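# Declarative factor-model structures for mixed ordinal/continuous item
# batteries: correlated domain factors, the classical bifactor model, and
# S-1 bifactor variants (one domain's specific factor removed so that the
# general factor is defined by the reference domain's items).
#
# Identification convention (reproduces the printed single-group df
# accounting): all factor variances fixed at 1, all loadings free, factor
# means 0 in single-group models; ordinal latent responses have unit total
# variance with no free residual variance (delta-style parameterisation);
# continuous items carry a free intercept and residual variance.

#' Build a confirmatory factor model specification
#'
#' @param kind One of \code{"correlated"} (one factor per domain, free
#'   factor correlations), \code{"bifactor"} (one general factor plus one
#'   orthogonal specific factor per domain, every item loading on the
#'   general and its domain factor), \code{"s1"} (bifactor with the
#'   \code{reference} domain's specific factor removed), or
#'   \code{"instrument"} (correlated-factors structure on the given item
#'   subset, e.g. a single questionnaire).
#' @param items Item metadata data frame (\code{name}, \code{type},
#'   \code{domain}).
#' @param residual_pairs Optional data frame (\code{a}, \code{b}) of free
#'   residual correlations.
#' @param reference Reference domain for \code{kind = "s1"}: the domain
#'   whose items define the general factor (its specific factor is removed).
#' @return An object of class \code{dualfactor_model}.
#' @examples
#' cfg <- default_mh_config()
#' m <- cfa_model("correlated", cfg$items, cfg$resid_pairs[c("a", "b")])
#' model_df(m)
#' @export
cfa_model <- function(kind = c("correlated", "bifactor", "s1", "instrument"),
                      items, residual_pairs = NULL, reference = NULL) {
  kind <- match.arg(kind)
  items <- as.data.frame(items)[, c("name", "type", "domain")]
  domains <- unique(items$domain)
  if (kind == "s1") {
    if (is.null(reference) || !(reference %in% domains))
      stop("s1 reference domain absent from items: ", reference)
  }
  if (kind %in% c("correlated", "instrument")) {
    factors <- data.frame(name = domains, kind = "domain", domain = domains,
                          stringsAsFactors = FALSE)
    lambda <- outer(items$domain, domains, "==")
    phi_free <- upper_lower_free(length(domains))
  } else {
    specific <- if (kind == "bifactor") domains else setdiff(domains, reference)
    factors <- data.frame(
      name = c("general", if (length(specific)) paste0("spec_", specific)),
      kind = c("general", rep("specific", length(specific))),
      domain = c(NA, specific), stringsAsFactors = FALSE)
    lambda <- cbind(TRUE, outer(items$domain, specific, "=="))
    phi_free <- matrix(FALSE, nrow(factors), nrow(factors))
  }
  dimnames(lambda) <- list(items$name, factors$name)
  dimnames(phi_free) <- list(factors$name, factors$name)
  rp <- if (is.null(residual_pairs) || nrow(residual_pairs) == 0) {
    data.frame(a = character(0), b = character(0), stringsAsFactors = FALSE)
  } else {
    data.frame(a = as.character(residual_pairs[[1]]),
               b = as.character(residual_pairs[[2]]),
               stringsAsFactors = FALSE)
  }
  if (nrow(rp) && !all(c(rp$a, rp$b) %in% items$name))
    stop("residual pairs reference unknown items")
  structure(list(kind = kind, items = items, factors = factors,
                 lambda = lambda, phi_free = phi_free, resid_pairs = rp,
                 reference = reference, covariates = character(0)),
            class = "dualfactor_model")
}

upper_lower_free <- function(m) {
  out <- matrix(TRUE, m, m)
  diag(out) <- FALSE
  out
}

#' @export
print.dualfactor_model <- function(x, ...) {
  cat("CFA model (", x$kind,
      if (!is.null(x$reference)) paste0(", reference = ", x$reference), "): ",
      nrow(x$items), " items, ", nrow(x$factors), " factors, ",
      nrow(x$resid_pairs), " residual pairs\n", sep = "")
  d <- model_df(x)
  cat("statistics:", d$statistics, " free parameters:", d$parameters,
      " df:", d$df, "\n")
  invisible(x)
}

#' Remove items from a model specification
#'
#' Drops the items, their loadings and thresholds, and any residual pair
#' touching them.  The factor set is unchanged; a factor left indicating
#' fewer than two items is an identification failure.
#'
#' @param spec A \code{dualfactor_model}.
#' @param item_names Character vector of items to remove.
#' @return The reduced \code{dualfactor_model}.
#' @export
drop_items <- function(spec, item_names) {
  unknown <- setdiff(item_names, spec$items$name)
  if (length(unknown)) stop("unknown items: ", paste(unknown, collapse = ", "))
  keep <- !(spec$items$name %in% item_names)
  spec$items <- spec$items[keep, , drop = FALSE]
  spec$lambda <- spec$lambda[keep, , drop = FALSE]
  rp <- spec$resid_pairs
  spec$resid_pairs <- rp[!(rp$a %in% item_names | rp$b %in% item_names), ,
                         drop = FALSE]
  short <- colSums(spec$lambda) < 2
  if (any(short))
    stop("factor(s) left with fewer than two items: ",
         paste(colnames(spec$lambda)[short], collapse = ", "))
  spec
}

# ---- parameter enumeration --------------------------------------------------

# Enumerate every model parameter as one row per group:
#   type in {lambda, phi, rcov, psi, nu, tau, kappa, scale, gamma,
#            cov_mean, cov_var}
# with a free flag, fixed/start value, and an equality label for
# cross-group constrained parameters.  `groups` is NULL (single group) or
# list(level = "configural"|"scalar", freed = character()).
param_table <- function(spec, groups = NULL) {
  it <- spec$items
  fnames <- colnames(spec$lambda)
  ngroups <- if (is.null(groups)) 1L else 2L
  level <- if (is.null(groups)) "single" else groups$level
  freed <- if (is.null(groups)) character(0) else groups$freed
  rows <- list()
  add <- function(type, item = NA, fac = NA, item2 = NA, group, free, value,
                  eq = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      type = type, item = item, fac = fac, item2 = item2, group = group,
      free = free, value = value, eq = eq, stringsAsFactors = FALSE)
  }
  for (g in seq_len(ngroups)) {
    shared <- ngroups == 2L && level == "scalar"
    for (j in seq_len(nrow(it))) {
      nm <- it$name[j]
      item_freed <- nm %in% freed
      for (f in fnames[spec$lambda[j, ]]) {
        start <- if (f == "general" || spec$factors$kind[match(f, fnames)] == "domain") 0.5 else 0.3
        add("lambda", nm, f, group = g, free = TRUE, value = start,
            eq = if (shared && !item_freed) paste("lambda", nm, f) else NA)
      }
      if (it$type[j] == "ordinal") {
        for (c in 1:2)
          add("tau", nm, fac = c, group = g, free = TRUE, value = c(-0.5, 0.5)[c],
              eq = if (shared && !item_freed) paste("tau", nm, c) else NA)
      } else {
        add("nu", nm, group = g, free = TRUE, value = 0,
            eq = if (shared && !item_freed) paste("nu", nm) else NA)
        add("psi", nm, group = g, free = TRUE, value = 0.5)
      }
    }
    for (a in seq_len(nrow(spec$factors))) for (b in seq_len(nrow(spec$factors))) {
      if (a < b) {
        add("phi", fac = fnames[a], item2 = fnames[b], group = g,
            free = spec$phi_free[a, b], value = 0)
      }
    }
    rp <- spec$resid_pairs
    for (q in seq_len(nrow(rp)))
      add("rcov", rp$a[q], item2 = rp$b[q], group = g, free = TRUE, value = 0)
    for (cv in spec$covariates) {
      for (f in fnames)
        add("gamma", cv, fac = f, group = g, free = TRUE, value = 0)
      add("cov_mean", cv, group = g, free = TRUE, value = 0)
      add("cov_var", cv, group = g, free = TRUE, value = 0.25)
    }
    if (g == 2L && level == "scalar") {
      for (f in fnames)
        add("kappa", fac = f, group = 2L, free = TRUE, value = 0)
      for (nm in it$name[it$type == "ordinal"])
        add("scale", nm, group = 2L, free = !(nm %in% freed), value = 1)
    }
  }
  ptab <- do.call(rbind, rows)
  # parameter ids: one per equality class, one per unlabelled free row
  ptab$par <- NA_integer_
  free_rows <- which(ptab$free)
  labels <- ifelse(is.na(ptab$eq[free_rows]),
                   paste0(".row", free_rows), ptab$eq[free_rows])
  ptab$par[free_rows] <- as.integer(factor(labels, levels = unique(labels)))
  ptab$name <- paste0(ptab$type,
                      ifelse(is.na(ptab$item), "", paste0(".", ptab$item)),
                      ifelse(is.na(ptab$fac), "", paste0(".", ptab$fac)),
                      ifelse(is.na(ptab$item2), "", paste0(".", ptab$item2)),
                      ifelse(ptab$group > 1, paste0(".g", ptab$group), ""))
  ptab
}

#' Statistic / parameter / degrees-of-freedom accounting
#'
#' Counts the limited-information sample statistics (two thresholds per
#' ordinal item, mean and variance per continuous item or covariate, all
#' pairwise correlations; summed over groups), the free parameters after
#' cross-group equality constraints, and their difference.
#'
#' @param spec A \code{dualfactor_model}.
#' @param groups \code{NULL} for a single-group model, or
#'   \code{list(level = "configural"|"scalar", freed = <character>)} for a
#'   two-group model.
#' @return List with \code{statistics}, \code{parameters} and \code{df}.
#' @export
model_df <- function(spec, groups = NULL) {
  it <- spec$items
  nvar <- nrow(it) + length(spec$covariates)
  n_ord <- sum(it$type == "ordinal")
  n_cont <- sum(it$type == "continuous") + length(spec$covariates)
  per_group <- 2 * n_ord + 2 * n_cont + nvar * (nvar - 1) / 2
  ngroups <- if (is.null(groups)) 1L else 2L
  stats_n <- per_group * ngroups
  ptab <- param_table(spec, groups)
  pars <- length(unique(stats::na.omit(ptab$par)))
  list(statistics = as.integer(stats_n), parameters = as.integer(pars),
       df = as.integer(stats_n - pars))
}

# ---- implied moments --------------------------------------------------------

# Compile a (spec, ptab) pair into a fast implied-statistics function of the
# parameter-table `value` column: all name matching and position lookup is
# done once, so the optimiser's objective is pure indexed arithmetic.
# The returned function(values, g) gives list(stats, ok, bad) where `bad`
# names an item whose implied ordinal residual variance is non-positive
# (Heywood case); `stats` is still computed (ordinal total variances are
# fixed by the scale parameters) so optimisers can traverse such points.
compile_implied <- function(spec, ptab) {
  it <- spec$items
  p <- nrow(it)
  fnames <- colnames(spec$lambda)
  m <- length(fnames)
  covs <- spec$covariates
  nc <- length(covs)
  nv <- p + nc
  is_ord <- it$type == "ordinal"
  pairsm <- utils::combn(nv, 2)
  i1 <- pairsm[1, ]; i2 <- pairsm[2, ]
  # output slot layout: per item 2 slots, per covariate 2 slots, then pairs
  nslots <- 2L * nv + ncol(pairsm)
  slot0 <- 2L * (seq_len(nv) - 1L)
  corr0 <- 2L * nv

  groups <- sort(unique(ptab$group))
  ginfo <- lapply(groups, function(g) {
    rows <- which(ptab$group == g)
    pg <- ptab[rows, ]
    pick <- function(ty) rows[pg$type == ty]
    lr <- pick("lambda")
    info <- list(
      lam_rows = lr,
      lam_pos = cbind(match(ptab$item[lr], it$name),
                      match(ptab$fac[lr], fnames)),
      phi_rows = pick("phi"),
      rcov_rows = pick("rcov"),
      kappa_rows = pick("kappa"),
      scale_rows = pick("scale"),
      gamma_rows = pick("gamma"),
      covm_rows = pick("cov_mean"),
      covv_rows = pick("cov_var")
    )
    pr <- info$phi_rows
    info$phi_pos <- cbind(match(ptab$fac[pr], fnames),
                          match(ptab$item2[pr], fnames))
    rr <- info$rcov_rows
    info$rcov_pos <- cbind(match(ptab$item[rr], it$name),
                           match(ptab$item2[rr], it$name))
    info$kappa_pos <- match(ptab$fac[info$kappa_rows], fnames)
    info$scale_pos <- match(ptab$item[info$scale_rows], it$name)
    gr <- info$gamma_rows
    info$gamma_pos <- cbind(match(ptab$fac[gr], fnames),
                            match(ptab$item[gr], covs))
    info$covm_pos <- match(ptab$item[info$covm_rows], covs)
    info$covv_pos <- match(ptab$item[info$covv_rows], covs)
    # per-item parameter rows for tau / nu / psi
    info$tau_rows <- lapply(seq_len(p), function(j)
      if (is_ord[j]) rows[pg$type == "tau" & pg$item == it$name[j]][
        order(as.integer(pg$fac[pg$type == "tau" & pg$item == it$name[j]]))]
      else integer(0))
    info$nu_row <- vapply(seq_len(p), function(j)
      if (!is_ord[j]) rows[pg$type == "nu" & pg$item == it$name[j]][1] else NA_integer_,
      0L)
    info$psi_row <- vapply(seq_len(p), function(j)
      if (!is_ord[j]) rows[pg$type == "psi" & pg$item == it$name[j]][1] else NA_integer_,
      0L)
    info
  })
  names(ginfo) <- as.character(groups)

  function(values, g) {
    gi <- ginfo[[as.character(g)]]
    L <- matrix(0, p, m)
    L[gi$lam_pos] <- values[gi$lam_rows]
    Phi <- diag(1, m)
    if (length(gi$phi_rows)) {
      Phi[gi$phi_pos] <- values[gi$phi_rows]
      Phi[gi$phi_pos[, c(2, 1), drop = FALSE]] <- values[gi$phi_rows]
    }
    kap <- numeric(m)
    if (length(gi$kappa_rows)) kap[gi$kappa_pos] <- values[gi$kappa_rows]
    if (nc) {
      G <- matrix(0, m, nc)
      G[gi$gamma_pos] <- values[gi$gamma_rows]
      mu_x <- numeric(nc); mu_x[gi$covm_pos] <- values[gi$covm_rows]
      var_x <- rep(1, nc); var_x[gi$covv_pos] <- values[gi$covv_rows]
      GS <- G * rep(var_x, each = m)
      cov_eta <- Phi + GS %*% t(G)
      mu_eta <- kap + as.vector(G %*% mu_x)
    } else {
      cov_eta <- Phi
      mu_eta <- kap
    }
    common <- L %*% cov_eta %*% t(L)
    scales <- rep(1, p)
    if (length(gi$scale_rows)) scales[gi$scale_pos] <- values[gi$scale_rows]
    vtot <- numeric(p)
    ok <- TRUE; bad <- NULL; viol <- 0
    psi_vals <- ifelse(is.na(gi$psi_row), 0, values[pmax(gi$psi_row, 1L)])
    for (j in seq_len(p)) {
      if (is_ord[j]) {
        vtot[j] <- scales[j]^2
        resid <- vtot[j] - common[j, j]
        if (resid <= 0) { ok <- FALSE; bad <- it$name[j] }
        if (resid < 0.005) viol <- viol + (0.005 - resid)^2
      } else {
        vtot[j] <- common[j, j] + psi_vals[j]
        if (vtot[j] <= 1e-10) return(list(stats = NULL, ok = FALSE, bad = it$name[j]))
      }
    }
    V <- common
    diag(V) <- vtot
    if (length(gi$rcov_rows)) {
      V[gi$rcov_pos] <- V[gi$rcov_pos] + values[gi$rcov_rows]
      V[gi$rcov_pos[, c(2, 1), drop = FALSE]] <- V[gi$rcov_pos]
    }
    if (nc) {
      Vyx <- L %*% GS
      V <- rbind(cbind(V, Vyx), cbind(t(Vyx), diag(var_x, nc)))
      vtot <- c(vtot, var_x)
    }
    sdv <- sqrt(vtot)
    out <- numeric(nslots)
    mu_item <- as.vector(L %*% mu_eta)
    for (j in seq_len(p)) {
      if (is_ord[j]) {
        out[slot0[j] + 1:2] <- (values[gi$tau_rows[[j]]] - mu_item[j]) / sdv[j]
      } else {
        out[slot0[j] + 1L] <- values[gi$nu_row[j]] + mu_item[j]
        out[slot0[j] + 2L] <- vtot[j]
      }
    }
    if (nc) {
      mu_x_full <- numeric(nc); mu_x_full[gi$covm_pos] <- values[gi$covm_rows]
      var_x_full <- rep(1, nc); var_x_full[gi$covv_pos] <- values[gi$covv_rows]
      for (cvi in seq_len(nc)) {
        out[slot0[p + cvi] + 1L] <- mu_x_full[cvi]
        out[slot0[p + cvi] + 2L] <- var_x_full[cvi]
      }
    }
    out[(corr0 + 1L):nslots] <- V[cbind(i1, i2)] / (sdv[i1] * sdv[i2])
    list(stats = out, ok = ok, bad = bad, viol = viol)
  }
}

# One-shot wrapper (used by user-facing helpers; fits compile once instead).
implied_stats_group <- function(spec, ptab, g) {
  compile_implied(spec, ptab)(ptab$value, g)
}

#' Model-implied moments at given parameter values
#'
#' Computes the implied thresholds, means, variances and item correlation
#' matrix of a single-group specification at user-supplied parameter values
#' (the sigma(theta) entering the discrepancy function).  Implied item
#' correlations are \code{lambda_i' Phi lambda_j + theta_ij}; ordinal items
#' are scaled to unit total variance, so a non-positive implied residual
#' variance is a Heywood condition and raises an error naming the item.
#'
#' @param spec A single-group \code{dualfactor_model}.
#' @param values Named list: \code{lambda} (matrix, free cells used),
#'   optional \code{phi} (matrix), \code{rcov} (vector in residual-pair
#'   order), \code{tau} (matrix, ordinal rows), \code{nu}, \code{psi}
#'   (named vectors, continuous items).
#' @return List with \code{thresholds}, \code{means}, \code{vars} and the
#'   implied correlation matrix \code{R}.
#' @export
model_implied_moments <- function(spec, values) {
  ptab <- param_table(spec)
  ptab <- fill_values(spec, ptab, values)
  res <- implied_stats_group(spec, ptab, 1L)
  if (!res$ok)
    stop("implied ordinal total variance <= 0 for item ", res$bad,
         " (Heywood case)")
  unpack_stats(spec, res$stats)
}

# Fill a parameter table's `value` column from a user-facing values list.
fill_values <- function(spec, ptab, values) {
  it <- spec$items
  for (r in seq_len(nrow(ptab))) {
    ty <- ptab$type[r]
    if (ty == "lambda") {
      ptab$value[r] <- values$lambda[ptab$item[r], ptab$fac[r]]
    } else if (ty == "phi" && !is.null(values$phi)) {
      ptab$value[r] <- values$phi[ptab$fac[r], ptab$item2[r]]
    } else if (ty == "rcov") {
      q <- which(spec$resid_pairs$a == ptab$item[r] &
                   spec$resid_pairs$b == ptab$item2[r])
      ptab$value[r] <- if (!is.null(values$rcov)) values$rcov[q] else 0
    } else if (ty == "tau" && !is.null(values$tau)) {
      ptab$value[r] <- values$tau[ptab$item[r], as.integer(ptab$fac[r])]
    } else if (ty == "nu" && !is.null(values$nu)) {
      ptab$value[r] <- values$nu[[ptab$item[r]]]
    } else if (ty == "psi" && !is.null(values$psi)) {
      ptab$value[r] <- values$psi[[ptab$item[r]]]
    }
  }
  ptab
}

# Reshape a stacked implied-statistic vector into named blocks.
unpack_stats <- function(spec, svec) {
  it <- spec$items
  p <- nrow(it)
  covs <- spec$covariates
  nv <- p + length(covs)
  thresholds <- list(); means <- c(); vars <- c()
  pos <- 1L
  for (j in seq_len(p)) {
    if (it$type[j] == "ordinal") {
      thresholds[[it$name[j]]] <- svec[pos:(pos + 1L)]
      pos <- pos + 2L
    } else {
      means[it$name[j]] <- svec[pos]
      vars[it$name[j]] <- svec[pos + 1L]
      pos <- pos + 2L
    }
  }
  for (cv in covs) {
    means[cv] <- svec[pos]; vars[cv] <- svec[pos + 1L]; pos <- pos + 2L
  }
  vnames <- c(it$name, covs)
  R <- diag(1, nv); dimnames(R) <- list(vnames, vnames)
  pairsm <- utils::combn(nv, 2)
  R[cbind(pairsm[1, ], pairsm[2, ])] <- svec[pos:(pos + ncol(pairsm) - 1L)]
  R[cbind(pairsm[2, ], pairsm[1, ])] <- R[cbind(pairsm[1, ], pairsm[2, ])]
  list(thresholds = thresholds, means = means, vars = vars, R = R)
}

# Generating parameter values of a simulation configuration, in the form
# model_implied_moments() expects; the shared oracle tying the generator and
# the model-implied moments together.  Continuous loadings/intercepts are on
# the observed 0-10 scale.
config_values <- function(cfg) {
  lam <- cfg$lambda
  psi <- c(); nu <- c()
  comm <- rowSums((lam %*% cfg$phi) * lam)
  for (j in which(cfg$items$type == "continuous")) {
    nm <- cfg$items$name[j]
    cc <- cfg$continuous[cfg$continuous$name == nm, ]
    lam[nm, ] <- lam[nm, ] * cc$sd
    psi[nm] <- cc$sd^2 * (1 - comm[nm])
    nu[nm] <- cc$intercept
  }
  # residual covariances on the standardised scale translate to the raw
  # scale by the product of the items' sds (1 for ordinal items)
  sds <- stats::setNames(rep(1, nrow(cfg$items)), cfg$items$name)
  for (nm in cfg$continuous$name)
    sds[nm] <- cfg$continuous$sd[cfg$continuous$name == nm]
  rcov <- cfg$resid_pairs$value * sds[cfg$resid_pairs$a] * sds[cfg$resid_pairs$b]
  tau <- cfg$thresholds
  list(lambda = lam, phi = cfg$phi, rcov = unname(rcov), tau = tau,
       nu = nu, psi = psi)
}

# ---- serialization ----------------------------------------------------------

#' Serialize / deserialize a model specification
#'
#' Lossless structured-text (YAML) representation of a
#' \code{dualfactor_model}.
#'
#' @param spec A \code{dualfactor_model}.
#' @param path File path.
#' @return \code{read_model} returns the \code{dualfactor_model}.
#' @export
write_model <- function(spec, path) {
  yaml::write_yaml(list(
    kind = spec$kind,
    reference = spec$reference,
    items = lapply(seq_len(nrow(spec$items)), function(i) as.list(spec$items[i, ])),
    factors = lapply(seq_len(nrow(spec$factors)), function(i) as.list(spec$factors[i, ])),
    lambda = apply(spec$lambda, 1, function(r) colnames(spec$lambda)[r],
                   simplify = FALSE),
    phi_free = apply(spec$phi_free, 1, function(r) colnames(spec$phi_free)[r],
                     simplify = FALSE),
    resid_pairs = lapply(seq_len(nrow(spec$resid_pairs)),
                         function(i) as.list(spec$resid_pairs[i, ])),
    covariates = spec$covariates
  ), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  y <- yaml::read_yaml(path)
  items <- do.call(rbind, lapply(y$items, as.data.frame))
  factors <- do.call(rbind, lapply(y$factors, function(f) {
    f$domain <- if (is.null(f$domain)) NA_character_ else f$domain
    as.data.frame(f)
  }))
  fnames <- factors$name
  lambda <- matrix(FALSE, nrow(items), length(fnames),
                   dimnames = list(items$name, fnames))
  for (nm in names(y$lambda)) lambda[nm, unlist(y$lambda[[nm]])] <- TRUE
  phi_free <- matrix(FALSE, length(fnames), length(fnames),
                     dimnames = list(fnames, fnames))
  for (nm in names(y$phi_free))
    if (length(y$phi_free[[nm]])) phi_free[nm, unlist(y$phi_free[[nm]])] <- TRUE
  rp <- if (length(y$resid_pairs))
    do.call(rbind, lapply(y$resid_pairs, as.data.frame))
  else data.frame(a = character(0), b = character(0))
  structure(list(kind = y$kind, items = items, factors = factors,
                 lambda = lambda, phi_free = phi_free, resid_pairs = rp,
                 reference = y$reference,
                 covariates = if (length(y$covariates)) unlist(y$covariates) else character(0)),
            class = "dualfactor_model")
}
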