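# Three-step multigroup measurement-invariance testing for mixed
# ordinal/continuous models (delta-parameterised categorical scheme):
#   1. per-group baseline fits;
#   2. configural model: same structure, all loadings/thresholds/intercepts
#      free per group, scale parameters fixed at 1 and factor means at 0 in
#      both groups;
#   3. scalar model: loadings and thresholds/intercepts equated in tandem,
#      group-2 factor means and ordinal scale parameters freed;
# followed, when scalar invariance is rejected by the scaled difference
# test, by an item-level partial-invariance search.

#' Three-step measurement-invariance sequence
#'
#' @param spec A single-group \code{dualfactor_model}.
#' @param data Item-response data frame with the binary grouping column.
#' @param group_var Name of the binary grouping column.
#' @param level Significance level for the invariance decisions
#'   (default .05).
#' @param max_free Cap on the number of items freed by the
#'   partial-invariance search.
#' @param min_group_n Minimum rows per group.
#' @return An object of class \code{dualfactor_invariance}: per-group
#'   baselines, configural and scalar fits, the scaled difference tests,
#'   freed items with their modification-index trail, applied fixes, and
#'   the verdict (\code{"full"}, \code{"partial"} or \code{"rejected"}).
#' @export
invariance_sequence <- function(spec, data, group_var, level = 0.05,
                                max_free = 5L, min_group_n = 100L) {
  g <- data[[group_var]]
  if (is.null(g)) stop("grouping column not found: ", group_var)
  vals <- sort(unique(stats::na.omit(g)))
  if (length(vals) != 2) stop("grouping variable must be binary")
  d1 <- data[!is.na(g) & g == vals[1], , drop = FALSE]
  d2 <- data[!is.na(g) & g == vals[2], , drop = FALSE]
  if (nrow(d1) < min_group_n || nrow(d2) < min_group_n)
    stop("a group has fewer than ", min_group_n, " rows")
  info <- attr(data, "items")
  info <- info[match(spec$items$name, info$name), ]
  mm1 <- mixed_moments(d1, info)
  mm2 <- mixed_moments(d2, info)

  baseline1 <- dwls_fit(spec, moments = mm1)
  baseline2 <- dwls_fit(spec, moments = mm2)
  configural <- dwls_fit(spec, group_moments = list(mm1, mm2),
                         groups = list(level = "configural",
                                       freed = character(0)))
  scalar <- dwls_fit(spec, group_moments = list(mm1, mm2),
                     groups = list(level = "scalar", freed = character(0)))
  test <- scaled_difference(scalar, configural)

  freed <- character(0); trail <- NULL
  verdict <- "full"
  fixes <- list()
  if (test$p < level) {
    search <- partial_invariance_search(spec, list(mm1, mm2), configural,
                                        scalar, level = level,
                                        max_free = max_free)
    freed <- search$freed
    trail <- search$trail
    scalar <- search$fit
    test <- search$test
    verdict <- search$verdict
  }
  # negative-residual-variance policy on the retained scalar model
  if (!is.null(scalar$negative_resid)) {
    fixed <- fix_negative_residual(scalar, level = level)
    scalar <- fixed
    fixes <- attr(fixed, "applied_fixes")
  }
  structure(list(
    group_var = group_var, group_values = vals,
    baseline = list(baseline1, baseline2),
    configural = configural, scalar = scalar, test = test,
    freed = freed, trail = trail, verdict = verdict,
    applied_fixes = fixes, level = level),
    class = "dualfactor_invariance")
}

#' @export
print.dualfactor_invariance <- function(x, ...) {
  cat("Measurement invariance over", x$group_var, "\n")
  row <- function(label, f)
    cat(sprintf("  %-22s chi2 = %8.3f (df = %3d)  RMSEA = %.3f  CFI = %.3f\n",
                label, f$chisq, f$df, f$fit_indices$rmsea, f$fit_indices$cfi))
  row(paste0("baseline (", x$group_values[1], ")"), x$baseline[[1]])
  row(paste0("baseline (", x$group_values[2], ")"), x$baseline[[2]])
  row("configural", x$configural)
  row(if (length(x$freed)) paste0("scalar (", paste(x$freed, collapse = "/"),
                                  " free)") else "scalar", x$scalar)
  cat(sprintf("  difference test: %.3f (df = %d), p = %.3f\n",
              x$test$stat, x$test$df, x$test$p))
  cat("  verdict:", x$verdict, "invariance\n")
  if (length(x$applied_fixes))
    cat("  applied fixes:", vapply(x$applied_fixes, function(f)
      paste0("residual variance of ", f$item, " (group ", f$group,
             ") fixed to 0"), ""), "\n")
  invisible(x)
}

#' Partial-invariance search
#'
#' Iteratively frees the loading + threshold (or intercept) block of the
#' constrained item with the largest block modification index (robust score
#' test of the item's group-2 deviations; ties broken towards the lower item
#' index), refits the scalar model, and stops when the scaled difference
#' against the configural model is non-significant or the freed-item cap is
#' hit.
#'
#' @param spec Model specification.
#' @param mm_list Two-group list of \code{mixed_moments}.
#' @param configural,scalar The configural and (rejected) scalar fits.
#' @param level Significance level.
#' @param max_free Freed-item cap.
#' @return List with \code{freed}, \code{trail} (data frame of freeing
#'   steps), the final \code{fit}, final \code{test} and \code{verdict}.
#' @export
partial_invariance_search <- function(spec, mm_list, configural, scalar,
                                      level = 0.05, max_free = 5L) {
  freed <- character(0)
  trail <- NULL
  fit <- scalar
  test <- scaled_difference(fit, configural)
  while (test$p < level && length(freed) < max_free) {
    cand <- setdiff(spec$items$name, freed)
    mi <- vapply(cand, function(nm) {
      st <- item_block_score(fit, nm)
      if (is.null(st)) NA_real_ else st$mi
    }, 0)
    if (all(is.na(mi))) break
    best <- cand[which.max(round(mi, 8))]   # ties -> first (lower item index)
    freed <- c(freed, best)
    trail <- rbind(trail, data.frame(item = best, mi = mi[[best]],
                                     p_before = test$p))
    fit <- dwls_fit(spec, group_moments = mm_list,
                    groups = list(level = "scalar", freed = freed))
    test <- scaled_difference(fit, configural)
  }
  verdict <- if (test$p >= level) "partial" else "rejected"
  list(freed = freed, trail = trail, fit = fit, test = test,
       verdict = verdict)
}

# Block modification index for freeing one item's cross-group equality
# constraints: numeric Jacobian columns of the group-2 deviations of the
# item's loadings and thresholds/intercept, score-tested jointly.
item_block_score <- function(fit, item) {
  ptab <- fit$ptab
  rows <- which(ptab$group == 2L & !is.na(ptab$item) & ptab$item == item &
                  ptab$type %in% c("lambda", "tau", "nu") & !is.na(ptab$eq))
  if (!length(rows)) return(NULL)
  spec <- fit$spec
  fn <- compile_implied(spec, ptab)
  h <- 1e-4
  per_group <- fit$nstat / fit$ngroups
  dcols <- vapply(rows, function(r) {
    vp <- ptab$value; vm <- ptab$value
    vp[r] <- vp[r] + h; vm[r] <- vm[r] - h
    d <- numeric(fit$nstat)
    for (g in 1:2) {
      sp <- fn(vp, g)$stats; sm <- fn(vm, g)$stats
      d[(g - 1) * per_group + seq_len(per_group)] <- (sp - sm) / (2 * h)
    }
    d
  }, numeric(fit$nstat))
  score_test(fit, dcols)
}

#' Negative residual-variance policy
#'
#' When a fit contains a negative continuous residual-variance estimate
#' that is non-significant at \code{level}, the model is refitted with that
#' variance fixed to zero and the fix recorded (attribute
#' \code{"applied_fixes"}); a significant negative variance is a model
#' misspecification signal and raises an error.  Fits without negative
#' variances pass through unchanged.
#'
#' @param fit A \code{dualfactor_fit} (DWLS path).
#' @param level Significance level for the non-significance requirement.
#' @return The (possibly refitted) \code{dualfactor_fit}.
#' @export
fix_negative_residual <- function(fit, level = 0.05) {
  nr <- fit$negative_resid
  if (is.null(nr) || nrow(nr) == 0) return(fit)
  sig <- nr[nr$p <= level, , drop = FALSE]
  if (nrow(sig))
    stop("significant negative residual variance for ",
         paste(sig$item, collapse = ", "),
         " (p = ", paste(signif(sig$p, 3), collapse = ", "),
         "): model misspecification")
  constraints <- lapply(seq_len(nrow(nr)), function(i)
    list(type = "psi", item = nr$item[i], group = nr$group[i], value = 0))
  refit <- dwls_fit(fit$spec,
                    moments = if (fit$ngroups == 1) fit$moments[[1]] else NULL,
                    group_moments = if (fit$ngroups > 1) fit$moments else NULL,
                    groups = fit$groups, constraints = constraints)
  attr(refit, "applied_fixes") <- lapply(seq_len(nrow(nr)), function(i)
    list(item = nr$item[i], group = nr$group[i], fixed = 0,
         estimate = nr$value[i], p = nr$p[i]))
  refit
}

#' Latent-factor associations with a binary covariate
#'
#' Extends the specification with regressions of every factor on one binary
#' covariate (a MIMIC structure, one covariate per run) and fits it by DWLS
#' with the covariate included in the statistic vector as an exogenous
#' observed variable.  Reports raw and standardised regression coefficients
#' with sandwich standard errors.
#'
#' @param spec A single-group \code{dualfactor_model}.
#' @param data Item-response data frame containing the covariate column.
#' @param covariate Covariate column name (binary).
#' @param level Significance level for the flag.
#' @return Data frame: factor, estimate, se, std (standardised coefficient),
#'   z, p, significant; the fit is attached as attribute \code{"fit"}.
#' @export
covariate_association <- function(spec, data, covariate, level = 0.05) {
  x <- data[[covariate]]
  if (is.null(x)) stop("covariate column not found: ", covariate)
  if (stats::var(x, na.rm = TRUE) == 0) stop("covariate is constant")
  spec$covariates <- covariate
  fit <- dwls_fit(spec, data = data)
  fnames <- colnames(spec$lambda)
  est <- fit$estimates; se <- fit$se
  out <- NULL
  vx <- est[[paste0("cov_var.", covariate)]]
  for (f in fnames) {
    nm <- paste0("gamma.", covariate, ".", f)
    gam <- est[[nm]]; s <- se[[nm]]
    sd_eta <- sqrt(1 + gam^2 * vx)
    std <- gam * sqrt(vx) / sd_eta
    z <- gam / s
    out <- rbind(out, data.frame(
      factor = f, covariate = covariate, estimate = gam, se = s, std = std,
      z = z, p = 2 * stats::pnorm(-abs(z)),
      significant = 2 * stats::pnorm(-abs(z)) < level))
  }
  rownames(out) <- NULL
  attr(out, "fit") <- fit
  out
}
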