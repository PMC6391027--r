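# S3 methods for fitted models.

#' @export
print.dualfactor_fit <- function(x, ...) {
  cat("DWLS" [x$method == "dwls"], if (x$method == "ml") "ML",
      "factor-model fit:", x$spec$kind, "model,",
      nrow(x$spec$items), "items, n =", x$n,
      if (x$ngroups > 1) paste0("(", x$ngroups, " groups, ",
                                x$groups$level, ")"), "\n")
  cat(sprintf("chi-square = %.3f (df = %d), p %s\n", x$chisq, x$df,
              format.pval(x$pvalue, digits = 3)))
  fi <- x$fit_indices
  cat(sprintf("RMSEA = %.3f (90%% CI %.3f, %.3f), CFI = %.3f, TLI = %.3f\n",
              fi$rmsea, fi$rmsea_ci[1], fi$rmsea_ci[2], fi$cfi, fi$tli))
  if (!is.null(x$heywood) && length(x$heywood))
    cat("Heywood case(s):", paste(unique(x$heywood), collapse = ", "), "\n")
  if (!is.null(x$negative_resid))
    cat("negative residual variance(s):",
        paste(x$negative_resid$item, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.dualfactor_fit <- function(object, ...) {
  z <- object$estimates / ifelse(object$se > 0, object$se, NA)
  tab <- data.frame(estimate = object$estimates, se = object$se, z = z,
                    p = 2 * stats::pnorm(-abs(z)))
  out <- list(fit = object, parameters = tab)
  class(out) <- "summary.dualfactor_fit"
  out
}

#' @export
print.summary.dualfactor_fit <- function(x, ...) {
  print(x$fit)
  cat("\nParameter estimates:\n")
  print(round(x$parameters, 4))
  invisible(x)
}

#' @export
coef.dualfactor_fit <- function(object, ...) object$estimates

#' @export
vcov.dualfactor_fit <- function(object, ...) object$vcov

#' @export
fitted.dualfactor_fit <- function(object, ...) {
  if (object$method == "dwls") object$implied else object$build_sigma(object$estimates)
}

#' @export
residuals.dualfactor_fit <- function(object, ...) {
  if (object$method == "dwls") object$residuals
  else object$S - object$build_sigma(object$estimates)
}

#' Standardised loading matrix of a fitted model
#'
#' Loadings rescaled to the correlation metric (unit total variance per
#' item), as used by the dimensionality indices.
#'
#' @param fit A \code{dualfactor_fit}.
#' @param group Group number (multigroup fits).
#' @return Numeric matrix, items x factors.
#' @export
standardized_loadings <- function(fit, group = 1L) {
  spec <- fit$spec
  it <- spec$items
  if (fit$method == "ml") {
    L <- matrix(0, nrow(it), ncol(spec$lambda), dimnames = dimnames(spec$lambda))
    L[spec$lambda] <- fit$estimates[seq_len(sum(spec$lambda))]
    Sig <- fit$build_sigma(fit$estimates)
    return(L / sqrt(diag(Sig)))
  }
  pg <- fit$ptab[fit$ptab$group == group, ]
  lrows <- pg[pg$type == "lambda", ]
  L <- matrix(0, nrow(it), ncol(spec$lambda), dimnames = dimnames(spec$lambda))
  L[cbind(match(lrows$item, it$name),
          match(lrows$fac, colnames(spec$lambda)))] <- lrows$value
  v <- implied_total_vars(fit)[[group]]
  L / sqrt(v)
}

#' Factor correlation estimates of a correlated-factors fit
#'
#' @param fit A \code{dualfactor_fit}.
#' @param group Group number.
#' @return Factor correlation matrix.
#' @export
factor_correlations <- function(fit, group = 1L) {
  spec <- fit$spec
  fnames <- colnames(spec$lambda)
  Phi <- diag(1, length(fnames))
  dimnames(Phi) <- list(fnames, fnames)
  pg <- fit$ptab[fit$ptab$group == group, ]
  prows <- pg[pg$type == "phi", ]
  for (r in seq_len(nrow(prows))) {
    ia <- match(prows$fac[r], fnames); ib <- match(prows$item2[r], fnames)
    Phi[ia, ib] <- Phi[ib, ia] <- prows$value[r]
  }
  Phi
}
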