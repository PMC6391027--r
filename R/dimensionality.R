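# Dimensionality indices for bifactor-family models: explained common
# variance (ECV), percent of uncontaminated correlations (PUC), the
# vanishing-specific-factor diagnostic, and the advisory unidimensionality
# rule (PUC > .80 and ECV > .60, strict).

#' Explained common variance
#'
#' Ratio of common variance attributable to the general factor:
#' \code{sum(lambda_g^2) / (sum(lambda_g^2) + sum(lambda_s^2))}, sums over
#' all items and specific factors, computed from completely standardised
#' loadings.
#'
#' @param general_loadings Numeric vector of general-factor loadings.
#' @param specific_loadings Numeric vector (or list of vectors) of
#'   specific-factor loadings.
#' @return ECV in [0, 1].
#' @export
explained_common_variance <- function(general_loadings, specific_loadings) {
  sg <- sum(general_loadings^2)
  ss <- sum(unlist(specific_loadings)^2)
  if (sg + ss <= 0) stop("all loadings are zero")
  sg / (sg + ss)
}

#' Percent of uncontaminated correlations
#'
#' Fraction of item pairs spanning different group factors:
#' \code{1 - sum(n_k (n_k - 1) / 2) / (p (p - 1) / 2)}.
#'
#' @param group_sizes Integer vector of group-factor item counts (>= 1).
#' @return PUC in [0, 1].
#' @examples
#' percent_uncontaminated(c(9, 6, 4))   # 114/171 = .667
#' @export
percent_uncontaminated <- function(group_sizes) {
  stopifnot(all(group_sizes >= 1), sum(group_sizes) >= 2)
  p <- sum(group_sizes)
  1 - sum(group_sizes * (group_sizes - 1) / 2) / (p * (p - 1) / 2)
}

#' Vanishing specific-factor diagnostic
#'
#' Flags a specific factor when the share of its loadings below
#' \code{loading_threshold} is at least \code{fraction} (strict inequality
#' on the loadings), or when its mean squared standardised loading falls
#' below \code{variance_threshold} -- the signature of a factor collapsing
#' after the general factor absorbs its covariance.
#'
#' @param fit A bifactor-family \code{dualfactor_fit}, or \code{NULL} when
#'   \code{loadings} is supplied directly.
#' @param loadings Optional named list of specific-factor loading vectors.
#' @param loading_threshold Loadings strictly below this count as low
#'   (default .3).
#' @param fraction Minimum share of low loadings to flag (default .5).
#' @param variance_threshold Mean-squared-loading floor (default .15).
#' @return Data frame per specific factor: flag, share of low loadings,
#'   mean squared loading, and the offending loadings as an attribute.
#' @export
vanishing_factor_diagnostic <- function(fit = NULL, loadings = NULL,
                                        loading_threshold = 0.3,
                                        fraction = 0.5,
                                        variance_threshold = 0.15) {
  if (is.null(loadings)) {
    spec <- fit$spec
    if (!any(spec$factors$kind == "specific"))
      stop("not a bifactor-family fit")
    L <- standardized_loadings(fit)
    loadings <- lapply(spec$factors$name[spec$factors$kind == "specific"],
                       function(f) {
      l <- L[, f]
      l[spec$lambda[, f]]
    })
    names(loadings) <- spec$factors$name[spec$factors$kind == "specific"]
  }
  out <- NULL; offending <- list()
  for (f in names(loadings)) {
    l <- abs(loadings[[f]])
    low <- l < loading_threshold
    msl <- mean(l^2)
    flag <- (mean(low) >= fraction) || (msl < variance_threshold)
    out <- rbind(out, data.frame(factor = f, flag = flag,
                                 low_share = mean(low), mean_sq_loading = msl))
    offending[[f]] <- loadings[[f]][low]
  }
  rownames(out) <- NULL
  attr(out, "offending") <- offending
  out
}

#' Advisory unidimensionality verdict
#'
#' \code{"consider unidimensional"} iff PUC > .80 and ECV > .60 (both
#' strict); otherwise \code{"multidimensional"}.  The verdict is advisory --
#' it never selects a model automatically.
#'
#' @param ecv,puc Indices in [0, 1].
#' @return List with \code{verdict}, \code{ecv}, \code{puc}.
#' @export
unidimensionality_decision <- function(ecv, puc) {
  stopifnot(ecv >= 0, ecv <= 1, puc >= 0, puc <= 1)
  verdict <- if (puc > 0.80 && ecv > 0.60) "consider unidimensional"
  else "multidimensional"
  list(verdict = verdict, ecv = ecv, puc = puc)
}

#' Dimensionality report for a bifactor-family fit
#'
#' ECV from the standardised loadings, PUC from the domain group sizes, the
#' vanishing-factor diagnostic, and the advisory unidimensionality verdict.
#'
#' @param fit A bifactor \code{dualfactor_fit}.
#' @param ... Passed to [vanishing_factor_diagnostic()].
#' @return List with \code{ecv}, \code{puc}, \code{specific_factors},
#'   \code{decision}.
#' @export
dimensionality_report <- function(fit, ...) {
  spec <- fit$spec
  if (!("general" %in% spec$factors$name))
    stop("dimensionality indices require a bifactor-family fit")
  L <- standardized_loadings(fit)
  gl <- L[, "general"]
  snames <- spec$factors$name[spec$factors$kind == "specific"]
  sl <- lapply(snames, function(f) L[spec$lambda[, f], f])
  ecv <- explained_common_variance(gl, sl)
  puc <- percent_uncontaminated(as.integer(table(spec$items$domain)))
  diag <- vanishing_factor_diagnostic(fit, ...)
  list(ecv = ecv, puc = puc, specific_factors = diag,
       decision = unidimensionality_decision(ecv, puc))
}
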