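# Audit serialisation: moments and fit objects as structured text (JSON),
# so every statistic entering or leaving the estimator can be inspected and
# a saved moments object can be re-fitted without the raw data.

#' Write / read a moments object
#'
#' Serialises a \code{mixed_moments} object (thresholds, means, variances,
#' correlation matrix, statistic ordering, asymptotic covariance, n) as
#' JSON.  The reader reconstructs a fully usable object: models can be
#' fitted to it directly.
#'
#' @param mm A \code{mixed_moments} object.
#' @param path File path.
#' @return \code{read_moments} returns the \code{mixed_moments} object.
#' @export
write_moments <- function(mm, path) {
  jsonlite::write_json(list(
    items = mm$items, thresholds = mm$thresholds,
    means = as.list(mm$means), vars = as.list(mm$vars),
    R = mm$R, index = mm$index, n = mm$n, gamma = mm$gamma,
    boundary_pairs = mm$boundary_pairs
  ), path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_moments
#' @export
read_moments <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  items <- as.data.frame(x$items)
  nm <- items$name
  R <- x$R
  dimnames(R) <- list(nm, nm)
  gamma <- x$gamma
  mm <- moments_from_blocks(
    items,
    thresholds = lapply(x$thresholds, as.numeric),
    means = unlist(x$means), vars = unlist(x$vars),
    R = R, n = x$n, gamma = gamma)
  mm$boundary_pairs <- x$boundary_pairs
  mm
}

#' Write a fitted model as an audit record
#'
#' JSON record of a \code{dualfactor_fit}: the parameter table (name,
#' estimate, standard error, z), the fit block (discrepancy, test statistic,
#' df, p, indices, convergence), and optionally a modification-index table.
#'
#' @param fit A \code{dualfactor_fit}.
#' @param path File path.
#' @param mi Optional modification-index data frame to embed.
#' @return \code{read_fit} returns the parsed record (a list).
#' @export
write_fit <- function(fit, path, mi = NULL) {
  z <- fit$estimates / ifelse(fit$se > 0, fit$se, NA)
  rec <- list(
    model = list(kind = fit$spec$kind, reference = fit$spec$reference,
                 items = fit$spec$items$name, method = fit$method,
                 ngroups = fit$ngroups),
    parameters = data.frame(name = names(fit$estimates),
                            estimate = unname(fit$estimates),
                            se = unname(fit$se), z = unname(z)),
    fit = list(Fmin = fit$Fmin, chisq = fit$chisq, df = fit$df,
               p = fit$pvalue, n = fit$n,
               rmsea = fit$fit_indices$rmsea,
               rmsea_ci = fit$fit_indices$rmsea_ci,
               cfi = fit$fit_indices$cfi, tli = fit$fit_indices$tli,
               converged = fit$converged),
    negative_resid = fit$negative_resid,
    heywood = fit$heywood)
  if (!is.null(mi)) rec$modification_indices <- mi
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
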