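# End-to-end analysis pipeline: instrument-level CFAs with
# modification-index screening of residual pairs, reliability, descriptive
# statistics, the four competing structures (correlated factors, classical
# bifactor, two S-1 variants) with scaled difference tests, dimensionality
# indices, measurement invariance over gender and income, and latent
# covariate associations.

#' Table-style descriptive statistics
#'
#' Per-scale sum scores (computed on rows complete for that scale), their
#' means, SDs and ranges, and the Pearson correlation matrix of the sum
#' scores with the binary covariates.
#'
#' @param data Item-response data frame with item metadata.
#' @return List with \code{scales} (data frame) and \code{correlations}.
#' @export
descriptives <- function(data) {
  info <- item_info(data)
  domains <- unique(info$domain)
  sums <- list()
  tab <- NULL
  for (d in domains) {
    items <- info$name[info$domain == d]
    X <- as.matrix(data[items])
    complete <- stats::complete.cases(X)
    sc <- rep(NA_real_, nrow(data))
    sc[complete] <- rowSums(X[complete, , drop = FALSE])
    sums[[d]] <- sc
    tab <- rbind(tab, data.frame(
      scale = d, items = length(items), n = sum(complete),
      mean = mean(sc, na.rm = TRUE), sd = stats::sd(sc, na.rm = TRUE),
      min = min(sc, na.rm = TRUE), max = max(sc, na.rm = TRUE)))
  }
  M <- cbind(do.call(cbind, sums), gender = data$gender, income = data$income)
  list(scales = tab,
       correlations = stats::cor(M, use = "pairwise.complete.obs"))
}

default_pair_whitelist <- function() {
  data.frame(a = c("int1", "int5", "int7", "wb1"),
             b = c("int3", "int6", "int8", "wb3"),
             stringsAsFactors = FALSE)
}

# Instrument-level CFA with modification-index screening: fit without
# residual pairs, flag whitelisted candidates whose MI exceeds the .99
# chi-square(1) quantile, refit with the retained pairs.
instrument_cfa <- function(data, info, domains, whitelist,
                           mi_cutoff = stats::qchisq(0.99, 1)) {
  items <- info[info$domain %in% domains, , drop = FALSE]
  spec0 <- cfa_model("instrument", items)
  fit0 <- dwls_fit(spec0, data = data)
  mi <- if (fit0$method == "dwls") modification_indices(fit0)
  else ml_modification_indices(fit0)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  wl <- key(whitelist$a, whitelist$b)
  flagged <- mi[key(mi$a, mi$b) %in% wl & mi$mi > mi_cutoff, , drop = FALSE]
  retained <- flagged[, c("a", "b")]
  spec1 <- cfa_model("instrument", items, residual_pairs = retained)
  fit1 <- if (nrow(retained)) dwls_fit(spec1, data = data) else fit0
  list(initial = fit0, final = fit1, mi = mi, retained = retained)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: descriptives, subscale reliability, instrument-level
#' CFAs with modification-index-supported residual pairs (screened against a
#' whitelist of conceptually-overlapping item pairs), the four competing
#' latent structures with scaled difference tests against the bifactor
#' solution, dimensionality indices on the bifactor fit, measurement
#' invariance over the binary covariates, and latent covariate associations
#' on models purged of non-invariant items.  Deterministic given
#' \code{(data | config, seed)}.
#'
#' @param data Item-response table; when \code{NULL}, simulated from
#'   \code{config} with \code{seed}.
#' @param config An \code{mh_config} (used when \code{data} is NULL and for
#'   item grouping).
#' @param seed Simulation seed.
#' @param stages Character subset of
#'   \code{c("descriptives", "reliability", "instruments", "models",
#'   "dimensionality", "invariance", "associations")}.
#' @param invariance_models Model labels to carry through invariance and
#'   association testing (subset of \code{c("correlated",
#'   "s1_internalising")}).
#' @param covariates Binary covariates to test (default gender and income).
#' @param whitelist Residual-pair whitelist for the instrument stage.
#' @param level Significance level for invariance decisions.
#' @return An object of class \code{dualfactor_report}.
#' @export
mh_pipeline <- function(data = NULL, config = default_mh_config(), seed = 1L,
                        stages = c("descriptives", "reliability",
                                   "instruments", "models", "dimensionality",
                                   "invariance", "associations"),
                        invariance_models = c("correlated",
                                              "s1_internalising"),
                        covariates = c("gender", "income"),
                        whitelist = default_pair_whitelist(),
                        level = 0.05) {
  if (is.null(data)) data <- simulate_mh(config, seed = seed)
  info <- item_info(data)
  report <- list(provenance = list(
    seed = seed, n = nrow(data),
    config_hash = config_hash(config),
    package_version = as.character(utils::packageVersion("dualfactor"))))

  if ("descriptives" %in% stages)
    report$descriptives <- descriptives(data)

  if ("reliability" %in% stages) {
    report$reliability <- lapply(
      split(info$name, info$domain)[unique(info$domain)],
      function(items) scale_reliability(data, items))
  }

  pairs_final <- whitelist
  if ("instruments" %in% stages) {
    symptom_domains <- unique(info$domain[info$type == "ordinal"])
    wb_domains <- unique(info$domain[info$type == "continuous"])
    mms <- instrument_cfa(data, info, symptom_domains, whitelist)
    cors <- instrument_cfa(data, info, wb_domains, whitelist)
    report$instruments <- list(symptoms = mms, wellbeing = cors)
    pairs_final <- rbind(mms$retained, cors$retained)
  }

  specs <- list(
    correlated = cfa_model("correlated", info, pairs_final),
    bifactor = cfa_model("bifactor", info, pairs_final),
    s1_wellbeing = cfa_model("s1", info, pairs_final,
                             reference = "wellbeing"),
    s1_internalising = cfa_model("s1", info, pairs_final,
                                 reference = "internalising"))

  if (any(c("models", "dimensionality", "invariance", "associations")
          %in% stages)) {
    mm <- mixed_moments(data, info)
    fits <- lapply(specs, dwls_fit, moments = mm)
    mt <- NULL
    for (nm in names(fits)) {
      f <- fits[[nm]]
      diff <- if (nm == "bifactor") list(stat = NA, df = NA, p = NA)
      else scaled_difference(f, fits$bifactor)
      mt <- rbind(mt, data.frame(
        model = nm, chisq = f$chisq, df = f$df,
        rmsea = f$fit_indices$rmsea,
        rmsea_lo = f$fit_indices$rmsea_ci[1],
        rmsea_hi = f$fit_indices$rmsea_ci[2],
        cfi = f$fit_indices$cfi, tli = f$fit_indices$tli,
        diff_chisq = diff$stat, diff_df = diff$df, diff_p = diff$p))
    }
    report$models <- list(table = mt, fits = fits)
  }

  if ("dimensionality" %in% stages)
    report$dimensionality <- dimensionality_report(report$models$fits$bifactor)

  freed_union <- character(0)
  if ("invariance" %in% stages) {
    report$invariance <- list()
    for (mname in invariance_models) {
      for (cv in covariates) {
        inv <- invariance_sequence(specs[[mname]], data, cv, level = level)
        report$invariance[[paste(mname, cv, sep = ".")]] <- inv
        freed_union <- union(freed_union, inv$freed)
      }
    }
  }

  if ("associations" %in% stages) {
    report$associations <- list()
    for (mname in invariance_models) {
      spec_red <- if (length(freed_union))
        drop_items(specs[[mname]], freed_union) else specs[[mname]]
      for (cv in covariates) {
        report$associations[[paste(mname, cv, sep = ".")]] <-
          covariate_association(spec_red, data, cv, level = level)
      }
    }
    report$freed_items <- freed_union
  }

  class(report) <- "dualfactor_report"
  report
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  unname(tools::md5sum(f))
}

#' @export
print.dualfactor_report <- function(x, digits = 3, ...) {
  cat("== Analysis report (seed", x$provenance$seed, ", n =",
      x$provenance$n, ") ==\n")
  if (!is.null(x$descriptives)) {
    cat("\nScale sum scores:\n")
    print(cbind(x$descriptives$scales[1:3],
                round(x$descriptives$scales[4:7], digits)))
  }
  if (!is.null(x$reliability)) {
    cat("\nReliability (alpha):",
        paste(names(x$reliability),
              round(vapply(x$reliability, `[[`, 0, "alpha"), digits),
              collapse = ", "), "\n")
  }
  if (!is.null(x$models)) {
    cat("\nModel comparison:\n")
    mt <- x$models$table
    mt[-1] <- round(mt[-1], digits)
    print(mt, row.names = FALSE)
  }
  if (!is.null(x$dimensionality)) {
    d <- x$dimensionality
    cat(sprintf("\nDimensionality: ECV = %.3f, PUC = %.3f -> %s\n",
                d$ecv, d$puc, d$decision$verdict))
    flagged <- d$specific_factors$factor[d$specific_factors$flag]
    if (length(flagged))
      cat("vanishing specific factor(s):", paste(flagged, collapse = ", "),
          "\n")
  }
  if (!is.null(x$invariance)) {
    cat("\nInvariance verdicts:\n")
    for (nm in names(x$invariance))
      cat(sprintf("  %-32s %s (p = %.3f)%s\n", nm, x$invariance[[nm]]$verdict,
                  x$invariance[[nm]]$test$p,
                  if (length(x$invariance[[nm]]$freed))
                    paste0("  freed: ",
                           paste(x$invariance[[nm]]$freed, collapse = ", "))
                  else ""))
  }
  if (!is.null(x$associations)) {
    cat("\nStandardised covariate associations:\n")
    for (nm in names(x$associations)) {
      a <- x$associations[[nm]]
      cat(sprintf("  %-32s %s\n", nm,
                  paste(a$factor, round(a$std, digits),
                        ifelse(a$significant, "*", ""), collapse = "  ")))
    }
  }
  invisible(x)
}

#' Machine-readable report
#'
#' Serialises the numeric content of a pipeline report to JSON.
#'
#' @param report A \code{dualfactor_report}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
report_json <- function(report, path) {
  x <- list(provenance = report$provenance)
  if (!is.null(report$descriptives))
    x$descriptives <- list(scales = report$descriptives$scales,
                           correlations = report$descriptives$correlations)
  if (!is.null(report$reliability))
    x$reliability <- lapply(report$reliability, function(r) r["alpha"])
  if (!is.null(report$models)) x$models <- report$models$table
  if (!is.null(report$dimensionality))
    x$dimensionality <- list(ecv = report$dimensionality$ecv,
                             puc = report$dimensionality$puc,
                             verdict = report$dimensionality$decision$verdict)
  if (!is.null(report$invariance))
    x$invariance <- lapply(report$invariance, function(i)
      list(verdict = i$verdict, freed = i$freed,
           diff_stat = i$test$stat, diff_df = i$test$df, diff_p = i$test$p))
  if (!is.null(report$associations))
    x$associations <- report$associations
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
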