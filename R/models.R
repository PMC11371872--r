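#' MTL imaging regions and their morphometry outcome columns
#'
#' Anterior/posterior hippocampus are measured by volume (with intracranial
#' volume as an additional covariate); entorhinal cortex, BA35, BA36 and
#' parahippocampal cortex by median thickness.
#'
#' @return Named character vector mapping region to outcome type
#'   (`"volume"` or `"thickness"`).
#' @export
imaging_regions <- function() {
  c(AH = "volume", PH = "volume", ERC = "thickness",
    BA35 = "thickness", BA36 = "thickness", PHC = "thickness")
}

#' Fit a standardized ROI-level pathology-morphometry model
#'
#' Ordinary least squares of a regional morphometry outcome (volume for
#' AH/PH, median thickness otherwise) on pathology burden measures plus
#' nuisance covariates (age at death, sex, MRI field strength, antemortem
#' interval; intracranial volume additionally for the volume outcomes).
#' The outcome and all continuous predictors are z-scored before fitting,
#' so pathology coefficients are standardized betas; binary covariates (sex,
#' field strength) enter as 0/1 and their coefficients are not interpreted
#' as standardized contrasts. Complete cases only (listwise deletion).
#'
#' One-sided p-values for the pathology contrasts test the negative
#' direction by default (`P(T <= t)`), reflecting the a priori expectation
#' that pathology burden is negatively associated with structure;
#' `one_sided = "positive"` or `"two_sided"` are available.
#'
#' @param data Data frame of subject records (see [generate_cohort()] for
#'   the column conventions).
#' @param region One of `names(imaging_regions())`.
#' @param pathology_predictors Character vector of pathology predictor
#'   columns (e.g. `c("tangles_q", "threads_q", "mtl_ptdp_sq")`).
#' @param covariates Nuisance covariate columns; defaults to age, sex,
#'   field strength and antemortem interval, with ICV appended automatically
#'   for the volume regions.
#' @param one_sided Direction of the one-sided test for pathology contrasts.
#' @return An object of class `roi_fit` with standardized coefficients,
#'   t-statistics, one-sided p-values for the pathology contrasts, residual
#'   degrees of freedom, adjusted R^2, AICc, BIC and residuals.
#' @export
fit_region_model <- function(data, region,
                             pathology_predictors,
                             covariates = c("age", "sex", "field_strength",
                                            "antemortem_interval"),
                             one_sided = c("negative", "positive",
                                           "two_sided")) {
  one_sided <- match.arg(one_sided)
  region <- match.arg(region, names(imaging_regions()))
  outcome <- region_outcome_column(region)
  if (imaging_regions()[[region]] == "volume" && !("icv" %in% covariates)) {
    covariates <- c(covariates, "icv")
  }
  binary_cols <- intersect(c("sex", "field_strength"), covariates)
  cols <- c(outcome, pathology_predictors, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  n <- nrow(d)
  p_design <- length(pathology_predictors) + length(covariates) + 1L
  if (n < p_design + 2L) {
    stop("too few complete cases (", n, ") for ", p_design, " parameters")
  }

  zscore <- function(x) (x - mean(x)) / stats::sd(x)
  for (col in setdiff(cols, binary_cols)) {
    if (stats::sd(d[[col]]) == 0) stop("zero variance in column ", col)
    d[[col]] <- zscore(d[[col]])
  }

  rhs <- paste(c(pathology_predictors, covariates), collapse = " + ")
  fml <- stats::as.formula(paste(outcome, "~", rhs))
  fit <- stats::lm(fml, data = d)
  qrr <- qr(fit)
  if (qrr$rank < p_design) {
    piv <- colnames(stats::model.matrix(fit))[qrr$pivot[(qrr$rank + 1L):p_design]]
    stop("rank-deficient design; collinear columns: ",
         paste(piv, collapse = ", "))
  }
  sm <- summary(fit)
  coefs <- sm$coefficients
  df_res <- fit$df.residual
  tvals <- coefs[pathology_predictors, "t value"]
  p_one <- switch(one_sided,
                  negative = stats::pt(tvals, df_res),
                  positive = stats::pt(tvals, df_res, lower.tail = FALSE),
                  two_sided = 2 * stats::pt(-abs(tvals), df_res))
  ic <- information_criteria(residuals = stats::residuals(fit),
                             n = n, n_coef = p_design)
  structure(
    list(region = region,
         outcome = outcome,
         coefficients = coefs[, "Estimate"],
         t_statistics = coefs[, "t value"],
         p_one_sided = stats::setNames(p_one, pathology_predictors),
         one_sided = one_sided,
         pathology_predictors = pathology_predictors,
         covariates = covariates,
         df_residual = df_res,
         n = n,
         r2_adj = sm$adj.r.squared,
         aicc = ic[["aicc"]],
         bic = ic[["bic"]],
         residuals = unname(stats::residuals(fit)),
         lm_fit = fit),
    class = "roi_fit"
  )
}

region_outcome_column <- function(region) {
  type <- imaging_regions()[[region]]
  paste0(tolower(region), if (type == "volume") "_vol" else "_thk")
}

#' @export
print.roi_fit <- function(x, digits = 3, ...) {
  cat(sprintf("ROI model: %s (%s), n = %d, residual df = %d\n",
              x$region, imaging_regions()[[x$region]], x$n, x$df_residual))
  cat(sprintf("  adj. R^2 = %.3f, AICc = %.2f, BIC = %.2f\n",
              x$r2_adj, x$aicc, x$bic))
  cat("  pathology contrasts (standardized beta, one-sided",
      x$one_sided, "p):\n")
  for (p in x$pathology_predictors) {
    cat(sprintf("    %-14s beta = %6.3f  t = %6.2f  p = %.3g\n",
                p, x$coefficients[[p]], x$t_statistics[[p]],
                x$p_one_sided[[p]]))
  }
  invisible(x)
}

#' @export
summary.roi_fit <- function(object, ...) {
  out <- data.frame(
    predictor = names(object$coefficients),
    beta = unname(object$coefficients),
    t = unname(object$t_statistics),
    row.names = NULL
  )
  out$p_one_sided <- NA_real_
  sel <- match(object$pathology_predictors, out$predictor)
  out$p_one_sided[sel] <- unname(object$p_one_sided)
  attr(out, "region") <- object$region
  attr(out, "n") <- object$n
  attr(out, "df_residual") <- object$df_residual
  out
}

#' @export
coef.roi_fit <- function(object, ...) object$coefficients

#' @export
residuals.roi_fit <- function(object, ...) object$residuals

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Familywise error rate (0 < alpha < 1).
#' @param m Number of comparisons (here, 6 MTL regions).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 6L) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / m
}

#' L1 prediction error of a fitted model
#'
#' Sum of absolute residuals.
#'
#' @param fit A `roi_fit`, an `lm`, or a numeric vector of residuals.
#' @return Scalar L1 norm of the residuals.
#' @export
prediction_error_l1 <- function(fit) {
  r <- if (is.numeric(fit)) fit else stats::residuals(fit)
  sum(abs(r))
}

#' Small-sample-corrected AIC and BIC from a Gaussian fit
#'
#' Computed from the residual sum of squares in the Gaussian log-likelihood
#' form with constant terms omitted:
#' `AIC = n log(RSS/n) + 2k`, `AICc = AIC + 2k(k+1)/(n-k-1)`,
#' `BIC = n log(RSS/n) + k log(n)`, where `k` counts the regression
#' coefficients (including the intercept) plus one for the error variance.
#' Because the constants are shared, differences between two models fitted
#' to identical data are unaffected by the omission.
#'
#' @param fit A `roi_fit` or `lm` object; alternatively supply `residuals`,
#'   `n` and `n_coef` directly.
#' @param residuals,n,n_coef Residual vector, sample size, and number of
#'   regression coefficients including the intercept.
#' @return Named numeric vector `c(aicc = ..., bic = ...)`; `aicc` is `NA`
#'   (with a warning) when `n <= k + 1`.
#' @export
information_criteria <- function(fit = NULL, residuals = NULL, n = NULL,
                                 n_coef = NULL) {
  if (!is.null(fit)) {
    residuals <- stats::residuals(fit)
    n <- length(residuals)
    n_coef <- if (inherits(fit, "roi_fit")) {
      length(fit$coefficients)
    } else {
      length(stats::coef(fit))
    }
  }
  rss <- sum(residuals^2)
  k <- n_coef + 1L  # + error variance
  aic <- n * log(rss / n) + 2 * k
  bic <- n * log(rss / n) + k * log(n)
  if (n <= k + 1L) {
    warning("AICc undefined for n <= k + 1")
    aicc <- NA_real_
  } else {
    aicc <- aic + 2 * k * (k + 1) / (n - k - 1)
  }
  c(aicc = aicc, bic = bic)
}

#' Compare quantitative and semi-quantitative pathology models
#'
#' Computes the differences (quantitative minus semi-quantitative) in
#' adjusted R^2, L1 prediction error, AICc and BIC between two non-nested
#' models of the same outcome on the same subjects. A positive difference in
#' adjusted R^2, and negative differences in prediction error, AICc and BIC,
#' favour the quantitative model. The evidence label grades `|dBIC|`:
#' greater than 2 is positive, greater than 6 strong, and greater than 10
#' very strong evidence for whichever model the sign favours.
#'
#' @param fit_quant,fit_semiquant `roi_fit` objects for the quantitative and
#'   semi-quantitative predictor sets; must share outcome and subjects.
#' @return An object of class `model_comparison`: list with `region`,
#'   `delta_r2_adj`, `delta_pred_error`, `delta_aicc`, `delta_bic`,
#'   `favours` (`"quantitative"`, `"semiquantitative"` or `"neither"`) and
#'   `evidence_label` in `{"none", "positive", "strong", "very_strong"}`.
#' @export
compare_models <- function(fit_quant, fit_semiquant) {
  stopifnot(inherits(fit_quant, "roi_fit"), inherits(fit_semiquant, "roi_fit"))
  if (!identical(fit_quant$outcome, fit_semiquant$outcome)) {
    stop("models have different outcomes")
  }
  if (fit_quant$n != fit_semiquant$n) {
    stop("models were fitted to different subject sets (n = ",
         fit_quant$n, " vs ", fit_semiquant$n, ")")
  }
  delta_bic <- fit_quant$bic - fit_semiquant$bic
  abs_bic <- abs(delta_bic)
  label <- if (abs_bic > 10) "very_strong" else if (abs_bic > 6) "strong"
           else if (abs_bic > 2) "positive" else "none"
  favours <- if (abs_bic <= 2) "neither"
             else if (delta_bic < 0) "quantitative" else "semiquantitative"
  structure(
    list(region = fit_quant$region,
         delta_r2_adj = fit_quant$r2_adj - fit_semiquant$r2_adj,
         delta_pred_error = prediction_error_l1(fit_quant) -
           prediction_error_l1(fit_semiquant),
         delta_aicc = fit_quant$aicc - fit_semiquant$aicc,
         delta_bic = delta_bic,
         favours = favours,
         evidence_label = label),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Model comparison (%s): quantitative - semi-quantitative\n",
              x$region))
  cat(sprintf("  dR2adj = %+.3f  dPredErr = %+.3f  dAICc = %+.2f  dBIC = %+.2f\n",
              x$delta_r2_adj, x$delta_pred_error, x$delta_aicc, x$delta_bic))
  cat(sprintf("  evidence: %s (favours %s)\n", x$evidence_label, x$favours))
  invisible(x)
}

#' Fit all six regional models in a cohort or staging subgroup
#'
#' Filters the cohort to the requested subgroup (whole cohort, advanced
#' ADNC = Braak stage V/VI, or LATE-NC = stage 1 or greater), fits the
#' standardized model for every imaging region, and flags contrasts passing
#' nominal `p < alpha` and the Bonferroni threshold `alpha / 6` separately.
#'
#' @param data Cohort data frame with `braak_stage` and `late_stage`
#'   columns.
#' @param pathology_predictors Passed to [fit_region_model()].
#' @param subgroup `"whole"`, `"advanced_adnc"` or `"late"`.
#' @param alpha Nominal significance level.
#' @param ... Further arguments to [fit_region_model()].
#' @return A list with `fits` (named list of `roi_fit`), `table` (long data
#'   frame: region, predictor, beta, t, p, significant, bonferroni) and
#'   `subgroup_n`. Regions with too few subjects are skipped with a warning.
#' @export
run_cohort_analyses <- function(data, pathology_predictors,
                                subgroup = c("whole", "advanced_adnc", "late"),
                                alpha = 0.05, ...) {
  subgroup <- match.arg(subgroup)
  d <- switch(subgroup,
              whole = data,
              advanced_adnc = data[!is.na(data$braak_stage) &
                                     data$braak_stage >= 5, , drop = FALSE],
              late = data[!is.na(data$late_stage) &
                            data$late_stage >= 1, , drop = FALSE])
  fits <- list()
  rows <- list()
  thresh <- bonferroni_threshold(alpha, length(imaging_regions()))
  for (region in names(imaging_regions())) {
    fit <- tryCatch(
      fit_region_model(d, region, pathology_predictors, ...),
      error = function(e) {
        warning("region ", region, " skipped: ", conditionMessage(e))
        NULL
      })
    if (is.null(fit)) next
    fits[[region]] <- fit
    rows[[region]] <- data.frame(
      region = region,
      predictor = fit$pathology_predictors,
      beta = unname(fit$coefficients[fit$pathology_predictors]),
      t = unname(fit$t_statistics[fit$pathology_predictors]),
      p_one_sided = unname(fit$p_one_sided),
      df_residual = fit$df_residual,
      significant = unname(fit$p_one_sided < alpha),
      bonferroni = unname(fit$p_one_sided < thresh),
      row.names = NULL)
  }
  list(fits = fits,
       table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       subgroup = subgroup,
       subgroup_n = nrow(d))
}
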