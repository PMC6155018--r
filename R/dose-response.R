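#' Langmuir occupancy
#'
#' Fraction of receptors occupied at ligand concentration `conc` with
#' dissociation constant `kd`: `conc / (conc + kd)`.
#'
#' @param conc Concentration (nM), `>= 0`.
#' @param kd Dissociation constant (nM), `> 0`.
#' @param complement If `TRUE`, return the unoccupied fraction
#'   `kd / (conc + kd)` (the drug-free, full-stroke fraction).
#' @return Fraction in \[0, 1\].
#' @export
langmuir_fraction <- function(conc, kd, complement = FALSE) {
  if (any(conc < 0) || kd <= 0) stop("langmuir_fraction: negative inputs")
  f <- conc / (conc + kd)
  if (complement) 1 - f else f
}

#' Three-parameter EC50 dose-response fit
#'
#' Least-squares fit of `y(c) = Max + (Min - Max) * c / (c + EC50)` (Hill
#' slope fixed at 1) to per-concentration summary statistics. Concentration
#' zero is handled exactly by the model (`y(0) = Max`); no log transform is
#' applied. The EC50 standard error comes from the fit covariance.
#'
#' @param conc Concentrations (nM); at least 4 values including 0 and a
#'   saturating one.
#' @param response Summary response per concentration (mean step, mean
#'   duration, mixture fraction, ...).
#' @param response_se Optional per-point standard errors; when given, points
#'   are weighted by `1/se^2`.
#' @return A `dose_response_fit` object: `min`, `max`, `ec50` (nM),
#'   `ec50_se`, `residual_ss`, `flagged` (TRUE when the dose-response model
#'   is not supported over a constant by AIC, e.g. constant response).
#' @export
fit_ec50 <- function(conc, response, response_se = NULL) {
  stopifnot(length(conc) == length(response), length(conc) >= 4L,
            any(conc == 0))
  w <- if (is.null(response_se)) rep(1, length(conc)) else 1 / response_se^2
  df <- data.frame(c = conc, y = response)
  start <- list(Max = response[which.min(conc)],
                Min = response[which.max(conc)],
                ec50 = stats::median(conc[conc > 0]))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ Max + (Min - Max) * c / (c + ec50),
                      data = df, start = start, weights = w,
                      lower = c(-Inf, -Inf, 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(fit)) stop("fit_ec50: model fit failed to converge")
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients["ec50", "Std. Error"],
                 error = function(e) NA_real_)
  rss <- sum(w * stats::resid(fit)^2)
  # AIC comparison against the constant model flags unidentifiable fits
  n <- length(conc)
  rss0 <- sum(w * (response - stats::weighted.mean(response, w))^2)
  aic_fit <- n * log(rss / n) + 2 * 4
  aic_const <- n * log(rss0 / n) + 2 * 2
  flagged <- !is.finite(se) || se > 1e3 * est[["ec50"]] ||
    aic_fit > aic_const ||
    diff(range(response)) < 1e-8 * (abs(mean(response)) + 1e-12)
  if (flagged) warning("fit_ec50: EC50 weakly identified (response ~ constant)")
  structure(list(min = est[["Min"]], max = est[["Max"]],
                 ec50 = est[["ec50"]], ec50_se = se,
                 residual_ss = rss, flagged = flagged),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("Dose-response fit: Max = %.3g, Min = %.3g, EC50 = %.3g nM (SE %.3g)\n",
              x$max, x$min, x$ec50, x$ec50_se))
  if (isTRUE(x$flagged)) cat("  warning: EC50 weakly identified\n")
  invisible(x)
}
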