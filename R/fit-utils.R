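#' Log-likelihood ratio test for nested fits
#'
#' Refers `2 * (logL_full - logL_nested)` to a chi-square distribution with
#' `df` degrees of freedom (Wilks), the number of extra parameters in the
#' full model. Both fits must be on identical data and weights.
#'
#' @param logL_nested,logL_full Log-likelihoods (numbers or fit objects with
#'   a `logL` element).
#' @param df Degrees-of-freedom difference.
#' @return List with `statistic` and `p`.
#' @export
llr_test <- function(logL_nested, logL_full, df = 1L) {
  ln <- if (is.list(logL_nested)) logL_nested$logL else logL_nested
  lf <- if (is.list(logL_full)) logL_full$logL else logL_full
  stat <- 2 * (lf - ln)
  if (stat < -1e-6) {
    stop("llr_test: full-model log-likelihood below nested (optimizer failure)")
  }
  stat <- max(stat, 0)
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  list(statistic = stat, p = p)
}

#' Percentile bootstrap confidence intervals for an arbitrary fit
#'
#' Resamples events with replacement within each molecule (preserving the
#' per-molecule weighting structure), refits, and returns the 2.5/97.5
#' percentiles of every numeric parameter the fit function reports. Refit
#' failures are dropped and counted; more than 10% failures sets a warning
#' status.
#'
#' @param fit_fun Function mapping a data frame to a fit; its result must be
#'   coercible to a numeric vector via `unlist` of numeric elements.
#' @param data Data frame of events; a `molecule_id` column (if present)
#'   defines the resampling strata.
#' @param n_boot Number of bootstrap rounds (>= 100).
#' @param seed Seed.
#' @return List with `ci` (matrix: rows 2.5%/97.5%), `n_failed`, `status`
#'   (`"ok"` or `"warning"`), `samples` (matrix of bootstrap estimates).
#' @export
bootstrap_ci <- function(fit_fun, data, n_boot = 200L, seed = 1L) {
  stopifnot(n_boot >= 100L)
  set.seed(seed)
  groups <- if ("molecule_id" %in% names(data)) {
    split(seq_len(nrow(data)), data$molecule_id)
  } else list(seq_len(nrow(data)))
  param_vec <- function(fit) {
    v <- unlist(fit[vapply(fit, is.numeric, logical(1))])
    v[is.finite(v) | is.na(v)]
  }
  point <- param_vec(fit_fun(data))
  out <- matrix(NA_real_, nrow = n_boot, ncol = length(point),
                dimnames = list(NULL, names(point)))
  failed <- 0L
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(groups, function(g) {
      g[sample.int(length(g), length(g), replace = TRUE)]
    }), use.names = FALSE)
    fit <- tryCatch(param_vec(fit_fun(data[idx, , drop = FALSE])),
                    error = function(e) NULL)
    if (is.null(fit) || length(fit) != length(point)) {
      failed <- failed + 1L
    } else {
      out[b, ] <- fit
    }
  }
  ok <- stats::complete.cases(out)
  ci <- apply(out[ok, , drop = FALSE], 2L,
              stats::quantile, probs = c(0.025, 0.975))
  list(ci = ci, n_failed = failed,
       status = if (failed > 0.1 * n_boot) "warning" else "ok",
       samples = out[ok, , drop = FALSE], point = point)
}

#' Least-squares fit of a single exponential plus a linear drift
#'
#' Fits `A * exp(-k * t) + m * t + c`, the standard form for stopped-flow
#' fluorescence transients where slow drift accumulates over the acquisition.
#' For a trial rate `k` the remaining parameters are linear, so the fit
#' profiles `k` by one-dimensional optimization over linear least squares.
#'
#' @param times Time points (s), at least 5.
#' @param signal Observed signal.
#' @return List with `amplitude`, `rate` (s^-1), `slope`, `offset`,
#'   `residual_ss`.
#' @export
fit_exp_plus_linear <- function(times, signal) {
  stopifnot(length(times) == length(signal), length(times) >= 5L)
  lin_fit <- function(k) {
    X <- cbind(exp(-k * times), times, 1)
    qr_ <- qr(X)
    if (qr_$rank < 3L) return(list(ss = Inf))
    beta <- qr.coef(qr_, signal)
    r <- signal - X %*% beta
    list(ss = sum(r^2), beta = beta)
  }
  span <- diff(range(times))
  opt <- stats::optimize(function(k) lin_fit(k)$ss,
                         interval = c(1e-6 / span, 1e3 / span))
  fit <- lin_fit(opt$minimum)
  if (!is.finite(fit$ss)) stop("fit_exp_plus_linear: rank-deficient design")
  list(amplitude = unname(fit$beta[1L]), rate = opt$minimum,
       slope = unname(fit$beta[2L]), offset = unname(fit$beta[3L]),
       residual_ss = fit$ss)
}
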