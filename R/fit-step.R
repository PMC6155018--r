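#' Global two-Gaussian mixture fit of step-size distributions
#'
#' Fits step amplitudes from several drug concentrations simultaneously with
#' a two-component Gaussian mixture in which the component means and
#' standard deviations are shared across conditions while the full-stroke
#' fraction varies per condition. Conditions contribute equally to the
#' likelihood and molecules contribute equally within a condition. Components
#' are labelled so `mean_full > mean_zero`. Conditions where a two-component
#' fit would not be justified on their own are still included: with heavily
#' overlapping components only the pooled, multi-condition likelihood
#' identifies the shared means.
#'
#' @param data Data frame with columns `step_nm`, `om_nM` and optionally
#'   `molecule_id`.
#' @param n_starts Number of extra jittered simplex starts beyond the
#'   deterministic moment-based starts.
#' @param shared_sd If `TRUE` the two components share one width:
#'   the model distinguishes the populations by their mean stroke size only,
#'   which is also what keeps the mixture identifiable when the component
#'   separation is below one width. `FALSE` frees the two widths.
#' @return A `gauss_mix_fit` object: `mean_full`, `mean_zero`, `sd_full`,
#'   `sd_zero` (nm), `fraction_full` (named per-condition), `logL`, `n`.
#' @export
fit_gauss_mix_global <- function(data, n_starts = 6L, shared_sd = FALSE) {
  stopifnot(all(c("step_nm", "om_nM") %in% names(data)))
  conds <- sort(unique(data$om_nM))
  if (length(conds) < 2L) stop("fit_gauss_mix_global: need >= 2 conditions")
  n <- nrow(data)
  w <- numeric(n)
  for (cc in conds) {
    sel <- data$om_nM == cc
    wc <- if ("molecule_id" %in% names(data)) {
      molecule_weights(data$molecule_id[sel])
    } else rep(1, sum(sel))
    w[sel] <- wc / sum(wc)
  }
  w <- w * n / sum(w)
  x <- data$step_nm
  cond_idx <- match(data$om_nM, conds)
  logLfun <- function(par) {
    m1 <- par[1L]; m2 <- par[2L]
    s1 <- exp(par[3L])
    s2 <- if (shared_sd) s1 else exp(par[4L])
    p <- stats::plogis(par[4L + cond_idx])
    f <- p * stats::dnorm(x, m1, s1) + (1 - p) * stats::dnorm(x, m2, s2)
    sum(w * log(pmax(f, 1e-300)))
  }
  # weighted EM with shared component parameters across conditions; the
  # simplex polish from the EM optimum guards against EM stalling on ridges
  em_fit <- function(m1, m2, s1, s2, p0, iter = 600L) {
    p <- rep(p0, length(conds))
    ll_old <- -Inf
    for (it in seq_len(iter)) {
      f1 <- stats::dnorm(x, m1, s1); f2 <- stats::dnorm(x, m2, s2)
      pc <- p[cond_idx]
      num <- pc * f1
      den <- pmax(num + (1 - pc) * f2, 1e-300)
      g <- num / den
      wg <- w * g; wng <- w * (1 - g)
      m1 <- sum(wg * x) / sum(wg); m2 <- sum(wng * x) / sum(wng)
      if (shared_sd) {
        s1 <- s2 <- sqrt((sum(wg * (x - m1)^2) + sum(wng * (x - m2)^2)) /
                           sum(w))
      } else {
        s1 <- sqrt(sum(wg * (x - m1)^2) / sum(wg))
        s2 <- sqrt(sum(wng * (x - m2)^2) / sum(wng))
      }
      s1 <- max(s1, 1e-3); s2 <- max(s2, 1e-3)
      p <- vapply(seq_along(conds), function(cc) {
        sel <- cond_idx == cc
        sum(w[sel] * g[sel]) / sum(w[sel])
      }, numeric(1))
      p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
      ll <- sum(w * log(pmax(p[cond_idx] * stats::dnorm(x, m1, s1) +
                               (1 - p[cond_idx]) * stats::dnorm(x, m2, s2),
                             1e-300)))
      if (is.finite(ll) && abs(ll - ll_old) < 1e-9) break
      ll_old <- ll
    }
    list(par = c(m1, m2, log(s1), log(s2), stats::qlogis(p)), value = ll)
  }
  cm <- tapply(x, cond_idx, mean)
  sd0 <- stats::sd(x)
  starts <- list(em_fit(max(cm), min(cm), sd0, sd0, 0.5))
  qs <- stats::quantile(x, c(0.15, 0.85))
  starts[[2L]] <- em_fit(qs[[2L]], qs[[1L]], sd0, sd0, 0.3)
  for (j in seq_len(max(n_starts - 2L, 0L))) {
    starts[[j + 2L]] <- em_fit(max(cm) + j * sd0 / n_starts,
                               min(cm) - j * sd0 / n_starts,
                               sd0 * (0.5 + j / n_starts), sd0, 0.6)
  }
  best <- NULL
  for (s0 in starts) {
    fit <- stats::optim(s0$par, logLfun, method = "Nelder-Mead",
                        control = list(fnscale = -1, maxit = 10000,
                                       reltol = 1e-10))
    if (fit$value < s0$value) fit <- s0   # keep EM optimum if NM regresses
    if (is.null(best) || fit$value > best$value) best <- fit
  }
  if (is.null(best) || !is.finite(best$value)) {
    stop("fit_gauss_mix_global: optimization failed from every start")
  }
  m1 <- best$par[1L]; m2 <- best$par[2L]
  s1 <- exp(best$par[3L])
  s2 <- if (shared_sd) s1 else exp(best$par[4L])
  p <- stats::plogis(best$par[4L + seq_along(conds)])
  if (m1 < m2) { tmp <- m1; m1 <- m2; m2 <- tmp
                 tmp <- s1; s1 <- s2; s2 <- tmp; p <- 1 - p }
  names(p) <- as.character(conds)
  structure(list(mean_full = m1, mean_zero = m2, sd_full = s1, sd_zero = s2,
                 fraction_full = p, logL = best$value, n = n),
            class = "gauss_mix_fit")
}

#' Weighted Gaussian MLE (single component)
#'
#' Reference fit for the degenerate one-component case; the weighted MLE is
#' the weighted mean and weighted (biased) standard deviation.
#'
#' @param x Values (nm).
#' @param weights Optional weights.
#' @return List with `mean`, `sd`, `logL`, `n`.
#' @export
fit_gauss <- function(x, weights = NULL) {
  w <- normalize_weights(weights, length(x))
  m <- sum(w * x) / sum(w)
  s <- sqrt(sum(w * (x - m)^2) / sum(w))
  list(mean = m, sd = s, n = length(x),
       logL = sum(w * stats::dnorm(x, m, s, log = TRUE)))
}

#' @export
print.gauss_mix_fit <- function(x, ...) {
  cat(sprintf("Global two-Gaussian fit: means %.3g / %.3g nm, sds %.3g / %.3g nm (n = %d)\n",
              x$mean_full, x$mean_zero, x$sd_full, x$sd_zero, x$n))
  cat("  full-stroke fraction by condition:\n")
  print(round(x$fraction_full, 4))
  invisible(x)
}
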