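#' Configuration for covariance-based event detection
#'
#' @param window Covariance window length (s); 8-15 ms is typical, shorter at
#'   saturating ATP where events are brief.
#' @param deadtime_factor Deadtime is `deadtime_factor * window`; events
#'   shorter than this cannot be detected reliably and are eliminated.
#' @param step_window_center Centre of the 1 ms step-measurement window,
#'   measured backwards from the detected event end (s). The window is placed
#'   within 4-10 ms before dissociation; the default sits at the midpoint.
#' @param step_window_width Width of the step-measurement window (s).
#' @param baseline_offset Start of the 1 ms post-event baseline window,
#'   measured from the detected event end (s).
#' @param force_margin Margin trimmed from both event boundaries when
#'   averaging the event force (s).
#' @param signal_choice Signals used for the covariance: `"force"` or
#'   `"position"` (identical up to the trap-stiffness scale factor; both beads
#'   always use the same choice).
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(window = 0.010,
                             deadtime_factor = 2,
                             step_window_center = 0.007,
                             step_window_width = 0.001,
                             baseline_offset = 0.004,
                             force_margin = 0.002,
                             signal_choice = c("force", "position")) {
  signal_choice <- match.arg(signal_choice)
  stopifnot(window > 0, deadtime_factor > 0, step_window_center > 0,
            step_window_width > 0, baseline_offset > 0, force_margin >= 0)
  structure(list(window = window, deadtime_factor = deadtime_factor,
                 step_window_center = step_window_center,
                 step_window_width = step_window_width,
                 baseline_offset = baseline_offset,
                 force_margin = force_margin,
                 signal_choice = signal_choice),
            class = "detection_config")
}

#' Sliding covariance of the two bead signals
#'
#' Computes the sample covariance of the two bead signals over a centred,
#' symmetric window of odd sample count at every interior sample. Binding of
#' a myosin head stiffens the bead-actin-bead dumbbell and lowers this
#' covariance, so the signal separates bound from unbound periods. Edge
#' samples without a full window carry no value (the returned series is
#' trimmed by half a window on each side).
#'
#' @param trace A `dumbbell_trace`.
#' @param cfg A [detection_config()].
#' @return An object of class `cov_signal`: list with `time`, `value`,
#'   `window_used` (s), `sample_rate`.
#' @export
sliding_covariance <- function(trace, cfg = detection_config()) {
  stopifnot(inherits(trace, "dumbbell_trace"))
  fs <- trace$config$sample_rate
  nw <- as.integer(round(cfg$window * fs))
  if (nw %% 2L == 0L) nw <- nw + 1L
  if (nw < 3L) stop("sliding_covariance: window shorter than 3 samples")
  if (nw > length(trace$time)) stop("sliding_covariance: trace shorter than window")
  sig <- if (cfg$signal_choice == "force") {
    list(trace$bead1_force, trace$bead2_force)
  } else {
    list(trace$bead1_pos, trace$bead2_pos)
  }
  v <- running_cov(sig[[1L]], sig[[2L]], nw)
  half <- (nw - 1L) %/% 2L
  structure(list(
    time = trace$time[(half + 1L):(length(trace$time) - half)],
    value = v,
    window_used = nw / fs,
    sample_rate = fs
  ), class = "cov_signal")
}

# O(n) centred running covariance via cumulative sums
running_cov <- function(x, y, nw) {
  n <- length(x)
  cx <- c(0, cumsum(x)); cy <- c(0, cumsum(y)); cxy <- c(0, cumsum(x * y))
  i0 <- 1L:(n - nw + 1L)
  sx <- cx[i0 + nw] - cx[i0]
  sy <- cy[i0 + nw] - cy[i0]
  sxy <- cxy[i0 + nw] - cxy[i0]
  (sxy - sx * sy / nw) / (nw - 1)
}

#' Two-Gaussian threshold for the covariance distribution
#'
#' Fits the distribution of covariance values with a two-component Gaussian
#' mixture (high mean = unbound, low mean = bound) and returns the threshold
#' between the two means that minimizes the summed misclassification areas of
#' the weighted component densities.
#'
#' @param cov A `cov_signal` from [sliding_covariance()].
#' @param max_points Covariance samples are thinned to at most this many
#'   (deterministic stride) before the mixture fit.
#' @return List with `threshold` and `mix_fit` (component `means`, `sds`,
#'   `weights`, ordered bound then unbound).
#' @export
covariance_threshold <- function(cov, max_points = 5e4) {
  stopifnot(inherits(cov, "cov_signal"))
  v <- cov$value[is.finite(cov$value)]
  if (length(v) > max_points) {
    v <- v[seq(1L, length(v), length.out = max_points)]
  }
  # EM (mclust, model "V") from informed starts. Bound periods occupy the low
  # tail of the covariance distribution and may be a small minority, so
  # default model-selection inits can split the dominant unbound peak
  # instead; two provisional splits (mid-range and low-tail) supply class
  # moments for the starts and the higher-likelihood solution wins.
  emV <- mclust::emV              # em() resolves the model worker by name
  em_from_split <- function(is_lo) {
    lo <- v[is_lo]; hi <- v[!is_lo]
    if (length(lo) < 10L || length(hi) < 10L) return(NULL)
    par0 <- list(
      pro = c(length(lo), length(hi)) / length(v),
      mean = c(mean(lo), mean(hi)),
      variance = list(modelName = "V", d = 1, G = 2,
                      sigmasq = pmax(c(stats::var(lo), stats::var(hi)),
                                     1e-12))
    )
    fit <- tryCatch(mclust::em(modelName = "V", data = v, parameters = par0),
                    error = function(e) NULL)
    if (is.null(fit) || is.null(fit$parameters) ||
          any(!is.finite(fit$parameters$mean)) ||
          !is.finite(fit$loglik)) return(NULL)
    fit
  }
  fits <- list(
    em_from_split(v < mean(stats::quantile(v, c(0.001, 0.999)))),
    em_from_split(v <= stats::quantile(v, 0.02))
  )
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (length(fits) == 0L) {
    stop(errorCondition("no events detectable: covariance distribution is unimodal",
                        class = c("myotrap_no_events", "error", "condition")))
  }
  fit <- fits[[which.max(vapply(fits, function(f) f$loglik, numeric(1)))]]
  mu <- fit$parameters$mean
  sd <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sd) == 1L) sd <- rep(sd, 2L)
  w <- fit$parameters$pro
  o <- order(mu)                      # low = bound, high = unbound
  mu <- mu[o]; sd <- sd[o]; w <- w[o]
  # separability: collapse of the fit, or components so overlapped that the
  # two-Gaussian description is indistinguishable from one mode
  # (Ashman's D < 2), means no bound periods are resolvable
  pooled <- sqrt(sum(w * sd^2))
  ashman_d <- sqrt(2) * abs(mu[2L] - mu[1L]) / sqrt(sd[1L]^2 + sd[2L]^2)
  if (abs(mu[2L] - mu[1L]) < 0.1 * pooled || ashman_d < 2) {
    stop(errorCondition("no events detectable: covariance distribution is unimodal",
                        class = c("myotrap_no_events", "error", "condition")))
  }
  thr <- min_overlap_threshold(mu, sd, w)
  list(threshold = thr,
       mix_fit = list(means = mu, sds = sd, weights = w))
}

# threshold minimizing w_lo * P(lo > t) + w_hi * P(hi < t) between the means
min_overlap_threshold <- function(mu, sd, w) {
  miscls <- function(t) {
    w[1L] * stats::pnorm(t, mu[1L], sd[1L], lower.tail = FALSE) +
      w[2L] * stats::pnorm(t, mu[2L], sd[2L])
  }
  stats::optimize(miscls, interval = c(mu[1L], mu[2L]),
                  tol = .Machine$double.eps^0.5 * (mu[2L] - mu[1L]))$minimum
}

#' Detect binding events from a thresholded covariance signal
#'
#' Events are the maximal intervals during which the covariance stays below
#' the threshold. Boundaries are refined by linear interpolation between the
#' two samples bracketing each threshold crossing (ties broken toward the
#' earlier sample); events shorter than the deadtime
#' (`deadtime_factor * window`) are discarded.
#'
#' Because the covariance window is finite, a detected boundary can sit up to
#' half a window inside the true event (the crossing happens once enough of
#' the window has changed state); downstream measurement windows are placed
#' with that bound in mind (see [analyze_trace()]).
#'
#' @param cov A `cov_signal`.
#' @param threshold Scalar threshold from [covariance_threshold()].
#' @param cfg A [detection_config()].
#' @param trace Optional source `dumbbell_trace`; if supplied, molecule and
#'   condition labels are attached.
#' @return An `event_record` data frame with columns `start`, `end`,
#'   `duration` (s) plus label columns; the deadtime used is stored in
#'   `attr(, "deadtime")`.
#' @export
detect_events <- function(cov, threshold, cfg = detection_config(),
                          trace = NULL) {
  stopifnot(inherits(cov, "cov_signal"), is.finite(threshold))
  deadtime <- cfg$deadtime_factor * cfg$window
  below <- cov$value < threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dt <- 1 / cov$sample_rate
  ev_start <- numeric(0); ev_end <- numeric(0)
  for (j in which(r$values)) {
    i0 <- starts[j]; i1 <- ends[j]
    t0 <- if (i0 == 1L) cov$time[1L] else {
      interp_cross(cov$time[i0 - 1L], cov$value[i0 - 1L],
                   cov$time[i0], cov$value[i0], threshold)
    }
    t1 <- if (i1 == length(cov$value)) cov$time[i1] else {
      interp_cross(cov$time[i1], cov$value[i1],
                   cov$time[i1 + 1L], cov$value[i1 + 1L], threshold)
    }
    ev_start <- c(ev_start, t0); ev_end <- c(ev_end, t1)
  }
  keep <- (ev_end - ev_start) >= deadtime
  out <- data.frame(start = ev_start[keep], end = ev_end[keep],
                    duration = ev_end[keep] - ev_start[keep])
  if (!is.null(trace)) {
    out$molecule_id <- if (nrow(out)) trace$molecule_id else character(0)
    out$atp_uM <- if (nrow(out)) trace$config$atp_conc else numeric(0)
    out$om_nM <- if (nrow(out)) trace$config$om_conc else numeric(0)
  }
  class(out) <- c("event_record", "data.frame")
  attr(out, "deadtime") <- deadtime
  out
}

# linear interpolation of the threshold crossing between two samples;
# degenerate (flat) segments resolve to the earlier sample
interp_cross <- function(t0, v0, t1, v1, thr) {
  if (v1 == v0) return(t0)
  t0 + (thr - v0) / (v1 - v0) * (t1 - t0)
}

#' Remove feedback-loop artifacts from isometric event lists
#'
#' Under isometric feedback, brief conformational transients can raise the
#' covariance mid-event and split one interaction into two. Detected unbound
#' gaps that both last less than two covariance windows and are not
#' accompanied by a return of the motor-bead force to baseline are treated as
#' artifacts and the flanking events are merged.
#'
#' @param events An `event_record` data frame (time-ordered).
#' @param force_time,force_value Motor-bead force series (s, pN).
#' @param cfg A [detection_config()].
#' @param baseline,baseline_sd Baseline force level and noise SD; when `NULL`
#'   they are estimated from the samples outside all events. The force is
#'   considered "returned" when it comes within one `baseline_sd` of
#'   `baseline`.
#' @return The merged `event_record` data frame.
#' @export
prune_feedback_artifacts <- function(events, force_time, force_value,
                                     cfg = detection_config(),
                                     baseline = NULL, baseline_sd = NULL) {
  if (nrow(events) < 2L) return(events)
  ord <- order(events$start)
  events <- events[ord, , drop = FALSE]
  if (is.null(baseline) || is.null(baseline_sd)) {
    unbound <- rep(TRUE, length(force_time))
    for (j in seq_len(nrow(events))) {
      unbound[force_time >= events$start[j] & force_time <= events$end[j]] <- FALSE
    }
    if (is.null(baseline)) baseline <- stats::median(force_value[unbound])
    if (is.null(baseline_sd)) baseline_sd <- stats::sd(force_value[unbound])
  }
  merged <- events[1L, , drop = FALSE]
  for (j in 2L:nrow(events)) {
    gap_start <- merged$end[nrow(merged)]
    gap_end <- events$start[j]
    short_gap <- (gap_end - gap_start) < 2 * cfg$window
    in_gap <- force_time > gap_start & force_time < gap_end
    returned <- any(abs(force_value[in_gap] - baseline) <= baseline_sd)
    if (short_gap && !returned) {
      merged$end[nrow(merged)] <- events$end[j]
      merged$duration[nrow(merged)] <-
        merged$end[nrow(merged)] - merged$start[nrow(merged)]
    } else {
      merged <- rbind(merged, events[j, , drop = FALSE])
    }
  }
  rownames(merged) <- NULL
  class(merged) <- class(events)
  attr(merged, "deadtime") <- attr(events, "deadtime")
  merged
}

#' Measure the total working-stroke displacement of one event
#'
#' Averages 1 ms of the bead-averaged displacement placed 4-10 ms before the
#' detected dissociation (window centred per the detection config) and
#' subtracts the baseline displacement averaged over a 1 ms window starting
#' `baseline_offset` after the detected end.
#'
#' @param trace A `dumbbell_trace`.
#' @param start,end Event boundaries (s).
#' @param cfg A [detection_config()].
#' @return Step size (nm), or `NA` when the event is too short for the
#'   pre-dissociation window or the post-event trace is unavailable (the
#'   event remains usable for duration analysis).
#' @export
measure_step <- function(trace, start, end, cfg = detection_config()) {
  half_w <- cfg$step_window_width / 2
  pre0 <- end - cfg$step_window_center - half_w
  pre1 <- end - cfg$step_window_center + half_w
  base0 <- end + cfg$baseline_offset
  base1 <- base0 + cfg$step_window_width
  if (pre0 < start) return(NA_real_)
  x <- (trace$bead1_pos + trace$bead2_pos) / 2
  pre <- window_mean(trace, x, pre0, pre1)
  base <- window_mean(trace, x, base0, base1)
  if (is.na(pre) || is.na(base)) return(NA_real_)
  pre - base
}

#' Measure step sizes for a table of events
#'
#' @param trace A `dumbbell_trace`.
#' @param events An `event_record` data frame.
#' @param cfg A [detection_config()].
#' @return `events` with a `step` column added.
#' @export
measure_steps <- function(trace, events, cfg = detection_config()) {
  events$step <- vapply(seq_len(nrow(events)), function(j) {
    measure_step(trace, events$start[j], events$end[j], cfg)
  }, numeric(1))
  events
}

#' Mean force developed during one event
#'
#' Averages the motor-bead force from 2 ms after the detected attachment to
#' 2 ms before detachment and subtracts the baseline force read 4 ms after
#' detachment. Positive values are loads resisting the working stroke.
#'
#' @param trace A `dumbbell_trace`.
#' @param start,end Event boundaries (s).
#' @param cfg A [detection_config()].
#' @param motor_bead Which bead carries the feedback motor trap (1 or 2).
#' @return Mean force (pN), or `NA` for events no longer than twice the force
#'   margin.
#' @export
event_force <- function(trace, start, end, cfg = detection_config(),
                        motor_bead = 1L) {
  if ((end - start) <= 2 * cfg$force_margin) return(NA_real_)
  f <- if (motor_bead == 1L) trace$bead1_force else trace$bead2_force
  during <- window_mean(trace, f, start + cfg$force_margin,
                        end - cfg$force_margin)
  base <- window_mean(trace, f, end + cfg$baseline_offset,
                      end + cfg$baseline_offset + cfg$step_window_width)
  if (is.na(during) || is.na(base)) return(NA_real_)
  during - base
}

#' Run the full covariance detection pipeline on one trace
#'
#' Convenience wrapper: sliding covariance, two-Gaussian threshold, event
#' detection and step measurement. Measurement windows are placed relative
#' to the detected boundaries but beyond the covariance window's half-width:
#' a detected boundary can sit up to half a window inside the true event,
#' and samples within the covariance window at the detected crossing are
#' correlated with the crossing time itself, so windows inside that reach
#' pick up a systematic offset. The post-event baseline starts at
#' `window/2 + 2 ms` (never closer than the 4 ms convention) and the 1 ms
#' pre-dissociation window is centred at `window/2 + 2.5 ms` before the
#' detected end (never closer than the 7 ms convention).
#'
#' @param trace A `dumbbell_trace`.
#' @param window Covariance window (s).
#' @param cfg Optional [detection_config()] overriding the derived one.
#' @return List with `events` (steps measured), `threshold`, `mix_fit`,
#'   `cfg`.
#' @export
analyze_trace <- function(trace, window = 0.010, cfg = NULL) {
  if (is.null(cfg)) {
    cfg <- detection_config(
      window = window,
      baseline_offset = max(0.004, window / 2 + 0.002),
      step_window_center = max(0.007, window / 2 + 0.0025)
    )
  }
  cov <- sliding_covariance(trace, cfg)
  th <- covariance_threshold(cov)
  ev <- detect_events(cov, th$threshold, cfg, trace)
  ev <- measure_steps(trace, ev, cfg)
  list(events = ev, threshold = th$threshold, mix_fit = th$mix_fit, cfg = cfg)
}

# mean of a signal over [t0, t1]; NA when the window leaves the trace
window_mean <- function(trace, x, t0, t1) {
  fs <- trace$config$sample_rate
  i0 <- as.integer(floor(t0 * fs)) + 1L
  i1 <- as.integer(floor(t1 * fs)) + 1L
  if (i0 < 1L || i1 > length(x) || i1 < i0) return(NA_real_)
  mean(x[i0:i1])
}
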