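#' Ensemble average of binding events aligned at start or end
#'
#' Aligns the bead-averaged displacement of every event at the chosen
#' boundary and averages across events, weighting events so that each
#' molecule contributes equally to the average. Events shorter than the
#' horizon contribute only their own extent (running-count normalization):
#' at each relative time the mean is taken over the events still bound there,
#' so no interpolation of missing tails occurs.
#'
#' The averaged signal retains a stretch of unbound baseline on the far side
#' of the alignment point (`margin`), which [extract_substeps()] uses as the
#' displacement zero.
#'
#' @param events An `event_record` data frame with `start`, `end`,
#'   `molecule_id` columns.
#' @param traces A named list of `dumbbell_trace` objects, indexed by
#'   `molecule_id` (a single trace is recycled for all events).
#' @param align `"start"` or `"end"`.
#' @param horizon How far into the event to average, from the alignment
#'   point (s).
#' @param margin Baseline retained beyond the alignment point on the unbound
#'   side (s).
#' @return An `ensemble_average` object: list with `time` (s, relative to the
#'   alignment point), `mean` (nm), `n_contributing`, `event_count`, `align`.
#' @export
ensemble_average <- function(events, traces, align = c("start", "end"),
                             horizon = 0.05, margin = 0.02) {
  align <- match.arg(align)
  if (nrow(events) == 0L) stop("ensemble_average: empty event set")
  if (inherits(traces, "dumbbell_trace")) traces <- list(traces)
  if (is.null(names(traces)) && length(traces) == 1L) {
    names(traces) <- unique(events$molecule_id)[1L]
  }
  mol <- if ("molecule_id" %in% names(events)) events$molecule_id else
    rep(names(traces)[1L], nrow(events))
  w_mol <- 1 / table(mol)                     # each molecule counts equally
  fs <- traces[[1L]]$config$sample_rate
  dt <- 1 / fs
  if (align == "start") {
    rel <- seq(-margin, horizon, by = dt)
  } else {
    rel <- seq(-horizon, margin, by = dt)
  }
  acc <- numeric(length(rel))
  wsum <- numeric(length(rel))
  for (j in seq_len(nrow(events))) {
    tr <- traces[[as.character(mol[j])]]
    if (is.null(tr)) tr <- traces[[1L]]
    x <- (tr$bead1_pos + tr$bead2_pos) / 2
    t0 <- if (align == "start") events$start[j] else events$end[j]
    idx <- as.integer(floor((t0 + rel) * fs)) + 1L
    ok <- idx >= 1L & idx <= length(x)
    # contribute only while bound plus the unbound-side baseline margin
    if (align == "start") {
      ok <- ok & (rel <= (events$end[j] - events$start[j]) | rel < 0)
    } else {
      ok <- ok & (rel >= -(events$end[j] - events$start[j]) | rel > 0)
    }
    w <- as.numeric(w_mol[[as.character(mol[j])]])
    acc[ok] <- acc[ok] + w * x[idx[ok]]
    wsum[ok] <- wsum[ok] + w
  }
  structure(list(
    time = rel,
    mean = ifelse(wsum > 0, acc / wsum, NA_real_),
    n_contributing = wsum,
    event_count = nrow(events),
    align = align
  ), class = "ensemble_average")
}

#' Extract working-stroke substeps from a pair of ensemble averages
#'
#' The first substep is read from the start-aligned average as the plateau
#' level 5-15 ms after attachment (relative to the pre-attachment baseline);
#' the total stroke is read from the end-aligned average as the level just
#' before detachment (1 ms window centred 7 ms before the end, the same
#' convention as [measure_step()]) minus the post-detachment baseline. The
#' second substep is the difference.
#'
#' @param start_avg Start-aligned [ensemble_average()].
#' @param end_avg End-aligned [ensemble_average()].
#' @param plateau_window Window for the post-attachment plateau (s, relative
#'   to the start).
#' @param pre_detach_window Window for the pre-detachment level (s, relative
#'   to the end).
#' @param baseline_window Post-detachment baseline window for the end-aligned
#'   average (s, relative to the end).
#' @param start_baseline_window Pre-attachment baseline window for the
#'   start-aligned average (s, relative to the start).
#' @return List with `step1`, `step2`, `total` (nm).
#' @export
extract_substeps <- function(start_avg, end_avg,
                             plateau_window = c(0.005, 0.015),
                             pre_detach_window = c(-0.0075, -0.0065),
                             baseline_window = c(0.004, 0.005),
                             start_baseline_window = c(-0.015, -0.005)) {
  stopifnot(inherits(start_avg, "ensemble_average"),
            inherits(end_avg, "ensemble_average"),
            start_avg$align == "start", end_avg$align == "end")
  lvl <- function(avg, w) {
    sel <- avg$time >= w[1L] & avg$time <= w[2L] & !is.na(avg$mean)
    if (!any(sel)) stop("extract_substeps: window outside the averaged data")
    mean(avg$mean[sel])
  }
  start_base <- lvl(start_avg, start_baseline_window)
  end_base <- lvl(end_avg, baseline_window)
  step1 <- lvl(start_avg, plateau_window) - start_base
  total <- lvl(end_avg, pre_detach_window) - end_base
  list(step1 = step1, step2 = total - step1, total = total)
}

#' @export
print.ensemble_average <- function(x, ...) {
  cat(sprintf("Ensemble average (%s-aligned) of %d events, %.0f-%.0f ms\n",
              x$align, x$event_count, 1e3 * min(x$time), 1e3 * max(x$time)))
  invisible(x)
}
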