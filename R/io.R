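#' Write a dumbbell trace to CSV with a JSON config sidecar
#'
#' The trace goes to a columnar CSV (`time_s`, `bead1_pos_nm`,
#' `bead2_pos_nm`, `bead1_force_pN`, `bead2_force_pN`) and the generating
#' configuration to `<path>.json` so a trace file is self-describing.
#'
#' @param trace A `dumbbell_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(time_s = trace$time,
                   bead1_pos_nm = trace$bead1_pos,
                   bead2_pos_nm = trace$bead2_pos,
                   bead1_force_pN = trace$bead1_force,
                   bead2_force_pN = trace$bead2_force)
  utils::write.csv(df, path, row.names = FALSE)
  cfg <- trace$config
  cfg$kinetics <- unclass(cfg$kinetics)
  meta <- list(molecule_id = trace$molecule_id, config = unclass(cfg))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a dumbbell trace written by [write_trace_csv()]
#'
#' @param path CSV path (the `<path>.json` sidecar must exist).
#' @return A `dumbbell_trace`.
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ccfg <- meta$config
  config <- trap_sim_config(
    sample_rate = ccfg$sample_rate, duration = ccfg$duration,
    trap_stiffness = ccfg$trap_stiffness, bead_drag = ccfg$bead_drag,
    myosin_stiffness = ccfg$myosin_stiffness, kT = ccfg$kT,
    substep1 = ccfg$substep1, substep2 = ccfg$substep2,
    rise_time = ccfg$rise_time, atp_conc = ccfg$atp_conc,
    om_conc = ccfg$om_conc, kinetics = do.call(kinetic_scheme, ccfg$kinetics),
    noise_partition = ccfg$noise_partition, seed = ccfg$seed
  )
  structure(list(time = df$time_s,
                 bead1_pos = df$bead1_pos_nm, bead2_pos = df$bead2_pos_nm,
                 bead1_force = df$bead1_force_pN,
                 bead2_force = df$bead2_force_pN,
                 molecule_id = meta$molecule_id, config = config),
            class = "dumbbell_trace")
}

#' Write an event table to CSV
#'
#' @param events An `event_record` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' Read an event table written by [write_events_csv()]
#'
#' @param path CSV path.
#' @return An `event_record` data frame.
#' @export
read_events_csv <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("event_record", "data.frame")
  out
}

#' Write a fit report as JSON
#'
#' Serializes any of the package's fit objects (parameters, log-likelihood,
#' CIs) for downstream tooling.
#'
#' @param fit A fit object (list-like).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
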