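#' Write a simulation series to delimited text
#'
#' Tab-separated values with the run configuration (schedule, interventions,
#' decimation, charge offset) embedded as JSON in '#'-prefixed header
#' lines, so a series file is self-describing and round-trips losslessly.
#'
#' @param sim An `ir_simulation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series <- function(sim, path) {
  if (is.null(sim$series)) abort("simulation carries no series")
  cfg <- list(schedule = unclass(sim$schedule),
              interventions = unclass(sim$interventions),
              out_every = sim$out_every,
              charge_offset = sim$charge_offset)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# reperfusim-series v1"), con)
  writeLines(paste0("# config: ",
                    jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)),
             con)
  utils::write.table(sim$series, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a series file written by [write_series()]
#'
#' @param path Input path.
#' @param required_columns Columns that must be present; a missing column
#'   is a named error.
#' @return A tibble with the embedded configuration in the `config`
#'   attribute.
#' @export
read_series <- function(path,
                        required_columns = c("t", "V", "Na_i", "Ca_i",
                                             "pH_i", "pH_o", "K_o")) {
  head2 <- readLines(path, n = 2)
  if (!startsWith(head2[1], "# reperfusim-series"))
    abort("not a reperfusim series file")
  cfg <- jsonlite::fromJSON(sub("^# config: ", "", head2[2]))
  dat <- utils::read.delim(path, comment.char = "#",
                           check.names = FALSE)
  missing <- setdiff(required_columns, names(dat))
  if (length(missing) > 0)
    abort(paste0("series file lacks columns: ",
                 paste(missing, collapse = ", ")))
  out <- as_tibble(dat)
  attr(out, "config") <- cfg
  out
}

#' Serialize / restore a run configuration
#'
#' A `RunConfig` is the schedule plus interventions plus output options; it
#' round-trips losslessly through JSON and unknown keys are rejected on
#' read.
#'
#' @param schedule An `ir_schedule`.
#' @param interventions An `ir_interventions`.
#' @param out_every Series decimation.
#' @return A list of class `ir_config`.
#' @export
ir_config <- function(schedule = protocol_schedule(),
                      interventions = intervention_schedule(),
                      out_every = NULL) {
  cfg <- list(schedule = schedule, interventions = interventions,
              out_every = out_every)
  class(cfg) <- c("ir_config", "list")
  cfg
}

#' @rdname ir_config
#' @param config An `ir_config`.
#' @param path File path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(
    list(schedule = unclass(config$schedule),
         interventions = unclass(config$interventions),
         out_every = config$out_every),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname ir_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::fromJSON(path)
  allowed <- c("schedule", "interventions", "out_every")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0)
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  sc_def <- protocol_schedule()
  unknown_sc <- setdiff(names(raw$schedule), names(sc_def))
  if (length(unknown_sc) > 0)
    abort(paste0("unknown schedule keys: ",
                 paste(unknown_sc, collapse = ", ")))
  sc <- utils::modifyList(unclass(sc_def), raw$schedule)
  class(sc) <- c("ir_schedule", "list")
  iv_def <- intervention_schedule()
  unknown_iv <- setdiff(names(raw$interventions), names(iv_def))
  if (length(unknown_iv) > 0)
    abort(paste0("unknown intervention keys: ",
                 paste(unknown_iv, collapse = ", ")))
  iv <- utils::modifyList(unclass(iv_def), raw$interventions)
  class(iv) <- c("ir_interventions", "list")
  ir_config(sc, iv, raw$out_every)
}

#' Deterministic short-run fixtures for tests
#'
#' Short protocol snapshots (seconds of pre-ischemia, optionally a
#' compressed ischemic segment) together with the configurations that
#' produced them.  There is no randomness anywhere in the pipeline, so
#' replaying a fixture's configuration reproduces its snapshot
#' bit-identically.
#'
#' @param params Calibrated parameters.
#' @param pre_s Seconds of pre-ischemic pacing.
#' @param isch_s Seconds of (time-compressed) ischemia.
#' @param compress Trajectory compression for the ischemic segment.
#' @return A named list of fixtures, each with `config`, `state` and the
#'   producing call's schedule.
#' @export
make_fixtures <- function(params = calibrated_parameters(),
                          pre_s = 10, isch_s = 60, compress = 20) {
  sc_pre <- protocol_schedule(pre_min = pre_s / 60, isch_min = 0,
                              rep_min = 0)
  sim_pre <- simulate_ir(sc_pre, intervention_schedule(), params = params,
                         record_series = FALSE, record_beats = FALSE)
  sc_isch <- protocol_schedule(pre_min = pre_s / 60, isch_min = isch_s / 60,
                               rep_min = 0, compress = compress)
  sim_isch <- simulate_ir(sc_isch, intervention_schedule(), params = params,
                          record_series = FALSE, record_beats = FALSE)
  list(
    pre_end = list(config = ir_config(sc_pre, intervention_schedule()),
                   state = sim_pre$final_state),
    ischemia_end = list(config = ir_config(sc_isch, intervention_schedule()),
                        state = sim_isch$final_state)
  )
}
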