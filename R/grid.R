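#' Run the intervention grid with shared protocol prefixes
#'
#' The seven published scenarios (and optionally the pump pH-clamp run)
#' differ only after a given protocol time, so the grid is run as restartable
#' segments: one pre-ischemic segment, shared ischemic segments (split at
#' mid-ischemia, where the M-series interventions begin), and one
#' reperfusion segment per scenario.  Segment restarts are exact for every
#' prescribed trajectory (the ischemic trajectory clock is carried across
#' segments), so a segmented scenario reproduces the corresponding
#' single-pass run.
#'
#' @param scenarios Character vector out of `control`, `R50`, `R0`, `M50`,
#'   `M0`, `I50`, `I0`, `R0_nak_ph_clamp`.
#' @param schedule An `ir_schedule` (ischemia duration must be positive).
#' @param params Calibrated parameters.
#' @param state Initial state.
#' @param out_every Series decimation for the reperfusion segments.
#' @return A list of class `ir_grid` with per-scenario summaries, sodium
#'   ledgers, reperfusion simulations and end-ischemic states.
#' @export
run_protocol_grid <- function(scenarios = c("control", "R50", "R0", "M50",
                                            "M0", "I50", "I0"),
                              schedule = protocol_schedule(),
                              params = NULL, state = NULL,
                              out_every = NULL) {
  known <- c("control", "R50", "R0", "M50", "M0", "I50", "I0",
             "R0_nak_ph_clamp")
  bad <- setdiff(scenarios, known)
  if (length(bad) > 0)
    abort(paste0("unknown scenarios: ", paste(bad, collapse = ", ")))
  if (schedule$isch_ms <= 0) abort("the grid needs a positive ischemia")
  if (is.null(params)) params <- calibrated_parameters()
  if (is.null(state)) state <- initial_state(params)

  seg_sched <- function(pre = 0, isch = 0, rep = 0) {
    sc <- schedule
    sc$pre_ms <- pre; sc$isch_ms <- isch; sc$rep_ms <- rep
    sc
  }
  # --- pre-ischemic segment (shared by everything) ---
  sim_pre <- simulate_ir(seg_sched(pre = schedule$pre_ms),
                         intervention_schedule(), state = state,
                         params = params, record_series = FALSE,
                         record_beats = FALSE)
  snapA <- sim_pre$final_state
  anch <- list(
    na_o = state[["Na_o"]], k_o = state[["K_o"]], ca_o = state[["Ca_o"]],
    cl_o = state[["Cl_o"]], hco3_o = state[["HCO3_o"]],
    co2_o = state[["CO2_o"]], ph_o = state[["pH_o"]],
    osm_normal = snapA[["Osm_i"]], ph_anchor = snapA[["pH_i"]],
    atp_pre = snapA[["ATP"]], pcr_pre = snapA[["PCr"]],
    nak_ph_normal = snapA[["pH_i"]])

  run_isch <- function(from, dur_ms, offset_ms, nhe_scale) {
    simulate_ir(seg_sched(isch = dur_ms),
                intervention_schedule(nhe_scale = nhe_scale,
                                      nhe_onset = if (nhe_scale < 1)
                                        "ischemia" else "none"),
                state = from, params = params,
                record_series = FALSE, record_beats = TRUE,
                anchors = c(anch, list(isch_t_offset_ms = offset_ms)))
  }

  half <- schedule$isch_ms / 2
  need_half <- any(scenarios %in% c("M50", "M0"))
  need_ctl_isch <- any(scenarios %in% c("control", "R50", "R0",
                                        "R0_nak_ph_clamp"))
  isch_end <- list()
  isch_sims <- list()
  if (need_ctl_isch || need_half) {
    sim_h1 <- run_isch(snapA, half, 0, 1.0)
    snapH <- sim_h1$final_state
    if (need_ctl_isch) {
      sim_h2 <- run_isch(snapH, half, half, 1.0)
      isch_sims$control <- list(sim_h1, sim_h2)
      for (nm in intersect(scenarios, c("control", "R50", "R0",
                                        "R0_nak_ph_clamp")))
        isch_end[[nm]] <- sim_h2$final_state
    }
    for (nm in intersect(scenarios, c("M50", "M0"))) {
      sc <- if (nm == "M50") 0.5 else 0.0
      sim_h2m <- run_isch(snapH, half, half, sc)
      isch_sims[[nm]] <- list(sim_h1, sim_h2m)
      isch_end[[nm]] <- sim_h2m$final_state
    }
  }
  for (nm in intersect(scenarios, c("I50", "I0"))) {
    sc <- if (nm == "I50") 0.5 else 0.0
    sim_i <- run_isch(snapA, schedule$isch_ms, 0, sc)
    isch_sims[[nm]] <- list(sim_i)
    isch_end[[nm]] <- sim_i$final_state
  }

  rep_iv <- function(nm) {
    switch(nm,
      control = intervention_schedule(),
      R50 = intervention_schedule(0.5, "reperfusion"),
      R0 = intervention_schedule(0.0, "reperfusion"),
      M50 = intervention_schedule(0.5, "reperfusion"),
      M0 = intervention_schedule(0.0, "reperfusion"),
      I50 = intervention_schedule(0.5, "reperfusion"),
      I0 = intervention_schedule(0.0, "reperfusion"),
      R0_nak_ph_clamp = intervention_schedule(0.0, "reperfusion",
                                              nak_clamp = TRUE))
  }
  rep_sims <- list()
  for (nm in scenarios) {
    rep_sims[[nm]] <- simulate_ir(seg_sched(rep = schedule$rep_ms),
                                  rep_iv(nm), state = isch_end[[nm]],
                                  params = params, out_every = out_every,
                                  record_series = TRUE, record_beats = TRUE,
                                  anchors = anch)
  }

  summ <- function(nm) {
    ser <- rep_sims[[nm]]$series
    e <- isch_end[[nm]]
    row <- function(col) {
      tibble(scenario = nm, quantity = col,
             peak = max(ser[[col]]), mean = mean(ser[[col]]),
             end_ischemic = e[[col]],
             end_reperfusion = ser[[col]][nrow(ser)],
             ratio = max(ser[[col]]) / e[[col]])
    }
    dplyr::bind_rows(row("Na_i"), row("Ca_i"), row("pH_i"), row("HCO3_i"))
  }
  summary <- dplyr::bind_rows(lapply(scenarios, summ))
  if ("control" %in% scenarios) {
    ctl <- dplyr::filter(summary, .data$scenario == "control")
    summary$normalized_ratio <-
      summary$ratio / ctl$ratio[match(summary$quantity, ctl$quantity)]
  }
  ledgers <- purrr::imap(rep_sims, function(s, nm)
    dplyr::mutate(sodium_ledger(s), scenario = nm, .before = 1))
  out <- list(summary = summary,
              ledgers = dplyr::bind_rows(ledgers),
              reperfusion = rep_sims,
              ischemia = isch_sims,
              ischemia_end = isch_end,
              pre_end = snapA, anchors = anch,
              schedule = schedule)
  class(out) <- "ir_grid"
  out
}

#' @export
print.ir_grid <- function(x, ...) {
  cat("<ir_grid> scenarios:", paste(names(x$reperfusion), collapse = ", "),
      "\n")
  print(x$summary, n = Inf)
  invisible(x)
}

#' @export
tidy.ir_grid <- function(x, ...) x$summary
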