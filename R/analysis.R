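#' Per-pathway sodium moles moved during reperfusion
#'
#' The net number of moles of sodium moved through each of the eight
#' sodium pathways over the reperfusion window, integrated over the
#' every-tenth-step samples exactly as the series would be written out
#' (this is a discretized ledger, not the exact integral): transporter
#' fluxes are multiplied by the sampling interval and the myoplasmic
#' volume; currents by the sampling interval times capacitive area over
#' Faraday's constant, with the three-sodium stoichiometry applied to the
#' pump and exchanger.  Positive entries move sodium into the cell; in the
#' simulated scenarios only the sodium-potassium pump is negative.
#'
#' @param sim An `ir_simulation` (the driver accumulates the ledger in-run).
#' @return A tibble with `pathway`, `moles` and `proportion`.
#' @export
sodium_ledger <- function(sim) {
  led <- sim$ledger
  tibble(pathway = names(led), moles = as.numeric(led),
         proportion = ledger_proportions(as.numeric(led)))
}

#' Ledger proportions
#'
#' Each pathway's share: absolute moles divided by the sum of absolute
#' moles across all eight pathways.
#'
#' @param moles Numeric vector of per-pathway moles.
#' @return Proportions summing to one.
#' @export
ledger_proportions <- function(moles) {
  tot <- sum(abs(moles))
  if (tot == 0) abort("all-zero ledger: proportions are undefined")
  abs(moles) / tot
}

#' Recompute the sodium ledger from a recorded series
#'
#' Rectangle-sum integration of a decimated flux/current series over the
#' reperfusion window (the independent route to the in-run ledger; the two
#' agree when the series decimation equals the ledger sampling of every
#' tenth step).
#'
#' @param series Series tibble covering the reperfusion window, with the
#'   flux/current columns and `V_myo`.
#' @param params Model parameters (capacitance and Faraday constant).
#' @param sample_ms Time between retained samples, ms.
#' @return A tibble with `pathway`, `moles`, `proportion`.
#' @export
integrate_sodium_moles <- function(series, params, sample_ms) {
  need <- c("J_NHE", "J_NBC", "I_NCX", "I_NaK", "I_Na", "I_Nab", "I_NaL",
            "I_CaL_Na", "V_myo")
  missing <- setdiff(need, names(series))
  if (length(missing) > 0)
    abort(paste0("series lacks columns: ", paste(missing, collapse = ", ")))
  mol_flux <- function(j) sum(j * sample_ms * series$V_myo * 1e-9)
  mol_cur <- function(i, stoich = 1)
    sum(-stoich * i * sample_ms * params$cap_total * 1e-9 / params$faraday)
  moles <- c(
    NHE = mol_flux(series$J_NHE), NBC = mol_flux(series$J_NBC),
    NCX = mol_cur(series$I_NCX, 3), NaK = mol_cur(series$I_NaK, 3),
    I_Na = mol_cur(series$I_Na), I_Nab = mol_cur(series$I_Nab),
    I_NaL = mol_cur(series$I_NaL), I_CaL_Na = mol_cur(series$I_CaL_Na))
  tibble(pathway = names(moles), moles = as.numeric(moles),
         proportion = ledger_proportions(as.numeric(moles)))
}

#' Per-beat extrema and action-potential detection
#'
#' Stimulus-anchored, half-open beat windows; per beat the extrema of
#' membrane potential, myoplasmic calcium and pump current, and a flag for
#' whether the stimulus elicited an action potential (V exceeds the
#' threshold within the window).
#'
#' @param sim An `ir_simulation` (beats are accumulated in-run at full
#'   temporal resolution).
#' @param ap_threshold Detection threshold, mV.
#' @return A tibble of per-beat metrics.
#' @export
beat_metrics <- function(sim, ap_threshold = -30) {
  b <- sim$beats
  if (is.null(b)) abort("simulation was run without beat recording")
  b$ap_elicited <- b$V_max > ap_threshold
  b
}

#' Reperfusion summary of a simulation
#'
#' Peak and time-mean over the reperfusion window, the end-ischemic value,
#' the peak/end-ischemic ratio and (when a control summary is supplied)
#' the ratio normalized to control, for intracellular sodium, calcium, pH
#' and bicarbonate.  "Peak" is the maximum of the decimated series over
#' reperfusion; "mean" is the time-average of the decimated samples.
#'
#' @param sim An `ir_simulation` whose series covers ischemia end and the
#'   reperfusion window.
#' @param control Optional control summary (from this function) used for
#'   the normalized ratio.
#' @return A tibble with one row per quantity, class `ir_summary`.
#' @export
summarize_ir <- function(sim, control = NULL) {
  ser <- sim$series
  if (is.null(ser)) abort("simulation was run without series recording")
  t_rep0 <- sim$schedule$pre_ms + sim$schedule$isch_ms
  rep <- dplyr::filter(ser, .data$t >= t_rep0)
  isch <- dplyr::filter(ser, .data$t < t_rep0)
  if (nrow(rep) == 0) abort("series does not cover the reperfusion window")
  end_isch <- function(col) {
    if (nrow(isch) == 0) NA_real_ else isch[[col]][nrow(isch)]
  }
  row <- function(col) {
    tibble(quantity = col,
           peak = max(rep[[col]]),
           mean = mean(rep[[col]]),
           end_ischemic = end_isch(col),
           end_reperfusion = rep[[col]][nrow(rep)],
           ratio = max(rep[[col]]) / end_isch(col))
  }
  out <- dplyr::bind_rows(row("Na_i"), row("Ca_i"), row("pH_i"),
                          row("HCO3_i"))
  if (!is.null(control)) {
    ctl <- control
    out$normalized_ratio <- out$ratio / ctl$ratio[match(out$quantity,
                                                        ctl$quantity)]
  }
  class(out) <- c("ir_summary", class(out))
  out
}

#' Run the full scenario grid and tabulate the summaries
#'
#' Convenience wrapper: runs the named intervention presets under one
#' schedule and returns the combined reperfusion summary table with ratios
#' normalized to the control run.
#'
#' @param scenarios Named list of `ir_interventions`
#'   (default: [scenario_presets()] subset).
#' @param schedule An `ir_schedule`.
#' @param params Calibrated parameters.
#' @param state Initial state.
#' @param ... Passed to [simulate_ir()].
#' @return A tibble with a `scenario` column, plus the summary columns.
#' @export
run_scenarios <- function(scenarios = scenario_presets()[1:7],
                          schedule = protocol_schedule(),
                          params = NULL, state = NULL, ...) {
  if (is.null(params)) params <- calibrated_parameters()
  if (is.null(state)) state <- initial_state(params)
  sims <- purrr::map(scenarios, function(iv)
    simulate_ir(schedule, iv, state = state, params = params, ...))
  ctl_sum <- summarize_ir(sims[[1]])
  tabs <- purrr::imap(sims, function(s, nm) {
    dplyr::mutate(summarize_ir(s, control = ctl_sum), scenario = nm,
                  .before = 1)
  })
  out <- dplyr::bind_rows(tabs)
  attr(out, "simulations") <- sims
  out
}
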