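#' Protocol schedule for the three-phase ischemia-reperfusion experiment
#'
#' Defines the phase durations, the integrator step, pacing, and the
#' prescribed trajectories that drive the ischemic and reperfusion phases:
#' the intracellular acidification curve, the ATP/phosphocreatine decay and
#' recovery schedules (recovery saturating at 40 and 75 percent of the
#' pre-ischemic concentrations), the linear osmolarity rise, the
#' extracellular washout (time constant 3.75e4 ms, about two minutes to
#' recovery) and the extracellular pH relaxation (time constant 1.5e5 ms,
#' about ten minutes to recovery).
#'
#' `compress` > 1 runs a time-compressed desk-scale protocol: phases are
#' shortened while every prescribed trajectory and relaxation advances
#' `compress` trajectory-milliseconds per simulated millisecond, so a short
#' run traverses the full severity of the imposed ischemic insult.
#'
#' @param pre_min,isch_min,rep_min Phase durations in minutes.
#' @param dt Euler time step, ms.
#' @param rate_hz Pacing rate, Hz.
#' @param stim_amp,stim_width Stimulus amplitude (uA/uF) and width (ms).
#' @param ph_end_isch Asymptote of the prescribed ischemic intracellular pH.
#' @param tau_ph_isch Time constant of the prescribed acidification, ms.
#' @param tau_pho Reperfusion extracellular-pH relaxation constant, ms.
#' @param tau_wash Reperfusion washout constant for extracellular species, ms.
#' @param tau_osm Reperfusion osmolarity relaxation constant, ms.
#' @param tau_metab_rec Phosphometabolite recovery constant, ms.
#' @param atp_rec_frac,pcr_rec_frac Recovery asymptotes as fractions of the
#'   pre-ischemic ATP and PCr concentrations.
#' @param osm_slope_per_min Linear ischemic osmolarity rise, mOsm/min.
#' @param isch_ref_min Reference ischemia length (min) for the ATP decay law.
#' @param atp_drop_frac,atp_drop_exp ATP decays to `1 - atp_drop_frac` of its
#'   pre-ischemic value over `isch_ref_min` with curvature `atp_drop_exp`.
#' @param pcr_floor,tau_pcr_ms Phosphocreatine floor fraction and decay
#'   constant during ischemia.
#' @param inal_ischemic One of "increase" (late-Na scale 0.0018 during
#'   ischemia) or "literal" (0.00018); the two printed readings of the
#'   ischemic late-sodium scale are both available.
#' @param compress Trajectory time-compression factor (>= 1).
#' @return A named list of class `ir_schedule`.
#' @export
protocol_schedule <- function(pre_min = 5, isch_min = 20, rep_min = 10,
                              dt = 0.005, rate_hz = 3,
                              stim_amp = -80.0, stim_width = 0.5,
                              ph_end_isch = 6.0, tau_ph_isch = 3e5,
                              tau_pho = 1.5e5, tau_wash = 3.75e4,
                              tau_osm = 3.75e4, tau_metab_rec = 9e4,
                              atp_rec_frac = 0.40, pcr_rec_frac = 0.75,
                              osm_slope_per_min = 1.0, isch_ref_min = 20,
                              atp_drop_frac = 0.75, atp_drop_exp = 1.5,
                              pcr_floor = 0.05, tau_pcr_ms = 1.5e5,
                              inal_ischemic = c("increase", "literal"),
                              compress = 1) {
  inal_ischemic <- match.arg(inal_ischemic)
  stopifnot(pre_min >= 0, isch_min >= 0, rep_min >= 0, dt > 0, rate_hz > 0,
            tau_pho > 0, tau_wash > 0, tau_osm > 0, tau_metab_rec > 0,
            atp_rec_frac >= 0, atp_rec_frac <= 1,
            pcr_rec_frac >= 0, pcr_rec_frac <= 1, compress >= 1)
  sc <- list(
    pre_ms = pre_min * 6e4, isch_ms = isch_min * 6e4, rep_ms = rep_min * 6e4,
    dt = dt, period = 1000 / rate_hz,
    stim_amp = stim_amp, stim_width = stim_width,
    tau_pho = tau_pho, tau_wash = tau_wash, tau_osm = tau_osm,
    tau_metab_rec = tau_metab_rec,
    ph_end_isch = ph_end_isch, tau_ph_isch = tau_ph_isch,
    osm_slope = osm_slope_per_min / 6e4,
    isch_ref_ms = isch_ref_min * 6e4,
    atp_drop_frac = atp_drop_frac, atp_drop_exp = atp_drop_exp,
    pcr_floor = pcr_floor, tau_pcr = tau_pcr_ms,
    pcr_rec_frac = pcr_rec_frac, atp_rec_frac = atp_rec_frac,
    compress = compress,
    g_na_isch_scale = 14.4 / 16.0,
    g_nal_normal = 7e-4,
    g_nal_isch = if (inal_ischemic == "increase") 1.8e-3 else 1.8e-4,
    inal_ischemic = inal_ischemic,
    tau_co2_prod = 6e4
  )
  class(sc) <- c("ir_schedule", "list")
  sc
}

#' Intervention schedule
#'
#' @param nhe_scale Fractional NHE flux remaining under inhibition (1.0 none,
#'   0.5 half block, 0.0 complete block).
#' @param nhe_onset When inhibition starts: "none", "reperfusion"
#'   (reperfusion onset), "mid-ischemia" (ischemia onset + half the ischemic
#'   duration, exactly), or "ischemia" (ischemia onset).
#' @param nak_clamp If `TRUE`, the sodium-potassium pump senses a normal
#'   (pre-ischemic) intracellular pH during reperfusion while the rest of
#'   the cell sees the true pH.
#' @param nak_clamp_ph Optional explicit pH for the clamp; by default the
#'   pH at the end of pre-ischemia is used.
#' @param nak_scale Pump current multiplier applied from reperfusion onset.
#' @param atp_recovery_frac Reperfusion ATP recovery asymptote as a fraction
#'   of the pre-ischemic concentration (0.40 default; 1.0 for the full
#'   ATP-recovery experiment).
#' @return A named list of class `ir_interventions`.
#' @export
intervention_schedule <- function(nhe_scale = 1.0,
                                  nhe_onset = c("none", "reperfusion",
                                                "mid-ischemia", "ischemia"),
                                  nak_clamp = FALSE, nak_clamp_ph = NA_real_,
                                  nak_scale = 1.0,
                                  atp_recovery_frac = 0.40) {
  nhe_onset <- match.arg(nhe_onset)
  if (nhe_scale < 0 || nhe_scale > 1)
    abort("nhe_scale must lie in [0, 1]")
  if (nak_scale <= 0) abort("nak_scale must be > 0")
  iv <- list(
    nhe_scale = nhe_scale,
    nhe_onset = match(nhe_onset,
                      c("none", "reperfusion", "mid-ischemia", "ischemia")) - 1L,
    nhe_onset_label = nhe_onset,
    nak_clamp = isTRUE(nak_clamp),
    nak_clamp_ph = nak_clamp_ph,
    nak_scale = nak_scale,
    atp_rec_frac = atp_recovery_frac
  )
  class(iv) <- c("ir_interventions", "list")
  iv
}

#' Named intervention presets for the published scenario grid
#'
#' Control plus the six NHE-inhibition scenarios (R50/R0 at reperfusion
#' onset, M50/M0 at mid-ischemia, I50/I0 at ischemia onset), the R0 run with
#' the pump pH-clamp, pump doubling at reperfusion, and full ATP recovery.
#'
#' @return A named list of `ir_interventions`.
#' @export
scenario_presets <- function() {
  list(
    control = intervention_schedule(),
    R50 = intervention_schedule(0.5, "reperfusion"),
    R0  = intervention_schedule(0.0, "reperfusion"),
    M50 = intervention_schedule(0.5, "mid-ischemia"),
    M0  = intervention_schedule(0.0, "mid-ischemia"),
    I50 = intervention_schedule(0.5, "ischemia"),
    I0  = intervention_schedule(0.0, "ischemia"),
    R0_nak_ph_clamp = intervention_schedule(0.0, "reperfusion",
                                            nak_clamp = TRUE),
    nak_x2_reperfusion = intervention_schedule(nak_scale = 2.0),
    atp_full_recovery = intervention_schedule(atp_recovery_frac = 1.0)
  )
}

# ---------------------------------------------------------------------------
# prescribed trajectories (closed forms; the driver uses the same algebra)

#' Prescribed intracellular pH during ischemia
#'
#' Exponential approach from the end-of-pre-ischemia pH (continuity anchor)
#' to the ischemic asymptote; monotonically non-increasing.
#'
#' @param t_min Ischemic time in minutes (trajectory time).
#' @param schedule An `ir_schedule`.
#' @param ph_start Anchor pH at ischemia onset.
#' @return pH value(s).
#' @export
pH_i_prescribed <- function(t_min, schedule = protocol_schedule(),
                            ph_start = 7.15) {
  t_ms <- t_min * 6e4
  if (any(t_min < 0) || any(t_ms > schedule$isch_ref_ms + 1e-9))
    abort("ischemic time outside the ischemia window")
  schedule$ph_end_isch +
    (ph_start - schedule$ph_end_isch) * exp(-t_ms / schedule$tau_ph_isch)
}

#' One reperfusion step of the prescribed extracellular pH
#'
#' Discrete exponential relaxation toward the pre-ischemic extracellular pH
#' (7.40); fixed point at the target, no overshoot.
#'
#' @param ph_o Current extracellular pH.
#' @param dt Step length, ms.
#' @param schedule An `ir_schedule`.
#' @param target Pre-ischemic pH (7.40).
#' @export
pH_o_reperfusion_step <- function(ph_o, dt, schedule = protocol_schedule(),
                                  target = 7.40) {
  ph_o + dt / schedule$tau_pho * (target - ph_o)
}

#' One reperfusion washout step for an extracellular species
#'
#' @param conc Current concentration, mM.
#' @param target Pre-ischemic concentration, mM.
#' @param dt Step length, ms.
#' @param schedule An `ir_schedule`.
#' @export
washout_step <- function(conc, target, dt, schedule = protocol_schedule()) {
  conc + dt / schedule$tau_wash * (target - conc)
}

#' Prescribed ATP and phosphocreatine trajectories
#'
#' During ischemia ATP and PCr decay along the imposed schedules; during
#' reperfusion they recover exponentially toward 40 percent (ATP) and 75
#' percent (PCr) of the pre-ischemic values, with most recovery in the
#' first few minutes.
#'
#' @param t_min Time in minutes within the phase (trajectory time).
#' @param phase "ischemia" or "reperfusion".
#' @param schedule An `ir_schedule`.
#' @param atp_pre,pcr_pre Pre-ischemic anchors.
#' @param atp_end,pcr_end End-ischemic anchors (reperfusion only).
#' @param atp_rec_frac Recovery asymptote fraction for ATP.
#' @return A list with elements `ATP` and `PCr`.
#' @export
phosphometabolite_schedule <- function(t_min,
                                       phase = c("ischemia", "reperfusion"),
                                       schedule = protocol_schedule(),
                                       atp_pre = 7.216, pcr_pre = 13.3,
                                       atp_end = NULL, pcr_end = NULL,
                                       atp_rec_frac = schedule$atp_rec_frac) {
  phase <- match.arg(phase)
  t_ms <- t_min * 6e4
  if (phase == "ischemia") {
    ttc <- pmin(t_ms, schedule$isch_ref_ms)
    atp <- atp_pre * (1 - schedule$atp_drop_frac *
                        (ttc / schedule$isch_ref_ms)^schedule$atp_drop_exp)
    atp <- pmax(atp, 0.05 * atp_pre)
    pcr <- pcr_pre * (schedule$pcr_floor + (1 - schedule$pcr_floor) *
                        exp(-t_ms / schedule$tau_pcr))
    list(ATP = atp, PCr = pcr)
  } else {
    if (is.null(atp_end) || is.null(pcr_end))
      abort("reperfusion schedule needs the end-ischemic anchors")
    er <- exp(-t_ms / schedule$tau_metab_rec)
    list(ATP = atp_rec_frac * atp_pre +
           (atp_end - atp_rec_frac * atp_pre) * er,
         PCr = schedule$pcr_rec_frac * pcr_pre +
           (pcr_end - schedule$pcr_rec_frac * pcr_pre) * er)
  }
}

#' Prescribed intracellular osmolarity
#'
#' Linear rise during ischemia; exponential relaxation back to the normal
#' osmolarity during reperfusion.  The impermeant osmolyte concentration is
#' recomputed from the osmolarity each step for the water-flux calculation.
#'
#' @param t_min Time in minutes within the phase (trajectory time).
#' @param phase "ischemia" or "reperfusion".
#' @param schedule An `ir_schedule`.
#' @param osm_normal Normal osmolarity, mOsm.
#' @param osm_end End-ischemic osmolarity (reperfusion only).
#' @export
osmolarity_schedule <- function(t_min, phase = c("ischemia", "reperfusion"),
                                schedule = protocol_schedule(),
                                osm_normal = 310, osm_end = NULL) {
  phase <- match.arg(phase)
  t_ms <- t_min * 6e4
  if (phase == "ischemia") {
    osm_normal + schedule$osm_slope * t_ms
  } else {
    if (is.null(osm_end)) abort("reperfusion schedule needs osm_end")
    osm_normal + (osm_end - osm_normal) * exp(-t_ms / schedule$tau_osm)
  }
}

#' Impermeant osmolyte concentration from a prescribed osmolarity
#' @param osm_i Intracellular osmolarity, mOsm.
#' @param state Named state vector (Na_i, K_i, Ca_i, Cl_i are used).
#' @export
x_i_from_osmolarity <- function(osm_i, state) {
  s <- state_vector(state)
  osm_i - (s[["Na_i"]] + s[["K_i"]] + s[["Ca_i"]] + s[["Cl_i"]])
}

#' Phase parameter overlay
#'
#' Which variables are prescribed versus dynamic in each phase, and the
#' phase-dependent conductances (sodium-channel conductance 14.4 instead of
#' 16.0 mS/uF during ischemia; the ischemic late-sodium scale).
#'
#' @param phase "pre-ischemia", "ischemia" or "reperfusion".
#' @param schedule An `ir_schedule`.
#' @return A list of phase modifiers.
#' @export
apply_phase_switches <- function(phase = c("pre-ischemia", "ischemia",
                                           "reperfusion"),
                                 schedule = protocol_schedule()) {
  phase <- match.arg(phase)
  switch(phase,
    "pre-ischemia" = list(
      g_na = 16.0, g_nal_scale = schedule$g_nal_normal,
      pH_i = "dynamic", pH_o = "clamped",
      extracellular = "clamped", co2_o_dynamic = FALSE),
    "ischemia" = list(
      g_na = 16.0 * schedule$g_na_isch_scale,
      g_nal_scale = schedule$g_nal_isch,
      pH_i = "prescribed", pH_o = "dynamic",
      extracellular = "dynamic", co2_o_dynamic = TRUE),
    "reperfusion" = list(
      g_na = 16.0, g_nal_scale = schedule$g_nal_normal,
      pH_i = "dynamic", pH_o = "prescribed",
      extracellular = "washout", co2_o_dynamic = FALSE))
}

#' Stimulus current at a given time
#'
#' -80 uA/uF pulses of 0.5 ms at the pacing rate, anchored at t = 0.
#'
#' @param t Time(s), ms.
#' @param schedule An `ir_schedule`.
#' @return Current in uA/uF (vectorized).
#' @export
stimulus_current <- function(t, schedule = protocol_schedule()) {
  tin <- t - floor(t / schedule$period + 1e-9) * schedule$period
  ifelse(tin < schedule$stim_width - 1e-9, schedule$stim_amp, 0)
}

# ---------------------------------------------------------------------------

#' Run the three-phase ischemia-reperfusion simulation
#'
#' Executes pre-ischemia, ischemia and reperfusion with the forward-Euler
#' driver, applying the prescribed trajectories and any interventions, and
#' returns the decimated time series, per-beat metrics, the reperfusion
#' sodium-flux ledger (sampled every tenth step), phase-boundary snapshots
#' and the final state.  The computation is fully deterministic.
#'
#' @param schedule An `ir_schedule`.
#' @param interventions An `ir_interventions`.
#' @param state Initial state (default: the shipped initial conditions).
#' @param params Calibrated parameters.
#' @param out_every Record every `out_every`-th step in the series output;
#'   `NULL` chooses a decimation that keeps about 50,000 rows (minimum 10,
#'   the ledger sampling).
#' @param record_series,record_beats Toggle the respective outputs.
#' @param anchors Optional named list overriding the run anchors (washout
#'   targets `na_o`, `k_o`, `ca_o`, `cl_o`, `hco3_o`, `co2_o`, `ph_o`;
#'   `osm_normal`, `ph_anchor`, `atp_pre`, `pcr_pre`, `nak_ph_normal`,
#'   `isch_t_offset_ms`), used to resume a protocol from a mid-run
#'   snapshot.
#' @return An object of class `ir_simulation`.
#' @export
simulate_ir <- function(schedule = protocol_schedule(),
                        interventions = intervention_schedule(),
                        state = NULL, params = NULL,
                        out_every = NULL, record_series = TRUE,
                        record_beats = TRUE, anchors = list()) {
  if (is.null(params)) params <- calibrated_parameters()
  if (is.null(state)) state <- initial_state(params)
  if (!is.finite(params$n_offset))
    abort("parameters are not calibrated; use calibrated_parameters()")
  n_tot <- round((schedule$pre_ms + schedule$isch_ms + schedule$rep_ms) /
                   schedule$dt)
  if (is.null(out_every)) out_every <- max(10, ceiling(n_tot / 5e4))
  out_every <- as.integer(out_every)
  res <- cpp_run(state_vector(state), params, schedule, interventions,
                 out_every, record_series, record_beats, anchors)
  sim <- list(
    series = if (!is.null(res$series)) as_tibble(as.data.frame(res$series)),
    beats = if (!is.null(res$beats)) as_tibble(as.data.frame(res$beats)),
    ledger = res$ledger,
    ledger_samples = res$ledger_samples,
    final_state = res$final_state,
    snapshots = list(pre_end = res$snapshot_pre_end,
                     ischemia_end = res$snapshot_ischemia_end),
    schedule = schedule, interventions = interventions,
    out_every = out_every,
    n_steps = res$n_steps,
    charge_offset = params$n_offset
  )
  class(sim) <- "ir_simulation"
  sim
}

#' Advance a state by a single forward-Euler step
#'
#' One deterministic Euler step of all dynamic variables under a fixed
#' phase overlay; prescribed variables are left untouched.
#'
#' @param state Named state vector.
#' @param params Calibrated parameters.
#' @param dt Step, ms.
#' @param phase "pre-ischemia", "ischemia" or "reperfusion".
#' @param istim Stimulus current, uA/uF.
#' @param nhe_scale,nak_scale,nak_ph Intervention values for this step;
#'   `nak_ph = NA` leaves the pump on the true pH.
#' @param schedule An `ir_schedule` (phase conductances).
#' @return The updated named state vector.
#' @export
step_euler <- function(state, params, dt = 0.005,
                       phase = "pre-ischemia", istim = 0,
                       nhe_scale = 1, nak_scale = 1, nak_ph = NA_real_,
                       schedule = protocol_schedule()) {
  s <- state_vector(state)
  r <- model_rates(s, params, phase = phase, istim = istim,
                   nhe_scale = nhe_scale, nak_scale = nak_scale,
                   nak_ph = nak_ph, schedule = schedule)
  d <- r$deriv
  upd <- setdiff(state_names(), c("V", "t"))
  s[upd] <- s[upd] + dt * d[upd]
  s[["t"]] <- s[["t"]] + dt
  s <- cpp_update_derived(s, params)
  s
}

#' @export
print.ir_simulation <- function(x, ...) {
  cat("<ir_simulation> ", format(x$n_steps, big.mark = ","),
      " Euler steps (dt = ", x$schedule$dt, " ms)\n", sep = "")
  cat("  phases (min): pre ", x$schedule$pre_ms / 6e4,
      ", ischemia ", x$schedule$isch_ms / 6e4,
      ", reperfusion ", x$schedule$rep_ms / 6e4,
      if (x$schedule$compress > 1)
        paste0(" (trajectory compression x", x$schedule$compress, ")"),
      "\n", sep = "")
  iv <- x$interventions
  cat("  NHE scale ", iv$nhe_scale, " (onset: ", iv$nhe_onset_label,
      "); NaK scale ", iv$nak_scale,
      if (iv$nak_clamp) "; NaK pH-clamp", "\n", sep = "")
  if (!is.null(x$series))
    cat("  series: ", nrow(x$series), " samples x ", ncol(x$series),
        " columns\n", sep = "")
  invisible(x)
}
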