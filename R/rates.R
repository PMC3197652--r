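#' Evaluate the model right-hand side at a state
#'
#' Computes the charge-difference membrane potential, every sarcolemmal
#' current, SR flux, acid-transporter flux, buffering power and state
#' derivative at the given state under a fixed phase overlay.  This is the
#' same compiled algebra the Euler driver integrates; tests check it
#' against independent closed-form evaluations.
#'
#' @param state Named state vector.
#' @param params Calibrated parameters.
#' @param phase "pre-ischemia", "ischemia" or "reperfusion".
#' @param istim Stimulus current, uA/uF.
#' @param nhe_scale NHE inhibition scale in \[0, 1\].
#' @param nak_scale Pump current multiplier.
#' @param nak_ph If finite, the pump senses this pH instead of `pH_i`.
#' @param dphi_dt Prescribed d(pH_i)/dt (1/ms) used by the anion
#'   bookkeeping during ischemia.
#' @param schedule An `ir_schedule` supplying phase conductances.
#' @return A list with `V` (mV), `deriv` (named derivative vector, per ms)
#'   and `currents` (named vector of currents and fluxes).
#' @export
model_rates <- function(state, params, phase = "pre-ischemia", istim = 0,
                        nhe_scale = 1, nak_scale = 1, nak_ph = NA_real_,
                        dphi_dt = 0, schedule = protocol_schedule()) {
  phase_id <- match(match.arg(phase, c("pre-ischemia", "ischemia",
                                       "reperfusion")),
                    c("pre-ischemia", "ischemia", "reperfusion")) - 1L
  if (nhe_scale < 0 || nhe_scale > 1) abort("nhe_scale must lie in [0, 1]")
  ctl <- list(
    phase = phase_id,
    g_na_scale = if (phase_id == 1L) schedule$g_na_isch_scale else 1.0,
    g_nal_scale = if (phase_id == 1L) schedule$g_nal_isch
                  else schedule$g_nal_normal,
    nhe_scale = nhe_scale, nak_scale = nak_scale,
    nak_clamp = is.finite(nak_ph),
    nak_ph = if (is.finite(nak_ph)) nak_ph else 7.15,
    istim = istim,
    pHi_prescribed = phase_id == 1L,
    dphi_dt_presc = dphi_dt,
    co2_prod_scale = if (phase_id == 1L) 0 else 1
  )
  r <- cpp_rates(state_vector(state), params, ctl)
  list(V = r$V, deriv = r$deriv, currents = r$aux)
}

#' ATP-dependent availability of L-type calcium channels
#'
#' Saturating fraction in (0, 1], monotonically increasing in ATP, that
#' multiplies the L-type conductance.
#'
#' @param atp ATP concentration, mM (> 0).
#' @param params Model parameters.
#' @return Availability fraction (vectorized).
#' @export
f_atp_lcc <- function(atp, params = cell_parameters()) {
  if (any(!is.finite(atp)) || any(atp <= 0))
    abort("ATP must be strictly positive")
  1 / (1 + (params$km_atp_lcc / atp)^params$hill_atp_lcc)
}

#' SERCA flux from a cycle rate
#'
#' The SR uptake flux is the pump cycling rate times the conversion factor
#' 0.00820 (myoplasm-referenced, mM/ms); the sign follows the cycle
#' direction.
#'
#' @param cycle_rate Pump cycling rate, 1/ms.
#' @param params Model parameters.
#' @export
serca_flux <- function(cycle_rate, params = cell_parameters()) {
  params$serca_factor * cycle_rate
}

#' Sodium-calcium exchanger current
#'
#' The proton-blocked (pK 7.0, Hill 0.75), 0.60-scaled exchanger current;
#' reverse mode (sodium efflux, calcium entry) occurs at depolarized
#' potentials and elevated intracellular sodium.
#'
#' @param state Named state vector.
#' @param params Calibrated parameters.
#' @return Current, uA/uF.
#' @export
ncx_current <- function(state, params) {
  model_rates(state, params)$currents[["I_NCX"]]
}

#' Proton-inhibition factor of the sodium-calcium exchanger
#' @param ph_i Intracellular pH (vectorized).
#' @param params Model parameters.
#' @export
ncx_proton_factor <- function(ph_i, params = cell_parameters()) {
  h <- 10^(3 - ph_i)
  1 / (1 + (h / 10^(3 - params$pk_ncx))^params$hill_ncx)
}

#' Sodium-potassium pump current
#'
#' The pump current with its sodium, potassium, voltage, phosphometabolite
#' and pH sensitivities.  `pH_override` evaluates the pump at a different
#' pH than the rest of the cell (the reperfusion pH-clamp experiment);
#' `scale` multiplies the current.
#'
#' @param state Named state vector.
#' @param params Calibrated parameters.
#' @param pH_override Optional pump-specific pH.
#' @param scale Current multiplier (> 0).
#' @return Current, uA/uF (always > 0: the pump extrudes sodium 3:2).
#' @export
nak_current <- function(state, params, pH_override = NULL, scale = 1) {
  if (scale <= 0) abort("scale must be > 0")
  ph <- if (is.null(pH_override)) NA_real_ else pH_override
  model_rates(state, params, nak_scale = scale,
              nak_ph = ph)$currents[["I_NaK"]]
}

#' Late sodium current
#'
#' @param state Named state vector.
#' @param params Calibrated parameters.
#' @param scale Conductance-like scale (0.0007 in the normal phases; the
#'   ischemic value is set by the protocol switch).
#' @return Current, uA/uF.
#' @export
late_na_current <- function(state, params, scale = 7e-4) {
  sc <- protocol_schedule()
  sc$g_nal_normal <- scale
  model_rates(state, params, schedule = sc)$currents[["I_NaL"]]
}

#' All membrane currents and SR fluxes at a state
#'
#' @param state Named state vector.
#' @param params Calibrated parameters.
#' @param phase Phase overlay ("pre-ischemia", "ischemia", "reperfusion").
#' @param ... Passed to [model_rates()].
#' @return A one-row tibble of currents (uA/uF) and fluxes (mM/ms).
#' @export
membrane_currents <- function(state, params, phase = "pre-ischemia", ...) {
  r <- model_rates(state, params, phase = phase, ...)
  out <- as_tibble(as.list(r$currents))
  out$V <- r$V
  out
}

#' Allosteric regulation factor of the sodium-proton exchanger
#'
#' Intracellular protons stimulate (Hill coefficient > 1), extracellular
#' protons inhibit (Hill coefficient 1); both sides share the same proton
#' binding constant.  The factor lies in \[0, 1\], rises with
#' intracellular acidosis and falls with extracellular acidosis.
#'
#' @param ph_i,ph_o Intra/extracellular pH (vectorized).
#' @param params Model parameters.
#' @export
nhe_allosteric_factor <- function(ph_i, ph_o, params = cell_parameters()) {
  h_i <- 10^(3 - ph_i); h_o <- 10^(3 - ph_o)
  f_act <- 1 / (1 + (params$k_h_nhe / h_i)^params$hill_nhe_i)
  f_inh <- 1 / (1 + (h_o / params$k_h_nhe)^params$hill_nhe_o)
  f_act * f_inh
}

#' Sodium-proton exchanger flux
#'
#' Allosterically regulated NHE flux times the inhibition scale; moves
#' sodium in and protons out with 1:1 coupling to both compartments' pH.
#'
#' @param state Named state vector.
#' @param inhibition_scale Fraction of flux remaining in \[0, 1\].
#' @param params Calibrated parameters.
#' @return Flux, mM/ms (myoplasm-referenced; > 0 is sodium entry).
#' @export
nhe_flux <- function(state, inhibition_scale = 1, params) {
  if (inhibition_scale < 0 || inhibition_scale > 1)
    abort("inhibition_scale must lie in [0, 1]")
  model_rates(state, params,
              nhe_scale = inhibition_scale)$currents[["J_NHE"]]
}

#' Acid-transporter fluxes and buffering powers at a state
#'
#' NHE, sodium-bicarbonate symporter, chloride-hydroxide exchanger, anion
#' exchanger, transmembrane CO2 transport, the CO2/bicarbonate
#' equilibration rates in both compartments, and both intrinsic buffering
#' powers.
#'
#' @param state Named state vector.
#' @param params Calibrated parameters.
#' @return A one-row tibble.
#' @export
acid_transporters <- function(state, params) {
  cur <- model_rates(state, params)$currents
  as_tibble(as.list(cur[c("J_NHE", "J_NBC", "J_CHE", "J_AE", "J_CO2m",
                          "R_CO2_i", "R_CO2_o", "beta_i", "beta_o")]))
}

#' Intracellular pH rate
#'
#' Combines NHE/CHE proton flux with CO2/bicarbonate equilibration through
#' the intrinsic buffering power.  During ischemia the intracellular pH is
#' prescribed by the protocol, so requesting its free dynamics is a
#' protocol error.
#'
#' @param state Named state vector.
#' @param params Calibrated parameters.
#' @param phase Protocol phase.
#' @return d(pH_i)/dt, 1/ms.
#' @export
d_pH_i <- function(state, params, phase = "pre-ischemia") {
  phase <- match.arg(phase, c("pre-ischemia", "ischemia", "reperfusion"))
  if (phase == "ischemia")
    abort("pH_i is prescribed during ischemia; its free dynamics are undefined")
  model_rates(state, params, phase = phase)$deriv[["pH_i"]]
}

#' Extracellular pH rate
#'
#' Mirror of the intracellular balance with reversed transporter signs and
#' extracellular volume and buffers; free only during ischemia (the
#' extracellular pH is clamped before ischemia and prescribed during
#' reperfusion).
#'
#' @param state Named state vector.
#' @param params Calibrated parameters.
#' @param phase Protocol phase.
#' @return d(pH_o)/dt, 1/ms.
#' @export
d_pH_o <- function(state, params, phase = "ischemia") {
  phase <- match.arg(phase, c("pre-ischemia", "ischemia", "reperfusion"))
  if (phase == "reperfusion")
    abort("pH_o is prescribed during reperfusion; its free dynamics are undefined")
  if (phase == "pre-ischemia") return(0)
  model_rates(state, params, phase = "ischemia")$deriv[["pH_o"]]
}

#' Extracellular CO2 accumulation rate during ischemia
#'
#' Transmembrane CO2 transport into the isolated extracellular space plus
#' the local CO2/bicarbonate equilibration.
#'
#' @param state Named state vector.
#' @param params Calibrated parameters.
#' @return d(CO2_o)/dt, mM/ms.
#' @export
update_extracellular_co2 <- function(state, params) {
  model_rates(state, params, phase = "ischemia")$deriv[["CO2_o"]]
}

#' Extracellular ion rates during ischemia
#'
#' Volume-scaled mirrors of the intracellular membrane fluxes for sodium,
#' potassium, calcium and chloride while the extracellular space is
#' isolated.
#'
#' @param state Named state vector.
#' @param params Calibrated parameters.
#' @param istim Stimulus current (its charge is carried by potassium and
#'   mirrored extracellularly).
#' @return A one-row tibble with `Na_o`, `K_o`, `Ca_o`, `Cl_o` rates, mM/ms.
#' @export
update_extracellular_ions <- function(state, params, istim = 0) {
  d <- model_rates(state, params, phase = "ischemia", istim = istim)$deriv
  tibble(Na_o = d[["Na_o"]], K_o = d[["K_o"]],
         Ca_o = d[["Ca_o"]], Cl_o = d[["Cl_o"]])
}

#' Algebraic anion surplus relative to a reference state
#'
#' The generic monovalent anion concentration that matches, 1:1, the
#' surplus of free plus buffer-bound protons relative to the reference
#' (initial) state.  This is the closed form the integrated anion state
#' reduces to when the imposed acidification is the only source of proton
#' change.
#'
#' @param state Current state (only `pH_i` is used).
#' @param ref Reference state (the start of the simulation).
#' @param params Model parameters.
#' @return Anion concentration, mM.
#' @export
anion_surplus <- function(state, ref, params = cell_parameters()) {
  htot <- function(ph) {
    10^(3 - ph) +
      params$buf1_conc / (1 + 10^(ph - params$buf1_pk)) +
      params$buf2_conc / (1 + 10^(ph - params$buf2_pk))
  }
  s <- state_vector(state); r <- state_vector(ref)
  htot(s[["pH_i"]]) - htot(r[["pH_i"]])
}

#' Osmotic water flux at a state
#'
#' Proportional to the difference between intracellular osmolarity
#' (sodium, potassium, calcium, chloride plus impermeant osmolytes, i.e.
#' the prescribed osmolarity variable) and the extracellular total.
#' Positive flux swells the cell and shrinks the extracellular space.
#'
#' @param state Named state vector.
#' @param params Calibrated parameters.
#' @return Volume rate, uL/ms.
#' @export
water_flux <- function(state, params) {
  model_rates(state, params)$currents[["J_water"]]
}

#' Dependent phosphometabolite pools
#'
#' ADP, AMP, inorganic phosphate and creatine from the prescribed ATP and
#' PCr via the creatine-kinase and adenylate-kinase equilibria and
#' conservation of the total creatine and phosphate pools.
#'
#' @param atp,pcr Prescribed concentrations, mM.
#' @param ph_i Intracellular pH (the CK equilibrium is proton-coupled).
#' @param params Calibrated parameters (pool constants).
#' @return A one-row tibble with `ADP`, `AMP`, `Pi`, `Cr`.
#' @export
phosphometabolite_pools <- function(atp, pcr, ph_i, params) {
  h <- 10^(3 - ph_i)
  cr <- params$total_cr - pcr
  adp <- atp * cr / (pcr * params$k_ck * h)
  amp <- params$k_ak * adp^2 / atp
  pi_ <- params$total_p - 3 * atp - 2 * adp - amp - pcr
  tibble(ADP = adp, AMP = amp, Pi = pi_, Cr = cr)
}
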