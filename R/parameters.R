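#' Model parameters for the ischemia-reperfusion myocyte model
#'
#' Returns the full constant set of the charge-difference guinea-pig
#' ventricular myocyte model: membrane geometry, channel conductances and
#' permeabilities, pump/exchanger constants (including the proton-block
#' constants of the sodium-calcium exchanger, pK 7.0 and Hill coefficient
#' 0.75, and the 0.60-scaled exchanger amplitude), the sarcolemmal calcium
#' pump maximum of 1.65 uA/uF, the SERCA cycle-to-flux conversion factor
#' 0.00820, intrinsic buffer concentrations and pK values (shared between
#' the intra- and extracellular compartments), CO2/bicarbonate kinetics,
#' acid-transporter scales, and the osmotic water-flux coefficient.
#'
#' Several entries are left `NA` and are filled by [calibrated_parameters()],
#' which anchors the charge-difference voltage offset and the stationarity
#' of chloride, pH, CO2 and the SR to the initial conditions.
#'
#' Units: concentrations mM, time ms, potential mV, current uA/uF,
#' volume uL, conductance mS/uF.
#'
#' @return A named list of class `ir_parameters_raw`.
#' @export
cell_parameters <- function() {
  p <- list(
    # physical constants and cell geometry
    faraday = 96485, rgas = 8.314, temp = 310,
    cap_total = 1.534e-4,          # total membrane capacitance, uF
    kw_mM2 = 1e-8,                 # water ion product in mM^2
    v_nsr = 2.098e-6, v_jsr = 1.82e-7,
    x_o = NA_real_,                # extracellular impermeant osmolytes, mM
    # fast and late sodium current
    g_na = 16.0,                   # 14.4 during ischemia (phase switch)
    g_nal = 7e-4,                  # normal late-Na scale
    # L-type and T-type calcium
    p_ca = 6.43e-4, p_ca_na = 6.75e-7, p_ca_k = 1.93e-7,
    gamma_cai = 1.0, gamma_cao = 0.341,
    gamma_nai = 0.75, gamma_nao = 0.75, gamma_ki = 0.75, gamma_ko = 0.75,
    km_fca = 6e-4,
    km_atp_lcc = 0.6, hill_atp_lcc = 2.0,   # ATP-dependent availability
    g_cat = 0.05,
    # potassium currents
    g_kr = 0.02614, g_ks_base = 0.433, g_k1 = 0.75, g_kp = 0.00552,
    p_nak_perm = 0.01833,
    g_katp = 55, katp_km_base = 0.0358, katp_km_adp = 0.0179,
    katp_km_exp = 0.256, katp_hill = 2, katp_ko_exp = 0.24,
    # sodium-potassium pump
    ibar_nak = NA_real_, km_nai_nak = 10, km_ko_nak = 1.5,
    km_atp_nak = 0.15, ki_adp_nak = 0.25, ki_pi_nak = 1.5,
    pk_nak = 6.9, hill_nak = 2.0, ph_ref_nak = 7.15,
    nak_pacing_reserve = 2.2,
    # sodium-calcium exchanger (0.60 x published amplitude)
    c_ncx = 0.60 * 2.5e-4, c2_ncx = 1e-4, gamma_ncx = 0.15,
    pk_ncx = 7.0, hill_ncx = 0.75,
    # sarcolemmal Ca pump and backgrounds
    ipca_max = 1.65, km_pca = 5e-4,
    g_nab = 6e-4, g_cab = 0.003016, g_clb = NA_real_,
    # SR calcium handling
    vmax_serca = 1.07, serca_factor = 0.00820,
    kmf_serca = 5e-4, kmr_serca = 1.7, keq_serca = 2.0, pk_serca = 6.6,
    grel = 12, kt_ryr = 0.5, tau_ro = 3, km_ri = 4e-4, tau_ri = 50,
    pk_ryr = 6.33, hill_ryr = 2, tau_tr = 180, kleak = NA_real_,
    # myoplasmic and JSR calcium buffers
    cmdn = 0.05, km_cmdn = 2.38e-3, trpn = 0.07, km_trpn = 5e-4,
    csqn = 10, km_csqn = 0.8,
    # intrinsic pH buffers (same constants in both compartments)
    buf1_conc = 84.22, buf1_pk = 6.03, buf2_conc = 29.38, buf2_pk = 7.57,
    # CO2 / bicarbonate system (apparent pK 6.10)
    k_a_co2 = 10^(3 - 6.10), k_hyd = 3e-3, p_co2 = 2e-4,
    j_co2_prod = NA_real_,
    tau_co2_prod = 6e4,            # metabolic CO2 shutdown during ischemia
    # acid transporters
    v_nhe = 4e-5, k_h_nhe = 10^(3 - 6.7),
    hill_nhe_i = 3, hill_nhe_o = 1, km_nao_nhe = 50,
    v_nbc = 4e-5, km_nbc = 10,
    k_che = NA_real_, k_ae = NA_real_,
    # osmotic water flux
    k_water = 3e-12,               # uL per ms per mOsm
    # reperfusion clearance of the accumulated metabolic acid (H+ + anion)
    tau_anion_wash = 7.5e5,
    # reference volumes for conserving intrinsic-buffer amounts
    buf_vmyo_ref = NA_real_, buf_vext_ref = NA_real_,
    # phosphometabolite couplings (closed from the initial pool)
    k_ck = NA_real_, k_ak = NA_real_,
    total_cr = NA_real_, total_p = NA_real_,
    # charge-difference calibration
    n_offset = NA_real_, v_at_offset = NA_real_
  )
  class(p) <- c("ir_parameters_raw", "list")
  p
}

#' Calibrate the model parameters against an initial state
#'
#' Closes the parameter set on a reference state (by default the shipped
#' initial conditions): the charge-difference voltage offset is fixed so
#' that the reference state maps exactly onto its stated membrane
#' potential; the chloride-hydroxide and anion exchangers, the background
#' chloride conductance, the SR leak and the metabolic CO2 production are
#' sized so that chloride, pH, bicarbonate, CO2 and the SR load are
#' stationary at the reference state; the sodium-potassium pump amplitude
#' is sized to the reference sodium influx times a pacing reserve; and the
#' creatine-kinase/adenylate-kinase equilibrium constants, total creatine
#' and total phosphate pools and the extracellular impermeant osmolyte
#' concentration are closed from the reference concentrations.
#'
#' @param state A named state vector, see [initial_state()].
#' @param params Raw parameters from [cell_parameters()].
#' @return A named list of class `ir_parameters` ready for simulation.
#' @export
calibrated_parameters <- function(state = initial_state(),
                                  params = cell_parameters()) {
  p <- unclass(params)
  h_i <- 10^(3 - state[["pH_i"]])
  p$k_ck <- state[["ATP"]] * state[["Cr"]] /
    (state[["PCr"]] * state[["ADP"]] * h_i)
  p$k_ak <- state[["AMP"]] * state[["ATP"]] / state[["ADP"]]^2
  p$total_cr <- state[["Cr"]] + state[["PCr"]]
  p$total_p <- 3 * state[["ATP"]] + 2 * state[["ADP"]] + state[["AMP"]] +
    state[["Pi"]] + state[["PCr"]]
  p$x_o <- state[["Osm_i"]] -
    (state[["Na_o"]] + state[["K_o"]] + state[["Ca_o"]] + state[["Cl_o"]])
  p$buf_vmyo_ref <- state[["V_myo"]]
  p$buf_vext_ref <- state[["V_ext"]]
  cal <- cpp_calibrate(state_vector(state), p, state[["V"]],
                       p$nak_pacing_reserve)
  for (nm in names(cal)) p[[nm]] <- cal[[nm]]
  class(p) <- c("ir_parameters", "list")
  p
}

#' @export
print.ir_parameters <- function(x, ...) {
  cat("<ir_parameters> ", length(x), " constants; charge offset ",
      format(x$n_offset, digits = 10), " mol at ",
      format(x$v_at_offset), " mV\n", sep = "")
  invisible(x)
}
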