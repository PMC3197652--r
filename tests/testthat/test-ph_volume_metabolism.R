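test_that("NHE allosteric factor: limits, range and the compiled route", {
  p <- test_params()
  # no intracellular stimulation as free protons vanish
  expect_lt(nhe_allosteric_factor(10.5, 7.4, p), 1e-8)
  # extracellular inhibition vanishes at high extracellular pH
  f_int_only <- 1 / (1 + (p$k_h_nhe / 10^(3 - 6.8))^p$hill_nhe_i)
  expect_rel(nhe_allosteric_factor(6.8, 13, p), f_int_only, 1e-5)
  # direct evaluation at a stated acidotic pair
  h_i <- 10^(3 - 6.5); h_o <- 10^(3 - 6.0)
  expected <- (1 / (1 + (p$k_h_nhe / h_i)^3)) * (1 / (1 + h_o / p$k_h_nhe))
  expect_equal(nhe_allosteric_factor(6.5, 6.0, p), expected)
  grid <- expand.grid(pi_ = seq(6, 7.8, 0.3), po = seq(6, 7.8, 0.3))
  f <- nhe_allosteric_factor(grid$pi_, grid$po, p)
  expect_true(all(f >= 0 & f <= 1))
  # stimulated by intracellular, inhibited by extracellular protons
  expect_true(all(diff(nhe_allosteric_factor(seq(7.4, 6.2, -0.2), 7.4, p)) > 0))
  expect_true(all(diff(nhe_allosteric_factor(6.8, seq(7.4, 6.2, -0.2), p)) < 0))
  # the compiled model evaluates the same regulation
  s <- settled_state()
  expect_rel(membrane_currents(s, p)$allo_NHE,
             nhe_allosteric_factor(s[["pH_i"]], s[["pH_o"]], p), 1e-12)
})

test_that("NHE flux scales linearly with inhibition and matches closed form", {
  p <- test_params()
  s <- settled_state()
  expect_equal(nhe_flux(s, 0, p), 0)
  expect_rel(nhe_flux(s, 0.5, p) / nhe_flux(s, 1, p), 0.5, 1e-12)
  expect_error(nhe_flux(s, 1.2, p), "\\[0, 1\\]")
  j_expected <- p$v_nhe *
    nhe_allosteric_factor(s[["pH_i"]], s[["pH_o"]], p) *
    s[["Na_o"]] / (s[["Na_o"]] + p$km_nao_nhe)
  expect_rel(nhe_flux(s, 1, p), j_expected, 1e-12)
})

test_that("bicarbonate symporter follows its transmembrane gradient", {
  p <- test_params()
  s <- settled_state()
  s_eq <- s; s_eq[["HCO3_i"]] <- s[["HCO3_o"]]
  expect_equal(acid_transporters(s_eq, p)$J_NBC, 0)
  # lowering intracellular bicarbonate at fixed extracellular increases
  # inward flux
  s_lo <- s; s_lo[["HCO3_i"]] <- 0.5 * s[["HCO3_i"]]
  expect_gt(acid_transporters(s_lo, p)$J_NBC,
            acid_transporters(s, p)$J_NBC)
  expect_gt(acid_transporters(s_lo, p)$J_NBC, 0)
})

test_that("intracellular pH dynamics: fixed point, structure, protocol guard", {
  p <- test_params()
  s0 <- test_state()
  # the calibration leaves the initial state stationary in pH
  expect_lt(abs(d_pH_i(s0, p)), 1e-12)
  # the rate is (J_NHE - J_CHE - R_CO2_i) / beta_i
  s <- ischemic_state()
  cur <- membrane_currents(s, p, phase = "reperfusion")
  expect_rel(d_pH_i(s, p, "reperfusion") -
               s[["Anion_i"]] / p$tau_anion_wash / cur$beta_i,
             (cur$J_NHE - cur$J_CHE - cur$R_CO2_i) / cur$beta_i, 1e-9)
  expect_error(d_pH_i(s, p, "ischemia"), "prescribed")
})

test_that("extracellular pH dynamics mirror with reversed signs", {
  p <- test_params()
  s <- ischemic_state()
  cur <- membrane_currents(s, p, phase = "ischemia")
  rv <- s[["V_myo"]] / s[["V_ext"]]
  expected <- (-cur$J_NHE * rv + cur$J_CHE * rv - cur$R_CO2_o) / cur$beta_o
  expect_rel(d_pH_o(s, p, "ischemia"), expected, 1e-9)
  expect_error(d_pH_o(s, p, "reperfusion"), "prescribed")
  expect_equal(d_pH_o(s, p, "pre-ischemia"), 0)
  # equal buffer constants: beta_o(pH) = beta_i(pH) at matched pH and
  # matched (reference) compartment volumes
  s_eq <- s; s_eq[["pH_o"]] <- s[["pH_i"]]
  s_eq[["V_myo"]] <- p$buf_vmyo_ref; s_eq[["V_ext"]] <- p$buf_vext_ref
  cur_eq <- membrane_currents(s_eq, p)
  expect_rel(cur_eq$beta_o, cur_eq$beta_i, 1e-12)
})

test_that("extracellular species mirror intracellular membrane fluxes", {
  p <- test_params()
  s <- ischemic_state()
  s[["Osm_i"]] <- s[["Na_i"]] + s[["K_i"]] + s[["Ca_i"]] + s[["Cl_i"]] +
    x_i_from_osmolarity(s[["Osm_i"]], s)  # keep as is; water flux nonzero ok
  r <- model_rates(s, p, phase = "ischemia", istim = -80)
  d <- r$deriv
  jw <- r$currents[["J_water"]]
  # amount balance: V_myo*dc_i + V_ext*dc_o + c*dV terms cancel exactly
  for (sp in c("Na", "K", "Cl")) {
    ci <- s[[paste0(sp, "_i")]]; co <- s[[paste0(sp, "_o")]]
    amt <- s[["V_myo"]] * d[[paste0(sp, "_i")]] + ci * jw +
      s[["V_ext"]] * d[[paste0(sp, "_o")]] + co * (-jw)
    expect_lt(abs(amt) / (abs(ci) * s[["V_myo"]]), 1e-12)
  }
  # total calcium (free + buffered + SR + extracellular) is conserved
  bca <- 1 / (1 + p$cmdn * p$km_cmdn / (p$km_cmdn + s[["Ca_i"]])^2 +
                p$trpn * p$km_trpn / (p$km_trpn + s[["Ca_i"]])^2)
  bjsr <- 1 / (1 + p$csqn * p$km_csqn / (p$km_csqn + s[["Ca_jsr"]])^2)
  amt_ca <- s[["V_myo"]] * (d[["Ca_i"]] / bca + s[["Ca_i"]] * jw / s[["V_myo"]]) +
    p$v_jsr * d[["Ca_jsr"]] / bjsr + p$v_nsr * d[["Ca_nsr"]] +
    s[["V_ext"]] * (d[["Ca_o"]] - s[["Ca_o"]] * jw / s[["V_ext"]])
  expect_lt(abs(amt_ca) / (s[["Ca_o"]] * s[["V_ext"]]), 1e-9)
  # potassium accumulates extracellularly over simulated ischemia
  expect_gt(ischemic_state()[["K_o"]], test_state()[["K_o"]])
  # carbon dioxide accumulates outside while the cell runs acidotic
  expect_gt(update_extracellular_co2(s, p), 0)
})

test_that("anion bookkeeping is exact under pure imposed acidification", {
  # disable every proton pathway except the prescription; then the
  # integrated anion equals the algebraic free + buffer-bound surplus
  p0 <- cell_parameters()
  p0$v_nhe <- 0; p0$v_nbc <- 0; p0$k_hyd <- 0; p0$p_co2 <- 0
  p0$k_water <- 0
  p <- calibrated_parameters(params = p0)
  s0 <- initial_state(p)
  sc <- protocol_schedule(pre_min = 0, isch_min = 0.25, rep_min = 0,
                          compress = 40)
  sim <- simulate_ir(sc, state = s0, params = p, record_series = FALSE,
                     record_beats = FALSE)
  fs <- sim$final_state
  expect_gt(fs[["Anion_i"]], 1)     # acid load accumulated
  expect_rel(fs[["Anion_i"]], anion_surplus(fs, s0, p), 1e-6)
  expect_equal(s0[["Anion_i"]], 0)
})

test_that("water flux follows the osmotic gradient", {
  p <- test_params()
  s <- test_state()
  expect_lt(abs(water_flux(s, p)), 1e-15)     # 310 vs 310 at start
  s_hyper <- s; s_hyper[["Na_o"]] <- s[["Na_o"]] + 10
  expect_lt(water_flux(s_hyper, p), 0)         # water leaves the cell
  s_swell <- s; s_swell[["Osm_i"]] <- 320
  ext_osm <- s[["Na_o"]] + s[["K_o"]] + s[["Ca_o"]] + s[["Cl_o"]] + p$x_o
  expect_rel(water_flux(s_swell, p), p$k_water * (320 - ext_osm), 1e-12)
})

test_that("phosphometabolite pools keep their conserved totals", {
  p <- test_params()
  for (frac in c(1, 0.7, 0.5, 0.3)) {
    atp <- 7.216 * frac; pcr <- 13.3 * frac
    pools <- phosphometabolite_pools(atp, pcr, 6.8, p)
    expect_rel(pools$Cr + pcr, p$total_cr, 1e-12)
    expect_rel(3 * atp + 2 * pools$ADP + pools$AMP + pools$Pi + pcr,
               p$total_p, 1e-12)
    expect_true(all(unlist(pools) > 0))
  }
  # direct evaluation at half the pre-ischemic ATP
  half <- phosphometabolite_pools(3.608, 6.65, 7.15, p)
  cr <- p$total_cr - 6.65
  adp <- 3.608 * cr / (6.65 * p$k_ck * 10^(3 - 7.15))
  expect_rel(half$ADP, adp, 1e-12)
  expect_rel(half$AMP, p$k_ak * adp^2 / 3.608, 1e-12)
})
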