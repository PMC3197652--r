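test_that("charge-difference voltage responds only to net charge", {
  p <- test_params()
  s <- test_state()
  v0 <- compute_voltage(s, p)
  # electroneutral pair: +delta K_i with +delta Anion_i leaves V unchanged
  s1 <- s; d <- 1e-3
  s1[["K_i"]] <- s1[["K_i"]] + d
  s1[["Anion_i"]] <- s1[["Anion_i"]] + d
  expect_lt(abs(compute_voltage(s1, p) - v0), 1e-9)
  # a bare cation increment shifts V by delta * F * V_myo / (C_m * A_cap)
  s2 <- s; d2 <- 1e-6
  s2[["K_i"]] <- s2[["K_i"]] + d2
  dv_expected <- d2 * 1e-9 * s[["V_myo"]] * p$faraday / (p$cap_total * 1e-6) *
    1e3  # mM*uL -> mol; F*Q/C in volts -> mV
  expect_rel(compute_voltage(s2, p) - v0, dv_expected, 1e-6)
})

test_that("ohmic currents vanish at their reversal potentials", {
  p <- test_params()
  s <- settled_state()
  v <- compute_voltage(s, p)
  rtf <- 1000 * p$rgas * p$temp / p$faraday
  # extracellular concentrations do not enter the charge sum, so they can
  # be placed to put each Nernst potential at the current V
  s_na <- s; s_na[["Na_o"]] <- s[["Na_i"]] * exp(v / rtf)
  cur <- membrane_currents(s_na, p)
  expect_lt(abs(cur$I_Nab), 1e-10)
  expect_lt(abs(cur$I_Na), 1e-10)
  s_cl <- s; s_cl[["Cl_o"]] <- s[["Cl_i"]] * exp(-v / rtf)
  expect_lt(abs(membrane_currents(s_cl, p)$I_Clb), 1e-10)
})

test_that("L-type availability saturates, grows with ATP, rejects bad input", {
  p <- test_params()
  expect_lt(abs(f_atp_lcc(1e6, p) - 1), 1e-6)
  expect_equal(f_atp_lcc(p$km_atp_lcc, p), 0.5)
  atp <- seq(0.2, 10, by = 0.2)
  expect_true(all(diff(f_atp_lcc(atp, p)) > 0))
  expect_true(all(f_atp_lcc(atp, p) > 0 & f_atp_lcc(atp, p) <= 1))
  expect_error(f_atp_lcc(0, p), "positive")
  expect_error(f_atp_lcc(-1, p), "positive")
})

test_that("SERCA flux is the cycle rate times 0.00820", {
  p <- test_params()
  expect_equal(serca_flux(0, p), 0)
  rates <- c(-2, 0.3, 1.7)
  expect_equal(serca_flux(rates, p) / rates, rep(0.00820, 3))
  # the driver's uptake flux obeys the same conversion
  cur <- membrane_currents(settled_state(), p)
  expect_rel(cur$J_up / cur$v_SERCA, 0.00820, 1e-12)
})

test_that("NCX proton block is half at pH 7.0 and relieved by alkalosis", {
  p <- test_params()
  expect_equal(ncx_proton_factor(7.0, p), 0.5)
  ph <- seq(6.0, 7.8, by = 0.1)
  expect_true(all(diff(ncx_proton_factor(ph, p)) > 0))
  # the compiled exchanger uses the same factor
  s <- settled_state()
  f_cpp <- membrane_currents(s, p)$f_H_NCX
  expect_rel(f_cpp, ncx_proton_factor(s[["pH_i"]], p), 1e-12)
  # current is linear in the amplitude scale (0.60 x published)
  p2 <- p; p2$c_ncx <- p$c_ncx / 0.60
  expect_rel(ncx_current(s, p) / ncx_current(s, p2), 0.60, 1e-10)
})

test_that("pump current loses substrate, gains from a pH clamp, scales", {
  p <- test_params()
  s <- settled_state()
  s_noatp <- s; s_noatp[["ATP"]] <- 1e-6
  expect_lt(nak_current(s_noatp, p), 1e-3 * nak_current(s, p))
  # an acidotic cell: overriding the pump's sensed pH to normal raises it
  si <- ischemic_state()
  expect_gt(nak_current(si, p, pH_override = 7.15), nak_current(si, p))
  expect_gt(nak_current(si, p), 0)
  expect_rel(nak_current(s, p, scale = 2) / nak_current(s, p), 2, 1e-12)
})

test_that("late sodium current is proportional to its scale", {
  p <- test_params()
  s <- settled_state()
  s0 <- s; s0[["m_L"]] <- 0
  expect_equal(late_na_current(s0, p), 0)
  i1 <- late_na_current(s, p, scale = 7e-4)
  i2 <- late_na_current(s, p, scale = 1.8e-3)
  expect_rel(i2 / i1, 1.8e-3 / 7e-4, 1e-10)
})

test_that("ischemic phase overlay switches conductances as published", {
  sw_pre <- apply_phase_switches("pre-ischemia")
  sw_isch <- apply_phase_switches("ischemia")
  expect_equal(sw_pre$g_na, 16.0)
  expect_equal(sw_isch$g_na, 14.4)
  expect_equal(sw_pre$g_nal_scale, 7e-4)
  # both printed readings of the ischemic late-Na scale are available
  expect_equal(protocol_schedule(inal_ischemic = "increase")$g_nal_isch,
               1.8e-3)
  expect_equal(protocol_schedule(inal_ischemic = "literal")$g_nal_isch,
               1.8e-4)
  # the fast-Na current itself shrinks by 10 percent under the overlay
  p <- test_params()
  s <- settled_state()
  ina_pre <- model_rates(s, p, phase = "pre-ischemia")$currents[["I_Na"]]
  ina_isch <- model_rates(s, p, phase = "ischemia")$currents[["I_Na"]]
  expect_rel(ina_isch / ina_pre, 14.4 / 16, 1e-10)
})

test_that("pump extrudes while channels and forward exchange load sodium", {
  p <- test_params()
  cur <- membrane_currents(settled_state(), p)
  expect_gt(cur$I_NaK, 0)              # net Na out
  expect_lt(cur$I_Nab, 0)              # background Na in
  expect_lt(cur$I_NCX, 0)              # forward mode at diastole: Na in
})
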