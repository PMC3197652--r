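# Bookkeeping properties of the charge-difference formulation: the same
# physics reached by two independent routes must agree.

test_that("voltage change equals the integrated membrane current", {
  # the charge-difference potential and -(1/C_m) * sum(I_total) dt follow
  # the same physics; they agree to integration tolerance (the nonlinear
  # rapid-buffer algebra makes the map first-order accurate, so the
  # residual must be small relative to the current turnover and shrink
  # when the step is halved)
  p <- test_params()
  resid <- function(dt) {
    sc <- protocol_schedule(pre_min = 5 / 60, isch_min = 0, rep_min = 0,
                            dt = dt)
    sim <- simulate_ir(sc, params = p, out_every = 1, record_beats = FALSE)
    ser <- sim$series
    dv_direct <- ser$V[nrow(ser)] - ser$V[1]
    dv_currents <- -sum(ser$I_total[-nrow(ser)]) * dt
    c(residual = abs(dv_direct - dv_currents),
      turnover = sum(abs(ser$I_total[-nrow(ser)])) * dt)
  }
  r1 <- resid(0.005); r2 <- resid(0.0025)
  expect_lt(r1[["residual"]], 1e-2 * r1[["turnover"]])
  expect_lt(r2[["residual"]], 0.75 * r1[["residual"]])
})

test_that("ions are conserved across the two compartments during ischemia", {
  p <- test_params()
  s <- ischemic_state()
  sc <- protocol_schedule(pre_min = 0, isch_min = 10 / 60, rep_min = 0)
  sim <- simulate_ir(sc, state = s, params = p, record_series = FALSE,
                     record_beats = FALSE)
  f <- sim$final_state
  amount <- function(st, sp) {
    st[[paste0(sp, "_i")]] * st[["V_myo"]] +
      st[[paste0(sp, "_o")]] * st[["V_ext"]]
  }
  for (sp in c("Na", "K", "Cl")) {
    expect_rel(amount(f, sp), amount(s, sp), 1e-6)
  }
  ca_total <- function(st) {
    ca <- st[["Ca_i"]]
    catot <- ca + p$cmdn * ca / (ca + p$km_cmdn) +
      p$trpn * ca / (ca + p$km_trpn)
    cajsr <- st[["Ca_jsr"]] + p$csqn * st[["Ca_jsr"]] /
      (st[["Ca_jsr"]] + p$km_csqn)
    catot * st[["V_myo"]] + cajsr * p$v_jsr + st[["Ca_nsr"]] * p$v_nsr +
      st[["Ca_o"]] * st[["V_ext"]]
  }
  # calcium closes through the nonlinear rapid-buffer factors, so its
  # conservation holds to Euler (first-order) tolerance
  expect_rel(ca_total(f), ca_total(s), 1e-4)
  # total volume is conserved by water flux
  expect_rel(f[["V_myo"]] + f[["V_ext"]], s[["V_myo"]] + s[["V_ext"]], 1e-9)
})

test_that("imposed acidification is charge-neutral through the anion", {
  # during prescribed ischemic acidification the membrane potential keeps
  # obeying the current-integral route: the imposed proton load is paired
  # with the generic anion and is invisible to the charge sum (again to
  # integration tolerance, shrinking under step halving)
  p <- test_params()
  s <- settled_state()
  resid <- function(dt) {
    sc <- protocol_schedule(pre_min = 0, isch_min = 5 / 60, rep_min = 0,
                            compress = 10, dt = dt)
    sim <- simulate_ir(sc, state = s, params = p, out_every = 1,
                       record_beats = FALSE,
                       anchors = list(ph_anchor = s[["pH_i"]]))
    ser <- sim$series
    dv_direct <- ser$V[nrow(ser)] - ser$V[1]
    dv_currents <- -sum(ser$I_total[-nrow(ser)]) * dt
    list(residual = abs(dv_direct - dv_currents),
         turnover = sum(abs(ser$I_total[-nrow(ser)])) * dt,
         anion = sim$final_state[["Anion_i"]])
  }
  r1 <- resid(0.005); r2 <- resid(0.0025)
  expect_lt(r1$residual, 1e-2 * r1$turnover)
  expect_lt(r2$residual, 0.75 * r1$residual)
  expect_gt(r1$anion, 0)
})

test_that("steady sodium rises with pacing rate and with resting acidosis", {
  p <- test_params()
  run_rate <- function(hz, minutes = 1) {
    sc <- protocol_schedule(pre_min = minutes, isch_min = 0, rep_min = 0,
                            rate_hz = max(hz, 1))
    if (hz == 0) sc$stim_width <- 0   # resting: no stimulus delivered
    simulate_ir(sc, params = p, record_series = FALSE,
                record_beats = FALSE)$final_state
  }
  f0 <- run_rate(0); f1 <- run_rate(1); f3 <- run_rate(3)
  # relative to the common start, faster pacing loads more sodium
  expect_lt(f0[["Na_i"]], f1[["Na_i"]])
  expect_lt(f1[["Na_i"]], f3[["Na_i"]])
  # resting sodium influx is larger under mild acidosis (pH_i 6.9);
  # the imposed proton load carries its conjugate anion so the state
  # stays charge-consistent
  s0 <- test_state()
  cur_n <- membrane_currents(s0, p)
  s_acid <- s0; s_acid[["pH_i"]] <- 6.9
  s_acid[["Anion_i"]] <- anion_surplus(s_acid, s0, p)
  cur_a <- membrane_currents(s_acid, p)
  # the acid-coupled sodium entry (NHE + NBC) rises while the
  # proton-blocked exchanger carries less
  expect_gt(cur_a$J_NHE + cur_a$J_NBC, cur_n$J_NHE + cur_n$J_NBC)
  expect_gt(cur_a$J_NHE, cur_n$J_NHE)
  expect_gt(abs(cur_a$I_NCX) < abs(cur_n$I_NCX), 0)
})
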