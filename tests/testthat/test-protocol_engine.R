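test_that("prescribed ischemic pH is anchored, monotone and guarded", {
  sc <- protocol_schedule()
  expect_equal(pH_i_prescribed(0, sc, ph_start = 7.12), 7.12)
  traj <- pH_i_prescribed(seq(0, 20, by = 0.5), sc, ph_start = 7.15)
  expect_true(all(diff(traj) < 0))
  expect_gt(traj[length(traj)], sc$ph_end_isch)
  expect_error(pH_i_prescribed(-1, sc), "window")
  expect_error(pH_i_prescribed(25, sc), "window")
})

test_that("extracellular pH relaxes to 7.40 in about ten minutes", {
  sc <- protocol_schedule()
  expect_equal(pH_o_reperfusion_step(7.40, sc$dt, sc), 7.40)
  # stepping never overshoots and is monotone upward from acidosis
  ph <- 6.45
  for (k in 1:200) {
    ph_next <- pH_o_reperfusion_step(ph, 50, sc)
    expect_gt(ph_next, ph); expect_lt(ph_next, 7.40)
    ph <- ph_next
  }
  # closed form: time to come within 0.01 of target from 6.45
  t_rec <- -sc$tau_pho * log(0.01 / (7.40 - 6.45))
  expect_gt(t_rec / 6e4, 8)
  expect_lt(t_rec / 6e4, 14)
})

test_that("washout recovers in about two minutes; half-time is tau ln 2", {
  sc <- protocol_schedule()
  expect_equal(washout_step(5.4, 5.4, sc$dt, sc), 5.4)
  # discrete iteration against the continuous half-recovery time
  dt <- 1; conc <- 15.4; target <- 5.4
  half <- target + (conc - target) / 2
  t <- 0
  while (conc > half) { conc <- washout_step(conc, target, dt, sc); t <- t + dt }
  expect_rel(t, sc$tau_wash * log(2), 1e-3)
  # two minutes reduce the initial gap by more than 90 percent
  expect_lt(exp(-12e4 / sc$tau_wash), 0.05)
})

test_that("metabolite schedules are continuous and saturate at 40/75 percent", {
  sc <- protocol_schedule()
  isch0 <- phosphometabolite_schedule(0, "ischemia", sc)
  expect_equal(isch0$ATP, 7.216)
  expect_equal(isch0$PCr, 13.3)
  endi <- phosphometabolite_schedule(20, "ischemia", sc)
  expect_lt(endi$ATP, 0.3 * 7.216)
  expect_lt(endi$PCr, 0.12 * 13.3)
  rec <- phosphometabolite_schedule(60, "reperfusion", sc,
                                    atp_end = endi$ATP, pcr_end = endi$PCr)
  expect_rel(rec$ATP, 0.40 * 7.216, 1e-6)
  expect_rel(rec$PCr, 0.75 * 13.3, 1e-6)
  # full ATP recovery mode reaches the pre-ischemic concentration
  rec_full <- phosphometabolite_schedule(60, "reperfusion", sc,
                                         atp_end = endi$ATP,
                                         pcr_end = endi$PCr,
                                         atp_rec_frac = 1.0)
  expect_rel(rec_full$ATP, 7.216, 1e-6)
  # most recovery happens within the first few minutes
  rec3 <- phosphometabolite_schedule(3, "reperfusion", sc,
                                     atp_end = endi$ATP, pcr_end = endi$PCr)
  expect_gt((rec3$ATP - endi$ATP) / (rec$ATP - endi$ATP), 0.8)
})

test_that("osmolarity rises linearly then relaxes; X_i follows", {
  sc <- protocol_schedule()
  o <- osmolarity_schedule(c(0, 5, 10, 20), "ischemia", sc)
  expect_equal(o[1], 310)
  expect_equal(diff(o), c(5, 5, 10) * sc$osm_slope * 6e4 / c(1, 1, 2) *
                 c(1, 1, 2), tolerance = 1e-9)
  expect_equal(osmolarity_schedule(0, "reperfusion", sc, osm_end = 330), 330)
  expect_rel(osmolarity_schedule(30, "reperfusion", sc, osm_end = 330),
             310, 1e-4)
  s <- test_state()
  expect_equal(x_i_from_osmolarity(320, s),
               320 - (s[["Na_i"]] + s[["K_i"]] + s[["Ca_i"]] + s[["Cl_i"]]))
})

test_that("phase switches prescribe the right variables per phase", {
  pre <- apply_phase_switches("pre-ischemia")
  isch <- apply_phase_switches("ischemia")
  rep_ <- apply_phase_switches("reperfusion")
  expect_equal(pre$extracellular, "clamped")
  expect_equal(pre$pH_i, "dynamic")
  expect_equal(isch$pH_i, "prescribed")
  expect_equal(isch$pH_o, "dynamic")
  expect_equal(rep_$pH_o, "prescribed")
  expect_equal(rep_$pH_i, "dynamic")
  expect_equal(rep_$extracellular, "washout")
})

test_that("stimulus: -80 uA/uF, 0.5 ms, 180 pulses per minute", {
  sc <- protocol_schedule()
  expect_equal(stimulus_current(0.25, sc), -80)
  expect_equal(stimulus_current(1.0, sc), 0)
  expect_equal(stimulus_current(1000 / 3 + 0.1, sc), -80)
  t <- seq(0, 6e4 - 0.5, by = 0.5)
  onsets <- sum(stimulus_current(t, sc) < 0)   # one sample inside each pulse
  expect_equal(onsets, 180)
})

test_that("the Euler driver is deterministic and honors degenerate phases", {
  p <- test_params()
  sc <- protocol_schedule(pre_min = 2 / 60, isch_min = 0, rep_min = 0)
  a <- simulate_ir(sc, params = p, record_series = FALSE,
                   record_beats = FALSE)
  b <- simulate_ir(sc, params = p, record_series = FALSE,
                   record_beats = FALSE)
  expect_identical(a$final_state, b$final_state)
  # a protocol with zero-length ischemia and reperfusion is plain pacing
  sc0 <- protocol_schedule(pre_min = 2 / 60, isch_min = 0, rep_min = 0)
  expect_identical(simulate_ir(sc0, params = p, record_series = FALSE,
                               record_beats = FALSE)$final_state,
                   a$final_state)
})

test_that("segmented runs reproduce the single-pass protocol exactly", {
  p <- test_params()
  s0 <- test_state()
  sc <- protocol_schedule(pre_min = 5 / 60, isch_min = 20 / 60,
                          rep_min = 10 / 60, compress = 30)
  one <- simulate_ir(sc, intervention_schedule(0, "reperfusion"),
                     state = s0, params = p, record_series = FALSE,
                     record_beats = FALSE)
  g <- run_protocol_grid("R0", sc, params = p, state = s0)
  seg <- g$reperfusion$R0$final_state
  keep <- setdiff(names(seg), "t")
  expect_lt(max(abs(seg[keep] - one$final_state[keep])), 1e-7)
})

test_that("Euler agrees with an adaptive-step reference on a short window", {
  skip_if_not_installed("deSolve")
  p <- test_params()
  s0 <- test_state()
  nm <- state_names()
  rhs <- function(t, y, parms) {
    names(y) <- nm
    d <- model_rates(y, p, phase = "pre-ischemia")$deriv
    d[["V"]] <- 0; d[["t"]] <- 0
    list(as.numeric(d))
  }
  t_end <- 400
  ref <- deSolve::lsoda(s0, c(0, t_end), rhs, NULL,
                        rtol = 1e-8, atol = 1e-12)
  ref_end <- ref[nrow(ref), -1]
  names(ref_end) <- nm
  # unpaced Euler window (stimulus width 0 disables pacing cleanly)
  sc <- protocol_schedule(pre_min = t_end / 6e4, isch_min = 0, rep_min = 0)
  sc$stim_width <- 0
  eul <- simulate_ir(sc, params = p, record_series = FALSE,
                     record_beats = FALSE)$final_state
  eul <- reperfusim:::cpp_update_derived(eul, p)
  expect_lt(abs(eul[["Na_i"]] - ref_end[["Na_i"]]), 1e-5)
  expect_lt(abs(eul[["K_i"]] - ref_end[["K_i"]]), 1e-4)
  expect_lt(abs(eul[["Ca_i"]] - ref_end[["Ca_i"]]), 1e-7)
  expect_lt(abs(eul[["pH_i"]] - ref_end[["pH_i"]]), 1e-6)
  v_ref <- compute_voltage(ref_end, p)
  expect_lt(abs(eul[["V"]] - v_ref), 0.05)
})

test_that("step halving converges on the paced membrane potential", {
  p <- test_params()
  run_dt <- function(dt) {
    sc <- protocol_schedule(pre_min = 2 / 60, isch_min = 0, rep_min = 0,
                            dt = dt)
    simulate_ir(sc, params = p, record_series = FALSE,
                record_beats = FALSE)$final_state
  }
  f1 <- run_dt(0.005); f2 <- run_dt(0.0025); f3 <- run_dt(0.00125)
  e1 <- abs(f1[["Na_i"]] - f3[["Na_i"]])
  e2 <- abs(f2[["Na_i"]] - f3[["Na_i"]])
  expect_lt(e2, e1)                       # refinement helps
  expect_lt(abs(f1[["V"]] - f3[["V"]]), 0.5)
  expect_lt(abs(f1[["Na_i"]] - f3[["Na_i"]]), 5e-4)
})

test_that("negative-concentration guard aborts instead of clamping", {
  p <- test_params()
  s <- test_state()
  s[["Ca_jsr"]] <- 1e-12   # release will drive JSR calcium through zero
  s[["Ca_nsr"]] <- 1e-12
  p2 <- p; p2$kleak <- 10  # absurd leak to force the crossing
  sc <- protocol_schedule(pre_min = 1 / 60, isch_min = 0, rep_min = 0)
  expect_error(simulate_ir(sc, state = s, params = p2,
                           record_series = FALSE, record_beats = FALSE),
               "left \\(0, Inf\\)|non-positive|diverged")
})
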