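# Shared, lazily-computed objects for the whole suite.  Everything here is
# deterministic; caching only avoids repeating identical simulations.

.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .cache)) {
    assign(name, force(expr), envir = .cache)
  }
  get(name, envir = .cache)
}

test_params <- function() cached("params", calibrated_parameters())

test_state <- function() cached("state", initial_state(test_params()))

# a paced mid-diastole state a few beats in (well-posed gates/currents)
settled_state <- function() cached("settled", {
  sc <- protocol_schedule(pre_min = 2 / 60, isch_min = 0, rep_min = 0)
  simulate_ir(sc, params = test_params(), record_series = FALSE,
              record_beats = FALSE)$final_state
})

# a (time-compressed) end-ischemic state for acidotic-condition tests
ischemic_state <- function() cached("ischemic", {
  sc <- protocol_schedule(pre_min = 2 / 60, isch_min = 1, rep_min = 0,
                          compress = 20)
  simulate_ir(sc, params = test_params(), record_series = FALSE,
              record_beats = FALSE)$final_state
})

# five minutes of pre-ischemic pacing at 3 Hz (steady-state checks)
pre5_sim <- function() cached("pre5", {
  sc <- protocol_schedule(pre_min = 5, isch_min = 0, rep_min = 0)
  simulate_ir(sc, params = test_params(), record_series = FALSE,
              record_beats = TRUE)
})

# the full-protocol grid (5 + 20 + 10 min) for control and the R-series
full_grid <- function() cached("full_grid", {
  run_protocol_grid(c("control", "R50", "R0"), protocol_schedule(),
                    params = test_params(), state = test_state())
})

# desk-scale grid (trajectory-compressed) covering all seven scenarios and
# the pump pH-clamp run
desk_grid <- function() cached("desk_grid", {
  sc <- protocol_schedule(pre_min = 5, isch_min = 5, rep_min = 2.5,
                          compress = 4)
  run_protocol_grid(c("control", "R50", "R0", "M50", "M0", "I50", "I0",
                      "R0_nak_ph_clamp"), sc,
                    params = test_params(), state = test_state())
})

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
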