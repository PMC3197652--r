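#' Canonical state-variable names
#'
#' The state vector layout is flat, ordered and frozen: the Euler driver,
#' the series output, snapshots and serialization all share it.
#'
#' @return Character vector of state names.
#' @export
state_names <- function() as.character(cpp_state_names())

# coerce a named vector/list/one-row data frame into the canonical order
state_vector <- function(state) {
  nm <- state_names()
  if (is.data.frame(state)) {
    if (nrow(state) != 1) abort("state data frame must have exactly one row")
    state <- unlist(state[1, , drop = TRUE])
  }
  state <- unlist(state)
  if (is.null(names(state))) {
    if (length(state) != length(nm))
      abort("unnamed state must have the full canonical length")
    names(state) <- nm
    return(state)
  }
  missing <- setdiff(nm, names(state))
  if (length(missing) > 0)
    abort(paste0("state is missing fields: ", paste(missing, collapse = ", ")))
  out <- as.numeric(state[nm])
  names(out) <- nm
  out
}

#' Load the pre-ischemic initial conditions
#'
#' Reads the shipped name-value fixture of the pre-ischemic initial state
#' (the single source of truth for the state mapping) and completes the
#' entries that are defined by equilibria rather than stated directly:
#' CO2 in each compartment from the bicarbonate/pH equilibrium at the
#' apparent pK of 6.10, the ryanodine-receptor inactivation gate at the
#' resting calcium, the proton-loaded intrinsic buffers at the initial pH,
#' and the impermeant osmolyte concentration from the initial osmolarity.
#'
#' @param params Raw or calibrated parameters; only the equilibrium
#'   constants are used.
#' @return A named numeric state vector in canonical order.
#' @export
load_initial_conditions <- function(params = cell_parameters()) {
  path <- system.file("extdata", "initial_conditions.tsv",
                      package = "reperfusim")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  s <- stats::setNames(rep(NA_real_, length(state_names())), state_names())
  stated <- tab$value != "derived"
  s[tab$name[stated]] <- as.numeric(tab$value[stated])
  h_i <- 10^(3 - s[["pH_i"]]); h_o <- 10^(3 - s[["pH_o"]])
  s[["CO2_i"]] <- h_i * s[["HCO3_i"]] / params$k_a_co2
  s[["CO2_o"]] <- h_o * s[["HCO3_o"]] / params$k_a_co2
  s[["ryr_i"]] <- params$km_ri / (params$km_ri + s[["Ca_i"]])
  s[["HBuf1_i"]] <- params$buf1_conc / (1 + 10^(s[["pH_i"]] - params$buf1_pk))
  s[["HBuf2_i"]] <- params$buf2_conc / (1 + 10^(s[["pH_i"]] - params$buf2_pk))
  s[["HBuf1_o"]] <- params$buf1_conc / (1 + 10^(s[["pH_o"]] - params$buf1_pk))
  s[["HBuf2_o"]] <- params$buf2_conc / (1 + 10^(s[["pH_o"]] - params$buf2_pk))
  s[["X_i"]] <- s[["Osm_i"]] -
    (s[["Na_i"]] + s[["K_i"]] + s[["Ca_i"]] + s[["Cl_i"]])
  s
}

#' @rdname load_initial_conditions
#' @export
initial_state <- load_initial_conditions

#' Validate a cell state against the model invariants
#'
#' Checks that every concentration is strictly positive (the generic anion
#' may be zero), every gating variable lies in \[0, 1\], both compartment
#' volumes are positive, and both pH values lie in the physiologically
#' simulable band (5.5, 8.5).
#'
#' @param state Named state vector or one-row data frame.
#' @return A tibble of violations (zero rows when the state is valid) with
#'   columns `field`, `value` and `violation`.
#' @export
validate_state <- function(state) {
  s <- state_vector(state)
  conc <- c("Na_i", "Na_o", "K_i", "K_o", "Cl_i", "Cl_o", "Ca_i", "Ca_o",
            "Ca_jsr", "Ca_nsr", "CO2_i", "CO2_o", "HCO3_i", "HCO3_o",
            "ATP", "ADP", "AMP", "Pi", "Cr", "PCr",
            "HBuf1_i", "HBuf2_i", "HBuf1_o", "HBuf2_o")
  gates <- c("m", "h", "j", "d", "f", "x_r", "x_s1", "x_s2", "b", "g",
             "m_L", "h_L", "h_Ls", "ryr_o", "ryr_i")
  v <- list()
  bad <- function(field, value, violation) {
    tibble(field = field, value = value, violation = violation)
  }
  for (nm in conc) {
    if (!is.finite(s[[nm]]) || s[[nm]] <= 0)
      v[[length(v) + 1]] <- bad(nm, s[[nm]], "must be > 0")
  }
  if (!is.finite(s[["Anion_i"]]) || s[["Anion_i"]] < 0)
    v[[length(v) + 1]] <- bad("Anion_i", s[["Anion_i"]], "must be >= 0")
  for (nm in gates) {
    if (!is.finite(s[[nm]]) || s[[nm]] < 0 || s[[nm]] > 1)
      v[[length(v) + 1]] <- bad(nm, s[[nm]], "must be in [0, 1]")
  }
  for (nm in c("V_myo", "V_ext")) {
    if (!is.finite(s[[nm]]) || s[[nm]] <= 0)
      v[[length(v) + 1]] <- bad(nm, s[[nm]], "must be > 0")
  }
  for (nm in c("pH_i", "pH_o")) {
    if (!is.finite(s[[nm]]) || s[[nm]] <= 5.5 || s[[nm]] >= 8.5)
      v[[length(v) + 1]] <- bad(nm, s[[nm]], "must be in (5.5, 8.5)")
  }
  if (length(v) == 0) {
    tibble(field = character(), value = numeric(), violation = character())
  } else {
    dplyr::bind_rows(v)
  }
}

#' Membrane potential from the charge-difference formulation
#'
#' The potential is an affine function of the valence-weighted intracellular
#' ion content (free ions, protons free and bound to the intrinsic buffers,
#' hydroxide, bicarbonate, buffered calcium, SR calcium and the generic
#' conjugate anion).  The offset is calibrated once against the initial
#' conditions by [calibrated_parameters()].
#'
#' @param state Named state vector.
#' @param params Calibrated parameters.
#' @return Membrane potential in mV.
#' @export
compute_voltage <- function(state, params) {
  if (!is.finite(params$n_offset))
    abort("charge-difference offset is not calibrated; use calibrated_parameters()")
  cpp_voltage(state_vector(state), params)
}

#' @rdname compute_voltage
#' @export
charge_content <- function(state, params) {
  cpp_charge_mol(state_vector(state), params)
}

#' Coerce a state vector to a one-row tibble
#' @param state Named state vector.
#' @return A one-row tibble with one column per state variable.
#' @export
state_tibble <- function(state) {
  as_tibble(as.list(state_vector(state)))
}
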