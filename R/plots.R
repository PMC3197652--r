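#' Plot a simulation's time series
#'
#' Faceted ggplot of selected state variables and currents against time
#' (minutes), with phase boundaries marked.
#'
#' @param object An `ir_simulation`.
#' @param vars Columns of the series to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ir_simulation <- function(object,
                                   vars = c("V", "Na_i", "Ca_i", "pH_i",
                                            "pH_o", "K_o"),
                                   ...) {
  ser <- object$series
  if (is.null(ser)) abort("simulation carries no series")
  d <- tidyr::pivot_longer(
    dplyr::select(ser, "t", dplyr::all_of(vars)),
    -"t", names_to = "variable", values_to = "value")
  d$variable <- factor(d$variable, levels = vars)
  t1 <- object$schedule$pre_ms / 6e4
  t2 <- (object$schedule$pre_ms + object$schedule$isch_ms) / 6e4
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t / 6e4, y = .data$value)) +
    ggplot2::geom_vline(xintercept = c(t1, t2), linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = NULL)
  }

#' Plot per-beat extrema
#'
#' Maximum and minimum of a per-beat quantity (calcium, pump current or
#' potential) over the run.
#'
#' @param sim An `ir_simulation`.
#' @param what One of "Ca", "I_NaK", "V".
#' @return A ggplot object.
#' @export
plot_beats <- function(sim, what = c("Ca", "I_NaK", "V")) {
  what <- match.arg(what)
  b <- beat_metrics(sim)
  cols <- switch(what, Ca = c("Ca_max", "Ca_min"),
                 I_NaK = c("I_NaK_max", "I_NaK_min"),
                 V = c("V_max", "V_min"))
  d <- tidyr::pivot_longer(b[, c("t_start", cols)], -"t_start",
                           names_to = "extreme", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t_start / 6e4, y = .data$value,
                                  colour = .data$extreme)) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::labs(x = "time (min)", y = what)
}

#' @export
autoplot.ir_summary <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$quantity, y = .data$ratio)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "peak / end-ischemic ratio")
}

#' Tidy the per-pathway sodium ledger of a simulation
#' @param x An `ir_simulation`.
#' @param ... Unused.
#' @return A tibble with one row per sodium pathway.
#' @export
tidy.ir_simulation <- function(x, ...) sodium_ledger(x)

#' One-row summary of a simulation
#' @param x An `ir_simulation`.
#' @param ... Unused.
#' @return A one-row tibble of headline reperfusion quantities.
#' @export
glance.ir_simulation <- function(x, ...) {
  s <- summarize_ir(x)
  tibble(
    peak_na_i = s$peak[s$quantity == "Na_i"],
    end_ischemic_na_i = s$end_ischemic[s$quantity == "Na_i"],
    peak_ca_i = s$peak[s$quantity == "Ca_i"],
    end_ph_i = s$end_reperfusion[s$quantity == "pH_i"],
    mean_ph_i = s$mean[s$quantity == "pH_i"],
    n_steps = x$n_steps
  )
}
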