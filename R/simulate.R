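#' Current-clamp stimulus protocols
#'
#' Constructors for the three protocol kinds used by the validation
#' metrics: a square step, a linear ramp, and a zero-current hold.
#' Times are relative to the end of equilibration; `onset_ms` delays the
#' stimulus and `tail_ms` extends the recording after it.
#'
#' @param amplitude_pA step amplitude, pA
#' @param duration_ms stimulus duration, ms
#' @param onset_ms delay after equilibration before stimulus onset, ms
#' @param tail_ms post-stimulus recording time, ms
#' @return a `stimulus_protocol` list
#' @export
protocol_step <- function(amplitude_pA, duration_ms = 500, onset_ms = 0,
                          tail_ms = 0) {
  stopifnot(is.finite(amplitude_pA), duration_ms > 0)
  structure(list(kind = "step", amplitude_pA = amplitude_pA,
                 duration_ms = duration_ms, onset_ms = onset_ms,
                 tail_ms = tail_ms),
            class = "stimulus_protocol")
}

#' @rdname protocol_step
#' @param from_pA,to_pA ramp start and end currents, pA
#' @export
protocol_ramp <- function(from_pA = 0, to_pA = 150, duration_ms = 1000,
                          onset_ms = 0, tail_ms = 0) {
  stopifnot(is.finite(from_pA), is.finite(to_pA), duration_ms > 0)
  structure(list(kind = "ramp", from_pA = from_pA, to_pA = to_pA,
                 duration_ms = duration_ms, onset_ms = onset_ms,
                 tail_ms = tail_ms),
            class = "stimulus_protocol")
}

#' @rdname protocol_step
#' @export
protocol_hold <- function(duration_ms = 500) {
  structure(list(kind = "hold", duration_ms = duration_ms, onset_ms = 0,
                 tail_ms = 0),
            class = "stimulus_protocol")
}

protocol_tstop <- function(p) p$onset_ms + p$duration_ms + p$tail_ms

protocol_current <- function(p, t) {
  # t relative to end of equilibration
  on <- p$onset_ms
  off <- p$onset_ms + p$duration_ms
  if (p$kind == "hold") return(rep(0, length(t)))
  inside <- t > on & t <= off
  i <- numeric(length(t))
  if (p$kind == "step") {
    i[inside] <- p$amplitude_pA
  } else {
    i[inside] <- p$from_pA +
      (p$to_pA - p$from_pA) * (t[inside] - on) / (off - on)
  }
  i
}

#' Simulate a cell under a current-clamp protocol
#'
#' Integrates the cable equation with backward Euler at the settings'
#' time step. The cell is first equilibrated for `t_equil` ms with no
#' stimulus (from the steady-state initialization at `v_init`), then the
#' protocol runs; the returned somatic trace covers equilibration plus
#' the protocol on the uniform `dt` grid.
#'
#' @param cell a `vpglu_cell` from [discretize()]
#' @param protocol a `stimulus_protocol`
#' @param settings a [simulation_settings()]
#' @param record_ca also record submembrane calcium at the first hillock
#'   compartment
#' @return object of class `voltage_trace`: data frame with `time_ms`,
#'   `v_mV` (somatic membrane potential) and `i_pA` (injected current),
#'   with attributes `diverged`, `dt`, `t_equil` and optionally `ca_mM`.
#' @export
simulate_cell <- function(cell, protocol, settings = simulation_settings(),
                          record_ca = FALSE) {
  stopifnot(inherits(cell, "vpglu_cell"),
            inherits(protocol, "stimulus_protocol"))
  res <- .sim_batch(cell, list(unclass(protocol)), settings$dt,
                    settings$t_equil, settings$v_init,
                    cell$inj_idx, settings$tau_scale,
                    NULL, record_ca, TRUE)
  v_eq <- res$equil_v[1, ]
  v_pr <- res$traces[[1]][1, ]
  v <- c(v_eq, v_pr[-1])
  n <- length(v)
  t <- seq(0, by = settings$dt, length.out = n)
  i <- c(rep(0, length(v_eq)),
         protocol_current(protocol,
                          t[-seq_along(v_eq)] - settings$t_equil))
  out <- data.frame(time_ms = t, v_mV = v, i_pA = i)
  attr(out, "diverged") <- res$diverged[[1]] || !res$equil_ok
  attr(out, "dt") <- settings$dt
  attr(out, "t_equil") <- settings$t_equil
  if (record_ca) {
    ca_eq <- rep(NA_real_, length(v_eq) - 1)
    attr(out, "ca_mM") <- c(ca_eq, res$ca[[1]])
  }
  class(out) <- c("voltage_trace", "data.frame")
  out
}

# One batched run: equilibrate once, then run each protocol from the
# cached equilibrium state. Records the soma (and optionally a second
# probe compartment). Used by the metric bundle and the calibration,
# where rebuilding state per protocol would dominate the cost.
run_protocols <- function(cell, protocols, settings,
                          record_idx = cell$inj_idx, record_ca = FALSE) {
  .sim_batch(cell, lapply(protocols, unclass), settings$dt,
             settings$t_equil, settings$v_init,
             as.integer(record_idx), settings$tau_scale,
             NULL, record_ca, FALSE)
}

#' Resting-state convergence diagnostic
#'
#' Runs the unstimulated cell from its steady-state initialization and
#' returns the maximum absolute rate of membrane-potential change over
#' all compartments at every step, which should decay toward zero as the
#' cell settles.
#'
#' @param cell a `vpglu_cell`
#' @param t_total diagnostic duration, ms
#' @param settings a [simulation_settings()]
#' @return numeric vector of max |dV/dt| (mV/ms) per step
#' @export
rest_convergence <- function(cell, t_total = 500,
                             settings = simulation_settings()) {
  .rest_dvdt(cell, settings$dt, t_total, settings$v_init,
             settings$tau_scale)
}
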