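#' Gate steady states and time constants
#'
#' Evaluates a channel's gating scheme at a membrane potential and (for
#' calcium-gated channels) a free-calcium concentration. Voltage gates
#' follow Boltzmann steady states with constant or bell-shaped time
#' constants; the SK gate is a Hill function of calcium; the BK gate is a
#' Boltzmann in voltage whose midpoint shifts with log10 calcium.
#'
#' @param channel one element of [load_channels()]
#' @param V membrane potential, mV
#' @param Ca free submembrane calcium, mM
#' @return list with named vectors `steady` and `tau` (ms), one entry per
#'   gate (`act`, and `inact` when present)
#' @export
gate_dynamics <- function(channel, V, Ca = 5e-5) {
  stopifnot(is.finite(V))
  ev <- function(g) {
    if (g$type == "v") {
      inf <- 1 / (1 + exp(-(V - g$vh) / g$k))
      tau <- eval_tau(g$tau, V)
    } else if (g$type == "sk") {
      cn <- Ca^g$hill_n
      inf <- cn / (cn + g$ec50^g$hill_n)
      tau <- g$tau_ms
    } else if (g$type == "bk") {
      vh <- g$vh0 - g$shift_per_decade * log10(Ca / g$caref)
      inf <- 1 / (1 + exp(-(V - vh) / g$k))
      tau <- g$tau_ms
    } else stop("unknown gate type: ", g$type)
    c(steady = inf, tau = tau)
  }
  gates <- list(act = ev(channel$act))
  if (channel$p_inact > 0) gates$inact <- ev(channel$inact)
  if (isTRUE(channel$p_inact2 > 0)) gates$inact2 <- ev(channel$inact2)
  list(steady = vapply(gates, `[[`, numeric(1), "steady"),
       tau = vapply(gates, `[[`, numeric(1), "tau"))
}

eval_tau <- function(tau, V) {
  if (tau$type == "const") return(tau$tmin)
  tau$tmin + tau$tamp /
    (exp((V - tau$vt) / tau$k1) + exp(-(V - tau$vt) / tau$k2))
}

#' Total ionic current density at the hillock membrane
#'
#' Sums the ohmic per-channel currents `g * gates * (V - E)` plus leak,
#' grouped by ion species. Gate values are taken as given (instantaneous
#' evaluation), which is how the integrator linearizes the membrane
#' current within a backward-Euler step.
#'
#' @param theta a [conductance_vector()]
#' @param gates named list: per channel, list with `act` and optional
#'   `inact` gate values in `[0,1]`. Missing channels default to their
#'   steady state at (`V`, `Ca`).
#' @param V membrane potential, mV
#' @param Ca free submembrane calcium, mM
#' @param config a [vpglu_config()] (channel tables and leak reversal)
#' @return named vector of current densities, mA/cm^2: one entry per ion
#'   species (`na`, `k`, `ca`, `leak`) plus `total`
#' @export
total_ionic_current <- function(theta, gates = NULL, V, Ca = 5e-5,
                                config = vpglu_config()) {
  theta <- conductance_vector(unclass(theta))
  chans <- config$channels
  species <- c(nav16 = "na", kdr = "k", ka = "k", sk = "k", bk = "k",
               km = "k", cal = "ca", cat = "ca")
  out <- c(na = 0, k = 0, ca = 0, leak = 0)
  for (nm in CHANNEL_ORDER) {
    ch <- chans[[nm]]
    g <- gates[[nm]]
    if (is.null(g)) {
      gd <- gate_dynamics(ch, V, Ca)
      g <- list(act = gd$steady[["act"]],
                inact = if (ch$p_inact > 0) gd$steady[["inact"]] else 1,
                inact2 = if (isTRUE(ch$p_inact2 > 0))
                  gd$steady[["inact2"]] else 1)
    }
    act <- g$act^ch$p_act
    inact <- if (ch$p_inact > 0) (if (is.null(g$inact)) 1 else g$inact)^ch$p_inact else 1
    inact2 <- if (isTRUE(ch$p_inact2 > 0))
      (if (is.null(g$inact2)) 1 else g$inact2)^ch$p_inact2 else 1
    i <- theta[[nm]] * act * inact * inact2 * (V - ch$erev) # mA/cm^2
    out[species[[nm]]] <- out[species[[nm]]] + i
  }
  out[["leak"]] <- theta[["leak"]] * (V - config$passive$e_leak)
  c(out, total = sum(out))
}

#' One step of submembrane calcium dynamics
#'
#' Single-shell calcium model: influx proportional to the inward calcium
#' current over the shell volume, first-order extrusion back to baseline.
#' Advanced by one implicit (backward Euler) step.
#'
#' @param state list with `ca_mM` (free calcium), `baseline_mM`,
#'   `tau_ms` (extrusion time constant), `depth_um` (shell depth)
#' @param i_ca calcium current density, mA/cm^2 (negative = inward)
#' @param dt time step, ms
#' @return updated state
#' @export
update_calcium <- function(state, i_ca, dt) {
  stopifnot(dt > 0)
  influx <- calcium_influx(i_ca, state$depth_um)
  ca_new <- (state$ca_mM + dt * (influx + state$baseline_mM / state$tau_ms)) /
    (1 + dt / state$tau_ms)
  state$ca_mM <- max(ca_new, 0)
  state
}

# mM/ms from a calcium current density (mA/cm^2); inward (negative)
# currents produce positive influx, outward flux is handled by extrusion.
calcium_influx <- function(i_ca, depth_um) {
  faraday <- 96485
  j <- -i_ca / (2 * faraday * depth_um * 1e-4)
  max(j, 0)
}

#' One step of calcium dynamics with the parvalbumin buffer
#'
#' Extends [update_calcium()] with mass-action binding to parvalbumin:
#' `d[CaPV]/dt = kon [Ca] ([PV]_tot - [CaPV]) - koff [CaPV]`, with the
#' calcium bound in a step removed from the free pool. Both equations are
#' advanced together by an implicit step (Newton iteration on the coupled
#' 2x2 system), so the update conserves calcium to machine precision:
#' the change of (free + bound) equals influx minus extrusion. Magnesium
#' competition for the binding sites is not modelled.
#'
#' @param ca_state calcium state as in [update_calcium()]
#' @param pv_state list with `total_mM`, `bound_mM`, `kon` (1/(mM ms)),
#'   `koff` (1/ms)
#' @param i_ca calcium current density, mA/cm^2
#' @param dt time step, ms
#' @return list with updated `ca` and `pv` states
#' @export
update_pv_buffer <- function(ca_state, pv_state, i_ca, dt) {
  stopifnot(dt > 0, pv_state$total_mM >= 0,
            pv_state$bound_mM >= 0, pv_state$bound_mM <= pv_state$total_mM)
  J <- calcium_influx(i_ca, ca_state$depth_um)
  ca0 <- ca_state$baseline_mM
  tau <- ca_state$tau_ms
  kon <- pv_state$kon
  koff <- pv_state$koff
  ptot <- pv_state$total_mM
  can <- ca_state$ca_mM
  bn <- pv_state$bound_mM
  ca <- can
  b <- bn
  for (it in 1:50) {
    bind <- kon * ca * (ptot - b) - koff * b
    f1 <- ca - can - dt * (J - (ca - ca0) / tau - bind)
    f2 <- b - bn - dt * bind
    j11 <- 1 + dt / tau + dt * kon * (ptot - b)
    j12 <- -dt * (kon * ca + koff)
    j21 <- -dt * kon * (ptot - b)
    j22 <- 1 + dt * (kon * ca + koff)
    det <- j11 * j22 - j12 * j21
    dca <- (-f1 * j22 + f2 * j12) / det
    db <- (-j11 * f2 + j21 * f1) / det
    ca <- ca + dca
    b <- b + db
    if (abs(dca) < 1e-16 && abs(db) < 1e-16) break
  }
  ca_state$ca_mM <- ca
  pv_state$bound_mM <- min(max(b, 0), ptot)
  list(ca = ca_state, pv = pv_state)
}

#' Equilibrium bound fraction of the buffer at clamped calcium
#'
#' Closed-form binding isotherm `Ca / (Ca + koff/kon)` used for buffer
#' initialization: at stimulus onset the buffer starts equilibrated to
#' baseline calcium rather than fully free, which avoids an artificial
#' onset transient.
#'
#' @param ca free calcium, mM
#' @param kon association rate, 1/(mM ms)
#' @param koff dissociation rate, 1/ms
#' @return bound fraction in `[0, 1]`
#' @export
pv_bound_fraction <- function(ca, kon, koff) {
  ca / (ca + koff / kon)
}
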