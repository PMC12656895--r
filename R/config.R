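#' Channel order used throughout the package
#'
#' The nine free parameters of a model are the maximal conductances of the
#' eight active hillock channels, in this order, followed by the passive
#' leak conductance.
#' @keywords internal
CHANNEL_ORDER <- c("nav16", "kdr", "ka", "sk", "bk", "km", "cal", "cat")

#' Parameter names of the conductance vector
#' @export
conductance_names <- function() c(CHANNEL_ORDER, "leak")

.vpglu_env <- new.env(parent = emptyenv())

#' Load a set of channel kinetic tables
#'
#' Channel kinetics are shipped as one structured text (YAML) file per
#' channel under `inst/extdata/channels`. Each file defines the gating
#' scheme: activation/inactivation steady-state midpoint and slope,
#' time-constant curve, gate exponents and reversal potential. The
#' defaults are explicit, auditable stand-ins for the published channel
#' formulations the model family is patterned on, and any file can be
#' overridden by pointing `path` at a directory with the same file names.
#'
#' @param path directory containing `<channel>.yaml` files; defaults to the
#'   tables shipped with the package.
#' @return named list of channel definitions in canonical order.
#' @export
load_channels <- function(path = NULL) {
  use_cache <- is.null(path)
  if (use_cache && !is.null(.vpglu_env$channels)) return(.vpglu_env$channels)
  if (is.null(path)) path <- system.file("extdata", "channels",
                                         package = "vpglu")
  chans <- lapply(CHANNEL_ORDER, function(nm) {
    f <- file.path(path, paste0(nm, ".yaml"))
    if (!file.exists(f)) stop("missing channel table: ", f)
    ch <- yaml::read_yaml(f)
    validate_channel(ch)
    ch
  })
  names(chans) <- CHANNEL_ORDER
  if (use_cache) .vpglu_env$channels <- chans
  chans
}

validate_channel <- function(ch) {
  stopifnot(is.character(ch$name), is.numeric(ch$erev),
            ch$p_act >= 0, ch$p_inact >= 0)
  if (ch$p_inact > 0 && is.null(ch$inact))
    stop("channel ", ch$name, ": p_inact > 0 but no inactivation gate")
  if (isTRUE(ch$p_inact2 > 0) && is.null(ch$inact2))
    stop("channel ", ch$name, ": p_inact2 > 0 but no slow gate")
  invisible(ch)
}

#' Simulation settings
#'
#' Integration settings shared by all protocols: backward-Euler time step
#' (ms), initialization potential (mV), nominal temperature (degrees C),
#' equilibration time before stimulation (ms), and a Q10 hook for
#' temperature rescaling of gate time constants. Kinetics are defined at
#' 23 degrees C and the Q10 defaults to 1, so no rescaling occurs unless
#' requested.
#'
#' @param dt integration step, ms
#' @param v_init initialization membrane potential, mV
#' @param temperature nominal temperature, degrees C
#' @param t_equil equilibration time before stimulus onset, ms
#' @param q10 temperature coefficient for gate time constants
#' @return a `simulation_settings` list
#' @export
simulation_settings <- function(dt = 0.025, v_init = -60, temperature = 23,
                                t_equil = 500, q10 = 1) {
  stopifnot(dt > 0, t_equil >= 0, q10 > 0)
  structure(list(dt = dt, v_init = v_init, temperature = temperature,
                 t_equil = t_equil, q10 = q10,
                 tau_scale = 1 / q10^((temperature - 23) / 10)),
            class = "simulation_settings")
}

#' Default configuration of the VP glutamatergic neuron model
#'
#' Returns the full nested configuration: morphology (dimensions in um),
#' passive constants, nodal squid-type kinetics, calcium-shell and
#' parvalbumin kinetics, channel tables, current-clamp protocol grids,
#' phenotype-classification thresholds, scoring normalizers and prior
#' bounds. Every value can be overridden through `...` (named nested
#' lists merged recursively), e.g.
#' `vpglu_config(passive = list(ra = 100))`.
#'
#' @param ... named overrides merged into the defaults
#' @return nested configuration list of class `vpglu_config`
#' @export
vpglu_config <- function(...) {
  cfg <- list(
    morphology = list(
      soma = list(L = 10, diam = 10, nseg = 1),
      hillock = list(L = 30, diam = 1, nseg = 3),
      dendrite = list(L = 1371, diam = 0.3, nseg = 41),
      axon = list(
        n_nodes = 100, n_internodes = 99,
        node = list(L = 1, diam = 1, nseg = 1),
        internode = list(L = 100, diam = 1, nseg = 1)
      )
    ),
    passive = list(
      cm = 1,               # uF/cm^2
      cm_internode = 0.005, # heavily myelinated internode; at higher
                            # values conduction across the 100 um
                            # internodes is decremental with the squid
                            # nodal densities
      ra = 150,             # axial resistivity, Ohm cm
      e_leak = -60,         # leak reversal, mV (matches v_init)
      g_internode = 1e-5    # myelin leak, S/cm^2
    ),
    # Squid-type nodal kinetics and densities as in the built-in 'hh'
    # scheme, defined at 6.3 C; rate_factor scales them to the 23 C
    # operating temperature with the mechanism's native Q10 of 3 (the
    # hillock tables are defined at 23 C directly).
    hh = list(gna = 0.12, gk = 0.036, gl = 3e-4,
              ena = 50, ek = -77, el = -54.3,
              rate_factor = 3^((23 - 6.3) / 10)),
    calcium = list(depth_um = 0.5, ca0_mM = 5e-5, tau_ms = 20),
    pv_kinetics = list(kon = 40,      # 1/(mM ms)
                       koff = 4e-4),  # 1/ms  (Kd = 10 nM)
    channels = NULL, # filled below (lazily, so overrides can replace)
    protocols = list(
      fi_grid = seq(0, 130, by = 10), # pA
      step_ms = 500,
      ramp = list(from = 0, to = 150, duration_ms = 1000),
      rin = list(amplitude_pA = -5, duration_ms = 500, window_ms = 50)
    ),
    classify = list(db_frac = 0.5, ndb_frac = 0.8),
    score = list(fi_norm_per_point = 5, # Hz per grid point
                 ramp_target = "rheobase"),
    settings = simulation_settings()
  )
  cfg$prior <- prior_spec()
  over <- list(...)
  if (length(over)) cfg <- modify_list_deep(cfg, over)
  if (is.null(cfg$channels)) cfg$channels <- load_channels()
  class(cfg) <- "vpglu_config"
  cfg
}

modify_list_deep <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(over[[nm]]))) {
      base[[nm]] <- modify_list_deep(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Read a configuration override file
#'
#' Reads a structured text (YAML) file of configuration overrides and
#' merges it into the defaults.
#' @param path YAML file of overrides
#' @return a `vpglu_config`
#' @export
read_config <- function(path) {
  over <- yaml::read_yaml(path)
  do.call(vpglu_config, over)
}
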