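#' Detect action potentials in a voltage trace
#'
#' A spike is a local maximum strictly above 0 mV; to be counted, the
#' trace must have crossed -20 mV upward since the previous counted spike
#' (debounce, so sub-oscillations riding a depolarization-block plateau
#' are not counted as spikes).
#'
#' @param trace a `voltage_trace`, or a numeric voltage vector
#' @param dt time step, ms (taken from the trace attribute when present)
#' @return numeric vector of spike times, ms
#' @export
detect_spikes <- function(trace, dt = NULL) {
  if (inherits(trace, "voltage_trace")) {
    v <- trace$v_mV
    if (is.null(dt)) dt <- attr(trace, "dt")
  } else {
    v <- as.numeric(trace)
    if (is.null(dt)) stop("dt required for a bare voltage vector")
  }
  n <- length(v)
  if (n < 3) return(numeric(0))
  mid <- 2:(n - 1)
  is_max <- v[mid] > v[mid - 1] & v[mid] >= v[mid + 1] & v[mid] > 0
  peaks <- mid[is_max]
  if (!length(peaks)) return(numeric(0))
  upcross <- which(v[-n] < -20 & v[-1] >= -20) + 1L
  counted <- integer(0)
  last <- 0L
  ui <- 1L
  nu <- length(upcross)
  for (p in peaks) {
    while (ui <= nu && upcross[ui] < last) ui <- ui + 1L
    if (ui <= nu && upcross[ui] <= p) {
      counted <- c(counted, p)
      last <- p
    }
  }
  (counted - 1L) * dt
}

#' Input resistance from a small hyperpolarizing step
#'
#' Injects -5 pA for 500 ms into the equilibrated cell and divides the
#' steady voltage change by the injected current. The voltage change is
#' the mean over the final 50 ms of the step minus the pre-step baseline.
#' Spiking during the probe invalidates the measurement (returns `NA`).
#'
#' @param cell a `vpglu_cell`
#' @param settings a [simulation_settings()]
#' @param config a [vpglu_config()] (probe amplitude/duration/window)
#' @return input resistance, MOhm (`NA` if the probe elicited spikes or
#'   the simulation diverged)
#' @export
input_resistance <- function(cell, settings = simulation_settings(),
                             config = vpglu_config()) {
  p <- config$protocols$rin
  res <- run_protocols(cell, list(protocol_step(p$amplitude_pA,
                                                p$duration_ms)), settings)
  rin_from_trace(res$traces[[1]][1, ], res$diverged[[1]] || !res$equil_ok,
                 p, settings$dt)
}

rin_from_trace <- function(v, diverged, p, dt) {
  if (diverged) return(NA_real_)
  if (length(detect_spikes(v, dt))) return(NA_real_)
  baseline <- v[1]
  n_off <- round(p$duration_ms / dt) + 1L
  n_win <- round(p$window_ms / dt)
  dv <- mean(v[(n_off - n_win):n_off]) - baseline
  rin <- dv / (p$amplitude_pA * 1e-3) # mV / nA = MOhm
  if (!is.finite(rin) || rin <= 0) return(NA_real_)
  rin
}

#' Frequency-current (F-I) curve
#'
#' Sequentially injects 500 ms square pulses over the amplitude grid
#' (default 0-130 pA in 10 pA increments) into the equilibrated cell and
#' counts spikes with peaks above 0 mV. Rate = count / 0.5 s.
#'
#' @param cell a `vpglu_cell`
#' @param grid injection amplitudes, pA
#' @param settings a [simulation_settings()]
#' @param config a [vpglu_config()]
#' @return named numeric vector of firing rates (Hz), one per amplitude;
#'   `NA` where the simulation diverged
#' @export
fi_curve <- function(cell, grid = NULL, settings = simulation_settings(),
                     config = vpglu_config()) {
  if (is.null(grid)) grid <- config$protocols$fi_grid
  stopifnot(length(grid) >= 1)
  dur <- config$protocols$step_ms
  prots <- lapply(grid, protocol_step, duration_ms = dur)
  res <- run_protocols(cell, prots, settings)
  rates <- vapply(seq_along(grid), function(i) {
    if (res$diverged[[i]] || !res$equil_ok) return(NA_real_)
    length(detect_spikes(res$traces[[i]][1, ], settings$dt)) /
      (dur / 1000)
  }, numeric(1))
  names(rates) <- grid
  rates
}

#' Ramp current threshold
#'
#' Injects a 1 s linear ramp from 0 to 150 pA and reports the
#' instantaneous injected current at the first detected spike. Returns
#' `NA` (the no-spike sentinel) if the ramp elicits no spike.
#'
#' @inheritParams fi_curve
#' @return threshold current, pA, or `NA`
#' @export
ramp_threshold <- function(cell, settings = simulation_settings(),
                           config = vpglu_config()) {
  r <- config$protocols$ramp
  res <- run_protocols(cell, list(protocol_ramp(r$from, r$to,
                                                r$duration_ms)), settings)
  ramp_from_trace(res$traces[[1]][1, ], res$diverged[[1]] || !res$equil_ok,
                  r, settings$dt)
}

ramp_from_trace <- function(v, diverged, r, dt) {
  if (diverged) return(NA_real_)
  st <- detect_spikes(v, dt)
  if (!length(st)) return(NA_real_)
  r$from + (r$to - r$from) * st[1] / r$duration_ms
}

#' Summary metrics from an F-I curve and its step traces
#'
#' Derives the square-pulse summary statistics: `peak_firing_current`
#' (grid amplitude maximizing the rate; ties resolved to the lowest
#' amplitude), `peak_firing_rate`, `rheobase` (lowest amplitude with at
#' least one spike) and, when the rheobase trace is supplied, the
#' afterhyperpolarization depth. The AHP is the action-potential
#' threshold (voltage where dV/dt first exceeds 10 mV/ms before the first
#' spike peak) minus the most negative voltage after the first spike
#' within the step.
#'
#' @param fi named rate vector from [fi_curve()]
#' @param rheo_trace optional numeric voltage vector of the rheobase step
#' @param dt time step of `rheo_trace`, ms
#' @param step_ms step duration, ms
#' @return list with `peak_firing_current`, `peak_firing_rate`,
#'   `rheobase`, `ahp` (NA without a trace) and `nonspiking`
#' @export
derive_summary <- function(fi, rheo_trace = NULL, dt = 0.025,
                           step_ms = 500) {
  stopifnot(length(fi) >= 1)
  grid <- as.numeric(names(fi))
  if (all(is.na(fi)) || all(fi[!is.na(fi)] == 0)) {
    return(list(peak_firing_current = NA_real_,
                peak_firing_rate = 0,
                rheobase = NA_real_, ahp = NA_real_, nonspiking = TRUE))
  }
  peak_i <- which.max(fi) # which.max takes the first (lowest) on ties
  spiking <- which(!is.na(fi) & fi > 0)
  out <- list(peak_firing_current = grid[peak_i],
              peak_firing_rate = unname(fi[peak_i]),
              rheobase = grid[min(spiking)],
              ahp = NA_real_, nonspiking = FALSE)
  if (!is.null(rheo_trace)) out$ahp <- ahp_from_trace(rheo_trace, dt)
  out
}

# AHP from a rheobase-step somatic trace: threshold minus trough.
ahp_from_trace <- function(v, dt, dvdt_thresh = 10) {
  st <- detect_spikes(v, dt)
  if (!length(st)) return(NA_real_)
  p1 <- round(st[1] / dt) + 1L
  dvdt <- diff(v) / dt
  up <- which(dvdt[seq_len(max(p1 - 1L, 1L))] > dvdt_thresh)
  if (!length(up)) return(NA_real_)
  thresh <- v[up[1]]
  if (length(st) >= 2) {
    p2 <- round(st[2] / dt) + 1L
    trough <- min(v[p1:p2])
  } else {
    trough <- min(v[p1:length(v)])
  }
  thresh - trough
}

#' Classify the firing phenotype from an F-I curve
#'
#' Operational rule: with `r_max` the peak rate and `r_end` the rate at
#' the largest injected amplitude, the model is `NDB` if
#' `r_end >= ndb_frac * r_max` (default 0.8), `DB` if
#' `r_end < db_frac * r_max` (default 0.5) with the peak before the final
#' amplitude, and `nonspiking` if no step elicits a spike. Curves between
#' the two cutoffs are indeterminate and treated as DB-leaning (labelled
#' `DB` with an attribute).
#'
#' @param fi named rate vector on the full grid
#' @param config a [vpglu_config()] (classification thresholds)
#' @return character: `"DB"`, `"NDB"` or `"nonspiking"`; indeterminate
#'   curves carry `attr(, "indeterminate") = TRUE`
#' @export
classify_phenotype <- function(fi, config = vpglu_config()) {
  if (any(is.na(fi))) return("nonspiking")
  r_max <- max(fi)
  if (r_max == 0) return("nonspiking")
  r_end <- fi[length(fi)]
  if (r_end >= config$classify$ndb_frac * r_max) return("NDB")
  if (r_end < config$classify$db_frac * r_max &&
      which.max(fi) < length(fi)) return("DB")
  structure("DB", indeterminate = TRUE)
}

#' Measure the full validation-metric bundle of a parameter set
#'
#' Runs the complete current-clamp battery on one conductance vector:
#' equilibration (cached across protocols), the -5 pA input-resistance
#' probe, the F-I step grid, and the 0-150 pA ramp; then derives the
#' summary metrics and the firing phenotype. This is the quantity the
#' calibration scores.
#'
#' @param theta a [conductance_vector()] (or length-9 numeric)
#' @param config a [vpglu_config()]
#' @param pv_mM total parvalbumin, mM
#' @param settings a [simulation_settings()] (defaults to the config's)
#' @return object of class `metric_bundle`: list with `input_resistance`
#'   (MOhm), `fi_curve` (Hz, named by pA), `ramp_threshold` (pA),
#'   `peak_firing_current` (pA), `peak_firing_rate` (Hz), `rheobase`
#'   (pA), `ahp` (mV), `rmp` (mV, reported only), `phenotype`, `failed`
#' @export
measure_metrics <- function(theta, config = vpglu_config(), pv_mM = 0,
                            settings = NULL) {
  if (is.null(settings)) settings <- config$settings
  cell <- discretize(build_morphology(config$morphology), theta, config,
                     pv_mM = pv_mM)
  grid <- config$protocols$fi_grid
  dur <- config$protocols$step_ms
  rin_p <- config$protocols$rin
  ramp_p <- config$protocols$ramp
  prots <- c(list(protocol_step(rin_p$amplitude_pA, rin_p$duration_ms)),
             lapply(grid, protocol_step, duration_ms = dur),
             list(protocol_ramp(ramp_p$from, ramp_p$to,
                                ramp_p$duration_ms)))
  res <- run_protocols(cell, prots, settings)
  dt <- settings$dt

  failed <- !res$equil_ok || any(res$diverged)
  rin <- rin_from_trace(res$traces[[1]][1, ],
                        res$diverged[[1]] || !res$equil_ok, rin_p, dt)
  rates <- vapply(seq_along(grid), function(i) {
    if (res$diverged[[i + 1]] || !res$equil_ok) return(NA_real_)
    length(detect_spikes(res$traces[[i + 1]][1, ], dt)) / (dur / 1000)
  }, numeric(1))
  names(rates) <- grid
  ramp <- ramp_from_trace(res$traces[[length(prots)]][1, ],
                          res$diverged[[length(prots)]] || !res$equil_ok,
                          ramp_p, dt)
  summ <- derive_summary(rates, dt = dt, step_ms = dur)
  if (!summ$nonspiking) {
    rheo_idx <- which(grid == summ$rheobase)
    summ$ahp <- ahp_from_trace(res$traces[[rheo_idx + 1]][1, ], dt)
  }
  phen <- if (failed) "nonspiking" else classify_phenotype(rates, config)

  structure(list(
    input_resistance = rin,
    fi_curve = rates,
    ramp_threshold = ramp,
    peak_firing_current = summ$peak_firing_current,
    peak_firing_rate = summ$peak_firing_rate,
    rheobase = summ$rheobase,
    ahp = summ$ahp,
    rmp = res$eq_state[cell$inj_idx + 1L],
    phenotype = as.character(phen),
    failed = failed
  ), class = "metric_bundle")
}

#' @export
print.metric_bundle <- function(x, ...) {
  cat("VP_Glu model validation metrics\n")
  cat(sprintf("  input resistance : %s MOhm\n", fmt_na(x$input_resistance)))
  cat(sprintf("  ramp threshold   : %s pA\n", fmt_na(x$ramp_threshold)))
  cat(sprintf("  peak firing      : %s Hz at %s pA\n",
              fmt_na(x$peak_firing_rate), fmt_na(x$peak_firing_current)))
  cat(sprintf("  rheobase         : %s pA | AHP: %s mV | RMP: %s mV\n",
              fmt_na(x$rheobase), fmt_na(x$ahp), fmt_na(x$rmp)))
  cat(sprintf("  phenotype        : %s%s\n", x$phenotype,
              if (x$failed) " (simulation failure)" else ""))
  cat("  F-I (Hz):", paste(signif(x$fi_curve, 3), collapse = " "), "\n")
  invisible(x)
}

fmt_na <- function(x) if (is.na(x)) "NA" else sprintf("%.4g", x)

# A bundle is complete when every scored metric is measurable.
metrics_complete <- function(m) {
  !m$failed && !is.na(m$input_resistance) && !is.na(m$ramp_threshold) &&
    !any(is.na(m$fi_curve)) && !is.na(m$peak_firing_current)
}
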