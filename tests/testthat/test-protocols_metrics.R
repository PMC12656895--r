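# Synthetic trace builders: triangular excursions on a quiet baseline.
triangle_trace <- function(peaks_mV, at_ms, dt = 0.025, total_ms = 200,
                           width_ms = 2, baseline = -65) {
  n <- round(total_ms / dt) + 1
  v <- rep(baseline, n)
  half <- round(width_ms / 2 / dt)
  for (k in seq_along(peaks_mV)) {
    c0 <- round(at_ms[k] / dt) + 1
    idx <- (c0 - half):(c0 + half)
    tri <- baseline + (peaks_mV[k] - baseline) *
      (1 - abs(seq(-half, half)) / half)
    v[idx] <- pmax(v[idx], tri)
  }
  v
}

test_that("three suprathreshold excursions count as three spikes", {
  v <- triangle_trace(c(20, 20, 20), c(50, 100, 150))
  expect_equal(length(detect_spikes(v, dt = 0.025)), 3)
  expect_equal(detect_spikes(v, dt = 0.025), c(50, 100, 150))
})

test_that("subthreshold traces and exact-zero peaks produce no spikes", {
  expect_length(detect_spikes(rep(-65, 1000), dt = 0.025), 0)
  v <- triangle_trace(-25, 50) # never exceeds -20
  expect_length(detect_spikes(v, dt = 0.025), 0)
  v0 <- triangle_trace(0, 50) # peak exactly at 0: strict inequality
  expect_length(detect_spikes(v0, dt = 0.025), 0)
})

test_that("plateau oscillations without a -20 mV recrossing are debounced", {
  dt <- 0.025
  n <- round(100 / dt) + 1
  v <- rep(-65, n)
  # one real spike, then a plateau at +5 with ripples to +10 mV
  i1 <- round(20 / dt)
  v[i1 + (-40:40)] <- -65 + (25 - (-65)) * (1 - abs(-40:40) / 40)
  plateau <- (round(30 / dt)):(round(80 / dt))
  v[plateau] <- 5 + 5 * sin(seq(0, 20 * pi, length.out = length(plateau)))
  expect_equal(length(detect_spikes(v, dt = dt)), 2) # spike + plateau entry
})

test_that("input resistance arithmetic: -5 mV change at -5 pA is 1000 MOhm", {
  dt <- 0.025
  p <- list(amplitude_pA = -5, duration_ms = 500, window_ms = 50)
  v <- c(-60, rep(-65, round(500 / dt)))
  expect_equal(vpglu:::rin_from_trace(v, FALSE, p, dt), 1000)
})

test_that("input resistance probe is invalid when the probe elicits spikes", {
  dt <- 0.025
  p <- list(amplitude_pA = -5, duration_ms = 500, window_ms = 50)
  v <- triangle_trace(20, 250, total_ms = 500)
  expect_true(is.na(vpglu:::rin_from_trace(v, FALSE, p, dt)))
  expect_true(is.na(vpglu:::rin_from_trace(v, TRUE, p, dt)))
})

test_that("input resistance is probe-amplitude invariant in the linear range", {
  cfg <- vpglu_config(hh = list(gna = 0, gk = 0))
  morph <- build_morphology(cfg$morphology)
  cell <- discretize(morph, passive_theta(), cfg)
  rins <- vapply(c(-2, -5, -10), function(a) {
    cfg2 <- cfg
    cfg2$protocols$rin$amplitude_pA <- a
    input_resistance(cell, cfg$settings, cfg2)
  }, numeric(1))
  expect_true(all(abs(rins - rins[2]) / rins[2] < 0.02))
})

test_that("the F-I grid has fourteen amplitudes and passive cells stay silent", {
  cfg <- fast_config()
  expect_equal(cfg$protocols$fi_grid, seq(0, 130, by = 10))
  cell <- discretize(build_morphology(cfg$morphology), passive_theta(),
                     cfg)
  fi <- fi_curve(cell, settings = cfg$settings, config = cfg)
  expect_length(fi, 14)
  expect_equal(names(fi), as.character(seq(0, 130, by = 10)))
  expect_true(all(fi == 0))
})

test_that("ramp threshold converts first-spike time to injected current", {
  dt <- 0.025
  r <- list(from = 0, to = 150, duration_ms = 1000)
  v <- triangle_trace(20, 400, total_ms = 1000)
  expect_equal(vpglu:::ramp_from_trace(v, FALSE, r, dt), 60)
  expect_true(is.na(vpglu:::ramp_from_trace(rep(-65, 1000), FALSE, r, dt)))
})

test_that("ramp threshold decreases as sodium density rises", {
  cfg <- fast_config()
  morph <- build_morphology(cfg$morphology)
  th <- unclass(reference_theta())
  ramps <- vapply(c(0.4, 0.6, 1.0), function(g) {
    th[["nav16"]] <- g
    cell <- discretize(morph, conductance_vector(th), cfg)
    ramp_threshold(cell, cfg$settings, cfg)
  }, numeric(1))
  expect_false(any(is.na(ramps)))
  expect_true(all(diff(ramps) <= 0))
})

test_that("summary metrics implement the argmax, tie and rheobase rules", {
  fi <- c(0, 0, 4, 10, 24, 30, 28, 26, 24, 22, 20, 18, 16, 14)
  names(fi) <- seq(0, 130, by = 10)
  s <- derive_summary(fi)
  expect_equal(s$peak_firing_current, 50)
  expect_equal(s$peak_firing_rate, 30)
  expect_equal(s$rheobase, 20)
  expect_false(s$nonspiking)

  fi_tie <- c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 30, 30, 20, 10)
  names(fi_tie) <- seq(0, 130, by = 10)
  expect_equal(derive_summary(fi_tie)$peak_firing_current, 100)

  fi0 <- setNames(rep(0, 14), seq(0, 130, by = 10))
  s0 <- derive_summary(fi0)
  expect_true(s0$nonspiking)
  expect_true(is.na(s0$rheobase))
})

test_that("AHP is threshold minus trough on a constructed spike", {
  dt <- 0.025
  n <- round(100 / dt) + 1
  v <- rep(-60, n)
  # linear rise at 20 mV/ms from -60 through threshold to +30, then fall
  # to a -75 afterhyperpolarization trough, then partial recovery
  i0 <- round(20 / dt)
  rise <- seq(-60, 30, by = 20 * dt)
  fall <- seq(30, -75, by = -20 * dt)
  rec <- seq(-75, -70, length.out = 400)
  seg <- c(rise, fall[-1], rec)
  v[i0:(i0 + length(seg) - 1)] <- seg
  # dV/dt exceeds 10 mV/ms right at the rise onset: threshold ~ -60,
  # trough -75, AHP = threshold - trough = 15 mV
  expect_equal(vpglu:::ahp_from_trace(v, dt), 15, tolerance = 0.05)
})

test_that("phenotype classification follows the rate-at-maximum rules", {
  grid <- seq(0, 130, by = 10)
  ndb <- setNames(c(0, 0, 2, seq(4, 26, by = 2)), grid)
  expect_equal(as.character(classify_phenotype(ndb)), "NDB")
  db <- setNames(c(0, 0, 4, 10, 24, 30, 20, 14, 10, 8, 6, 4, 3, 3), grid)
  expect_equal(as.character(classify_phenotype(db)), "DB")
  expect_equal(classify_phenotype(setNames(rep(0, 14), grid)),
               "nonspiking")
  indet <- setNames(c(0, 0, 4, 10, 24, 30, 28, 26, 24, 22, 21, 21, 20,
                      20), grid)
  out <- classify_phenotype(indet)
  expect_equal(as.character(out), "DB")
  expect_true(isTRUE(attr(out, "indeterminate")))
})

test_that("the full metric bundle is internally consistent for the reference model", {
  cfg <- fast_config()
  m <- measure_metrics(reference_theta(), cfg)
  expect_s3_class(m, "metric_bundle")
  expect_false(m$failed)
  expect_gt(m$input_resistance, 100)
  expect_equal(m$peak_firing_rate, max(m$fi_curve))
  expect_equal(as.numeric(names(which.max(m$fi_curve))),
               m$peak_firing_current)
  expect_equal(m$rheobase,
               as.numeric(names(which(m$fi_curve > 0)[1])))
  expect_true(m$phenotype %in% c("DB", "NDB"))
  expect_true(vpglu:::metrics_complete(m))
})
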