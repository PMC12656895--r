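# A metric bundle that matches a target bundle exactly.
bundle_from_target <- function(tgt) {
  structure(list(
    input_resistance = tgt$metrics$input_resistance$mean,
    fi_curve = tgt$fi_mean,
    ramp_threshold = tgt$metrics$rheobase$mean,
    peak_firing_current = tgt$metrics$peak_firing_current$mean,
    peak_firing_rate = tgt$metrics$peak_firing_rate$mean,
    rheobase = tgt$metrics$rheobase$mean,
    ahp = tgt$metrics$ahp$mean, rmp = tgt$metrics$rmp$mean,
    phenotype = tgt$phenotype, failed = FALSE
  ), class = "metric_bundle")
}

test_that("the score is zero at the target and 1/4 per normalizer unit of error", {
  tgt <- builtin_targets("NDB")
  m <- bundle_from_target(tgt)
  expect_equal(score_parameter_set(m, tgt), 0)

  m1 <- m
  m1$input_resistance <- m$input_resistance +
    tgt$metrics$input_resistance$normalizer
  expect_equal(score_parameter_set(m1, tgt), 1 / 4)

  m2 <- m
  m2$ramp_threshold <- m$ramp_threshold - tgt$metrics$rheobase$normalizer
  expect_equal(score_parameter_set(m2, tgt), 1 / 4)
})

test_that("worsening any single metric never decreases the score", {
  tgt <- builtin_targets("DB")
  m <- bundle_from_target(tgt)
  s0 <- score_parameter_set(m, tgt)
  for (field in c("input_resistance", "ramp_threshold",
                  "peak_firing_current")) {
    prev <- s0
    for (delta in c(1, 5, 20)) {
      m1 <- m
      m1[[field]] <- m[[field]] + delta
      s <- score_parameter_set(m1, tgt)
      expect_gte(s, prev)
      prev <- s
    }
  }
  m3 <- m
  m3$fi_curve <- m$fi_curve + 2
  expect_gt(score_parameter_set(m3, tgt), s0)
})

test_that("incomplete metric bundles score infinity", {
  tgt <- builtin_targets("NDB")
  m <- bundle_from_target(tgt)
  m$ramp_threshold <- NA_real_
  expect_equal(score_parameter_set(m, tgt), Inf)
  m2 <- bundle_from_target(tgt)
  m2$failed <- TRUE
  expect_equal(score_parameter_set(m2, tgt), Inf)
})

test_that("log-probability is -Inf outside the prior and scales with temperature", {
  tgt <- builtin_targets("NDB")
  prior <- prior_spec()
  th_bad <- unclass(reference_theta())
  th_bad[["kdr"]] <- -1e-6
  expect_equal(log_probability(th_bad, tgt, prior), -Inf)
  th_big <- unclass(reference_theta())
  th_big[["nav16"]] <- prior$upper[["nav16"]] * 2
  expect_equal(log_probability(th_big, tgt, prior), -Inf)

  m <- bundle_from_target(tgt)
  expect_equal(log_probability(unclass(reference_theta()), tgt, prior,
                               metrics = m), 0)
  m$input_resistance <- m$input_resistance + 100
  lp1 <- log_probability(unclass(reference_theta()), tgt, prior,
                         temperature = 0.05, metrics = m)
  lp2 <- log_probability(unclass(reference_theta()), tgt, prior,
                         temperature = 0.025, metrics = m)
  expect_equal(lp2, 2 * lp1)
})

test_that("the stretch-move scale density has the closed-form mean", {
  set.seed(1)
  z <- sample_stretch_z(1e6, a = 2)
  expect_true(all(z >= 0.5 & z <= 2))
  # density ~ 1/sqrt(z) on [1/2, 2]: E[z] = 7/6
  expect_rel_equal(mean(z), 7 / 6, 0.003)
})

test_that("the ensemble recovers a two-dimensional Gaussian", {
  set.seed(42)
  logp <- function(x) -0.5 * sum(x^2)
  n <- 32
  pos <- matrix(rnorm(2 * n, 0, 0.5), n, 2)
  state <- list(pos = pos, logp = apply(pos, 1, logp))
  burn <- 500
  keep <- 5000
  samples <- matrix(NA_real_, keep * n, 2)
  for (it in seq_len(burn + keep)) {
    state <- stretch_update(state, logp, a = 2)
    if (it > burn)
      samples[((it - burn - 1) * n + 1):((it - burn) * n), ] <- state$pos
  }
  expect_lt(max(abs(colMeans(samples))), 0.05)
  cv <- stats::cov(samples)
  expect_lt(max(abs(cv - diag(2))), 0.1)
})

test_that("the stretch move is invariant under affine transformation", {
  L <- matrix(c(3, 0, 1.5, 0.25), 2, 2) # target covariance L L^T
  logp_iso <- function(x) -0.5 * sum(x^2)
  logp_aff <- function(x) {
    y <- solve(L, x)
    -0.5 * sum(y^2)
  }
  run_acc <- function(logp, transform) {
    set.seed(7)
    n <- 32
    pos <- matrix(rnorm(2 * n, 0, 0.5), n, 2)
    if (transform) pos <- t(L %*% t(pos))
    state <- list(pos = pos, logp = apply(pos, 1, logp))
    acc <- 0
    iters <- 400
    for (it in seq_len(iters)) {
      state <- stretch_update(state, logp, a = 2)
      acc <- acc + mean(state$accept)
    }
    acc / iters
  }
  a_iso <- run_acc(logp_iso, FALSE)
  a_aff <- run_acc(logp_aff, TRUE)
  # identical seeds: the chain of z-draws and partner picks coincide, so
  # acceptance rates agree up to the Monte-Carlo effect of accept/reject
  # interleaving
  expect_lt(abs(a_iso - a_aff), 0.02)
})

test_that("a symmetric two-point target is occupied half and half", {
  set.seed(3)
  logp <- function(x) {
    if (abs(x[1]) < 0.5 || abs(x[1] - 3) < 0.5) 0 else -Inf
  }
  n <- 20
  pos <- matrix(c(rep(0, n / 2), rep(3, n / 2)), n, 1)
  state <- list(pos = pos, logp = apply(pos, 1, logp))
  occ_hi <- 0
  iters <- 4000
  for (it in seq_len(iters)) {
    state <- stretch_update(state, logp, a = 2)
    occ_hi <- occ_hi + mean(state$pos[, 1] > 1.5)
  }
  expect_lt(abs(occ_hi / iters - 0.5), 0.02)
})

test_that("calibration histories are bit-identical under a fixed seed", {
  cfg <- fast_config()
  tgt <- ground_truth_fixture(reference_theta(), cfg)
  cal <- suppressWarnings(
    calibration_config(n_runs = 1, n_walkers = 4, n_iterations = 2,
                       threshold = 1))
  h1 <- run_calibration(tgt, cal, seed = 5, config = cfg)
  h2 <- run_calibration(tgt, cal, seed = 5, config = cfg)
  expect_identical(h1$pos, h2$pos)
  expect_identical(h1$score, h2$score)
  h3 <- run_calibration(tgt, cal, seed = 6, config = cfg)
  expect_false(identical(h1$pos, h3$pos))
})

test_that("the default configuration has the published ensemble shape", {
  cal <- scale_preset("paper")
  expect_equal(cal$n_runs, 10)
  expect_equal(cal$n_walkers, 400)
  expect_equal(cal$n_iterations, 25)
  # history shape contract on a miniature analogue
  cfg <- fast_config()
  tgt <- ground_truth_fixture(reference_theta(), cfg)
  cal2 <- suppressWarnings(
    calibration_config(n_runs = 2, n_walkers = 4, n_iterations = 2))
  h <- run_calibration(tgt, cal2, seed = 1, config = cfg)
  expect_equal(dim(h$pos), c(2, 3, 4, 9))
  expect_equal(dim(h$score), c(2, 3, 4))
})

test_that("population assembly deduplicates, filters and re-simulates", {
  cfg <- fast_config()
  tgt <- ground_truth_fixture(reference_theta(), cfg)
  th <- unclass(reference_theta())
  # hand-built history: the same point twice, plus an off-target point
  pos <- array(NA_real_, c(1, 1, 4, 9))
  pos[1, 1, 1, ] <- th
  pos[1, 1, 2, ] <- th            # bit-identical duplicate
  pos[1, 1, 3, ] <- th * 1.5      # different, high score
  pos[1, 1, 4, ] <- th
  score <- array(c(0, 0, 9, 0), c(1, 1, 4))
  hist <- structure(list(pos = pos, score = score, target = tgt,
                         cfg = suppressWarnings(
                           calibration_config(n_runs = 1, n_walkers = 4,
                                              n_iterations = 1,
                                              threshold = 0.5)),
                         seed = 1),
                    class = "calibration_history")
  pop <- assemble_population(hist, config = cfg)
  expect_equal(nrow(pop$theta), 1) # duplicates collapse to one member
  expect_equal(unname(pop$theta[1, ]), unname(th))
  expect_equal(pop$phenotype, tgt$phenotype)
  # caching integrity: stored metrics equal a fresh re-simulation
  m_new <- measure_metrics(pop$theta[1, ], cfg)
  expect_identical(pop$metrics[[1]], m_new)
  expect_identical(pop$scores[1], score_parameter_set(m_new, tgt))
})

test_that("a zero threshold on a continuous score empties the population", {
  cfg <- fast_config()
  tgt <- builtin_targets("NDB", config = cfg)
  th <- unclass(reference_theta())
  pos <- array(NA_real_, c(1, 1, 4, 9))
  for (w in 1:4) pos[1, 1, w, ] <- th
  score <- array(rep(0.4, 4), c(1, 1, 4))
  hist <- structure(list(pos = pos, score = score, target = tgt,
                         cfg = suppressWarnings(
                           calibration_config(n_runs = 1, n_walkers = 4,
                                              n_iterations = 1)),
                         seed = 1),
                    class = "calibration_history")
  expect_warning(pop <- assemble_population(hist, threshold = 0,
                                            config = cfg),
                 "empty")
  expect_equal(nrow(pop$theta), 0)
})
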