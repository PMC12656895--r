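#' Uniform prior box over the conductance space
#'
#' Independent uniform priors constrained to physiologic ranges: every
#' conductance is nonnegative with a per-parameter upper bound. The
#' default upper bounds reflect plausible maximal densities for each
#' channel class at an axon initial segment: large for the fast sodium
#' and delayed-rectifier conductances, small for the calcium channels
#' and the calcium-activated and muscarinic potassium conductances whose
#' physiologic densities are orders of magnitude lower, and a leak bound
#' compatible with the gigaohm-range input resistances of these cells.
#'
#' @param lower,upper length-9 bound vectors in [conductance_names()]
#'   order
#' @return a `prior_spec` list
#' @export
prior_spec <- function(lower = rep(0, 9),
                       upper = c(nav16 = 1, kdr = 0.5, ka = 0.1,
                                 sk = 0.01, bk = 0.05, km = 0.01,
                                 cal = 0.002, cat = 0.002,
                                 leak = 4e-4)) {
  stopifnot(length(lower) == 9, length(upper) == 9,
            all(lower >= 0), all(lower < upper))
  structure(list(lower = stats::setNames(lower, conductance_names()),
                 upper = stats::setNames(upper, conductance_names())),
            class = "prior_spec")
}

in_prior <- function(theta, prior) {
  all(theta >= prior$lower) && all(theta <= prior$upper)
}

#' Score a metric bundle against a target bundle
#'
#' The score is the mean, over the four validation metrics, of the
#' normalized distances |model - target mean| / normalizer: input
#' resistance, ramp threshold, peak firing current, and the F-I term
#' (sum of absolute rate differences over the grid, divided by the F-I
#' normalizer). Lower is better; an incomplete bundle (simulation
#' failure, nonspiking, unmeasurable probe) scores +Inf.
#'
#' @param m a `metric_bundle`
#' @param target a `target_bundle`
#' @return nonnegative score (possibly `Inf`)
#' @export
score_parameter_set <- function(m, target) {
  if (!metrics_complete(m)) return(Inf)
  tm <- target$metrics
  terms <- c(
    abs(m$input_resistance - tm$input_resistance$mean) /
      tm$input_resistance$normalizer,
    abs(m$ramp_threshold - tm$rheobase$mean) / tm$rheobase$normalizer,
    abs(m$peak_firing_current - tm$peak_firing_current$mean) /
      tm$peak_firing_current$normalizer,
    sum(abs(m$fi_curve - target$fi_mean)) / target$fi_normalizer
  )
  mean(terms)
}

#' Log-probability of a conductance vector
#'
#' Boltzmann form: -Inf outside the prior box, otherwise
#' `-score / temperature`. The temperature sets how sharply the ensemble
#' concentrates around low scores.
#'
#' @param theta length-9 conductance vector
#' @param target a `target_bundle`
#' @param prior a [prior_spec()]
#' @param temperature likelihood temperature (> 0)
#' @param config a [vpglu_config()]
#' @param metrics optional pre-computed `metric_bundle` for `theta`
#' @return scalar log-probability (possibly `-Inf`)
#' @export
log_probability <- function(theta, target, prior = prior_spec(),
                            temperature = 0.05, config = vpglu_config(),
                            metrics = NULL) {
  stopifnot(temperature > 0)
  if (!in_prior(theta, prior)) return(-Inf)
  if (is.null(metrics)) metrics <- measure_metrics(theta, config)
  -score_parameter_set(metrics, target) / temperature
}

#' Draw from the stretch-move scale density
#'
#' Samples `z` with density proportional to `1/sqrt(z)` on
#' `[1/a, a]` via inverse transform: `z = ((a-1) u + 1)^2 / a`.
#'
#' @param n number of draws
#' @param a stretch parameter (> 1)
#' @return numeric vector of scale factors
#' @export
sample_stretch_z <- function(n, a = 2) {
  stopifnot(a > 1)
  ((a - 1) * stats::runif(n) + 1)^2 / a
}

#' One affine-invariant ensemble update (stretch move)
#'
#' Updates every walker once using the stretch move: walker `X_i`
#' proposes `Y = X_j + z (X_i - X_j)` with a partner `X_j` drawn from the
#' complementary half of the ensemble and `z` from the `1/sqrt(z)`
#' density on `[1/a, a]`; the proposal is accepted with probability
#' `min(1, z^(d-1) exp(logp(Y) - logp(X_i)))`. The ensemble is split
#' into two halves updated alternately, so each proposal uses already
#' updated partners from the other half.
#'
#' @param state list with `pos` (n_walkers x d matrix) and `logp`
#'   (length n_walkers)
#' @param logp_fn function(theta) -> scalar log-probability
#' @param a stretch parameter
#' @return updated state; also carries `accept` (logical per walker)
#' @export
stretch_update <- function(state, logp_fn, a = 2) {
  pos <- state$pos
  logp <- state$logp
  n <- nrow(pos)
  d <- ncol(pos)
  stopifnot(n >= 4, n %% 2 == 0)
  halves <- list(seq_len(n / 2), seq_len(n / 2) + n / 2)
  accept <- logical(n)
  for (h in 1:2) {
    idx <- halves[[h]]
    other <- halves[[3 - h]]
    z <- sample_stretch_z(length(idx), a)
    partner <- other[sample.int(length(other), length(idx),
                                replace = TRUE)]
    for (k in seq_along(idx)) {
      i <- idx[k]
      y <- pos[partner[k], ] + z[k] * (pos[i, ] - pos[partner[k], ])
      lp_y <- logp_fn(y)
      log_ratio <- (d - 1) * log(z[k]) + lp_y - logp[i]
      if (is.nan(log_ratio)) log_ratio <- -Inf # -Inf - -Inf
      if (log(stats::runif(1)) < log_ratio) {
        pos[i, ] <- y
        logp[i] <- lp_y
        accept[i] <- TRUE
      }
    }
  }
  list(pos = pos, logp = logp, accept = accept)
}

#' Calibration configuration
#'
#' Ensemble-search settings: number of independent restarts, walkers and
#' iterations per run, the restart noise schedule (the standard deviation
#' of the Gaussian initialization noise for run `r` is
#' `init_noise_frac * r` times the prior box width, clipped into the
#' box), the stretch parameter, likelihood temperature, and the score
#' threshold under which parameter sets join the final population.
#'
#' @param n_runs independent restarts
#' @param n_walkers ensemble size (even, >= 4; >= 2 x dimension for a
#'   proper sampler)
#' @param n_iterations stretch updates per run
#' @param a stretch parameter
#' @param temperature likelihood temperature
#' @param threshold population score cutoff
#' @param init_noise_frac per-run growth of the initialization noise, as
#'   a fraction of the box width
#' @param base_guess `"reference"` (the package's reference exemplar of
#'   the target's phenotype, [reference_theta()]), `"center"` (of the
#'   prior box), or a length-9 vector
#' @return a `calibration_config` list
#' @export
calibration_config <- function(n_runs = 10, n_walkers = 400,
                               n_iterations = 25, a = 2,
                               temperature = 0.05, threshold = 0.5,
                               init_noise_frac = 0.05,
                               base_guess = "reference") {
  stopifnot(n_runs >= 1, n_walkers >= 4, n_walkers %% 2 == 0,
            n_iterations >= 1, a > 1, temperature > 0, threshold >= 0,
            init_noise_frac > 0)
  if (n_walkers < 18)
    warning("fewer than 2 x dimension walkers: search remains usable ",
            "but the ensemble is confined to a parameter subspace")
  structure(list(n_runs = n_runs, n_walkers = n_walkers,
                 n_iterations = n_iterations, a = a,
                 temperature = temperature, threshold = threshold,
                 init_noise_frac = init_noise_frac,
                 base_guess = base_guess),
            class = "calibration_config")
}

#' Scale presets for the calibration
#'
#' `smoke` is a minutes-scale wiring check, `desk` a single-workstation
#' run, `paper` the full configuration (10 restarts of 400 walkers x 25
#' iterations).
#'
#' @param scale one of `"smoke"`, `"desk"`, `"paper"`
#' @param ... overrides passed to [calibration_config()]
#' @return a `calibration_config`
#' @export
scale_preset <- function(scale = c("desk", "smoke", "paper"), ...) {
  scale <- match.arg(scale)
  args <- switch(scale,
    smoke = list(n_runs = 1, n_walkers = 20, n_iterations = 5),
    desk = list(n_runs = 3, n_walkers = 64, n_iterations = 15),
    paper = list(n_runs = 10, n_walkers = 400, n_iterations = 25))
  do.call(calibration_config, utils::modifyList(args, list(...)))
}

#' Run the ensemble calibration against a target bundle
#'
#' Performs `n_runs` independent restarts of the affine-invariant
#' ensemble search. Run `r` initializes its walkers at the base guess
#' plus Gaussian noise with the r-th schedule standard deviation, clipped
#' into the prior box, then performs `n_iterations` stretch updates.
#' Every evaluated position and its score are kept in the returned
#' history; identical seeds yield identical histories.
#'
#' @param target a `target_bundle`
#' @param cfg a [calibration_config()]
#' @param seed integer seed for the ensemble RNG
#' @param config a [vpglu_config()]
#' @param progress print per-iteration best scores
#' @return object of class `calibration_history`: arrays `pos`
#'   (runs x iterations+1 x walkers x 9) and `score`
#'   (runs x iterations+1 x walkers), acceptance-rate and best-score
#'   traces, plus the target, cfg and seed
#' @export
run_calibration <- function(target, cfg = scale_preset("desk"), seed = 1,
                            config = vpglu_config(), progress = FALSE) {
  d <- 9L
  prior <- config$prior
  width <- prior$upper - prior$lower
  base <- if (identical(cfg$base_guess, "reference")) {
    phen <- if (identical(target$phenotype, "DB")) "DB" else "NDB"
    unclass(reference_theta(phen))
  } else if (identical(cfg$base_guess, "center")) {
    (prior$lower + prior$upper) / 2
  } else {
    stopifnot(length(cfg$base_guess) == d)
    as.numeric(cfg$base_guess)
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  # score cache so history scores come from the same evaluation as the
  # accepted log-probabilities
  score_of <- function(theta) {
    m <- measure_metrics(theta, config)
    score_parameter_set(m, target)
  }
  logp_fn <- function(theta) {
    if (!in_prior(theta, prior)) return(structure(-Inf, score = Inf))
    s <- score_of(theta)
    structure(-s / cfg$temperature, score = s)
  }

  nw <- cfg$n_walkers
  nit <- cfg$n_iterations
  pos_h <- array(NA_real_, c(cfg$n_runs, nit + 1, nw, d))
  score_h <- array(NA_real_, c(cfg$n_runs, nit + 1, nw))
  acc_h <- matrix(NA_real_, cfg$n_runs, nit)
  best_h <- matrix(NA_real_, cfg$n_runs, nit + 1)

  for (r in seq_len(cfg$n_runs)) {
    sd_r <- cfg$init_noise_frac * r * width
    pos <- t(vapply(seq_len(nw), function(i) {
      pmin(pmax(base + stats::rnorm(d, 0, sd_r), prior$lower),
           prior$upper)
    }, numeric(d)))
    colnames(pos) <- conductance_names()
    lp <- numeric(nw)
    sc <- numeric(nw)
    for (i in seq_len(nw)) {
      v <- logp_fn(pos[i, ])
      lp[i] <- as.numeric(v)
      sc[i] <- attr(v, "score")
    }
    if (all(!is.finite(lp)))
      stop("calibration setup: every initial walker is infeasible ",
           "(all scores infinite); widen the noise schedule or move ",
           "the base guess")
    pos_h[r, 1, , ] <- pos
    score_h[r, 1, ] <- sc
    best_h[r, 1] <- min(sc)
    state <- list(pos = pos, logp = lp, score = sc)

    for (it in seq_len(nit)) {
      # wrap logp_fn so stretch_update can carry scores through
      new_state <- stretch_update_scored(state, logp_fn, cfg$a)
      state <- new_state
      pos_h[r, it + 1, , ] <- state$pos
      score_h[r, it + 1, ] <- state$score
      acc_h[r, it] <- mean(state$accept)
      best_h[r, it + 1] <- min(state$score)
      if (progress)
        message(sprintf("run %d iter %2d: best %.3f acc %.2f", r, it,
                        best_h[r, it + 1], acc_h[r, it]))
    }
  }

  structure(list(pos = pos_h, score = score_h, acceptance = acc_h,
                 best = best_h, target = target, cfg = cfg, seed = seed),
            class = "calibration_history")
}

# stretch_update, but carrying the score attribute produced by the
# calibration's log-probability through to the history.
stretch_update_scored <- function(state, logp_fn, a) {
  pos <- state$pos
  logp <- state$logp
  score <- state$score
  n <- nrow(pos)
  d <- ncol(pos)
  halves <- list(seq_len(n / 2), seq_len(n / 2) + n / 2)
  accept <- logical(n)
  for (h in 1:2) {
    idx <- halves[[h]]
    other <- halves[[3 - h]]
    z <- sample_stretch_z(length(idx), a)
    partner <- other[sample.int(length(other), length(idx),
                                replace = TRUE)]
    for (k in seq_along(idx)) {
      i <- idx[k]
      y <- pos[partner[k], ] + z[k] * (pos[i, ] - pos[partner[k], ])
      lp_y <- logp_fn(y)
      log_ratio <- (d - 1) * log(z[k]) + as.numeric(lp_y) - logp[i]
      if (is.nan(log_ratio)) log_ratio <- -Inf
      if (log(stats::runif(1)) < log_ratio) {
        pos[i, ] <- y
        logp[i] <- as.numeric(lp_y)
        score[i] <- attr(lp_y, "score")
        accept[i] <- TRUE
      }
    }
  }
  list(pos = pos, logp = logp, score = score, accept = accept)
}

#' @export
print.calibration_history <- function(x, ...) {
  cat(sprintf("Calibration history [%s target]: %d runs x %d iterations x %d walkers\n",
              x$target$phenotype, dim(x$pos)[1], dim(x$pos)[2] - 1,
              dim(x$pos)[3]))
  cat(sprintf("  best score: %.4f | mean acceptance: %.2f\n",
              min(x$score, na.rm = TRUE),
              mean(x$acceptance, na.rm = TRUE)))
  invisible(x)
}

#' Assemble the final model population from a calibration history
#'
#' Collects every evaluated parameter set with score at or below the
#' threshold, deduplicates within 1e-9 relative tolerance, re-simulates
#' each survivor's metrics from scratch (nothing is cached from the
#' search), and keeps those whose re-simulated score still passes and
#' whose phenotype matches the target bundle's phenotype.
#'
#' @param history a `calibration_history`
#' @param target a `target_bundle` (defaults to the history's)
#' @param threshold score cutoff (defaults to the history cfg's)
#' @param config a [vpglu_config()]
#' @return object of class `model_population`: list with `theta` (matrix
#'   n x 9), `metrics` (list of `metric_bundle`), `scores`, `phenotype`
#' @export
assemble_population <- function(history, target = history$target,
                                threshold = history$cfg$threshold,
                                config = vpglu_config()) {
  stopifnot(length(history$score) > 0)
  nd <- dim(history$pos)
  flat_pos <- matrix(aperm(history$pos, c(3, 2, 1, 4)), ncol = nd[4])
  flat_score <- as.vector(aperm(history$score, c(3, 2, 1)))
  keep <- which(is.finite(flat_score) & flat_score <= threshold)
  if (!length(keep)) {
    warning("no parameter set met the score threshold; empty population")
    return(empty_population(target$phenotype))
  }
  cand <- flat_pos[keep, , drop = FALSE]
  key <- apply(signif(cand, 10), 1, paste, collapse = "|")
  first <- !duplicated(key)
  cand <- cand[first, , drop = FALSE]

  metrics <- vector("list", nrow(cand))
  scores <- numeric(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    metrics[[i]] <- measure_metrics(cand[i, ], config)
    scores[i] <- score_parameter_set(metrics[[i]], target)
  }
  ok <- scores <= threshold &
    vapply(metrics, function(m) identical(m$phenotype, target$phenotype),
           logical(1))
  if (!any(ok)) {
    warning("no parameter set matched the target phenotype at the ",
            "threshold; empty population")
    return(empty_population(target$phenotype))
  }
  theta <- cand[ok, , drop = FALSE]
  colnames(theta) <- conductance_names()
  structure(list(theta = theta, metrics = metrics[ok],
                 scores = scores[ok], phenotype = target$phenotype),
            class = "model_population")
}

empty_population <- function(phenotype) {
  structure(list(theta = matrix(numeric(0), 0, 9,
                                dimnames = list(NULL,
                                                conductance_names())),
                 metrics = list(), scores = numeric(0),
                 phenotype = phenotype),
            class = "model_population")
}

#' @export
print.model_population <- function(x, ...) {
  cat(sprintf("Model population [%s]: %d members\n", x$phenotype,
              nrow(x$theta)))
  if (nrow(x$theta)) {
    cat(sprintf("  scores: %.3f - %.3f\n", min(x$scores), max(x$scores)))
    s <- population_summary(x$metrics)
    cat(sprintf("  mean peak firing: %.3g Hz at %.3g pA | mean ramp threshold: %.3g pA\n",
                s$means[["peak_firing_rate"]],
                s$means[["peak_firing_current"]],
                s$means[["ramp_threshold"]]))
  }
  invisible(x)
}
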