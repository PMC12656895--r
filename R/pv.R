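#' Titrate parvalbumin across a calibrated model population
#'
#' Re-simulates every member of a calibrated population through the full
#' current-clamp battery at each total parvalbumin concentration, with
#' the buffer equilibrated to baseline calcium at stimulus onset. The
#' baseline (0 mM) level is the population's stored metrics: the buffer
#' equations reduce exactly to the unbuffered calcium model at zero
#' total concentration. Members whose simulation fails at some
#' concentration are flagged and excluded from that concentration's
#' summary.
#'
#' @param pop a `model_population`
#' @param concentrations total PV concentrations, mM (0 is always
#'   prepended as the baseline)
#' @param config a [vpglu_config()]
#' @return object of class `titration_result`: per-concentration metric
#'   bundles, population summaries, and mean F-I curves
#' @export
titrate_pv <- function(pop, concentrations = c(1, 2, 5, 10),
                       config = vpglu_config()) {
  stopifnot(nrow(pop$theta) >= 1, all(concentrations >= 0))
  concentrations <- setdiff(unique(concentrations), 0)
  levels <- c(0, concentrations)
  n <- nrow(pop$theta)

  per_conc <- vector("list", length(levels))
  names(per_conc) <- levels
  per_conc[["0"]] <- pop$metrics
  for (ci in seq_along(concentrations)) {
    conc <- concentrations[ci]
    bundles <- vector("list", n)
    for (i in seq_len(n))
      bundles[[i]] <- measure_metrics(pop$theta[i, ], config,
                                      pv_mM = conc)
    per_conc[[as.character(conc)]] <- bundles
  }

  summaries <- lapply(per_conc, function(bundles) {
    ok <- vapply(bundles, metrics_complete, logical(1))
    if (any(!ok))
      warning(sum(!ok), " member(s) failed at a titration level; ",
              "excluded from that level's summary")
    population_summary(bundles[ok])
  })

  structure(list(concentrations = levels, metrics = per_conc,
                 summaries = summaries, phenotype = pop$phenotype),
            class = "titration_result")
}

#' @export
print.titration_result <- function(x, ...) {
  cat(sprintf("PV titration [%s population], %d members\n", x$phenotype,
              length(x$metrics[[1]])))
  cat(sprintf("  %6s %12s %12s %12s %8s\n", "PV mM", "peak I (pA)",
              "peak f (Hz)", "ramp (pA)", "DB frac"))
  for (lv in as.character(x$concentrations)) {
    s <- x$summaries[[lv]]
    db <- db_fraction(x$metrics[[lv]])
    cat(sprintf("  %6s %7.1f+/-%-5.1f %6.2f+/-%-5.2f %6.1f+/-%-5.1f %8.2f\n",
                lv, s$means[["peak_firing_current"]],
                s$sds[["peak_firing_current"]],
                s$means[["peak_firing_rate"]],
                s$sds[["peak_firing_rate"]],
                s$means[["ramp_threshold"]],
                s$sds[["ramp_threshold"]], db))
  }
  invisible(x)
}

#' Population summary statistics
#'
#' Arithmetic mean and sample standard deviation of each scalar metric,
#' plus the pointwise mean F-I curve over the grid.
#'
#' @param bundles list of `metric_bundle`
#' @return list with `means`, `sds` (named vectors over
#'   `input_resistance`, `ramp_threshold`, `peak_firing_current`,
#'   `peak_firing_rate`, `rheobase`, `ahp`), `fi_mean`, and `n`
#' @export
population_summary <- function(bundles) {
  stopifnot(length(bundles) >= 1)
  fields <- c("input_resistance", "ramp_threshold", "peak_firing_current",
              "peak_firing_rate", "rheobase", "ahp")
  vals <- vapply(fields, function(f)
    vapply(bundles, function(b) as.numeric(b[[f]]), numeric(1)),
    numeric(length(bundles)))
  vals <- matrix(vals, nrow = length(bundles),
                 dimnames = list(NULL, fields))
  fi <- do.call(rbind, lapply(bundles, `[[`, "fi_curve"))
  sds <- if (length(bundles) == 1) {
    stats::setNames(rep(0, ncol(vals)), colnames(vals))
  } else {
    apply(vals, 2, stats::sd, na.rm = TRUE)
  }
  list(means = colMeans(vals, na.rm = TRUE),
       sds = sds,
       fi_mean = colMeans(fi),
       n = length(bundles))
}

# Fraction of bundles classified DB.
db_fraction <- function(bundles) {
  if (!length(bundles)) return(NA_real_)
  mean(vapply(bundles, function(b) identical(b$phenotype, "DB"),
              logical(1)))
}

#' Mann-Whitney U test
#'
#' Rank-sum test between two independent samples with midrank handling
#' of ties. For small samples (n1 + n2 <= 20) the two-sided p-value is
#' computed by exact enumeration of all partitions of the pooled ranks;
#' for larger samples by the normal approximation with tie correction
#' and continuity correction. Reports `U = min(U1, U2)` and persists
#' both one-sided statistics.
#'
#' @param x,y numeric samples
#' @param exact_max largest pooled size for exact enumeration
#' @return list with `U`, `U1`, `U2`, `p`, `method`
#' @export
mann_whitney_u <- function(x, y, exact_max = 20) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled) # midranks
  U1 <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  if (n1 + n2 <= exact_max) {
    p <- mwu_exact_p(rk, n1, U1)
    method <- "exact enumeration"
  } else {
    ties <- table(rk)
    tie_term <- sum(ties^3 - ties)
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U1 - n1 * n2 / 2) - 0.5) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-max(z, 0))
    }
    method <- "normal approximation with tie correction"
  }
  list(U = min(U1, U2), U1 = U1, U2 = U2, p = min(p, 1), method = method)
}

# Exact two-sided p by enumeration over all choose(n, n1) assignments of
# the pooled midranks: P(|U - n1 n2 / 2| >= |U_obs - n1 n2 / 2|).
mwu_exact_p <- function(rk, n1, U1) {
  n <- length(rk)
  n2 <- n - n1
  dev_obs <- abs(U1 - n1 * n2 / 2)
  combos <- utils::combn(n, n1)
  base <- n1 * (n1 + 1) / 2
  hits <- 0L
  for (j in seq_len(ncol(combos))) {
    u <- sum(rk[combos[, j]]) - base
    if (abs(u - n1 * n2 / 2) >= dev_obs - 1e-12) hits <- hits + 1L
  }
  hits / ncol(combos)
}

#' Pairwise population comparisons across a titration
#'
#' Mann-Whitney U tests of each metric between the baseline (0 mM)
#' population and each PV concentration, mirroring the per-comparison
#' presentation of the source experiment (no multiple-testing
#' correction by default; set `p_adjust` to a `stats::p.adjust` method
#' to correct).
#'
#' @param titr a `titration_result`
#' @param metrics metric fields to compare
#' @param p_adjust `"none"` or a method name for [stats::p.adjust()]
#' @return data frame with concentration, metric, U, U1, U2, p
#' @export
titration_tests <- function(titr,
                            metrics = c("peak_firing_current",
                                        "peak_firing_rate",
                                        "ramp_threshold"),
                            p_adjust = "none") {
  base <- titr$metrics[["0"]]
  rows <- list()
  for (lv in as.character(setdiff(titr$concentrations, 0))) {
    for (f in metrics) {
      xv <- metric_values(base, f)
      yv <- metric_values(titr$metrics[[lv]], f)
      mw <- mann_whitney_u(xv[!is.na(xv)], yv[!is.na(yv)])
      rows[[length(rows) + 1L]] <-
        data.frame(pv_mM = as.numeric(lv), metric = f, U = mw$U,
                   U1 = mw$U1, U2 = mw$U2, p = mw$p,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (!identical(p_adjust, "none"))
    out$p_adj <- stats::p.adjust(out$p, method = p_adjust)
  out
}

metric_values <- function(bundles, field) {
  vapply(bundles, function(b) as.numeric(b[[field]]), numeric(1))
}
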