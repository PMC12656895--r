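#' Write a model population as delimited text
#'
#' One row per model: the nine conductances (S/cm^2), scalar metrics,
#' the F-I rates, phenotype and score. Numeric values are written in
#' full precision so a read round-trips bit-exactly. The header row
#' carries units in the column names.
#'
#' @param pop a `model_population`
#' @param path output TSV file
#' @export
write_population <- function(pop, path) {
  n <- nrow(pop$theta)
  grid <- if (n) as.numeric(names(pop$metrics[[1]]$fi_curve))
          else seq(0, 130, by = 10)
  header <- c(paste0("g_", conductance_names(), "_S_cm2"),
              "input_resistance_MOhm", "ramp_threshold_pA",
              "peak_firing_current_pA", "peak_firing_rate_Hz",
              "rheobase_pA", "ahp_mV", "rmp_mV",
              paste0("fi_", grid, "pA_Hz"), "phenotype", "score")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  if (!n) {
    warning("writing empty population: header-only file")
    return(invisible(path))
  }
  for (i in seq_len(n)) {
    m <- pop$metrics[[i]]
    row <- c(full_prec(pop$theta[i, ]),
             full_prec(c(m$input_resistance, m$ramp_threshold,
                         m$peak_firing_current, m$peak_firing_rate,
                         m$rheobase, m$ahp, m$rmp, m$fi_curve)),
             m$phenotype, full_prec(pop$scores[i]))
    writeLines(paste(row, collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], as.numeric) # integers -> double for exact
                                         # round trips
  gcols <- paste0("g_", conductance_names(), "_S_cm2")
  ficols <- grep("^fi_", names(df), value = TRUE)
  grid <- as.numeric(sub("^fi_([0-9.]+)pA_Hz$", "\\1", ficols))
  if (!nrow(df)) return(empty_population(NA_character_))
  theta <- as.matrix(df[gcols])
  colnames(theta) <- conductance_names()
  metrics <- lapply(seq_len(nrow(df)), function(i) {
    fi <- as.numeric(df[i, ficols])
    names(fi) <- grid
    structure(list(
      input_resistance = df$input_resistance_MOhm[i],
      fi_curve = fi,
      ramp_threshold = df$ramp_threshold_pA[i],
      peak_firing_current = df$peak_firing_current_pA[i],
      peak_firing_rate = df$peak_firing_rate_Hz[i],
      rheobase = df$rheobase_pA[i],
      ahp = df$ahp_mV[i],
      rmp = df$rmp_mV[i],
      phenotype = df$phenotype[i],
      failed = FALSE
    ), class = "metric_bundle")
  })
  structure(list(theta = theta, metrics = metrics, scores = df$score,
                 phenotype = df$phenotype[1]),
            class = "model_population")
}

#' Write a voltage trace as delimited text
#'
#' @param trace a `voltage_trace`
#' @param path output TSV file
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(time_ms = full_prec(trace$time_ms),
                   v_mV = full_prec(trace$v_mV),
                   i_pA = full_prec(trace$i_pA))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Save / load a batch of traces in a binary array container
#'
#' Batch runs produce large arrays; they are stored with R's native
#' serialization together with their metadata (time step, equilibration,
#' protocol descriptions), and round-trip bit-exactly.
#'
#' @param traces list of `voltage_trace` objects
#' @param path output `.rds` file
#' @export
save_traces <- function(traces, path) {
  meta <- list(dt_us = attr(traces[[1]], "dt") * 1000,
               t_equil_ms = attr(traces[[1]], "t_equil"),
               n = length(traces))
  saveRDS(list(meta = meta, traces = traces), path)
  invisible(path)
}

#' @rdname save_traces
#' @export
load_traces <- function(path) readRDS(path)

#' Write a titration result as delimited text
#'
#' Emits two files: `<stem>_models.tsv`, one row per (model,
#' concentration) with all metrics, and `<stem>_summary.tsv`, one row
#' per concentration with population means/SDs and the mean F-I curve.
#'
#' @param titr a `titration_result`
#' @param stem output path stem
#' @return the two file paths, invisibly
#' @export
write_titration <- function(titr, stem) {
  rows <- list()
  for (lv in as.character(titr$concentrations)) {
    bundles <- titr$metrics[[lv]]
    for (i in seq_along(bundles)) {
      m <- bundles[[i]]
      rows[[length(rows) + 1L]] <- data.frame(
        model = i, pv_mM = as.numeric(lv),
        input_resistance_MOhm = m$input_resistance,
        ramp_threshold_pA = m$ramp_threshold,
        peak_firing_current_pA = m$peak_firing_current,
        peak_firing_rate_Hz = m$peak_firing_rate,
        rheobase_pA = m$rheobase, ahp_mV = m$ahp,
        phenotype = m$phenotype, stringsAsFactors = FALSE)
    }
  }
  models_path <- paste0(stem, "_models.tsv")
  utils::write.table(do.call(rbind, rows), models_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  units <- c(input_resistance = "input_resistance_MOhm",
             ramp_threshold = "ramp_threshold_pA",
             peak_firing_current = "peak_firing_current_pA",
             peak_firing_rate = "peak_firing_rate_Hz",
             rheobase = "rheobase_pA", ahp = "ahp_mV")
  srows <- lapply(as.character(titr$concentrations), function(lv) {
    s <- titr$summaries[[lv]]
    cbind(data.frame(pv_mM = as.numeric(lv), n = s$n),
          as.data.frame(as.list(c(
            stats::setNames(s$means, paste0(units[names(s$means)],
                                            "_mean")),
            stats::setNames(s$sds, paste0(units[names(s$sds)], "_sd")),
            stats::setNames(s$fi_mean,
                            paste0("fi_", names(s$fi_mean),
                                   "pA_Hz_mean"))))))
  })
  summary_path <- paste0(stem, "_summary.tsv")
  utils::write.table(do.call(rbind, srows), summary_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(models_path, summary_path))
}

#' Run manifest
#'
#' Records what produced a set of artifacts: command, configuration
#' hash, seed, package version, timestamps and output paths, so any
#' deterministic stage can be regenerated from its manifest.
#'
#' @param command the stage name
#' @param config the configuration used
#' @param seed integer seed
#' @param outputs character vector of artifact paths
#' @return manifest list
#' @export
run_manifest <- function(command, config, seed, outputs) {
  list(command = command,
       config_hash = config_hash(config),
       seed = seed,
       package_version = as.character(utils::packageVersion("vpglu")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       outputs = outputs)
}

config_hash <- function(config) {
  # stable content hash of the configuration via its serialized text
  txt <- paste(utils::capture.output(utils::str(config, digits.d = 17,
                                                vec.len = 1e6)),
               collapse = "\n")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 97 + 1)) %% .Machine$integer.max)
}

#' @rdname run_manifest
#' @param manifest a manifest list
#' @param path output JSON file
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
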