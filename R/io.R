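# Configuration and result serialisation: YAML run configs, tidy CSV time
# courses with JSON sidecars, and JSON report writers. Every output embeds
# the package version, a config hash, and the seed.

#' Assemble a run configuration
#'
#' @param architecture Architecture selector: id(s), `"all"`, or NULL.
#' @param variant_index Optional explicit variant indices.
#' @param tasks Tasks to run.
#' @param serotonin_types 5-HT neuron types to include.
#' @param dt,horizon,record_stride Integration settings (see `sim_config()`).
#' @param d2_factors Dose factors for the D2 screen.
#' @param seed Integer seed recorded in outputs (the shipped analyses are
#'   deterministic; the seed feeds the stochastic calibration search only).
#' @param output_dir Directory for result files.
#' @return Object of class `drnvta_run_config` (a named list, fully
#'   YAML-serialisable).
#' @export
run_config <- function(architecture = "all", variant_index = NULL,
                       tasks = c("punishment", "reward"),
                       serotonin_types = c("I", "II"),
                       dt = 0.5, horizon = 8000, record_stride = 4,
                       d2_factors = c(1, 10, 40, 70, 100),
                       seed = 1, output_dir = "drnvta-results") {
  structure(list(
    architecture = architecture, variant_index = variant_index,
    tasks = tasks, serotonin_types = serotonin_types,
    dt = dt, horizon = horizon, record_stride = record_stride,
    d2_factors = d2_factors, seed = seed, output_dir = output_dir
  ), class = "drnvta_run_config")
}

#' Write / read a run configuration as YAML
#'
#' Round-trip is lossless for all fields of `run_config()`.
#'
#' @param config A `drnvta_run_config`.
#' @param path File path.
#' @return `read_run_config()` returns the `drnvta_run_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, x[names(x) %in% names(formals(run_config))])
}

# Stable short hash of a configuration (no external digest dependency).
.config_hash <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  # polynomial rolling hash over the serialised text (stays in double range)
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.meta <- function(config = NULL, seed = NULL) {
  list(package = "drnvta",
       version = as.character(utils::packageVersion("drnvta")),
       config_hash = if (is.null(config)) NA_character_ else .config_hash(config),
       seed = seed)
}

#' Write a time course as tidy CSV with a JSON sidecar
#'
#' Long format: columns `time_ms`, `series` (population or state variable),
#' `value`. The sidecar `<path>.json` records the variant, task, type,
#' integration settings, package version, config hash and seed.
#'
#' @param tc A `drnvta_timecourse`.
#' @param path CSV file path.
#' @param config Optional `drnvta_run_config` for provenance.
#' @param seed Optional seed for provenance.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(tc, path, config = NULL, seed = NULL) {
  long <- rbind(
    do.call(rbind, lapply(colnames(tc$rates), function(p) {
      data.frame(time_ms = tc$time, series = p, value = tc$rates[, p])
    })),
    do.call(rbind, lapply(colnames(tc$states), function(s) {
      data.frame(time_ms = tc$time, series = s, value = tc$states[, s])
    }))
  )
  write.csv(long, path, row.names = FALSE)
  side <- c(.meta(config, seed),
            list(variant_index = tc$variant_index,
                 architecture = tc$architecture, task = tc$task,
                 serotonin_type = tc$serotonin_type,
                 dt = tc$config$dt, horizon = tc$config$horizon,
                 record_stride = tc$config$record_stride))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a tidy time-course CSV back into matrices
#'
#' @param path CSV path written by `write_timecourse()`.
#' @return A `drnvta_timecourse` (metadata restored from the sidecar when
#'   present).
#' @export
read_timecourse <- function(path) {
  long <- read.csv(path)
  wide <- function(series) {
    out <- sapply(series, function(s) long$value[long$series == s])
    rownames(out) <- NULL
    out
  }
  tm <- sort(unique(long$time_ms))
  meta <- if (file.exists(paste0(path, ".json"))) {
    jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  } else list()
  structure(list(
    time = tm,
    rates = wide(population_ids()),
    states = wide(.state_names),
    variant_index = meta$variant_index, architecture = meta$architecture,
    task = meta$task, serotonin_type = meta$serotonin_type,
    config = sim_config(dt = meta$dt %||% 0.5,
                        horizon = meta$horizon %||% max(tm),
                        record_stride = meta$record_stride %||% 1)
  ), class = "drnvta_timecourse")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an analysis report as JSON
#'
#' Serialises a data-frame report (stability battery, screen summary, D2
#' report) as a JSON object with a provenance header and a `records` array.
#'
#' @param report A data frame.
#' @param path Output path.
#' @param config,seed Optional provenance.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path, config = NULL, seed = NULL) {
  jsonlite::write_json(list(meta = .meta(config, seed),
                            records = as.data.frame(report)),
                       path, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Pivot a D2 report into a dose-by-architecture signature table
#'
#' One row per architecture and condition, one column per dose factor,
#' holding the violating-population signature (empty when the cell is
#' clean).
#'
#' @param report A `drnvta_d2_report`.
#' @return Data frame.
#' @export
d2_pivot <- function(report) {
  ok <- report[report$status == "ok", ]
  keys <- unique(ok[, c("architecture", "task", "serotonin_type")])
  factors <- sort(unique(ok$X))
  out <- keys
  for (X in factors) {
    col <- vapply(seq_len(nrow(keys)), function(i) {
      s <- ok[ok$architecture == keys$architecture[i] &
                ok$task == keys$task[i] &
                ok$serotonin_type == keys$serotonin_type[i] & ok$X == X, ]
      paste(sort(unique(unlist(strsplit(s$violating[s$violating != ""], ",")))),
            collapse = "+")
    }, "")
    out[[paste0("X", X)]] <- col
  }
  out[order(out$architecture, out$task, out$serotonin_type), ]
}
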