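# Time-domain simulation: the six slow state variables are advanced with a
# classical fixed-step 4th-order scheme while the five population rates are
# re-solved algebraically at every integration stage.

#' Simulation configuration
#'
#' @param dt Integration step (ms), default 0.5.
#' @param horizon Simulated duration (ms), default 8000 (the protocol events
#'   end by 6.7 s; the margin covers the analysis window comfortably).
#' @param record_stride Record every `record_stride`-th step (default 4,
#'   i.e. a 2 ms output grid with the default `dt`).
#' @param initial_state `"auto"` (start from the tonic fixed point of the
#'   protocol's constant inputs) or a named numeric vector of the six state
#'   variables (`auto_5ht`, `auto_da`, `mod_5ht`, `mod_da`, `c_5ht`,
#'   `c_da`).
#' @return Object of class `drnvta_sim_config`.
#' @export
sim_config <- function(dt = 0.5, horizon = 8000, record_stride = 4,
                       initial_state = "auto") {
  stopifnot(dt > 0, horizon > 0, record_stride >= 1)
  structure(list(dt = dt, horizon = horizon,
                 record_stride = as.integer(record_stride),
                 initial_state = initial_state),
            class = "drnvta_sim_config")
}

.state_names <- c("auto_5ht", "auto_da", "mod_5ht", "mod_da", "c_5ht", "c_da")

# Pack a variant into the list consumed by the compiled kernels.
.net_list <- function(variant) {
  m <- variant_matrices(variant)
  sp <- slow_current_params()
  rel <- release_params()
  list(gain = m$gain, threshold = m$threshold, bias = m$bias,
       Jf = m$Jf, Ws = m$Ws,
       slow_tau = sp$tau, slow_k = sp$k, slow_slope = sp$slope,
       slow_offset = sp$offset,
       rel_per = rel$release_per_rate, rel_vmax = rel$vmax,
       rel_km = rel$km, rel_scale = rel$rate_scale)
}

# Events matrix for the compiled kernel (0-based population index).
.event_matrix <- function(protocol) {
  e <- protocol$events
  if (is.null(e) || nrow(e) == 0) {
    return(matrix(numeric(0), ncol = 6))
  }
  cbind(match(e$target, population_ids()) - 1,
        e$sign,
        e$amplitude,
        ifelse(e$shape == "constant", 0, e$onset),
        ifelse(e$shape == "constant", 1e300, e$offset),
        e$smoothing_tau)
}

#' Integrate a model variant under a task protocol
#'
#' Produces the time courses of the six slow state variables (four
#' neuromodulator-induced currents and the two transmitter concentrations)
#' and the five instantaneous population firing rates.
#'
#' In `"auto"` initial-state mode the run starts at the tonic fixed point of
#' the protocol's constant inputs, so the pre-cue segment is an exact steady
#' state.
#'
#' @param variant A calibrated `drnvta_variant`.
#' @param protocol A `drnvta_protocol` (default: the variant's protocol for
#'   `task`).
#' @param config A `drnvta_sim_config`.
#' @param task Used when `protocol` is NULL.
#' @return Object of class `drnvta_timecourse`: list with `time` (ms),
#'   `rates` (matrix, columns = populations), `states` (matrix, columns =
#'   state variables), `variant_index`, `task`, `serotonin_type`, `config`.
#' @export
simulate_circuit <- function(variant, protocol = NULL, config = sim_config(),
                             task = "punishment") {
  if (is.null(protocol)) protocol <- protocol_for_variant(variant, task)
  net <- .net_list(variant)
  evm <- .event_matrix(protocol)
  y0 <- if (identical(config$initial_state, "auto")) {
    fp <- find_fixed_point(variant, constant_externals(protocol))
    fp$state
  } else {
    stopifnot(all(.state_names %in% names(config$initial_state)))
    config$initial_state[.state_names]
  }
  res <- cpp_integrate(net, evm, as.numeric(y0), config$dt, config$horizon,
                       config$record_stride)
  if (!identical(res$status, "ok")) {
    stop("integration failed: ", res$status)
  }
  rates <- res$rates
  colnames(rates) <- population_ids()
  states <- res$states
  colnames(states) <- .state_names
  structure(list(
    time = res$time, rates = rates, states = states,
    variant_index = variant$index, architecture = variant$architecture,
    task = protocol$task, serotonin_type = protocol$serotonin_type,
    config = config
  ), class = "drnvta_timecourse")
}

#' @export
print.drnvta_timecourse <- function(x, ...) {
  cat(sprintf("<drnvta_timecourse> variant #%s (%s), %s task, Type %s; %d samples over %.0f ms\n",
              x$variant_index, x$architecture, x$task, x$serotonin_type,
              length(x$time), max(x$time)))
  invisible(x)
}

#' Mean firing rates over a time window
#'
#' Arithmetic mean of each population's rate over `window` (default: the
#' second preceding cue onset, the baseline used throughout the screening
#' analyses).
#'
#' @param tc A `drnvta_timecourse`.
#' @param window Numeric length-2 vector `c(from, to)` in ms.
#' @return Named numeric vector of mean rates (Hz).
#' @export
baseline_statistics <- function(tc, window = c(3500, 4500)) {
  sel <- tc$time >= window[1] & tc$time <= window[2]
  if (!any(sel)) stop("window does not intersect the recorded time grid")
  colMeans(tc$rates[sel, , drop = FALSE])
}
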