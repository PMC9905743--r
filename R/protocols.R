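# Task protocols: timed external-input programs for the four conditions
# (reward/punishment crossed with Type I / Type II 5-HT neurons).
#
# Cue onset is at 4.5 s and outcome onset at 5.7 s. All inputs are
# excitatory except architecture-specific compensatory inputs to the DRN
# GABA population, which carry an explicit inhibitory sign. Transient
# (step/pulse) inputs are smoothed with 50 ms exponential edges; constants
# are on from t = 0 so the network settles to its tonic state before cue.

.CUE_MS <- 4500
.OUTCOME_MS <- 5700
.PULSE_MS <- 200
.SMOOTH_MS <- 50

.event <- function(target, shape, amplitude, onset = 0, offset = Inf,
                   sign = +1, smoothing_tau = .SMOOTH_MS) {
  stopifnot(amplitude >= 0, sign %in% c(-1, 1))
  data.frame(target = target, shape = shape, amplitude = amplitude,
             onset = onset, offset = offset, sign = sign,
             smoothing_tau = if (shape == "constant") 0 else smoothing_tau)
}

#' Build the external-input protocol for one task condition
#'
#' Event program per condition:
#' * reward, Type I: constant 50 a.u. to 5-HT and DA (long-term reward
#'   signal); 200 ms pulse of 1000 a.u. to DRN Glu at cue (4.5 s); step of
#'   200 a.u. to VTA GABA from cue to outcome (4.5-5.7 s); nothing to DRN
#'   GABA.
#' * punishment, Type I: 200 ms pulses of 1000 a.u. to VTA GABA and DRN GABA
#'   at outcome (5.7 s); nothing else.
#' * reward, Type II: constants 50 a.u. to 5-HT and DA; additional step of
#'   100 a.u. to 5-HT from cue to outcome (sustained reward expectation);
#'   200 ms pulse of 1000 a.u. to DRN Glu at cue; nothing to either GABA
#'   pool.
#' * punishment, Type II: 200 ms pulses of 1000 a.u. to DRN GABA and 5-HT at
#'   outcome.
#'
#' Architecture flags add inhibitory inputs to DRN GABA: `extra_inhibition`
#' (architectures A and L) is a constant inhibitory current during reward
#' trials; `gd_compensation` (architectures lacking the 5-HT to DRN GABA
#' edge) adds a calibrated constant inhibition in both tasks, a reward
#' component, and - for Type II reward - a slow-ramp cue-interval component
#' mimicking the template's serotonin-driven GABA suppression.
#'
#' @param task `"reward"` or `"punishment"`.
#' @param serotonin_type `"I"` or `"II"`.
#' @param extra_inhibition Constant inhibitory amplitude (a.u.) to DRN GABA
#'   during reward trials (0 for none).
#' @param gd_compensation Optional named vector `constant`, `reward`,
#'   `cue_type2` of compensatory inhibitory amplitudes (a.u.).
#' @param smoothing Logical; apply the 50 ms exponential edge smoothing to
#'   transient events (default TRUE).
#' @return Object of class `drnvta_protocol`.
#' @export
build_protocol <- function(task = c("reward", "punishment"),
                           serotonin_type = c("I", "II"),
                           extra_inhibition = 0,
                           gd_compensation = NULL,
                           smoothing = TRUE) {
  task <- match.arg(task)
  serotonin_type <- match.arg(serotonin_type)
  cue <- .CUE_MS; out <- .OUTCOME_MS
  ev <- list()
  add <- function(...) ev[[length(ev) + 1]] <<- .event(...)
  if (task == "reward") {
    add("HT5_DRN", "constant", 50)
    add("DA_VTA", "constant", 50)
    add("GLU_DRN", "pulse", 1000, cue, cue + .PULSE_MS)
    if (serotonin_type == "I") {
      add("GABA_VTA", "step", 200, cue, out)
    } else {
      add("HT5_DRN", "step", 100, cue, out)
    }
    if (extra_inhibition > 0) {
      add("GABA_DRN", "constant", extra_inhibition, sign = -1)
    }
  } else {
    if (serotonin_type == "I") {
      add("GABA_VTA", "pulse", 1000, out, out + .PULSE_MS)
      add("GABA_DRN", "pulse", 1000, out, out + .PULSE_MS)
    } else {
      add("GABA_DRN", "pulse", 1000, out, out + .PULSE_MS)
      add("HT5_DRN", "pulse", 1000, out, out + .PULSE_MS)
    }
  }
  if (!is.null(gd_compensation)) {
    if (gd_compensation[["constant"]] > 0) {
      add("GABA_DRN", "constant", gd_compensation[["constant"]], sign = -1)
    }
    if (task == "reward" && gd_compensation[["reward"]] > 0) {
      add("GABA_DRN", "constant", gd_compensation[["reward"]], sign = -1)
    }
    if (task == "reward" && serotonin_type == "II" &&
        gd_compensation[["cue_type2"]] > 0) {
      add("GABA_DRN", "step", gd_compensation[["cue_type2"]], cue, out,
          sign = -1, smoothing_tau = 1200)
    }
  }
  events <- do.call(rbind, ev)
  if (!smoothing) events$smoothing_tau <- 0
  structure(list(
    task = task, serotonin_type = serotonin_type,
    cue_time = cue, outcome_time = out, events = events
  ), class = "drnvta_protocol")
}

#' Protocol for a calibrated variant
#'
#' Convenience wrapper around `build_protocol()` that passes the variant's
#' calibrated architecture-specific input amplitudes.
#'
#' @param variant A calibrated `drnvta_variant`.
#' @param task `"reward"` or `"punishment"`.
#' @param smoothing Logical, see `build_protocol()`.
#' @return A `drnvta_protocol`.
#' @export
protocol_for_variant <- function(variant, task, smoothing = TRUE) {
  build_protocol(task, variant$serotonin_type,
                 extra_inhibition = variant$extra_reward_inhibition,
                 gd_compensation = variant$gd_compensation,
                 smoothing = smoothing)
}

# Time course of one event (scalar t, vectorised over events elsewhere).
.event_value <- function(amplitude, onset, offset, smoothing_tau, t) {
  if (t < onset) return(0)
  if (smoothing_tau <= 0) {
    return(if (t <= offset) amplitude else 0)
  }
  if (t <= offset) {
    amplitude * (1 - exp(-(t - onset) / smoothing_tau))
  } else {
    peak <- amplitude * (1 - exp(-(offset - onset) / smoothing_tau))
    peak * exp(-(t - offset) / smoothing_tau)
  }
}

#' External input to one population at a given time
#'
#' Sum of all active protocol events targeting the population, with
#' transient events' onsets and offsets smoothed by their exponential
#' factors. Inhibitory events contribute negatively.
#'
#' @param protocol A `drnvta_protocol`.
#' @param pop Population id.
#' @param t Time (ms); vectorised.
#' @return External current (a.u.) at each `t`.
#' @export
external_input <- function(protocol, pop, t) {
  e <- protocol$events
  if (is.null(e)) return(rep(0, length(t)))
  e <- e[e$target == pop, , drop = FALSE]
  vapply(t, function(tt) {
    tot <- 0
    for (i in seq_len(nrow(e))) {
      on <- if (e$shape[i] == "constant") 0 else e$onset[i]
      off <- if (e$shape[i] == "constant") Inf else e$offset[i]
      tot <- tot + e$sign[i] *
        .event_value(e$amplitude[i], on, off, e$smoothing_tau[i], tt)
    }
    tot
  }, 0)
}

# Externals for all populations at time t (named vector), used by the
# fixed-point code.
.externals_at <- function(protocol, t) {
  setNames(vapply(population_ids(), function(p) {
    external_input(protocol, p, t)
  }, 0), population_ids())
}

#' Constant-input portion of a protocol
#'
#' The external inputs present from t = 0 (the tonic condition): constants
#' only, transient events excluded. Used to define the tonic fixed point and
#' the automatic initial state of simulations.
#'
#' @param protocol A `drnvta_protocol`.
#' @return Named numeric vector of constant external inputs per population.
#' @export
constant_externals <- function(protocol) {
  e <- protocol$events
  ext <- setNames(numeric(5), population_ids())
  if (is.null(e)) return(ext)
  e <- e[e$shape == "constant", , drop = FALSE]
  for (i in seq_len(nrow(e))) {
    ext[e$target[i]] <- ext[e$target[i]] + e$sign[i] * e$amplitude[i]
  }
  ext
}

#' Peak (phasic) external inputs of a protocol
#'
#' External inputs with every event, transient or constant, held at its full
#' amplitude simultaneously - the quasi-static freeze used for the phasic
#' stability condition.
#'
#' @param protocol A `drnvta_protocol`.
#' @return Named numeric vector of external inputs per population.
#' @export
phasic_externals <- function(protocol) {
  e <- protocol$events
  ext <- setNames(numeric(5), population_ids())
  for (i in seq_len(nrow(e))) {
    ext[e$target[i]] <- ext[e$target[i]] + e$sign[i] * e$amplitude[i]
  }
  ext
}
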