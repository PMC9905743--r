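# Model constants and elementary rate-equation pieces.
#
# Conventions used throughout the package: time in ms, concentrations in uM
# (model units), firing rates in Hz, currents in arbitrary units (a.u.).
# Population order is fixed everywhere:
#   HT5_DRN, DA_VTA, GLU_DRN, GABA_DRN, GABA_VTA.

#' Population identifiers
#'
#' The five neural populations of the DRN-VTA circuit model, in the canonical
#' order used by every matrix and vector in the package: DRN serotonin
#' neurons, VTA dopamine neurons, DRN glutamate neurons, DRN GABA neurons,
#' VTA GABA neurons.
#'
#' @return Character vector of length five.
#' @export
population_ids <- function() {
  c("HT5_DRN", "DA_VTA", "GLU_DRN", "GABA_DRN", "GABA_VTA")
}

#' Population input-output parameters
#'
#' Threshold-linear transfer parameters `F = gain * [I - threshold]_+` and the
#' constant bias current of each population. Gains for the DA and 5-HT
#' populations (0.019 and 0.033 Hz per a.u.) and all five bias currents
#' (99.87, 210, 100, 450, 200 a.u.) are literature-constrained constants; the
#' gains of the glutamate and GABA pools are calibrated once so that the
#' template circuit reproduces the reference baseline firing rates (see
#' `baseline_targets()` and the methods vignette).
#'
#' @return Data frame with columns `pop`, `gain`, `threshold`, `bias`.
#' @export
population_params <- function() {
  cal <- .template_gains()
  data.frame(
    pop = population_ids(),
    gain = c(0.033, 0.019, cal["GLU_DRN"], cal["GABA_DRN"], cal["GABA_VTA"]),
    threshold = c(0.13, -10, 0, 0, 0),
    bias = c(99.87, 210, 100, 450, 200),
    row.names = population_ids()
  )
}

#' Slow neuromodulator-induced current parameters
#'
#' Parameters of the four first-order sigmoidal current equations
#' `tau * dI/dt = -I + k / (1 + exp(-slope * (c - offset)))`:
#' the 5-HT1A and D2 autoreceptor self-inhibition currents and the two
#' cross-modulation currents (5-HT concentration acting on DA and other
#' targets; DA concentration acting on 5-HT and other targets). Both
#' cross-modulation sigmoids are centred at 0.1 uM (see the methods
#' vignette for the choice of the DA-driven offset).
#'
#' @return Data frame with columns `state`, `driver` (which transmitter
#'   concentration drives the sigmoid), `tau` (ms), `k` (a.u.),
#'   `slope` (per uM), `offset` (uM).
#' @export
slow_current_params <- function() {
  data.frame(
    state = c("auto_5ht", "auto_da", "mod_5ht", "mod_da"),
    driver = c("HT5", "DA", "HT5", "DA"),
    tau = c(500, 150, 1200, 1000),
    k = c(80, 80, 0.03, 0.03),
    slope = c(10, 10, 20, 20),
    offset = c(0.1, 0.1, 0.1, 0.1),
    row.names = c("auto_5ht", "auto_da", "mod_5ht", "mod_da")
  )
}

#' Release-and-reuptake parameters
#'
#' Michaelis-Menten release/uptake constants for serotonin and dopamine:
#' `dc/dt = release_per_rate * F / rate_scale - vmax * c / (km + c)`.
#'
#' @return Data frame with columns `transmitter`, `release_per_rate`,
#'   `vmax` (uM per ms), `km` (uM), `rate_scale`.
#' @export
release_params <- function() {
  data.frame(
    transmitter = c("HT5", "DA"),
    release_per_rate = c(0.08, 0.1),
    vmax = c(0.0013, 0.004),
    km = c(0.17, 0.15),
    rate_scale = c(1000, 1000),
    row.names = c("HT5", "DA")
  )
}

#' Threshold-linear population transfer function
#'
#' `F = gain * (I - threshold)` when the total current `I` exceeds the
#' threshold, and 0 otherwise (rates never go negative; a current exactly at
#' threshold yields rate 0).
#'
#' @param gain Gain (Hz per a.u.), positive.
#' @param threshold Threshold current (a.u.).
#' @param current Total afferent current (a.u.); vectorised.
#' @return Firing rate(s) in Hz.
#' @export
rate_from_input <- function(gain, threshold, current) {
  stopifnot(gain > 0)
  pmax(gain * (current - threshold), 0)
}

#' Sigmoid steady-state value of a slow current
#'
#' @param params One row of `slow_current_params()`.
#' @param concentration Driving transmitter concentration (uM); vectorised.
#' @return Steady-state current `k / (1 + exp(-slope * (c - offset)))`.
#' @export
slow_current_steady <- function(params, concentration) {
  params$k / (1 + exp(-params$slope * (concentration - params$offset)))
}

#' Right-hand side of a slow neuromodulator current equation
#'
#' @param params One row of `slow_current_params()`.
#' @param current Present current value (a.u.).
#' @param concentration Driving transmitter concentration (uM), nonnegative.
#' @return Time derivative of the current (a.u. per ms).
#' @export
slow_current_rhs <- function(params, current, concentration) {
  (-current + slow_current_steady(params, concentration)) / params$tau
}

#' Right-hand side of a release-and-reuptake equation
#'
#' @param params One row of `release_params()`.
#' @param rate Presynaptic population firing rate (Hz), nonnegative.
#' @param concentration Transmitter concentration (uM), nonnegative.
#' @return Time derivative of the concentration (uM per ms).
#' @export
concentration_rhs <- function(params, rate, concentration) {
  params$release_per_rate * rate / params$rate_scale -
    params$vmax * concentration / (params$km + concentration)
}

#' Steady-state rate-concentration prefactor
#'
#' Setting the release-and-reuptake equation to zero gives the closed-form
#' steady-state relation `F = prefactor * c / (km + c)` with
#' `prefactor = vmax * rate_scale / release_per_rate` (16.25 Hz for 5-HT,
#' 40 Hz for DA with the default constants).
#'
#' @param params One row of `release_params()`.
#' @return The multiplicative prefactor (Hz).
#' @export
steady_rate_prefactor <- function(params) {
  params$vmax * params$rate_scale / params$release_per_rate
}

#' Steady-state firing rate at a given concentration
#'
#' @param params One row of `release_params()`.
#' @param concentration Concentration (uM); vectorised.
#' @return Rate (Hz) on the steady-state release-uptake balance curve.
#' @export
steady_state_rate <- function(params, concentration) {
  steady_rate_prefactor(params) * concentration / (params$km + concentration)
}

#' Steady-state concentration at a given firing rate
#'
#' Inverse of `steady_state_rate()`; only defined for rates strictly below the
#' prefactor (the maximal clearance-limited rate).
#'
#' @param params One row of `release_params()`.
#' @param rate Rate (Hz), `0 <= rate < steady_rate_prefactor(params)`.
#' @return Concentration (uM).
#' @export
steady_state_concentration <- function(params, rate) {
  pre <- steady_rate_prefactor(params)
  stopifnot(all(rate >= 0), all(rate < pre))
  params$km * rate / (pre - rate)
}
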