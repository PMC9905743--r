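# Instantaneous firing rates.
#
# Fast ionotropic synapses are quasi-steady, so at any moment the five
# population rates satisfy the coupled threshold-linear equations
#   F_p = g_p * [ bias_p + ext_p + (Wslow %*% s)_p + (Jfast %*% F)_p - I0_p ]_+
# where s holds the four slow-current state variables. The rectification is
# resolved by an active-set search over supra-threshold populations.

# Matrix form of a variant: signed fast coupling matrix (target x source) and
# signed slow-current loading matrix (target x slow state).
variant_matrices <- function(variant) {
  pops <- population_ids()
  states <- c("auto_5ht", "auto_da", "mod_5ht", "mod_da")
  Jf <- matrix(0, 5, 5, dimnames = list(pops, pops))
  Ws <- matrix(0, 5, 4, dimnames = list(pops, states))
  e <- variant$edges
  for (i in seq_len(nrow(e))) {
    w <- e$sign[i] * e$weight[i]
    if (e$mechanism[i] == "fast") {
      Jf[e$target[i], e$source[i]] <- Jf[e$target[i], e$source[i]] + w
    } else {
      st <- .slow_state_of(e$source[i], e$target[i])
      Ws[e$target[i], st] <- Ws[e$target[i], st] + w
    }
  }
  pp <- population_params()
  list(Jf = Jf, Ws = Ws, gain = pp$gain, threshold = pp$threshold,
       bias = pp$bias)
}

#' Total afferent current into one population
#'
#' Sums the population's bias current, external input, slow
#' neuromodulator-induced currents weighted by the variant's signed loadings,
#' and fast synaptic currents proportional to the presynaptic rates.
#'
#' @param variant A calibrated `drnvta_variant`.
#' @param pop Population id.
#' @param state Named numeric vector with the four slow currents
#'   (`auto_5ht`, `auto_da`, `mod_5ht`, `mod_da`); extra elements (the
#'   concentrations) are ignored.
#' @param rates Named numeric vector of the five population rates (Hz).
#' @param external External input current (a.u.).
#' @return Total current (a.u.).
#' @export
afferent_current <- function(variant, pop, state, rates, external = 0) {
  m <- variant_matrices(variant)
  i <- match(pop, population_ids())
  if (is.na(i)) stop("unknown population: ", pop)
  s <- state[c("auto_5ht", "auto_da", "mod_5ht", "mod_da")]
  m$bias[i] + external + sum(m$Ws[i, ] * s) +
    sum(m$Jf[i, ] * rates[population_ids()])
}

#' Solve the instantaneous population rates
#'
#' Finds the unique self-consistent rate vector of the quasi-steady
#' threshold-linear system for a given slow-current state and external
#' inputs, by active-set search: solve the linear system restricted to an
#' assumed set of supra-threshold populations, verify the rectification
#' conditions, and swap violating populations (falling back to exhaustive
#' enumeration of all 2^5 active sets).
#'
#' @param variant A calibrated `drnvta_variant`.
#' @param state Named numeric vector with the four slow currents.
#' @param externals Named numeric vector of external inputs per population
#'   (missing entries are 0).
#' @return Named numeric vector of the five rates (Hz), all nonnegative.
#' @export
solve_rates <- function(variant, state, externals = NULL) {
  .rates_net(variant_matrices(variant), state, externals)
}

# Fast path used by the fixed-point and Jacobian code: `net` is a
# precomputed variant_matrices() list.
.rates_net <- function(net, state, externals = NULL) {
  ext <- setNames(numeric(5), population_ids())
  if (!is.null(externals)) ext[names(externals)] <- externals
  s <- state[c("auto_5ht", "auto_da", "mod_5ht", "mod_da")]
  base <- net$bias + ext + as.numeric(net$Ws %*% s)
  .active_set_solve(net$gain, net$threshold, net$Jf, base)
}

# Core active-set solver shared by solve_rates and the fixed-point code.
.active_set_solve <- function(gain, threshold, Jf, base, tol = 1e-9) {
  n <- length(gain)
  try_set <- function(active) {
    f <- numeric(n)
    if (any(active)) {
      G <- diag(gain[active], sum(active))
      A <- diag(sum(active)) - G %*% Jf[active, active, drop = FALSE]
      rhs <- gain[active] * (base[active] - threshold[active])
      sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
      if (is.null(sol)) return(NULL)
      f[active] <- sol
    }
    cur <- base + as.numeric(Jf %*% f)
    ok_active <- all(f[active] >= -tol)
    ok_inactive <- all(cur[!active] <= threshold[!active] + tol)
    list(f = pmax(f, 0), cur = cur, ok = ok_active && ok_inactive)
  }
  active <- rep(TRUE, n)
  for (iter in 1:20) {
    r <- try_set(active)
    if (is.null(r)) break
    if (r$ok) {
      return(setNames(r$f, population_ids()))
    }
    new_active <- active
    new_active[active][r$f[active] < -tol] <- FALSE
    new_active[!active & r$cur > threshold + tol] <- TRUE
    # guard against cycling
    if (identical(new_active, active)) break
    active <- new_active
  }
  # deterministic lexicographic fallback over all subsets
  for (code in 0:(2^n - 1)) {
    active <- as.logical(bitwAnd(code, 2^(0:(n - 1))))
    r <- try_set(active)
    if (!is.null(r) && r$ok) {
      return(setNames(r$f, population_ids()))
    }
  }
  stop("no consistent active set exists for the instantaneous rate system")
}
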