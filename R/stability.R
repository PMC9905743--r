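# Fixed points and linear stability.
#
# At a steady state the four slow currents equal their sigmoid values and
# the two release-reuptake equations pin the rates to the clearance curves
# F = prefactor * c / (km + c), so fixed-point finding reduces to a
# two-dimensional root problem in the transmitter concentrations. Stability
# is judged from the eigenvalues of the 6x6 Jacobian of the full system,
# with the rates re-solved (and the active set re-derived) at every
# perturbed state.

# Slow-current steady values at concentrations (c5, cda).
.slow_steady_at <- function(c5, cda) {
  sp <- slow_current_params()
  setNames(c(
    slow_current_steady(sp["auto_5ht", ], c5),
    slow_current_steady(sp["auto_da", ], cda),
    slow_current_steady(sp["mod_5ht", ], c5),
    slow_current_steady(sp["mod_da", ], cda)
  ), c("auto_5ht", "auto_da", "mod_5ht", "mod_da"))
}

#' Time derivatives of the six state variables
#'
#' The full right-hand side of the model: the instantaneous rates are solved
#' from the current state, then the four slow-current equations and the two
#' release-and-reuptake equations are evaluated.
#'
#' @param variant A calibrated `drnvta_variant`.
#' @param state Named numeric vector of the six state variables.
#' @param externals Named numeric vector of external inputs per population.
#' @return Named numeric vector of the six derivatives (per ms).
#' @export
state_derivatives <- function(variant, state, externals = NULL) {
  .derivs_net(variant_matrices(variant), state, externals)
}

.derivs_net <- function(net, state, externals = NULL) {
  sp <- slow_current_params()
  rel <- release_params()
  c5 <- max(state[["c_5ht"]], 0)
  cda <- max(state[["c_da"]], 0)
  rates <- .rates_net(net, state, externals)
  drivers <- c(c5, cda, c5, cda)
  dslow <- vapply(1:4, function(i) {
    slow_current_rhs(sp[i, ], state[[.state_names[i]]], drivers[i])
  }, 0)
  dc5 <- concentration_rhs(rel["HT5", ], rates[["HT5_DRN"]], c5)
  dcda <- concentration_rhs(rel["DA", ], rates[["DA_VTA"]], cda)
  setNames(c(dslow, dc5, dcda), .state_names)
}

# Residuals of the reduced 2-D problem at concentrations (c5, cda): the slow
# currents are set to their sigmoid values, the rates are solved, and the
# two release-reuptake balances are returned. Uses the compiled rate solver
# (`use_cpp = TRUE`) in the inner loop; the R solver verifies the final
# residual.
.conc_residual_net <- function(net, c5, cda, externals, use_cpp = FALSE) {
  s <- .slow_steady_at(c5, cda)
  rates <- if (use_cpp) {
    ext <- setNames(numeric(5), population_ids())
    if (!is.null(externals)) ext[names(externals)] <- externals
    r <- cpp_solve_rates(net, as.numeric(s), as.numeric(ext))
    if (!isTRUE(r$ok)) return(c(NA_real_, NA_real_))
    setNames(r$rates, population_ids())
  } else {
    .rates_net(net, s, externals)
  }
  rel <- release_params()
  c(concentration_rhs(rel["HT5", ], rates[["HT5_DRN"]], c5),
    concentration_rhs(rel["DA", ], rates[["DA_VTA"]], cda))
}

#' Find a fixed point under constant inputs
#'
#' Solves the steady state of the six-variable system for time-invariant
#' external inputs by damped Newton iteration on the two transmitter
#' concentrations (slow currents substituted by their sigmoid steady values,
#' rates pinned to the release-reuptake balance curves), started from a
#' deterministic log-spaced grid. The residual of the full six-dimensional
#' system is verified at the returned point. All distinct roots found are
#' reported; the principal one minimises the residual norm.
#'
#' @param variant A calibrated `drnvta_variant`.
#' @param externals Named numeric vector of constant external inputs.
#' @param tol Residual tolerance on the full system (default 1e-10).
#' @return Object of class `drnvta_fixed_point`: list with `state` (six
#'   variables), `rates`, `residual_norm`, `roots` (matrix of all distinct
#'   concentration roots).
#' @export
find_fixed_point <- function(variant, externals = NULL, tol = 1e-10) {
  net <- .net_list(variant)
  grid <- 10^seq(-4, 0.5, length.out = 10)
  ext <- setNames(numeric(5), population_ids())
  if (!is.null(externals)) ext[names(externals)] <- externals
  ext <- as.numeric(ext)
  # numeric copies of the constant parameters for the inner loop
  sk <- net$slow_k; ssl <- net$slow_slope; sof <- net$slow_offset
  per <- net$rel_per; vmx <- net$rel_vmax; km <- net$rel_km; scl <- net$rel_scale
  resid <- function(x) {
    cc <- c(x[1], x[2], x[1], x[2])
    s <- sk / (1 + exp(-ssl * (cc - sof)))
    r <- cpp_solve_rates(net, s, ext)
    if (!isTRUE(r$ok)) return(c(NA_real_, NA_real_))
    c(per[1] * r$rates[1] / scl[1] - vmx[1] * x[1] / (km[1] + x[1]),
      per[2] * r$rates[2] / scl[2] - vmx[2] * x[2] / (km[2] + x[2]))
  }
  newton <- function(x0) {
    x <- x0
    for (iter in 1:40) {
      r <- resid(x)
      if (!all(is.finite(r))) return(NULL)
      if (sqrt(sum(r^2)) < 1e-14) break
      h <- pmax(1e-7 * pmax(abs(x), 1e-3), 1e-9)
      J <- matrix(0, 2, 2)
      for (j in 1:2) {
        xp <- x; xp[j] <- x[j] + h[j]
        xm <- x; xm[j] <- max(x[j] - h[j], 0)
        J[, j] <- (resid(xp) - resid(xm)) / (xp[j] - xm[j])
      }
      step <- tryCatch(solve(J, r), error = function(e) NULL)
      if (is.null(step)) return(NULL)
      lambda <- 1
      repeat {
        xn <- pmax(x - lambda * step, 0)
        rn <- resid(xn)
        if (all(is.finite(rn)) &&
            (sqrt(sum(rn^2)) < sqrt(sum(r^2)) || lambda < 1e-4)) break
        lambda <- lambda / 2
      }
      if (sqrt(sum((xn - x)^2)) < 1e-14) { x <- xn; break }
      x <- xn
    }
    x
  }
  roots <- NULL
  for (a in grid) for (b in grid) {
    x <- newton(c(a, b))
    if (is.null(x)) next
    r <- resid(x)
    if (sqrt(sum(r^2)) < 1e-12) {
      if (is.null(roots) ||
          !any(sqrt(rowSums(sweep(roots, 2, x)^2)) < 1e-6)) {
        roots <- rbind(roots, x)
      }
    }
  }
  if (is.null(roots)) {
    stop("no fixed point found in the search box (the release rate may ",
         "exceed the maximal clearance rate under these inputs)")
  }
  best <- NULL; best_norm <- Inf
  for (i in seq_len(nrow(roots))) {
    s <- .slow_steady_at(roots[i, 1], roots[i, 2])
    state <- setNames(c(s, roots[i, 1], roots[i, 2]), .state_names)
    res <- .derivs_net(net, state, externals)
    nrm <- sqrt(sum(res^2))
    if (nrm < best_norm) {
      best_norm <- nrm
      best <- list(state = state,
                   rates = .rates_net(net, state, externals))
    }
  }
  if (best_norm > tol) {
    stop(sprintf("fixed-point residual %.3g exceeds tolerance %.3g",
                 best_norm, tol))
  }
  structure(list(state = best$state, rates = best$rates,
                 residual_norm = best_norm, roots = unname(roots),
                 externals = externals),
            class = "drnvta_fixed_point")
}

#' Jacobian of the six-variable system at a state
#'
#' Central finite differences of `state_derivatives()`, with the
#' instantaneous rates (and their active set) re-solved at every perturbed
#' state. The diagonal of the four current rows is exactly -1/500, -1/150,
#' -1/1200, -1/1000 (the slow-current time constants).
#'
#' @param variant A calibrated `drnvta_variant`.
#' @param fp A `drnvta_fixed_point`, or a named state vector.
#' @param externals External inputs (taken from `fp` if absent).
#' @param h Relative finite-difference step (default 1e-6).
#' @return 6x6 numeric matrix.
#' @export
jacobian_at <- function(variant, fp, externals = NULL, h = 1e-6) {
  state <- if (inherits(fp, "drnvta_fixed_point")) fp$state else fp[.state_names]
  if (is.null(externals) && inherits(fp, "drnvta_fixed_point")) {
    externals <- fp$externals
  }
  net <- variant_matrices(variant)
  J <- matrix(0, 6, 6, dimnames = list(.state_names, .state_names))
  for (j in 1:6) {
    hj <- max(h * abs(state[[j]]), h * 1e-2)
    sp <- state; sp[j] <- sp[j] + hj
    sm <- state; sm[j] <- sm[j] - hj
    # concentrations live on c >= 0: difference into the admissible region
    # when the state sits on the boundary
    if (j >= 5 && sm[j] < 0) sm[j] <- state[[j]]
    J[, j] <- (.derivs_net(net, sp, externals) -
                 .derivs_net(net, sm, externals)) / (sp[[j]] - sm[[j]])
  }
  J
}

#' Analytic Jacobian at a state
#'
#' Closed-form Jacobian assembled from the sigmoid and Michaelis-Menten
#' derivatives and the implicit derivative of the active-set rate solution
#' with respect to the slow states; serves as an independent cross-check of
#' the finite-difference Jacobian.
#'
#' @inheritParams jacobian_at
#' @return 6x6 numeric matrix.
#' @export
jacobian_analytic <- function(variant, fp, externals = NULL) {
  state <- if (inherits(fp, "drnvta_fixed_point")) fp$state else fp[.state_names]
  if (is.null(externals) && inherits(fp, "drnvta_fixed_point")) {
    externals <- fp$externals
  }
  m <- variant_matrices(variant)
  sp <- slow_current_params()
  rel <- release_params()
  rates <- solve_rates(variant, state, externals)
  active <- rates > 0
  # dF/ds (5 x 4): on the active set, F_A = (I - G J)^-1 G (base_A - thr_A)
  dF <- matrix(0, 5, 4)
  if (any(active)) {
    G <- diag(m$gain[active], sum(active))
    A <- diag(sum(active)) - G %*% m$Jf[active, active, drop = FALSE]
    dF[active, ] <- solve(A, G %*% m$Ws[active, , drop = FALSE])
  }
  J <- matrix(0, 6, 6, dimnames = list(.state_names, .state_names))
  c5 <- state[["c_5ht"]]; cda <- state[["c_da"]]
  dsig <- function(p, cc) {
    e <- exp(-p$slope * (cc - p$offset))
    p$k * p$slope * e / (1 + e)^2
  }
  for (i in 1:4) {
    J[i, i] <- -1 / sp$tau[i]
    cc <- if (i %in% c(2, 4)) cda else c5
    J[i, if (i %in% c(2, 4)) "c_da" else "c_5ht"] <- dsig(sp[i, ], cc) / sp$tau[i]
  }
  duptake <- function(p, cc) p$vmax * p$km / (p$km + cc)^2
  J["c_5ht", 1:4] <- rel["HT5", "release_per_rate"] / rel["HT5", "rate_scale"] * dF[1, ]
  J["c_5ht", "c_5ht"] <- -duptake(rel["HT5", ], c5)
  J["c_da", 1:4] <- rel["DA", "release_per_rate"] / rel["DA", "rate_scale"] * dF[2, ]
  J["c_da", "c_da"] <- -duptake(rel["DA", ], cda)
  J
}

#' Stability verdict for one variant and condition
#'
#' Locates the fixed point of the tonic condition (the protocol's constant
#' inputs) or the phasic condition (every protocol event frozen at its full
#' amplitude), computes the Jacobian eigenvalues there, and issues the
#' verdict: dynamically stable iff every eigenvalue has negative real part.
#' The `max_magnitude_real_part` field records the real part of the
#' largest-magnitude eigenvalue (the "maximal eigenvalue").
#'
#' @param variant A calibrated `drnvta_variant`.
#' @param condition `"tonic"` or `"phasic"`.
#' @param task `"punishment"` or `"reward"`.
#' @return Object of class `drnvta_stability`: list with `variant_index`,
#'   `architecture`, `condition`, `task`, `eigenvalues` (complex, 6),
#'   `max_magnitude_real_part`, `verdict`, `fixed_point`.
#' @export
stability_verdict <- function(variant, condition = c("tonic", "phasic"),
                              task = "punishment") {
  condition <- match.arg(condition)
  protocol <- protocol_for_variant(variant, task)
  ext <- if (condition == "tonic") {
    constant_externals(protocol)
  } else {
    phasic_externals(protocol)
  }
  fp <- find_fixed_point(variant, ext)
  ev <- eigen(jacobian_at(variant, fp), only.values = TRUE)$values
  mx <- ev[which.max(Mod(ev))]
  structure(list(
    variant_index = variant$index, architecture = variant$architecture,
    serotonin_type = variant$serotonin_type,
    condition = condition, task = task,
    eigenvalues = ev,
    max_magnitude_real_part = Re(mx),
    verdict = if (all(Re(ev) < 0)) "stable" else "unstable",
    fixed_point = fp
  ), class = "drnvta_stability")
}

#' Stability battery over a set of variants
#'
#' Runs `stability_verdict()` for each variant under the tonic and phasic
#' conditions of the given task and collects one row per variant and
#' condition. Conditions whose frozen-input system has no fixed point (the
#' release rate exceeds the maximal clearance rate, as happens when a strong
#' phasic drive is held constant) are recorded with `verdict =
#' "no_fixed_point"`.
#'
#' @param variants List of calibrated variants (default: all 84).
#' @param task Task protocol supplying the inputs (default punishment).
#' @param conditions Character vector of conditions to analyse.
#' @return Data frame with one row per variant x condition.
#' @export
stability_battery <- function(variants = enumerate_variants(),
                              task = "punishment",
                              conditions = c("tonic", "phasic")) {
  rows <- list()
  for (v in variants) for (cond in conditions) {
    rep <- tryCatch(stability_verdict(v, cond, task), error = function(e) e)
    rows[[length(rows) + 1]] <- if (inherits(rep, "error")) {
      data.frame(variant_index = v$index, architecture = v$architecture,
                 serotonin_type = v$serotonin_type, condition = cond,
                 task = task, max_magnitude_real_part = NA_real_,
                 max_real_part = NA_real_, max_imag_abs = NA_real_,
                 verdict = "no_fixed_point")
    } else {
      data.frame(variant_index = rep$variant_index,
                 architecture = rep$architecture,
                 serotonin_type = rep$serotonin_type,
                 condition = cond, task = task,
                 max_magnitude_real_part = rep$max_magnitude_real_part,
                 max_real_part = max(Re(rep$eigenvalues)),
                 max_imag_abs = max(abs(Im(rep$eigenvalues))),
                 verdict = rep$verdict)
    }
  }
  do.call(rbind, rows)
}
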