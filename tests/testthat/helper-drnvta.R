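# Shared test helpers: coarse simulation settings, cached template runs and
# variant lists, and independent oracles for the rate solver.

fast_cfg <- function(dt = 1, stride = 8) sim_config(dt = dt, record_stride = stride)

# Cached expensive objects (built once per test run).
.cache <- new.env()

all_variants <- function() {
  if (is.null(.cache$variants)) .cache$variants <- enumerate_variants()
  .cache$variants
}

cached_templates <- function(cfg = fast_cfg()) {
  key <- paste0("tpl_", cfg$dt, "_", cfg$record_stride)
  if (is.null(.cache[[key]])) {
    .cache[[key]] <- lapply(setNames(c("I", "II"), c("I", "II")), function(ty) {
      list(punishment = template_timecourse("punishment", ty, cfg),
           reward = template_timecourse("reward", ty, cfg))
    })
  }
  .cache[[key]]
}

# Random small-weight variant generator for solver property tests: random
# signed fast couplings and slow loadings on the template skeleton.
random_net <- function(seed) {
  set.seed(seed)
  pops <- population_ids()
  Jf <- matrix(runif(25, -0.5, 0.5) * rbinom(25, 1, 0.5), 5, 5,
               dimnames = list(pops, pops))
  diag(Jf) <- -abs(diag(Jf))  # self-inhibition keeps the system contractive
  Ws <- matrix(runif(20, -50, 50) * rbinom(20, 1, 0.5), 5, 4)
  pp <- population_params()
  list(Jf = Jf, Ws = Ws, gain = pp$gain, threshold = pp$threshold,
       bias = pp$bias * runif(5, 0.2, 1))
}

random_state <- function(seed) {
  set.seed(seed + 1000)
  setNames(c(runif(4, 0, 60), runif(2, 0, 0.5)),
           c("auto_5ht", "auto_da", "mod_5ht", "mod_da", "c_5ht", "c_da"))
}

# Damped fixed-point iteration oracle for the rectified rate system.
relaxation_rates <- function(net, base, damping = 0.2, iters = 20000,
                             tol = 1e-12) {
  f <- rep(0, 5)
  for (i in seq_len(iters)) {
    target <- pmax(net$gain * (base + as.numeric(net$Jf %*% f) - net$threshold), 0)
    fn <- (1 - damping) * f + damping * target
    if (max(abs(fn - f)) < tol) return(fn)
    f <- fn
  }
  f
}

# Exhaustive active-set oracle: try all 32 subsets, return every consistent
# solution.
brute_force_rates <- function(net, base, tol = 1e-9) {
  sols <- list()
  for (code in 0:31) {
    active <- as.logical(bitwAnd(code, 2^(0:4)))
    f <- rep(0, 5)
    ok <- TRUE
    if (any(active)) {
      G <- diag(net$gain[active], sum(active))
      A <- diag(sum(active)) - G %*% net$Jf[active, active, drop = FALSE]
      sol <- tryCatch(solve(A, net$gain[active] *
                              (base[active] - net$threshold[active])),
                      error = function(e) NULL)
      if (is.null(sol)) next
      f[active] <- sol
    }
    cur <- base + as.numeric(net$Jf %*% f)
    if (any(f[active] < -tol)) ok <- FALSE
    if (any(cur[!active] > net$threshold[!active] + tol)) ok <- FALSE
    if (ok) sols[[length(sols) + 1]] <- pmax(f, 0)
  }
  sols
}

# Direct access to the internal solver for net-level tests.
solve_rates_net <- function(net, base) {
  drnvta:::.active_set_solve(net$gain, net$threshold, net$Jf, base)
}
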