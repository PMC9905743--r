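# Degeneracy screening: percent deviation from the template activity
# profile, the inclusion criterion, the stochastic weight-calibration
# search, and robustness sweeps.

#' Inclusion thresholds
#'
#' Maximal admissible time-averaged percent deviation from the template
#' activity profile, per population: 10% for DA, 5-HT and Glu, 16% for the
#' two GABA pools.
#'
#' @return Named numeric vector (percent), in canonical population order.
#' @export
inclusion_thresholds <- function() {
  setNames(c(10, 10, 10, 16, 16), population_ids())
}

#' The template variant
#'
#' The minimal circuit (architecture K) with the requested 5-HT neuron type;
#' its activity profiles are the template against which the degeneracy and
#' D2 screens are judged.
#'
#' @param serotonin_type `"I"` or `"II"`.
#' @return A calibrated `drnvta_variant`.
#' @export
template_variant <- function(serotonin_type = c("I", "II")) {
  serotonin_type <- match.arg(serotonin_type)
  vs <- enumerate_variants("K")
  vs[[which(vapply(vs, function(v) v$serotonin_type, "") == serotonin_type)]]
}

#' Template activity time course
#'
#' @param task `"reward"` or `"punishment"`.
#' @param serotonin_type `"I"` or `"II"`.
#' @param config A `drnvta_sim_config`.
#' @return A `drnvta_timecourse` of the template run.
#' @export
template_timecourse <- function(task, serotonin_type, config = sim_config()) {
  v <- template_variant(serotonin_type)
  simulate_circuit(v, protocol_for_variant(v, task), config)
}

#' Time-averaged percent deviation between two runs
#'
#' For each population, the mean over the analysis window of
#' `100 * |F_test - F_template| / max(F_template, eps)`. The template is
#' always the denominator; `eps` (0.1 Hz) guards near-zero template
#' activity. The test run is linearly resampled onto the template grid when
#' the grids differ.
#'
#' @param test,template `drnvta_timecourse` objects.
#' @param window Analysis window in ms (default: 1 s before cue onset to 1 s
#'   after outcome onset, 3500-6700 ms).
#' @param eps Denominator floor (Hz).
#' @return Named numeric vector of percent deviations per population.
#' @export
percent_deviation <- function(test, template, window = c(3500, 6700),
                              eps = 0.1) {
  sel <- template$time >= window[1] & template$time <= window[2]
  if (!any(sel)) stop("window outside the recorded time grid")
  tt <- template$time[sel]
  out <- setNames(numeric(5), population_ids())
  for (p in population_ids()) {
    f_tpl <- template$rates[sel, p]
    f_test <- if (isTRUE(all.equal(test$time, template$time))) {
      test$rates[sel, p]
    } else {
      approx(test$time, test$rates[, p], xout = tt, rule = 2)$y
    }
    out[p] <- mean(100 * abs(f_test - f_tpl) / pmax(f_tpl, eps))
  }
  out
}

#' Inclusion check of a variant against the template profiles
#'
#' Simulates the variant under both tasks (with its own 5-HT type), computes
#' the percent deviations from the matching template runs, and issues the
#' verdict: included iff every population's deviation is below its threshold
#' in every condition.
#'
#' @param variant A calibrated `drnvta_variant`.
#' @param templates Optional named list of template time courses (elements
#'   `punishment`, `reward` for the variant's 5-HT type); computed if
#'   missing.
#' @param thresholds Named numeric vector, see `inclusion_thresholds()`.
#' @param config A `drnvta_sim_config`.
#' @return Object of class `drnvta_inclusion`: list with `variant_index`,
#'   `deviations` (matrix task x population), `verdict`
#'   (`"included"`/`"excluded"`), `violations` (data frame).
#' @export
inclusion_check <- function(variant, templates = NULL,
                            thresholds = inclusion_thresholds(),
                            config = sim_config()) {
  if (is.null(templates)) {
    templates <- list(
      punishment = template_timecourse("punishment", variant$serotonin_type, config),
      reward = template_timecourse("reward", variant$serotonin_type, config)
    )
  }
  devs <- matrix(NA_real_, 2, 5,
                 dimnames = list(c("punishment", "reward"), population_ids()))
  for (task in c("punishment", "reward")) {
    tc <- simulate_circuit(variant, protocol_for_variant(variant, task), config)
    devs[task, ] <- percent_deviation(tc, templates[[task]])
  }
  viol <- which(sweep(devs, 2, thresholds[population_ids()], ">="), arr.ind = TRUE)
  violations <- if (nrow(viol) == 0) {
    data.frame(task = character(), pop = character(), deviation = numeric())
  } else {
    data.frame(task = rownames(devs)[viol[, 1]],
               pop = colnames(devs)[viol[, 2]],
               deviation = devs[viol])
  }
  structure(list(
    variant_index = variant$index, architecture = variant$architecture,
    serotonin_type = variant$serotonin_type,
    deviations = devs,
    verdict = if (nrow(violations) == 0) "included" else "excluded",
    violations = violations
  ), class = "drnvta_inclusion")
}

#' Degeneracy screen over a set of variants
#'
#' Runs `inclusion_check()` for every variant, sharing the four template
#' runs, and returns a summary table.
#'
#' @param variants List of calibrated variants (default: all 84).
#' @param config A `drnvta_sim_config`.
#' @return Data frame with one row per variant: index, architecture, type,
#'   worst deviation per population (percent, across tasks) and verdict.
#' @export
screen_variants <- function(variants = enumerate_variants(),
                            config = sim_config()) {
  tpl <- list()
  for (ty in c("I", "II")) {
    tpl[[ty]] <- list(
      punishment = template_timecourse("punishment", ty, config),
      reward = template_timecourse("reward", ty, config)
    )
  }
  rows <- lapply(variants, function(v) {
    ic <- inclusion_check(v, tpl[[v$serotonin_type]], config = config)
    worst <- apply(ic$deviations, 2, max)
    cbind(data.frame(variant_index = v$index, architecture = v$architecture,
                     serotonin_type = v$serotonin_type),
          as.data.frame(as.list(worst)),
          data.frame(verdict = ic$verdict))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stochastic weight calibration search
#'
#' Bounded stochastic search over a set of free connection weights:
#' Latin-hypercube seeding followed by coordinate-wise refinement,
#' minimising the worst threshold-normalised deviation from the template
#' profiles. Returns the first weight set achieving inclusion, or the best
#' found with a failure flag. Deterministic for a fixed seed. (The shipped
#' fixtures are produced by the analytic baseline calibration,
#' `calibrate_baseline()`; this search is for user-supplied specifications.)
#'
#' @param variant A `drnvta_variant` (weights act as the search's centre
#'   where bounds do not say otherwise).
#' @param free Character vector of edge names to search over.
#' @param bounds Named list of `c(lower, upper)` per free edge.
#' @param seed Integer seed.
#' @param n_seed Number of Latin-hypercube seed points.
#' @param n_refine Coordinate refinement passes.
#' @param config A `drnvta_sim_config` (coarser grids speed the search).
#' @return List with `variant` (weights set to the best found), `weights`,
#'   `objective` (worst normalised deviation, < 1 means included),
#'   `included` (logical), `report` (the final `drnvta_inclusion`).
#' @export
calibrate <- function(variant, free, bounds, seed = 1,
                      n_seed = 20, n_refine = 2,
                      config = sim_config(dt = 1, record_stride = 10)) {
  stopifnot(all(free %in% variant$edges$name),
            all(free %in% names(bounds)))
  thresholds <- inclusion_thresholds()
  templates <- list(
    punishment = template_timecourse("punishment", variant$serotonin_type, config),
    reward = template_timecourse("reward", variant$serotonin_type, config)
  )
  objective <- function(w) {
    v <- variant
    for (n in names(w)) v$edges[n, "weight"] <- w[[n]]
    ic <- tryCatch(inclusion_check(v, templates, thresholds, config),
                   error = function(e) NULL)
    if (is.null(ic)) return(list(val = Inf, ic = NULL))
    list(val = max(sweep(ic$deviations, 2, thresholds[population_ids()], "/")),
         ic = ic)
  }
  lo <- vapply(bounds[free], `[`, 0, 1)
  hi <- vapply(bounds[free], `[`, 0, 2)
  set.seed(seed)
  lh <- lhs::randomLHS(n_seed, length(free))
  best <- NULL; best_val <- Inf
  for (i in seq_len(n_seed)) {
    w <- setNames(lo + lh[i, ] * (hi - lo), free)
    r <- objective(w)
    if (r$val < best_val) { best_val <- r$val; best <- list(w = w, ic = r$ic) }
    if (best_val < 1) break
  }
  # coordinate refinement: golden-ratio style shrinking steps per weight
  for (pass in seq_len(n_refine)) {
    if (best_val < 1) break
    for (j in seq_along(free)) {
      span <- (hi[j] - lo[j]) / (2^pass)
      for (cand in c(best$w[j] - span / 2, best$w[j] + span / 2)) {
        cand <- min(max(cand, lo[j]), hi[j])
        w <- best$w; w[j] <- cand
        r <- objective(w)
        if (r$val < best_val) { best_val <- r$val; best <- list(w = w, ic = r$ic) }
      }
    }
  }
  v <- variant
  for (n in names(best$w)) v$edges[n, "weight"] <- best$w[[n]]
  list(variant = v, weights = best$w, objective = best_val,
       included = best_val < 1, report = best$ic)
}

#' Robustness sweep around calibrated weights
#'
#' Perturbs each searchable weight one at a time by the given fractions
#' (multiplicatively, `w * (1 + fraction)`) and re-evaluates the inclusion
#' criterion.
#'
#' @param variant A calibrated `drnvta_variant`.
#' @param edges Edge names to perturb (default: all with positive weight).
#' @param fractions Numeric vector of perturbation fractions (e.g.
#'   `c(-0.5, 0.5)`); 0 is the unperturbed check.
#' @param config A `drnvta_sim_config`.
#' @return Data frame with columns `edge`, `fraction`, `verdict`,
#'   `worst_deviation`.
#' @export
robustness_sweep <- function(variant, edges = NULL,
                             fractions = c(-0.5, 0, 0.5),
                             config = sim_config(dt = 1, record_stride = 10)) {
  if (is.null(edges)) {
    edges <- variant$edges$name[variant$edges$weight > 0 &
                                  !grepl("^self_", variant$edges$name)]
  }
  templates <- list(
    punishment = template_timecourse("punishment", variant$serotonin_type, config),
    reward = template_timecourse("reward", variant$serotonin_type, config)
  )
  rows <- list()
  for (e in edges) for (f in fractions) {
    v <- variant
    v$edges[e, "weight"] <- variant$edges[e, "weight"] * (1 + f)
    ic <- tryCatch(inclusion_check(v, templates, config = config),
                   error = function(err) NULL)
    rows[[length(rows) + 1]] <- data.frame(
      edge = e, fraction = f,
      verdict = if (is.null(ic)) "failed" else ic$verdict,
      worst_deviation = if (is.null(ic)) NA_real_ else max(ic$deviations)
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
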