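# Simulated D2-receptor agonist screen: scale every D2-tagged connection
# weight (all connections emanating from the VTA DA population, including
# the DA autoreceptor) by a dose factor X and test which architectures
# deviate beyond the inclusion criterion from the unscaled template.

#' D2 screen configuration
#'
#' @param factors Dose factors X (default `c(1, 10, 40, 70, 100)`; X = 1 is
#'   the baseline condition).
#' @param tasks Tasks to screen (default both).
#' @param thresholds Inclusion thresholds, see `inclusion_thresholds()`.
#' @return Object of class `drnvta_d2_config`.
#' @export
d2_config <- function(factors = c(1, 10, 40, 70, 100),
                      tasks = c("punishment", "reward"),
                      thresholds = inclusion_thresholds()) {
  stopifnot(all(factors >= 1))
  structure(list(factors = factors, tasks = tasks, thresholds = thresholds),
            class = "drnvta_d2_config")
}

#' Scale a variant's D2-mediated connection weights
#'
#' Multiplies the weights of all D2-tagged connections (source = VTA DA,
#' including the autoreceptor) by the dose factor `X`; all other weights are
#' untouched.
#'
#' @param variant A calibrated `drnvta_variant`.
#' @param X Dose factor, `X >= 1`.
#' @return The scaled variant.
#' @export
apply_d2_factor <- function(variant, X) {
  stopifnot(X >= 1)
  e <- variant$edges
  e$weight[e$d2] <- e$weight[e$d2] * X
  variant$edges <- e
  variant$d2_factor <- X
  variant
}

#' D2 agonist screen over a set of variants
#'
#' For every variant, dose factor and task, simulates the scaled variant and
#' computes its percent deviation from the unscaled (X = 1) template
#' profile; a cell is flagged when at least one population's deviation
#' violates the inclusion criterion. Simulation failures are recorded per
#' cell, not fatal.
#'
#' @param variants List of calibrated variants (default: all 84).
#' @param config A `drnvta_d2_config`.
#' @param sim A `drnvta_sim_config`.
#' @return Data frame of class `drnvta_d2_report`: one row per variant x
#'   factor x task with per-population deviations (percent), `flagged`,
#'   and the comma-separated `violating` population list.
#' @export
d2_screen <- function(variants = enumerate_variants(), config = d2_config(),
                      sim = sim_config()) {
  thresholds <- config$thresholds[population_ids()]
  tpl <- list()
  for (ty in c("I", "II")) {
    tpl[[ty]] <- list(
      punishment = template_timecourse("punishment", ty, sim),
      reward = template_timecourse("reward", ty, sim)
    )
  }
  rows <- list()
  for (v in variants) for (X in config$factors) {
    vx <- apply_d2_factor(v, X)
    for (task in config$tasks) {
      devs <- tryCatch({
        tc <- simulate_circuit(vx, protocol_for_variant(vx, task), sim)
        percent_deviation(tc, tpl[[v$serotonin_type]][[task]])
      }, error = function(e) NULL)
      rows[[length(rows) + 1]] <- if (is.null(devs)) {
        cbind(data.frame(variant_index = v$index, architecture = v$architecture,
                         serotonin_type = v$serotonin_type, task = task, X = X,
                         status = "failed"),
              as.data.frame(as.list(setNames(rep(NA_real_, 5), population_ids()))),
              data.frame(flagged = NA, violating = NA_character_))
      } else {
        viol <- population_ids()[devs >= thresholds]
        cbind(data.frame(variant_index = v$index, architecture = v$architecture,
                         serotonin_type = v$serotonin_type, task = task, X = X,
                         status = "ok"),
              as.data.frame(as.list(devs)),
              data.frame(flagged = length(viol) > 0,
                         violating = paste(viol, collapse = ",")))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("drnvta_d2_report", class(out))
  out
}

#' Distinguishability signatures at a dose factor
#'
#' Operationalises distinguishability: at a given dose factor, a variant's
#' signature is its map from (task, 5-HT type) to the set of populations
#' violating the inclusion criterion. Architectures whose variants share one
#' signature, different from every other group's, form a distinguishable
#' subset.
#'
#' @param report A `drnvta_d2_report`.
#' @param X Dose factor to evaluate.
#' @return List with `signatures` (one per architecture) and `n_subsets`
#'   (number of distinct architecture-level signatures).
#' @export
d2_signatures <- function(report, X) {
  sub <- report[report$X == X & report$status == "ok", ]
  sig_of <- function(arch) {
    s <- sub[sub$architecture == arch, ]
    keys <- sort(paste(s$task, s$serotonin_type,
                       vapply(strsplit(s$violating, ","), function(v) {
                         paste(sort(v), collapse = "+")
                       }, ""), sep = ":"))
    paste(unique(keys), collapse = "; ")
  }
  archs <- sort(unique(sub$architecture))
  sigs <- setNames(vapply(archs, sig_of, ""), archs)
  list(signatures = sigs, n_subsets = length(unique(sigs)))
}
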