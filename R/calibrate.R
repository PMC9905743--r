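# Baseline calibration.
#
# The reference activity profile fixes the tonic (pre-cue) firing rates of
# all five populations in both tasks. At a tonic fixed point the transmitter
# concentrations, and hence all four slow currents, are algebraic functions
# of the pinned rates, so every population's current-balance equation is
# linear in the connection weights. Calibration therefore reduces to small
# per-population linear solves: the template's unknown gains (Glu and the two
# GABA pools) are solved once, and each variant's core weights are solved
# given its architecture's extra edges and sign choices.

#' Reference baseline firing rates
#'
#' Tonic pre-cue firing rates of the five populations in the punishment and
#' reward tasks that every calibrated variant reproduces: 5-HT 3.0/4.5 Hz,
#' DA 4.8/4.8 Hz, DRN Glu 4.1/4.1 Hz, DRN GABA 21.5/19.4 Hz, VTA GABA
#' 13.5/16.3 Hz (punishment/reward).
#'
#' @return Data frame with columns `pop`, `punishment`, `reward` (Hz).
#' @export
baseline_targets <- function() {
  data.frame(
    pop = population_ids(),
    punishment = c(3.0, 4.8, 4.1, 21.5, 13.5),
    reward = c(4.5, 4.8, 4.1, 19.4, 16.3),
    row.names = population_ids()
  )
}

# Constant external drive present throughout a trial (the across-trial
# long-term reward signal: +50 a.u. to 5-HT and DA in reward trials).
.baseline_externals <- function(task) {
  ext <- setNames(numeric(5), population_ids())
  if (task == "reward") ext[c("HT5_DRN", "DA_VTA")] <- 50
  ext
}

# Pinned fixed-point context for one task: target rates, concentrations and
# steady slow currents.
.pinned_context <- function(task) {
  tg <- baseline_targets()[[task]]
  names(tg) <- population_ids()
  rel <- release_params()
  c5 <- unname(steady_state_concentration(rel["HT5", ], tg[["HT5_DRN"]]))
  cda <- unname(steady_state_concentration(rel["DA", ], tg[["DA_VTA"]]))
  sp <- slow_current_params()
  slow <- c(
    auto_5ht = slow_current_steady(sp["auto_5ht", ], c5),
    auto_da = slow_current_steady(sp["auto_da", ], cda),
    mod_5ht = slow_current_steady(sp["mod_5ht", ], c5),
    mod_da = slow_current_steady(sp["mod_da", ], cda)
  )
  list(task = task, rates = tg, c5 = c5, cda = cda, slow = slow,
       ext = .baseline_externals(task))
}

# Which slow state an edge reads.
.slow_state_of <- function(source, target) {
  ifelse(source == "HT5_DRN" & target == "HT5_DRN", "auto_5ht",
  ifelse(source == "DA_VTA" & target == "DA_VTA", "auto_da",
  ifelse(source == "HT5_DRN", "mod_5ht", "mod_da")))
}

# Presynaptic signal carried by one edge at a pinned context.
.edge_signal <- function(edge, ctx) {
  if (edge$mechanism == "fast") {
    ctx$rates[[edge$source]]
  } else {
    ctx$slow[[.slow_state_of(edge$source, edge$target)]]
  }
}

# Template gains for the Glu and GABA pools, solved once from the reference
# baselines of the minimal template circuit (memoised).
.gain_cache <- new.env(parent = emptyenv())

.template_gains <- function() {
  if (!is.null(.gain_cache$g)) return(.gain_cache$g)
  tg <- baseline_targets()
  ctx_p <- .pinned_context("punishment")
  ctx_r <- .pinned_context("reward")
  im5p <- ctx_p$slow[["mod_5ht"]]
  im5r <- ctx_r$slow[["mod_5ht"]]
  # Glu: F = g * (0.5 F + 100), identical in both tasks.
  g_glu <- 4.1 / (0.5 * 4.1 + 100)
  # DRN GABA: F = g * (450 - 0.5 F - W * Imod5); the task pair determines
  # both the gain and the template 5-HT -> DRN GABA weight uniquely.
  fp <- tg["GABA_DRN", "punishment"]; fr <- tg["GABA_DRN", "reward"]
  froot <- function(W) {
    fp * (450 - 0.5 * fr - W * im5r) - fr * (450 - 0.5 * fp - W * im5p)
  }
  W_gd <- uniroot(froot, c(0, 1e7), tol = 1e-12)$root
  g_gd <- fp / (450 - 0.5 * fp - W_gd * im5p)
  # VTA GABA: F = g * (200 - 10 F + W * Imod5).
  fp <- tg["GABA_VTA", "punishment"]; fr <- tg["GABA_VTA", "reward"]
  froot <- function(W) {
    fp * (200 - 10 * fr + W * im5r) - fr * (200 - 10 * fp + W * im5p)
  }
  W_gv <- uniroot(froot, c(0, 1e7), tol = 1e-12)$root
  g_gv <- fp / (200 - 10 * fp + W_gv * im5p)
  .gain_cache$g <- c(GLU_DRN = g_glu, GABA_DRN = g_gd, GABA_VTA = g_gv)
  .gain_cache$template_w <- c(ht5_gd = W_gd, ht5_gv = W_gv)
  .gain_cache$g
}

# Fixture coupling of the VTA GABA -> DRN GABA edge when it is not solved.
.gv_gd_default <- 0.1

#' Calibrate a variant's connection weights to the reference baselines
#'
#' Solves the variant's core connection weights (5-HT autoreceptor,
#' Glu to 5-HT, Glu to DA, VTA GABA to DA, 5-HT to the two GABA pools) and,
#' where the architecture provides them, the extra reward-trial inhibitory
#' input and the DRN GABA compensatory input, so that the variant's tonic
#' fixed points in both tasks reproduce `baseline_targets()`. Architecture
#' edges that are not solved keep their fixture weights.
#'
#' @param variant A `drnvta_variant` whose solved weights may be `NA`.
#' @return The variant with all weights and input amplitudes filled in.
#' @export
calibrate_baseline <- function(variant) {
  pp <- population_params()
  ctx <- list(punishment = .pinned_context("punishment"),
              reward = .pinned_context("reward"))
  edges <- variant$edges

  # Required total current and the known (fixed-weight) part, per population
  # and task; unknown-edge coefficient columns are built alongside.
  required <- function(pop, task) {
    ctx[[task]]$rates[[pop]] / pp[pop, "gain"] + pp[pop, "threshold"]
  }
  known <- function(pop, task, skip) {
    ct <- ctx[[task]]
    tot <- pp[pop, "bias"] + ct$ext[[pop]]
    sub <- edges[edges$target == pop, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      e <- sub[i, ]
      if (e$name %in% skip) next
      w <- if (is.na(e$weight) && e$name == "gv_gd") .gv_gd_default else e$weight
      stopifnot(!is.na(w))
      tot <- tot + e$sign * w * .edge_signal(e, ct)
    }
    tot
  }
  coef_of <- function(name, task) {
    e <- edges[name, ]
    e$sign * .edge_signal(e, ctx[[task]])
  }
  solve2 <- function(unknowns, pop) {
    # exact 2x2 or least-squares solve of the two task equations
    A <- rbind(vapply(unknowns, coef_of, 0, task = "punishment"),
               vapply(unknowns, coef_of, 0, task = "reward"))
    b <- c(required(pop, "punishment") - known(pop, "punishment", unknowns),
           required(pop, "reward") - known(pop, "reward", unknowns))
    w <- if (length(unknowns) == 2) solve(A, b) else qr.solve(A, b)
    names(w) <- unknowns
    w
  }
  set_w <- function(w) {
    for (n in names(w)) {
      if (w[[n]] < -1e-6) {
        stop(sprintf("calibration produced a negative weight for %s (%.4g) in variant %d",
                     n, w[[n]], variant$index))
      }
      edges[n, "weight"] <<- max(w[[n]], 0)
    }
  }

  set_w(solve2(c("auto_5ht", "glu_5ht"), "HT5_DRN"))
  set_w(solve2(c("glu_da", "gv_da"), "DA_VTA"))

  # DRN GABA: unknown set depends on the architecture.
  has <- function(n) n %in% edges$name
  im5 <- c(punishment = ctx$punishment$slow[["mod_5ht"]],
           reward = ctx$reward$slow[["mod_5ht"]])
  if (!is.null(variant$gd_compensation)) {
    # no 5-HT -> DRN GABA edge: compensatory external inhibition, solved so
    # that both tonic baselines are met exactly
    comp_const <- known("GABA_DRN", "punishment", character()) -
      required("GABA_DRN", "punishment")
    comp_reward <- known("GABA_DRN", "reward", character()) -
      required("GABA_DRN", "reward") - comp_const
    stopifnot(comp_const >= 0, comp_reward >= 0)
    variant$gd_compensation["constant"] <- comp_const
    variant$gd_compensation["reward"] <- comp_reward
  } else if (has("ht5_gd") && edges["ht5_gd", "sign"] < 0) {
    if (isTRUE(variant$extra_flag)) {
      # solve the weight from the punishment baseline and let the extra
      # reward-trial inhibitory input absorb the reward equation; when that
      # input would have to be negative (excitatory), drop it and fit the
      # weight to both tasks by least squares instead
      w <- (known("GABA_DRN", "punishment", "ht5_gd") -
              required("GABA_DRN", "punishment")) / im5[["punishment"]]
      extra <- known("GABA_DRN", "reward", "ht5_gd") -
        w * im5[["reward"]] - required("GABA_DRN", "reward")
      if (extra >= 0) {
        set_w(c(ht5_gd = w))
        variant$extra_reward_inhibition <- extra
      } else {
        set_w(solve2("ht5_gd", "GABA_DRN"))
        variant$extra_reward_inhibition <- 0
      }
    } else {
      set_w(solve2("ht5_gd", "GABA_DRN"))
    }
  } else {
    # excitatory 5-HT -> DRN GABA (architecture A): the fixture weight is
    # kept and the VTA GABA -> DRN GABA coupling plus the extra reward
    # inhibition absorb the baseline equations
    jp <- ctx$punishment$rates[["GABA_VTA"]]
    jr <- ctx$reward$rates[["GABA_VTA"]]
    j <- (known("GABA_DRN", "punishment", "gv_gd") -
            required("GABA_DRN", "punishment")) / jp
    extra <- known("GABA_DRN", "reward", "gv_gd") - j * jr -
      required("GABA_DRN", "reward")
    if (extra >= 0) {
      set_w(c(gv_gd = j))
      variant$extra_reward_inhibition <- extra
    } else {
      set_w(solve2("gv_gd", "GABA_DRN"))
      variant$extra_reward_inhibition <- 0
    }
  }
  if (has("gv_gd") && is.na(edges["gv_gd", "weight"])) {
    edges["gv_gd", "weight"] <- .gv_gd_default
  }

  set_w(solve2("ht5_gv", "GABA_VTA"))
  variant$edges <- edges

  # Type II cue-interval tracking: the template suppresses DRN GABA between
  # cue and outcome through its serotonin link. A variant whose own edges
  # (inhibitory 5-HT -> DRN GABA, VTA GABA -> DRN GABA) cannot supply that
  # inhibitory increment receives a calibrated slow-ramp inhibitory input
  # covering the shortfall (zero for inhibitory-edge variants).
  .template_gains()
  w_tpl <- .gain_cache$template_w[["ht5_gd"]]
  f5s <- .sustained_5ht_rate(variant)
  rel <- release_params()
  c5s <- steady_state_concentration(rel["HT5", ], f5s)
  spar <- slow_current_params()
  d_im5 <- slow_current_steady(spar["mod_5ht", ], c5s) - im5[["reward"]]
  needed <- w_tpl * d_im5
  provided <- 0
  if (has("ht5_gd")) {
    provided <- provided - edges["ht5_gd", "sign"] * edges["ht5_gd", "weight"] * d_im5
  }
  if (has("gv_gd")) {
    g_gv <- population_params()["GABA_VTA", "gain"]
    d_fgv <- edges["ht5_gv", "weight"] * d_im5 * g_gv / (1 + 10 * g_gv)
    provided <- provided + edges["gv_gd", "weight"] * d_fgv
  }
  ramp <- max(needed - provided, 0)
  if (is.null(variant$gd_compensation)) {
    variant$gd_compensation <- c(constant = 0, reward = 0, cue_type2 = 0)
  }
  variant$gd_compensation["cue_type2"] <- if (ramp > 1e-6) ramp else 0
  variant
}

# Quasi-steady 5-HT rate under the Type II sustained reward input (+100 a.u.
# between cue and outcome), holding the other populations at their reward
# baselines; scalar self-consistent solve through the autoreceptor.
.sustained_5ht_rate <- function(variant) {
  pp <- population_params()
  ctx_r <- .pinned_context("reward")
  edges <- variant$edges
  rel <- release_params()
  sp <- slow_current_params()
  base <- pp["HT5_DRN", "bias"] + 50 + 100
  sub <- edges[edges$target == "HT5_DRN" & edges$name != "auto_5ht", , drop = FALSE]
  for (i in seq_len(nrow(sub))) {
    base <- base + sub$sign[i] * sub$weight[i] * .edge_signal(sub[i, ], ctx_r)
  }
  wa <- edges["auto_5ht", "weight"]
  g <- pp["HT5_DRN", "gain"]; th <- pp["HT5_DRN", "threshold"]
  froot <- function(f) {
    c5 <- steady_state_concentration(rel["HT5", ], min(f, 16.2))
    ia <- slow_current_steady(sp["auto_5ht", ], c5)
    g * (base - wa * ia - th) - f
  }
  uniroot(froot, c(0, 16.2), tol = 1e-10)$root
}
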