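# Inclusion criterion, percent deviation, calibration and robustness.

test_that("percent deviation is zero on identity and scales linearly", {
  tc <- template_timecourse("punishment", "I", fast_cfg())
  expect_equal(unname(percent_deviation(tc, tc)), rep(0, 5))
  # uniform 12% scaling of a trace that stays above the denominator floor
  # gives exactly 12% for that population
  tc2 <- tc
  tc2$rates[, "DA_VTA"] <- 1.12 * tc2$rates[, "DA_VTA"]
  d <- percent_deviation(tc2, tc, window = c(3500, 4500))
  expect_equal(unname(d["DA_VTA"]), 12, tolerance = 1e-8)
  expect_equal(unname(d[setdiff(population_ids(), "DA_VTA")]), rep(0, 4))
  # over the full window the DA trace is phasically silenced below the
  # 0.1 Hz floor, where the floored denominator damps the ratio
  dfull <- percent_deviation(tc2, tc)
  expect_lte(dfull[["DA_VTA"]], 12)
  expect_gt(dfull[["DA_VTA"]], 10)
})

test_that("resampling onto a finer recorded grid is faithful", {
  a <- template_timecourse("punishment", "I", sim_config(dt = 0.5, record_stride = 1))
  b <- template_timecourse("punishment", "I", sim_config(dt = 0.5, record_stride = 2))
  expect_lt(max(percent_deviation(b, a)), 0.01)
})

test_that("the inclusion verdict follows the per-population thresholds", {
  v <- template_variant("I")
  tpl <- cached_templates()[["I"]]
  ic <- inclusion_check(v, tpl, config = fast_cfg())
  expect_identical(ic$verdict, "included")
  expect_lt(max(ic$deviations), 0.01)
  # removing the strong Glu -> DA drive collapses DA beyond its 10% bound
  v2 <- v
  v2$edges["glu_da", "weight"] <- 0
  ic2 <- inclusion_check(v2, tpl, config = fast_cfg())
  expect_identical(ic2$verdict, "excluded")
  expect_true("DA_VTA" %in% ic2$violations$pop)
})

test_that("every enumerated variant satisfies the inclusion criterion", {
  sc <- screen_variants(all_variants(), config = fast_cfg())
  expect_equal(nrow(sc), 84)
  expect_true(all(sc$verdict == "included"))
  expect_true(all(sc[, population_ids()] < inclusion_thresholds()[population_ids()]))
})

test_that("the stochastic calibration search is deterministic", {
  v <- template_variant("I")
  w0 <- v$edges["ht5_gv", "weight"]
  r1 <- calibrate(v, free = "ht5_gv",
                  bounds = list(ht5_gv = c(0.5 * w0, 2 * w0)),
                  seed = 42, n_seed = 4, n_refine = 1)
  r2 <- calibrate(v, free = "ht5_gv",
                  bounds = list(ht5_gv = c(0.5 * w0, 2 * w0)),
                  seed = 42, n_seed = 4, n_refine = 1)
  expect_identical(r1$weights, r2$weights)
  expect_true(r1$included)
  # the analytically calibrated weight set passes at iteration zero
  r0 <- calibrate(v, free = "ht5_gv", bounds = list(ht5_gv = c(w0, w0)),
                  seed = 1, n_seed = 1, n_refine = 0)
  expect_true(r0$included)
  expect_lt(r0$objective, 0.01)
})

test_that("robustness: zero perturbation passes, extreme perturbation fails", {
  v <- template_variant("I")
  sw <- robustness_sweep(v, edges = c("glu_da", "ht5_gv"),
                         fractions = c(0, 99), config = fast_cfg())
  expect_true(all(sw$verdict[sw$fraction == 0] == "included"))
  expect_true(all(sw$verdict[sw$fraction == 99] != "included"))
})

test_that("inhibitory 5-HT to Glu coupling is less robust than excitatory", {
  # architecture B: at matched perturbations of the 5-HT -> Glu weight the
  # inhibitory-sign variant sits closer to exclusion than the excitatory one
  vs <- enumerate_variants("B")
  pick <- function(sg) {
    for (v in vs) {
      if (v$serotonin_type == "I" && v$signs[["ht5_da"]] == 1 &&
          v$signs[["da_gv"]] == 1 && v$signs[["ht5_glu"]] == sg) return(v)
    }
  }
  cfg <- fast_cfg()
  worst <- function(v) {
    sw <- robustness_sweep(v, edges = "ht5_glu", fractions = c(1, 3),
                           config = cfg)
    sw$worst_deviation
  }
  w_exc <- worst(pick(+1))
  w_inh <- worst(pick(-1))
  expect_true(all(w_inh > w_exc))
})

test_that("moderate weight variation preserves inclusion (model robustness)", {
  v <- all_variants()[[61]]  # architecture E
  sw <- robustness_sweep(v, edges = "ht5_glu", fractions = c(-0.5, 0.5),
                         config = fast_cfg())
  expect_true(all(sw$verdict == "included"))
})
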