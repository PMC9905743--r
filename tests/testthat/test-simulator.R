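# Integration: equilibrium invariance, fixed-point consistency, step-size
# convergence, determinism, and the calibrated baseline statistics.

test_that("a run started at the tonic fixed point stays there", {
  v <- template_variant("I")
  prot <- build_protocol("punishment", "I")
  # constants only: strip the transient events
  prot$events <- prot$events[prot$events$shape == "constant", , drop = FALSE]
  tc <- simulate_circuit(v, prot, fast_cfg())
  drift <- apply(tc$rates, 2, function(x) max(abs(x - x[1])))
  expect_lt(max(drift), 1e-6)
})

test_that("a long constant-input run converges to the fixed point", {
  v <- all_variants()[[33]]  # architecture B
  prot <- build_protocol("reward", v$serotonin_type)
  prot$events <- prot$events[prot$events$shape == "constant", , drop = FALSE]
  fp <- find_fixed_point(v, constant_externals(prot))
  cfg <- sim_config(dt = 1, horizon = 20000, record_stride = 500,
                    initial_state = fp$state * 1.01 + 1e-4)
  tc <- simulate_circuit(v, prot, cfg)
  endpoint <- tc$states[nrow(tc$states), ]
  expect_lt(max(abs(endpoint - fp$state)), 1e-5)
})

test_that("halving the step changes template rates by less than 0.1%", {
  v <- template_variant("I")
  for (task in c("punishment", "reward")) {
    tc1 <- simulate_circuit(v, task = task,
                            config = sim_config(dt = 1, record_stride = 50))
    tc2 <- simulate_circuit(v, task = task,
                            config = sim_config(dt = 0.5, record_stride = 100))
    expect_equal(tc1$time, tc2$time)
    rel <- abs(tc2$rates - tc1$rates) / pmax(abs(tc2$rates), 0.1)
    expect_lt(max(rel), 1e-3)
  }
})

test_that("identical configuration gives bit-identical output", {
  v <- all_variants()[[77]]  # architecture L, fast 5-HT to DA
  a <- simulate_circuit(v, task = "reward", config = fast_cfg())
  b <- simulate_circuit(v, task = "reward", config = fast_cfg())
  expect_identical(a$rates, b$rates)
  expect_identical(a$states, b$states)
})

test_that("the silent system clears its transmitters monotonically", {
  # all weights, biases and inputs zero: rates are zero, release stops, and
  # uptake clears both transmitter pools toward zero
  v <- template_variant("I")
  v$edges$weight <- 0
  net <- drnvta:::.net_list(v)
  net$bias <- rep(0, 5)
  net$threshold <- rep(0, 5)
  y0 <- c(0, 0, 0, 0, 0.4, 0.4)
  res <- drnvta:::cpp_integrate(net, matrix(numeric(0), ncol = 6), y0,
                                1, 60000, 50)
  expect_identical(res$status, "ok")
  expect_true(all(res$rates == 0))
  for (j in 5:6) {
    cc <- res$states[, j]
    expect_true(all(diff(cc) <= 0))
    expect_lt(cc[length(cc)], 0.01)
  }
})

test_that("baseline statistics average the pre-cue window", {
  v <- template_variant("II")
  tc <- simulate_circuit(v, task = "punishment", config = fast_cfg())
  b <- baseline_statistics(tc)
  expect_equal(unname(b), c(3.0, 4.8, 4.1, 21.5, 13.5), tolerance = 1e-6)
  # a constant series averages to itself
  tc$rates[] <- 7
  expect_equal(unname(baseline_statistics(tc)), rep(7, 5))
  expect_error(baseline_statistics(tc, window = c(9000, 9500)), "window")
})

test_that("reward baselines differ from punishment as calibrated", {
  v <- template_variant("I")
  tc <- simulate_circuit(v, task = "reward", config = fast_cfg())
  expect_equal(unname(baseline_statistics(tc)),
               c(4.5, 4.8, 4.1, 19.4, 16.3), tolerance = 1e-6)
})

test_that("reward Type II sustains elevated 5-HT between cue and outcome", {
  tc <- template_timecourse("reward", "II", fast_cfg())
  pre <- mean(tc$rates[tc$time >= 3500 & tc$time <= 4500, "HT5_DRN"])
  mid <- tc$rates[tc$time >= 4800 & tc$time <= 5700, "HT5_DRN"]
  expect_true(all(mid > pre + 1))
  # and the serotonin drive gradually suppresses DRN GABA while raising
  # VTA GABA activity
  gd_mid <- mean(tc$rates[tc$time >= 5400 & tc$time <= 5700, "GABA_DRN"])
  gv_mid <- mean(tc$rates[tc$time >= 5400 & tc$time <= 5700, "GABA_VTA"])
  expect_lt(gd_mid, 19.4 - 1)
  expect_gt(gv_mid, 16.3 + 1)
})

test_that("phasic responses match the published signatures", {
  cfg <- fast_cfg()
  # punishment Type I: VTA GABA spikes, DA is phasically inhibited
  tc <- template_timecourse("punishment", "I", cfg)
  at_outcome <- tc$time >= 5700 & tc$time <= 6000
  expect_gt(max(tc$rates[at_outcome, "GABA_VTA"]), 30)
  expect_lt(min(tc$rates[at_outcome, "DA_VTA"]), 0.5)
  # reward: Glu pulse at cue drives a phasic DA burst
  tr <- template_timecourse("reward", "I", cfg)
  at_cue <- tr$time >= 4500 & tr$time <= 4900
  expect_gt(max(tr$rates[at_cue, "DA_VTA"]), 20)
})
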