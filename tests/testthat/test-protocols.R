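# Task protocol construction and external-input evaluation.

test_that("reward Type I protocol carries the four published input groups", {
  p <- build_protocol("reward", "I")
  e <- p$events
  expect_equal(p$cue_time, 4500)
  expect_equal(p$outcome_time, 5700)
  # constants 50 a.u. to 5-HT and DA
  const <- e[e$shape == "constant", ]
  expect_setequal(const$target, c("HT5_DRN", "DA_VTA"))
  expect_true(all(const$amplitude == 50))
  # 200 ms Glu pulse of 1000 a.u. at cue
  glu <- e[e$target == "GLU_DRN", ]
  expect_equal(nrow(glu), 1)
  expect_equal(unname(unlist(glu[, c("amplitude", "onset", "offset")])),
               c(1000, 4500, 4700))
  # VTA GABA step 200 a.u. on [4500, 5700]
  gv <- e[e$target == "GABA_VTA", ]
  expect_equal(unname(unlist(gv[, c("shape", "amplitude", "onset", "offset")])),
               c("step", "200", "4500", "5700"))
  # nothing to DRN GABA
  expect_false("GABA_DRN" %in% e$target)
})

test_that("punishment protocols drive only the published targets", {
  p1 <- build_protocol("punishment", "I")
  expect_setequal(p1$events$target, c("GABA_VTA", "GABA_DRN"))
  expect_true(all(p1$events$amplitude == 1000))
  expect_true(all(p1$events$onset == 5700 & p1$events$offset == 5900))
  for (pop in c("DA_VTA", "HT5_DRN", "GLU_DRN")) {
    expect_equal(external_input(p1, pop, c(0, 4600, 5750, 7000)), rep(0, 4))
  }
  p2 <- build_protocol("punishment", "II")
  expect_setequal(p2$events$target, c("GABA_DRN", "HT5_DRN"))
  expect_true(all(p2$events$amplitude == 1000))
})

test_that("reward Type II replaces the GABA step by sustained 5-HT drive", {
  p <- build_protocol("reward", "II")
  e <- p$events
  expect_false(any(grepl("GABA", e$target)))
  step <- e[e$shape == "step", ]
  expect_equal(unname(unlist(step[, c("target", "amplitude")])),
               c("HT5_DRN", "100"))
})

test_that("reward minus punishment constant drive to 5-HT and DA is +50", {
  for (ty in c("I", "II")) {
    cr <- constant_externals(build_protocol("reward", ty))
    cp <- constant_externals(build_protocol("punishment", ty))
    expect_equal(unname((cr - cp)[c("HT5_DRN", "DA_VTA")]), c(50, 50))
  }
})

test_that("transient inputs rise and decay with the 50 ms smoothing factor", {
  p <- build_protocol("reward", "I")
  # before any event: constants only
  expect_equal(external_input(p, "GLU_DRN", 1000), 0)
  expect_equal(external_input(p, "HT5_DRN", 1000), 50)
  # pulse rises toward 1000 with tau = 50 ms
  expect_equal(external_input(p, "GLU_DRN", 4550),
               1000 * (1 - exp(-1)))
  # long after the pulse the contribution decays to ~0
  expect_lt(external_input(p, "GLU_DRN", 6000), 1e-8)
  # unsmoothed protocol uses sharp boxes
  ps <- build_protocol("reward", "I", smoothing = FALSE)
  expect_equal(external_input(ps, "GLU_DRN", 4550), 1000)
  expect_equal(external_input(ps, "GLU_DRN", 4750), 0)
})

test_that("protocol construction is pure and deterministic", {
  a <- build_protocol("reward", "II")
  b <- build_protocol("reward", "II")
  expect_identical(a, b)
})

test_that("architecture-specific inhibitory inputs carry the inhibitory sign", {
  p <- build_protocol("reward", "I", extra_inhibition = 25)
  gd <- p$events[p$events$target == "GABA_DRN", ]
  expect_equal(unname(unlist(gd[, c("sign", "amplitude")])), c(-1, 25))
  expect_equal(external_input(p, "GABA_DRN", 100), -25)
  # compensatory program: constant both tasks, reward component, Type II ramp
  comp <- c(constant = 30, reward = 10, cue_type2 = 60)
  pr <- build_protocol("reward", "II", gd_compensation = comp)
  expect_equal(external_input(pr, "GABA_DRN", 100), -40)
  ramp <- pr$events[pr$events$shape == "step", ]
  ramp <- ramp[ramp$target == "GABA_DRN", ]
  expect_equal(ramp$smoothing_tau, 1200)
  pp <- build_protocol("punishment", "II", gd_compensation = comp)
  expect_equal(external_input(pp, "GABA_DRN", 100), -30)
})
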