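# Fixed points, Jacobians and eigenvalue stability.

test_that("fixed points satisfy the full six-dimensional residual", {
  v <- template_variant("I")
  for (task in c("punishment", "reward")) {
    ext <- constant_externals(build_protocol(task, "I"))
    fp <- find_fixed_point(v, ext)
    expect_lt(fp$residual_norm, 1e-10)
    res <- state_derivatives(v, fp$state, ext)
    expect_lt(max(abs(res)), 1e-10)
    expect_true(all(fp$rates >= 0))
  }
})

test_that("the template fixed points reproduce the calibrated baselines", {
  v <- template_variant("I")
  fp_p <- find_fixed_point(v, constant_externals(build_protocol("punishment", "I")))
  expect_equal(unname(fp_p$rates), c(3.0, 4.8, 4.1, 21.5, 13.5),
               tolerance = 1e-8)
  fp_r <- find_fixed_point(v, constant_externals(build_protocol("reward", "I")))
  expect_equal(unname(fp_r$rates), c(4.5, 4.8, 4.1, 19.4, 16.3),
               tolerance = 1e-8)
})

test_that("Jacobian current rows carry the slow time-constant diagonal", {
  v <- all_variants()[[57]]  # architecture D
  fp <- find_fixed_point(v, constant_externals(
    build_protocol("punishment", v$serotonin_type)))
  J <- jacobian_at(v, fp)
  expect_equal(unname(diag(J)[1:4]),
               c(-1 / 500, -1 / 150, -1 / 1200, -1 / 1000), tolerance = 1e-9)
})

test_that("finite-difference and analytic Jacobians agree on random states", {
  v <- template_variant("II")
  for (seed in 1:6) {
    st <- random_state(seed)
    Jfd <- jacobian_at(v, st, externals = NULL)
    Jan <- jacobian_analytic(v, st, externals = NULL)
    expect_lt(max(abs(Jfd - Jan)), 1e-6)
  }
})

test_that("a decoupled system has a triangular Jacobian with the slow poles", {
  v <- template_variant("I")
  v$edges$weight <- 0
  st <- random_state(2)
  J <- jacobian_analytic(v, st)
  # currents do not feed back: the only off-diagonal entries are the
  # concentration columns of the current rows and the uptake diagonals
  expect_equal(unname(J[1:4, 1:4]), diag(c(-1/500, -1/150, -1/1200, -1/1000)))
  expect_true(all(J[5:6, 1:4] == 0))
  ev <- sort(Re(eigen(J, only.values = TRUE)$values))
  expect_equal(ev, sort(unname(diag(J))), tolerance = 1e-12)
})

test_that("the stability verdict is stable iff all real parts are negative", {
  v <- template_variant("I")
  s <- stability_verdict(v, "tonic", "punishment")
  expect_identical(s$verdict, "stable")
  expect_true(all(Re(s$eigenvalues) < 0))
  expect_lt(s$max_magnitude_real_part, 0)
})

test_that("sampled variants are stable with real eigenvalues in both conditions", {
  # tonic: both serotonin types; phasic: Type I variants (the Type II
  # punishment pulse drives 5-HT beyond its clearance capacity when frozen,
  # see the clearance test below)
  tonic_idx <- c(1, 24, 33, 49, 57, 61, 65, 67, 69, 71, 73, 76, 77, 81)
  for (v in all_variants()[tonic_idx]) {
    s <- stability_verdict(v, "tonic", "punishment")
    expect_identical(s$verdict, "stable", label = paste(v$index, "tonic"))
    expect_lt(max(abs(Im(s$eigenvalues))), 1e-9)
  }
  phasic_idx <- c(1, 16, 33, 49, 57, 65, 75, 77)
  for (v in all_variants()[phasic_idx]) {
    s <- stability_verdict(v, "phasic", "punishment")
    expect_identical(s$verdict, "stable", label = paste(v$index, "phasic"))
    expect_lt(max(abs(Im(s$eigenvalues))), 1e-9)
  }
})

test_that("phasic punishment freezes are at least as stable as tonic", {
  idx <- c(1, 33, 57, 75, 77)
  for (v in all_variants()[idx]) {
    tonic <- stability_verdict(v, "tonic", "punishment")
    phasic <- stability_verdict(v, "phasic", "punishment")
    expect_lte(phasic$max_magnitude_real_part,
               tonic$max_magnitude_real_part + 1e-9)
  }
})

test_that("frozen phasic drives beyond clearance capacity have no fixed point", {
  # holding the cue-locked Glu drive constant pushes the DA release rate
  # past the maximal Michaelis-Menten uptake, so no fixed point exists and
  # the battery records the condition instead of failing
  v <- template_variant("I")
  expect_error(stability_verdict(v, "phasic", "reward"), "no fixed point")
  b <- stability_battery(list(v), task = "reward")
  expect_setequal(b$verdict, c("stable", "no_fixed_point"))
  # the frozen Type II punishment pulse does the same through serotonin:
  # 5-HT is driven far above the 16.25 Hz clearance-limited maximum
  v2 <- template_variant("II")
  expect_error(stability_verdict(v2, "phasic", "punishment"), "no fixed point")
})
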