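# Threshold-linear rates, slow-current and release-reuptake right-hand
# sides, afferent-current assembly, and the active-set rate solver.

test_that("threshold-linear transfer rectifies at and below threshold", {
  expect_equal(rate_from_input(0.019, -10, -20), 0)
  expect_equal(rate_from_input(0.033, 0.13, 0.13), 0)
  expect_equal(rate_from_input(0.019, -10, 210), 0.019 * 220)
  # vectorised, never negative
  x <- seq(-100, 400, by = 7)
  expect_true(all(rate_from_input(0.033, 0.13, x) >= 0))
})

test_that("slow-current dynamics vanish exactly at the sigmoid value", {
  sp <- slow_current_params()
  for (nm in rownames(sp)) {
    p <- sp[nm, ]
    for (c in c(0, 0.05, 0.1, 0.4)) {
      expect_equal(slow_current_rhs(p, slow_current_steady(p, c), c), 0)
    }
  }
  # sigmoid midpoint: auto-5HT at its offset gives k/2, so rhs = 40/500
  p <- sp["auto_5ht", ]
  expect_equal(slow_current_rhs(p, 0, p$offset), 80 / 2 / 500)
  # saturation: far above offset the drive approaches k/tau
  expect_equal(slow_current_rhs(p, 0, 100), 80 / 500)
})

test_that("release-reuptake balance reproduces the closed-form curves", {
  rel <- release_params()
  expect_equal(steady_rate_prefactor(rel["HT5", ]), 16.25)
  expect_equal(steady_rate_prefactor(rel["DA", ]), 40)
  expect_equal(concentration_rhs(rel["HT5", ], 0, 0), 0)
  # rhs is zero exactly on F = prefactor * c / (km + c)
  for (c in c(0.01, 0.05, 0.2, 1)) {
    expect_equal(concentration_rhs(rel["HT5", ], 16.25 * c / (0.17 + c), c), 0)
    expect_equal(concentration_rhs(rel["DA", ], 40 * c / (0.15 + c), c), 0)
  }
  # inverse relation round-trips
  expect_equal(steady_state_concentration(rel["DA", ],
                                          steady_state_rate(rel["DA", ], 0.3)),
               0.3)
})

test_that("afferent current assembles bias, slow and fast terms", {
  v <- template_variant("I")
  # zero out everything: bias only
  v0 <- v
  v0$edges$weight <- 0
  state0 <- setNames(rep(0, 6), c("auto_5ht", "auto_da", "mod_5ht", "mod_da",
                                  "c_5ht", "c_da"))
  rates0 <- setNames(rep(0, 5), population_ids())
  expect_equal(afferent_current(v0, "DA_VTA", state0, rates0), 210)
  # 5-HT with only its autoreceptor active (weight 1, I_auto = 40)
  v1 <- v0
  v1$edges["auto_5ht", "weight"] <- 1
  st <- state0; st["auto_5ht"] <- 40
  expect_equal(afferent_current(v1, "HT5_DRN", st, rates0), 99.87 - 40)
  # external input adds linearly
  expect_equal(afferent_current(v0, "GLU_DRN", state0, rates0, external = 12),
               112)
})

test_that("decoupled rate solver reduces to the scalar transfer function", {
  net <- random_net(1)
  net$Jf[] <- 0
  base <- c(50, 180, 90, 400, 150)
  f <- solve_rates_net(net, base)
  expect_equal(unname(f), pmax(net$gain * (base - net$threshold), 0))
})

test_that("active-set solver agrees with damped relaxation on random nets", {
  for (seed in 1:12) {
    net <- random_net(seed)
    set.seed(seed + 500)
    base <- runif(5, -50, 300)
    f <- solve_rates_net(net, base)
    f_or <- relaxation_rates(net, base)
    expect_lt(max(abs(f - f_or)), 1e-8)
  }
})

test_that("active-set solver returns the unique brute-force solution", {
  for (seed in 1:20) {
    net <- random_net(seed * 7)
    set.seed(seed)
    base <- runif(5, -100, 400)
    sols <- brute_force_rates(net, base)
    expect_gte(length(sols), 1)
    # all consistent solutions coincide (uniqueness up to tolerance)
    if (length(sols) > 1) {
      for (s in sols[-1]) expect_lt(max(abs(s - sols[[1]])), 1e-7)
    }
    f <- solve_rates_net(net, base)
    expect_lt(max(abs(f - sols[[1]])), 1e-7)
  }
})

test_that("compiled and R rate solvers agree", {
  v <- template_variant("I")
  net <- drnvta:::.net_list(v)
  for (seed in 1:10) {
    st <- random_state(seed)
    r_cpp <- drnvta:::cpp_solve_rates(net, as.numeric(st[1:4]), numeric(5))
    r_r <- solve_rates(v, st)
    expect_true(r_cpp$ok)
    expect_lt(max(abs(r_cpp$rates - unname(r_r))), 1e-10)
  }
})

test_that("rates are never negative and sign flips only flip contributions", {
  v <- template_variant("II")
  for (seed in 1:10) {
    st <- random_state(seed)
    f <- solve_rates(v, st, externals = c(HT5_DRN = runif(1, 0, 500)))
    expect_true(all(f >= 0))
  }
  # flipping an edge sign changes the sign, not the magnitude, of its
  # current contribution
  vs <- enumerate_variants("E")
  e_pos <- vs[[which(vapply(vs, function(v) v$signs[["ht5_glu"]], 0) == 1 &
                       vapply(vs, function(v) v$serotonin_type, "") == "I")]]
  e_neg <- vs[[which(vapply(vs, function(v) v$signs[["ht5_glu"]], 0) == -1 &
                       vapply(vs, function(v) v$serotonin_type, "") == "I")]]
  st <- random_state(3)
  rates <- setNames(rep(4, 5), population_ids())
  base <- afferent_current(e_pos, "GLU_DRN", st * 0, rates)
  up <- afferent_current(e_pos, "GLU_DRN", st, rates)
  # make the weights comparable before measuring the contribution
  e_neg$edges["ht5_glu", "weight"] <- e_pos$edges["ht5_glu", "weight"]
  base_n <- afferent_current(e_neg, "GLU_DRN", st * 0, rates)
  dn <- afferent_current(e_neg, "GLU_DRN", st, rates)
  expect_equal(up - base, -(dn - base_n))
})
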