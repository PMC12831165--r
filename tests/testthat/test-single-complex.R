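test_that("the DUB suppression formula matches its closed form", {
  expect_equal(dub_effective_rate(1, 1), 500 / 501)
  expect_equal(dub_effective_rate(1, 10), 500 / 5001)
  # strictly decreasing in affinity
  affs <- c(1e-4, 0.01, 0.1, 1, 10)
  expect_true(all(diff(dub_effective_rate(1, affs)) < 0))
  expect_error(dub_effective_rate(1, 0), "affinity")
})

test_that("the ODE right-hand side matches direct substitution", {
  p <- single_complex_params(kgrowth = 1, klimit = 1, kdbasal = 1,
                             kxbasal = 1, kxdbasal = 1)
  expect_equal(unname(ode_rhs(0, 0, 1, 1, p)), c(1, 0))
  expect_equal(unname(ode_rhs(1, 1, 1, 1, p)), c(1 / 2 - 1, 0))
  # with the formation gate off, intensity can only decay
  expect_lte(ode_rhs(2, 3, 0, 1, p)[["dI"]], 0)
  expect_error(ode_rhs(-1, 0, 1, 1, p), "nonnegative")
})

test_that("steady-state intensity agrees with an independent root finder", {
  p <- single_complex_params(kgrowth = 1, klimit = 1, kdbasal = 1,
                             kxbasal = 1, kxdbasal = 1)
  # fixed point solves I^3 + I^2 - 1 = 0; polyroot is the oracle
  roots <- polyroot(c(-1, 0, 1, 1))
  oracle <- Re(roots[abs(Im(roots)) < 1e-9 & Re(roots) > 0])
  expect_equal(steady_state_intensity(p), oracle, tolerance = 1e-9)
  # monotone in the growth rate
  p2 <- p; p2$kgrowth <- 2
  expect_gt(steady_state_intensity(p2), steady_state_intensity(p))
  p3 <- p; p3$kgrowth <- 1e-8
  expect_lt(steady_state_intensity(p3), 1e-3)
})

test_that("no growth means identically zero tracks", {
  p <- single_complex_params(kgrowth = 0, n_spots = 10L, t_end = 10,
                             seed = 3L)
  tr <- simulate_single_complexes(p)
  expect_true(all(tr$intensity == 0) && all(tr$xbasal == 0))
})

test_that("permanent binding reproduces the ungated deterministic run", {
  # bound_toggle with k_unbind_ref = 0 never leaves the bound state, so it
  # must match growth_scale with a unit coupling factor sample-for-sample
  p1 <- single_complex_params(variant = "bound_toggle", k_unbind_ref = 0,
                              n_spots = 5L, t_end = 20, seed = 11L)
  p2 <- single_complex_params(variant = "growth_scale", growth_k_half = 0,
                              n_spots = 5L, t_end = 20, seed = 11L)
  t1 <- simulate_single_complexes(p1)
  t2 <- simulate_single_complexes(p2)
  expect_equal(t1$intensity, t2$intensity, tolerance = 1e-12)
  expect_equal(t1$xbasal, t2$xbasal, tolerance = 1e-12)
})

test_that("a constantly gated spot converges to the fixed point", {
  p <- single_complex_params(variant = "growth_scale", growth_k_half = 0,
                             n_spots = 1L, t_end = 600, dt = 0.01,
                             record_interval = 10, seed = 2L)
  tr <- simulate_single_complexes(p)
  istar <- steady_state_intensity(p)
  expect_lt(abs(tail(tr$intensity, 1) - istar) / istar, 1e-4)
})

test_that("intensity and feedback stay nonnegative across parameter sets", {
  for (s in 1:4) {
    set.seed(s)
    p <- single_complex_params(kgrowth = runif(1, 1, 200),
                               klimit = runif(1, 5, 100),
                               kdbasal = 10^runif(1, -4, -1),
                               kxbasal = runif(1, 0.05, 1),
                               kxdbasal = runif(1, 0.05, 1),
                               affinity = 10^runif(1, -3, 0),
                               variant = sample(c("bound_toggle",
                                                  "growth_scale",
                                                  "dub_suppression"), 1),
                               n_spots = 10L, t_end = 30, seed = 100L + s)
    tr <- simulate_single_complexes(p)
    expect_true(all(tr$intensity >= 0) && all(tr$xbasal >= 0))
    # intensity is zero before each spot's formation time
    form <- attr(tr, "formation_times")
    for (k in c(1L, 10L)) {
      sub <- tr[tr$spot_id == k, ]
      expect_true(all(sub$intensity[sub$time < form[k] - 1e-9] == 0))
    }
  }
})

test_that("telegraph occupancy matches the two-state equilibrium", {
  p <- single_complex_params(variant = "bound_toggle", affinity = 1,
                             n_spots = 300L, spot_interval = 0,
                             t_end = 200, record_interval = 1, seed = 8L)
  tr <- simulate_single_complexes(p)
  expected <- p$k_bind / (p$k_bind + p$k_unbind_ref / p$affinity)
  # ~300 spots x 200 min of exposure: generous Monte-Carlo tolerance
  expect_lt(abs(mean(tr$bound) - expected), 0.02)
})

test_that("mean spot AUC falls monotonically as affinity drops, all variants", {
  affs <- c(1, 0.1, 0.01, 1e-4)
  for (v in c("bound_toggle", "growth_scale", "dub_suppression")) {
    means <- vapply(affs, function(a) {
      p <- single_complex_params(variant = v, affinity = a, n_spots = 100L,
                                 seed = derive_seed(7, paste0(v, a)))
      mean(spot_descriptors(simulate_single_complexes(p))$auc)
    }, numeric(1))
    expect_true(all(diff(means) < 0),
                info = sprintf("variant %s: %s", v,
                               paste(signif(means, 3), collapse = ", ")))
  }
})
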