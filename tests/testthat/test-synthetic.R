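test_that("noiseless cohorts saturate at the configured amplitude and peak", {
  spec <- synthetic_cohort_spec(doses = 1e6, n_cells_per_dose = 1L,
                                noise_cv = 0, max_amplitude = 60,
                                peak_time_mean = 30, seed = 1L)
  tc <- gen_spot_count_timecourses(spec)
  expect_equal(max(tc$value), 60, tolerance = 1e-6)
  expect_equal(tc$time[which.max(tc$value)], 30)
})

test_that("the Hill midpoint dose gives half-maximal amplitude", {
  # effective EC50 = reference_ec50 / relative_affinity
  spec <- synthetic_cohort_spec(relative_affinity = 0.1, reference_ec50 = 2,
                                doses = 2 / 0.1, n_cells_per_dose = 1L,
                                noise_cv = 0, max_amplitude = 80, seed = 1L)
  tc <- gen_spot_count_timecourses(spec)
  expect_equal(max(tc$value), 40, tolerance = 1e-6)
})

test_that("cohort generation is byte-identical under a fixed seed", {
  spec <- synthetic_cohort_spec(n_cells_per_dose = 3L, noise_cv = 0.3,
                                doses = c(1, 10), seed = 77L)
  expect_identical(gen_spot_count_timecourses(spec),
                   gen_spot_count_timecourses(spec))
})

test_that("noisy cohorts are nonnegative integer counts with one main pulse", {
  spec <- synthetic_cohort_spec(n_cells_per_dose = 5L, noise_cv = 0.25,
                                doses = 10, seed = 3L)
  tc <- gen_spot_count_timecourses(spec)
  expect_true(all(tc$value >= 0))
  expect_true(all(tc$value == round(tc$value)))
  # population mean peaks in the first half and adapts near baseline
  m <- vapply(split(tc$value, tc$time), mean, numeric(1))
  tt <- as.numeric(names(m))
  expect_lt(tt[which.max(m)], 60)
  expect_lt(mean(m[tt >= 110]), 0.15 * max(m))
})

test_that("cohort validation rejects impossible settings", {
  expect_error(synthetic_cohort_spec(doses = c(1, -1)), "> 0")
  expect_error(synthetic_cohort_spec(relative_affinity = 0), "> 0")
  expect_error(synthetic_cohort_spec(noise_cv = -0.1), "noise_cv")
  expect_error(synthetic_cohort_spec(duration = 50,
                                     adaptation_time_mean = 90), "duration")
})

test_that("SPT-style tracks honor framing, growth and seeding contracts", {
  p <- single_complex_params(n_spots = 4L, t_end = 5, seed = 1L)
  tr <- gen_single_spot_tracks(p, n_tracks = 4L, seed = 5L)
  expect_equal(sort(unique(round(diff(sort(unique(tr$time_s)))))), 10)
  expect_true(all(tr$intensity >= 0))
  expect_identical(tr, gen_single_spot_tracks(p, n_tracks = 4L, seed = 5L))
  p0 <- single_complex_params(kgrowth = 0, n_spots = 3L, t_end = 5)
  expect_true(all(gen_single_spot_tracks(p0, seed = 2L)$intensity == 0))
  expect_equal(nrow(gen_single_spot_tracks(p, n_tracks = 0L, seed = 1L)), 0)
})

test_that("synthetic melt curves match their two-state construction", {
  spec <- melt_curve_spec(midpoint = 61.3, noise_sd = 0,
                          grid = seq(30, 95, by = 0.5))
  mc <- gen_melt_curve(spec)
  # max finite-difference derivative at the grid point nearest the midpoint
  d <- diff(mc$fluorescence) / diff(mc$temperatures)
  mid <- (mc$temperatures[-1] + mc$temperatures[-length(mc$temperatures)]) / 2
  expect_lt(abs(mid[which.max(d)] - 61.3), 0.5)
  expect_true(all(diff(mc$fluorescence) >= 0))
  # different seeds differ only through the added noise
  a <- gen_melt_curve(melt_curve_spec(midpoint = 60, noise_sd = 0.02,
                                      seed = 1L))
  b <- gen_melt_curve(melt_curve_spec(midpoint = 60, noise_sd = 0.02,
                                      seed = 2L))
  clean <- gen_melt_curve(melt_curve_spec(midpoint = 60, noise_sd = 0))
  expect_false(identical(a$fluorescence, b$fluorescence))
  expect_lt(max(abs(a$fluorescence - clean$fluorescence)), 0.1)
  expect_error(melt_curve_spec(midpoint = 20, grid = seq(30, 90, 1)),
               "within the grid")
})
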