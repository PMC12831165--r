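test_that("a symmetric triangle pulse yields its analytic descriptors", {
  d <- compute_descriptors(triangle_traj())
  expect_equal(d$auc, 50)
  expect_equal(d$max, 10)
  expect_equal(d$t_max, 5)
  expect_equal(d$t50_up, 2.5)
  expect_equal(d$t50_down, 7.5)
  expect_equal(d$fwhm, 5)
  expect_equal(d$rate_up, 2)
  expect_equal(d$rate_down, 2)
  expect_equal(d$adaptation_time, 10)
})

test_that("value scaling scales amplitudes and leaves times alone", {
  for (s in 1:5) {
    tr <- random_pulse(s)
    c0 <- runif(1, 0.1, 9)
    d1 <- compute_descriptors(tr)
    d2 <- compute_descriptors(trajectory(tr$times, tr$values * c0))
    expect_equal(d2$auc, d1$auc * c0)
    expect_equal(d2$max, d1$max * c0)
    expect_equal(d2$rate_up, d1$rate_up * c0)
    expect_equal(d2$rate_down, d1$rate_down * c0)
    expect_equal(d2$t_max, d1$t_max)
    expect_equal(d2$t50_up, d1$t50_up)
    expect_equal(d2$t50_down, d1$t50_down)
    expect_equal(d2$fwhm, d1$fwhm)
    expect_equal(d2$adaptation_time, d1$adaptation_time)
  }
})

test_that("degenerate trajectories are handled explicitly", {
  d <- compute_descriptors(trajectory(0:5, rep(0, 6)))
  expect_equal(d$auc, 0)
  expect_equal(d$max, 0)
  expect_equal(d$rate_up, 0)
  expect_true(is.na(d$t_max) && is.na(d$fwhm) && is.na(d$adaptation_time))
  expect_error(compute_descriptors(trajectory(0:1, c(0, 1))), "3 samples")
  expect_error(trajectory(c(0, 1, 1), c(0, 1, 2)), "ascending")
  expect_error(trajectory(0:2, c(0, -1, 2)), "nonnegative")
})

test_that("appending post-adaptation zeros leaves descriptors unchanged", {
  tr <- triangle_traj()
  ext <- trajectory(c(tr$times, 11:15), c(tr$values, rep(0, 5)))
  d1 <- compute_descriptors(tr)
  d2 <- compute_descriptors(ext)
  for (f in c("auc", "max", "rate_up", "rate_down", "t_max", "t50_up",
              "t50_down", "fwhm", "adaptation_time")) {
    expect_equal(d2[[f]], d1[[f]], info = f)
  }
})

test_that("cell aggregation is the pointwise sum of its tracks", {
  grid <- seq(0, 10, by = 1)
  one <- data.frame(spot_id = 1L, time = grid, intensity = grid^2 / 10)
  agg1 <- aggregate_cell_intensity(one, grid)
  expect_equal(agg1$values, one$intensity)
  two <- rbind(one, transform(one, spot_id = 2L))
  agg2 <- aggregate_cell_intensity(two, grid)
  expect_equal(agg2$values, 2 * one$intensity)
  # AUC linearity: sum of per-track AUCs equals the aggregate AUC
  set.seed(1)
  three <- rbind(two, data.frame(spot_id = 3L, time = grid,
                                 intensity = runif(11)))
  auc_each <- vapply(split(three, three$spot_id), function(sub)
    compute_descriptors(trajectory(sub$time, sub$intensity))$auc, numeric(1))
  agg3 <- aggregate_cell_intensity(three, grid)
  expect_equal(compute_descriptors(agg3)$auc, sum(auc_each))
  # empty input gives a zero trajectory
  empty <- one[0, ]
  expect_true(all(aggregate_cell_intensity(empty, grid)$values == 0))
})

test_that("the early-track filter keeps the four-minute boundary inclusive", {
  tracks <- data.frame(spot_id = rep(1:3, each = 2),
                       time = rep(c(0, 5), 3),
                       intensity = 1,
                       formation_time = rep(c(3.9, 4.0, 4.1), each = 2))
  kept <- filter_early_tracks(tracks, cutoff = 4)
  expect_setequal(unique(kept$spot_id), c(1L, 2L))
  expect_equal(nrow(filter_early_tracks(tracks[0, ])), 0)
  # without an explicit column, formation is the first positive-intensity time
  t2 <- data.frame(spot_id = rep(1:2, each = 3), time = rep(c(2, 4.5, 6), 2),
                   intensity = c(0, 1, 1, 1, 1, 1))
  expect_setequal(unique(filter_early_tracks(t2, 4)$spot_id), 2L)
})

test_that("descriptor tables carry metadata through", {
  spec <- synthetic_cohort_spec(doses = c(1, 10), n_cells_per_dose = 2L,
                                noise_cv = 0, seed = 1L)
  tc <- gen_spot_count_timecourses(spec)
  dt <- descriptor_table(tc, id = "cell_id")
  expect_equal(nrow(dt), 4)
  expect_true(all(c("species", "dose", "auc", "max", "fwhm") %in% names(dt)))
})
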