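test_that("Hill fits recover noiseless generating parameters", {
  doses <- c(1, 3.16, 10, 31.6, 100)
  for (pars in list(c(100, 10, 1), c(50, 5, 2), c(7, 30, 0.8))) {
    y <- pars[1] / (1 + (pars[2] / doses)^pars[3])
    fit <- fit_hill(doses, y)
    expect_true(fit$converged)
    expect_lt(abs(fit$y_max - pars[1]) / pars[1], 1e-6)
    expect_lt(abs(fit$ka - pars[2]) / pars[2], 1e-6)
    expect_lt(abs(fit$n - pars[3]) / pars[3], 1e-6)
    expect_gt(fit$r2, 1 - 1e-10)
    # midpoint identity: fitted curve at ka is half of y_max
    expect_equal(fit$y_max / (1 + (fit$ka / fit$ka)^fit$n), fit$y_max / 2)
  }
})

test_that("Hill fitting flags degenerate inputs instead of guessing", {
  expect_false(fit_hill(c(1, 2, 4, 8), rep(0, 4))$converged)
  expect_false(fit_hill(c(1, 2, 4, 8), rep(3, 4))$converged)
  expect_error(fit_hill(c(1, 2, 4), 1:3), "4 dose points")
  expect_error(fit_hill(c(-1, 2, 4, 8), 1:4), "> 0")
})

test_that("logistic fits recover parameters and respect x-shifts", {
  x <- seq(-2, 2, length.out = 8)
  y <- 1 / (1 + exp(-2 * (x - 0)))
  fit <- fit_logistic(x, y)
  expect_true(fit$converged)
  expect_lt(abs(fit$y_max - 1), 1e-6)
  expect_lt(abs(fit$ka - 2), 1e-6)
  expect_lt(abs(fit$x0 - 0), 1e-6)
  # y(x0) = y_max / 2 by construction of the form
  fit2 <- fit_logistic(x + 1, y)
  expect_equal(fit2$x0, fit$x0 + 1, tolerance = 1e-6)
  expect_false(fit_logistic(x, rep(1, 8))$converged)
})

test_that("EC50 extraction maps both fit forms onto dose units", {
  doses <- c(0.5, 2, 8, 32, 128)
  y <- 40 / (1 + (10 / doses))
  hf <- fit_hill(doses, y)
  expect_equal(ec50(hf), hf$ka)
  x <- seq(-1, 3, length.out = 6)
  lf <- fit_logistic(x, 5 / (1 + exp(-1.5 * (x - 1))))
  expect_equal(ec50(lf), 10, tolerance = 1e-6)
  bad <- fit_hill(c(1, 2, 4, 8), rep(0, 4))
  expect_error(ec50(bad), "converge")
})

test_that("EC50 shifts in proportion to the generator affinity", {
  # noiseless synthetic cohorts at affinities 100x apart
  ec <- vapply(c(1, 0.01), function(a) {
    spec <- synthetic_cohort_spec(relative_affinity = a,
                                  doses = 10^seq(-2, 3, length.out = 8),
                                  n_cells_per_dose = 1L, noise_cv = 0,
                                  seed = 1L)
    tc <- gen_spot_count_timecourses(spec)
    peaks <- vapply(split(tc$value, tc$dose), max, numeric(1))
    ec50(fit_hill(as.numeric(names(peaks)), unname(peaks)))
  }, numeric(1))
  expect_lt(abs(ec[1] - 1), 0.01)        # reference_ec50 / affinity = 1
  expect_lt(abs(ec[2] / ec[1] - 100) / 100, 0.01)
})

test_that("Fano factors follow the variance/mean definition and exclusions", {
  df <- data.frame(g = rep(c("a", "b", "c"), each = 3),
                   v = c(1, 2, 3, 5, 5, 5, 0, 0, 0))
  out <- group_fano(df, "g", "v")
  expect_equal(out$fano[out$g == "a"], 0.5)  # sample variance, n - 1
  expect_equal(out$fano[out$g == "b"], 0)
  expect_true(out$excluded[out$g == "c"])    # zero mean is excluded
  expect_true(is.na(out$fano[out$g == "c"]))
})

test_that("Poisson data have unit Fano factor", {
  set.seed(99)
  df <- data.frame(g = "p", v = rpois(10000, 10))
  out <- group_fano(df, "g", "v")
  expect_lt(abs(out$fano - 1), 0.05)
})

test_that("EC50 is invariant to rescaling the responses", {
  doses <- c(1, 3.16, 10, 31.6, 100)
  y <- 100 / (1 + (10 / doses)^1.5)
  f1 <- fit_hill(doses, y)
  f2 <- fit_hill(doses, y * 17)
  expect_equal(ec50(f2), ec50(f1), tolerance = 1e-6)
})
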