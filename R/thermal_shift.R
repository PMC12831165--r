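#' Construct a melt curve
#'
#' A thermal-shift (differential scanning fluorimetry) melt curve: dye
#' fluorescence versus temperature for one well, on a strictly ascending
#' temperature grid.
#'
#' @param temperatures degrees C, strictly ascending.
#' @param fluorescence arbitrary units, same length.
#' @param well well / sample identifier.
#' @return an object of class `melt_curve`.
#' @export
melt_curve <- function(temperatures, fluorescence, well = "A1") {
  .check(length(temperatures) == length(fluorescence), "lengths differ")
  .check(all(is.finite(temperatures)) && all(diff(temperatures) > 0),
         "temperatures must be finite and strictly ascending")
  .check(all(is.finite(fluorescence)), "fluorescence must be finite")
  structure(list(temperatures = as.numeric(temperatures),
                 fluorescence = as.numeric(fluorescence),
                 well = as.character(well)),
            class = "melt_curve")
}

#' Rescale raw fluorescence to the unit interval
#'
#' Linear min-max normalization: the curve minimum maps to 0 and the
#' maximum to 1. Idempotent on already-normalized curves; a constant curve
#' (no signal) is an error.
#'
#' @param curve a [melt_curve()].
#' @return the normalized `melt_curve`.
#' @export
normalize_curve <- function(curve) {
  stopifnot(inherits(curve, "melt_curve"))
  f <- curve$fluorescence
  rng <- range(f)
  .check(diff(rng) > 0, "constant fluorescence: cannot normalize")
  melt_curve(curve$temperatures, (f - rng[1]) / diff(rng), curve$well)
}

#' Savitzky-Golay smoothing of a melt curve
#'
#' Smooths fluorescence with a quadratic (order-2) Savitzky-Golay filter
#' over a rolling window of 15 temperature points (defaults). Endpoints are
#' handled by the filter's own least-squares transients, so polynomials up
#' to the filter order (constants, quadratics) are reproduced exactly
#' everywhere including the edges. An even `window` is increased to the
#' next odd number.
#'
#' @param curve a [melt_curve()].
#' @param window rolling window length in temperature points (odd).
#' @param order polynomial order of the filter.
#' @return the smoothed `melt_curve`.
#' @export
smooth_savgol <- function(curve, window = 15L, order = 2L) {
  stopifnot(inherits(curve, "melt_curve"))
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  .check(order < window, "order must be < window")
  .check(length(curve$fluorescence) >= window,
         sprintf("curve has %d points but the window is %d",
                 length(curve$fluorescence), window))
  sm <- signal::sgolayfilt(curve$fluorescence, p = order, n = window)
  melt_curve(curve$temperatures, sm, curve$well)
}

#' Call the melt temperature from a processed curve
#'
#' Runs the standard processing order — [normalize_curve()], then
#' [smooth_savgol()] — unless `preprocess = FALSE`, estimates the first
#' derivative dF/dT, and reports Tm as the temperature of the maximum
#' derivative. The search is restricted to temperatures up to and including
#' the global fluorescence maximum, so the post-peak decline of dye curves
#' (aggregation / dye release after full unfolding) cannot masquerade as a
#' transition. All local derivative peaks above `prominence` (fraction of
#' the derivative maximum) on the searched region are also reported for
#' inspection of bi-phasic curves.
#'
#' On a uniform grid, the derivative is estimated with a Savitzky-Golay
#' first-derivative filter whose bandwidth `deriv_span` (degrees C) is
#' matched to the width of a typical unfolding transition: an unfolding
#' step spreads its fluorescence rise over several degrees, so slopes
#' estimated over a comparable span average the measurement noise without
#' blurring the transition, whereas two-point differences at a fine
#' temperature resolution are noise-dominated. The called Tm is refined to
#' sub-grid resolution by the vertex of a quadratic least-squares fit to
#' the derivative around its maximum. Irregular grids fall back to central
#' differences.
#'
#' A curve with no rising transition (non-positive maximum derivative)
#' yields a flagged no-call (`tm = NA`).
#'
#' @param curve a [melt_curve()].
#' @param window,order Savitzky-Golay settings, see [smooth_savgol()].
#' @param preprocess run normalize + smooth first (default `TRUE`).
#' @param prominence minimum height of secondary derivative peaks, as a
#'   fraction of the maximum derivative.
#' @param deriv_span bandwidth of the derivative filter, degrees C.
#' @return an object of class `melt_result`: list with `tm`, `called`,
#'   `well`, `derivative` (data.frame `temperature`, `dfdt`), `peaks`
#'   (temperatures of qualifying local derivative maxima), and the
#'   processed `curve`.
#' @export
melt_temperature <- function(curve, window = 15L, order = 2L,
                             preprocess = TRUE, prominence = 0.25,
                             deriv_span = 8) {
  stopifnot(inherits(curve, "melt_curve"))
  proc <- if (preprocess) smooth_savgol(normalize_curve(curve),
                                        window, order) else curve
  tt <- proc$temperatures
  f <- proc$fluorescence
  n <- length(f)
  .check(n >= 5, "need at least 5 points for derivative estimation")
  steps <- diff(tt)
  uniform <- diff(range(steps)) < 1e-8 * mean(steps)
  if (uniform) {
    h <- steps[1]
    dn <- as.integer(round(deriv_span / h)) + 1L
    if (dn %% 2L == 0L) dn <- dn + 1L
    dn <- max(5L, min(dn, if (n %% 2L == 1L) n else n - 1L))
    dfdt <- signal::sgolayfilt(f, p = order, n = dn, m = 1, ts = h)
  } else {
    dfdt <- numeric(n)
    dfdt[2:(n - 1)] <- (f[3:n] - f[1:(n - 2)]) / (tt[3:n] - tt[1:(n - 2)])
    dfdt[1] <- (f[2] - f[1]) / (tt[2] - tt[1])
    dfdt[n] <- (f[n] - f[n - 1]) / (tt[n] - tt[n - 1])
  }
  imax_f <- which.max(f)
  region <- seq_len(imax_f)
  if (length(region) < 2 || max(dfdt[region]) <= 0) {
    return(structure(list(tm = NA_real_, called = FALSE, well = proc$well,
                          derivative = data.frame(temperature = tt,
                                                  dfdt = dfdt),
                          peaks = numeric(0), curve = proc),
                     class = "melt_result"))
  }
  d <- dfdt[region]
  k <- which.max(d)
  tm <- tt[region][k]
  # sub-grid refinement: vertex of a least-squares parabola fit to the
  # derivative in a window around its maximum
  span_pts <- if (uniform) max(4L, as.integer(round(deriv_span / 4 /
                                                      steps[1]))) else 4L
  lo <- max(1L, k - span_pts)
  hi <- min(length(d), k + span_pts)
  if (hi - lo >= 2L) {
    tw <- tt[region][lo:hi]
    tc <- tw - tw[1]
    dw <- d[lo:hi]
    X <- cbind(1, tc, tc^2)
    cf <- tryCatch(solve(crossprod(X), crossprod(X, dw)),
                   error = function(e) NULL)
    if (!is.null(cf) && is.finite(cf[3]) && cf[3] < 0) {
      vertex <- tw[1] - cf[2] / (2 * cf[3])
      if (vertex >= tw[1] && vertex <= tw[length(tw)]) tm <- vertex
    }
  }
  thr <- prominence * max(d)
  is_peak <- rep(FALSE, length(d))
  if (length(d) >= 3) {
    core <- 2:(length(d) - 1)
    is_peak[core] <- d[core] >= d[core - 1] & d[core] >= d[core + 1] &
      d[core] >= thr
  }
  structure(list(tm = tm, called = TRUE, well = proc$well,
                 derivative = data.frame(temperature = tt, dfdt = dfdt),
                 peaks = tt[region][is_peak], curve = proc),
            class = "melt_result")
}

#' Tm table for a set of wells
#'
#' Applies the normalize / smooth / maximum-derivative pipeline to each
#' well of a long melt-curve table.
#'
#' @param df data.frame with columns `well`, `temperature_c`,
#'   `fluorescence`.
#' @param ... passed to [melt_temperature()].
#' @return data.frame with columns `well`, `tm_c`, `called`.
#' @export
melt_table <- function(df, ...) {
  .check(all(c("well", "temperature_c", "fluorescence") %in% names(df)),
         "df must have columns well, temperature_c, fluorescence")
  wells <- unique(df$well)
  rows <- lapply(wells, function(w) {
    sub <- df[df$well == w, , drop = FALSE]
    sub <- sub[order(sub$temperature_c), , drop = FALSE]
    res <- melt_temperature(melt_curve(sub$temperature_c, sub$fluorescence,
                                       w), ...)
    data.frame(well = w, tm_c = res$tm, called = res$called)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
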