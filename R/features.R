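#' Construct a trajectory (time course) object
#'
#' A trajectory is a nonnegative time course on a strictly ascending (not
#' necessarily regular) time grid: NEMO spot counts per cell, summed spot
#' intensity per cell, or a single spot's intensity.
#'
#' @param times numeric, strictly ascending, minutes.
#' @param values numeric, nonnegative, same length as `times`.
#' @param metadata optional named list carried along (cell id, species,
#'   dose, ...).
#' @return an object of class `trajectory`.
#' @export
trajectory <- function(times, values, metadata = list()) {
  .check(length(times) == length(values), "times and values lengths differ")
  .check(all(is.finite(times)) && all(diff(times) > 0),
         "times must be finite and strictly ascending")
  .check(all(is.finite(values)) && all(values >= 0),
         "values must be finite and nonnegative")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 metadata = metadata),
            class = "trajectory")
}

#' Nine quantitative descriptors of a response time course
#'
#' Computes, for one trajectory:
#' * `auc`: trapezoidal integral of the whole trajectory;
#' * `max` and `t_max`: global maximum and its time (earliest if tied);
#' * `rate_up`: maximum absolute OLS slope over all windows of three
#'   consecutive samples between time zero and `t_max`;
#' * `rate_down`: same over windows between `t_max` and the end;
#' * `t50_up`: first time the trajectory reaches half of `max` (linear
#'   interpolation between samples);
#' * `t50_down`: first time after `t_max` it falls back to half of `max`;
#' * `fwhm`: `t50_down - t50_up`;
#' * `adaptation_time`: first time after `t_max` at which the trajectory
#'   enters its lower plateau and stays there. The plateau baseline is the
#'   mean of the final `plateau_frac` of samples; "enters" means value
#'   `<= baseline + plateau_tol * (max - baseline)` for at least
#'   `plateau_run` consecutive samples.
#'
#' Windows with fewer than three points (short rise or decay phases) fall
#' back to the two-point slope. An all-zero trajectory returns zero `auc`,
#' `max` and rates, and `NA` for the time descriptors. Descriptors scale as
#' expected: multiplying the values by `c > 0` multiplies `auc`, `max` and
#' the rates by `c` and leaves all time descriptors unchanged.
#'
#' @param traj a [trajectory()], or anything coercible via
#'   `trajectory(times, values)`.
#' @param plateau_frac fraction of trailing samples defining the baseline.
#' @param plateau_tol plateau entry tolerance as a fraction of
#'   `max - baseline`.
#' @param plateau_run consecutive samples required inside the plateau band.
#' @return a one-row list of class `trajectory_descriptors` with the nine
#'   fields above.
#' @export
#' @examples
#' tri <- trajectory(0:10, c(0, 2, 4, 6, 8, 10, 8, 6, 4, 2, 0))
#' unlist(compute_descriptors(tri))
compute_descriptors <- function(traj, plateau_frac = 0.1,
                                plateau_tol = 0.05, plateau_run = 3L) {
  stopifnot(inherits(traj, "trajectory"))
  tt <- traj$times
  y <- traj$values
  n <- length(y)
  .check(n >= 3, "need at least 3 samples to compute descriptors")

  auc <- sum(diff(tt) * (head(y, -1) + tail(y, -1)) / 2)
  ymax <- max(y)
  if (ymax == 0) {
    out <- list(auc = 0, max = 0, rate_up = 0, rate_down = 0,
                t_max = NA_real_, t50_up = NA_real_, t50_down = NA_real_,
                fwhm = NA_real_, adaptation_time = NA_real_)
    class(out) <- c("trajectory_descriptors", class(out))
    return(out)
  }
  imax <- which.max(y) # earliest index at ties
  tmax <- tt[imax]

  slope3 <- function(idx) {
    # max |OLS slope| over 3-point windows wholly inside idx; 2-point
    # fallback when the phase is too short
    if (length(idx) < 2) return(0)
    if (length(idx) < 3) {
      return(abs(diff(y[idx]) / diff(tt[idx])))
    }
    s <- vapply(seq_len(length(idx) - 2), function(k) {
      w <- idx[k:(k + 2)]
      xc <- tt[w] - mean(tt[w])
      sum(xc * y[w]) / sum(xc^2)
    }, numeric(1))
    max(abs(s))
  }
  rate_up <- slope3(seq_len(imax))
  rate_down <- slope3(imax:n)

  half <- ymax / 2
  cross_up <- function() {
    # first upward crossing of half-max in [0, t_max]
    for (i in seq_len(imax)) {
      if (y[i] >= half) {
        if (i == 1) return(tt[1])
        return(tt[i - 1] + (half - y[i - 1]) * (tt[i] - tt[i - 1]) /
                 (y[i] - y[i - 1]))
      }
    }
    NA_real_
  }
  cross_down <- function() {
    # first downward crossing of half-max after t_max
    if (imax == n) return(NA_real_)
    for (i in (imax + 1):n) {
      if (y[i] <= half) {
        if (y[i - 1] == y[i]) return(tt[i])
        return(tt[i - 1] + (y[i - 1] - half) * (tt[i] - tt[i - 1]) /
                 (y[i - 1] - y[i]))
      }
    }
    NA_real_
  }
  t50u <- cross_up()
  t50d <- cross_down()
  fwhm <- if (is.na(t50u) || is.na(t50d)) NA_real_ else t50d - t50u

  n_tail <- max(1L, ceiling(plateau_frac * n))
  baseline <- mean(y[(n - n_tail + 1):n])
  band <- baseline + plateau_tol * (ymax - baseline)
  adapt <- NA_real_
  if (imax < n) {
    inside <- y <= band
    for (i in (imax + 1):n) {
      run_end <- min(n, i + plateau_run - 1L)
      if (all(inside[i:run_end])) { adapt <- tt[i]; break }
    }
  }
  out <- list(auc = auc, max = ymax, rate_up = rate_up,
              rate_down = rate_down, t_max = tmax, t50_up = t50u,
              t50_down = t50d, fwhm = fwhm, adaptation_time = adapt)
  class(out) <- c("trajectory_descriptors", class(out))
  out
}

#' @export
as.data.frame.trajectory_descriptors <- function(x, ...) {
  data.frame(auc = x$auc, max = x$max, rate_up = x$rate_up,
             rate_down = x$rate_down, t_max = x$t_max, t50_up = x$t50_up,
             t50_down = x$t50_down, fwhm = x$fwhm,
             adaptation_time = x$adaptation_time)
}

#' Descriptor table for many trajectories
#'
#' Applies [compute_descriptors()] to each trajectory in a long table
#' (grouped by an id column) and returns one row per trajectory with
#' metadata columns passed through.
#'
#' @param df long data.frame with a time column, a value column and an id
#'   column.
#' @param id,time,value column names.
#' @param ... passed to [compute_descriptors()].
#' @return data.frame with the id, descriptor columns, and any constant
#'   per-id metadata columns.
#' @export
descriptor_table <- function(df, id = "cell_id", time = "time",
                             value = "value", ...) {
  .check(all(c(id, time, value) %in% names(df)),
         sprintf("df must contain columns '%s', '%s', '%s'", id, time, value))
  ids <- unique(df[[id]])
  rows <- lapply(ids, function(g) {
    sub <- df[df[[id]] == g, , drop = FALSE]
    sub <- sub[order(sub[[time]]), , drop = FALSE]
    d <- as.data.frame(compute_descriptors(
      trajectory(sub[[time]], sub[[value]]), ...))
    meta <- sub[1, setdiff(names(sub), c(time, value)), drop = FALSE]
    cbind(meta, d, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sum single-spot tracks into a per-cell intensity trajectory
#'
#' At each grid time, sums the intensities of all tracks present; a track
#' contributes 0 outside its sampled range (absent spots carry no
#' intensity). Tracks sampled on other grids are linearly interpolated.
#'
#' @param tracks a `spot_tracks` data.frame (long format, columns `spot_id`,
#'   `time`, `intensity`) from [simulate_single_complexes()] or equivalent.
#' @param grid output time grid; defaults to the sorted unique track times.
#' @return a [trajectory()] of summed intensity on `grid` (all zeros for
#'   empty input).
#' @export
aggregate_cell_intensity <- function(tracks, grid = NULL) {
  if (is.null(grid)) grid <- sort(unique(tracks$time))
  .check(length(grid) > 0, "an output grid is required")
  total <- numeric(length(grid))
  if (nrow(tracks) > 0) {
    for (g in unique(tracks$spot_id)) {
      sub <- tracks[tracks$spot_id == g, , drop = FALSE]
      v <- approx(sub$time, sub$intensity, xout = grid, rule = 1)$y
      v[is.na(v)] <- 0
      total <- total + v
    }
  }
  trajectory(grid, pmax(total, 0))
}

#' Keep only tracks that formed early in the movie
#'
#' Retains tracks whose formation time is at or before `cutoff` (inclusive
#' boundary: a spot forming at exactly 4 minutes is kept). Formation times
#' are taken from the `formation_time` column if present, otherwise from
#' each track's first sampled time with positive intensity, otherwise its
#' first sampled time.
#'
#' @param tracks long-format track data.frame with `spot_id` and `time`
#'   columns.
#' @param cutoff minutes; default 4.
#' @return the filtered data.frame (possibly zero rows).
#' @export
filter_early_tracks <- function(tracks, cutoff = 4) {
  if (nrow(tracks) == 0) return(tracks)
  ids <- unique(tracks$spot_id)
  form <- vapply(ids, function(g) {
    sub <- tracks[tracks$spot_id == g, , drop = FALSE]
    if ("formation_time" %in% names(sub)) return(sub$formation_time[1])
    pos <- sub$time[sub$intensity > 0]
    if (length(pos)) min(pos) else min(sub$time)
  }, numeric(1))
  keep <- ids[form <= cutoff]
  tracks[tracks$spot_id %in% keep, , drop = FALSE]
}
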