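#' Specification of a synthetic single-cell spot-count cohort
#'
#' Describes the cohort of single-cell NEMO spot-count time courses the
#' generator emulates: a stimulus-dependent pulse that peaks within tens of
#' minutes and adapts back toward baseline, with amplitude following a Hill
#' function of dose whose effective midpoint is
#' `reference_ec50 / relative_affinity` — so higher-affinity ligands shift
#' the dose-response left without changing its shape.
#'
#' @param species_label text label carried into outputs.
#' @param relative_affinity dimensionless, > 0.
#' @param doses ligand concentrations (ng/mL), all > 0.
#' @param n_cells_per_dose cells per dose.
#' @param peak_time_mean minutes to the response peak (default 30).
#' @param adaptation_time_mean minutes to return near baseline (default 90,
#'   within the observed 60-120 min range).
#' @param max_amplitude saturating peak spot count per cell.
#' @param reference_ec50 half-maximal dose at affinity 1, ng/mL.
#' @param noise_cv lognormal coefficient of variation of the per-cell
#'   amplitude; 0 gives the deterministic mean curve.
#' @param frame_interval minutes between frames.
#' @param duration movie length, minutes; must cover
#'   `adaptation_time_mean`.
#' @param seed integer RNG seed.
#' @return an object of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(species_label = "human",
                                  relative_affinity = 1,
                                  doses = c(0.1, 0.3, 1, 3, 10, 30, 100),
                                  n_cells_per_dose = 20L,
                                  peak_time_mean = 30,
                                  adaptation_time_mean = 90,
                                  max_amplitude = 60,
                                  reference_ec50 = 1,
                                  noise_cv = 0.2,
                                  frame_interval = 2,
                                  duration = 120,
                                  seed = 1L) {
  .check(is.finite(relative_affinity) && relative_affinity > 0,
         "relative_affinity must be > 0")
  .check(all(doses > 0), "doses must be > 0")
  .check(n_cells_per_dose >= 1, "n_cells_per_dose must be >= 1")
  .check(peak_time_mean > 0 && adaptation_time_mean > peak_time_mean,
         "need 0 < peak_time_mean < adaptation_time_mean")
  .check(duration >= adaptation_time_mean,
         "duration must cover adaptation_time_mean")
  .check(max_amplitude > 0 && reference_ec50 > 0,
         "max_amplitude and reference_ec50 must be > 0")
  .check(noise_cv >= 0, "noise_cv must be >= 0")
  .check(frame_interval > 0, "frame_interval must be > 0")
  structure(list(species_label = species_label,
                 relative_affinity = relative_affinity, doses = doses,
                 n_cells_per_dose = as.integer(n_cells_per_dose),
                 peak_time_mean = peak_time_mean,
                 adaptation_time_mean = adaptation_time_mean,
                 max_amplitude = max_amplitude,
                 reference_ec50 = reference_ec50, noise_cv = noise_cv,
                 frame_interval = frame_interval, duration = duration,
                 seed = as.integer(seed)),
            class = "synthetic_cohort_spec")
}

# internal: gamma-like unit pulse g(t) = (t/tp)^a exp(-a (t/tp - 1)),
# peaking at exactly 1 at t = tp; the shape exponent a is solved so the
# pulse has decayed to `tail_frac` of its peak by t = ta.
.pulse_shape <- function(times, tp, ta, tail_frac = 0.05) {
  r <- ta / tp
  a <- log(tail_frac) / (log(r) - (r - 1)) # log g(ta) = a (log r - (r-1))
  s <- pmax(times, 0) / tp
  ifelse(s <= 0, 0, exp(a * (log(s) - (s - 1))))
}

#' Generate synthetic single-cell spot-count time courses
#'
#' Each cell's mean response is a gamma-like pulse peaking at
#' `peak_time_mean` and decaying to 5% of peak by `adaptation_time_mean`,
#' with expected amplitude `max_amplitude * dose / (dose + ec50_eff)` where
#' `ec50_eff = reference_ec50 / relative_affinity`. With `noise_cv > 0`,
#' each cell draws a lognormal amplitude factor (unit mean, CV `noise_cv`)
#' and frame counts are Poisson around the cell's mean curve, giving
#' nonnegative integer counts. With `noise_cv = 0` the deterministic mean
#' curve itself is returned (the noiseless limit used for exact
#' dose-response recovery checks).
#'
#' @param spec a [synthetic_cohort_spec()].
#' @return a long data.frame with columns `species`, `dose`, `cell_id`,
#'   `time`, `value`.
#' @export
#' @examples
#' spec <- synthetic_cohort_spec(doses = c(1, 10), n_cells_per_dose = 2,
#'                               noise_cv = 0)
#' head(gen_spot_count_timecourses(spec))
gen_spot_count_timecourses <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  times <- seq(0, spec$duration, by = spec$frame_interval)
  g <- .pulse_shape(times, spec$peak_time_mean, spec$adaptation_time_mean)
  ec50_eff <- spec$reference_ec50 / spec$relative_affinity
  set.seed(spec$seed)
  rows <- list()
  cell <- 0L
  for (dose in spec$doses) {
    amp <- spec$max_amplitude * dose / (dose + ec50_eff)
    for (i in seq_len(spec$n_cells_per_dose)) {
      cell <- cell + 1L
      if (spec$noise_cv > 0) {
        sdlog <- sqrt(log(1 + spec$noise_cv^2))
        fac <- rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
        vals <- rpois(length(times), lambda = amp * fac * g)
      } else {
        vals <- amp * g
      }
      rows[[cell]] <- data.frame(species = spec$species_label, dose = dose,
                                 cell_id = sprintf("cell_%04d", cell),
                                 time = times, value = vals)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate single-spot intensity tracks at SPT framing
#'
#' Wraps [simulate_single_complexes()] and resamples each track on a
#' 10-second frame grid, mirroring short-term single-particle imaging.
#'
#' @param params a [single_complex_params()].
#' @param n_tracks number of tracks to produce (overrides
#'   `params$n_spots`); 0 gives an empty table.
#' @param seed integer RNG seed (overrides `params$seed`).
#' @param frame_interval_s frame spacing in seconds (default 10).
#' @return a long data.frame with columns `spot_id`, `time_s`, `time`
#'   (minutes), `intensity`, `xbasal`, `bound`, and a `formation_times`
#'   attribute (minutes).
#' @export
gen_single_spot_tracks <- function(params, n_tracks = params$n_spots,
                                   seed = params$seed,
                                   frame_interval_s = 10) {
  stopifnot(inherits(params, "single_complex_params"))
  .check(n_tracks >= 0, "n_tracks must be >= 0")
  if (n_tracks == 0L) {
    out <- data.frame(spot_id = integer(0), time_s = numeric(0),
                      time = numeric(0), intensity = numeric(0),
                      xbasal = numeric(0), bound = integer(0))
    attr(out, "formation_times") <- numeric(0)
    return(out)
  }
  p <- params
  p$n_spots <- as.integer(n_tracks)
  p$seed <- as.integer(seed)
  p$record_interval <- frame_interval_s / 60
  tracks <- simulate_single_complexes(p)
  out <- data.frame(spot_id = tracks$spot_id,
                    time_s = tracks$time * 60, time = tracks$time,
                    intensity = tracks$intensity, xbasal = tracks$xbasal,
                    bound = tracks$bound)
  attr(out, "formation_times") <- attr(tracks, "formation_times")
  out
}

#' Specification of a synthetic melt curve
#'
#' A two-state unfolding model: fluorescence rises from a lower to an upper
#' baseline through a logistic transition centered at `midpoint` with width
#' `slope_scale`, plus linear pre/post baseline slopes and optional
#' Gaussian noise. An optional post-transition decline emulates the fall of
#' dye fluorescence after full unfolding.
#'
#' @param midpoint transition midpoint, degrees C; must lie inside `grid`.
#' @param slope_scale logistic width, degrees C.
#' @param baseline_pre,baseline_post baseline slopes, fluorescence per
#'   degree C.
#' @param grid strictly ascending temperature vector, degrees C.
#' @param noise_sd Gaussian noise SD, fluorescence a.u.
#' @param span fluorescence span of the transition.
#' @param post_peak_decline if `TRUE`, fluorescence decays above
#'   `decline_onset`.
#' @param decline_onset degrees C above `midpoint` at which the decline
#'   starts.
#' @param decline_rate fractional decay per degree C of the decline.
#' @param seed integer RNG seed.
#' @return an object of class `melt_curve_spec`.
#' @export
melt_curve_spec <- function(midpoint = 60, slope_scale = 1.5,
                            baseline_pre = 0, baseline_post = 0,
                            grid = seq(25, 99, by = 0.1), noise_sd = 0,
                            span = 1, post_peak_decline = FALSE,
                            decline_onset = 10, decline_rate = 0.02,
                            seed = 1L) {
  .check(all(diff(grid) > 0), "grid must be strictly ascending")
  .check(midpoint >= min(grid) && midpoint <= max(grid),
         "midpoint must lie within the grid range")
  .check(slope_scale > 0, "slope_scale must be > 0")
  .check(noise_sd >= 0, "noise_sd must be >= 0")
  .check(span > 0, "span must be > 0")
  structure(list(midpoint = midpoint, slope_scale = slope_scale,
                 baseline_pre = baseline_pre, baseline_post = baseline_post,
                 grid = grid, noise_sd = noise_sd, span = span,
                 post_peak_decline = isTRUE(post_peak_decline),
                 decline_onset = decline_onset,
                 decline_rate = decline_rate, seed = as.integer(seed)),
            class = "melt_curve_spec")
}

#' Generate a synthetic melt curve
#'
#' Evaluates the two-state model of [melt_curve_spec()] on its temperature
#' grid and adds Gaussian noise.
#'
#' @param spec a [melt_curve_spec()].
#' @param well well label for the output curve.
#' @return a [melt_curve()].
#' @export
gen_melt_curve <- function(spec, well = "A1") {
  stopifnot(inherits(spec, "melt_curve_spec"))
  tt <- spec$grid
  logistic <- 1 / (1 + exp(-(tt - spec$midpoint) / spec$slope_scale))
  f <- spec$span * logistic +
    spec$baseline_pre * (tt - min(tt)) * (1 - logistic) +
    spec$baseline_post * pmax(tt - spec$midpoint, 0) * logistic
  if (spec$post_peak_decline) {
    onset <- spec$midpoint + spec$decline_onset
    f <- f * exp(-spec$decline_rate * pmax(tt - onset, 0))
  }
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    f <- f + rnorm(length(tt), sd = spec$noise_sd)
  }
  melt_curve(tt, f, well)
}

#' Write a three-chain toy structure with known geometry
#'
#' Builds a PDB-format poly-alanine-like fixture (CA-only residues) for
#' exercising the structure utilities with analytically known answers:
#' chain A (a stand-in ligand) runs along x; chain B faces it at a
#' perpendicular offset of exactly `inter_chain_gap`, so each facing
#' residue pair's minimal distance is `inter_chain_gap`; chain C is placed
#' far from A, with its C-terminal CA exactly `terminal_separation` from
#' chain B's C-terminal CA.
#'
#' @param inter_chain_gap angstrom, > 0: minimal distance between facing
#'   residues of chains A and B.
#' @param terminal_separation angstrom, > 0: CA-CA distance between the
#'   C-terminal residues of chains B and C.
#' @param n_res residues per chain.
#' @param path optional file path; if given, the text is written there.
#' @return the PDB text, invisibly if `path` is given.
#' @export
gen_toy_structure <- function(inter_chain_gap = 4.4,
                              terminal_separation = 19.9, n_res = 5L,
                              path = NULL) {
  .check(inter_chain_gap > 0 && terminal_separation > 0, "gaps must be > 0")
  .check(n_res >= 2, "need at least 2 residues per chain")
  spacing <- 3.8 # consecutive CA-CA distance along each chain
  xs <- (seq_len(n_res) - 1) * spacing
  atoms <- rbind(
    data.frame(chain = "A", resno = seq_len(n_res), x = xs, y = 0, z = 0),
    data.frame(chain = "B", resno = seq_len(n_res), x = xs,
               y = inter_chain_gap, z = 0),
    data.frame(chain = "C", resno = seq_len(n_res),
               x = rev(xs)[1] - (n_res - seq_len(n_res)) * spacing,
               y = inter_chain_gap, z = terminal_separation))
  lines <- character(0)
  serial <- 0L
  for (ch in c("A", "B", "C")) {
    sub <- atoms[atoms$chain == ch, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial, ch, sub$resno[i], sub$x[i], sub$y[i], sub$z[i]))
    }
    lines <- c(lines, "TER")
  }
  txt <- paste(c(lines, "END", ""), collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}
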