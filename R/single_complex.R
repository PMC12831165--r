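#' Parameters for the hybrid single-complex (HyDeS) model
#'
#' Models the intensity dynamics of individual NEMO spots. Each spot `i`
#' carries two coupled ODEs: an intensity `I_i` (a continuous proxy for
#' ubiquitin chain size and NEMO activity at the complex) and a basal
#' deubiquitinase feedback `X_i` that is recruited in proportion to intensity
#' and degrades it:
#'
#' \deqn{dI/dt = P_{form} P_{bound} K_{growth}/(K_{limit}+I) - K_{dbasal} X I}
#' \deqn{dX/dt = K_{xbasal} I - K_{xdbasal} X}
#'
#' Spots form at regular intervals (`spot_interval`), `n_spots` in total,
#' approximating a single stimulated cell. Ligand affinity couples to the
#' dynamics through one of three mechanisms (`variant`):
#'
#' * `"bound_toggle"`: `P_bound` is a two-state telegraph process; the
#'   unbinding rate is `k_unbind_ref / affinity`, so contact duration is
#'   proportional to affinity and lower affinity means a lower fraction of
#'   time spent bound.
#' * `"growth_scale"`: `P_bound = 1` and the growth rate is scaled by a
#'   bounded monotone factor `affinity / (affinity + growth_k_half)`.
#' * `"dub_suppression"`: `P_bound = 1` and high affinity suppresses DUB
#'   activity via [dub_effective_rate()].
#'
#' @param kgrowth intensity growth coefficient, intensity * min^-1.
#' @param klimit saturation constant of growth, intensity units; defaults
#'   keep peak intensities below `klimit` (sub-saturated growth).
#' @param kdbasal DUB-mediated degradation coefficient, intensity^-1 min^-1.
#' @param kxbasal,kxdbasal feedback production and decay rates, min^-1.
#' @param k_bind telegraph binding rate, min^-1 (`bound_toggle` only).
#' @param k_unbind_ref reference unbinding rate at affinity 1, min^-1; the
#'   realized rate is `k_unbind_ref / affinity`.
#' @param affinity dimensionless relative ligand affinity, > 0.
#' @param variant one of `"bound_toggle"`, `"growth_scale"`,
#'   `"dub_suppression"`.
#' @param growth_k_half half-saturation of the `growth_scale` coupling.
#' @param use_telegraph if `FALSE` under `bound_toggle`, the binary telegraph
#'   gate is replaced by its constant mean-field occupancy
#'   `k_bind / (k_bind + k_unbind)`.
#' @param n_spots number of spots (default 75, one cell's response).
#' @param spot_interval minutes between consecutive spot formation times.
#' @param t_end simulated duration, minutes.
#' @param dt RK4 integration step, minutes.
#' @param record_interval output sampling interval, minutes.
#' @param seed integer RNG seed.
#' @return an object of class `single_complex_params`.
#' @seealso [simulate_single_complexes()], [steady_state_intensity()]
#' @export
single_complex_params <- function(kgrowth = 100, klimit = 50,
                                  kdbasal = 2e-3,
                                  kxbasal = 0.5, kxdbasal = 0.5,
                                  k_bind = 0.5, k_unbind_ref = 0.05,
                                  affinity = 1,
                                  variant = c("bound_toggle", "growth_scale",
                                              "dub_suppression"),
                                  growth_k_half = 0.1,
                                  use_telegraph = TRUE,
                                  n_spots = 75L, spot_interval = 0.5,
                                  t_end = 60, dt = 0.01,
                                  record_interval = 0.5, seed = 1L) {
  variant <- match.arg(variant)
  rates <- c(kgrowth, klimit, kdbasal, kxbasal, kxdbasal, k_bind,
             k_unbind_ref, growth_k_half)
  .check(all(is.finite(rates)) && all(rates >= 0),
         "all rates must be finite and >= 0")
  .check(is.finite(affinity) && affinity > 0, "affinity must be > 0")
  .check(n_spots >= 0 && n_spots == round(n_spots),
         "n_spots must be a nonnegative integer")
  .check(spot_interval >= 0, "spot_interval must be >= 0")
  .check(t_end > 0, "t_end must be > 0")
  .check(dt > 0, "dt must be > 0")
  .check(record_interval > 0, "record_interval must be > 0")
  structure(list(kgrowth = kgrowth, klimit = klimit, kdbasal = kdbasal,
                 kxbasal = kxbasal, kxdbasal = kxdbasal,
                 k_bind = k_bind, k_unbind_ref = k_unbind_ref,
                 affinity = affinity, variant = variant,
                 growth_k_half = growth_k_half,
                 use_telegraph = isTRUE(use_telegraph),
                 n_spots = as.integer(n_spots),
                 spot_interval = spot_interval, t_end = t_end, dt = dt,
                 record_interval = record_interval, seed = as.integer(seed)),
            class = "single_complex_params")
}

#' Affinity-suppressed effective DUB rate
#'
#' Under the `dub_suppression` coupling, higher ligand affinity inhibits
#' basal deubiquitinase activity at the complex:
#' `kdbasal' = 500 * kdbasal / (500 * affinity + 1)`. The multiplier 500
#' steepens the affinity dependence. The function is strictly decreasing in
#' affinity.
#'
#' @param kdbasal basal DUB rate coefficient.
#' @param affinity relative affinity, > 0.
#' @return the effective rate, same units as `kdbasal`.
#' @export
#' @examples
#' dub_effective_rate(1, 1)   # 500/501
#' dub_effective_rate(1, 10)  # 500/5001
dub_effective_rate <- function(kdbasal, affinity) {
  .check(all(is.finite(affinity)) && all(affinity > 0),
         "affinity must be > 0")
  .check(all(kdbasal >= 0), "kdbasal must be >= 0")
  500 * kdbasal / (500 * affinity + 1)
}

#' Right-hand side of the single-complex ODE pair
#'
#' Exposed mainly for inspection and testing; the simulator integrates the
#' same expressions in compiled code. Variant couplings are applied to the
#' rates before substitution, exactly as in [simulate_single_complexes()].
#'
#' @param I,X nonnegative state (intensity and feedback).
#' @param pform,pbound gate values in `{0, 1}` (or a fractional occupancy
#'   for mean-field `pbound`).
#' @param params a [single_complex_params()] object.
#' @return numeric vector `c(dI, dX)`.
#' @export
ode_rhs <- function(I, X, pform, pbound, params) {
  stopifnot(inherits(params, "single_complex_params"))
  .check(all(I >= 0) && all(X >= 0), "state must be nonnegative")
  eff <- .effective_rates(params)
  dI <- pform * pbound * eff$kgrowth / (params$klimit + I) -
    eff$kdbasal * X * I
  dX <- params$kxbasal * I - params$kxdbasal * X
  c(dI = dI, dX = dX)
}

# internal: variant-specific substitutions into (kgrowth, kdbasal)
.effective_rates <- function(params) {
  kg <- params$kgrowth
  kd <- params$kdbasal
  if (params$variant == "growth_scale") {
    kg <- kg * params$affinity / (params$affinity + params$growth_k_half)
  } else if (params$variant == "dub_suppression") {
    kd <- dub_effective_rate(kd, params$affinity)
  }
  list(kgrowth = kg, kdbasal = kd)
}

#' Simulate single-complex NEMO intensity tracks
#'
#' Spots form at times `0, spot_interval, 2 * spot_interval, ...`
#' (`n_spots` in total). Under the `bound_toggle` variant each spot carries
#' an independent telegraph process (rates `k_bind`,
#' `k_unbind_ref / affinity`) gating growth; switch times are sampled
#' exactly from exponential dwell distributions and the ODEs are integrated
#' with fixed-step RK4 between switches, the state continuous across them.
#' Under `growth_scale` and `dub_suppression` the gate is identically 1 and
#' affinity enters through the growth or DUB rate instead. Spots are not
#' removed once formed; tracks run to `t_end`.
#'
#' @param params a [single_complex_params()] object.
#' @return a data.frame of class `spot_tracks` in long format with columns
#'   `spot_id`, `time`, `intensity`, `xbasal`, `bound`, plus attributes
#'   `formation_times` and `params`.
#' @export
#' @examples
#' p <- single_complex_params(n_spots = 5, t_end = 20, seed = 1)
#' tr <- simulate_single_complexes(p)
#' head(tr)
simulate_single_complexes <- function(params) {
  stopifnot(inherits(params, "single_complex_params"))
  n <- params$n_spots
  form <- seq_len(n) * params$spot_interval - params$spot_interval
  rec <- seq(0, params$t_end, by = params$record_interval)
  eff <- .effective_rates(params)
  telegraph <- params$variant == "bound_toggle" && params$use_telegraph
  k_unbind <- params$k_unbind_ref / params$affinity
  pbound_const <- if (params$variant == "bound_toggle" && !params$use_telegraph) {
    if (params$k_bind + k_unbind > 0) {
      params$k_bind / (params$k_bind + k_unbind)
    } else 1
  } else 1
  if (n == 0L) {
    out <- data.frame(spot_id = integer(0), time = numeric(0),
                      intensity = numeric(0), xbasal = numeric(0),
                      bound = integer(0))
    attr(out, "formation_times") <- numeric(0)
    attr(out, "params") <- params
    class(out) <- c("spot_tracks", "data.frame")
    return(out)
  }
  set.seed(params$seed)
  sim <- hydes_simulate_cpp(form, rec, eff$kgrowth, params$klimit,
                            eff$kdbasal, params$kxbasal, params$kxdbasal,
                            telegraph, params$k_bind, k_unbind,
                            pbound_const, params$dt)
  out <- data.frame(spot_id = rep(seq_len(n), each = length(rec)),
                    time = rep(rec, n),
                    intensity = as.vector(sim$intensity),
                    xbasal = as.vector(sim$xbasal),
                    bound = as.vector(sim$bound))
  attr(out, "formation_times") <- form
  attr(out, "params") <- params
  class(out) <- c("spot_tracks", "data.frame")
  out
}

#' Steady-state intensity of a permanently gated spot
#'
#' With `Pform * Pbound = 1` held constant, the feedback nullcline gives
#' `X = (kxbasal / kxdbasal) I`, and the intensity fixed point is the unique
#' positive root `I*` of
#' `kgrowth / (klimit + I) = (kdbasal * kxbasal / kxdbasal) * I^2`,
#' i.e. of the cubic `c I^3 + c klimit I^2 - kgrowth = 0` with
#' `c = kdbasal * kxbasal / kxdbasal`. Variant couplings are applied to the
#' rates first, so the value matches the long-run limit of
#' [simulate_single_complexes()] with a constant unit gate.
#'
#' @param params a [single_complex_params()] object with positive `kgrowth`,
#'   `kdbasal`, `kxbasal`, `kxdbasal`.
#' @return the positive fixed-point intensity `I*`.
#' @export
#' @examples
#' p <- single_complex_params(kgrowth = 1, klimit = 1, kdbasal = 1,
#'                            kxbasal = 1, kxdbasal = 1)
#' steady_state_intensity(p) # root of I^3 + I^2 - 1 = 0, ~0.754878
steady_state_intensity <- function(params) {
  stopifnot(inherits(params, "single_complex_params"))
  eff <- .effective_rates(params)
  .check(eff$kgrowth > 0 && eff$kdbasal > 0 && params$kxbasal > 0 &&
           params$kxdbasal > 0,
         "kgrowth, kdbasal, kxbasal, kxdbasal must all be > 0")
  cc <- eff$kdbasal * params$kxbasal / params$kxdbasal
  f <- function(I) cc * I^2 * (params$klimit + I) - eff$kgrowth
  upper <- 1
  while (f(upper) < 0) upper <- upper * 2
  uniroot(f, c(0, upper), tol = 1e-12)$root
}
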