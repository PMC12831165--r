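#' Fit a Hill dose-response curve to mean responses
#'
#' Fits `y = y_max / (1 + (ka / x)^n)` by bounded nonlinear least squares
#' (Levenberg-Marquardt via \pkg{minpack.lm}) with data-driven multi-start:
#' `y_max` starts at the maximum response, `ka` at the dose nearest
#' half-maximum, and the Hill exponent `n` at each of several spans. `ka` is
#' the half-maximal dose, so `EC50 == ka`. Set `fix_n = TRUE` for the
#' one-site (`n = 1`) variant.
#'
#' Non-convergence (degenerate or constant responses) is reported through
#' the `converged` flag and a diagnostic message, never silently.
#'
#' @param doses positive doses (ng/mL), at least 4.
#' @param mean_responses mean response per dose.
#' @param fix_n fix the Hill exponent at 1.
#' @return an object of class `hill_fit`: list with `y_max`, `ka`, `n`,
#'   `r2`, `converged`, `message`, `fitted`, `doses`, `responses`.
#' @seealso [fit_logistic()], [ec50()]
#' @export
#' @examples
#' d <- c(1, 3.16, 10, 31.6, 100)
#' y <- 100 / (1 + (10 / d)^1)
#' fit_hill(d, y)$ka
fit_hill <- function(doses, mean_responses, fix_n = FALSE) {
  .check(length(doses) == length(mean_responses), "lengths differ")
  .check(length(doses) >= 4, "need at least 4 dose points")
  .check(all(doses > 0), "doses must be > 0")
  y <- mean_responses
  bad <- .degenerate_response(y)
  if (!is.null(bad)) return(.failed_fit("hill_fit", bad, doses, y))

  half <- max(y) / 2
  ka0 <- doses[which.min(abs(y - half))]
  starts <- expand.grid(y_max = max(y), ka = ka0,
                        n = if (fix_n) 1 else c(0.5, 1, 2, 4))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch({
      if (fix_n) {
        minpack.lm::nlsLM(y ~ y_max / (1 + (ka / doses)),
                          start = as.list(starts[i, c("y_max", "ka")]),
                          lower = c(1e-12, 1e-12),
                          control = minpack.lm::nls.lm.control(maxiter = 500))
      } else {
        minpack.lm::nlsLM(y ~ y_max / (1 + (ka / doses)^n),
                          start = as.list(starts[i, ]),
                          lower = c(1e-12, 1e-12, 1e-12),
                          control = minpack.lm::nls.lm.control(maxiter = 500))
      }
    }, error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(.failed_fit("hill_fit", "optimizer failed from all starts",
                       doses, y))
  }
  cf <- coef(best$fit)
  fitted_y <- predict(best$fit)
  structure(list(y_max = unname(cf["y_max"]), ka = unname(cf["ka"]),
                 n = if (fix_n) 1 else unname(cf["n"]),
                 r2 = .r2(y, fitted_y), converged = TRUE, message = "ok",
                 fitted = fitted_y, doses = doses, responses = y),
            class = "hill_fit")
}

#' Fit a logistic curve in log10 dose
#'
#' Fits `y = y_max / (1 + exp(-ka * (x - x0)))` where `x` is log10 dose;
#' `ka` is the slope per log10 dose and `x0` the log10 dose at half-maximal
#' response, so `EC50 = 10^x0` in dose units. This is the form used for
#' dose-response curves built from stochastic simulations.
#'
#' @param log10_doses log10-transformed doses, at least 4 points.
#' @param mean_responses mean response per dose.
#' @return an object of class `logistic_fit`: list with `y_max`, `ka`,
#'   `x0`, `r2`, `converged`, `message`, `fitted`, `log10_doses`,
#'   `responses`.
#' @export
#' @examples
#' x <- seq(-2, 2, length.out = 6)
#' y <- 1 / (1 + exp(-2 * (x - 0)))
#' fit_logistic(x, y)$x0
fit_logistic <- function(log10_doses, mean_responses) {
  .check(length(log10_doses) == length(mean_responses), "lengths differ")
  .check(length(log10_doses) >= 4, "need at least 4 points")
  x <- log10_doses
  y <- mean_responses
  bad <- .degenerate_response(y)
  if (!is.null(bad)) return(.failed_fit("logistic_fit", bad, x, y))

  x0_0 <- x[which.min(abs(y - max(y) / 2))]
  best <- NULL
  for (ka0 in c(0.5, 1, 2, 5)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ y_max / (1 + exp(-ka * (x - x0))),
                        start = list(y_max = max(y), ka = ka0, x0 = x0_0),
                        lower = c(1e-12, 1e-12, -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(.failed_fit("logistic_fit", "optimizer failed from all starts",
                       x, y))
  }
  cf <- coef(best$fit)
  fitted_y <- predict(best$fit)
  structure(list(y_max = unname(cf["y_max"]), ka = unname(cf["ka"]),
                 x0 = unname(cf["x0"]), r2 = .r2(y, fitted_y),
                 converged = TRUE, message = "ok", fitted = fitted_y,
                 log10_doses = x, responses = y),
            class = "logistic_fit")
}

.degenerate_response <- function(y) {
  if (all(!is.finite(y))) return("responses are not finite")
  if (max(y) <= 0) return("responses are all zero or negative")
  if (isTRUE(all.equal(var(y), 0))) return("responses are constant")
  NULL
}

.failed_fit <- function(cls, msg, x, y) {
  structure(list(y_max = NA_real_, ka = NA_real_,
                 n = NA_real_, x0 = NA_real_, r2 = NA_real_,
                 converged = FALSE, message = msg, fitted = NULL,
                 doses = x, responses = y),
            class = cls)
}

.r2 <- function(y, yhat) 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)

#' Half-maximal effective concentration of a fitted curve
#'
#' The dose at which the fitted sigmoid reaches half its maximum: `ka` for a
#' [fit_hill()] result, `10^x0` (back on the dose scale) for a
#' [fit_logistic()] result.
#'
#' @param fit a converged `hill_fit` or `logistic_fit`.
#' @return EC50 in ng/mL (dose units).
#' @export
ec50 <- function(fit) {
  .check(isTRUE(fit$converged), "fit did not converge; no EC50")
  if (inherits(fit, "hill_fit")) return(fit$ka)
  if (inherits(fit, "logistic_fit")) return(10^fit$x0)
  stop("unsupported fit object", call. = FALSE)
}

#' Fano factor (variance over mean) of a descriptor by group
#'
#' Groups rows of a descriptor table by the given keys and computes, per
#' group, the sample mean, sample variance (denominator `n - 1`) and their
#' ratio, the Fano factor — the standard variance-to-mean noise measure
#' (equal to 1 for Poisson variability). A group is excluded (flagged, Fano
#' `NA`) when its mean is zero or undefined, including empty and
#' single-observation groups.
#'
#' @param descriptor_table data.frame with the feature column and group key
#'   columns.
#' @param group_keys character vector of grouping column names.
#' @param feature name of the feature column.
#' @return data.frame with the group keys, `n`, `mean`, `variance`, `fano`,
#'   `excluded`.
#' @export
#' @examples
#' df <- data.frame(g = c("a", "a", "a"), auc = c(1, 2, 3))
#' group_fano(df, "g", "auc") # fano = 0.5
group_fano <- function(descriptor_table, group_keys, feature) {
  .check(feature %in% names(descriptor_table),
         sprintf("feature column '%s' not found", feature))
  .check(all(group_keys %in% names(descriptor_table)),
         "all group_keys must be columns of the table")
  key <- interaction(descriptor_table[group_keys], drop = TRUE, sep = "\r")
  rows <- lapply(levels(key), function(lv) {
    sub <- descriptor_table[key == lv, , drop = FALSE]
    v <- sub[[feature]]
    v <- v[is.finite(v)]
    m <- if (length(v)) mean(v) else NA_real_
    s2 <- if (length(v) >= 2) var(v) else NA_real_
    excluded <- !is.finite(m) || m == 0 || !is.finite(s2)
    fano <- if (excluded) NA_real_ else s2 / m
    cbind(sub[1, group_keys, drop = FALSE],
          data.frame(n = length(v), mean = m, variance = s2, fano = fano,
                     excluded = excluded), row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
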