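#' Bootstrap means of a descriptor from a small track set
#'
#' Resamples a set of per-track descriptor values with replacement
#' `n_iter` times at a fixed `sample_size` and returns the vector of
#' resample means. Defaults (100,000 iterations, sample size 5) suit
#' conditions where very few tracks were recovered and direct group
#' comparisons would be unstable.
#'
#' @param descriptors numeric vector of per-track descriptor values
#'   (nonempty).
#' @param n_iter number of bootstrap iterations.
#' @param sample_size with-replacement sample size per iteration.
#' @param seed integer RNG seed.
#' @param condition optional condition label carried in the result.
#' @param feature optional feature name carried in the result.
#' @return an object of class `bootstrap_result`: list with `means`
#'   (length `n_iter`), `condition`, `feature`, `n_iterations`,
#'   `sample_size`, `seed`.
#' @export
#' @examples
#' b <- bootstrap_descriptor_means(c(1, 2, 3), n_iter = 1000, seed = 1)
#' mean(b$means)
bootstrap_descriptor_means <- function(descriptors, n_iter = 100000L,
                                       sample_size = 5L, seed = 1L,
                                       condition = NA_character_,
                                       feature = NA_character_) {
  .check(length(descriptors) >= 1, "descriptors must be nonempty")
  .check(all(is.finite(descriptors)), "descriptors must be finite")
  .check(n_iter >= 1 && sample_size >= 1,
         "n_iter and sample_size must be >= 1")
  set.seed(seed)
  draws <- sample.int(length(descriptors), n_iter * sample_size,
                      replace = TRUE)
  m <- matrix(descriptors[draws], nrow = n_iter, ncol = sample_size)
  structure(list(means = rowMeans(m), condition = condition,
                 feature = feature, n_iterations = as.integer(n_iter),
                 sample_size = as.integer(sample_size),
                 seed = as.integer(seed)),
            class = "bootstrap_result")
}

#' Left-tailed two-sample t-test
#'
#' Tests the alternative hypothesis that the mean of `sample_a` is smaller
#' than the mean of `sample_b` (H1: mean(a) < mean(b)). Welch's
#' unequal-variance form is the default; set `var_equal = TRUE` for the
#' pooled Student form. When both samples are constant and identical, the
#' statistic is undefined; by convention p = 0.5 is returned with
#' `degenerate = TRUE`.
#'
#' @param sample_a,sample_b numeric vectors, each of length >= 2.
#' @param var_equal use the pooled-variance Student test.
#' @return list with `p_value`, `statistic`, `df`, `degenerate`.
#' @export
#' @examples
#' left_tailed_t_test(rnorm(10, 0), rnorm(10, 5))$p_value
left_tailed_t_test <- function(sample_a, sample_b, var_equal = FALSE) {
  .check(length(sample_a) >= 2 && length(sample_b) >= 2,
         "both samples must have at least 2 observations")
  if (sd(sample_a) == 0 && sd(sample_b) == 0) {
    if (mean(sample_a) == mean(sample_b)) {
      return(list(p_value = 0.5, statistic = NA_real_, df = NA_real_,
                  degenerate = TRUE))
    }
    # constant but different: separation is certain
    p <- if (mean(sample_a) < mean(sample_b)) 0 else 1
    return(list(p_value = p, statistic = NA_real_, df = NA_real_,
                degenerate = TRUE))
  }
  tt <- t.test(sample_a, sample_b, alternative = "less",
               var.equal = var_equal)
  list(p_value = unname(tt$p.value), statistic = unname(tt$statistic),
       df = unname(tt$parameter), degenerate = FALSE)
}

#' Pairwise left-tailed comparisons across conditions
#'
#' For every ordered pair of conditions, tests whether the first condition's
#' descriptor mean is below the second's. Returns the raw one-sided
#' p-values; an optional Benjamini-Hochberg adjustment column can be added
#' (off by default).
#'
#' @param values numeric descriptor values.
#' @param condition condition label per value.
#' @param var_equal see [left_tailed_t_test()].
#' @param adjust add a `p_adj` column (Benjamini-Hochberg).
#' @return data.frame with `condition_a`, `condition_b`, `p_value`,
#'   `statistic`, and optionally `p_adj`.
#' @export
compare_conditions <- function(values, condition, var_equal = FALSE,
                               adjust = FALSE) {
  .check(length(values) == length(condition), "lengths differ")
  conds <- unique(as.character(condition))
  .check(length(conds) >= 2, "need at least two conditions")
  pairs <- expand.grid(condition_a = conds, condition_b = conds,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$condition_a != pairs$condition_b, , drop = FALSE]
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- values[condition == pairs$condition_a[i]]
    b <- values[condition == pairs$condition_b[i]]
    tt <- left_tailed_t_test(a, b, var_equal = var_equal)
    data.frame(condition_a = pairs$condition_a[i],
               condition_b = pairs$condition_b[i],
               p_value = tt$p_value, statistic = tt$statistic)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (adjust) out$p_adj <- p.adjust(out$p_value, method = "BH")
  out
}
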