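#' Clopper-Pearson exact binomial confidence interval
#'
#' Two-sided exact interval for a binomial proportion, computed from beta
#' quantiles: the lower bound is the `alpha/2` quantile of
#' `Beta(x, n - x + 1)` (0 when `x = 0`) and the upper bound the
#' `1 - alpha/2` quantile of `Beta(x + 1, n - x)` (1 when `x = n`).
#'
#' @param successes Number of successes `x` (0..n).
#' @param trials Number of trials `n` (>= 1).
#' @param level Confidence level in (0,1), default 0.95.
#' @return Named numeric vector `c(low, high)` on the fraction scale.
#' @examples
#' round(100 * clopper_pearson_ci(10, 17), 1)  # 32.9 81.6
#' @export
clopper_pearson_ci <- function(successes, trials, level = 0.95) {
  if (length(trials) != 1L || is.na(trials) || trials < 1) {
    stop("trials must be a positive count")
  }
  if (successes < 0 || successes > trials) {
    stop("successes must lie in 0..trials")
  }
  stopifnot(level > 0, level < 1)
  alpha <- 1 - level
  low <- if (successes == 0) 0 else
    stats::qbeta(alpha / 2, successes, trials - successes + 1)
  high <- if (successes == trials) 1 else
    stats::qbeta(1 - alpha / 2, successes + 1, trials - successes)
  c(low = low, high = high)
}

#' Summarise NUMT transmission across father-offspring pairs
#'
#' @param transmitted Logical vector, one entry per father-offspring pair:
#'   did the offspring inherit the father's NUMT?
#' @param level Confidence level for the exact binomial interval.
#' @return A list of class `transmission_summary` with counts, the
#'   transmission proportion and Clopper-Pearson bounds, all proportions
#'   on the percentage scale.
#' @examples
#' transmission_summary(rep(c(TRUE, FALSE), c(10, 7)))
#' @export
transmission_summary <- function(transmitted, level = 0.95) {
  transmitted <- as.logical(transmitted)
  if (!length(transmitted) || anyNA(transmitted)) {
    stop("transmission_summary needs a non-empty logical vector")
  }
  n <- length(transmitted)
  x <- sum(transmitted)
  ci <- clopper_pearson_ci(x, n, level)
  structure(list(n_pairs = n, n_transmitted = x,
                 proportion = 100 * x / n,
                 ci_low = 100 * ci[["low"]], ci_high = 100 * ci[["high"]],
                 ci_level = level),
            class = "transmission_summary")
}

#' @export
print.transmission_summary <- function(x, ...) {
  cat(sprintf(
    "NUMT transmission: %d of %d father-offspring pairs (%.1f%%, %.0f%% CI %.1f-%.1f)\n",
    x$n_transmitted, x$n_pairs, x$proportion, 100 * x$ci_level,
    x$ci_low, x$ci_high))
  invisible(x)
}

#' Determine genetic sex from sex-chromosome depth
#'
#' A sample is called female when the mean chromosome X depth is at least
#' ten times the mean chromosome Y depth (a zero Y depth is female);
#' otherwise male.
#'
#' @param depth_x Mean chrX depth (> 0).
#' @param depth_y Mean chrY depth (>= 0).
#' @return `"female"` or `"male"` (vectorised).
#' @export
determine_sex <- function(depth_x, depth_y) {
  if (any(!is.finite(depth_x)) || any(depth_x <= 0)) {
    stop("depth_x must be positive")
  }
  if (any(!is.finite(depth_y)) || any(depth_y < 0)) {
    stop("depth_y must be non-negative")
  }
  ifelse(depth_y == 0 | depth_x >= 10 * depth_y, "female", "male")
}

#' Count extreme nuclear heterozygotes
#'
#' Contamination heuristic: among nuclear heterozygous sites, count allele
#' fractions falling beyond the 25-75% range (strictly below `low` or
#' strictly above `high`; the endpoints themselves are within range).
#' Contaminated samples show an excess of such sites.
#'
#' @param het_afs Numeric vector of heterozygous-site allele fractions in
#'   \[0,1\].
#' @param low,high Range bounds, defaults 0.25 and 0.75.
#' @return Integer count.
#' @export
count_extreme_heterozygotes <- function(het_afs, low = 0.25, high = 0.75) {
  stopifnot(low < high)
  if (any(het_afs < 0 | het_afs > 1, na.rm = TRUE)) {
    stop("allele fractions must lie in [0,1]")
  }
  sum(het_afs < low | het_afs > high, na.rm = TRUE)
}
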