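# Binomial proportion confidence intervals. Two methods are carried side by
# side because published validation tables in this field mix them: the
# Wilson score interval (well-behaved at zero events) and the exact
# Clopper-Pearson interval (conservative coverage).

# Vectorised bounds; x, n may be vectors. Used by the scalar constructors
# and by the coverage simulations.
.wilson_bounds <- function(x, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- (z / denom) * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  cbind(lower = pmax(0, centre - half), upper = pmin(1, centre + half))
}

.clopper_pearson_bounds <- function(x, n, level = 0.95) {
  alpha <- 1 - level
  lower <- ifelse(x == 0, 0, stats::qbeta(alpha / 2, x, n - x + 1))
  upper <- ifelse(x == n, 1, stats::qbeta(1 - alpha / 2, x + 1, n - x))
  cbind(lower = lower, upper = upper)
}

.new_proportion_ci <- function(events, trials, bounds, method, level) {
  structure(
    list(events = as.integer(events), trials = as.integer(trials),
         point = events / trials,
         lower = unname(bounds[1, "lower"]),
         upper = unname(bounds[1, "upper"]),
         method = method, level = level),
    class = "proportion_ci"
  )
}

.check_ci_args <- function(events, trials, level) {
  if (length(events) != 1 || length(trials) != 1)
    stop("events and trials must be scalars")
  if (is.na(trials) || trials < 1) stop("trials must be >= 1")
  if (is.na(events) || events < 0 || events > trials)
    stop("events must lie in 0..trials")
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
}

#' Wilson score interval for a binomial proportion
#'
#' Inverts the score test: the interval is centred at
#' \eqn{(\hat p + z^2/2n)/(1 + z^2/n)} with half-width
#' \eqn{z\sqrt{\hat p(1-\hat p)/n + z^2/4n^2}/(1+z^2/n)}. At zero events the
#' upper bound is \eqn{z^2/(n+z^2)}, which is what makes the method usable
#' for the all-benign classes of a validation cohort.
#'
#' @param events Number of successes (0..trials).
#' @param trials Number of trials (>= 1).
#' @param level Confidence level in (0, 1); default 0.95.
#' @return A `proportion_ci` object with fields `events`, `trials`, `point`,
#'   `lower`, `upper`, `method`, `level`.
#' @examples
#' wilson_interval(0, 68)   # upper ~ 0.053
#' wilson_interval(7, 11)   # ~ 0.354 .. 0.848
#' @export
wilson_interval <- function(events, trials, level = 0.95) {
  .check_ci_args(events, trials, level)
  .new_proportion_ci(events, trials, .wilson_bounds(events, trials, level),
                     "wilson", level)
}

#' Clopper-Pearson exact interval for a binomial proportion
#'
#' Exact interval from beta quantiles: lower bound
#' `qbeta(alpha/2, x, n - x + 1)` (zero when `x = 0`), upper bound
#' `qbeta(1 - alpha/2, x + 1, n - x)` (one when `x = n`). For zero events
#' the upper bound reduces to \eqn{1 - (\alpha/2)^{1/n}}.
#'
#' @inheritParams wilson_interval
#' @return A `proportion_ci` object.
#' @examples
#' clopper_pearson_interval(1, 2)   # ~ 0.013 .. 0.987
#' @export
clopper_pearson_interval <- function(events, trials, level = 0.95) {
  .check_ci_args(events, trials, level)
  .new_proportion_ci(events, trials,
                     .clopper_pearson_bounds(events, trials, level),
                     "clopper_pearson", level)
}

#' Binomial proportion interval by method name
#'
#' @inheritParams wilson_interval
#' @param method `"wilson"` or `"clopper_pearson"`.
#' @return A `proportion_ci` object.
#' @export
binom_ci <- function(events, trials, level = 0.95,
                     method = c("wilson", "clopper_pearson")) {
  method <- match.arg(method)
  switch(method,
         wilson = wilson_interval(events, trials, level),
         clopper_pearson = clopper_pearson_interval(events, trials, level))
}

#' @export
print.proportion_ci <- function(x, ...) {
  cat(sprintf("%d/%d = %.1f%% (%d%% CI %.1f-%.1f%%, %s)\n",
              x$events, x$trials, 100 * x$point, round(100 * x$level),
              100 * x$lower, 100 * x$upper, x$method))
  invisible(x)
}

# Display rounding used in reports: whole percent, half away from zero.
.round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a proportion interval as whole percents
#'
#' Rounds point estimate and bounds to whole percent, half away from zero —
#' the convention used throughout the package's reports.
#'
#' @param ci A `proportion_ci` object.
#' @return Character string like `"64% (95% CI 35-85%)"`.
#' @export
format_percent_ci <- function(ci) {
  sprintf("%d%% (%d%% CI %d-%d%%)",
          .round_half_up(100 * ci$point), round(100 * ci$level),
          .round_half_up(100 * ci$lower), .round_half_up(100 * ci$upper))
}
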