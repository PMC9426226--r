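#' Directional r squared
#'
#' Pearson's r between estimates and targets, reported as `r * |r|`: the
#' proportion of variance explained, signed by the direction of the
#' relationship. A two-sided pretest p-value from the exact t transform of
#' r (`t = r * sqrt((n - 2) / (1 - r^2))`, `n - 2` df) is attached, along
#' with the number of complete pairs used. If either vector is constant
#' (e.g. the constant chance estimate of percent agreement) the
#' correlation does not exist and `NA` is returned with a message
#' attribute.
#'
#' @param x numeric vector of estimates.
#' @param y numeric vector of targets, same length; `NA` pairs dropped.
#' @return numeric scalar `dr2` in `[-1, 1]` (or `NA`), with attributes
#'   `p.value` and `n`.
#' @examples
#' directional_r2(1:10, (1:10)^2)
#' @export
directional_r2 <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3)
    return(structure(NA_real_, p.value = NA_real_, n = n,
                     reason = "fewer than 3 complete pairs"))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(NA_real_, p.value = NA_real_, n = n,
                     reason = "constant vector: correlation undefined"))
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  structure(r * abs(r), p.value = p, n = n)
}

#' Mean of errors (scalar accuracy)
#'
#' Mean absolute deviation of the estimates from their targets across
#' sessions, with the standard deviation of the absolute errors and a
#' normal-approximation 95% confidence interval
#' (`mean +/- 1.96 * sd / sqrt(n)`) attached.
#'
#' @inheritParams directional_r2
#' @return numeric scalar `m_e >= 0` with attributes `sd`, `conf.int`, `n`.
#' @export
mean_of_errors <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) == 0) stop("no complete pairs")
  err <- abs(x - y)
  m <- mean(err)
  s <- stats::sd(err)
  half <- if (is.na(s)) NA_real_ else 1.96 * s / sqrt(length(err))
  structure(m, sd = s, conf.int = c(m - half, m + half), n = length(err))
}

#' Error of means (vector bias)
#'
#' Mean estimate minus mean target: over- and under-estimation of
#' individual sessions offset during averaging, so `|e_m|` never exceeds
#' the mean of errors. A 95% CI based on the paired differences is
#' attached.
#'
#' @inheritParams directional_r2
#' @return numeric scalar `e_m` with attributes `sd`, `conf.int`, `n`.
#' @export
error_of_means <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) == 0) stop("no complete pairs")
  d <- x - y
  m <- mean(d)
  s <- stats::sd(d)
  half <- if (is.na(s)) NA_real_ else 1.96 * s / sqrt(length(d))
  structure(m, sd = s, conf.int = c(m - half, m + half), n = length(d))
}

#' Benchmark verdicts for an index's accuracy scores
#'
#' Predictive accuracy is judged against `dr2 > 0.8` (primary) with
#' `dr2 > 0.67` as tentative acceptance; approximating accuracy against
#' `m_e` below a threshold (default 0.2). Undefined inputs yield
#' `"not assessable"`.
#'
#' @param dr2 directional r squared of the index against its estimand.
#' @param m_e mean of errors of the index against its estimand.
#' @param primary,tentative dr2 cutoffs.
#' @param secondary m_e cutoff.
#' @return named character vector with elements `primary`, `tentative`,
#'   `secondary`, each `"pass"`, `"fail"` or `"not assessable"`.
#' @export
benchmark_verdicts <- function(dr2, m_e, primary = 0.8, tentative = 0.67,
                               secondary = 0.2) {
  verdict <- function(value, cutoff, greater) {
    if (is.na(value)) return("not assessable")
    ok <- if (greater) value > cutoff else value < cutoff
    if (ok) "pass" else "fail"
  }
  c(primary = verdict(dr2, primary, TRUE),
    tentative = verdict(dr2, tentative, TRUE),
    secondary = verdict(m_e, secondary, FALSE))
}

## Pretest stars at the .05/.01/.001 tiers (reported as a pretest, not a
## significance claim).
pretest_stars <- function(p) {
  if (is.na(p)) return("")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}
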