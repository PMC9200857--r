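#' Bland-Altman agreement analysis
#'
#' Paired-method agreement between annotated and predicted recording-level
#' category fractions. The error is `predicted - annotated`; a two-tailed
#' one-sample t-test (df = n - 1) tests the null hypothesis of zero mean
#' error, and the +/- 2 SD band describes its spread. An optional monthly
#' developmental change `delta` (same units as the fractions, per month)
#' can be attached for context.
#'
#' @param annotated,predicted paired numeric vectors (n >= 3), typically
#'   in percentage points.
#' @param delta optional monthly-change slope for the band overlay.
#' @return a `bland_altman` list: `mean_error`, `sd_error`, `band`
#'   (mean +/- 2 SD), `t`, `df`, `p`, `n`, `delta`,
#'   `within_delta_fraction` (when `delta` given).
#' @export
bland_altman <- function(annotated, predicted, delta = NULL) {
  stopifnot(length(annotated) == length(predicted))
  n <- length(annotated)
  if (n < 3) stop("need at least 3 paired values")
  e <- predicted - annotated
  m <- mean(e)
  s <- stats::sd(e)
  t_stat <- if (s > 0) m / (s / sqrt(n)) else 0
  p <- if (s > 0) 2 * stats::pt(-abs(t_stat), df = n - 1) else 1
  out <- list(mean_error = m, sd_error = s, band = c(m - 2 * s, m + 2 * s),
              t = t_stat, df = n - 1, p = p, n = n, errors = e,
              delta = delta)
  if (!is.null(delta))
    out$within_delta_fraction <- mean(abs(e) <= abs(delta))
  structure(out, class = "bland_altman")
}

#' Monthly developmental change of a category fraction
#'
#' Ordinary least-squares slope of the category's occupancy fraction
#' against age, reported in percentage points per month.
#'
#' @param ages ages in months (n >= 3 with positive variance).
#' @param fractions occupancy fractions in `[0, 1]`.
#' @return slope in percentage points / month.
#' @export
monthly_delta <- function(ages, fractions) {
  stopifnot(length(ages) == length(fractions))
  if (length(ages) < 3) stop("need at least 3 points")
  if (stats::var(ages) == 0) stop("age variance is zero")
  unname(stats::coef(stats::lm(fractions ~ ages))[2]) * 100
}

#' Correlation with two-tailed p value
#'
#' Pearson's r (p from the t transform) or Spearman's rho (exact null
#' distribution for small n without ties, t approximation otherwise), both
#' against the two-tailed null of zero correlation.
#'
#' @param x,y numeric vectors (n >= 3).
#' @param method `"pearson"` or `"spearman"`.
#' @return list: `estimate`, `p`, `n`, `method`.
#' @export
correlations <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         alternative = "two.sided"))
  list(estimate = unname(ct$estimate), p = ct$p.value, n = length(x),
       method = method)
}

#' Battery of tests comparing two dependent overlapping correlations
#'
#' Tests `H0: r.jk = r.jh` for correlations sharing the variable `j`
#' (two dependent groups, overlapping), given the three pairwise
#' correlations and n. Implements the ten classical sub-tests from the
#' published statistical literature: Pearson-Filon's z, Hotelling's t,
#' Williams' t, Olkin's z, Dunn & Clark's z, Hendrickson-Stanley-Hills' t,
#' Steiger's averaged-correlation z, Meng-Rosenthal-Rubin's z,
#' Hittner-May-Silver's backtransformed-average z, and Zou's confidence
#' interval for `r.jk - r.jh`.
#'
#' @param r.jk,r.jh the two correlations being compared (share variable j).
#' @param r.kh the correlation between the non-shared variables.
#' @param n sample size (>= 4).
#' @param alpha significance level for Zou's interval.
#' @return a `cocor_result`: data.frame `tests` (statistic, df, p per
#'   sub-test), `zou_ci`, and the inputs.
#' @export
cocor_battery <- function(r.jk, r.jh, r.kh, n, alpha = 0.05) {
  if (any(abs(c(r.jk, r.jh, r.kh)) > 1)) stop("correlations must be in [-1, 1]")
  if (n < 4) stop("n must be at least 4")
  R <- matrix(c(1, r.jk, r.jh, r.jk, 1, r.kh, r.jh, r.kh, 1), 3, 3)
  detR <- det(R)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("correlation triple is not positive semi-definite")
  r12 <- r.jk; r13 <- r.jh; r23 <- r.kh
  z12 <- atanh(r12); z13 <- atanh(r13)
  two_p_z <- function(z) 2 * stats::pnorm(-abs(z))
  two_p_t <- function(t, df) 2 * stats::pt(-abs(t), df)

  # covariance term of Dunn & Clark (1969)
  covar <- function(a, b, c) {
    (c * (1 - a^2 - b^2) - 0.5 * a * b * (1 - a^2 - b^2 - c^2)) /
      ((1 - a^2) * (1 - b^2))
  }

  res <- list()

  # (1) Pearson & Filon (1898)
  k <- r23 * (1 - r12^2 - r13^2) -
    0.5 * r12 * r13 * (1 - r12^2 - r13^2 - r23^2)
  z1 <- (r12 - r13) * sqrt(n) /
    sqrt((1 - r12^2)^2 + (1 - r13^2)^2 - 2 * k)
  res$pearson1898 <- c(statistic = z1, df = NA, p = two_p_z(z1))

  # (2) Hotelling (1940)
  t2 <- (r12 - r13) * sqrt((n - 3) * (1 + r23) / (2 * detR))
  res$hotelling1940 <- c(statistic = t2, df = n - 3, p = two_p_t(t2, n - 3))

  # (3) Williams (1959)
  rbar <- (r12 + r13) / 2
  t3 <- (r12 - r13) * sqrt((n - 1) * (1 + r23) /
    (2 * detR * (n - 1) / (n - 3) + rbar^2 * (1 - r23)^3))
  res$williams1959 <- c(statistic = t3, df = n - 3, p = two_p_t(t3, n - 3))

  # (4) Olkin (1967)
  z4 <- (r12 - r13) * sqrt(n) /
    sqrt((1 - r12^2)^2 + (1 - r13^2)^2 - 2 * r23^3 -
         (2 * r23 - r12 * r13) * (1 - r12^2 - r13^2 - r23^2))
  res$olkin1967 <- c(statistic = z4, df = NA, p = two_p_z(z4))

  # (5) Dunn & Clark (1969)
  c5 <- covar(r12, r13, r23)
  z5 <- (z12 - z13) * sqrt((n - 3) / (2 - 2 * c5))
  res$dunn1969 <- c(statistic = z5, df = NA, p = two_p_z(z5))

  # (6) Hendrickson, Stanley & Hills (1970)
  t6 <- (r12 - r13) * sqrt((n - 3) * (1 + r23)) /
    sqrt(2 * detR + ((r12 - r13)^2 * (1 - r23)^3) / (4 * (n - 3)))
  res$hendrickson1970 <- c(statistic = t6, df = n - 3,
                           p = two_p_t(t6, n - 3))

  # (7) Steiger (1980): Dunn & Clark with average correlation
  c7 <- (r23 * (1 - 2 * rbar^2) - 0.5 * rbar^2 *
           (1 - 2 * rbar^2 - r23^2)) / (1 - rbar^2)^2
  z7 <- (z12 - z13) * sqrt((n - 3) / (2 - 2 * c7))
  res$steiger1980 <- c(statistic = z7, df = NA, p = two_p_z(z7))

  # (8) Meng, Rosenthal & Rubin (1992)
  rsq <- (r12^2 + r13^2) / 2
  f <- min((1 - r23) / (2 * (1 - rsq)), 1)
  h <- (1 - f * rsq) / (1 - rsq)
  z8 <- (z12 - z13) * sqrt((n - 3) / (2 * (1 - r23) * h))
  res$meng1992 <- c(statistic = z8, df = NA, p = two_p_z(z8))

  # (9) Hittner, May & Silver (2003): backtransformed average Fisher z
  rbz <- tanh((z12 + z13) / 2)
  c9 <- (r23 * (1 - 2 * rbz^2) - 0.5 * rbz^2 *
           (1 - 2 * rbz^2 - r23^2)) / (1 - rbz^2)^2
  z9 <- (z12 - z13) * sqrt((n - 3) / (2 - 2 * c9))
  res$hittner2003 <- c(statistic = z9, df = NA, p = two_p_z(z9))

  # (10) Zou (2007) confidence interval for r12 - r13
  zc <- stats::qnorm(1 - alpha / 2)
  l1 <- tanh(z12 - zc / sqrt(n - 3)); u1 <- tanh(z12 + zc / sqrt(n - 3))
  l2 <- tanh(z13 - zc / sqrt(n - 3)); u2 <- tanh(z13 + zc / sqrt(n - 3))
  corr_r <- covar(r12, r13, r23)
  L <- r12 - r13 - sqrt((r12 - l1)^2 + (u2 - r13)^2 -
                          2 * corr_r * (r12 - l1) * (u2 - r13))
  U <- r12 - r13 + sqrt((u1 - r12)^2 + (r13 - l2)^2 -
                          2 * corr_r * (u1 - r12) * (r13 - l2))

  tests <- do.call(rbind, lapply(names(res), function(nm)
    data.frame(test = nm, statistic = res[[nm]][["statistic"]],
               df = res[[nm]][["df"]], p = res[[nm]][["p"]],
               stringsAsFactors = FALSE)))
  structure(list(tests = tests, zou_ci = c(lower = L, upper = U),
                 r.jk = r.jk, r.jh = r.jh, r.kh = r.kh, n = n,
                 alpha = alpha),
            class = "cocor_result")
}

#' Quadratic age-trajectory fit with confidence band
#'
#' Degree-2 least-squares fit of a category fraction against age with a
#' pointwise 95% confidence band, as used to describe nonlinear
#' (bell-shaped) developmental trajectories.
#'
#' @param ages ages in months (n >= 4, at least 3 distinct values).
#' @param fractions occupancy fractions.
#' @param conf confidence level.
#' @param grid ages at which to evaluate the band (default: the data).
#' @return list: `coefficients` (intercept, linear, quadratic), `fit`
#'   data.frame (`age`, `fit`, `lwr`, `upr`), `model`.
#' @export
quadratic_trajectory <- function(ages, fractions, conf = 0.95,
                                 grid = NULL) {
  stopifnot(length(ages) == length(fractions))
  if (length(ages) < 4) stop("need at least 4 points")
  if (length(unique(ages)) < 3) stop("design is collinear: need 3 distinct ages")
  fit <- stats::lm(fractions ~ ages + I(ages^2))
  grid <- grid %||% sort(unique(ages))
  pr <- stats::predict(fit, newdata = data.frame(ages = grid),
                       interval = "confidence", level = conf)
  list(coefficients = unname(stats::coef(fit)),
       fit = data.frame(age = grid, fit = pr[, "fit"], lwr = pr[, "lwr"],
                        upr = pr[, "upr"]),
       model = fit)
}

#' Posture and movement transition rates
#'
#' Counts label changes between consecutive retained frames on each track
#' and divides by the analyzed duration in minutes. A gap in the retained
#' frames (masked-out stretch) does not count as a transition.
#'
#' @param posture,movement per-frame hard labels.
#' @param hop_s frame hop in seconds (default 60/52).
#' @param mask logical retain mask (e.g. from [acd_filter()]).
#' @return list: `posture_per_min`, `movement_per_min`,
#'   `analyzed_minutes`.
#' @export
transition_rates <- function(posture, movement, hop_s = 60 / 52,
                             mask = NULL) {
  stopifnot(length(posture) == length(movement))
  n <- length(posture)
  if (n < 2) stop("need at least 2 frames")
  if (is.null(mask)) mask <- rep(TRUE, n)
  idx <- which(mask)
  minutes <- length(idx) * hop_s / 60
  adjacent <- which(diff(idx) == 1)
  a <- idx[adjacent]; b <- idx[adjacent + 1]
  list(posture_per_min = sum(posture[a] != posture[b]) / minutes,
       movement_per_min = sum(movement[a] != movement[b]) / minutes,
       analyzed_minutes = minutes)
}
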