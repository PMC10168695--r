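#' Summary statistics for a group
#'
#' Convenience container for `(mean, SEM, n)` triples, used to run Welch
#' tests directly on published summary data.
#'
#' @param mean Group mean.
#' @param sem Standard error of the mean.
#' @param n Number of biological replicates.
#' @return An object of class `group_summary`.
#' @export
group_summary <- function(mean, sem, n) {
  stopifnot(is.numeric(mean), is.numeric(sem), sem >= 0, n >= 2)
  structure(list(mean = mean, sem = sem, n = as.integer(n)), class = "group_summary")
}

as_summary <- function(x) {
  if (inherits(x, "group_summary")) return(x)
  x <- as.numeric(x)
  if (length(x) < 2) stop("need n >= 2 per group")
  group_summary(mean(x), stats::sd(x) / sqrt(length(x)), length(x))
}

#' Welch two-sample (or paired) t-test
#'
#' Unpaired: `t = (m1 - m2) / sqrt(sem1^2 + sem2^2)` with Welch-Satterthwaite
#' degrees of freedom; this form accepts either raw samples or `(mean, SEM,
#' n)` summaries ([group_summary()]), so published group summaries can be
#' re-tested directly. Paired: a one-sample t-test on the differences
#' (variance pooling is moot on differences), raw samples only.
#'
#' @param x,y Numeric samples, or `group_summary` objects (unpaired only).
#' @param paired Logical.
#' @return An object of class `welch_result` with `t`, `df`, `p` (two-sided)
#'   and per-group summaries.
#' @export
welch_t <- function(x, y, paired = FALSE) {
  if (paired) {
    x <- as.numeric(x)
    y <- as.numeric(y)
    if (length(x) != length(y)) stop("paired length mismatch")
    if (length(x) < 2) stop("need n >= 2")
    d <- x - y
    n <- length(d)
    se <- stats::sd(d) / sqrt(n)
    t <- mean(d) / se
    df <- n - 1
  } else {
    sx <- as_summary(x)
    sy <- as_summary(y)
    v1 <- sx$sem^2
    v2 <- sy$sem^2
    t <- (sx$mean - sy$mean) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (sx$n - 1) + v2^2 / (sy$n - 1))
  }
  p <- 2 * stats::pt(-abs(t), df)
  out <- list(
    t = t, df = df, p = p, paired = paired,
    groups = if (paired) NULL else list(x = as_summary(x), y = as_summary(y))
  )
  class(out) <- "welch_result"
  out
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf(
    "<welch_result%s> t = %.4g, df = %.4g, p = %.3g (two-sided)\n",
    if (x$paired) ", paired" else "", x$t, x$df, x$p
  ))
  invisible(x)
}

#' Mean difference (point estimate of effect size)
#'
#' Unpaired: difference of group means `mean(x) - mean(y)`; paired: mean of
#' the pairwise differences. Accepts [group_summary()] objects for the
#' unpaired case.
#'
#' @inheritParams welch_t
#' @return The mean difference (units of the input).
#' @export
mean_difference <- function(x, y, paired = FALSE) {
  if (paired) {
    x <- as.numeric(x)
    y <- as.numeric(y)
    if (length(x) != length(y)) stop("paired length mismatch")
    mean(x - y)
  } else {
    mx <- if (inherits(x, "group_summary")) x$mean else mean(as.numeric(x))
    my <- if (inherits(y, "group_summary")) y$mean else mean(as.numeric(y))
    mx - my
  }
}

# BCa interval machinery. Conventions (documented in the methods vignette):
# bias correction z0 = qnorm(#{theta* < theta_hat} / B) (Efron); acceleration
# from the jackknife skewness of the statistic; adjusted percentile
# endpoints taken with quantile type 7 (linear interpolation).
bca_interval <- function(thetas, theta_hat, jack, conf) {
  alpha <- (1 - conf) / 2
  if (stats::sd(thetas) == 0) {
    return(c(theta_hat, theta_hat))
  }
  prop <- mean(thetas < theta_hat)
  prop <- min(max(prop, 1 / (length(thetas) + 1)), length(thetas) / (length(thetas) + 1))
  z0 <- stats::qnorm(prop)
  jm <- mean(jack)
  num <- sum((jm - jack)^3)
  den <- 6 * (sum((jm - jack)^2))^1.5
  a <- if (den == 0) 0 else num / den
  adj <- function(z_alpha) {
    stats::pnorm(z0 + (z0 + z_alpha) / (1 - a * (z0 + z_alpha)))
  }
  probs <- c(adj(stats::qnorm(alpha)), adj(stats::qnorm(1 - alpha)))
  unname(stats::quantile(thetas, probs, type = 7))
}

#' Mean difference with a BCa bootstrap confidence interval
#'
#' Bias-corrected and accelerated (BCa) bootstrap interval for the unpaired
#' difference of means (independent resampling of each group), the paired
#' mean difference (resampling of the pairwise differences), or a one-sample
#' mean (`y = NULL`). With `exhaustive = TRUE` (feasible only for tiny
#' one-sample problems) all `n^n` equally likely resamples are enumerated
#' instead of sampled.
#'
#' @param x,y Numeric samples (`y = NULL` for a one-sample mean).
#' @param n_resamples Number of bootstrap resamples (>= 1000 recommended for
#'   reported intervals).
#' @param conf Confidence level.
#' @param seed Integer seed for reproducibility.
#' @param paired Logical; `x` and `y` must then have equal length.
#' @param exhaustive Enumerate all resamples (one-sample / paired only).
#' @return An object of class `effect_size`: `estimate`, `ci_low`, `ci_high`,
#'   `conf`, `n_resamples`, `seed`, `paired`, `degenerate`.
#' @export
bootstrap_bca_ci <- function(x, y = NULL, n_resamples = 5000, conf = 0.95,
                             seed = NULL, paired = FALSE, exhaustive = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  x <- as.numeric(x)
  if (!is.null(y)) y <- as.numeric(y)

  if (paired) {
    if (is.null(y) || length(x) != length(y)) stop("paired length mismatch")
    d <- x - y
    return(one_sample_bca(d, n_resamples, conf, seed, paired = TRUE, exhaustive))
  }
  if (is.null(y)) {
    return(one_sample_bca(x, n_resamples, conf, seed, paired = FALSE, exhaustive))
  }

  if (exhaustive) stop("exhaustive enumeration is implemented for one-sample/paired statistics only")
  n1 <- length(x)
  n2 <- length(y)
  theta_hat <- mean(x) - mean(y)
  bx <- matrix(sample(x, n1 * n_resamples, replace = TRUE), nrow = n1)
  by <- matrix(sample(y, n2 * n_resamples, replace = TRUE), nrow = n2)
  thetas <- colMeans(bx) - colMeans(by)
  # jackknife over every observation of both groups
  jack <- c(
    vapply(seq_len(n1), function(i) mean(x[-i]) - mean(y), numeric(1)),
    vapply(seq_len(n2), function(i) mean(x) - mean(y[-i]), numeric(1))
  )
  finalize_effect(thetas, theta_hat, jack, conf, n_resamples, seed, paired = FALSE)
}

one_sample_bca <- function(d, n_resamples, conf, seed, paired, exhaustive) {
  n <- length(d)
  theta_hat <- mean(d)
  if (exhaustive) {
    if (n^n > 1e6) stop("exhaustive enumeration infeasible for n = ", n)
    grid <- do.call(expand.grid, rep(list(seq_len(n)), n))
    thetas <- apply(grid, 1, function(ix) mean(d[ix]))
    n_resamples <- length(thetas)
  } else {
    b <- matrix(sample(d, n * n_resamples, replace = TRUE), nrow = n)
    thetas <- colMeans(b)
  }
  jack <- vapply(seq_len(n), function(i) mean(d[-i]), numeric(1))
  finalize_effect(thetas, theta_hat, jack, conf, n_resamples, seed, paired)
}

finalize_effect <- function(thetas, theta_hat, jack, conf, n_resamples, seed, paired) {
  degenerate <- stats::sd(thetas) == 0
  ci <- bca_interval(thetas, theta_hat, jack, conf)
  structure(
    list(
      estimate = theta_hat, ci_low = ci[1], ci_high = ci[2], conf = conf,
      n_resamples = n_resamples, seed = seed, paired = paired,
      degenerate = degenerate
    ),
    class = "effect_size"
  )
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf(
    "<effect_size%s> %.4g [%.4g, %.4g] (%g%% BCa, %d resamples)\n",
    if (x$paired) ", paired" else "", x$estimate, x$ci_low, x$ci_high,
    100 * x$conf, x$n_resamples
  ))
  invisible(x)
}

#' Box-and-whisker summary
#'
#' Median, quartiles (linear interpolation between order statistics,
#' `quantile` type 7) and whiskers at the most extreme data points within
#' 1.5 inter-quartile ranges of the box:
#' `whisker_low = min(x[x > Q1 - 1.5 * IQR])`,
#' `whisker_high = max(x[x < Q3 + 1.5 * IQR])`.
#'
#' @param x Numeric sample (n >= 1).
#' @return An object of class `box_summary` with `median`, `q1`, `q3`,
#'   `whisker_low`, `whisker_high`, `n`.
#' @export
box_summary <- function(x) {
  x <- as.numeric(x)
  stopifnot(length(x) >= 1)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  wl <- min(x[x > q[1] - 1.5 * iqr])
  wh <- max(x[x < q[3] + 1.5 * iqr])
  structure(
    list(median = q[2], q1 = q[1], q3 = q[3], whisker_low = wl, whisker_high = wh, n = length(x)),
    class = "box_summary"
  )
}

#' @export
print.box_summary <- function(x, ...) {
  cat(sprintf(
    "<box_summary> median %.4g [Q1 %.4g, Q3 %.4g], whiskers [%.4g, %.4g], n = %d\n",
    x$median, x$q1, x$q3, x$whisker_low, x$whisker_high, x$n
  ))
  invisible(x)
}
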