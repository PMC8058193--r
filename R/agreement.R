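# Agreement statistics for comparing computed against experimental
# quantities: trapezoid AUC, Bland-Altman limits of agreement,
# paired t-test, and point-by-point percent difference.

#' Trapezoid area under a sampled curve
#'
#' Composite trapezoid rule over points falling inside a time range.
#'
#' @param time,value sampled curve, times ascending (minutes).
#' @param range optional \code{c(t0, t1)}; only points inside are used.
#' @return AUC in value-units times minutes.
#' @export
auc_trapezoid <- function(time, value, range = NULL) {
  if (length(time) != length(value))
    stop("auc_trapezoid: time and value lengths differ", call. = FALSE)
  if (any(diff(time) <= 0))
    stop("auc_trapezoid: times must be strictly ascending", call. = FALSE)
  if (!is.null(range)) {
    keep <- time >= range[1] & time <= range[2]
    time <- time[keep]; value <- value[keep]
  }
  if (length(time) < 2L)
    stop("auc_trapezoid: need >= 2 points in range", call. = FALSE)
  pracma::trapz(time, value)
}

#' Bland-Altman agreement analysis
#'
#' Differences are oriented computed minus experimental (\code{y - x}).
#' Reports the mean difference (bias), the sample standard deviation of the
#' differences (precision), the 95 percent limits of agreement
#' \eqn{\bar d \pm 1.96\,SD}, the percentage of points inside the limits,
#' and the mean percentage difference
#' \eqn{100\,\overline{d_i / \mathrm{mean}(x_i, y_i)}}.
#'
#' @param x experimental values.
#' @param y computed values (same units, same length, n >= 2).
#' @param labels optional point labels.
#' @return An object of class \code{"bland_altman"} with fields
#'   \code{mean_diff}, \code{sd_diff}, \code{loa_low}, \code{loa_high},
#'   \code{pct_within}, \code{mean_pct_diff}, \code{n}, and the per-point
#'   table \code{points}.
#' @export
bland_altman <- function(x, y, labels = NULL) {
  if (length(x) != length(y))
    stop("bland_altman: x and y lengths differ", call. = FALSE)
  if (length(x) < 2L)
    stop("bland_altman: need >= 2 pairs", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("bland_altman: values must be finite", call. = FALSE)
  d <- y - x
  m <- (x + y) / 2
  mean_diff <- mean(d)
  sd_diff <- stats::sd(d)
  loa_low <- mean_diff - 1.96 * sd_diff
  loa_high <- mean_diff + 1.96 * sd_diff
  structure(list(mean_diff = mean_diff, sd_diff = sd_diff,
                 loa_low = loa_low, loa_high = loa_high,
                 pct_within = 100 * mean(d >= loa_low & d <= loa_high),
                 mean_pct_diff = 100 * mean(d / m),
                 n = length(d),
                 points = data.frame(
                   label = if (is.null(labels)) seq_along(d) else labels,
                   mean = m, diff = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, digits = 4, ...) {
  cat(sprintf("Bland-Altman (computed - experimental), n = %d\n", x$n))
  cat(sprintf("  mean difference: %.4g  (mean %% difference %.3g%%)\n",
              x$mean_diff, x$mean_pct_diff))
  cat(sprintf("  SD of differences: %.4g\n", x$sd_diff))
  cat(sprintf("  limits of agreement: [%.4g, %.4g]; %.1f%% of points within\n",
              x$loa_low, x$loa_high, x$pct_within))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$points$mean, x$points$diff, pch = 16,
                 xlab = "mean of methods", ylab = "computed - experimental",
                 main = "Bland-Altman", ...)
  graphics::abline(h = c(x$mean_diff, x$loa_low, x$loa_high),
                   lty = c(1, 2, 2), col = c(1, 2, 2))
  invisible(x)
}

#' Two-sided paired t-test
#'
#' Wraps \code{stats::t.test(y, x, paired = TRUE)}. A zero-variance
#' difference vector is degenerate for the t statistic and handled
#' explicitly: all-zero differences give t = 0, p = 1; a constant nonzero
#' shift is flagged with an infinite statistic and p = 0.
#'
#' @param x experimental values.
#' @param y computed values (same length, n >= 2).
#' @return list with \code{t}, \code{p}, \code{df}, \code{mean_diff},
#'   \code{degenerate}.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y))
    stop("paired_t: x and y lengths differ", call. = FALSE)
  n <- length(x)
  if (n < 2L)
    stop("paired_t: need >= 2 pairs", call. = FALSE)
  d <- y - x
  if (stats::sd(d) == 0) {
    if (mean(d) == 0)
      return(list(t = 0, p = 1, df = n - 1L, mean_diff = 0,
                  degenerate = TRUE))
    return(list(t = sign(mean(d)) * Inf, p = 0, df = n - 1L,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(y, x, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_diff = unname(tt$estimate),
       degenerate = FALSE)
}

#' Point-by-point percent difference between two curves
#'
#' Mean over frames of \eqn{100\,(a_i - b_i)/a_i}, with \code{a} the
#' experimental reference — positive when the comparison curve runs below
#' the reference. Frames whose reference value is at or below \code{floor}
#' are excluded and counted.
#'
#' @param a reference (experimental) values per frame.
#' @param b comparison (computed) values per frame.
#' @param floor exclusion threshold on the reference (default 0).
#' @return list with \code{mean_pct} and \code{n_used}, \code{n_excluded}.
#' @export
pointwise_percent_difference <- function(a, b, floor = 0) {
  if (inherits(a, "tac")) a <- a$values
  if (inherits(b, "tac")) b <- b$values
  if (length(a) != length(b))
    stop("pointwise_percent_difference: curves have different lengths",
         call. = FALSE)
  use <- a > floor
  if (!any(use))
    stop("pointwise_percent_difference: no frames above the reference floor",
         call. = FALSE)
  list(mean_pct = mean(100 * (a[use] - b[use]) / a[use]),
       n_used = sum(use), n_excluded = sum(!use))
}
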