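# Seven-parameter Feng arterial input model and its exact integral calculus.
#
# Ca(t) = (A1*u - A2 - A3) e^{-lam1 u} + A2 e^{-lam2 u} + A3 e^{-lam3 u},
# u = t - tau (0 before tau).  All downstream model outputs are frame
# averages of linear functionals of Ca (its running integral and its
# convolution with decaying exponentials), so every primitive below has a
# closed form; the small-exponent branches keep them stable when rate
# constants collide or vanish.

# ---- stable exponential-moment primitives (scalar rate, vector u >= 0) ----

# int_0^u e^{-lam v} dv
.e1 <- function(lam, u) {
  if (lam <= 0) return(u)
  -expm1(-lam * u) / lam
}

# int_0^u v e^{-lam v} dv
.m1 <- function(lam, u) {
  if (lam <= 0) return(u^2 / 2)
  x <- lam * u
  out <- (1 - (1 + x) * exp(-x)) / lam^2
  small <- x < 1e-3
  if (any(small)) {
    xs <- x[small]
    out[small] <- u[small]^2 * (0.5 - xs / 3 + xs^2 / 8 - xs^3 / 30)
  }
  out
}

# int_0^u v^2 e^{-lam v} dv
.m2 <- function(lam, u) {
  if (lam <= 0) return(u^3 / 3)
  x <- lam * u
  out <- (2 - exp(-x) * (x^2 + 2 * x + 2)) / lam^3
  small <- x < 1e-3
  if (any(small)) {
    xs <- x[small]
    out[small] <- u[small]^3 * (1 / 3 - xs / 4 + xs^2 / 10 - xs^3 / 36)
  }
  out
}

# int_0^u e^{-lam v} e^{-beta (u - v)} dv  (lam, beta >= 0; lam ~ beta safe)
.d0 <- function(lam, beta, u) {
  a <- beta - lam
  x <- a * u
  out <- numeric(length(u))
  big <- abs(x) > 1e-3
  if (any(big)) {
    ub <- u[big]
    out[big] <- (exp(-lam * ub) - exp(-beta * ub)) / a
  }
  if (any(!big)) {
    us <- u[!big]
    xs <- x[!big]
    out[!big] <- us * exp(-beta * us) * (1 + xs / 2 + xs^2 / 6 + xs^3 / 24)
  }
  out
}

# int_0^u v e^{-lam v} e^{-beta (u - v)} dv
.d1 <- function(lam, beta, u) {
  a <- beta - lam
  x <- a * u
  out <- numeric(length(u))
  big <- abs(x) > 1e-3
  if (any(big)) {
    ub <- u[big]
    out[big] <- (exp(-lam * ub) * (x[big] - 1) + exp(-beta * ub)) / a^2
  }
  if (any(!big)) {
    us <- u[!big]
    xs <- x[!big]
    out[!big] <- us^2 * exp(-beta * us) * (0.5 + xs / 3 + xs^2 / 8 + xs^3 / 30)
  }
  out
}

# ---- Feng input object ----------------------------------------------------

#' Seven-parameter arterial input model
#'
#' Constructs the standard seven-parameter sum-of-exponentials description of
#' an FDG bolus in arterial whole blood,
#' \deqn{C_a(t) = (A_1 u - A_2 - A_3)e^{-\lambda_1 u} + A_2 e^{-\lambda_2 u} +
#'   A_3 e^{-\lambda_3 u}, \quad u = t - \tau,}
#' with \eqn{C_a(t) = 0} for \eqn{t < \tau}. The curve is continuous and zero
#' at the appearance delay \eqn{\tau}, rises to a first-pass peak governed by
#' \eqn{A_1, \lambda_1}, and washes out through the two slower exponentials.
#'
#' @param A1 linear-rise amplitude, kBq/cc/min (\eqn{\ge 0}).
#' @param A2,A3 exponential amplitudes, kBq/cc (\eqn{\ge 0}).
#' @param lam1,lam2,lam3 decay rates, 1/min; must satisfy
#'   \code{lam1 > lam2 > lam3 >= 0}.
#' @param tau appearance delay, minutes (\eqn{\ge 0}).
#' @return An object of class \code{"feng_input"}: a named numeric vector of
#'   the seven parameters.
#' @seealso [eval_feng()], [feng_auc()], [fit_feng()]
#' @examples
#' p <- feng_input(A1 = 3000, A2 = 40, A3 = 25,
#'                 lam1 = 4, lam2 = 0.6, lam3 = 0.01, tau = 0.2)
#' eval_feng(p, c(0.1, 0.5, 5, 60))
#' @export
feng_input <- function(A1, A2, A3, lam1, lam2, lam3, tau) {
  p <- c(A1 = A1, A2 = A2, A3 = A3,
         lam1 = lam1, lam2 = lam2, lam3 = lam3, tau = tau)
  if (any(!is.finite(p)))
    stop("feng_input: all parameters must be finite", call. = FALSE)
  if (A1 < 0 || A2 < 0 || A3 < 0)
    stop("feng_input: amplitudes A1, A2, A3 must be >= 0", call. = FALSE)
  if (!(lam1 > lam2 && lam2 > lam3 && lam3 >= 0))
    stop("feng_input: rates must satisfy lam1 > lam2 > lam3 >= 0",
         call. = FALSE)
  if (tau < 0)
    stop("feng_input: appearance delay tau must be >= 0", call. = FALSE)
  structure(p, class = "feng_input")
}

#' @export
print.feng_input <- function(x, digits = 4, ...) {
  cat("Seven-parameter arterial input model (kBq/cc, 1/min)\n")
  print(signif(unclass(x), digits))
  invisible(x)
}

.as_feng <- function(p) {
  if (inherits(p, "feng_input")) return(p)
  stop("expected a 'feng_input' object", call. = FALSE)
}

#' Evaluate the arterial input model
#'
#' @param p a [feng_input()] object.
#' @param t times in minutes (vectorized).
#' @return Blood activity concentration \eqn{C_a(t)} in kBq/cc; 0 for
#'   \code{t < tau}.
#' @export
eval_feng <- function(p, t) {
  p <- .as_feng(p)
  u <- t - p[["tau"]]
  out <- numeric(length(t))
  pos <- u > 0
  if (any(pos)) {
    up <- u[pos]
    out[pos] <- (p[["A1"]] * up - p[["A2"]] - p[["A3"]]) *
      exp(-p[["lam1"]] * up) +
      p[["A2"]] * exp(-p[["lam2"]] * up) +
      p[["A3"]] * exp(-p[["lam3"]] * up)
  }
  out
}

# running integral  I1(t) = int_0^t Ca
.feng_int <- function(p, t) {
  u <- pmax(t - p[["tau"]], 0)
  p[["A1"]] * .m1(p[["lam1"]], u) -
    (p[["A2"]] + p[["A3"]]) * .e1(p[["lam1"]], u) +
    p[["A2"]] * .e1(p[["lam2"]], u) +
    p[["A3"]] * .e1(p[["lam3"]], u)
}

# double integral  J(t) = int_0^t I1(s) ds
.feng_int2 <- function(p, t) {
  u <- pmax(t - p[["tau"]], 0)
  G <- .feng_int(p, t)
  vg <- p[["A1"]] * .m2(p[["lam1"]], u) -
    (p[["A2"]] + p[["A3"]]) * .m1(p[["lam1"]], u) +
    p[["A2"]] * .m1(p[["lam2"]], u) +
    p[["A3"]] * .m1(p[["lam3"]], u)
  u * G - vg
}

# convolution  (Ca (*) e^{-beta t})(t),  beta >= 0
.feng_conv <- function(p, beta, t) {
  u <- pmax(t - p[["tau"]], 0)
  p[["A1"]] * .d1(p[["lam1"]], beta, u) -
    (p[["A2"]] + p[["A3"]]) * .d0(p[["lam1"]], beta, u) +
    p[["A2"]] * .d0(p[["lam2"]], beta, u) +
    p[["A3"]] * .d0(p[["lam3"]], beta, u)
}

# running integral of the convolution: int_0^t (Ca (*) e^{-beta s}) ds.
# From d/dt conv = Ca - beta*conv:  int conv = (I1 - conv)/beta; beta -> 0
# degenerates to the double integral J.
.feng_conv_int <- function(p, beta, t) {
  if (beta < 1e-9) return(.feng_int2(p, t))
  (.feng_int(p, t) - .feng_conv(p, beta, t)) / beta
}

#' Analytic area under the arterial input curve
#'
#' Exact closed-form \eqn{\int_0^T C_a(t)\,dt} for a [feng_input()] model.
#'
#' @param p a [feng_input()] object.
#' @param T upper limit in minutes (vectorized); must be positive.
#' @return AUC in kBq·min/cc.
#' @export
feng_auc <- function(p, T) {
  p <- .as_feng(p)
  if (any(T <= 0)) stop("feng_auc: T must be > 0", call. = FALSE)
  .feng_int(p, T)
}

#' Peak of the arterial input model
#'
#' Locates the maximum of \eqn{C_a(t)} on \code{[0, t_max]} by a dense grid
#' scan refined with golden-section search.
#'
#' @param p a [feng_input()] object.
#' @param t_max scan end, minutes.
#' @return list with \code{time} (min) and \code{value} (kBq/cc).
#' @export
feng_peak <- function(p, t_max = 60) {
  p <- .as_feng(p)
  grid <- seq(p[["tau"]], t_max, length.out = 4001L)
  v <- eval_feng(p, grid)
  i <- which.max(v)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  if (hi > lo) {
    op <- stats::optimize(function(t) eval_feng(p, t), c(lo, hi),
                          maximum = TRUE, tol = 1e-10)
    if (op$objective >= v[i]) return(list(time = op$maximum,
                                          value = op$objective))
  }
  list(time = grid[i], value = v[i])
}
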