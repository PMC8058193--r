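# Forward two-tissue compartment model (reversible and irreversible), the
# macro uptake rate Ki, and Patlak graphical analysis.
#
# Plasma -> free tissue pool (K1 in, k2 out) -> phosphorylated pool
# (k3 in, k4 out); FDG is effectively irreversible (k4 = 0) over a 60-min
# scan. With a Feng input all solutions are sums of exponential
# convolutions and are evaluated in closed form.

#' Two-tissue compartment rate constants
#'
#' @param K1 plasma-to-tissue transport, ml/min/cc (written 1/min).
#' @param k2 tissue-to-plasma efflux, 1/min.
#' @param k3 phosphorylation (trapping), 1/min.
#' @param k4 dephosphorylation, 1/min; 0 for the irreversible model.
#' @return An object of class \code{"two_tissue_params"}.
#' @export
two_tissue_params <- function(K1, k2, k3, k4 = 0) {
  p <- c(K1 = K1, k2 = k2, k3 = k3, k4 = k4)
  if (any(!is.finite(p)) || any(p < 0))
    stop("two_tissue_params: rate constants must be finite and >= 0",
         call. = FALSE)
  structure(p, class = "two_tissue_params")
}

#' @export
print.two_tissue_params <- function(x, digits = 4, ...) {
  cat("Two-tissue compartment rates (1/min)\n")
  print(signif(unclass(x), digits))
  if (x[["k2"]] + x[["k3"]] > 0)
    cat(sprintf("Ki = K1*k3/(k2+k3) = %.5g 1/min\n", ki_from_micro(x)))
  invisible(x)
}

# impulse-response decomposition: C_T(t) = sum_j c_j * (Ca (*) e^{-alpha_j t}).
# For k4 = 0: alpha = (0, k2+k3) with c = (K1*k3/(k2+k3), K1*k2/(k2+k3));
# alpha = 0 convolution is the running integral of Ca. A repeated root
# (disc = 0, only possible when k3 = 0 and k2 = k4) is split by an
# eps-nudge of k4; the induced error is O(1e-6*k4).
.tissue_modes <- function(kin) {
  K1 <- kin[["K1"]]; k2 <- kin[["k2"]]; k3 <- kin[["k3"]]; k4 <- kin[["k4"]]
  if (k4 <= 0) {
    beta <- k2 + k3
    if (beta < 1e-9) return(list(alpha = 0, coef = K1))
    return(list(alpha = c(0, beta), coef = c(K1 * k3 / beta, K1 * k2 / beta)))
  }
  s <- k2 + k3 + k4
  disc2 <- s^2 - 4 * k2 * k4
  if (disc2 < 1e-18) {
    k4 <- k4 * (1 - 1e-6)
    s <- k2 + k3 + k4
    disc2 <- s^2 - 4 * k2 * k4
  }
  disc <- sqrt(disc2)
  a1 <- (s - disc) / 2
  a2 <- (s + disc) / 2
  list(alpha = c(a1, a2),
       coef = K1 * c(k3 + k4 - a1, a2 - k3 - k4) / disc)
}

.conv_mode <- function(p, alpha, t) {
  if (alpha < 1e-9) .feng_int(p, t) else .feng_conv(p, alpha, t)
}
.conv_mode_int <- function(p, alpha, t) {
  if (alpha < 1e-9) .feng_int2(p, t) else .feng_conv_int(p, alpha, t)
}

#' Solve the two-tissue model forward in time
#'
#' Total tissue concentration \eqn{C_T(t) = C_1(t) + C_2(t)} for the system
#' \deqn{dC_1/dt = K_1 C_a - (k_2 + k_3) C_1 + k_4 C_2, \quad
#'       dC_2/dt = k_3 C_1 - k_4 C_2,}
#' evaluated in closed form as a sum of exponential convolutions of the
#' input. For \eqn{k_4 = 0} this reduces to
#' \eqn{C_T = K_i \int_0^t C_a + \frac{K_1 k_2}{k_2+k_3}
#' (C_a \ast e^{-(k_2+k_3)t})}; the degenerate \eqn{k_2 + k_3 = 0} branch is
#' pure accumulation \eqn{K_1 \int_0^t C_a}.
#'
#' @param kin a [two_tissue_params()].
#' @param input a [feng_input()] arterial model.
#' @param t times in minutes (vectorized).
#' @return \eqn{C_T(t)} in kBq/cc.
#' @export
solve_tissue <- function(kin, input, t) {
  stopifnot(inherits(kin, "two_tissue_params"))
  input <- .as_feng(input)
  md <- .tissue_modes(kin)
  out <- numeric(length(t))
  for (j in seq_along(md$alpha))
    out <- out + md$coef[j] * .conv_mode(input, md$alpha[j], t)
  out
}

# exact frame averages of C_T over a schedule (shared by the dual-output
# heart model and the regional brain model)
.tissue_frame_avg <- function(kin, input, schedule) {
  md <- .tissue_modes(kin)
  Fe <- numeric(nrow(schedule)); Fb <- numeric(nrow(schedule))
  for (j in seq_along(md$alpha)) {
    Fe <- Fe + md$coef[j] * .conv_mode_int(input, md$alpha[j], schedule$end)
    Fb <- Fb + md$coef[j] * .conv_mode_int(input, md$alpha[j], schedule$start)
  }
  (Fe - Fb) / schedule$dur
}

# exact frame averages of Ca itself
.input_frame_avg <- function(input, schedule) {
  (.feng_int(input, schedule$end) - .feng_int(input, schedule$start)) /
    schedule$dur
}

#' Macro uptake rate constant from micro-parameters
#'
#' \deqn{K_i = \frac{K_1 k_3}{k_2 + k_3}} — the net rate of irreversible FDG
#' trapping.
#'
#' @param kin a [two_tissue_params()] or anything with named elements
#'   \code{K1}, \code{k2}, \code{k3}.
#' @return \eqn{K_i} in 1/min.
#' @export
ki_from_micro <- function(kin) {
  K1 <- kin[["K1"]]; k2 <- kin[["k2"]]; k3 <- kin[["k3"]]
  if (k2 + k3 <= 0)
    stop("ki_from_micro: k2 + k3 must be > 0", call. = FALSE)
  K1 * k3 / (k2 + k3)
}

#' Patlak graphical influx analysis
#'
#' Ordinary least-squares slope of \eqn{C_T(t)/C_a(t)} against the
#' normalized time \eqn{\int_0^t C_a / C_a(t)} over frames with midpoint
#' \eqn{\ge t^*}. For an irreversible tracer the late-time slope equals
#' \eqn{K_i}; used as an independent check on compartmental estimates.
#'
#' @param tissue a [tac()] of tissue activity.
#' @param input a [feng_input()] arterial model.
#' @param t_star start of the linear phase, minutes (default 20).
#' @return list with \code{slope} (1/min), \code{intercept} (the effective
#'   distribution volume) and \code{n} frames used.
#' @export
patlak_slope <- function(tissue, input, t_star = 20) {
  stopifnot(inherits(tissue, "tac"))
  input <- .as_feng(input)
  mid <- tissue$schedule$mid
  use <- which(mid >= t_star)
  if (length(use) < 3L)
    stop("patlak_slope: need >= 3 frames with midpoint >= t_star",
         call. = FALSE)
  ca <- eval_feng(input, mid[use])
  x <- .feng_int(input, mid[use]) / ca
  y <- tissue$values[use] / ca
  fit <- stats::lm.fit(cbind(1, x), y)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       n = length(use))
}
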