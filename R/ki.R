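# Four-parameter regional cerebral model, per-VOI and super-region batch
# fitting, and the derived uptake rate Ki and recovery coefficient
# RC = 1 - TBV.
#
# Frame-wise regional model (frame [t1, t2], input Cp):
#   Cm_i = 1/(t2-t1) * int_{t1}^{t2} { (1-TBV) * C_T(T) + TBV * Cp(T) } dT
# with C_T the irreversible two-tissue solution driven by Cp. TBV couples
# the blood spillover (TBV * Cp) and the tissue partial-volume loss
# (1 - TBV) into a single parameter.

#' Regional cerebral model parameters
#'
#' @param K1 plasma-to-tissue transport, 1/min.
#' @param k2,k3 efflux and trapping rates, 1/min.
#' @param TBV blood-volume/spillover fraction, in \[0, 1\]; the tissue
#'   recovery coefficient is \code{RC = 1 - TBV}.
#' @return An object of class \code{"region_ki_params"}.
#' @export
region_ki_params <- function(K1, k2, k3, TBV) {
  p <- c(K1 = K1, k2 = k2, k3 = k3, TBV = TBV)
  if (any(!is.finite(p)) || any(p < 0))
    stop("region_ki_params: parameters must be finite and >= 0",
         call. = FALSE)
  if (TBV > 1)
    stop("region_ki_params: TBV must lie in [0, 1]", call. = FALSE)
  structure(p, class = "region_ki_params")
}

#' Frame-wise regional model predictions
#'
#' Exact frame averages of \eqn{(1-TBV)\,C_T(T) + TBV\,C_p(T)}, where
#' \eqn{C_T} is the irreversible two-tissue solution
#' \eqn{\frac{K_1 k_3}{k_2+k_3}\int_0^T C_p +
#' \frac{K_1 k_2}{k_2+k_3}(C_p \ast e^{-(k_2+k_3)T})} driven by the
#' continuous input \eqn{C_p} (the MCIF or any input model). The
#' \eqn{TBV\,C_p} term uses the continuous input, not its frame average —
#' the outer frame integral handles discretization.
#'
#' @param params a [region_ki_params()].
#' @param input a [feng_input()] (e.g. the MCIF from [extract_mcif()] /
#'   \code{fit$params$input}).
#' @param schedule a [frame_schedule()].
#' @return Numeric vector of per-frame kBq/cc.
#' @export
model_region_frames <- function(params, input, schedule) {
  stopifnot(inherits(params, "region_ki_params"),
            inherits(schedule, "frame_schedule"))
  input <- .as_feng(input)
  kin <- two_tissue_params(params[["K1"]], params[["k2"]], params[["k3"]], 0)
  (1 - params[["TBV"]]) * .tissue_frame_avg(kin, input, schedule) +
    params[["TBV"]] * .input_frame_avg(input, schedule)
}

.region_default_bounds <- function() {
  list(lower = c(K1 = 1e-4, k2 = 1e-4, k3 = 1e-4, TBV = 0),
       upper = c(K1 = 2, k2 = 2, k3 = 2, TBV = 0.5))
}

#' Fit the four-parameter regional model to a brain TAC
#'
#' Bounded least-squares fit of [model_region_frames()] to a regional
#' time-activity curve, from a fixed initial guess plus Latin-hypercube
#' multi-starts. The uptake rate \eqn{K_i = K_1 k_3/(k_2+k_3)} and recovery
#' coefficient \eqn{RC = 1 - TBV} are derived from the fitted parameters.
#'
#' @param region_tac a [tac()] with at least 4 frames.
#' @param input a [feng_input()] driving the model (typically the MCIF).
#' @param bounds list with \code{lower}, \code{upper} over
#'   \code{K1, k2, k3, TBV}.
#' @param start initial guess (defaults: K1 = 0.1, k2 = 0.2, k3 = 0.05,
#'   TBV = 0.05).
#' @param n_starts additional Latin-hypercube starts.
#' @param seed integer seed for the multi-start draw.
#' @param volume optional region volume, mm^3 (carried into the result).
#' @return An object of class \code{"ki_fit"}: \code{params}
#'   (a [region_ki_params()]), \code{Ki} (1/min), \code{RC},
#'   \code{residual} (residual sum of squares, (kBq/cc)^2), \code{region},
#'   \code{volume}, \code{converged}, \code{fitted}. Methods: \code{print},
#'   \code{coef}, \code{fitted}, \code{residuals}, \code{predict},
#'   \code{plot}.
#' @export
fit_region <- function(region_tac, input,
                       bounds = .region_default_bounds(),
                       start = c(K1 = 0.1, k2 = 0.2, k3 = 0.05, TBV = 0.05),
                       n_starts = 10, seed = 1, volume = NA_real_) {
  stopifnot(inherits(region_tac, "tac"))
  input <- .as_feng(input)
  sch <- region_tac$schedule
  if (nrow(sch) < 4L)
    stop("fit_region: need >= 4 frames for 4 parameters", call. = FALSE)
  y <- region_tac$values
  lower <- bounds$lower
  upper <- bounds$upper

  resid_fn <- function(theta) {
    names(theta) <- names(lower)
    p <- region_ki_params(theta[["K1"]], theta[["k2"]], theta[["k3"]],
                          theta[["TBV"]])
    model_region_frames(p, input, sch) - y
  }

  starts <- rbind(pmin(pmax(start[names(lower)], lower), upper),
                  .lhs_starts(n_starts, lower, upper, seed))
  colnames(starts) <- names(lower)
  best <- .multistart_lm(resid_fn, starts, lower, upper)
  if (!best$ok)
    warning("fit_region: best start did not formally converge; returning best-so-far")
  th <- best$fit$par
  names(th) <- names(lower)
  params <- region_ki_params(th[["K1"]], th[["k2"]], th[["k3"]], th[["TBV"]])
  fit_vals <- model_region_frames(params, input, sch)
  structure(list(params = params,
                 Ki = ki_from_micro(params),
                 RC = 1 - params[["TBV"]],
                 residual = sum((fit_vals - y)^2),
                 region = region_tac$label,
                 volume = volume,
                 converged = best$ok,
                 fitted = fit_vals,
                 tac = region_tac, input = input, seed = seed),
            class = "ki_fit")
}

#' @export
coef.ki_fit <- function(object, ...) unclass(object$params)

#' @export
print.ki_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Regional Ki fit '%s': Ki = %.4g 1/min, RC = %.4g, RSS = %.4g%s\n",
              x$region, x$Ki, x$RC, x$residual,
              if (x$converged) "" else " (NOT converged)"))
  print(signif(unclass(x$params), digits))
  invisible(x)
}

#' @export
fitted.ki_fit <- function(object, ...) object$fitted

#' @export
residuals.ki_fit <- function(object, ...) object$tac$values - object$fitted

#' @export
predict.ki_fit <- function(object, schedule = NULL, ...) {
  if (is.null(schedule)) return(object$fitted)
  model_region_frames(object$params, object$input, schedule)
}

#' @export
plot.ki_fit <- function(x, ...) {
  sch <- x$tac$schedule
  graphics::plot(sch$mid, x$tac$values, pch = 16,
                 xlab = "time (min)", ylab = "activity (kBq/cc)",
                 main = sprintf("%s (Ki = %.3g 1/min)", x$region, x$Ki), ...)
  graphics::lines(sch$mid, x$fitted, col = 2)
  invisible(x)
}

#' Volume-weighted super-region time-activity curve
#'
#' @param tacs list of member [tac()]s on one schedule.
#' @param volumes member volumes, mm^3 (> 0).
#' @param label name of the combined region.
#' @return A [tac()] equal to the volume-weighted mean of the members.
#' @export
combine_tacs <- function(tacs, volumes, label = "super") {
  stopifnot(length(tacs) == length(volumes), length(tacs) >= 1L)
  if (any(volumes <= 0))
    stop("combine_tacs: volumes must be > 0", call. = FALSE)
  sch <- tacs[[1]]$schedule
  for (tc in tacs[-1])
    if (!.same_schedule(sch, tc$schedule))
      stop("combine_tacs: member TACs are on different schedules",
           call. = FALSE)
  vals <- Reduce(`+`, Map(function(tc, v) v * tc$values, tacs, volumes)) /
    sum(volumes)
  tac(sch, vals, label = label, noisy = any(vapply(tacs, `[[`, TRUE, "noisy")))
}

#' Batch regional fitting with super-region aggregation
#'
#' Fits every VOI independently with [fit_region()], then builds each super
#' region's TAC as the volume-weighted mean of its members and fits those
#' too.
#'
#' @param tacs named list of VOI [tac()]s.
#' @param volumes named numeric vector of VOI volumes, mm^3 (> 0), aligned
#'   with \code{tacs}.
#' @param input a [feng_input()] (typically the MCIF).
#' @param super_map named list: super-region name -> character vector of
#'   member VOI names (each must exist in \code{tacs}).
#' @param ... passed to [fit_region()].
#' @return An object of class \code{"ki_batch"}: a data frame with one row
#'   per VOI and per super region and columns \code{region}, \code{level},
#'   \code{K1}, \code{k2}, \code{k3}, \code{TBV}, \code{Ki}, \code{RC},
#'   \code{residual}, \code{volume}. The individual \code{"ki_fit"} objects
#'   are attached as attribute \code{"fits"}.
#' @export
batch_fit <- function(tacs, volumes, input, super_map = list(), ...) {
  stopifnot(is.list(tacs), length(tacs) >= 1L)
  if (is.null(names(tacs)))
    names(tacs) <- vapply(tacs, `[[`, "", "label")
  if (!all(names(tacs) %in% names(volumes)))
    stop("batch_fit: every TAC needs a volume", call. = FALSE)
  unknown <- setdiff(unlist(super_map), names(tacs))
  if (length(unknown))
    stop(sprintf("batch_fit: super_map names unknown VOI(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  fits <- lapply(names(tacs), function(nm)
    fit_region(tacs[[nm]], input, volume = volumes[[nm]], ...))
  names(fits) <- names(tacs)
  sfits <- lapply(names(super_map), function(snm) {
    members <- super_map[[snm]]
    stac <- combine_tacs(tacs[members], volumes[members], label = snm)
    fit_region(stac, input, volume = sum(volumes[members]), ...)
  })
  names(sfits) <- names(super_map)
  all_fits <- c(fits, sfits)
  row1 <- function(f, level)
    data.frame(region = f$region, level = level,
               K1 = f$params[["K1"]], k2 = f$params[["k2"]],
               k3 = f$params[["k3"]], TBV = f$params[["TBV"]],
               Ki = f$Ki, RC = f$RC, residual = f$residual,
               volume = f$volume)
  out <- do.call(rbind, c(lapply(fits, row1, level = "voi"),
                          lapply(sfits, row1, level = "super")))
  rownames(out) <- NULL
  structure(out, fits = all_fits, class = c("ki_batch", "data.frame"))
}

#' @export
print.ki_batch <- function(x, digits = 4, ...) {
  cat(sprintf("Regional Ki fits: %d VOIs, %d super regions\n",
              sum(x$level == "voi"), sum(x$level == "super")))
  print.data.frame(cbind(x[, c("region", "level")],
                         signif(x[, c("Ki", "RC", "K1", "k2", "k3", "TBV")],
                                digits)),
                   row.names = FALSE)
  invisible(x)
}
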