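# Frame schedules, time-activity curves, arterial sample series, file I/O,
# and the frame-average operator. Internal units are minutes and kBq/cc
# throughout; readers normalize on ingest.

#' Build an acquisition frame schedule
#'
#' Constructs contiguous acquisition frames from a compact
#' (count, duration) description, e.g. the standard 23-frame/60-minute
#' dynamic FDG protocol \code{list(c(11, 8), c(1, 12), c(2, 60), c(1, 180),
#' c(8, 400))} — eleven 8-s frames, one 12-s frame, and so on. Frames start
#' at t = 0 and durations are given in seconds; the schedule is stored in
#' minutes.
#'
#' @param spec list of \code{c(count, duration_s)} pairs (or a 2-column
#'   matrix), counts \eqn{\ge} 1 and durations \eqn{>} 0.
#' @return A \code{"frame_schedule"}: a data frame with columns
#'   \code{start}, \code{end}, \code{mid}, \code{dur} (minutes).
#' @examples
#' sch <- frame_schedule(list(c(11, 8), c(1, 12), c(2, 60), c(1, 180), c(8, 400)))
#' nrow(sch)            # 23 frames
#' max(sch$end)         # 60 minutes
#' @export
frame_schedule <- function(spec) {
  if (is.matrix(spec)) spec <- lapply(seq_len(nrow(spec)), function(i) spec[i, ])
  if (!is.list(spec) || length(spec) == 0L)
    stop("frame_schedule: spec must be a non-empty list of (count, duration) pairs",
         call. = FALSE)
  counts <- vapply(spec, function(x) x[[1]], numeric(1))
  durs <- vapply(spec, function(x) x[[2]], numeric(1))
  if (any(!is.finite(counts)) || any(!is.finite(durs)) ||
      any(counts < 1) || any(counts != round(counts)) || any(durs <= 0))
    stop("frame_schedule: counts must be integers >= 1 and durations > 0",
         call. = FALSE)
  dur_min <- rep(durs, counts) / 60
  end <- cumsum(dur_min)
  start <- c(0, end[-length(end)])
  as_frame_schedule(start, end)
}

#' Assemble a frame schedule from explicit start/end times
#'
#' @param start,end frame boundaries in minutes. Frames must be ascending,
#'   non-overlapping, with \code{start < end} and the first start \eqn{\ge} 0.
#' @return A \code{"frame_schedule"} data frame.
#' @export
as_frame_schedule <- function(start, end) {
  if (length(start) != length(end) || length(start) == 0L)
    stop("as_frame_schedule: start and end must be equal-length, non-empty",
         call. = FALSE)
  bad <- which(!(start < end))
  if (length(bad))
    stop(sprintf("as_frame_schedule: frame %d has start >= end", bad[1]),
         call. = FALSE)
  if (start[1] < 0)
    stop("as_frame_schedule: first frame starts before t = 0", call. = FALSE)
  if (length(start) > 1L) {
    ov <- which(start[-1] < end[-length(end)] - 1e-12)
    if (length(ov))
      stop(sprintf("as_frame_schedule: frames %d and %d overlap or are out of order",
                   ov[1], ov[1] + 1L), call. = FALSE)
  }
  structure(
    data.frame(start = start, end = end, mid = (start + end) / 2,
               dur = end - start),
    class = c("frame_schedule", "data.frame"))
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("Frame schedule: %d frames, %.4g min total\n",
              nrow(x), max(x$end) - min(x$start)))
  print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE)
  if (nrow(x) > 6) cat(sprintf("  ... %d more frames\n", nrow(x) - 6L))
  invisible(x)
}

.same_schedule <- function(a, b, tol = 1e-9) {
  nrow(a) == nrow(b) && all(abs(a$start - b$start) < tol) &&
    all(abs(a$end - b$end) < tol)
}

#' The standard 23-frame/60-minute rat acquisition schedule
#'
#' @return A 23-frame [frame_schedule()] (11 x 8 s, 1 x 12 s, 2 x 60 s,
#'   1 x 180 s, 8 x 400 s; 60 min total).
#' @export
rat_frame_schedule <- function() {
  frame_schedule(list(c(11, 8), c(1, 12), c(2, 60), c(1, 180), c(8, 400)))
}

#' Standard arterial sampling timetable
#'
#' The twelve-sample arterial draw schedule used with the 60-minute scan:
#' 10, 20, 36, 49 s, then 1, 1.2, 2.2, 3.3, 5, 10, 30 and 60 min.
#'
#' @return Numeric vector of sample times in minutes.
#' @export
arterial_sample_times <- function() {
  c(10 / 60, 20 / 60, 36 / 60, 49 / 60, 1, 1.2, 2.2, 3.3, 5, 10, 30, 60)
}

# ---- time-activity curves -------------------------------------------------

#' Time-activity curve
#'
#' A per-frame activity concentration series for one region (blood pool,
#' myocardium, or a brain VOI).
#'
#' @param schedule a [frame_schedule()].
#' @param values activity concentration per frame, kBq/cc (one per frame,
#'   finite). Negative values are rejected unless \code{noisy = TRUE}
#'   (measured curves can dip below zero in low-count frames).
#' @param label region name.
#' @param noisy flag allowing negative values.
#' @return An object of class \code{"tac"}.
#' @export
tac <- function(schedule, values, label = "", noisy = FALSE) {
  if (!inherits(schedule, "frame_schedule"))
    stop("tac: schedule must be a frame_schedule", call. = FALSE)
  if (length(values) != nrow(schedule))
    stop("tac: need exactly one value per frame", call. = FALSE)
  if (any(!is.finite(values)))
    stop("tac: values must be finite", call. = FALSE)
  if (!noisy && any(values < 0))
    stop("tac: negative values; pass noisy = TRUE for measured data",
         call. = FALSE)
  structure(list(schedule = schedule, values = as.numeric(values),
                 label = as.character(label), noisy = isTRUE(noisy)),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("TAC '%s': %d frames over %.4g min, range [%.4g, %.4g] kBq/cc\n",
              x$label, nrow(x$schedule), max(x$schedule$end),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.tac <- function(x, ...) {
  data.frame(frame_start_min = x$schedule$start,
             frame_end_min = x$schedule$end,
             activity_kBq_cc = x$values)
}

#' @export
plot.tac <- function(x, ..., xlab = "time (min)",
                     ylab = "activity (kBq/cc)", type = "b", pch = 16) {
  graphics::plot(x$schedule$mid, x$values, xlab = xlab, ylab = ylab,
                 type = type, pch = pch, main = x$label, ...)
  invisible(x)
}

#' Arterial blood sample series
#'
#' @param times sample times in minutes, strictly ascending, \eqn{\ge} 0.
#' @param activities whole-blood activity, kBq/cc.
#' @param weights optional fit weights (same length).
#' @return An object of class \code{"blood_samples"}.
#' @export
blood_samples <- function(times, activities, weights = NULL) {
  if (length(times) != length(activities) || length(times) == 0L)
    stop("blood_samples: times and activities must be equal-length, non-empty",
         call. = FALSE)
  if (any(times < 0) || any(diff(times) <= 0))
    stop("blood_samples: times must be strictly ascending and >= 0",
         call. = FALSE)
  if (!is.null(weights) && length(weights) != length(times))
    stop("blood_samples: weights must match times", call. = FALSE)
  structure(list(time = as.numeric(times), activity = as.numeric(activities),
                 weights = weights),
            class = "blood_samples")
}

#' @export
print.blood_samples <- function(x, ...) {
  cat(sprintf("Blood samples: n = %d over [%.3g, %.3g] min\n",
              length(x$time), min(x$time), max(x$time)))
  invisible(x)
}

# ---- file I/O -------------------------------------------------------------

# Columns: frame_start_min, frame_end_min, activity_kBq_cc (or
# activity_Bq_cc, converted /1000). One optional '# units=...' comment line.
.read_units <- function(path) {
  head <- readLines(path, n = 5L)
  m <- grep("^#\\s*units\\s*=", head, value = TRUE)
  if (length(m)) trimws(sub("^#\\s*units\\s*=", "", m[1])) else NA_character_
}

#' Read / write a time-activity curve
#'
#' CSV with header \code{frame_start_min,frame_end_min,activity_kBq_cc} and
#' an optional \code{# units=kBq/cc} comment line. Activities given in Bq/cc
#' (column \code{activity_Bq_cc} or \code{# units=Bq/cc}) are converted to
#' kBq/cc on ingest. Frame invariants are enforced on read with the
#' offending row named.
#'
#' @param path CSV file path.
#' @param label region label (defaults to the file name).
#' @param noisy passed to [tac()].
#' @return \code{read_tac}: a [tac()]; \code{write_tac}: the path, invisibly.
#' @export
read_tac <- function(path, label = NULL, noisy = TRUE) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("frame_start_min", "frame_end_min")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("read_tac: %s missing column(s) %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  units <- .read_units(path)
  if (!is.na(units) && !units %in% c("kBq/cc", "Bq/cc"))
    stop(sprintf("read_tac: %s has unsupported units '%s'", path, units),
         call. = FALSE)
  if ("activity_kBq_cc" %in% names(df)) {
    act <- df$activity_kBq_cc
    if (identical(units, "Bq/cc")) act <- act / 1000
  } else if ("activity_Bq_cc" %in% names(df)) {
    act <- df$activity_Bq_cc / 1000
  } else {
    stop(sprintf("read_tac: %s missing column activity_kBq_cc", path),
         call. = FALSE)
  }
  sch <- tryCatch(as_frame_schedule(df$frame_start_min, df$frame_end_min),
                  error = function(e)
                    stop(sprintf("read_tac: %s: %s", path, conditionMessage(e)),
                         call. = FALSE))
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  tac(sch, act, label = label, noisy = noisy)
}

#' @param x a [tac()] object.
#' @rdname read_tac
#' @export
write_tac <- function(x, path) {
  stopifnot(inherits(x, "tac"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# units=kBq/cc", con)
  utils::write.csv(format(as.data.frame(x), digits = 17, trim = TRUE,
                          scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write arterial blood samples
#'
#' CSV with header \code{time_min,activity_kBq_cc} (optional \code{weight}
#' column and \code{# units=} comment, as for [read_tac()]).
#'
#' @param path CSV file path.
#' @return \code{read_blood_samples}: a [blood_samples()] object.
#' @export
read_blood_samples <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time_min", "activity_kBq_cc") %in% names(df)))
    stop(sprintf("read_blood_samples: %s needs columns time_min, activity_kBq_cc",
                 path), call. = FALSE)
  act <- df$activity_kBq_cc
  if (identical(.read_units(path), "Bq/cc")) act <- act / 1000
  blood_samples(df$time_min, act,
                weights = if ("weight" %in% names(df)) df$weight else NULL)
}

#' @param x a [blood_samples()] object.
#' @rdname read_blood_samples
#' @export
write_blood_samples <- function(x, path) {
  stopifnot(inherits(x, "blood_samples"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# units=kBq/cc", con)
  df <- data.frame(time_min = x$time, activity_kBq_cc = x$activity)
  if (!is.null(x$weights)) df$weight <- x$weights
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- frame averaging and peaks --------------------------------------------

#' Frame-average a continuous function
#'
#' The operator \eqn{\frac{1}{t_e - t_b}\int_{t_b}^{t_e} f(t)\,dt} applied by
#' all model-output equations. Uses adaptive quadrature
#' (\code{stats::integrate}, absolute tolerance \code{1e-8}); the model
#' internals use exact antiderivatives instead and this generic form is for
#' arbitrary user functions and cross-checks.
#'
#' @param f vectorized function of time (minutes) returning kBq/cc.
#' @param frame numeric \code{c(t_b, t_e)} with \code{t_b < t_e}, or a
#'   [frame_schedule()] (then one average per frame is returned).
#' @param ... passed on to \code{f}.
#' @return Frame-averaged value(s), kBq/cc.
#' @export
frame_average <- function(f, frame, ...) {
  if (inherits(frame, "frame_schedule")) {
    return(vapply(seq_len(nrow(frame)), function(i)
      frame_average(f, c(frame$start[i], frame$end[i]), ...), numeric(1)))
  }
  tb <- frame[[1]]; te <- frame[[2]]
  if (!is.finite(tb) || !is.finite(te) || tb >= te)
    stop("frame_average: need t_b < t_e", call. = FALSE)
  q <- stats::integrate(f, tb, te, ..., abs.tol = 1e-8, rel.tol = 1e-8,
                        subdivisions = 500L)
  q$value / (te - tb)
}

#' Peak frame of a time-activity curve
#'
#' Returns the maximum per-frame value within a time window, with frames
#' assigned to the window by their midpoints and ties broken by the earliest
#' frame. The peak is the frame-averaged value as measured — not a
#' continuous-time supremum — because dynamic-PET data only exist at frame
#' resolution.
#'
#' @param x a [tac()].
#' @param window \code{c(t_min, t_max)} in minutes; default spans the scan.
#' @return list with \code{time} (frame midpoint, min), \code{value}
#'   (kBq/cc) and \code{frame} (index).
#' @export
peak_of_tac <- function(x, window = c(-Inf, Inf)) {
  stopifnot(inherits(x, "tac"))
  inwin <- x$schedule$mid >= window[1] & x$schedule$mid <= window[2]
  if (!any(inwin))
    stop("peak_of_tac: window contains no frame midpoints", call. = FALSE)
  idx <- which(inwin)
  i <- idx[which.max(x$values[idx])]   # which.max takes the earliest tie
  list(time = x$schedule$mid[i], value = x$values[i], frame = i)
}
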