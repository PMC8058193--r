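test_that("frame_schedule builds the 23-frame protocol and simple cases", {
  sch <- frame_schedule(list(c(11, 8), c(1, 12), c(2, 60), c(1, 180),
                             c(8, 400)))
  expect_equal(nrow(sch), 23L)
  expect_equal(max(sch$end) * 60, 3600)
  expect_equal(c(sch$start[1], sch$end[1]), c(0, 8 / 60))

  one <- frame_schedule(list(c(1, 60)))
  expect_equal(nrow(one), 1L)
  expect_equal(c(one$start, one$end), c(0, 1))

  three <- frame_schedule(list(c(2, 30), c(1, 60)))
  expect_equal(three$start, c(0, 0.5, 1))
  expect_equal(three$end, c(0.5, 1, 2))
  expect_equal(sum(three$dur) * 60, 120)
})

test_that("frame_schedule total duration is exact and errors are raised", {
  spec <- list(c(7, 13), c(3, 17), c(5, 111))
  sch <- frame_schedule(spec)
  expect_identical(max(sch$end) * 60,
                   sum(vapply(spec, function(x) x[1] * x[2], numeric(1))))
  expect_error(frame_schedule(list()), "non-empty")
  expect_error(frame_schedule(list(c(0, 10))), "counts")
  expect_error(frame_schedule(list(c(2, -5))), "durations|counts")
  expect_error(as_frame_schedule(c(0, 1), c(2, 3)), "overlap")
  expect_error(as_frame_schedule(1, 1), "start >= end")
})

test_that("frame_average reproduces means of known functions", {
  expect_equal(frame_average(function(t) rep(3.7, length(t)), c(2, 5)), 3.7)
  expect_equal(frame_average(identity, c(0, 1)), 0.5)
  expect_equal(frame_average(function(t) exp(-t), c(0, 1)),
               1 - exp(-1), tolerance = 1e-9)
  expect_error(frame_average(identity, c(1, 1)), "t_b < t_e")
})

test_that("frame_average is linear and bounded by monotone extremes", {
  set.seed(11)
  for (i in 1:10) {
    a <- runif(1, -2, 2); b <- runif(1, -2, 2)
    l1 <- runif(1, 0.1, 3); l2 <- runif(1, 0.1, 3)
    f <- function(t) exp(-l1 * t)
    g <- function(t) t * exp(-l2 * t)
    fr <- sort(runif(2, 0, 5))
    expect_equal(frame_average(function(t) a * f(t) + b * g(t), fr),
                 a * frame_average(f, fr) + b * frame_average(g, fr),
                 tolerance = 1e-7)
  }
  # monotone decreasing f: average within [f(t_e), f(t_b)]
  av <- frame_average(function(t) exp(-t), c(1, 2))
  expect_gt(av, exp(-2))
  expect_lt(av, exp(-1))
})

test_that("TAC file round-trip is the identity and units are normalized", {
  sch <- rat_frame_schedule()
  set.seed(3)
  x <- tac(sch, runif(23, 0, 500), label = "lv")
  path <- withr::local_tempfile(fileext = ".csv")
  write_tac(x, path)
  y <- read_tac(path)
  expect_lt(rel_err(y$values, x$values), 1e-9)
  expect_equal(y$schedule$start, sch$start, tolerance = 1e-12)

  # Bq/cc inputs are divided by 1000
  df <- data.frame(frame_start_min = c(0, 1), frame_end_min = c(1, 2),
                   activity_Bq_cc = c(1500, 2500))
  p2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, p2, row.names = FALSE)
  expect_equal(read_tac(p2)$values, c(1.5, 2.5))

  # unit comment line is honored
  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# units=Bq/cc", "frame_start_min,frame_end_min,activity_kBq_cc",
               "0,1,1000"), p3)
  expect_equal(read_tac(p3)$values, 1)
})

test_that("malformed TAC files fail with informative errors", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame_start_min,frame_end_min,activity_kBq_cc",
               "0,2,1", "1,3,2"), p)
  expect_error(read_tac(p), "overlap")
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame_start_min,activity_kBq_cc", "0,1"), p2)
  expect_error(read_tac(p2), "missing column")
  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# units=Ci/ml", "frame_start_min,frame_end_min,activity_kBq_cc",
               "0,1,1"), p3)
  expect_error(read_tac(p3), "units")
})

test_that("blood sample file round-trip and invariants hold", {
  s <- blood_samples(arterial_sample_times(),
                     eval_feng(ref_feng(), arterial_sample_times()))
  p <- withr::local_tempfile(fileext = ".csv")
  write_blood_samples(s, p)
  s2 <- read_blood_samples(p)
  expect_lt(rel_err(s2$activity, s$activity), 1e-9)
  expect_error(blood_samples(c(1, 1, 2), c(1, 2, 3)), "ascending")
  expect_error(blood_samples(c(-1, 2), c(1, 2)), "ascending|>= 0")
})

test_that("peak_of_tac finds windowed maxima with earliest-tie rule", {
  sch <- frame_schedule(list(c(4, 60)))
  mono <- tac(sch, c(9, 7, 4, 1), "mono")
  expect_equal(peak_of_tac(mono)$frame, 1L)

  tied <- tac(sch, c(1, 5, 5, 2), "tied")
  pk <- peak_of_tac(tied)
  expect_equal(pk$value, 5)
  expect_equal(pk$frame, 2L)

  # rising TAC, early window: max over frames with midpoint <= window end
  sch23 <- rat_frame_schedule()
  vals <- seq_len(23)
  rising <- tac(sch23, vals, "rise")
  win <- c(0, 10)
  idx <- which(sch23$mid >= win[1] & sch23$mid <= win[2])
  expect_equal(peak_of_tac(rising, win)$value, max(vals[idx]))
  expect_error(peak_of_tac(rising, c(70, 80)), "window")
})
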