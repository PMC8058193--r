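test_that("regional model limiting cases are exact", {
  sch <- rat_frame_schedule()
  p <- ref_feng()
  ca_avg <- vapply(seq_len(nrow(sch)), function(i)
    frame_average(function(t) eval_feng(p, t),
                  c(sch$start[i], sch$end[i])), numeric(1))
  # pure blood region
  expect_equal(model_region_frames(region_ki_params(0.1, 0.2, 0.05, 1), p,
                                   sch),
               ca_avg, tolerance = 1e-7)
  # no tissue, no blood
  expect_equal(model_region_frames(region_ki_params(0, 0.2, 0.05, 0), p,
                                   sch),
               rep(0, 23))
})

test_that("regional model matches brute-force nested quadrature", {
  sch <- rat_frame_schedule()
  p <- ref_feng()
  set.seed(13)
  for (rep in 1:3) {
    rp <- region_ki_params(runif(1, 0.05, 0.2), runif(1, 0.1, 0.4),
                           runif(1, 0.02, 0.12), runif(1, 0, 0.05))
    mr <- model_region_frames(rp, p, sch)
    for (i in c(4, 14, 23)) {
      ref <- quad_region_frame(rp, p, sch$start[i], sch$end[i])
      expect_lt(abs(mr[i] - ref) / abs(ref), 1e-5)
    }
  }
})

test_that("regional model with TBV = 0 equals the frame-averaged tissue model", {
  sch <- rat_frame_schedule()
  p <- ref_feng()
  rp <- region_ki_params(0.12, 0.3, 0.07, 0)
  kin <- two_tissue_params(0.12, 0.3, 0.07, 0)
  mr <- model_region_frames(rp, p, sch)
  ct_avg <- vapply(seq_len(nrow(sch)), function(i)
    frame_average(function(t) solve_tissue(kin, p, t),
                  c(sch$start[i], sch$end[i])), numeric(1))
  expect_lt(rel_err(mr, ct_avg, floor = 1e-8 * max(ct_avg)), 1e-7)
})

test_that("fit_region recovers noiseless regional parameters", {
  sch <- rat_frame_schedule()
  p <- ref_feng()
  rp <- region_ki_params(0.11, 0.22, 0.06, 0.02)
  y <- tac(sch, model_region_frames(rp, p, sch), "voi")
  f <- fit_region(y, p, seed = 1)
  ki_true <- ki_from_micro(rp)
  expect_lt(abs(f$Ki - ki_true) / ki_true, 0.01)
  # derived quantities are definitional
  expect_identical(f$Ki, ki_from_micro(f$params))
  expect_identical(f$RC, 1 - f$params[["TBV"]])
  expect_true(f$RC >= 0 && f$RC <= 1)
})

test_that("a blood-only TAC drives TBV to one and Ki to zero", {
  sch <- rat_frame_schedule()
  p <- ref_feng()
  blood <- tac(sch, model_region_frames(region_ki_params(0, 0.2, 0.05, 1),
                                        p, sch), "blood")
  b <- list(lower = c(K1 = 1e-4, k2 = 1e-4, k3 = 1e-4, TBV = 0),
            upper = c(K1 = 2, k2 = 2, k3 = 2, TBV = 1))
  f <- fit_region(blood, p, bounds = b, seed = 1)
  expect_gt(f$params[["TBV"]], 0.99)
  # at TBV = 1 the kinetic rates drop out of the model, so check the fitted
  # tissue contribution rather than Ki itself
  expect_lt((1 - f$params[["TBV"]]) * f$Ki, 1e-3)
  expect_lt(rel_err(f$fitted, blood$values, floor = 1), 1e-4)
})

test_that("fit_region needs at least four frames", {
  sch3 <- frame_schedule(list(c(3, 1200)))
  p <- ref_feng()
  y <- tac(sch3, model_region_frames(region_ki_params(0.1, 0.2, 0.05, 0),
                                     p, sch3), "short")
  expect_error(fit_region(y, p), ">= 4 frames")
})

test_that("combine_tacs is a volume-weighted mean", {
  sch <- frame_schedule(list(c(4, 60)))
  t1 <- tac(sch, rep(4, 4), "a")
  t2 <- tac(sch, rep(8, 4), "b")
  expect_equal(combine_tacs(list(t1, t1), c(2, 5))$values, rep(4, 4))
  expect_equal(combine_tacs(list(t1, t2), c(1, 3))$values, rep(7, 4))
  expect_error(combine_tacs(list(t1, t2), c(1, -1)), "volumes")
})

test_that("batch_fit fits VOIs and volume-weighted super regions", {
  truth <- generate_truth(11, layout = stats::setNames(
    rep(c("sa", "sb"), each = 3), paste0("v", 1:6)))
  study <- simulate_study(truth, seed = 12)
  res <- batch_fit(study$regions, study$volumes, truth$dual$input,
                   super_map = truth$super_map, seed = 1)
  expect_equal(nrow(res), 8L)  # 6 VOIs + 2 super regions
  expect_true(all(res$RC >= 0 & res$RC <= 1))
  expect_equal(res$Ki, res$K1 * res$k3 / (res$k2 + res$k3))
  # noiseless VOI fits recover the generating Ki
  voi <- res[res$level == "voi", ]
  i <- match(voi$region, truth$regions$region)
  expect_lt(max(abs(voi$Ki - truth$regions$Ki[i]) / truth$regions$Ki[i]),
            0.01)
  expect_error(batch_fit(study$regions, study$volumes, truth$dual$input,
                         super_map = list(bad = "nope")), "unknown VOI")
})
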