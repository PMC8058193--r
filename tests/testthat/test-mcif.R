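make_dual <- function(S_mb = 0.3, S_bm = 0.2, r_b = 0.9, r_m = 0.8,
                      kin = two_tissue_params(0.2, 0.4, 0.1, 0),
                      input = ref_feng()) {
  dual_output_params(input, kin, spillover_params(S_mb, S_bm, r_b, r_m))
}

test_that("dual-output frame models reduce to their components", {
  sch <- rat_frame_schedule()
  p <- ref_feng()
  ca_avg <- vapply(seq_len(nrow(sch)), function(i)
    frame_average(function(t) eval_feng(p, t),
                  c(sch$start[i], sch$end[i])), numeric(1))
  # no contamination, full recovery: frame-averaged Ca exactly
  expect_equal(model_idif_frames(make_dual(S_mb = 0, r_b = 1), sch), ca_avg,
               tolerance = 1e-7)
  # null output
  expect_equal(model_idif_frames(make_dual(S_mb = 0, r_b = 1e-12), sch),
               1e-12 * ca_avg, tolerance = 1e-7)
  # myocardium: r_m = 1, S_bm = 0 is frame-averaged C_T
  kin <- two_tissue_params(0.2, 0.4, 0.1, 0)
  ct_avg <- vapply(seq_len(nrow(sch)), function(i)
    frame_average(function(t) solve_tissue(kin, p, t),
                  c(sch$start[i], sch$end[i])), numeric(1))
  expect_equal(model_myo_frames(make_dual(S_bm = 0, r_m = 1, kin = kin), sch),
               ct_avg, tolerance = 1e-7)
  # K1 = 0: pure blood spillover
  expect_equal(
    model_myo_frames(make_dual(S_bm = 0.5,
                               kin = two_tissue_params(0, 0.4, 0.1, 0)), sch),
    0.5 * ca_avg, tolerance = 1e-7)
})

test_that("frame models are the stated linear combinations (quadrature oracle)", {
  sch <- rat_frame_schedule()
  dp <- make_dual(S_mb = 0.3, S_bm = 0.2, r_b = 0.8, r_m = 0.85)
  kin <- two_tissue_params(0.2, 0.4, 0.1, 0)
  p <- ref_feng()
  idx <- c(1, 5, 12, 19, 23)
  for (i in idx) {
    fr <- c(sch$start[i], sch$end[i])
    ca <- frame_average(function(t) eval_feng(p, t), fr)
    ct <- frame_average(function(t) solve_tissue(kin, p, t), fr)
    expect_equal(model_idif_frames(dp, sch)[i], 0.3 * ct + 0.8 * ca,
                 tolerance = 1e-7)
    expect_equal(model_myo_frames(dp, sch)[i], 0.85 * ct + 0.2 * ca,
                 tolerance = 1e-7)
  }
})

test_that("objective O1 sums squared frame residuals over both outputs", {
  sch <- rat_frame_schedule()
  dp <- make_dual()
  idif <- tac(sch, model_idif_frames(dp, sch), "idif")
  myo <- tac(sch, model_myo_frames(dp, sch), "myo")
  expect_equal(objective_o1(dp, idif, myo), 0)
  # +1 kBq/cc on every blood frame: 23 frames x 1^2
  idif_off <- tac(sch, idif$values + 1, "idif")
  expect_equal(objective_o1(dp, idif_off, myo), 23)
  # random toy case equals a direct loop
  set.seed(21)
  yi <- tac(sch, idif$values + rnorm(23), "yi", noisy = TRUE)
  ym <- tac(sch, myo$values + rnorm(23), "ym", noisy = TRUE)
  o1_loop <- 0
  mi <- model_idif_frames(dp, sch); mm <- model_myo_frames(dp, sch)
  for (i in 1:23)
    o1_loop <- o1_loop + (mi[i] - yi$values[i])^2 + (mm[i] - ym$values[i])^2
  expect_equal(objective_o1(dp, yi, ym), o1_loop, tolerance = 1e-12)
  # schedule mismatch
  sch2 <- frame_schedule(list(c(23, 120)))
  expect_error(objective_o1(dp, tac(sch2, yi$values, ""), ym),
               "different schedules")
})

test_that("objective O2 squares the windowed peak mismatches", {
  sch <- rat_frame_schedule()
  dp <- make_dual()
  mi <- model_idif_frames(dp, sch)
  mm <- model_myo_frames(dp, sch)
  idif <- tac(sch, mi, "idif")
  myo <- tac(sch, mm, "myo")
  expect_equal(objective_o2(dp, idif, myo), 0)
  # blood data peak lowered so the model peak exceeds it by 2
  v <- mi; v[which.max(v)] <- max(v) - 2
  expect_equal(objective_o2(dp, tac(sch, v, "idif"), myo), 4)
  # equals a peak_of_tac-based brute-force computation on a toy case
  set.seed(8)
  yi <- tac(sch, mi * (1 + 0.1 * rnorm(23)), "yi", noisy = TRUE)
  ym <- tac(sch, mm * (1 + 0.1 * rnorm(23)), "ym", noisy = TRUE)
  inw <- sch$mid >= 0 & sch$mid <= 10
  brute <- (max(mi) - peak_of_tac(yi)$value)^2 +
    (max(mm[inw]) - peak_of_tac(ym, c(0, 10))$value)^2
  expect_equal(objective_o2(dp, yi, ym), brute, tolerance = 1e-12)
  expect_error(objective_o2(dp, yi, ym, myo_peak_window = c(70, 80)),
               "window")
})

test_that("fit_mcif recovers a noiseless synthetic study", {
  truth <- generate_truth(42)
  study <- simulate_study(truth, seed = 2)
  recov <- c(r_b = truth$dual$contamination[["r_b"]],
             r_m = truth$dual$contamination[["r_m"]])
  fit <- fit_mcif(study$pet_idif, study$pet_myo, recovery = recov,
                  fix_k4 = TRUE, n_starts = 10, seed = 1)
  expect_true(fit$converged)
  expect_equal(fit$o_total, fit$o1 + fit$o2)
  auc_t <- feng_auc(truth$dual$input, 60)
  auc_f <- feng_auc(fit$params$input, 60)
  expect_lt(abs(auc_f - auc_t) / auc_t, 0.02)
})

test_that("fit_mcif guards frames, bounds and is deterministic", {
  sch10 <- frame_schedule(list(c(10, 360)))
  dp <- make_dual()
  yi <- tac(sch10, model_idif_frames(dp, sch10), "i")
  ym <- tac(sch10, model_myo_frames(dp, sch10), "m")
  expect_error(fit_mcif(yi, ym), ">= 15 frames")

  truth <- generate_truth(7)
  study <- simulate_study(truth, noise = noise_config(sigma0 = 1), seed = 3)
  f1 <- suppressWarnings(fit_mcif(study$pet_idif, study$pet_myo, seed = 5))
  f2 <- suppressWarnings(fit_mcif(study$pet_idif, study$pet_myo, seed = 5))
  expect_identical(coef(f1), coef(f2))
  expect_error(fit_mcif(study$pet_idif, study$pet_myo,
                        r_bounds = c(0.9, 0.5)), "r_bounds")
})

test_that("extract_mcif returns the uncontaminated fitted input", {
  truth <- generate_truth(42)
  study <- simulate_study(truth, seed = 2)
  recov <- c(r_b = truth$dual$contamination[["r_b"]],
             r_m = truth$dual$contamination[["r_m"]])
  fit <- fit_mcif(study$pet_idif, study$pet_myo, recovery = recov,
                  fix_k4 = TRUE, n_starts = 10, seed = 1)
  # pointwise recovery within 2% of the true peak
  tt <- seq(0.25, 60, by = 0.25)
  mc <- extract_mcif(fit, times = tt)
  pk <- feng_peak(truth$dual$input, 60)$value
  expect_lt(max(abs(mc$activity - eval_feng(truth$dual$input, tt))) / pk,
            0.02)
  # pre-appearance times evaluate to zero
  expect_equal(extract_mcif(fit, times = 1e-6)$activity, 0)
  # AUC consistency with the fitted parameters
  sch <- study$pet_idif$schedule
  mtac <- extract_mcif(fit, schedule = sch)
  expect_equal(sum(mtac$values * sch$dur), feng_auc(fit$params$input, 60),
               tolerance = 1e-10)
  # unconverged fits refuse extraction
  bad <- fit; bad$converged <- FALSE
  expect_error(extract_mcif(bad, times = tt), "converge")
  expect_error(extract_mcif(fit), "exactly one")
})
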