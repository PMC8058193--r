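test_that("generate_truth is deterministic and respects its ranges", {
  t1 <- generate_truth(5)
  t2 <- generate_truth(5)
  expect_identical(unclass(t1$dual$input), unclass(t2$dual$input))
  expect_identical(t1$regions, t2$regions)
  # implied cerebral Ki bounded by the range arithmetic (<= 0.2*0.12/0.12)
  expect_true(all(t1$regions$Ki > 0 & t1$regions$Ki <= 0.2))
  expect_true(all(t1$regions$TBV <= 0.03))
  expect_equal(nrow(t1$regions), 35L)
  expect_equal(length(t1$super_map), 4L)
  expect_error(generate_truth(1, layout = character(0)), "empty")
})

test_that("implied cerebral Ki distribution overlaps the reported range", {
  kis <- unlist(lapply(1:30, function(s) generate_truth(s)$regions$Ki))
  expect_gt(mean(kis >= 0.019 & kis <= 0.032), 0.1)
  expect_lt(min(kis), 0.019)
  expect_gt(max(kis), 0.032)
})

test_that("zero-noise simulation equals the deterministic forward model", {
  truth <- generate_truth(3)
  sch <- rat_frame_schedule()
  st <- simulate_study(truth, seed = 9)
  expect_identical(st$pet_idif$values, model_idif_frames(truth$dual, sch))
  expect_identical(st$pet_myo$values, model_myo_frames(truth$dual, sch))
  r1 <- truth$regions[1, ]
  expect_identical(st$regions[[r1$region]]$values,
                   model_region_frames(
                     region_ki_params(r1$K1, r1$k2, r1$k3, r1$TBV),
                     truth$dual$input, sch))
  expect_identical(st$samples$activity,
                   eval_feng(truth$dual$input, arterial_sample_times()))
})

test_that("seeded simulation is bit-identical across runs", {
  truth <- generate_truth(3)
  n <- noise_config(sigma0 = 0.5, sample_cv = 0.03)
  a <- simulate_study(truth, noise = n, seed = 4)
  b <- simulate_study(truth, noise = n, seed = 4)
  expect_identical(a$pet_idif$values, b$pet_idif$values)
  expect_identical(a$samples$activity, b$samples$activity)
  expect_true(a$pet_idif$noisy)
  expect_error(simulate_study(truth, sample_times = c(1, 65)),
               "beyond scan end")
})

test_that("frame noise is unbiased with the configured variance", {
  layout <- c(v1 = "s1")   # single region keeps replication cheap
  truth <- generate_truth(6, layout = layout)
  sch <- rat_frame_schedule()
  v0 <- model_idif_frames(truth$dual, sch)
  sigma0 <- 0.6
  reps <- sapply(1:300, function(k)
    simulate_study(truth, noise = noise_config(sigma0 = sigma0),
                   seed = k)$pet_idif$values)
  sd_target <- sigma0 * sqrt(pmax(v0, 0) / sch$dur)
  sd_emp <- apply(reps, 1, sd)
  pos <- sd_target > 0   # pre-appearance frames are exactly noise-free
  expect_identical(sd_emp[!pos], rep(0, sum(!pos)))
  expect_lt(max(abs(sd_emp[pos] - sd_target[pos]) / sd_target[pos]), 0.25)
  expect_lt(median(abs(sd_emp[pos] - sd_target[pos]) / sd_target[pos]), 0.10)
  # unbiasedness: replicate means within a few standard errors
  se <- sd_target[pos] / sqrt(300)
  expect_true(all(abs(rowMeans(reps)[pos] - v0[pos]) < 5 * se))
})

test_that("study fixtures round-trip through the file readers", {
  dir <- withr::local_tempdir()
  st <- make_study_fixture(dir, seed = 8)
  idif <- read_tac(st$paths$idif)
  expect_lt(rel_err(idif$values, st$pet_idif$values), 1e-9)
  samp <- read_blood_samples(st$paths$samples)
  expect_lt(rel_err(samp$activity, st$samples$activity), 1e-9)
  reg1 <- read_tac(st$paths$regions[[1]])
  expect_lt(rel_err(reg1$values, st$regions[[1]]$values), 1e-9)

  # truth sidecar regenerates the identical noiseless study
  tj <- jsonlite::read_json(st$paths$truth, simplifyVector = TRUE)
  inp <- do.call(feng_input, as.list(tj$input))
  kin <- do.call(two_tissue_params, as.list(tj$kinetics))
  sp <- do.call(spillover_params, as.list(tj$contamination))
  dual <- dual_output_params(inp, kin, sp)
  sch <- rat_frame_schedule()
  expect_lt(rel_err(model_idif_frames(dual, sch), st$pet_idif$values), 1e-9)
  r1 <- tj$regions[1, ]
  expect_lt(rel_err(model_region_frames(
    region_ki_params(r1$K1, r1$k2, r1$k3, r1$TBV), inp, sch),
    st$regions[[r1$region]]$values), 1e-9)
})
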