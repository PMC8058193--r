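# Digital-rat phantom: ground-truth parameter generation and forward
# simulation of contaminated blood/myocardium TACs, regional brain TACs and
# arterial samples on the standard schedules, so every stage of the
# pipeline is testable without animal data.

#' Default phantom parameter ranges
#'
#' Uniform sampling ranges for [generate_truth()]. Regional rates are chosen
#' so the implied cerebral \eqn{K_i = K_1 k_3/(k_2+k_3)} falls in the
#' 0.02--0.03 1/min regime typical of fasted rats, TBV stays at or below
#' 0.03 (so RC = 1-TBV lies in \[0.97, 1\]), and the input amplitudes give a
#' first-pass blood peak of a few hundred kBq/cc as seen after a
#' 200--300 uCi tail-vein FDG bolus.
#'
#' @return Nested list of \code{c(min, max)} ranges.
#' @export
phantom_ranges <- function() {
  list(
    input = list(A1 = c(2000, 5000), A2 = c(20, 60), A3 = c(20, 40),
                 lam1 = c(3, 6), lam2 = c(0.3, 1.2), lam3 = c(0.005, 0.02),
                 tau = c(0.1, 0.3)),
    kinetics = list(K1 = c(0.1, 0.6), k2 = c(0.1, 0.8), k3 = c(0.05, 0.3)),
    contamination = list(S_mb = c(0.1, 0.4), S_bm = c(0.1, 0.4),
                         r_b = c(0.85, 0.98), r_m = c(0.75, 0.95)),
    region = list(K1 = c(0.05, 0.2), k2 = c(0.1, 0.4), k3 = c(0.02, 0.12),
                  TBV = c(0, 0.03), volume = c(20, 400)))
}

# default VOI layout: 35 VOIs binned into the four super regions
.default_region_layout <- function() {
  counts <- c(cerebellum = 9, frontal_cortex = 10, hippocampus = 8,
              striatum = 8)
  unlist(lapply(names(counts), function(s)
    stats::setNames(rep(s, counts[[s]]),
                    sprintf("%s_%02d", s, seq_len(counts[[s]])))))
}

#' Draw a ground-truth digital rat
#'
#' Draws the full 15-parameter dual-output state (with \eqn{k_4 = 0}:
#' irreversible FDG over a 60-min scan) and per-VOI regional parameters from
#' the documented uniform ranges. Deterministic per seed.
#'
#' @param seed integer seed.
#' @param layout named character vector VOI name -> super-region name
#'   (default: 35 VOIs in 4 super regions).
#' @param ranges sampling ranges, see [phantom_ranges()].
#' @return An object of class \code{"phantom_truth"}: \code{dual}
#'   (a [dual_output_params()]), \code{regions} (data frame with region,
#'   super, K1, k2, k3, TBV, Ki, volume), \code{super_map}, \code{seed}.
#' @export
generate_truth <- function(seed, layout = .default_region_layout(),
                           ranges = phantom_ranges()) {
  if (length(layout) == 0L)
    stop("generate_truth: empty region layout", call. = FALSE)
  draw <- function(r) stats::runif(1, r[1], r[2])
  .with_seed(seed, {
    inp <- feng_input(A1 = draw(ranges$input$A1), A2 = draw(ranges$input$A2),
                      A3 = draw(ranges$input$A3),
                      lam1 = draw(ranges$input$lam1),
                      lam2 = draw(ranges$input$lam2),
                      lam3 = draw(ranges$input$lam3),
                      tau = draw(ranges$input$tau))
    kin <- two_tissue_params(draw(ranges$kinetics$K1),
                             draw(ranges$kinetics$k2),
                             draw(ranges$kinetics$k3), 0)
    sp <- spillover_params(draw(ranges$contamination$S_mb),
                           draw(ranges$contamination$S_bm),
                           draw(ranges$contamination$r_b),
                           draw(ranges$contamination$r_m))
    n <- length(layout)
    rg <- ranges$region
    regions <- data.frame(
      region = names(layout), super = unname(layout),
      K1 = stats::runif(n, rg$K1[1], rg$K1[2]),
      k2 = stats::runif(n, rg$k2[1], rg$k2[2]),
      k3 = stats::runif(n, rg$k3[1], rg$k3[2]),
      TBV = stats::runif(n, rg$TBV[1], rg$TBV[2]),
      volume = stats::runif(n, rg$volume[1], rg$volume[2]))
    regions$Ki <- regions$K1 * regions$k3 / (regions$k2 + regions$k3)
    super_map <- split(regions$region, regions$super)
    structure(list(dual = dual_output_params(inp, kin, sp),
                   regions = regions, super_map = super_map, seed = seed),
              class = "phantom_truth")
  })
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("Digital-rat phantom truth (seed %d): %d VOIs in %d super regions\n",
              x$seed, nrow(x$regions), length(x$super_map)))
  cat(sprintf("  implied cerebral Ki range: [%.4g, %.4g] 1/min\n",
              min(x$regions$Ki), max(x$regions$Ki)))
  invisible(x)
}

#' Noise configuration for the phantom
#'
#' Frame noise is additive zero-mean Gaussian with
#' \eqn{SD_i = \sigma_0\sqrt{\mathrm{value}_i/\Delta t_i}} — variance
#' proportional to activity over frame duration, the standard surrogate for
#' reconstructed-PET frame statistics. Arterial-sample noise is proportional
#' with coefficient of variation \code{sample_cv} (gamma-counter
#' repeatability). Negative noisy values are retained (clipping would bias
#' low-activity frames); the resulting TACs carry \code{noisy = TRUE}.
#'
#' @param sigma0 frame-noise scale (0 disables), kBq/cc per sqrt(kBq/cc/min).
#' @param sample_cv fractional SD of arterial samples (0 disables).
#' @return list of class \code{"noise_config"}.
#' @export
noise_config <- function(sigma0 = 0, sample_cv = 0) {
  if (sigma0 < 0 || sample_cv < 0)
    stop("noise_config: noise scales must be >= 0", call. = FALSE)
  structure(list(sigma0 = sigma0, sample_cv = sample_cv),
            class = "noise_config")
}

#' Frame-noise scale giving a target relative SD at the blood peak
#'
#' Solves \eqn{\sigma_0\sqrt{v_{peak}/\Delta t_{peak}} = cv \cdot v_{peak}}
#' for \eqn{\sigma_0}, where \eqn{v_{peak}} is the largest noiseless
#' blood-pool frame value.
#'
#' @param truth a [generate_truth()] object.
#' @param schedule a [frame_schedule()].
#' @param cv target relative SD at the peak frame (default 0.05).
#' @return \eqn{\sigma_0} for [noise_config()].
#' @export
sigma0_for_peak_cv <- function(truth, schedule = rat_frame_schedule(),
                               cv = 0.05) {
  v <- model_idif_frames(truth$dual, schedule)
  i <- which.max(v)
  cv * sqrt(v[i] * schedule$dur[i])
}

#' Simulate one dynamic PET study from a phantom truth
#'
#' Noiseless forward curves come from [model_idif_frames()],
#' [model_myo_frames()] and [model_region_frames()]; arterial samples are
#' the true \eqn{C_a} at the draw times. Noise is then added per
#' [noise_config()]. Seeded and reproducible.
#'
#' @param truth a [generate_truth()] object.
#' @param schedule acquisition [frame_schedule()].
#' @param sample_times arterial draw times, minutes (must lie within the
#'   scan).
#' @param noise a [noise_config()].
#' @param seed integer seed for the noise draw.
#' @return list with \code{pet_idif}, \code{pet_myo} ([tac()]s),
#'   \code{regions} (named list of [tac()]s), \code{volumes} (named vector),
#'   \code{samples} (a [blood_samples()]), \code{truth}.
#' @export
simulate_study <- function(truth, schedule = rat_frame_schedule(),
                           sample_times = arterial_sample_times(),
                           noise = noise_config(), seed = 1) {
  stopifnot(inherits(truth, "phantom_truth"))
  if (any(sample_times > max(schedule$end) + 1e-9))
    stop("simulate_study: sample time beyond scan end", call. = FALSE)
  idif0 <- model_idif_frames(truth$dual, schedule)
  myo0 <- model_myo_frames(truth$dual, schedule)
  reg0 <- lapply(seq_len(nrow(truth$regions)), function(i) {
    r <- truth$regions[i, ]
    model_region_frames(region_ki_params(r$K1, r$k2, r$k3, r$TBV),
                        truth$dual$input, schedule)
  })
  samp0 <- eval_feng(truth$dual$input, sample_times)
  .with_seed(seed, {
    addn <- function(v) {
      if (noise$sigma0 == 0) return(v)
      v + stats::rnorm(length(v),
                       sd = noise$sigma0 * sqrt(pmax(v, 0) / schedule$dur))
    }
    noisy <- noise$sigma0 > 0
    regions <- lapply(seq_along(reg0), function(i)
      tac(schedule, addn(reg0[[i]]), label = truth$regions$region[i],
          noisy = noisy))
    names(regions) <- truth$regions$region
    samp <- if (noise$sample_cv > 0)
      samp0 * (1 + noise$sample_cv * stats::rnorm(length(samp0)))
    else samp0
    list(pet_idif = tac(schedule, addn(idif0), label = "LV blood pool",
                        noisy = noisy),
         pet_myo = tac(schedule, addn(myo0), label = "myocardium",
                       noisy = noisy),
         regions = regions,
         volumes = stats::setNames(truth$regions$volume,
                                   truth$regions$region),
         samples = blood_samples(sample_times, samp),
         truth = truth)
  })
}

#' Write a complete one-rat study fixture to disk
#'
#' Emits blood-pool and myocardium TAC CSVs, one CSV per VOI, the arterial
#' sample CSV, a ground-truth JSON sidecar (including the scanner
#' recovery-coefficient calibration) and a manifest.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed (drives both truth and noise).
#' @param noise a [noise_config()]; default is noiseless.
#' @return Invisibly, the simulated study list with \code{$paths} attached.
#' @export
make_study_fixture <- function(dir, seed, noise = noise_config()) {
  truth <- generate_truth(seed)
  study <- simulate_study(truth, noise = noise, seed = seed + 1L)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rdir <- file.path(dir, "regions")
  if (!dir.exists(rdir)) dir.create(rdir)
  paths <- list(idif = file.path(dir, "idif.csv"),
                myo = file.path(dir, "myo.csv"),
                samples = file.path(dir, "samples.csv"),
                truth = file.path(dir, "truth.json"),
                manifest = file.path(dir, "manifest.json"),
                regions = stats::setNames(
                  file.path(rdir, paste0(truth$regions$region, ".csv")),
                  truth$regions$region))
  write_tac(study$pet_idif, paths$idif)
  write_tac(study$pet_myo, paths$myo)
  for (nm in names(study$regions))
    write_tac(study$regions[[nm]], paths$regions[[nm]])
  write_blood_samples(study$samples, paths$samples)
  tj <- list(seed = seed,
             input = as.list(unclass(truth$dual$input)),
             kinetics = as.list(unclass(truth$dual$kinetics)),
             contamination = as.list(unclass(truth$dual$contamination)),
             regions = truth$regions,
             super_map = truth$super_map)
  jsonlite::write_json(tj, paths$truth, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  jsonlite::write_json(
    list(seed = seed, noise = unclass(noise),
         n_frames = nrow(study$pet_idif$schedule),
         n_regions = nrow(truth$regions),
         files = list(idif = basename(paths$idif), myo = basename(paths$myo),
                      samples = basename(paths$samples),
                      truth = basename(paths$truth),
                      regions = file.path("regions",
                                          basename(paths$regions)))),
    paths$manifest, auto_unbox = TRUE, digits = NA)
  study$paths <- paths
  invisible(study)
}
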