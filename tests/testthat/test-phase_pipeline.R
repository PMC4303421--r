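test_that("frame-time mapping is linear in the sampling interval", {
  expect_equal(frame_minutes(0), 0)
  expect_equal(frame_minutes(12, 5), 60)
  expect_equal(frame_minutes(c(1, 2), 2.5), c(2.5, 5))
})

test_that("artifact-frame detection flags half-frame intensity splits", {
  frames <- replicate(10, constant_image(100, 10, 10), simplify = FALSE)
  shifted <- matrix(100, 10, 10); shifted[1:5, ] <- 160
  frames[[7]] <- grey_image(shifted)
  expect_equal(detect_artifact_frames(frames, 6), 6L)  # 0-based index

  clean <- replicate(8, constant_image(55), simplify = FALSE)
  expect_length(detect_artifact_frames(clean, 6), 0L)
  expect_error(detect_artifact_frames(clean[1:3], 6),
               class = "stackops_parameter_error")
})

test_that("difference signals of identical frames are degenerate", {
  frames <- replicate(6, constant_image(80, 12, 12), simplify = FALSE)
  sig <- compute_phase_signals(frames)
  expect_length(sig$energy, 5L)
  expect_equal(sig$energy$values, rep(1, 5))
  expect_equal(sig$entropy$values, rep(0, 5))
  expect_equal(sig$skewness$values, rep(0, 5))
  expect_equal(sig$kurtosis$values, rep(0, 5))

  two <- compute_phase_signals(frames[1:2])
  expect_length(two$skewness, 1L)
  expect_error(compute_phase_signals(frames[1]),
               class = "stackops_parameter_error")
  expect_error(
    compute_phase_signals(list(constant_image(1, 4, 4),
                               constant_image(1, 4, 5))),
    class = "stackops_validation_error")
})

test_that("boundary estimation combines per-signal extrema as mean +/- se", {
  shape <- function(peak) {
    v <- c(seq(0, 10, length.out = peak + 1),
           seq(10, 1, length.out = 30 - peak),
           seq(1, 8, length.out = 20))
    signal_item(v)
  }
  sigs <- list(energy = shape(20), entropy = signal_item(-shape(20)$values),
               skewness = shape(20), kurtosis = shape(20))
  est <- estimate_boundaries(sigs, phase_config(median_window = 1L))
  expect_equal(est$boundary_I_II$mean, 20)
  expect_equal(est$boundary_I_II$se, 0)

  # maxima at 19/20/21/20 -> mean 20, se = sd/2
  sigs2 <- list(energy = shape(19), entropy = signal_item(-shape(20)$values),
                skewness = shape(21), kurtosis = shape(20))
  est2 <- estimate_boundaries(sigs2, phase_config(median_window = 1L))
  expect_equal(est2$boundary_I_II$mean, 20)
  expect_equal(est2$boundary_I_II$se, sd(c(19, 20, 21, 20)) / 2,
               tolerance = 1e-12)

  monotone <- lapply(1:4, function(i) signal_item(seq_len(50)))
  names(monotone) <- c("energy", "entropy", "skewness", "kurtosis")
  expect_error(estimate_boundaries(monotone, phase_config()),
               class = "stackops_detection_error")
})

test_that("the monolayer frame is where the area reaches and keeps its minimum", {
  expect_equal(monolayer_frame(c(100, 50, 10, 0, 0, 0), 0), 3L)
  expect_equal(monolayer_frame(c(100, 50, 0, 5, 0, 0), 0), 4L)
  expect_equal(monolayer_frame(7, 0), 0L)
  expect_equal(monolayer_frame(c(40, 12, 9, 11, 10), 2), 2L)
  expect_error(monolayer_frame(c(1, 2), -1), class = "stackops_parameter_error")
})

test_that("the full pipeline recovers ground-truth phases on synthetic video", {
  tl <- small_timelapse(seed = 77, b = c(15, 45, 70), n = 90, noise = 4)
  rep <- analyze_timelapse(tl$frames, phase_config(spot_seed = tl$spot_seed))
  expect_lte(abs(rep$boundary_I_II$mean - 15), 3)
  expect_lte(abs(rep$boundary_II_III$mean - 45), 3)
  expect_lte(abs(rep$monolayer_frame - 70), 2)
  # report invariants
  expect_equal(rep$t23, rep$t123 - rep$t1$minutes)
  expect_equal(rep$t2$minutes,
               (rep$boundary_II_III$mean - rep$boundary_I_II$mean) * 5)
  expect_equal(rep$t123, rep$monolayer_frame * 5)
  expect_lt(rep$boundary_I_II$mean, rep$boundary_II_III$mean)
  expect_lt(rep$boundary_II_III$mean, rep$monolayer_frame)
})

test_that("a constant video yields a detection error, tagged with its stage", {
  frames <- replicate(12, constant_image(90, 16, 16), simplify = FALSE)
  err <- tryCatch(
    analyze_timelapse(frames, phase_config(spot_seed = c(8, 8))),
    error = function(e) e)
  expect_s3_class(err, "stackops_detection_error")
  expect_match(conditionMessage(err), "boundary estimation")
})

test_that("the pipeline is invariant to a global intensity offset", {
  # compress the dynamic range first so the offset clamps nothing
  tl <- small_timelapse(seed = 31, noise = 2)
  base <- lapply(tl$frames, function(f) grey_image(floor(f$pixels * 0.9)))
  offset_frames <- lapply(base, function(f) grey_image(f$pixels + 10))
  cfg <- phase_config(spot_seed = tl$spot_seed)
  a <- analyze_timelapse(base, cfg)
  b <- analyze_timelapse(offset_frames, cfg)
  expect_equal(a$boundary_I_II$mean, b$boundary_I_II$mean)
  expect_equal(a$boundary_II_III$mean, b$boundary_II_III$mean)
  expect_equal(a$monolayer_frame, b$monolayer_frame)
})

test_that("sparse artifact frames barely move the recovered boundaries", {
  clean <- small_timelapse(seed = 19)
  dirty <- small_timelapse(seed = 19, artifacts = c(30L, 55L))
  cfg_c <- phase_config(spot_seed = clean$spot_seed)
  a <- analyze_timelapse(clean$frames, cfg_c)
  b <- analyze_timelapse(dirty$frames, cfg_c)
  expect_true(all(c(30L, 55L) %in% b$artifact_frames))
  expect_lte(length(b$artifact_frames), 4L)
  expect_lte(abs(a$boundary_I_II$mean - b$boundary_I_II$mean), 1)
  expect_lte(abs(a$boundary_II_III$mean - b$boundary_II_III$mean), 1)
  expect_lte(abs(a$monolayer_frame - b$monolayer_frame), 1)
})
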