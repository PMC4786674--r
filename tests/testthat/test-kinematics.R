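test_that("tail angle: straight, perpendicular and mirrored bodies", {
  tr <- make_track(c(0, 0, 0))
  expect_equal(compute_tail_angle(tr), c(0, 0, 0), tolerance = 1e-12)
  tr90 <- make_track(c(90, -90))
  expect_equal(compute_tail_angle(tr90), c(90, -90), tolerance = 1e-10)
  ## mirroring the track across the body axis negates alpha frame-wise
  tr2 <- make_track(c(10, -35, 72, 0))
  mir <- tr2
  mir$points[, , 2] <- -mir$points[, , 2]
  expect_equal(compute_tail_angle(mir), -compute_tail_angle(tr2),
               tolerance = 1e-10)
})

test_that("tail angle handles missing points", {
  tr <- make_track(c(5, 10, 15))
  tr$points[2, 11, ] <- NaN              # lose the tail tip in frame 2
  a <- compute_tail_angle(tr)
  expect_true(is.nan(a[2]) && !is.nan(a[1]) && !is.nan(a[3]))
  tr$points[, 3, ] <- NaN                # swim bladder gone everywhere
  expect_error(compute_tail_angle(tr), "unusable")
})

test_that("angle preprocessing interpolates, despikes and smooths", {
  x <- rep(7, 80); x[c(10, 11, 40)] <- NaN
  expect_equal(preprocess_angle(x), rep(7, 80), tolerance = 1e-8)
  ## single-frame 50-degree spike is removed by the 5-frame median filter
  sp <- rep(0, 80); sp[40] <- 50
  expect_lt(max(abs(preprocess_angle(sp))), 10)
  expect_error(preprocess_angle(rep(NaN, 20)), "finite")
  ## extrema of a noise-free sinusoid shift by at most one frame
  y <- 70 * sin(2 * pi * (0:649) / 20)   # 10-frame hemicycle
  ys <- preprocess_angle(y)
  expect_lte(abs(which.max(ys[1:20]) - which.max(y[1:20])), 1)
  expect_gt(max(ys), 0.95 * max(y))      # light attenuation only
})

test_that("angular velocity matches analytic derivatives", {
  ramp <- 2 * (1:100)
  v <- compute_angular_velocity(ramp)
  expect_equal(v[10:90], rep(2, 81), tolerance = 0.01)
  expect_equal(compute_angular_velocity(rep(3, 50)), rep(0, 50),
               tolerance = 1e-8)
  A <- 30; T <- 50
  x <- A * sin(2 * pi * (0:649) / T)
  expect_equal(max(abs(compute_angular_velocity(x))), 2 * pi * A / T,
               tolerance = 0.1)
})

test_that("motion threshold is strict and sign-free", {
  expect_identical(detect_motion_frames(c(1.5, 1.0, -1.5, 0.99)),
                   c(TRUE, FALSE, TRUE, FALSE))
})

test_that("morphological closing merges short gaps only", {
  m <- rep(FALSE, 60)
  m[11:20] <- TRUE; m[26:35] <- TRUE     # 5-frame gap
  b <- close_bouts(m, 10)
  expect_identical(b, data.frame(start_frame = 11L, end_frame = 35L))
  m2 <- rep(FALSE, 80)
  m2[11:20] <- TRUE; m2[41:50] <- TRUE   # 20-frame gap
  expect_identical(nrow(close_bouts(m2, 10)), 2L)
  expect_identical(nrow(close_bouts(rep(FALSE, 30), 10)), 0L)
})

test_that("closing equals the run-length gap-fill reference on random masks", {
  set.seed(42)
  for (i in 1:300) {
    n <- sample(20:120, 1); blk <- sample(2:15, 1)
    m <- runif(n) < runif(1, 0.1, 0.6)
    expect_identical(close_bouts(m, blk),
                     bouts_from_mask(oracle_close(m, blk)))
  }
})

test_that("escape-bout selection prefers the nearest post-stimulus start", {
  b <- data.frame(start_frame = c(50L, 500L), end_frame = c(80L, 540L))
  expect_identical(select_escape_bout(b, 130)$start_frame, 500L)
  b2 <- data.frame(start_frame = c(140L, 300L), end_frame = c(200L, 350L))
  expect_identical(select_escape_bout(b2, 130)$start_frame, 140L)
  expect_null(select_escape_bout(b[0, ], 130))
  expect_null(select_escape_bout(
    data.frame(start_frame = 50L, end_frame = 60L), 130))
  ## length filter and pre-stimulus tolerance
  b3 <- data.frame(start_frame = c(132L, 140L), end_frame = c(134L, 240L))
  expect_identical(select_escape_bout(b3, 130, min_frames = 10)$start_frame,
                   140L)
  b4 <- data.frame(start_frame = 125L, end_frame = 240L)
  expect_null(select_escape_bout(b4, 130))
  expect_identical(select_escape_bout(b4, 130, tolerance = 10)$start_frame,
                   125L)
})

test_that("peak detection matches the brute-force alternating-extrema search", {
  ## triangle wave: one peak per half-period, all sequential, hemicycle 10
  tri <- 80 * (2 / pi) * asin(sin(2 * pi * (1:200) / 20))
  pk <- detect_peaks(tri, NULL, delta = 15)
  expect_true(all(abs(pk$amplitude) > 70))
  expect_true(all(pk$hemicycle[-nrow(pk)] == 10))
  expect_true(all(pk$sequential[-nrow(pk)]))
  expect_false(pk$sequential[nrow(pk)])
  ## monotone trace: nothing to report
  expect_identical(nrow(detect_peaks(seq(0, 50, length.out = 60), NULL, 10)),
                   0L)
  ## a dip shallower than delta does not split a peak
  x <- c(seq(0, 50, length.out = 20), seq(50, 45, length.out = 5),
         seq(45, 52, length.out = 5), seq(52, 0, length.out = 20))
  expect_identical(nrow(detect_peaks(x, NULL, delta = 15)), 1L)
  expect_error(detect_peaks(x, NULL, delta = 0), "delta")
  ## randomized equivalence with the independent envelope-scan oracle
  set.seed(99)
  for (i in 1:200) {
    n <- sample(50:400, 1)
    x <- cumsum(rnorm(n)) + 20 * sin(2 * pi * (1:n) / sample(10:60, 1))
    delta <- runif(1, 2, 25)
    got <- detect_peaks(x, NULL, delta)[, c("frame", "amplitude", "direction")]
    rownames(got) <- NULL
    expect_equal(got, oracle_peaks(x, delta), tolerance = 1e-12)
  }
})

test_that("onset detection finds the foot of a clean rise", {
  al <- c(rep(0, 143), pmin(5 * (1:60), 75), rep(75, 50))
  o <- detect_onset(al, 131, 158)
  expect_identical(o$method, "expfit")
  expect_lte(abs(o$onset_frame - 144), 1)
  ## grid refit of the same weighted objective reproduces the curve
  w_fit <- o$fit
  tt <- seq(131, 158)
  target <- pmax(0, 5 * (tt - 143)) / max(pmax(0, 5 * (tt - 143))) * 75
  ref <- oracle_expfit(tt, target, 1 / (1 + target)^1.25)
  expect_equal(w_fit$b, ref$b, tolerance = 1e-2)
  ## pure noise, no bend anywhere near threshold: no onset
  set.seed(1)
  noise <- rnorm(200, 0, 0.5)
  expect_true(is.na(detect_onset(noise, 100, 150)$onset_frame) ||
                detect_onset(noise, 100, 150)$method == "fallback")
})

test_that("onset is invariant to scaling the whole trace", {
  devs <- vapply(1:100, function(s) {
    set.seed(s)
    n <- 300; stim <- 100
    p <- escape_sim_params(n_frames = n, stimulus_time = (stim - 1) / 0.65,
                           latency = 21.5, c_bend_amplitude = runif(1, 65, 95),
                           oscillation_frequency = 35, angle_noise_sd = 0,
                           dropout_prob = 0, seed = s)
    al <- escapekin:::escape_waveform((0:(n - 1)) / 650 * 1000, p) +
      rnorm(n, 0, 2)
    bout <- data.frame(start_frame = stim, end_frame = n)
    s1 <- preprocess_angle(al)
    s2 <- preprocess_angle(2 * al)
    cb <- function(pk, thr) pk$frame[which(abs(pk$amplitude) > thr)[1]]
    o1 <- detect_onset(s1, stim, cb(detect_peaks(s1, bout, 10), 50))
    o2 <- detect_onset(s2, stim, cb(detect_peaks(s2, bout, 10), 100))
    o2$onset_frame - o1$onset_frame
  }, numeric(1))
  expect_true(all(abs(devs) <= 1))
})

test_that("escape inclusion criteria are applied exactly", {
  ## 650 frames/s; stimulus at frame 131
  f25 <- 131 + round(0.025 * 650)        # 25 ms latency
  f40 <- 131 + round(0.040 * 650)
  expect_true(classify_escape(f25, 70, 131, 650))
  expect_false(classify_escape(f40, 70, 131, 650))
  expect_false(classify_escape(f25, 50, 131, 650))
  expect_false(classify_escape(f25, -50, 131, 650))
  expect_true(classify_escape(f25, -70, 131, 650))   # magnitude rule
  expect_false(classify_escape(NA_integer_, 70, 131, 650))
})

test_that("kinematic parameters follow their definitions", {
  g <- gen_escape_pointtrack(escape_sim_params(angle_noise_sd = 0,
                                               dropout_prob = 0, seed = 1))
  tr <- g$track
  bout <- data.frame(start_frame = 140L, end_frame = 260L)
  ## 3 positive + 2 negative peaks: n_oscillations = 2.5
  peaks <- data.frame(frame = c(150L, 160L, 170L, 180L, 190L),
                      amplitude = c(70, -60, 50, -40, 30),
                      direction = c(1L, -1L, 1L, -1L, 1L),
                      sequential = c(TRUE, TRUE, TRUE, TRUE, FALSE),
                      hemicycle = c(10, 10, 10, 10, NA))
  k <- extract_kinematics(tr, bout, peaks, onset_frame = 145L)
  expect_equal(k$n_oscillations, 2.5)
  expect_equal(k$tbf_hz, 650 / (2 * 10))           # 32.5 Hz
  expect_equal(k$c_bend_amplitude, 70)
  expect_equal(k$latency_ms, (145 - 131) / 650 * 1000)
  ## the generator keeps the swim bladder stationary: distance and speed 0
  expect_equal(k$distance_mm, 0)
  expect_equal(k$speed_mm_s, 0)
  ## fewer than two sequential peaks: TBF undefined but reported
  p1 <- peaks[c(1, 5), ]; p1$sequential <- c(TRUE, FALSE)
  k1 <- extract_kinematics(tr, bout, p1, 145L)
  expect_false(k1$tbf_defined)
  expect_true(is.na(k1$tbf_hz))
  expect_equal(k1$n_oscillations, 1)
})

test_that("full pipeline recovers ground truth and reports rejections", {
  g <- gen_escape_pointtrack(escape_sim_params(
    oscillation_frequency = 32.5, c_bend_amplitude = 75, latency = 20,
    angle_noise_sd = 0, dropout_prob = 0, seed = 1))
  a <- run_kinematics_pipeline(g$track)
  expect_true(a$accepted)
  expect_lt(abs(a$kinematics$tbf_hz - 32.5), 0.5)
  expect_lt(abs(a$kinematics$c_bend_amplitude - 75), 1)
  expect_lte(abs(a$onset$onset_frame - g$truth$onset_frame), 2)
  ## no movement at all
  g0 <- gen_escape_pointtrack(escape_sim_params(
    c_bend_amplitude = 0.01, angle_noise_sd = 0, dropout_prob = 0, seed = 1))
  expect_identical(run_kinematics_pipeline(g0$track)$reject_reason, "no_bout")
  ## bout beginning 50 ms after the stimulus fails the latency criterion
  gl <- gen_escape_pointtrack(escape_sim_params(
    latency = 50, angle_noise_sd = 0, dropout_prob = 0, seed = 2))
  expect_identical(run_kinematics_pipeline(gl$track)$reject_reason, "latency")
  ## sub-threshold first bend fails the C-bend criterion
  gs <- gen_escape_pointtrack(escape_sim_params(
    c_bend_amplitude = 50, latency = 25, angle_noise_sd = 0,
    dropout_prob = 0, seed = 3))
  expect_identical(run_kinematics_pipeline(gs$track)$reject_reason, "c_bend")
})

test_that("pipeline results are equivariant under mirroring and time shift", {
  g <- gen_escape_pointtrack(escape_sim_params(seed = 21))
  a <- run_kinematics_pipeline(g$track)
  ## mirror across the body axis
  mir <- g$track
  mir$points[, , 2] <- -mir$points[, , 2]
  am <- run_kinematics_pipeline(mir)
  expect_true(am$accepted)
  expect_equal(am$kinematics$tbf_hz, a$kinematics$tbf_hz, tolerance = 1e-9)
  expect_equal(am$kinematics$latency_ms, a$kinematics$latency_ms)
  expect_equal(am$kinematics$c_bend_amplitude, a$kinematics$c_bend_amplitude,
               tolerance = 1e-9)
  expect_equal(am$kinematics$duration_ms, a$kinematics$duration_ms)
  ## shift track and stimulus by k frames
  k <- 40L
  sh <- g$track
  n <- dim(sh$points)[1]
  sh$points <- sh$points[c(rep(1, k), seq_len(n - k)), , , drop = FALSE]
  sh$stimulus_frame <- sh$stimulus_frame + k
  as_ <- run_kinematics_pipeline(sh)
  expect_true(as_$accepted)
  expect_equal(as_$onset$onset_frame, a$onset$onset_frame + k)
  expect_equal(as_$kinematics$latency_ms, a$kinematics$latency_ms)
  expect_equal(as_$kinematics$tbf_hz, a$kinematics$tbf_hz, tolerance = 1e-6)
})

test_that("noisy escapes are recovered within stated tolerances", {
  res <- vapply(1:50, function(s) {
    g <- gen_escape_pointtrack(escape_sim_params(
      oscillation_frequency = 34, angle_noise_sd = 2, seed = s))
    a <- run_kinematics_pipeline(g$track)
    if (!a$accepted) return(c(NA_real_, NA_real_))
    c(a$kinematics$tbf_hz - 34,
      abs(a$onset$onset_frame - g$truth$onset_frame))
  }, numeric(2))
  expect_gt(sum(!is.na(res[1, ])), 40)
  expect_lt(median(abs(res[1, ]), na.rm = TRUE), 0.5)
  expect_lte(median(res[2, ], na.rm = TRUE), 2)
})
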