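## Synthetic-data generators with known ground truth.
##
## Three generators emulate the study's recordings: high-speed 11-point body
## tracks of acoustic escape responses, two-channel fluorescence movies of
## moving cells, and behavioral trial tables with nested (fish/trial)
## structure. Every generator is deterministic given its seed and returns the
## injected parameters as a ground-truth record so downstream estimates can be
## validated against the truth.

#' Parameters for a synthetic escape point track
#'
#' Defaults reproduce the study conditions: 1-s recordings at 650 frames/s
#' with an acoustic stimulus 200 ms into the recording; escapes with short
#' latency, a large first bend (C-bend) and a damped 30-40 Hz tail
#' oscillation.
#'
#' @param frame_rate Camera frame rate in frames/s.
#' @param n_frames Number of recorded frames.
#' @param stimulus_time Stimulus onset, ms from recording start.
#' @param latency Escape latency in ms (onset - stimulus).
#' @param c_bend_amplitude First-bend (C-bend) amplitude in degrees.
#' @param oscillation_frequency Tail-beat frequency of the bout, Hz
#'   (ground-truth TBF). Must be below `frame_rate / 4`.
#' @param decay_rate Exponential damping of the oscillation envelope, 1/s.
#' @param n_oscillations Number of full tail-beat cycles after the first bend.
#' @param angle_noise_sd Per-frame Gaussian noise added to the tail angle,
#'   degrees (tracker noise).
#' @param dropout_prob Per-frame, per-point probability that a tracked point
#'   is missing (encoded as NaN coordinates).
#' @param pixel_scale Spatial calibration, mm per pixel.
#' @param seed Integer seed; identical parameters and seed give bitwise
#'   identical tracks.
#' @return A validated parameter list of class `escape_sim_params`.
#' @seealso [gen_escape_pointtrack()]
#' @export
escape_sim_params <- function(frame_rate = 650, n_frames = 650,
                              stimulus_time = 200, latency = 20,
                              c_bend_amplitude = 75,
                              oscillation_frequency = 35,
                              decay_rate = 8, n_oscillations = 5,
                              angle_noise_sd = 2, dropout_prob = 0.002,
                              pixel_scale = 0.02, seed = 1L) {
  p <- list(frame_rate = frame_rate, n_frames = n_frames,
            stimulus_time = stimulus_time, latency = latency,
            c_bend_amplitude = c_bend_amplitude,
            oscillation_frequency = oscillation_frequency,
            decay_rate = decay_rate, n_oscillations = n_oscillations,
            angle_noise_sd = angle_noise_sd, dropout_prob = dropout_prob,
            pixel_scale = pixel_scale, seed = as.integer(seed))
  if (p$frame_rate <= 0) stop("frame_rate must be > 0")
  if (p$n_frames < 2) stop("n_frames must be >= 2")
  if (p$oscillation_frequency <= 0 ||
      p$oscillation_frequency >= p$frame_rate / 4)
    stop("oscillation_frequency must be in (0, frame_rate/4)")
  if (p$dropout_prob < 0 || p$dropout_prob >= 1)
    stop("dropout_prob must be in [0, 1)")
  if (p$latency < 0) stop("latency must be >= 0")
  if (p$angle_noise_sd < 0) stop("angle_noise_sd must be >= 0")
  if (p$stimulus_time < 0 ||
      p$stimulus_time >= 1000 * p$n_frames / p$frame_rate)
    stop("stimulus_time outside the recording")
  class(p) <- "escape_sim_params"
  p
}

## Continuous ground-truth tail angle of the simulated escape, degrees.
## Zero until onset, quarter-sine rise to the C-bend peak over a quarter
## period (explosive start, smooth entry into the peak), then a damped
## cosine oscillation for n_oscillations cycles. The bout ends at the zero
## crossing a quarter period after the last positive peak so the trace
## returns to rest without an amplitude step.
escape_waveform <- function(t_ms, p) {
  onset_ms <- p$stimulus_time + p$latency
  f <- p$oscillation_frequency
  rise_ms <- 1000 / (4 * f)              # quarter period up to the first peak
  peak_ms <- onset_ms + rise_ms
  end_ms <- peak_ms + 1000 * (p$n_oscillations + 0.25) / f
  a <- numeric(length(t_ms))
  ris <- t_ms > onset_ms & t_ms <= peak_ms
  osc <- t_ms > peak_ms & t_ms <= end_ms
  a[ris] <- p$c_bend_amplitude *
    sin(pi / 2 * (t_ms[ris] - onset_ms) / rise_ms)
  tt <- (t_ms[osc] - peak_ms) / 1000     # seconds past the first peak
  a[osc] <- p$c_bend_amplitude * exp(-p$decay_rate * tt) *
    cos(2 * pi * f * tt)
  a
}

## Fixed larva geometry, pixels. Swim bladder at the origin, head rostral
## (negative x), tail caudal (positive x). One point per eye, the swim
## bladder, and eight tail points at equal arc spacing.
larva_geometry <- function() {
  list(eye_l = c(-30, 8), eye_r = c(-30, -8), sb = c(0, 0),
       tail_r = seq(15, 120, length.out = 8))
}

#' Generate a synthetic escape point track
#'
#' Synthesizes the output of an 11-point body tracker (one point per eye,
#' one for the swim bladder, eight along the tail) for an acoustic escape
#' response. The tail chain is bent rigidly at the swim bladder by the
#' ground-truth angle waveform: zero before onset, a quarter-sine rise to
#' the C-bend amplitude starting at the injected latency, then a damped
#' oscillation at the injected tail-beat frequency. Missing points are encoded as NaN
#' coordinates (rows are never dropped, preserving the stimulus clock).
#'
#' @param params An [escape_sim_params()] object.
#' @return A list with `track` (a `body_point_track`: `points` array of
#'   dimension frames x 11 x 2, `frame_rate`, `stimulus_frame` (1-based),
#'   `pixel_scale`) and `truth` (every injected parameter plus the
#'   noise-free angle trace and derived onset/peak frames).
#' @export
gen_escape_pointtrack <- function(params) {
  p <- if (inherits(params, "escape_sim_params")) params
       else do.call(escape_sim_params, params)
  set.seed(p$seed)
  n <- p$n_frames
  t_ms <- (seq_len(n) - 1) / p$frame_rate * 1000
  alpha_true <- escape_waveform(t_ms, p)
  alpha <- alpha_true
  if (p$angle_noise_sd > 0) alpha <- alpha + rnorm(n, 0, p$angle_noise_sd)

  geom <- larva_geometry()
  pts <- array(NA_real_, dim = c(n, 11, 2))
  pts[, 1, 1] <- geom$eye_l[1]; pts[, 1, 2] <- geom$eye_l[2]
  pts[, 2, 1] <- geom$eye_r[1]; pts[, 2, 2] <- geom$eye_r[2]
  pts[, 3, 1] <- geom$sb[1];    pts[, 3, 2] <- geom$sb[2]
  th <- alpha * pi / 180
  for (k in seq_len(8)) {
    r <- geom$tail_r[k]
    pts[, 3 + k, 1] <- r * cos(th)
    pts[, 3 + k, 2] <- r * sin(th)
  }
  if (p$dropout_prob > 0) {
    drop <- matrix(runif(n * 11) < p$dropout_prob, n, 11)
    for (j in seq_len(11)) {
      pts[drop[, j], j, 1] <- NaN
      pts[drop[, j], j, 2] <- NaN
    }
  }
  stim_frame <- floor(p$stimulus_time / 1000 * p$frame_rate) + 1L
  track <- structure(
    list(points = pts, frame_rate = p$frame_rate,
         stimulus_frame = stim_frame, pixel_scale = p$pixel_scale),
    class = "body_point_track")
  onset_ms <- p$stimulus_time + p$latency
  truth <- c(unclass(p), list(
    alpha_true = alpha_true,
    onset_time_ms = onset_ms,
    onset_frame = floor(onset_ms / 1000 * p$frame_rate) + 1L,
    first_peak_time_ms = onset_ms + 1000 / (4 * p$oscillation_frequency),
    tbf_true = p$oscillation_frequency))
  list(track = track, truth = truth)
}

#' Parameters for a synthetic two-channel fluorescence movie
#'
#' Emulates two-photon imaging of spinal neurons co-expressing a calcium
#' indicator (GCaMP) and an activity-independent reference fluorophore
#' (tagRFP) at 9 or 11 Hz. Cells are rendered as 2-D Gaussian intensity
#' spots displaced frame-by-frame along `motion_trajectory`; the GCaMP
#' channel additionally carries a calcium transient (instantaneous rise at
#' `transient_onset_frame`, exponential decay with time constant
#' `decay_tau`).
#'
#' @param frame_rate Acquisition rate, Hz (9 or 11 in the emulated study).
#' @param n_frames Number of frames (>= 11; baseline needs 10 frames).
#' @param height,width Frame size in pixels.
#' @param cell_positions Matrix (n_cells x 2) of cell-center `(x, y)` pixel
#'   coordinates in frame 1.
#' @param motion_trajectory Matrix (n_frames x 2) of per-frame `(dx, dy)`
#'   displacements applied to every cell; NULL means no motion.
#' @param stimulus_frame Frame index (1-based) of the stimulus.
#' @param transient_onset_frame Frame at which the GCaMP transient peaks
#'   (the rise occurs during the motion period, which is not imaged).
#' @param transient_amplitude Peak of the ground-truth dF/F (and dR/R)
#'   transient; 0 means no transient.
#' @param decay_tau Transient decay time constant, seconds.
#' @param shot_noise_sd SD of additive Gaussian intensity noise per pixel,
#'   in intensity units (images are unit-scaled; baseline cell peak is
#'   about 0.3).
#' @param background_level Spatially uniform background intensity.
#' @param cell_sigma Gaussian radius of rendered cells, pixels.
#' @param gcamp_peak,rfp_peak Baseline peak intensity of a cell above
#'   background in each channel.
#' @param seed Integer seed.
#' @return A validated parameter list of class `movie_sim_params`.
#' @export
movie_sim_params <- function(frame_rate = 11, n_frames = 60,
                             height = 64, width = 64,
                             cell_positions = matrix(c(32, 32), 1),
                             motion_trajectory = NULL,
                             stimulus_frame = 15,
                             transient_onset_frame = 16,
                             transient_amplitude = 0.9,
                             decay_tau = 1.18,
                             shot_noise_sd = 0,
                             background_level = 0.05,
                             cell_sigma = 2.5,
                             gcamp_peak = 0.25, rfp_peak = 0.3,
                             seed = 1L) {
  if (is.null(motion_trajectory))
    motion_trajectory <- matrix(0, n_frames, 2)
  p <- list(frame_rate = frame_rate, n_frames = as.integer(n_frames),
            height = as.integer(height), width = as.integer(width),
            cell_positions = as.matrix(cell_positions),
            motion_trajectory = as.matrix(motion_trajectory),
            stimulus_frame = as.integer(stimulus_frame),
            transient_onset_frame = as.integer(transient_onset_frame),
            transient_amplitude = transient_amplitude,
            decay_tau = decay_tau, shot_noise_sd = shot_noise_sd,
            background_level = background_level, cell_sigma = cell_sigma,
            gcamp_peak = gcamp_peak, rfp_peak = rfp_peak,
            seed = as.integer(seed))
  if (p$n_frames < 11) stop("n_frames must be >= 11 (10 baseline frames)")
  if (nrow(p$motion_trajectory) != p$n_frames)
    stop("motion_trajectory must have n_frames rows")
  if (p$decay_tau <= 0) stop("decay_tau must be > 0")
  if (p$transient_amplitude < 0) stop("transient_amplitude must be >= 0")
  if (p$background_level >= min(p$gcamp_peak, p$rfp_peak) + p$background_level)
    stop("background_level must be below baseline cell intensity")
  if (p$shot_noise_sd < 0) stop("shot_noise_sd must be >= 0")
  class(p) <- "movie_sim_params"
  p
}

## Ground-truth dF/F time course: 0 before the transient peak frame, then
## amplitude * exp(-t/tau). The calcium rise happens during the stimulus /
## motion period, which the emulated experiments cannot image.
transient_time_course <- function(p) {
  g <- numeric(p$n_frames)
  k <- p$transient_onset_frame
  if (p$transient_amplitude > 0 && k <= p$n_frames) {
    t_s <- (seq(k, p$n_frames) - k) / p$frame_rate
    g[k:p$n_frames] <- p$transient_amplitude * exp(-t_s / p$decay_tau)
  }
  g
}

render_frame <- function(height, width, centers, amps, sigma, background) {
  img <- matrix(background, height, width)
  xs <- seq_len(width); ys <- seq_len(height)
  for (i in seq_len(nrow(centers))) {
    gx <- exp(-((xs - centers[i, 1])^2) / (2 * sigma^2))
    gy <- exp(-((ys - centers[i, 2])^2) / (2 * sigma^2))
    img <- img + amps[i] * outer(gy, gx)
  }
  img
}

#' Generate a synthetic two-channel fluorescence movie
#'
#' Renders a GCaMP-like channel (baseline plus calcium transient) and a
#' tagRFP-like channel (motion only, no transient), both displaced per
#' frame along the motion trajectory, over a uniform background.
#'
#' @param params A [movie_sim_params()] object.
#' @return A list with `gcamp` and `rfp` (`channel_movie` objects: `frames`
#'   array of dimension height x width x n_frames, `frame_rate`,
#'   `channel_label`, `stimulus_frame`) and `truth` (injected parameters,
#'   per-frame true cell positions, and the true dF/F and dR/R time
#'   courses).
#' @export
gen_two_channel_movie <- function(params) {
  p <- if (inherits(params, "movie_sim_params")) params
       else do.call(movie_sim_params, params)
  set.seed(p$seed)
  n <- p$n_frames
  ncell <- nrow(p$cell_positions)
  g <- transient_time_course(p)
  margin <- 3 * p$cell_sigma
  true_pos <- vector("list", n)
  gc <- array(0, dim = c(p$height, p$width, n))
  rf <- array(0, dim = c(p$height, p$width, n))
  for (t in seq_len(n)) {
    ctr <- sweep(p$cell_positions, 2, p$motion_trajectory[t, ], "+")
    if (any(ctr[, 1] < 1 + margin) || any(ctr[, 1] > p$width - margin) ||
        any(ctr[, 2] < 1 + margin) || any(ctr[, 2] > p$height - margin))
      stop(sprintf("motion trajectory moves a cell out of frame at frame %d",
                   t))
    true_pos[[t]] <- ctr
    gc[, , t] <- render_frame(p$height, p$width, ctr,
                              rep(p$gcamp_peak * (1 + g[t]), ncell),
                              p$cell_sigma, p$background_level)
    rf[, , t] <- render_frame(p$height, p$width, ctr,
                              rep(p$rfp_peak, ncell),
                              p$cell_sigma, p$background_level)
  }
  if (p$shot_noise_sd > 0) {
    gc <- gc + array(rnorm(length(gc), 0, p$shot_noise_sd), dim = dim(gc))
    rf <- rf + array(rnorm(length(rf), 0, p$shot_noise_sd), dim = dim(rf))
    gc[gc < 0] <- 0
    rf[rf < 0] <- 0
  }
  mk <- function(frames, label) structure(
    list(frames = frames, frame_rate = p$frame_rate, channel_label = label,
         stimulus_frame = p$stimulus_frame),
    class = "channel_movie")
  truth <- c(unclass(p), list(
    true_positions = true_pos,
    true_dff = g,
    true_drr = g))
  list(gcamp = mk(gc, "GCaMP"), rfp = mk(rf, "tagRFP"), truth = truth)
}

#' Parameters for a synthetic behavioral cohort
#'
#' Emulates a cohort of larvae, each subjected to repeated escape trials at
#' 2-min intervals. Tail-beat frequency follows
#' `TBF = genotype mean + trial_slope * (trial - 1) + fish intercept +
#' residual`, with a Gaussian random intercept per fish (between-animal
#' variability) and Gaussian residual trial-to-trial noise. The negative
#' default trial slope emulates habituation across trials.
#'
#' @param n_fish_per_genotype Number of fish in each genotype arm.
#' @param n_trials Trials per fish.
#' @param genotype_means Named numeric vector of ground-truth mean TBF (Hz)
#'   per genotype; names become genotype labels (first = reference).
#' @param trial_slope Change in TBF per trial, Hz (habituation).
#' @param fish_sd SD of the per-fish random intercept, Hz.
#' @param residual_sd Within-fish residual SD, Hz.
#' @param seed Integer seed.
#' @return A validated parameter list of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(n_fish_per_genotype = 70, n_trials = 5,
                              genotype_means = c(wt = 35.2, mut = 32.8),
                              trial_slope = -0.5, fish_sd = 2,
                              residual_sd = 2.5, seed = 1L) {
  p <- list(n_fish_per_genotype = as.integer(n_fish_per_genotype),
            n_trials = as.integer(n_trials),
            genotype_means = genotype_means, trial_slope = trial_slope,
            fish_sd = fish_sd, residual_sd = residual_sd,
            seed = as.integer(seed))
  if (p$n_trials < 1) stop("n_trials must be >= 1")
  if (p$fish_sd < 0 || p$residual_sd < 0) stop("SDs must be >= 0")
  if (is.null(names(p$genotype_means)) || anyDuplicated(names(p$genotype_means)))
    stop("genotype_means must be a uniquely named vector")
  if (p$n_fish_per_genotype < 1) stop("n_fish_per_genotype must be >= 1")
  class(p) <- "cohort_sim_params"
  p
}

#' Generate a synthetic behavioral cohort
#'
#' @param params A [cohort_sim_params()] object.
#' @return A list with `table` (long-format data frame: `fish_id`,
#'   `genotype`, `trial`, `tbf`, one row per fish and trial) and `truth`
#'   (injected effects, including each fish's random intercept).
#' @export
gen_behavior_cohort <- function(params) {
  p <- if (inherits(params, "cohort_sim_params")) params
       else do.call(cohort_sim_params, params)
  set.seed(p$seed)
  genos <- names(p$genotype_means)
  n_fish <- p$n_fish_per_genotype * length(genos)
  fish_geno <- rep(genos, each = p$n_fish_per_genotype)
  fish_int <- rnorm(n_fish, 0, p$fish_sd)
  fish_id <- sprintf("fish%03d", seq_len(n_fish))
  tab <- expand.grid(trial = seq_len(p$n_trials), fish = seq_len(n_fish))
  mu <- p$genotype_means[fish_geno[tab$fish]] +
    p$trial_slope * (tab$trial - 1) + fish_int[tab$fish]
  tbf <- mu + rnorm(nrow(tab), 0, p$residual_sd)
  table <- data.frame(fish_id = fish_id[tab$fish],
                      genotype = factor(fish_geno[tab$fish], levels = genos),
                      trial = tab$trial, tbf = tbf,
                      stringsAsFactors = FALSE)
  table <- table[order(table$fish_id, table$trial), ]
  rownames(table) <- NULL
  truth <- c(unclass(p), list(
    fish_intercepts = setNames(fish_int, fish_id),
    genotype_effect = unname(p$genotype_means[-1] - p$genotype_means[1])))
  list(table = table, truth = truth)
}
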