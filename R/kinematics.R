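## Escape kinematics from 11-point body tracks.
##
## Stage order: tail angle -> preprocessing (interpolate, median filter,
## smoothing spline) -> angular velocity -> motion mask -> morphological
## closing into bouts -> escape-bout selection -> alternating-extremum peak
## detection -> exponential-fit onset -> inclusion criteria -> parameters.
## All frame indices are 1-based; intervals are inclusive of both ends;
## angles are in degrees.

point_xy <- function(track, frame, idx) track$points[frame, idx, ]

#' Compute the signed tail angle from an 11-point body track
#'
#' For each frame: the head direction runs from the midpoint of the two eye
#' points to the swim-bladder center; the tail direction runs from the
#' swim bladder to the last tail point. The tail angle `alpha` is the angle
#' between the tail vector and the caudally directed body axis (the head
#' vector prolonged), so a straight body gives 0 degrees. The magnitude is
#' the inverse cosine of the normalized dot product; the sign comes from
#' the 2-D cross product. Frames missing any required point give NaN.
#'
#' @param track A `body_point_track` (see [gen_escape_pointtrack()] or
#'   [read_pointtrack_csv()]).
#' @return Numeric vector of per-frame angles, degrees.
#' @export
compute_tail_angle <- function(track) {
  pts <- track$points
  eye_mid_x <- (pts[, 1, 1] + pts[, 2, 1]) / 2
  eye_mid_y <- (pts[, 1, 2] + pts[, 2, 2]) / 2
  hx <- pts[, 3, 1] - eye_mid_x          # caudally directed body axis
  hy <- pts[, 3, 2] - eye_mid_y
  tx <- pts[, 11, 1] - pts[, 3, 1]       # tail vector
  ty <- pts[, 11, 2] - pts[, 3, 2]
  dot <- hx * tx + hy * ty
  crs <- hx * ty - hy * tx
  alpha <- atan2(crs, dot) * 180 / pi
  alpha[!is.finite(alpha)] <- NaN
  if (all(is.nan(alpha)))
    stop("unusable track: required points are missing in every frame")
  alpha
}

## Linear interpolation across NaN gaps; endpoints extended with the nearest
## finite value.
interpolate_nan <- function(x) {
  ok <- is.finite(x)
  if (!any(ok)) stop("trace is entirely NaN")
  if (all(ok)) return(x)
  approx(which(ok), x[ok], xout = seq_along(x), rule = 2)$y
}

#' Denoise a tail-angle trace
#'
#' NaN gaps are filled by linear interpolation between the nearest finite
#' neighbours, a running median filter removes single-frame tracker
#' glitches, and a lightly penalized smoothing spline removes residual
#' frame-to-frame noise. The spline penalty default is calibrated so that a
#' 40 Hz oscillation sampled at 650 frames/s is attenuated by well under
#' 5%, keeping escape-frequency content intact.
#'
#' @param alpha_raw Per-frame angle trace, degrees (NaN allowed).
#' @param median_kernel Odd window length of the median filter, frames.
#' @param spline_lambda Penalty of [stats::smooth.spline()] (with
#'   `all.knots = TRUE`; the abscissa is internally scaled to `[0, 1]`, so
#'   the default is tuned for traces of a few hundred frames).
#' @return Finite numeric vector, same length as the input.
#' @export
preprocess_angle <- function(alpha_raw, median_kernel = 5,
                             spline_lambda = 1e-9) {
  if (sum(is.finite(alpha_raw)) < 5)
    stop("need at least 5 finite values to preprocess an angle trace")
  x <- interpolate_nan(alpha_raw)
  x <- as.numeric(stats::runmed(x, median_kernel, endrule = "median"))
  fit <- smooth.spline(seq_along(x), x, lambda = spline_lambda,
                       all.knots = TRUE)
  predict(fit, seq_along(x))$y
}

#' Estimate smoothed angular velocity
#'
#' First difference of the raw (interpolated but unsmoothed) angle trace,
#' then denoised by the same median-filter + spline scheme as the angle.
#' The default spline penalty is heavier than for the angle trace:
#' differentiation amplifies frame-to-frame tracker noise, and the velocity
#' trace only feeds the motion threshold, where suppressing the noise floor
#' matters far more than preserving the oscillation amplitude. The first
#' element is 0 so the output matches the input length.
#'
#' @inheritParams preprocess_angle
#' @return Numeric vector of angular velocity, degrees/frame.
#' @export
compute_angular_velocity <- function(alpha_raw, median_kernel = 5,
                                     spline_lambda = 1e-8) {
  if (sum(is.finite(alpha_raw)) < 5)
    stop("need at least 5 finite values to estimate angular velocity")
  x <- interpolate_nan(alpha_raw)
  v <- c(0, diff(x))
  preprocess_angle(v, median_kernel = median_kernel,
                   spline_lambda = spline_lambda)
}

#' Flag frames in motion
#'
#' A frame is "in motion" iff the magnitude of its angular velocity
#' strictly exceeds the threshold (default 1 degree/frame).
#'
#' @param ang_vel Angular velocity, degrees/frame.
#' @param threshold Motion threshold, degrees/frame.
#' @return Logical vector.
#' @export
detect_motion_frames <- function(ang_vel, threshold = 1) {
  abs(ang_vel) > threshold
}

#' Connect motion frames into movement bouts
#'
#' Morphological closing (dilation followed by erosion) of the binary
#' motion mask with a flat structuring element of length `block` merges
#' motion runs separated by interior gaps shorter than the element, leaving
#' the runs themselves untouched; maximal runs of the closed mask become
#' bouts. The mask is padded with background on both sides, so gaps
#' adjacent to the recording edges are not filled and edge-touching runs
#' are not eroded.
#'
#' @param mask Logical motion mask.
#' @param block Structuring-element length, frames.
#' @return Data frame with one row per bout: `start_frame`, `end_frame`
#'   (1-based, inclusive). Zero rows if there is no motion.
#' @export
close_bouts <- function(mask, block = 10) {
  mask <- as.logical(mask)
  n <- length(mask)
  out <- data.frame(start_frame = integer(0), end_frame = integer(0))
  if (n == 0 || !any(mask)) return(out)
  a <- (block - 1) %/% 2                 # element spans [i - a, i + b];
  b <- block - 1 - a                     # erosion uses the reflection
  pad <- rep(FALSE, block)
  mp <- c(pad, mask, pad)
  idx <- seq_along(mp)
  dil <- vapply(idx, function(i)
    any(mp[max(1, i - a):min(length(mp), i + b)]), logical(1))
  clo <- vapply(idx, function(i)
    all(dil[max(1, i - b):min(length(mp), i + a)]), logical(1))
  clo <- clo[block + seq_len(n)]
  r <- rle(clo)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start_frame = starts[keep], end_frame = ends[keep])
}

#' Select the escape bout
#'
#' The escape is the bout whose start is nearest to, and not before, the
#' stimulus; bouts beginning before the stimulus are spontaneous movements
#' and are discarded.
#'
#' @param bouts Data frame from [close_bouts()], sorted by start.
#' @param stimulus_frame Stimulus frame index (1-based).
#' @param min_frames Bouts spanning fewer frames are ignored (brief
#'   threshold crossings from residual tracker noise rather than
#'   swimming); 0 considers every bout.
#' @param tolerance Frames a candidate's start may precede the stimulus.
#'   Morphological closing can pull a bout's start back by up to the
#'   closing block when a noise crossing sits just before the true motion
#'   onset, so the pipeline allows one block of slack; the latency
#'   criterion, computed from the detected onset, still rejects genuinely
#'   pre-stimulus movements.
#' @return A one-row data frame, or NULL if no bout qualifies.
#' @export
select_escape_bout <- function(bouts, stimulus_frame, min_frames = 0,
                               tolerance = 0) {
  len <- bouts$end_frame - bouts$start_frame + 1
  cand <- bouts[bouts$start_frame >= stimulus_frame - tolerance &
                  len >= min_frames, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  cand[which.min(abs(cand$start_frame - stimulus_frame)), , drop = FALSE]
}

#' Detect alternating tail-bend peaks within a bout
#'
#' Alternating-extremum detection in the style of the classic `peakdet`
#' scheme: a running maximum (minimum) is emitted as a peak when the trace
#' retreats from it by more than `delta`, after which the search switches
#' to the opposite extremum. The search starts looking for a maximum, so
#' the input should be oriented with the first bend positive (the pipeline
#' re-signs the trace so the C-bend direction is positive before calling
#' this). Peaks are flagged `sequential` when followed
#' by a peak in the opposite direction (a bend to the other side); each
#' peak's `hemicycle` is the number of frames to the next peak in sequence,
#' regardless of direction (NA for the last peak).
#'
#' @param alpha_smooth Smoothed angle trace, degrees.
#' @param bout One-row data frame (`start_frame`, `end_frame`) delimiting
#'   the search, or NULL for the whole trace.
#' @param delta Minimum retreat, degrees (> 0).
#' @return Data frame with columns `frame`, `amplitude` (signed, degrees),
#'   `direction` (+1 positive / -1 negative), `sequential`, `hemicycle`.
#' @export
detect_peaks <- function(alpha_smooth, bout = NULL, delta = 10) {
  if (delta <= 0) stop("delta must be > 0")
  if (is.null(bout)) {
    lo <- 1L; hi <- length(alpha_smooth)
  } else {
    lo <- bout$start_frame[1]; hi <- bout$end_frame[1]
    if (lo < 1 || hi > length(alpha_smooth) || lo > hi)
      stop("bout outside the trace")
  }
  x <- alpha_smooth[lo:hi]
  mx <- -Inf; mn <- Inf; mx_i <- mn_i <- NA_integer_
  look_max <- TRUE  # classic peakdet: look for a maximum first
  pk_frame <- integer(0); pk_amp <- numeric(0); pk_dir <- integer(0)
  for (i in seq_along(x)) {
    v <- x[i]
    if (v > mx) { mx <- v; mx_i <- i }
    if (v < mn) { mn <- v; mn_i <- i }
    if (look_max && v < mx - delta) {
      pk_frame <- c(pk_frame, mx_i); pk_amp <- c(pk_amp, mx)
      pk_dir <- c(pk_dir, 1L)
      mn <- v; mn_i <- i; look_max <- FALSE
    } else if (!look_max && v > mn + delta) {
      pk_frame <- c(pk_frame, mn_i); pk_amp <- c(pk_amp, mn)
      pk_dir <- c(pk_dir, -1L)
      mx <- v; mx_i <- i; look_max <- TRUE
    }
  }
  n <- length(pk_frame)
  seqn <- rep(FALSE, n)
  hemi <- rep(NA_real_, n)
  if (n > 1) {
    seqn[-n] <- pk_dir[-n] != pk_dir[-1]
    hemi[-n] <- diff(pk_frame)
  }
  data.frame(frame = pk_frame + lo - 1L, amplitude = pk_amp,
             direction = pk_dir, sequential = seqn, hemicycle = hemi)
}

## Weighted least-squares fit of y = a * exp(b * t) by 1-D search over the
## rate b (a has a closed form given b). Robust for the short composite
## traces the onset detector builds; never fails on finite input.
fit_growing_exponential <- function(t, y, w = rep(1, length(y)),
                                    b_range = c(1e-4, 8)) {
  sse <- function(b) {
    e <- exp(b * (t - t[1]))
    a <- sum(w * y * e) / sum(w * e * e)
    sum(w * (y - a * e)^2)
  }
  opt <- optimize(sse, b_range)
  b <- opt$minimum
  e <- exp(b * (t - t[1]))
  a <- sum(w * y * e) / sum(w * e * e)
  list(a = a, b = b, t0 = t[1], sse = opt$objective)
}

#' Detect escape onset by the exponential-fit method
#'
#' A straight line is fit by least squares to the ascending limb of the
#' first bend (from the last frame whose magnitude is below `limb_start_deg`
#' before the first peak, up to the peak). A composite target trace is
#' built: zero from the stimulus to the line's crossing of the baseline
#' `y = 0`, then the line itself. A single-term exponential
#' `y = a * exp(b * t)` is fit to the composite, and the onset is the first
#' frame at which the fitted exponential exceeds the `threshold_deg`
#' threshold (default 2 degrees at the reference amplitude). The whole
#' construction operates on the trace normalized to a reference first-bend
#' amplitude (`reference_deg`), which makes the detected onset independent
#' of the amplitude of the first bend by construction and robust to noise
#' in the angle trace. If the exponential cannot be evaluated, the first
#' frame whose magnitude exceeds the threshold is used instead and
#' flagged.
#'
#' @param alpha_smooth Smoothed angle trace, degrees, oriented so the first
#'   peak is positive.
#' @param stimulus_frame Stimulus frame (1-based).
#' @param first_peak Frame index of the first detected peak.
#' @param threshold_deg Onset threshold on the fitted curve, degrees at
#'   the reference amplitude.
#' @param limb_start_deg Magnitude defining the foot of the ascending
#'   limb, degrees at the reference amplitude.
#' @param reference_deg Reference first-bend amplitude the trace is
#'   normalized to (default 75, a typical C-bend).
#' @return List with `onset_frame`, `method` (`"expfit"` or `"fallback"`),
#'   and the fitted exponential parameters.
#' @export
detect_onset <- function(alpha_smooth, stimulus_frame, first_peak,
                         threshold_deg = 2, limb_start_deg = 2,
                         reference_deg = 75) {
  if (length(first_peak) != 1 || is.na(first_peak))
    stop("first peak is undefined")
  if (first_peak <= stimulus_frame)
    stop("first peak must lie after the stimulus")
  ## Work on a trace normalized to a reference first-bend amplitude: every
  ## geometric step (limb foot, line fit, composite, exponential fit,
  ## threshold crossing) then commutes with rescaling the input, making
  ## the detected onset independent of the bend amplitude by construction.
  amp <- abs(alpha_smooth[first_peak])
  scale <- if (amp > 0) reference_deg / amp else 1
  seg <- alpha_smooth[stimulus_frame:first_peak] * scale
  below <- which(abs(seg) < limb_start_deg)
  foot <- if (length(below)) stimulus_frame + max(below) - 1L else
    stimulus_frame
  fallback <- function() {
    idx <- which(abs(seg) > threshold_deg)
    list(onset_frame = if (length(idx)) stimulus_frame + min(idx) - 1L else
           NA_integer_,
         method = "fallback", fit = NULL)
  }
  if (first_peak - foot < 2) return(fallback())
  limb_t <- seq(foot, first_peak)
  line <- lm(y ~ t, data = data.frame(
    t = limb_t, y = alpha_smooth[limb_t] * scale))
  slope <- coef(line)[["t"]]
  if (!is.finite(slope) || slope <= 0) return(fallback())
  x0 <- -coef(line)[["(Intercept)"]] / slope   # line crosses the baseline
  tt <- seq(stimulus_frame, first_peak)
  target <- ifelse(tt < x0, 0, coef(line)[["(Intercept)"]] + slope * tt)
  target[target < 0] <- 0
  ## Inverse-amplitude weights make the fit track the foot of the rise
  ## rather than the steep limb; the exponent balances the residual bias
  ## across shallow and steep first bends.
  w <- 1 / (1 + target)^1.25
  fit <- tryCatch(fit_growing_exponential(tt, target, w),
                  error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$a) || fit$a <= 0) return(fallback())
  fitted <- fit$a * exp(fit$b * (tt - fit$t0))
  idx <- which(fitted > threshold_deg)
  if (!length(idx)) return(fallback())
  list(onset_frame = tt[min(idx)], method = "expfit", fit = fit)
}

#' Apply the escape inclusion criteria
#'
#' A movement bout is accepted as an escape iff its onset occurs within
#' `latency_max_ms` of the stimulus (inclusive) and the magnitude of the
#' first bend exceeds `cbend_min_deg` (a C-bend).
#'
#' @param onset_frame Onset frame (1-based).
#' @param first_peak_amplitude Signed amplitude of the first peak, degrees.
#' @param stimulus_frame Stimulus frame (1-based).
#' @param frame_rate Frames/s.
#' @param latency_max_ms Maximum latency, ms.
#' @param cbend_min_deg Minimum first-bend magnitude, degrees.
#' @return Logical.
#' @export
classify_escape <- function(onset_frame, first_peak_amplitude,
                            stimulus_frame, frame_rate,
                            latency_max_ms = 30, cbend_min_deg = 60) {
  if (is.na(onset_frame)) return(FALSE)
  latency_ms <- (onset_frame - stimulus_frame) / frame_rate * 1000
  latency_ms >= 0 && latency_ms <= latency_max_ms &&
    abs(first_peak_amplitude) > cbend_min_deg
}

#' Derive per-escape kinematic parameters
#'
#' Latency (onset minus stimulus), bout duration, swim distance (path
#' length of the swim-bladder point over the bout, mm), speed
#' (distance/duration), number of oscillations (positive plus negative
#' peaks, divided by two), C-bend amplitude (first peak) and mean tail-beat
#' frequency, computed as the inverse of twice the mean hemicycle of
#' sequential peaks.
#'
#' @param track A `body_point_track`.
#' @param bout One-row bout data frame.
#' @param peaks Peak table from [detect_peaks()].
#' @param onset_frame Onset frame from [detect_onset()].
#' @param accepted Escape-inclusion flag from [classify_escape()].
#' @return An object of class `escape_kinematics` (list with fields
#'   `latency_ms`, `duration_ms`, `distance_mm`, `speed_mm_s`,
#'   `n_oscillations`, `c_bend_amplitude`, `tbf_hz`, `accepted`,
#'   `n_peaks`). `tbf_hz` is NA, with `tbf_defined = FALSE`, when fewer
#'   than two sequential peaks exist.
#' @export
extract_kinematics <- function(track, bout, peaks, onset_frame,
                               accepted = TRUE) {
  fr <- track$frame_rate
  latency_ms <- (onset_frame - track$stimulus_frame) / fr * 1000
  duration_ms <- (bout$end_frame - bout$start_frame) / fr * 1000
  sb <- track$points[bout$start_frame:bout$end_frame, 3, , drop = FALSE]
  step <- sqrt(diff(sb[, 1, 1])^2 + diff(sb[, 1, 2])^2)
  distance_mm <- sum(step, na.rm = TRUE) * track$pixel_scale
  speed <- if (duration_ms > 0) distance_mm / (duration_ms / 1000) else 0
  hemi <- peaks$hemicycle[peaks$sequential]
  hemi <- hemi[is.finite(hemi)]
  tbf_defined <- sum(peaks$sequential) >= 2 && length(hemi) >= 2
  tbf <- if (tbf_defined) fr / (2 * mean(hemi)) else NA_real_
  structure(list(
    latency_ms = latency_ms, duration_ms = duration_ms,
    distance_mm = distance_mm, speed_mm_s = speed,
    n_oscillations = nrow(peaks) / 2,
    c_bend_amplitude = if (nrow(peaks)) peaks$amplitude[1] else NA_real_,
    tbf_hz = tbf, tbf_defined = tbf_defined,
    n_peaks = nrow(peaks), accepted = accepted,
    onset_frame = onset_frame,
    bout_start = bout$start_frame, bout_end = bout$end_frame),
    class = "escape_kinematics")
}

#' @export
print.escape_kinematics <- function(x, ...) {
  cat("Escape kinematics", if (!x$accepted) "(rejected)", "\n")
  cat(sprintf("  latency        %6.1f ms\n", x$latency_ms))
  cat(sprintf("  duration       %6.1f ms\n", x$duration_ms))
  cat(sprintf("  distance       %6.2f mm\n", x$distance_mm))
  cat(sprintf("  speed          %6.1f mm/s\n", x$speed_mm_s))
  cat(sprintf("  C-bend         %6.1f deg\n", x$c_bend_amplitude))
  cat(sprintf("  oscillations   %6.1f\n", x$n_oscillations))
  cat(sprintf("  TBF            %6.1f Hz%s\n", x$tbf_hz,
              if (!x$tbf_defined) " (undefined: <2 sequential peaks)" else ""))
  invisible(x)
}

## Re-read a peak's amplitude from the interpolated raw trace: the median
## filter and spline slightly clip sharp extrema, so the reported bend
## amplitude is the raw-trace extremum within +/- 3 frames of the detected
## peak position.
refine_peak_amplitudes <- function(peaks, alpha_interp) {
  if (!nrow(peaks)) return(peaks)
  n <- length(alpha_interp)
  for (i in seq_len(nrow(peaks))) {
    w <- max(1, peaks$frame[i] - 3):min(n, peaks$frame[i] + 3)
    peaks$amplitude[i] <- if (peaks$direction[i] > 0)
      max(alpha_interp[w]) else min(alpha_interp[w])
  }
  peaks
}

#' Run the full escape-kinematics pipeline on one track
#'
#' Deterministic chain: tail angle, preprocessing, angular velocity, motion
#' mask, morphological closing into bouts, escape-bout selection, peak
#' detection (the trace is globally re-signed so the first bend of the
#' escape is positive, i.e. in the direction of the C-bend), exponential-fit
#' onset, inclusion criteria, kinematic parameters. A track that fails any
#' stage yields a rejection record naming the failed criterion instead of
#' an error.
#'
#' @param track A `body_point_track`.
#' @param config Pipeline tunables from [kinematics_config()].
#' @return An object of class `escape_analysis`: list with `accepted`,
#'   `kinematics` (an `escape_kinematics`, or NULL), `reject_reason`
#'   (`"no_bout"`, `"no_peaks"`, `"no_onset"`, `"latency"` or `"c_bend"`;
#'   NULL when accepted), plus the intermediate `alpha_raw`, `alpha_smooth`,
#'   `ang_vel`, `bout`, `peaks`, `onset`.
#' @export
run_kinematics_pipeline <- function(track, config = kinematics_config()) {
  cfg <- config
  alpha_raw <- compute_tail_angle(track)
  alpha_interp <- interpolate_nan(alpha_raw)
  alpha_smooth <- preprocess_angle(alpha_raw,
                                   median_kernel = cfg$median_kernel,
                                   spline_lambda = cfg$spline_lambda)
  ang_vel <- compute_angular_velocity(alpha_raw,
                                      median_kernel = cfg$median_kernel,
                                      spline_lambda = cfg$spline_lambda_vel)
  mask <- detect_motion_frames(ang_vel, cfg$motion_threshold)
  bouts <- close_bouts(mask, cfg$closing_block)
  res <- function(reason, bout = NULL, peaks = NULL, onset = NULL, kin = NULL)
    structure(list(accepted = is.null(reason), kinematics = kin,
                   reject_reason = reason, alpha_raw = alpha_raw,
                   alpha_smooth = alpha_smooth, ang_vel = ang_vel,
                   bout = bout, peaks = peaks, onset = onset,
                   frame_rate = track$frame_rate,
                   stimulus_frame = track$stimulus_frame),
              class = "escape_analysis")
  ## Candidate bouts in priority order (start nearest to, not before, the
  ## stimulus). Bouts without any bend excursion beyond the peak delta are
  ## residual-noise crossings, not swimming: they are discarded and the
  ## next candidate is considered.
  bout <- NULL; seg <- NULL
  repeat {
    bout <- select_escape_bout(bouts, track$stimulus_frame,
                               cfg$min_bout_frames, cfg$closing_block)
    if (is.null(bout)) break
    seg <- alpha_smooth[bout$start_frame:bout$end_frame]
    if (any(abs(seg) > cfg$peak_delta)) break
    bouts <- bouts[bouts$start_frame != bout$start_frame, , drop = FALSE]
    bout <- NULL
  }
  if (is.null(bout)) return(res("no_bout"))
  ## Orient the trace so the first bend (C-bend direction) is positive.
  first_exc <- which(abs(seg) > cfg$peak_delta)
  if (seg[min(first_exc)] < 0) {
    alpha_raw <- -alpha_raw; alpha_interp <- -alpha_interp
    alpha_smooth <- -alpha_smooth
  }
  peaks <- detect_peaks(alpha_smooth, bout, cfg$peak_delta)
  if (!nrow(peaks)) return(res("no_peaks", bout))
  peaks <- refine_peak_amplitudes(peaks, alpha_interp)
  onset <- detect_onset(alpha_smooth, track$stimulus_frame, peaks$frame[1],
                        threshold_deg = cfg$onset_threshold,
                        limb_start_deg = cfg$onset_threshold)
  if (is.na(onset$onset_frame)) return(res("no_onset", bout, peaks))
  latency_ms <- (onset$onset_frame - track$stimulus_frame) /
    track$frame_rate * 1000
  if (latency_ms < 0 || latency_ms > cfg$latency_max_ms)
    return(res("latency", bout, peaks, onset))
  if (abs(peaks$amplitude[1]) <= cfg$cbend_min_deg)
    return(res("c_bend", bout, peaks, onset))
  kin <- extract_kinematics(track, bout, peaks, onset$onset_frame,
                            accepted = TRUE)
  res(NULL, bout, peaks, onset, kin)
}

#' @export
print.escape_analysis <- function(x, ...) {
  if (x$accepted) {
    cat("Accepted escape\n")
    print(x$kinematics)
  } else {
    cat("Rejected bout: ", x$reject_reason, "\n", sep = "")
  }
  invisible(x)
}

#' Kinematics pipeline configuration
#'
#' @param median_kernel Median-filter window, frames (odd).
#' @param spline_lambda Smoothing-spline penalty for the angle trace (see
#'   [preprocess_angle()]).
#' @param spline_lambda_vel Spline penalty for the angular-velocity trace
#'   (see [compute_angular_velocity()]).
#' @param motion_threshold Motion threshold, degrees/frame.
#' @param closing_block Morphological-closing element length, frames.
#' @param min_bout_frames Minimum bout length considered by
#'   [select_escape_bout()], frames.
#' @param peak_delta Peak-detection retreat, degrees.
#' @param onset_threshold Onset threshold, degrees.
#' @param latency_max_ms Escape inclusion: maximum latency, ms.
#' @param cbend_min_deg Escape inclusion: minimum first-bend magnitude,
#'   degrees.
#' @return Named list of tunables.
#' @export
kinematics_config <- function(median_kernel = 5, spline_lambda = 1e-9,
                              spline_lambda_vel = 1e-8,
                              motion_threshold = 1, closing_block = 10,
                              min_bout_frames = 10,
                              peak_delta = 10, onset_threshold = 2,
                              latency_max_ms = 30, cbend_min_deg = 60) {
  list(median_kernel = median_kernel, spline_lambda = spline_lambda,
       spline_lambda_vel = spline_lambda_vel,
       motion_threshold = motion_threshold, closing_block = closing_block,
       min_bout_frames = min_bout_frames,
       peak_delta = peak_delta, onset_threshold = onset_threshold,
       latency_max_ms = latency_max_ms, cbend_min_deg = cbend_min_deg)
}
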