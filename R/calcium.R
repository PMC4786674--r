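## Motion-corrected calcium imaging of moving cells.
##
## ROIs are tracked across frames by normalized cross-correlation of a
## template taken from the first frame; frames whose best correlation falls
## below a threshold are omitted. Fluorescence is summarized as dF/F against
## a 10-frame baseline with background subtraction, and as the ratiometric
## dR/R of a GCaMP channel against an activity-independent tagRFP channel,
## which cancels motion artifacts shared by both channels.

roi_rect <- function(roi) {
  ## roi = c(x, y, w, h): x,y top-left corner (1-based), w along columns.
  list(x = roi[1], y = roi[2], w = roi[3], h = roi[4])
}

roi_patch <- function(frame, roi) {
  r <- roi_rect(roi)
  frame[r$y:(r$y + r$h - 1), r$x:(r$x + r$w - 1)]
}

roi_in_bounds <- function(roi, height, width) {
  r <- roi_rect(roi)
  r$x >= 1 && r$y >= 1 && r$x + r$w - 1 <= width && r$y + r$h - 1 <= height
}

#' Track a region of interest by normalized cross-correlation
#'
#' The ROI patch from the first frame serves as a fixed template (it is not
#' updated frame-to-frame, avoiding drift accumulation). In every frame the
#' template is compared, by Pearson correlation, against all integer
#' displacements within `search_radius` pixels, and the displacement with
#' the highest correlation wins. Frames whose best normalized correlation
#' falls below `corr_threshold` (movement artifact, cell leaving the focal
#' plane) are marked invalid and omitted from downstream signals.
#'
#' @param movie A `channel_movie`.
#' @param roi0 Numeric `c(x, y, w, h)`: initial ROI, 1-based top-left
#'   corner plus size in pixels.
#' @param corr_threshold Validity threshold on the correlation coefficient,
#'   in (0, 1). The emulated experiments adjusted it per movie.
#' @param search_radius Maximum displacement searched, pixels.
#' @return An object of class `roi_track`: `roi0`, `positions` (n_frames x
#'   2 matrix of ROI centers, `(x, y)`), `displacement` (integer offsets
#'   from frame 1), `valid`, `corr`.
#' @export
track_roi <- function(movie, roi0, corr_threshold = 0.7,
                      search_radius = 20) {
  dims <- dim(movie$frames)
  height <- dims[1]; width <- dims[2]; n <- dims[3]
  if (!roi_in_bounds(roi0, height, width))
    stop("roi0 out of bounds")
  if (corr_threshold <= 0 || corr_threshold >= 1)
    stop("corr_threshold must be in (0, 1)")
  r <- roi_rect(roi0)
  tmpl <- as.vector(roi_patch(movie$frames[, , 1], roi0))
  if (sd(tmpl) == 0) stop("template has zero variance")
  dxs <- -search_radius:search_radius
  disp <- matrix(0L, n, 2)
  corr <- numeric(n)
  for (t in seq_len(n)) {
    fr <- movie$frames[, , t]
    best <- -Inf; bx <- 0L; by <- 0L
    for (dy in dxs) {
      y0 <- r$y + dy
      if (y0 < 1 || y0 + r$h - 1 > height) next
      for (dx in dxs) {
        x0 <- r$x + dx
        if (x0 < 1 || x0 + r$w - 1 > width) next
        patch <- as.vector(fr[y0:(y0 + r$h - 1), x0:(x0 + r$w - 1)])
        s <- sd(patch)
        cc <- if (s == 0) 0 else cor(tmpl, patch)
        if (cc > best) { best <- cc; bx <- dx; by <- dy }
      }
    }
    disp[t, ] <- c(bx, by)
    corr[t] <- best
  }
  valid <- corr >= corr_threshold
  centers <- cbind(r$x + (r$w - 1) / 2 + disp[, 1],
                   r$y + (r$h - 1) / 2 + disp[, 2])
  structure(list(roi0 = roi0, positions = centers, displacement = disp,
                 valid = valid, corr = corr),
            class = "roi_track")
}

#' Extract raw fluorescence along a tracked ROI
#'
#' `F(t)` is the mean intensity inside the tracked ROI (NaN in invalid
#' frames); `Fbg(t)` is the mean intensity in a static background region
#' containing only background signal.
#'
#' @param movie A `channel_movie`.
#' @param track An `roi_track` (typically computed on the reference
#'   channel and reused here).
#' @param bg_roi Numeric `c(x, y, w, h)` static background ROI.
#' @return List with numeric vectors `F` and `Fbg`.
#' @export
extract_fluorescence <- function(movie, track, bg_roi) {
  dims <- dim(movie$frames)
  n <- dims[3]
  if (nrow(track$positions) != n)
    stop("track and movie have different lengths")
  if (!roi_in_bounds(bg_roi, dims[1], dims[2]))
    stop("background ROI out of bounds")
  r0 <- roi_rect(track$roi0)
  bg <- roi_rect(bg_roi)
  overlaps <- function(ax, aw, bx, bw) ax <= bx + bw - 1 && bx <= ax + aw - 1
  for (t in seq_len(n)) {
    x0 <- r0$x + track$displacement[t, 1]
    y0 <- r0$y + track$displacement[t, 2]
    if (track$valid[t] &&
        overlaps(x0, r0$w, bg$x, bg$w) && overlaps(y0, r0$h, bg$y, bg$h))
      stop("background ROI overlaps the tracked ROI")
  }
  f <- rep(NaN, n)
  fbg <- numeric(n)
  for (t in seq_len(n)) {
    fr <- movie$frames[, , t]
    fbg[t] <- mean(roi_patch(fr, bg_roi))
    if (track$valid[t]) {
      roi_t <- c(r0$x + track$displacement[t, 1],
                 r0$y + track$displacement[t, 2], r0$w, r0$h)
      if (roi_in_bounds(roi_t, dims[1], dims[2]))
        f[t] <- mean(roi_patch(fr, roi_t))
    }
  }
  list(F = f, Fbg = fbg)
}

first_valid_mean <- function(x, k = 10) {
  idx <- which(is.finite(x))
  if (length(idx) < 1) stop("no valid frames for baseline")
  use <- idx[seq_len(min(k, length(idx)))]
  list(value = mean(x[use]), frames = use,
       flagged = !identical(use, seq_len(k)))
}

#' Baseline-normalized fluorescence change (dF/F)
#'
#' `dF/F = (F(t) - F0) / (F0 - Fbg0)` where `F0` is the mean of the first
#' 10 valid frames of the ROI trace and `Fbg0` the mean of the first 10
#' frames of the background trace. When early frames are invalid, the first
#' 10 valid frames are used and the result is flagged.
#'
#' @param f ROI fluorescence trace (NaN where invalid).
#' @param fbg Background trace.
#' @param n_baseline Baseline length, frames.
#' @return List with `dff` (NaN propagates), `F0`, `Fbg0`,
#'   `baseline_flagged`.
#' @export
delta_f_over_f <- function(f, fbg, n_baseline = 10) {
  b <- first_valid_mean(f, n_baseline)
  f0 <- b$value
  fbg0 <- mean(fbg[seq_len(min(n_baseline, length(fbg)))], na.rm = TRUE)
  if (!is.finite(f0) || f0 <= fbg0)
    stop("degenerate baseline: F0 must exceed the background baseline")
  list(dff = (f - f0) / (f0 - fbg0), F0 = f0, Fbg0 = fbg0,
       baseline_flagged = b$flagged)
}

#' Ratiometric fluorescence change (dR/R)
#'
#' `dR/R = (Fg(t) * F0r) / (F0g * Fr(t)) - 1`, with all quantities
#' background-corrected. Per-frame gains applied equally to both channels
#' (motion artifacts) cancel exactly. Frames where either channel is
#' invalid, or where the corrected reference signal is not positive, give
#' NaN.
#'
#' @param f_gcamp,f_rfp Raw ROI traces of the two channels.
#' @param fbg_gcamp,fbg_rfp Background traces of the two channels.
#' @param n_baseline Baseline length, frames.
#' @return List with `drr`, baselines, and `n_nonpositive_ref` (count of
#'   frames dropped because the corrected reference was not positive).
#' @export
delta_r_over_r <- function(f_gcamp, f_rfp, fbg_gcamp, fbg_rfp,
                           n_baseline = 10) {
  g <- f_gcamp - fbg_gcamp
  r <- f_rfp - fbg_rfp
  both <- is.finite(g) & is.finite(r)
  f0g <- first_valid_mean(ifelse(both, g, NaN), n_baseline)$value
  f0r <- first_valid_mean(ifelse(both, r, NaN), n_baseline)$value
  if (!is.finite(f0g) || !is.finite(f0r) || f0g <= 0 || f0r <= 0)
    stop("baselines must be positive after background correction")
  bad_ref <- both & r <= 0
  if (any(bad_ref))
    warning(sprintf("%d frames with non-positive corrected reference signal",
                    sum(bad_ref)))
  drr <- rep(NaN, length(g))
  use <- both & r > 0
  drr[use] <- (g[use] * f0r) / (f0g * r[use]) - 1
  list(drr = drr, F0_gcamp = f0g, F0_rfp = f0r,
       n_nonpositive_ref = sum(bad_ref))
}

#' Stimulus-locked response amplitude
#'
#' `difference = post - pre`, where `pre` is the mean of the `n_pre`
#' scheduled time points ending immediately before the stimulus and `post`
#' the mean of the `n_post` points starting `gap` frames after it (the gap
#' skips frames lost to motion). Invalid (NaN) points are excluded from the
#' means; window lengths count scheduled frames, not valid ones.
#'
#' @param trace Signal trace (dF/F or dR/R), NaN where invalid.
#' @param stimulus_frame Stimulus frame (1-based).
#' @param n_pre,n_post Window lengths, frames.
#' @param gap Frames skipped after the stimulus before the post window.
#' @return List with `pre`, `post`, `difference`, window definitions and
#'   valid counts.
#' @export
stimulus_difference <- function(trace, stimulus_frame, n_pre = 5,
                                n_post = 5, gap = 4) {
  pre_idx <- (stimulus_frame - n_pre):(stimulus_frame - 1)
  post_idx <- (stimulus_frame + gap):(stimulus_frame + gap + n_post - 1)
  if (min(pre_idx) < 1 || max(post_idx) > length(trace))
    stop("pre/post windows fall outside the trace")
  pre_v <- trace[pre_idx]; post_v <- trace[post_idx]
  if (!any(is.finite(pre_v)) || !any(is.finite(post_v)))
    stop("undefined response: a window contains no valid points")
  pre <- mean(pre_v, na.rm = TRUE)
  post <- mean(post_v, na.rm = TRUE)
  list(pre = pre, post = post, difference = post - pre,
       n_pre = n_pre, n_post = n_post, gap = gap,
       n_pre_valid = sum(is.finite(pre_v)),
       n_post_valid = sum(is.finite(post_v)))
}

#' Fit the decay time constant of a calcium transient
#'
#' Least-squares single-exponential fit `y = A exp(-(t - t_peak)/tau) + c`
#' to the post-peak segment of a dF/F (or dR/R) trace; the offset `c`
#' absorbs a non-zero resting baseline. Fitting uses Levenberg-Marquardt
#' with starting values from a log-linear regression.
#'
#' @param trace Signal trace.
#' @param peak_frame Index of the transient peak; the fit uses frames
#'   `peak_frame` onward (valid points only).
#' @param frame_rate Acquisition rate, Hz (converts frames to seconds).
#' @return List with `tau` (seconds), `A`, `c` and the residual standard
#'   deviation.
#' @export
fit_decay <- function(trace, peak_frame, frame_rate) {
  seg <- trace[peak_frame:length(trace)]
  t_s <- (seq_along(seg) - 1) / frame_rate
  ok <- is.finite(seg)
  if (sum(ok) < 5) stop("need at least 5 valid points after the peak")
  y <- seg[ok]; t_s <- t_s[ok]
  if (max(y) - min(y) < 1e-12 || sd(y) == 0)
    stop("no decay: trace is constant after the peak")
  ## log-linear starting values on the positive excursion
  c0 <- min(y)
  pos <- y - c0 + 1e-6
  ll <- lm(log(pos) ~ t_s)
  tau0 <- -1 / min(coef(ll)[["t_s"]], -1e-6)
  a0 <- max(y) - c0
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-t_s / tau) + c,
                      start = list(A = a0, tau = max(tau0, 1e-3), c = c0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop(sprintf(
        "decay fit did not converge (%s); residual sd of start: %.3g",
        conditionMessage(e), sd(y - (a0 * exp(-t_s / tau0) + c0)))))
  est <- coef(fit)
  if (est[["tau"]] <= 0) stop("decay fit returned a non-positive tau")
  list(tau = est[["tau"]], A = est[["A"]], c = est[["c"]],
       resid_sd = sd(residuals(fit)))
}

#' Calcium imaging pipeline configuration
#'
#' @param corr_threshold ROI-tracking validity threshold.
#' @param search_radius Tracking search radius, pixels.
#' @param n_baseline Baseline length, frames.
#' @param n_pre,n_post,gap Stimulus-difference windows (defaults follow the
#'   pressure-stimulation protocol; tail-free experiments use 3/3 and a
#'   1-frame gap).
#' @param bg_roi Static background ROI `c(x, y, w, h)`.
#' @return Named list of tunables.
#' @export
calcium_config <- function(corr_threshold = 0.7, search_radius = 20,
                           n_baseline = 10, n_pre = 5, n_post = 5, gap = 4,
                           bg_roi = c(1, 1, 8, 8)) {
  list(corr_threshold = corr_threshold, search_radius = search_radius,
       n_baseline = n_baseline, n_pre = n_pre, n_post = n_post, gap = gap,
       bg_roi = bg_roi)
}

#' Run the calcium pipeline on a two-channel movie
#'
#' Per ROI: track on the tagRFP channel (its signal is
#' activity-independent, so correlation drops reflect motion only), reuse
#' the tracked positions on the GCaMP channel, compute dF/F for both
#' channels, the ratiometric dR/R, and the stimulus-locked response
#' amplitude. A failing ROI is reported with its error message without
#' aborting the remaining ROIs.
#'
#' @param gcamp,rfp `channel_movie` objects, temporally aligned.
#' @param rois Data frame with columns `roi_id`, `x`, `y`, `w`, `h` (and
#'   optionally `class`).
#' @param config From [calcium_config()].
#' @return Object of class `calcium_result`: `traces` (long data frame:
#'   `roi_id`, `frame`, `F_gcamp`, `F_rfp`, `dff`, `drr`, `valid`),
#'   `responses` (one row per ROI: `pre`, `post`, `difference`, `error`),
#'   and per-ROI `tracks`.
#' @export
run_calcium_pipeline <- function(gcamp, rfp, rois,
                                 config = calcium_config()) {
  cfg <- config
  stopifnot(dim(gcamp$frames)[3] == dim(rfp$frames)[3])
  traces <- list(); tracks <- list()
  resp <- data.frame(roi_id = rois$roi_id, pre = NA_real_, post = NA_real_,
                     difference = NA_real_, error = NA_character_,
                     stringsAsFactors = FALSE)
  for (i in seq_len(nrow(rois))) {
    id <- rois$roi_id[i]
    out <- tryCatch({
      roi <- c(rois$x[i], rois$y[i], rois$w[i], rois$h[i])
      trk <- track_roi(rfp, roi, cfg$corr_threshold, cfg$search_radius)
      if (!any(trk$valid)) stop("all frames invalid for this ROI")
      fg <- extract_fluorescence(gcamp, trk, cfg$bg_roi)
      fr <- extract_fluorescence(rfp, trk, cfg$bg_roi)
      dg <- delta_f_over_f(fg$F, fg$Fbg, cfg$n_baseline)
      rr <- delta_r_over_r(fg$F, fr$F, fg$Fbg, fr$Fbg, cfg$n_baseline)
      sd_ <- stimulus_difference(rr$drr, gcamp$stimulus_frame,
                                 cfg$n_pre, cfg$n_post, cfg$gap)
      list(trk = trk,
           tr = data.frame(roi_id = id,
                           frame = seq_len(length(fg$F)),
                           F_gcamp = fg$F, F_rfp = fr$F,
                           dff = dg$dff, drr = rr$drr,
                           valid = trk$valid, stringsAsFactors = FALSE),
           sd_ = sd_)
    }, error = function(e) e)
    if (inherits(out, "error")) {
      resp$error[i] <- conditionMessage(out)
    } else {
      tracks[[as.character(id)]] <- out$trk
      traces[[as.character(id)]] <- out$tr
      resp$pre[i] <- out$sd_$pre
      resp$post[i] <- out$sd_$post
      resp$difference[i] <- out$sd_$difference
    }
  }
  structure(list(traces = do.call(rbind, traces), responses = resp,
                 tracks = tracks),
            class = "calcium_result")
}

#' @export
print.calcium_result <- function(x, ...) {
  cat("Calcium imaging result:", nrow(x$responses), "ROI(s)\n")
  print(x$responses, row.names = FALSE)
  invisible(x)
}
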