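## Independent reference implementations used to cross-check the package's
## algorithms. They are deliberately written with different mechanics than
## the production code paths.

## Alternating-extrema search by repeated scanning of running envelopes
## (vectorized cummax/cummin), rather than the single-pass state machine in
## detect_peaks. Looks for a maximum first.
oracle_peaks <- function(x, delta) {
  frames <- integer(0); amps <- numeric(0); dirs <- integer(0)
  start <- 1L
  looking_max <- TRUE
  n <- length(x)
  while (start <= n) {
    seg <- x[start:n]
    if (looking_max) {
      env <- cummax(seg)
      hit <- which(env - seg > delta)
    } else {
      env <- cummin(seg)
      hit <- which(seg - env > delta)
    }
    if (!length(hit)) break
    j <- hit[1]
    ext_rel <- if (looking_max) which.max(seg[1:j]) else which.min(seg[1:j])
    frames <- c(frames, start + ext_rel - 1L)
    amps <- c(amps, seg[ext_rel])
    dirs <- c(dirs, if (looking_max) 1L else -1L)
    start <- start + j - 1L
    looking_max <- !looking_max
  }
  data.frame(frame = frames, amplitude = amps, direction = dirs)
}

## Morphological closing expressed as run-length gap filling: a closing
## with a flat element of length `block` fills every interior gap shorter
## than the element and leaves the runs themselves untouched.
oracle_close <- function(mask, block) {
  r <- rle(as.logical(mask))
  v <- r$values
  for (i in seq_along(v)) {
    if (!v[i] && i > 1 && i < length(v) && r$lengths[i] <= block - 1)
      v[i] <- TRUE
  }
  inverse.rle(list(lengths = r$lengths, values = v))
}

bouts_from_mask <- function(mask) {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start_frame = starts[r$values], end_frame = ends[r$values])
}

## Brute-force grid fit of the weighted growing-exponential objective used
## by the onset detector.
oracle_expfit <- function(t, y, w, b_grid = seq(1e-4, 8, length.out = 4000)) {
  best <- Inf; a_best <- NA; b_best <- NA
  for (b in b_grid) {
    e <- exp(b * (t - t[1]))
    a <- sum(w * y * e) / sum(w * e * e)
    s <- sum(w * (y - a * e)^2)
    if (s < best) { best <- s; a_best <- a; b_best <- b }
  }
  list(a = a_best, b = b_best, t0 = t[1])
}

## Log-linear decay-constant estimate for offset-free exponentials.
oracle_tau_loglin <- function(y, frame_rate) {
  t_s <- (seq_along(y) - 1) / frame_rate
  ok <- is.finite(y) & y > 0
  -1 / coef(lm(log(y[ok]) ~ t_s[ok]))[[2]]
}

## Small hand-built body point track: one frame per row of `alpha_deg`,
## straight head along +x, tail rotated rigidly by alpha.
make_track <- function(alpha_deg, frame_rate = 650, stimulus_frame = 1,
                       pixel_scale = 1) {
  n <- length(alpha_deg)
  pts <- array(NA_real_, dim = c(n, 11, 2))
  pts[, 1, ] <- matrix(rep(c(-30, 8), each = n), n)
  pts[, 2, ] <- matrix(rep(c(-30, -8), each = n), n)
  pts[, 3, ] <- 0
  th <- alpha_deg * pi / 180
  for (k in seq_len(8)) {
    r <- 15 * k
    pts[, 3 + k, 1] <- r * cos(th)
    pts[, 3 + k, 2] <- r * sin(th)
  }
  structure(list(points = pts, frame_rate = frame_rate,
                 stimulus_frame = stimulus_frame,
                 pixel_scale = pixel_scale),
            class = "body_point_track")
}

## Static ROI track covering `roi0` in every frame (for extraction tests
## that do not involve the tracker).
make_static_track <- function(roi0, n_frames, valid = rep(TRUE, n_frames)) {
  structure(list(roi0 = roi0,
                 positions = cbind(rep(roi0[1] + (roi0[3] - 1) / 2, n_frames),
                                   rep(roi0[2] + (roi0[4] - 1) / 2, n_frames)),
                 displacement = matrix(0L, n_frames, 2),
                 valid = valid, corr = as.numeric(valid)),
            class = "roi_track")
}
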