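#' Zero-phase low-pass Butterworth filter
#'
#' Applies an order-`order` digital Butterworth low-pass forward and backward
#' (zero phase, so stride timing is not shifted). The effective magnitude
#' response is the squared single-pass response. Back-segment marker data are
#' filtered at 30 Hz by default in the trial pipeline to remove high-frequency
#' noise.
#'
#' @param x Uniformly sampled numeric vector (no NAs).
#' @param rate Sampling rate, Hz.
#' @param cutoff_hz Cut-off frequency, Hz; must be below the Nyquist rate.
#' @param order Filter order (default 4).
#' @return Filtered vector, same length as `x`.
#' @export
lowpass_filter <- function(x, rate, cutoff_hz, order = 4) {
  stopifnot(is.numeric(x), rate > 0, order >= 1)
  if (cutoff_hz <= 0 || cutoff_hz >= rate / 2) {
    stop("cutoff_hz must lie in (0, rate/2); got ", cutoff_hz,
         " with Nyquist ", rate / 2)
  }
  if (anyNA(x)) {
    stop("lowpass_filter requires gap-free input; fill or drop gaps first")
  }
  flt <- signal::butter(order, cutoff_hz / (rate / 2), type = "low")
  # odd-reflection padding suppresses the start/end transients of the
  # forward-backward pass (and keeps the filter exact on constants)
  n <- length(x)
  np <- min(n - 1, max(100, ceiling(3 * rate / cutoff_hz)))
  if (np > 0) {
    head_pad <- 2 * x[1] - x[(np + 1):2]
    tail_pad <- 2 * x[n] - x[(n - 1):(n - np)]
    y <- signal::filtfilt(flt, c(head_pad, x, tail_pad))
    as.numeric(y[(np + 1):(np + n)])
  } else {
    as.numeric(signal::filtfilt(flt, x))
  }
}

# Smoothed derivative: slope of a centred moving linear regression.
# Returns d(x)/dt in units of x per second. Edge frames use the one-sided
# window that fits.
smoothed_slope <- function(x, rate, window_s = 0.5) {
  n <- length(x)
  stopifnot(n >= 3)
  w <- max(3L, as.integer(round(window_s * rate)))
  if (w %% 2L == 0L) w <- w + 1L
  if (w > n) w <- if (n %% 2L == 1L) n else n - 1L
  half <- (w - 1L) %/% 2L
  k <- seq(-half, half)
  wts <- k / sum(k^2)
  out <- rep(NA_real_, n)
  core <- (half + 1L):(n - half)
  # centred convolution for the interior
  out[core] <- vapply(core, function(i) sum(wts * x[i + k]), numeric(1))
  if (n > 2L * half) {
    for (i in seq_len(half)) {
      idx <- 1L:(i + half)
      t0 <- idx - mean(idx)
      out[i] <- sum(t0 * x[idx]) / sum(t0^2)
      idx <- (n - i - half + 1L):n
      t0 <- idx - mean(idx)
      out[n - i + 1L] <- sum(t0 * x[idx]) / sum(t0^2)
    }
  }
  out * rate
}

#' Heading-based horse reference frame
#'
#' Builds a per-frame orthonormal frame from the horizontal track of a body
#' marker: x-hat is the unit smoothed horizontal velocity (direction of
#' travel), z-hat is vertical (up), y-hat = z-hat x x-hat points horizontally
#' to the horse's left. On a circle the frame follows the tangent, so
#' sagittal/dorsal/frontal planes are meaningful on straight lines and lunge
#' circles alike. Velocity is smoothed as the slope of a centred moving
#' linear regression (default span 0.5 s), which suppresses the within-stride
#' oscillation of the track.
#'
#' @param track_xy n x 2 matrix of horizontal positions (mm) of the body
#'   marker (the tuber sacrale in the trial pipeline).
#' @param rate Sampling rate, Hz.
#' @param window_s Smoothing span in seconds (default 0.5).
#' @return A `horse_frame`: list of n x 3 matrices `x`, `y`, `z` plus
#'   `lean_deg` (0 until [lean_correct()] is applied).
#' @export
heading_frame <- function(track_xy, rate, window_s = 0.5) {
  track_xy <- as.matrix(track_xy)
  stopifnot(ncol(track_xy) == 2, nrow(track_xy) >= 3)
  vx <- smoothed_slope(track_xy[, 1], rate, window_s)
  vy <- smoothed_slope(track_xy[, 2], rate, window_s)
  sp <- sqrt(vx^2 + vy^2)
  if (any(is.finite(sp) & sp < 1e-9) || all(!is.finite(sp))) {
    stop("degenerate heading: track has (near-)zero displacement")
  }
  xh <- cbind(vx / sp, vy / sp, 0)
  yh <- cbind(-vy / sp, vx / sp, 0)
  zh <- matrix(rep(c(0, 0, 1), each = nrow(xh)), ncol = 3)
  structure(list(x = xh, y = yh, z = zh, lean_deg = 0),
            class = "horse_frame")
}

#' Correct a horse frame for body lean
#'
#' On the lunge the horse leans into the circle; measuring projection angles
#' in an upright frame then contaminates them with projection error. The
#' correction rotates the frame's y and z axes about the direction of travel
#' by the body lean angle, conventionally estimated as the stride-mean pelvic
#' roll, so that the stride-mean pelvic roll recomputed in the corrected
#' frame is approximately zero.
#'
#' @param frame A `horse_frame`.
#' @param lean_deg Body lean angle in degrees (sign as measured by pelvic
#'   roll in the uncorrected frame).
#' @return The corrected `horse_frame`; `lean_deg` fields accumulate.
#' @export
lean_correct <- function(frame, lean_deg) {
  stopifnot(inherits(frame, "horse_frame"), is.finite(lean_deg))
  th <- lean_deg * pi / 180
  y2 <- cos(th) * frame$y + sin(th) * frame$z
  z2 <- -sin(th) * frame$y + cos(th) * frame$z
  frame$y <- y2
  frame$z <- z2
  frame$lean_deg <- frame$lean_deg + lean_deg
  frame
}

# row-wise dot product of an n x 3 matrix (or length-3 vector) with the
# frame axis components
frame_coords <- function(v, frame) {
  if (is.null(dim(v))) v <- matrix(v, ncol = 3)
  v <- as.matrix(v)
  cbind(rowSums(v * frame$x),
        rowSums(v * frame$y),
        rowSums(v * frame$z))
}

wrap180 <- function(deg) {
  w <- deg %% 360
  w[!is.na(w) & w > 180] <- w[!is.na(w) & w > 180] - 360
  w
}

#' Signed projection angle of a vector in an anatomical plane
#'
#' Projects `v` into one of the three planes of the (lean-corrected) horse
#' frame — sagittal = span(x, z), dorsal/horizontal = span(x, y), frontal =
#' span(y, z) — and returns the signed angle from a reference axis to the
#' projection, in (-180, 180] degrees. Pelvic roll, pitch and yaw are
#' projection angles of pelvis marker vectors in the frontal, sagittal and
#' dorsal plane respectively.
#'
#' @param v n x 3 matrix (or length-3 vector) in world coordinates.
#' @param frame A `horse_frame`.
#' @param plane `"sagittal"`, `"dorsal"` or `"frontal"`.
#' @param reference Length-3 numeric: reference axis expressed in frame
#'   coordinates (components along x-hat, y-hat, z-hat); must lie in the
#'   chosen plane. Default is the plane's first axis.
#' @return Numeric vector of signed angles in degrees.
#' @export
projection_angle <- function(v, frame,
                             plane = c("sagittal", "dorsal", "frontal"),
                             reference = NULL) {
  plane <- match.arg(plane)
  if (is.null(dim(v))) v <- matrix(v, ncol = 3)
  stopifnot(inherits(frame, "horse_frame"), ncol(v) == 3)
  ax <- switch(plane,
               sagittal = c(1, 3), # (x, z)
               dorsal   = c(1, 2), # (x, y)
               frontal  = c(2, 3)) # (y, z)
  if (is.null(reference)) {
    reference <- c(0, 0, 0)
    reference[ax[1]] <- 1
  }
  stopifnot(length(reference) == 3)
  if (abs(reference[setdiff(1:3, ax)]) > 1e-8 * sqrt(sum(reference^2))) {
    stop("reference axis does not lie in the ", plane, " plane")
  }
  fc <- frame_coords(v, frame)
  a <- fc[, ax[1]]
  b <- fc[, ax[2]]
  nrm <- sqrt(a^2 + b^2)
  scale <- sqrt(rowSums(v^2))
  if (any(is.finite(nrm) & nrm < 1e-9 * pmax(scale, 1))) {
    stop("degenerate projection: vector (near-)orthogonal to the ",
         plane, " plane")
  }
  ra <- reference[ax[1]]
  rb <- reference[ax[2]]
  unname(wrap180((atan2(b, a) - atan2(rb, ra)) * 180 / pi))
}

#' Pelvic roll, pitch and yaw
#'
#' Computes the three pelvis projection angles from the T-strip markers:
#' roll (axial rotation) is the angle of the line between the tubera coxae in
#' the frontal plane, pitch (flexion-extension) the angle of the tuber
#' sacrale to tubera-coxae-midpoint vector in the sagittal plane, and yaw
#' (lateral bending) the tubera coxae line in the dorsal plane. Angles of a
#' level, square pelvis are roll = yaw = 0; pitch carries the constant
#' anatomical inclination of the tuber sacrale relative to the coxae
#' midpoint, which cancels in range-of-motion measures.
#'
#' @param ts,ltc,rtc n x 3 world positions of the tuber sacrale and
#'   left/right tubera coxae.
#' @param frame A `horse_frame`.
#' @return List of numeric vectors `roll`, `pitch`, `yaw` (degrees).
#' @export
pelvic_angles <- function(ts, ltc, rtc, frame) {
  u <- rtc - ltc # left -> right
  list(
    roll  = projection_angle(u, frame, "frontal", reference = c(0, -1, 0)),
    pitch = projection_angle((ltc + rtc) / 2 - ts, frame, "sagittal",
                             reference = c(1, 0, 0)),
    yaw   = projection_angle(u, frame, "dorsal", reference = c(0, -1, 0))
  )
}

#' Back angle from a cranial-apex-caudal marker triple
#'
#' The deviation from collinearity of the two projected segments
#' cranial-apex and apex-caudal: 0 when the three markers are collinear in
#' the chosen plane. Whole-back flexion-extension and lateral bending use
#' (withers, T15, tuber sacrale) in the sagittal and dorsal plane; segmental
#' angles use the markers immediately cranial and caudal to the vertebra in
#' question (e.g. T15 flexion-extension from T12, T15, T18). Sign: positive
#' when the apex lies below the cranial-caudal chord (sagittal) or to its
#' left (dorsal). Range of motion is unaffected by the sign convention.
#'
#' @param cranial,apex,caudal n x 3 world positions.
#' @param frame A `horse_frame`.
#' @param plane `"sagittal"` or `"dorsal"`.
#' @return Numeric vector of signed angles in degrees.
#' @export
back_angle <- function(cranial, apex, caudal, frame,
                       plane = c("sagittal", "dorsal")) {
  plane <- match.arg(plane)
  ax <- if (plane == "sagittal") c(1, 3) else c(1, 2)
  p1 <- frame_coords(cranial, frame)[, ax, drop = FALSE]
  p2 <- frame_coords(apex, frame)[, ax, drop = FALSE]
  p3 <- frame_coords(caudal, frame)[, ax, drop = FALSE]
  d1 <- p2 - p1
  d2 <- p3 - p2
  n1 <- sqrt(rowSums(d1^2))
  n2 <- sqrt(rowSums(d2^2))
  if (any(is.finite(n1) & n1 < 1e-9) || any(is.finite(n2) & n2 < 1e-9)) {
    stop("degenerate back segment: zero-length projection")
  }
  cross <- d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1]
  dt <- rowSums(d1 * d2)
  mag <- atan2(abs(cross), dt) * 180 / pi
  # apex offset from the cranial-caudal chord decides the sign
  ch <- p3 - p1
  off <- p2 - p1
  perp <- off[, 2] * ch[, 1] - off[, 1] * ch[, 2] # >0: apex on the chord's
  # clockwise side in (u, w) coords
  s <- if (plane == "sagittal") sign(perp) else -sign(perp)
  s[s == 0] <- 1
  s * mag
}

# horizontal signed angle from direction `b` to direction `n`,
# positive when `n` points to the right of `b` (seen from above)
horiz_angle_right <- function(n, b, frame) {
  nb <- frame_coords(n, frame)
  bb <- frame_coords(b, frame)
  wrap180(-(atan2(nb[, 2], nb[, 1]) - atan2(bb[, 2], bb[, 1])) * 180 / pi)
}

#' Body tracking angle
#'
#' Straightness of the body relative to the direction of motion: the
#' horizontal-plane angle between the body direction (pelvis to withers,
#' pointing forward) and the body velocity vector. Positive values indicate
#' tracking of the forehand to the right (hind quarters to the left).
#'
#' @param withers,ts n x 3 world positions of the withers (mid) and tuber
#'   sacrale markers.
#' @param frame A `horse_frame` (x axis = velocity direction).
#' @return Numeric vector of signed angles in degrees.
#' @export
body_tracking_angle <- function(withers, ts, frame) {
  d <- withers - ts
  nrm <- sqrt(rowSums(frame_coords(d, frame)[, 1:2, drop = FALSE]^2))
  if (any(is.finite(nrm) & nrm < 1e-9)) {
    stop("degenerate body axis: withers and tuber sacrale coincide ",
         "in the horizontal plane")
  }
  horiz_angle_right(d, frame$x, frame)
}

#' Head swivel angle
#'
#' Proxy for cervical lateral bending: the horizontal-plane angle between
#' the cervical spine (head to withers) and the body (withers to pelvis).
#' Positive values indicate cervical bending to the right.
#'
#' @param head,withers,ts n x 3 world positions of the head reference,
#'   withers (mid) and tuber sacrale markers.
#' @param frame A `horse_frame`.
#' @return Numeric vector of signed angles in degrees.
#' @export
head_swivel_angle <- function(head, withers, ts, frame) {
  neck <- head - withers # forward along the neck
  body <- withers - ts   # forward along the back
  for (seg in list(neck, body)) {
    nrm <- sqrt(rowSums(frame_coords(seg, frame)[, 1:2, drop = FALSE]^2))
    if (any(is.finite(nrm) & nrm < 1e-9)) {
      stop("degenerate segment in head swivel computation")
    }
  }
  horiz_angle_right(neck, body, frame)
}

#' Speed from the horizontal track of a marker
#'
#' Smoothed differentiation of the horizontal (x, y) coordinates — the
#' magnitude of the moving-regression velocity of the tuber sacrale marker in
#' the trial pipeline. Input positions are in mm; the result is in m/s.
#'
#' @param track_xy n x 2 horizontal positions (mm).
#' @param rate Sampling rate, Hz.
#' @param window_s Smoothing span, seconds (default 0.5).
#' @return Numeric vector of speeds (m/s), one per frame.
#' @export
speed_from_marker <- function(track_xy, rate, window_s = 0.5) {
  track_xy <- as.matrix(track_xy)
  stopifnot(ncol(track_xy) == 2)
  if (nrow(track_xy) < 3) {
    stop("need at least 3 frames to differentiate")
  }
  vx <- smoothed_slope(track_xy[, 1], rate, window_s)
  vy <- smoothed_slope(track_xy[, 2], rate, window_s)
  sqrt(vx^2 + vy^2) / 1000
}

# linear interpolation across NA gaps (ends extended with nearest value);
# used only to stabilise filtering — gap frames are re-masked afterwards
fill_gaps_linear <- function(x) {
  if (!anyNA(x)) return(x)
  idx <- which(!is.na(x))
  if (length(idx) == 0) return(x)
  stats::approx(idx, x[idx], xout = seq_along(x), rule = 2)$y
}
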