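#' Configuration for the kinematic trot simulator
#'
#' Ground-truth parameters for [simulate_trot_markers()]. The simulator is
#' kinematic: angle waveforms are prescribed, not produced by a dynamic
#' model, so every quantity the analysis pipeline estimates has an exact
#' known truth. The phase structure matches trot: vertical displacement of
#' head/withers/sacrum and back/pelvic flexion-extension oscillate at twice
#' the stride frequency, while lateral bending, pelvic yaw and pelvic roll
#' (axial rotation) complete one cycle per stride.
#'
#' Amplitude defaults are seeded from typical soft-straight measurement
#' medians of sound trotting warmbloods so that synthetic output is
#' magnitude-realistic; a sinusoid of amplitude A yields a per-stride range
#' of motion of 2A.
#'
#' @param stride_frequency Strides per second (default 1.34 Hz).
#' @param speed Forward speed, m/s (default 3.79).
#' @param path `"straight"` or `"circle"`.
#' @param circle_radius_m Lunge circle radius in metres (default 4.85,
#'   i.e. a 9.7 m diameter circle).
#' @param circle_direction `"left"` (counter-clockwise seen from above) or
#'   `"right"`.
#' @param amp_flexext_deg,amp_latbend_deg Whole-back flexion-extension /
#'   lateral bending amplitude at the T15 apex (degrees).
#' @param amp_roll_deg,amp_pitch_deg,amp_yaw_deg Pelvic rotation amplitudes
#'   (degrees).
#' @param head_swivel_offset_deg,amp_head_swivel_deg Constant cervical
#'   bending offset and oscillation amplitude (degrees; positive = right).
#' @param body_tracking_deg Constant body tracking angle (degrees; positive
#'   = forehand right of travel).
#' @param amp_head_mm,amp_withers_mm,amp_sacrum_mm Vertical oscillation
#'   amplitudes (mm).
#' @param lean_deg Body lean angle (degrees). `NULL` (default) means 0 on the
#'   straight and the banking angle `atan(v^2 / (g r))` on the circle.
#' @param noise_sd_mm Additive Gaussian marker noise, per coordinate (mm);
#'   the default 3.2 mm mirrors a typical optical-capture calibration
#'   residual.
#' @param misplacement_mm Optional named list (role -> length-3 offset, mm)
#'   emulating marker misplacement between sessions.
#' @param n_strides Number of complete stride cycles in the trial.
#' @param sampling_rate Hz (default 100).
#' @param seed RNG seed for the noise; `NULL` leaves the RNG state alone.
#' @return A `trot_sim_config` list.
#' @export
trot_sim_config <- function(stride_frequency = 1.34, speed = 3.79,
                            path = c("straight", "circle"),
                            circle_radius_m = 4.85,
                            circle_direction = c("left", "right"),
                            amp_flexext_deg = 2.5, amp_latbend_deg = 3.7,
                            amp_roll_deg = 4.8, amp_pitch_deg = 3.8,
                            amp_yaw_deg = 2.15,
                            head_swivel_offset_deg = -1.3,
                            amp_head_swivel_deg = 5,
                            body_tracking_deg = 0,
                            amp_head_mm = 35, amp_withers_mm = 47,
                            amp_sacrum_mm = 48,
                            lean_deg = NULL, noise_sd_mm = 3.2,
                            misplacement_mm = NULL, n_strides = 14,
                            sampling_rate = 100, seed = NULL) {
  path <- match.arg(path)
  circle_direction <- match.arg(circle_direction)
  amps <- c(amp_flexext_deg, amp_latbend_deg, amp_roll_deg, amp_pitch_deg,
            amp_yaw_deg, amp_head_swivel_deg, amp_head_mm, amp_withers_mm,
            amp_sacrum_mm)
  stopifnot(stride_frequency > 0, speed > 0, all(amps >= 0),
            circle_radius_m > 0, noise_sd_mm >= 0, n_strides >= 1,
            sampling_rate > 0)
  if (is.null(lean_deg)) {
    lean_deg <- if (path == "circle") {
      atan(speed^2 / (9.81 * circle_radius_m)) * 180 / pi
    } else 0
  }
  structure(as.list(environment()), class = "trot_sim_config")
}

# static marker geometry in body coordinates (mm): x forward from the
# withers, y left, z up from the ground
spine_geometry <- function() {
  list(
    long = c(head_ref = 900, withers_mid = 0, T12 = -400, T15 = -550,
             T18 = -700, L3 = -900, L5 = -1000, tuber_sacrale = -1150,
             S5 = -1280),
    z_withers = 1700, z_ts = 1680, z_head = 1500,
    withers_lat = 200, z_withers_lat = 1650,
    pelvis_d = c(50, 0, -130), # tuber sacrale -> tubera coxae midpoint
    pelvis_halfspan = 250,
    neck_len = 900
  )
}

#' Simulate labelled trot marker trajectories
#'
#' Generates a [marker_series] for the full 13-marker set (head reference,
#' withers triad, T12-S5 spinous processes, pelvic T-strip) advected along a
#' straight line or a lunge circle, with prescribed sinusoidal angle and
#' displacement waveforms (see [trot_sim_config()] for the phase structure),
#' optional constant body lean, additive Gaussian marker noise and constant
#' marker misplacement. Deterministic for a fixed seed.
#'
#' The back is bent by displacing the T15 apex so that the *measured*
#' whole-back angle equals the prescribed waveform (the small-angle chord
#' construction is exact to well below 0.1%), with the remaining spinous
#' markers following a smooth half-sine bending shape. The pelvis is a rigid
#' body rotated by the prescribed roll, yaw and pitch.
#'
#' @param config A `trot_sim_config`.
#' @return A `marker_series` whose labels equal the role names, suitable for
#'   the default [marker_config()].
#' @export
simulate_trot_markers <- function(config = trot_sim_config()) {
  stopifnot(inherits(config, "trot_sim_config"))
  g <- spine_geometry()
  f <- config$stride_frequency
  rate <- config$sampling_rate
  pad <- 0.3 # lead-in/out seconds outside the counted strides
  n <- ceiling((config$n_strides / f + 2 * pad) * rate) + 1L
  t <- (seq_len(n) - 1) / rate
  # phase chosen so stride boundaries (sacrum minima with rising roll,
  # phi = 7*pi/4 mod 2*pi) fall at t = pad + k/f
  phi <- 2 * pi * f * (t - pad) + 7 * pi / 4
  d2r <- pi / 180

  v_w <- config$amp_withers_mm * sin(2 * phi)
  v_s <- config$amp_sacrum_mm * sin(2 * phi)
  v_h <- config$amp_head_mm * sin(2 * phi + 0.5)

  # chord endpoints in body coordinates
  W <- cbind(0, 0, g$z_withers + v_w)
  S <- cbind(g$long[["tuber_sacrale"]], 0, g$z_ts + v_s)

  body <- list(
    withers_mid = W,
    withers_left = cbind(0, g$withers_lat, g$z_withers_lat + v_w),
    withers_right = cbind(0, -g$withers_lat, g$z_withers_lat + v_w)
  )

  # whole-back bending: exact apex offsets for the prescribed angles
  ch <- S - W
  ch_sag <- sqrt(ch[, 1]^2 + ch[, 3]^2)
  ch_dor <- abs(ch[, 1])
  lam <- g$long[c("T12", "T15", "T18", "L3", "L5", "S5")] /
    g$long[["tuber_sacrale"]]
  lam15 <- lam[["T15"]]
  th_fe <- config$amp_flexext_deg * d2r * sin(2 * phi)
  th_lb <- config$amp_latbend_deg * d2r * sin(phi + 0.9)
  h15 <- th_fe * (lam15 * (1 - lam15) * ch_sag) # a*b/(a+b), a+b = |chord|
  w15 <- th_lb * (lam15 * (1 - lam15) * ch_dor)
  # downward unit perpendicular of the sagittal chord
  perp_x <- -ch[, 3] / ch_sag
  perp_z <- ch[, 1] / ch_sag # chord x-component < 0, so z-component < 0: down
  shape <- sin(pi * lam) / sin(pi * lam15)
  for (nm in c("T12", "T15", "T18", "L3", "L5", "S5")) {
    base <- W + lam[[nm]] * ch
    h <- h15 * shape[[nm]]
    w <- w15 * shape[[nm]]
    body[[nm]] <- cbind(base[, 1] + h * perp_x,
                        base[, 2] + w,
                        base[, 3] + h * perp_z)
  }
  body$tuber_sacrale <- S

  # rigid pelvis: Rx(roll) %*% Rz(yaw) %*% Ry(pitch) about the tuber sacrale
  roll <- config$amp_roll_deg * d2r * sin(phi)
  yaw <- config$amp_yaw_deg * d2r * sin(phi + 1.2)
  pitch <- config$amp_pitch_deg * d2r * sin(2 * phi + 0.7)
  rot_pelvis <- function(local) {
    # local: length-3; returns n x 3, rotation applied per frame
    x <- local[1]; y <- local[2]; z <- local[3]
    # Ry(pitch)
    x1 <- x * cos(pitch) + z * sin(pitch)
    z1 <- -x * sin(pitch) + z * cos(pitch)
    y1 <- rep(y, length(pitch))
    # Rz(yaw)
    x2 <- x1 * cos(yaw) - y1 * sin(yaw)
    y2 <- x1 * sin(yaw) + y1 * cos(yaw)
    # Rx(roll)
    y3 <- y2 * cos(roll) - z1 * sin(roll)
    z3 <- y2 * sin(roll) + z1 * cos(roll)
    cbind(x2, y3, z3)
  }
  body$tuber_coxae_left <- S +
    rot_pelvis(g$pelvis_d + c(0, g$pelvis_halfspan, 0))
  body$tuber_coxae_right <- S +
    rot_pelvis(g$pelvis_d + c(0, -g$pelvis_halfspan, 0))

  # head: neck swivelled horizontally about the withers, positive = right
  sw <- (config$head_swivel_offset_deg +
           config$amp_head_swivel_deg * sin(phi + 0.4)) * d2r
  body$head_ref <- cbind(g$neck_len * cos(sw), -g$neck_len * sin(sw),
                         g$z_head + v_h)

  if (!is.null(config$misplacement_mm)) {
    for (nm in names(config$misplacement_mm)) {
      off <- config$misplacement_mm[[nm]]
      body[[nm]] <- sweep(body[[nm]], 2, off, "+")
    }
  }

  # constant body tracking: rotate the whole body about the vertical axis
  # through the tuber sacrale (positive = forehand to the right)
  if (config$body_tracking_deg != 0) {
    bt <- -config$body_tracking_deg * d2r # clockwise seen from above
    pivot <- body$tuber_sacrale
    for (nm in names(body)) {
      dx <- body[[nm]][, 1] - pivot[, 1]
      dy <- body[[nm]][, 2] - pivot[, 2]
      body[[nm]][, 1] <- pivot[, 1] + dx * cos(bt) - dy * sin(bt)
      body[[nm]][, 2] <- pivot[, 2] + dx * sin(bt) + dy * cos(bt)
    }
  }

  # body lean: tilt about the ground-level longitudinal axis, toward the
  # circle centre on the lunge (sign chosen so the analyzer's stride-mean
  # pelvic roll estimates it)
  lean <- config$lean_deg * d2r
  if (config$path == "circle" && config$circle_direction == "left") {
    lean <- -lean # centre is to the left
  }
  if (lean != 0) {
    for (nm in names(body)) {
      y <- body[[nm]][, 2]
      z <- body[[nm]][, 3]
      body[[nm]][, 2] <- y * cos(lean) - z * sin(lean)
      body[[nm]][, 3] <- y * sin(lean) + z * cos(lean)
    }
  }

  # advect along the path
  v_mm <- config$speed * 1000
  markers <- list()
  if (config$path == "straight") {
    for (nm in names(body)) {
      markers[[nm]] <- cbind(body[[nm]][, 1] + v_mm * t,
                             body[[nm]][, 2],
                             body[[nm]][, 3])
    }
  } else {
    r_mm <- config$circle_radius_m * 1000
    dir <- if (config$circle_direction == "left") 1 else -1
    for (nm in names(body)) {
      # each marker rides at its own arc position so the body follows the
      # circle instead of spanning a rigid chord
      alpha <- dir * (v_mm * t + body[[nm]][, 1]) / r_mm
      rad <- r_mm - dir * body[[nm]][, 2] # left lunge: left is inward
      markers[[nm]] <- cbind(rad * cos(alpha), rad * sin(alpha),
                             body[[nm]][, 3])
    }
  }

  if (config$noise_sd_mm > 0) {
    if (!is.null(config$seed)) set.seed(config$seed)
    for (nm in names(markers)) {
      markers[[nm]] <- markers[[nm]] +
        matrix(stats::rnorm(3 * n, sd = config$noise_sd_mm), ncol = 3)
    }
  }
  marker_series(markers[marker_roles()], rate)
}
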