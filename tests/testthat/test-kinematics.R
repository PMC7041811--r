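test_that("zero-phase Butterworth matches its closed-form magnitude", {
  fs <- 100
  fc <- 30
  t <- seq(0, 20, by = 1 / fs)
  # bilinear-transform (prewarped) magnitude of an order-4 Butterworth,
  # squared because the filter runs forward and backward
  gain2 <- function(f) 1 / (1 + (tan(pi * f / fs) / tan(pi * fc / fs))^8)
  amp <- function(y) {
    m <- y[floor(length(y) / 3):floor(2 * length(y) / 3)]
    sqrt(2 * mean((m - mean(m))^2))
  }
  # DC gain is exactly 1
  expect_equal(lowpass_filter(rep(7, 500), fs, fc), rep(7, 500),
               tolerance = 1e-9)
  # passband: 2 Hz preserved within 1%
  x2 <- sin(2 * pi * 2 * t)
  expect_equal(amp(lowpass_filter(x2, fs, fc)) / amp(x2), 1,
               tolerance = 0.01)
  # transition band and stopband match the analytic response
  for (f in c(35, 45)) {
    x <- sin(2 * pi * f * t)
    expect_equal(amp(lowpass_filter(x, fs, fc)) / amp(x), gain2(f),
                 tolerance = 0.02)
  }
  expect_error(lowpass_filter(x2, fs, cutoff_hz = 60), "Nyquist")
  expect_error(lowpass_filter(c(1, NA, 3), fs, fc), "gap-free")
})

test_that("heading frame tracks the direction of travel", {
  n <- 200
  # straight +X
  f <- heading_frame(cbind(1:n * 30, 0), 100)
  expect_equal(f$x, matrix(rep(c(1, 0, 0), each = n), ncol = 3),
               tolerance = 1e-9)
  expect_equal(f$y, matrix(rep(c(0, 1, 0), each = n), ncol = 3),
               tolerance = 1e-9)
  # straight +Y: x-hat = (0,1,0), y-hat = (-1,0,0)
  f2 <- heading_frame(cbind(0, 1:n * 30), 100)
  expect_equal(f2$x[1, ], c(0, 1, 0), tolerance = 1e-9)
  expect_equal(f2$y[1, ], c(-1, 0, 0), tolerance = 1e-9)
  # counter-clockwise circle: y-hat points to the centre
  th <- seq(0, 2 * pi, length.out = 500)
  track <- cbind(5000 * cos(th), 5000 * sin(th))
  f3 <- heading_frame(track, 100)
  mid <- 100:400
  to_centre <- -track[mid, ] / 5000
  agree <- rowSums(f3$y[mid, 1:2] * to_centre)
  expect_true(all(agree > 0.99))
  expect_error(heading_frame(cbind(rep(1, 100), 0), 100), "degenerate")
})

test_that("projection angles follow hand trigonometry", {
  fr <- straight_frame(1)
  # parallel to the reference: zero
  expect_equal(projection_angle(c(5, 0, 0), fr, "sagittal"), 0)
  # tubera coxae line with a 0.2 height drop over a 2.0 lateral span
  ltc <- c(0, 1, 1)
  rtc <- c(0, -1, 0.8)
  ang <- projection_angle(rtc - ltc, fr, "frontal", reference = c(0, -1, 0))
  expect_equal(ang, atan2(0.2, 2) * 180 / pi, tolerance = 1e-9) # 5.7106
  # joint rotation of vector and frame about the vertical leaves it unchanged
  th <- 73 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  fr_rot <- fr
  fr_rot$x <- fr$x %*% t(R)
  fr_rot$y <- fr$y %*% t(R)
  v <- c(3, 0.4, 0.2)
  expect_equal(projection_angle(as.numeric(R %*% v), fr_rot, "dorsal"),
               projection_angle(v, fr, "dorsal"), tolerance = 1e-9)
  expect_error(projection_angle(c(0, 0, 1), fr, "dorsal"), "degenerate")
  expect_error(projection_angle(c(1, 0, 0), fr, "sagittal",
                                reference = c(0, 1, 0)),
               "does not lie in")
})

test_that("pelvic angles recover prescribed geometry and waveforms", {
  fr <- straight_frame(1)
  # level, symmetric pelvis square to travel
  ts <- c(0, 0, 1680)
  ltc <- c(50, 250, 1550)
  rtc <- c(50, -250, 1550)
  pa <- pelvic_angles(ts, ltc, rtc, fr)
  expect_equal(pa$roll, 0)
  expect_equal(pa$yaw, 0)
  expect_equal(pa$pitch, atan2(-130, 50) * 180 / pi)
  # right tuber coxae raised 0.2 on a 2.0 span: 5.71 degrees magnitude,
  # negative under the right-side-down-positive convention
  pa2 <- pelvic_angles(c(0, 0, 1), c(0, 1, 0), c(0, -1, 0.2), fr)
  expect_equal(pa2$roll, -atan2(0.2, 2) * 180 / pi, tolerance = 1e-9)
  # simulator closure: 4 degree roll amplitude -> 8 degree ROM within 2%
  res <- sim_record(trot_sim_config(noise_sd_mm = 0, amp_roll_deg = 4))
  expect_equal(res$record$pelvis_roll_rom, 8, tolerance = 0.02)
})

test_that("lean correction is an exact inverse pair and zeroes mean roll", {
  fr <- straight_frame(3)
  expect_equal(lean_correct(fr, 0), fr)
  fr2 <- lean_correct(lean_correct(fr, 10), -10)
  expect_equal(fr2$y, fr$y, tolerance = 1e-12)
  expect_equal(fr2$z, fr$z, tolerance = 1e-12)
  # constant 10 degree lean on the circle: corrected stride-mean roll ~ 0
  cfg <- trot_sim_config(noise_sd_mm = 0, path = "circle",
                         circle_direction = "left", speed = 3.3,
                         lean_deg = 10, n_strides = 8)
  kin <- compute_kinematics(simulate_trot_markers(cfg))
  seg <- kin$segmentation
  expect_gt(nrow(seg), 4)
  inb <- unlist(Map(function(s, e) s:(e - 1), seg$start, seg$end))
  expect_lt(abs(mean(kin$series$pelvis_roll[inb])), 0.1)
})

test_that("back angle measures deviation from collinearity", {
  fr <- straight_frame(1)
  # collinear markers: zero in both planes
  p1 <- c(2000, 0, 1700)
  p3 <- c(0, 0, 1700)
  mid <- (p1 + p3) / 2
  expect_equal(back_angle(p1, mid, p3, fr, "sagittal"), 0)
  expect_equal(back_angle(p1, mid, p3, fr, "dorsal"), 0)
  # apex perpendicular offset h with half-chord c: angle = 2*atan(h/c),
  # positive below the chord
  h <- 100
  c0 <- 1000
  apex <- mid + c(0, 0, -h)
  expect_equal(back_angle(p1, apex, p3, fr, "sagittal"),
               2 * atan(h / c0) * 180 / pi, tolerance = 1e-9)
  # apex left of the chord is positive in the dorsal plane
  apexL <- mid + c(0, h, 0)
  expect_equal(back_angle(p1, apexL, p3, fr, "dorsal"),
               2 * atan(h / c0) * 180 / pi, tolerance = 1e-9)
  # translation invariance
  dd <- c(4321, -555, 77)
  expect_equal(back_angle(p1 + dd, apex + dd, p3 + dd, fr, "sagittal"),
               back_angle(p1, apex, p3, fr, "sagittal"), tolerance = 1e-12)
})

test_that("body tracking and head swivel have the stated sign conventions", {
  fr <- straight_frame(1)
  ts <- c(0, 0, 1680)
  w_aligned <- c(1150, 0, 1700)
  expect_equal(body_tracking_angle(w_aligned, ts, fr), 0)
  # forehand 10 degrees to the right of travel
  th <- 10 * pi / 180
  w_right <- c(1150 * cos(th), -1150 * sin(th), 1700)
  expect_equal(body_tracking_angle(w_right, ts, fr), 10, tolerance = 1e-9)
  # mirroring the scene left-right negates the angle
  mirror <- function(p) p * c(1, -1, 1)
  expect_equal(body_tracking_angle(mirror(w_right), mirror(ts), fr), -10,
               tolerance = 1e-9)

  head0 <- c(2050, 0, 1500)
  expect_equal(head_swivel_angle(head0, w_aligned, ts, fr), 0)
  phi <- 8 * pi / 180
  headR <- w_aligned + c(900 * cos(phi), -900 * sin(phi), -200)
  expect_equal(head_swivel_angle(headR, w_aligned, ts, fr), 8,
               tolerance = 1e-9)
  expect_equal(head_swivel_angle(mirror(headR), mirror(w_aligned),
                                 mirror(ts), fr), -8, tolerance = 1e-9)
})

test_that("speed estimation matches prescribed motion", {
  n <- 400
  t <- (seq_len(n) - 1) / 100
  # uniform 3.35 m/s
  sp <- speed_from_marker(cbind(3350 * t, 0), 100)
  expect_equal(mean(sp), 3.35, tolerance = 1e-6)
  # circular motion: speed = r * omega within 1%
  r <- 4850
  om <- 0.7
  sp2 <- speed_from_marker(cbind(r * cos(om * t), r * sin(om * t)), 100)
  expect_equal(mean(sp2[50:350]), r * om / 1000, tolerance = 0.01)
  # stationary marker: zero speed
  expect_equal(max(speed_from_marker(cbind(rep(1, n), 1), 100)), 0)
  expect_error(speed_from_marker(cbind(1:2, 0), 100), "at least 3")
})

test_that("all pipeline angles are invariant to rigid world motion", {
  cfg <- trot_sim_config(noise_sd_mm = 0, n_strides = 6)
  ms <- simulate_trot_markers(cfg)
  th <- 35 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  shift <- c(12345, -6789, 321)
  mk2 <- lapply(ms$markers, function(m) {
    sweep(m %*% t(R), 2, shift, "+")
  })
  ms2 <- marker_series(mk2, ms$rate)
  meta <- list(horse = "H1", day = "1", measurement = 1,
               path = "straight", surface = "soft")
  r1 <- suppressMessages(analyze_trial(ms, meta))$record
  r2 <- suppressMessages(analyze_trial(ms2, meta))$record
  num <- vapply(r1, is.numeric, logical(1))
  expect_equal(as.numeric(r2[, num]), as.numeric(r1[, num]),
               tolerance = 1e-6)
})
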