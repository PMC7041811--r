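test_that("stride segmentation recovers prescribed stride timing", {
  cfg <- trot_sim_config(noise_sd_mm = 0, stride_frequency = 1.333,
                         n_strides = 14)
  kin <- compute_kinematics(simulate_trot_markers(cfg))
  seg <- kin$segmentation
  # 14 simulated strides -> 14 intervals
  expect_equal(nrow(seg), 14)
  # stride duration 1/1.333 = 0.75 s within one frame
  expect_equal(mean(seg$duration_s), 1 / 1.333, tolerance = 0.01 / 0.75)
  # intervals ordered and non-overlapping; frames within the signal
  expect_true(all(seg$end > seg$start))
  expect_true(all(diff(seg$start) > 0))
  expect_true(all(seg$start[-1] == seg$end[-nrow(seg)]))
  expect_lte(sum(seg$end - seg$start), n_frames(simulate_trot_markers(cfg)))
})

test_that("constant signals yield an empty segmentation, short ones error", {
  z <- rep(1680, 500)
  roll <- rep(0, 500)
  seg <- segment_strides(z, roll, 100)
  expect_equal(nrow(seg), 0)
  expect_error(segment_strides(rep(1, 100), rep(0, 100), 100), "2 s")
})

test_that("per-stride ROM and mean follow closed forms and drop gaps", {
  rate <- 100
  f <- 2 # one cycle per 50 frames
  t <- (0:499) / rate
  x <- 3 * sin(2 * pi * f * t)
  seg <- make_seg(c(1, 51, 101), c(51, 101, 151), rate)
  rom <- per_stride_values(x, seg, "rom")
  expect_equal(rom$value, rep(6, 3), tolerance = 1e-2) # 2A, discretisation
  cm <- per_stride_values(rep(4.2, 500), seg, "mean")
  expect_equal(cm$value, rep(4.2, 3))
  # a fully gapped stride is absent from the output
  x2 <- x
  x2[55:60] <- NA
  rom2 <- per_stride_values(x2, seg, "rom")
  expect_identical(rom2$stride, c(1L, 3L))
  expect_error(per_stride_values(x[1:100], seg, "rom"), "past the end")
})

test_that("measurement aggregation applies the stride-count rule", {
  mk_tab <- function(n, rom = 4.91, dur = 0.75) {
    tibble::tibble(stride = seq_len(n), duration_s = dur,
                   back_flexext_rom = rom)
  }
  meta <- list(horse = "H1", day = "1", measurement = 1,
               path = "straight", surface = "hard")
  # five complete strides or fewer: discarded
  expect_message(out5 <- aggregate_measurement(mk_tab(5), meta), "discarded")
  expect_true(out5$discarded)
  expect_null(out5$record)
  # six kept
  out6 <- aggregate_measurement(mk_tab(6), meta)
  expect_false(out6$discarded)
  # 14 identical ROMs: measurement mean equals them; frequency = 1/duration
  out14 <- aggregate_measurement(mk_tab(14), meta)
  expect_equal(out14$record$back_flexext_rom, 4.91)
  expect_equal(out14$record$n_strides, 14)
  expect_equal(out14$record$stride_frequency, 1 / 0.75)
  # gapped strides do not count as complete
  tab <- mk_tab(8)
  tab$back_flexext_rom[1:3] <- NA
  expect_message(out <- aggregate_measurement(tab, meta), "discarded")
  expect_equal(out$n_strides, 5)
})

test_that("circle diameter comes from a least-squares fit", {
  th <- seq(0, 1.5 * pi, length.out = 400)
  # exact circle of radius 5 m
  expect_equal(circle_diameter(cbind(5000 * cos(th), 5000 * sin(th))), 10)
  # radius 4.85 m with 5 cm marker noise
  set.seed(3)
  noisy <- cbind(4850 * cos(th) + rnorm(400, sd = 50),
                 4850 * sin(th) + rnorm(400, sd = 50))
  expect_equal(circle_diameter(noisy), 9.7, tolerance = 0.05 / 9.7)
  # straight line: degenerate
  expect_error(circle_diameter(cbind(1:400 * 10, 0)), "degenerate|circle")
  # less than half a revolution
  th2 <- seq(0, 0.4 * pi, length.out = 200)
  expect_error(circle_diameter(cbind(5000 * cos(th2), 5000 * sin(th2))),
               "half a revolution")
})

test_that("stronger smoothing cannot raise range of motion", {
  cfg <- trot_sim_config(noise_sd_mm = 2, n_strides = 8, seed = 5)
  ms <- simulate_trot_markers(cfg)
  meta <- list(horse = "H1", day = "1", measurement = 1,
               path = "straight", surface = "soft")
  r30 <- suppressMessages(analyze_trial(ms, meta, cutoff_hz = 30))$record
  r08 <- suppressMessages(analyze_trial(ms, meta, cutoff_hz = 8))$record
  roms <- grep("_rom$", names(r30), value = TRUE)
  expect_true(all(unlist(r08[roms]) <= unlist(r30[roms]) + 1e-6))
})
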