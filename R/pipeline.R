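# Marker triples defining the back angles: whole back plus one angle per
# instrumented vertebra, each from the markers immediately cranial and
# caudal to it.
back_angle_triples <- function() {
  list(
    back = c("withers_mid", "T15", "tuber_sacrale"),
    T12  = c("withers_mid", "T12", "T15"),
    T15  = c("T12", "T15", "T18"),
    T18  = c("T15", "T18", "L3"),
    L3   = c("T18", "L3", "L5"),
    L5   = c("L3", "L5", "tuber_sacrale"),
    TS   = c("L5", "tuber_sacrale", "S5")
  )
}

#' Compute all kinematic parameter time series for one trial
#'
#' Full single-trial kinematics: low-pass filtering (4th-order zero-phase
#' Butterworth, 30 Hz default), heading frame from the smoothed tuber sacrale
#' track, stride segmentation, body-lean estimation (stride-mean pelvic roll)
#' and correction, then every angle and displacement series: whole-back and
#' segmental flexion-extension/lateral bending, pelvic roll/pitch/yaw, body
#' tracking, head swivel, vertical head/withers/sacrum displacement, and
#' speed.
#'
#' Gaps are kept explicit: filtering and heading estimation run on
#' temporarily gap-bridged signals for numerical stability, but every output
#' series is `NA` wherever a contributing marker was untracked, so gapped
#' strides are dropped downstream rather than interpolated.
#'
#' @param series A `marker_series`.
#' @param config A `marker_config` mapping roles to the series' labels.
#' @param cutoff_hz Low-pass cutoff for marker data (default 30 Hz).
#' @param heading_window_s Smoothing span of the heading/speed regression
#'   (default 0.5 s).
#' @param apply_lean_correction Correct planes for body lean (default TRUE).
#' @return A `trial_kinematics` list: `series` (named list of per-frame
#'   numeric vectors), `segmentation`, `frame`, `lean_deg`, `rate`.
#' @export
compute_kinematics <- function(series, config = marker_config(),
                               cutoff_hz = 30, heading_window_s = 0.5,
                               apply_lean_correction = TRUE) {
  stopifnot(inherits(series, "marker_series"))
  check <- validate_marker_set(series, config, max_gap_fraction = 1)
  if (length(check$missing_roles) > 0) {
    stop("marker series lacks roles: ",
         paste(check$missing_roles, collapse = ", "))
  }
  rate <- series$rate
  filled <- list()  # filtered, gap-bridged
  masked <- list()  # filtered, gaps re-imposed
  for (role in marker_roles()) {
    lb <- config[[role]]
    m <- series$markers[[lb]]
    f <- apply(m, 2, function(col) {
      lowpass_filter(fill_gaps_linear(col), rate,
                     min(cutoff_hz, rate / 2.5))
    })
    filled[[role]] <- f
    g <- series$gap[, lb]
    f[g, ] <- NA_real_
    masked[[role]] <- f
  }

  frame0 <- heading_frame(filled$tuber_sacrale[, 1:2], rate,
                          heading_window_s)
  roll0 <- pelvic_angles(filled$tuber_sacrale, filled$tuber_coxae_left,
                         filled$tuber_coxae_right, frame0)$roll
  seg <- segment_strides(filled$tuber_sacrale[, 3], roll0, rate)
  lean <- 0
  if (apply_lean_correction && nrow(seg) > 0) {
    in_stride <- unlist(lapply(seq_len(nrow(seg)),
                               function(i) seg$start[i]:(seg$end[i] - 1L)))
    lean <- mean(roll0[in_stride])
  }
  frame <- if (apply_lean_correction) lean_correct(frame0, lean) else frame0

  out <- list()
  pel <- pelvic_angles(masked$tuber_sacrale, masked$tuber_coxae_left,
                       masked$tuber_coxae_right, frame)
  out$pelvis_roll <- pel$roll
  out$pelvis_pitch <- pel$pitch
  out$pelvis_yaw <- pel$yaw
  for (nm in names(back_angle_triples())) {
    tri <- back_angle_triples()[[nm]]
    key <- if (nm == "back") "back" else nm
    out[[paste0(if (nm == "back") "back_flexext" else paste0("flexext_", nm))]] <-
      back_angle(masked[[tri[1]]], masked[[tri[2]]], masked[[tri[3]]],
                 frame, "sagittal")
    out[[paste0(if (nm == "back") "back_latbend" else paste0("latbend_", nm))]] <-
      back_angle(masked[[tri[1]]], masked[[tri[2]]], masked[[tri[3]]],
                 frame, "dorsal")
  }
  out$body_tracking <- body_tracking_angle(masked$withers_mid,
                                           masked$tuber_sacrale, frame)
  out$head_swivel <- head_swivel_angle(masked$head_ref, masked$withers_mid,
                                       masked$tuber_sacrale, frame)
  out$head_z <- masked$head_ref[, 3]
  out$withers_z <- masked$withers_mid[, 3]
  out$sacrum_z <- masked$tuber_sacrale[, 3]
  sp <- speed_from_marker(filled$tuber_sacrale[, 1:2], rate,
                          heading_window_s)
  sp[series$gap[, config[["tuber_sacrale"]]]] <- NA_real_
  out$speed <- sp

  structure(list(series = out, segmentation = seg, frame = frame,
                 lean_deg = lean, rate = rate),
            class = "trial_kinematics")
}

# map measurement parameters to (time series name, aggregation mode)
param_series_map <- function() {
  tibble::tribble(
    ~parameter,          ~series,         ~mode,
    "speed",             "speed",         "mean",
    "head_rom",          "head_z",        "rom",
    "withers_rom",       "withers_z",     "rom",
    "sacrum_rom",        "sacrum_z",      "rom",
    "pelvis_roll_rom",   "pelvis_roll",   "rom",
    "pelvis_pitch_rom",  "pelvis_pitch",  "rom",
    "pelvis_yaw_rom",    "pelvis_yaw",    "rom",
    "body_tracking",     "body_tracking", "mean",
    "head_swivel",       "head_swivel",   "mean",
    "back_flexext_rom",  "back_flexext",  "rom",
    "back_latbend_rom",  "back_latbend",  "rom",
    "flexext_T12_rom",   "flexext_T12",   "rom",
    "latbend_T12_rom",   "latbend_T12",   "rom",
    "flexext_T15_rom",   "flexext_T15",   "rom",
    "latbend_T15_rom",   "latbend_T15",   "rom",
    "flexext_T18_rom",   "flexext_T18",   "rom",
    "latbend_T18_rom",   "latbend_T18",   "rom",
    "flexext_L3_rom",    "flexext_L3",    "rom",
    "latbend_L3_rom",    "latbend_L3",    "rom",
    "flexext_L5_rom",    "flexext_L5",    "rom",
    "latbend_L5_rom",    "latbend_L5",    "rom",
    "flexext_TS_rom",    "flexext_TS",    "rom",
    "latbend_TS_rom",    "latbend_TS",    "rom"
  )
}

#' Per-stride parameter table for one trial
#'
#' Applies [per_stride_values()] to every kinematic series of a trial,
#' aligned on the trial's stride segmentation.
#'
#' @param kin A `trial_kinematics` object from [compute_kinematics()].
#' @return Tibble with columns `stride`, `duration_s` and one column per
#'   parameter (`NA` where the stride is gapped for that parameter).
#' @export
stride_table <- function(kin) {
  stopifnot(inherits(kin, "trial_kinematics"))
  seg <- kin$segmentation
  tab <- tibble::tibble(stride = seq_len(nrow(seg)),
                        duration_s = seg$duration_s)
  pm <- param_series_map()
  for (i in seq_len(nrow(pm))) {
    vals <- per_stride_values(kin$series[[pm$series[i]]], seg,
                              mode = pm$mode[i])
    tab[[pm$parameter[i]]] <-
      vals$value[match(tab$stride, vals$stride)]
  }
  tab
}

#' Analyse one trot-up end to end
#'
#' Convenience wrapper: [compute_kinematics()], [stride_table()] and
#' [aggregate_measurement()] for a single trial, yielding one measurement
#' record (or a logged discard when fewer than `min_strides` complete strides
#' were collected).
#'
#' @param series A `marker_series`.
#' @param meta Identifiers: named list with `horse`, `day`, `measurement`,
#'   `path`, `surface`.
#' @param config A `marker_config`.
#' @param min_strides Stride-count quality threshold (default 6).
#' @param ... Passed to [compute_kinematics()].
#' @return List with `record`, `discarded`, `reason`, `n_strides`,
#'   `per_stride`, `kinematics`.
#' @export
analyze_trial <- function(series, meta, config = marker_config(),
                          min_strides = 6, ...) {
  kin <- compute_kinematics(series, config, ...)
  ps <- stride_table(kin)
  agg <- aggregate_measurement(ps, meta, min_strides = min_strides)
  c(agg, list(per_stride = ps, kinematics = kin))
}

#' Tidy export of trial angle series
#'
#' @param kin A `trial_kinematics`.
#' @return Long tibble with columns `frame`, `time_s`, `parameter`, `value`,
#'   ready for CSV export or plotting.
#' @export
kinematics_tidy <- function(kin) {
  stopifnot(inherits(kin, "trial_kinematics"))
  n <- length(kin$series[[1]])
  dplyr::bind_rows(lapply(names(kin$series), function(p) {
    tibble::tibble(frame = seq_len(n), time_s = (seq_len(n) - 1) / kin$rate,
                   parameter = p, value = kin$series[[p]])
  }))
}
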