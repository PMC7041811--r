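#' Kinematic parameters computed by the pipeline
#'
#' Names, units and aggregation mode of every kinematic parameter the trial
#' pipeline produces. ROM-type parameters are per-stride range of motion
#' (max - min); mean-type parameters are signed per-stride means (head swivel,
#' body tracking, speed). Angles are in degrees, vertical displacement ROM of
#' the head/withers/sacrum markers in millimetres, speed in m/s.
#'
#' @return A tibble with columns `parameter`, `units`, `mode` (`"rom"` or
#'   `"mean"`).
#' @export
kinematic_parameters <- function() {
  tibble::tribble(
    ~parameter,               ~units, ~mode,
    "stride_duration",        "s",    "mean",
    "stride_frequency",       "Hz",   "mean",
    "speed",                  "m/s",  "mean",
    "head_rom",               "mm",   "rom",
    "withers_rom",            "mm",   "rom",
    "sacrum_rom",             "mm",   "rom",
    "pelvis_roll_rom",        "deg",  "rom",
    "pelvis_pitch_rom",       "deg",  "rom",
    "pelvis_yaw_rom",         "deg",  "rom",
    "body_tracking",          "deg",  "mean",
    "head_swivel",            "deg",  "mean",
    "back_flexext_rom",       "deg",  "rom",
    "back_latbend_rom",       "deg",  "rom",
    "flexext_T12_rom",        "deg",  "rom",
    "latbend_T12_rom",        "deg",  "rom",
    "flexext_T15_rom",        "deg",  "rom",
    "latbend_T15_rom",        "deg",  "rom",
    "flexext_T18_rom",        "deg",  "rom",
    "latbend_T18_rom",        "deg",  "rom",
    "flexext_L3_rom",         "deg",  "rom",
    "latbend_L3_rom",         "deg",  "rom",
    "flexext_L5_rom",         "deg",  "rom",
    "latbend_L5_rom",         "deg",  "rom",
    "flexext_TS_rom",         "deg",  "rom",
    "latbend_TS_rom",         "deg",  "rom"
  )
}

#' Path-surface condition label
#'
#' The study design has four path-surface combinations: straight line on hard
#' (tarmac) and soft surface, and left/right lunge circles on soft surface
#' only (circles are never trotted on hard ground).
#'
#' @param path `"straight"`, `"lunge_left"` or `"lunge_right"`.
#' @param surface `"hard"` or `"soft"`.
#' @return Character vector of condition labels, one of `"hard_straight"`,
#'   `"soft_straight"`, `"soft_left"`, `"soft_right"`.
#' @export
condition_label <- function(path, surface) {
  stopifnot(all(path %in% c("straight", "lunge_left", "lunge_right")),
            all(surface %in% c("hard", "soft")))
  bad <- path != "straight" & surface == "hard"
  if (any(bad)) {
    stop("lunge measurements on hard surface are not part of the design")
  }
  dplyr::case_when(
    path == "straight" & surface == "hard" ~ "hard_straight",
    path == "straight" & surface == "soft" ~ "soft_straight",
    path == "lunge_left" ~ "soft_left",
    path == "lunge_right" ~ "soft_right"
  )
}

conditions_all <- function() {
  c("hard_straight", "soft_straight", "soft_left", "soft_right")
}

# identifier columns of a measurement-record table
record_id_cols <- function() {
  c("horse", "day", "measurement", "path", "surface", "n_strides")
}
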