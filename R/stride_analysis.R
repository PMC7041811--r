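#' Segment a trot trial into strides
#'
#' At trot the vertical displacement of the sacrum oscillates at twice the
#' stride frequency (one minimum per diagonal step), so its low-pass-filtered
#' minima mark half-stride boundaries. Pelvic roll completes exactly one
#' cycle per stride and is used to phase-align the segmentation: stride
#' boundaries are placed at those sacrum minima where pelvic roll is
#' increasing, so every interval spans one full stride. Absence of
#' oscillation yields zero strides, not an error.
#'
#' @param sacrum_z Vertical tuber sacrale displacement (mm), gap-free.
#' @param pelvic_roll Pelvic roll angle series (degrees), gap-free.
#' @param rate Sampling rate, Hz.
#' @param cutoff_hz Low-pass cutoff used for event detection (default 10 Hz).
#' @param min_amplitude Minimum peak-to-peak oscillation (same units as
#'   `sacrum_z`) below which the signal is treated as oscillation-free.
#' @return A `stride_segmentation`: tibble with columns `start`, `end`
#'   (half-open frame intervals) and `duration_s`, with the sampling rate as
#'   attribute `rate`.
#' @export
segment_strides <- function(sacrum_z, pelvic_roll, rate,
                            cutoff_hz = 10, min_amplitude = 1) {
  stopifnot(length(sacrum_z) == length(pelvic_roll), rate > 0)
  n <- length(sacrum_z)
  if (n < 2 * rate) {
    stop("need at least 2 s of data to segment strides")
  }
  empty <- tibble::tibble(start = integer(0), end = integer(0),
                          duration_s = numeric(0))
  z <- lowpass_filter(fill_gaps_linear(sacrum_z), rate,
                      min(cutoff_hz, rate / 2.5))
  roll <- lowpass_filter(fill_gaps_linear(pelvic_roll), rate,
                         min(cutoff_hz, rate / 2.5))
  if (diff(range(z)) < min_amplitude) {
    return(structure(empty, rate = rate, class = c("stride_segmentation",
                                                   class(empty))))
  }
  dz <- diff(z)
  minima <- which(dz[-length(dz)] < 0 & dz[-1] >= 0) + 1L
  minima <- minima[z[minima] < stats::median(z)] # guard spurious dimples
  if (diff(range(roll)) > 1e-6) {
    droll <- c(NA, (roll[-(1:2)] - roll[1:(n - 2)]) / 2, NA)
    starts <- minima[!is.na(droll[minima]) & droll[minima] > 0]
  } else {
    # no roll signal to phase-align on: take every second minimum
    starts <- minima[seq(1, length(minima), by = 2)]
  }
  if (length(starts) < 2) {
    return(structure(empty, rate = rate, class = c("stride_segmentation",
                                                   class(empty))))
  }
  seg <- tibble::tibble(start = starts[-length(starts)], end = starts[-1])
  seg$duration_s <- (seg$end - seg$start) / rate
  # drop pathological intervals (missed or doubled events)
  med <- stats::median(seg$duration_s)
  seg <- seg[seg$duration_s > 0.55 * med & seg$duration_s < 1.8 * med, ]
  structure(seg, rate = rate, class = c("stride_segmentation", class(seg)))
}

#' Per-stride range of motion or mean of a signal
#'
#' ROM-type kinematic parameters are summarised as max - min within each
#' stride; signed parameters (head swivel, body tracking, speed) as the
#' within-stride arithmetic mean. Strides containing any gap (`NA`) in the
#' signal are dropped, not interpolated.
#'
#' @param values Numeric signal, one value per frame (`NA` at gaps).
#' @param seg A `stride_segmentation`.
#' @param mode `"rom"` or `"mean"`.
#' @return Tibble with columns `stride` (index into `seg`) and `value`;
#'   gapped strides are absent.
#' @export
per_stride_values <- function(values, seg, mode = c("rom", "mean")) {
  mode <- match.arg(mode)
  stopifnot(inherits(seg, "stride_segmentation"))
  if (nrow(seg) > 0 && max(seg$end) - 1 > length(values)) {
    stop("segmentation extends past the end of the signal")
  }
  out <- lapply(seq_len(nrow(seg)), function(i) {
    v <- values[seg$start[i]:(seg$end[i] - 1L)]
    if (length(v) == 0) {
      message("stride ", i, " is empty; skipped")
      return(NULL)
    }
    if (anyNA(v)) return(NULL) # gapped stride: dropped
    val <- if (mode == "rom") max(v) - min(v) else mean(v)
    tibble::tibble(stride = i, value = val)
  })
  dplyr::bind_rows(out)
}

#' Aggregate per-stride values to a measurement record
#'
#' One trot-up yields one measurement record: the mean over complete strides
#' of each parameter, plus mean stride duration and stride frequency
#' (1 / mean duration). A stride is complete when every parameter is
#' available for it (no marker gaps). Following the study's quality rule,
#' measurements with five or fewer complete strides are discarded (the
#' default `min_strides = 6` keeps records with at least six).
#'
#' @param per_stride Tibble with columns `stride`, `duration_s` and one
#'   column per kinematic parameter (`NA` where the stride is gapped for that
#'   parameter).
#' @param meta Named list or one-row data frame of identifiers: `horse`,
#'   `day`, `measurement`, `path`, `surface`.
#' @param min_strides Minimum number of complete strides to keep the record.
#' @return List with `record` (one-row tibble, or `NULL` if discarded),
#'   `discarded` (logical), `reason` (character or `NA`) and `n_strides`.
#' @export
aggregate_measurement <- function(per_stride, meta, min_strides = 6) {
  meta <- as.list(meta)
  pcols <- setdiff(names(per_stride), c("stride", "duration_s"))
  complete <- stats::complete.cases(per_stride[, pcols, drop = FALSE])
  n <- sum(complete)
  if (n < min_strides) {
    reason <- sprintf("only %d complete strides (need >= %d)", n, min_strides)
    message("measurement discarded: ", reason)
    return(list(record = NULL, discarded = TRUE, reason = reason,
                n_strides = n))
  }
  ps <- per_stride[complete, , drop = FALSE]
  rec <- tibble::as_tibble(meta[c("horse", "day", "measurement",
                                  "path", "surface")])
  rec$n_strides <- n
  rec$stride_duration <- mean(ps$duration_s)
  rec$stride_frequency <- 1 / rec$stride_duration
  for (p in pcols) rec[[p]] <- mean(ps[[p]])
  list(record = rec, discarded = FALSE, reason = NA_character_, n_strides = n)
}

#' Lunge circle diameter from a horizontal track
#'
#' Least-squares circle fit (algebraic/Kasa fit) to the horizontal
#' trajectory of the tuber sacrale marker, as used to report the realised
#' lunge circle size. The path must subtend at least half a revolution;
#' straight tracks raise a degenerate-fit error.
#'
#' @param track_xy n x 2 horizontal positions in mm.
#' @return Circle diameter in metres.
#' @export
circle_diameter <- function(track_xy) {
  track_xy <- as.matrix(track_xy)
  track_xy <- track_xy[stats::complete.cases(track_xy), , drop = FALSE]
  stopifnot(ncol(track_xy) == 2, nrow(track_xy) >= 10)
  x <- track_xy[, 1]
  y <- track_xy[, 2]
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  fit <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(fit)) {
    stop("degenerate circle fit: track is straight or ill-conditioned")
  }
  cx <- fit[1]
  cy <- fit[2]
  r <- sqrt(fit[3] + cx^2 + cy^2)
  span <- max(diff(range(x)), diff(range(y)))
  if (!is.finite(r) || r > 50 * span) {
    stop("degenerate circle fit: radius vastly exceeds the track extent")
  }
  theta <- atan2(y - cy, x - cx)
  # unwrap and require at least half a revolution of coverage
  dth <- diff(theta)
  dth <- ifelse(dth > pi, dth - 2 * pi, ifelse(dth < -pi, dth + 2 * pi, dth))
  if (abs(sum(dth)) < pi) {
    stop("track subtends less than half a revolution; cannot fit a circle")
  }
  2 * r / 1000
}
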