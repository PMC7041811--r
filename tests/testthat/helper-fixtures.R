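# shared fixture builders -----------------------------------------------

# static frame aligned with the world axes (travel along +x), n frames
straight_frame <- function(n = 1) {
  f <- heading_frame(cbind(seq_len(max(n, 5)) * 10, 0), rate = 100)
  f$x <- f$x[rep(1L, n), , drop = FALSE]
  f$y <- f$y[rep(1L, n), , drop = FALSE]
  f$z <- f$z[rep(1L, n), , drop = FALSE]
  f
}

# hand-built stride segmentation
make_seg <- function(starts, ends, rate = 100) {
  seg <- tibble::tibble(start = as.integer(starts), end = as.integer(ends),
                        duration_s = (ends - starts) / rate)
  structure(seg, rate = rate,
            class = c("stride_segmentation", class(tibble::tibble())))
}

# hand-built deviation records for fitting the variability model directly
make_devs <- function(y, horse, day = "1", measurement = 1,
                      path = "straight", surface = "soft",
                      parameter = "p", speed_cov = NA_real_) {
  n <- length(y)
  d <- tibble::tibble(
    horse = rep_len(horse, n), day = rep_len(day, n),
    measurement = rep_len(measurement, n),
    path = rep_len(path, n), surface = rep_len(surface, n),
    speed_cov = rep_len(speed_cov, n),
    parameter = parameter, value = NA_real_, deviation = NA_real_, y = y
  )
  d$rep_index <- spinekin:::rep_index_from_measurement(d$measurement)
  d$condition <- condition_label(d$path, d$surface)
  d
}

# balanced one-condition records: k measurements (M1..Mk) per horse
balanced_records <- function(values, horses, parameter = "p",
                             path = "straight", surface = "soft") {
  k <- length(values) / length(horses)
  stopifnot(k == round(k), k <= 12)
  out <- tibble::tibble(
    horse = rep(horses, each = k),
    day = rep(rep(c("1", "2", "recheck"), times = c(5, 5, 2))[seq_len(k)],
              times = length(horses)),
    measurement = rep(seq_len(k), times = length(horses)),
    path = path, surface = surface, n_strides = 14L,
    value = values
  )
  names(out)[names(out) == "value"] <- parameter
  out
}

# quick full-pipeline result for a simulated trial
sim_record <- function(cfg, path = "straight", surface = "soft") {
  ms <- simulate_trot_markers(cfg)
  suppressMessages(analyze_trial(
    ms, meta = list(horse = "H1", day = "1", measurement = 1,
                    path = path, surface = surface)))
}

# one-way ANOVA ICC(1) closed form on balanced data (independent oracle)
anova_icc1 <- function(value, group) {
  k <- as.numeric(table(group))
  stopifnot(length(unique(k)) == 1)
  k <- k[1]
  fit <- stats::aov(value ~ factor(group))
  ms <- summary(fit)[[1]][["Mean Sq"]]
  (ms[1] - ms[2]) / (ms[1] + (k - 1) * ms[2])
}

# method-of-moments variance components on balanced one-way data
mom_varcomp <- function(value, group) {
  k <- as.numeric(table(group))
  stopifnot(length(unique(k)) == 1)
  k <- k[1]
  fit <- stats::aov(value ~ factor(group))
  ms <- summary(fit)[[1]][["Mean Sq"]]
  c(sigma2_group = max((ms[1] - ms[2]) / k, 0), sigma2_resid = ms[2])
}
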