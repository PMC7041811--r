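#' Configuration for the synthetic measurement-mean study
#'
#' Ground truth for [simulate_measurement_dataset()], which emulates a
#' repeated-measures normal-range study: `n_horses` horses, each trotted up
#' 12 times (five repetitions on day one, five on day two, two at a recheck)
#' in four path-surface conditions (hard/soft straight, soft left/right
#' lunge). Each measurement mean is
#' `condition mean + horse effect + day effect + repetition trend + noise`,
#' with the horse effect drawn once per horse and parameter
#' (`N(0, sigma_horse^2)`) and residual noise `N(0, sigma_resid^2)`, so the
#' true one-way ICC per condition is
#' `sigma_horse^2 / (sigma_horse^2 + sigma_resid^2)`.
#'
#' The default parameter table covers the five main spinal parameters plus
#' speed with condition means, between-horse and residual spreads of
#' magnitudes typical for sound trotting horses; its defaults put
#' substantially more variation between than within horses. A positive
#' `recheck` day effect (one residual-sd by default) emulates the commonly
#' observed extra variation at a recheck weeks later.
#'
#' @param n_horses Number of horses (default 12).
#' @param parameters Data frame with columns `parameter`, the four condition
#'   means (`hard_straight`, `soft_straight`, `soft_left`, `soft_right`),
#'   `sigma_horse`, `sigma_resid`, `day2`, `recheck` (additive day effects),
#'   `rep_slope` (additive mean-level trend per within-day repetition step)
#'   and `rep_sd_slope` (multiplicative trend of the residual sd per
#'   repetition step: `sd = sigma_resid * (1 + rep_sd_slope * (rep - 1))`,
#'   floored at 10% of `sigma_resid`; a negative value emulates variation
#'   shrinking as horses get accustomed over repeated trot-ups). `NULL` uses
#'   the built-in defaults.
#' @param absent_recheck Integer indices of horses missing the recheck
#'   (default horses 3, 8 and 10, a realistic drop-out pattern).
#' @param seed RNG seed; `NULL` leaves the RNG state alone.
#' @return A `study_sim_config` list.
#' @export
study_sim_config <- function(n_horses = 12, parameters = NULL,
                             absent_recheck = c(3, 8, 10), seed = NULL) {
  if (is.null(parameters)) {
    parameters <- tibble::tribble(
      ~parameter, ~hard_straight, ~soft_straight, ~soft_left, ~soft_right,
      ~sigma_horse, ~sigma_resid, ~day2, ~recheck, ~rep_slope, ~rep_sd_slope,
      "back_flexext_rom", 4.91, 4.97, 5.71, 5.55, 0.50, 0.35, 0, 0.35, 0, -0.05,
      "back_latbend_rom", 6.46, 7.45, 7.80, 7.77, 0.95, 0.45, 0, 0.45, 0, -0.05,
      "pelvis_roll_rom",  8.51, 9.65, 8.77, 9.35, 1.20, 0.60, 0, 0.60, 0, -0.05,
      "pelvis_pitch_rom", 6.98, 7.62, 8.08, 8.27, 0.95, 0.45, 0, 0.45, 0, -0.05,
      "pelvis_yaw_rom",   3.95, 4.29, 5.23, 5.26, 0.55, 0.30, 0, 0.30, 0, -0.05,
      "speed",            3.35, 3.79, 3.30, 3.35, 0.20, 0.18, 0, 0.18, 0, -0.05
    )
  }
  parameters <- tibble::as_tibble(parameters)
  if (!"rep_sd_slope" %in% names(parameters)) parameters$rep_sd_slope <- 0
  need <- c("parameter", conditions_all(), "sigma_horse", "sigma_resid",
            "day2", "recheck", "rep_slope", "rep_sd_slope")
  stopifnot(all(need %in% names(parameters)),
            all(parameters$sigma_horse >= 0),
            all(parameters$sigma_resid >= 0),
            n_horses >= 2)
  structure(list(n_horses = n_horses, parameters = parameters,
                 absent_recheck = absent_recheck, seed = seed),
            class = "study_sim_config")
}

#' Simulate a measurement-mean study dataset
#'
#' Draws a full measurement-record table from a [study_sim_config()]: one
#' row per horse x measurement (M1-M12 over three days) x condition, with
#' one column per parameter. Horses listed in `absent_recheck` have no
#' M11/M12 rows. Deterministic for a fixed seed.
#'
#' @param config A `study_sim_config`.
#' @return Measurement-record tibble (same layout as
#'   [read_measurement_table()] returns), with the per-horse true effects
#'   attached as attribute `horse_effects`.
#' @export
simulate_measurement_dataset <- function(config = study_sim_config()) {
  stopifnot(inherits(config, "study_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  pars <- config$parameters
  schedule <- tibble::tibble(
    measurement = 1:12,
    day = rep(c("1", "2", "recheck"), times = c(5, 5, 2))
  )
  schedule$rep_index <- rep_index_from_measurement(schedule$measurement)
  conds <- tibble::tibble(
    path = c("straight", "straight", "lunge_left", "lunge_right"),
    surface = c("hard", "soft", "soft", "soft")
  )
  grid <- tidyr::expand_grid(horse = sprintf("H%02d", seq_len(config$n_horses)),
                             schedule, conds)
  absent <- sprintf("H%02d", config$absent_recheck)
  grid <- grid[!(grid$horse %in% absent & grid$day == "recheck"), ]
  grid$condition <- condition_label(grid$path, grid$surface)

  horse_eff <- matrix(
    stats::rnorm(config$n_horses * nrow(pars)),
    nrow = config$n_horses,
    dimnames = list(sprintf("H%02d", seq_len(config$n_horses)),
                    pars$parameter)
  )
  horse_eff <- sweep(horse_eff, 2, pars$sigma_horse, "*")

  for (i in seq_len(nrow(pars))) {
    p <- pars$parameter[i]
    cm <- unlist(pars[i, conditions_all()])
    day_eff <- c(`1` = 0, `2` = pars$day2[i], recheck = pars$recheck[i])
    mu <- cm[grid$condition] + horse_eff[cbind(grid$horse, p)] +
      day_eff[grid$day] + pars$rep_slope[i] * (grid$rep_index - 1)
    sd_i <- pars$sigma_resid[i] *
      pmax(1 + pars$rep_sd_slope[i] * (grid$rep_index - 1), 0.1)
    grid[[p]] <- as.numeric(mu) + stats::rnorm(nrow(grid), sd = sd_i)
  }
  grid$n_strides <- ifelse(grid$path == "straight",
                           pmax(6, round(stats::rnorm(nrow(grid), 14, 3.8))),
                           pmax(6, round(stats::rnorm(nrow(grid), 36.8, 5.6))))
  out <- grid[, c("horse", "day", "measurement", "path", "surface",
                  "n_strides", pars$parameter)]
  out <- validate_measurement_records(out)
  attr(out, "horse_effects") <- horse_eff
  out
}
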