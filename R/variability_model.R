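#' Offset-adjust measurement means
#'
#' Isolates between-measurement variation by centering: within each horse x
#' path x surface cell (and per parameter), the mean of that horse's
#' available measurements (M1-M12) is subtracted, so each horse's data are
#' zero-centered per condition. The square-root of the absolute deviation
#' (`y = sqrt(|deviation|)`) is attached as the modelling response; the
#' transform counteracts the right skew of absolute deviations.
#'
#' @param records Measurement-record tibble.
#' @param parameters Parameter columns to adjust; defaults to every
#'   non-identifier numeric column.
#' @return Long tibble of deviation records: identifiers, `rep_index`
#'   (within-day repetition 1-5), `condition`, `speed_cov` (the record's
#'   measured speed, carried as a covariate when a speed column exists),
#'   `parameter`, `value`, `deviation`, `y`.
#' @export
offset_adjust <- function(records, parameters = NULL) {
  records <- validate_measurement_records(records)
  if (is.null(parameters)) {
    parameters <- setdiff(names(records)[vapply(records, is.numeric,
                                                logical(1))],
                          record_id_cols())
  }
  records$condition <- condition_label(records$path, records$surface)
  records$rep_index <- rep_index_from_measurement(records$measurement)
  speed_cov <- if ("speed" %in% names(records)) records$speed else NA_real_
  id_cols <- c("horse", "day", "measurement", "path", "surface",
               "condition", "rep_index")
  records$speed_cov <- speed_cov
  long <- records[, c(id_cols, "speed_cov", parameters)] |>
    tidyr::pivot_longer(dplyr::all_of(parameters), names_to = "parameter",
                        values_to = "value") |>
    dplyr::group_by(.data$horse, .data$path, .data$surface,
                    .data$parameter) |>
    dplyr::mutate(deviation = .data$value - mean(.data$value, na.rm = TRUE)) |>
    dplyr::ungroup() |>
    dplyr::mutate(y = sqrt(abs(.data$deviation)))
  long[, c(id_cols, "speed_cov", "parameter", "value", "deviation", "y")]
}

# within-day repetition index: M1-5 -> 1-5, M6-10 -> 1-5, M11-12 -> 1-2
rep_index_from_measurement <- function(measurement) {
  m <- as.integer(measurement)
  stopifnot(all(m %in% 1:12))
  ifelse(m <= 5, m, ifelse(m <= 10, m - 5L, m - 10L))
}

#' Fit the between-measurement variability model for one parameter
#'
#' Linear mixed model on the square-root-transformed absolute deviations:
#' fixed effects are day (3-level factor, day one as reference), within-day
#' repetition index (numeric 1-5, capturing the tendency of variation to
#' change over repeated trot-ups), path (straight line as reference) and
#' surface (soft as reference); horse is a random intercept. Fitted by REML;
#' no interactions (the design has no hard-surface circles, so they are not
#' estimable) and no model reduction. Optionally adds measured speed as a
#' linear covariate. Factors with a single observed level are dropped with a
#' message (the model is then a within-condition variability model).
#'
#' @param devs Deviation records from [offset_adjust()].
#' @param parameter Which parameter to model; may be omitted when `devs`
#'   contains exactly one.
#' @param with_speed Add speed as a linear fixed effect (default FALSE).
#' @return A `variability_fit`: list with the fitted `model` (lmerModLmerTest,
#'   or `NULL` for a degenerate constant response), fixed effects `beta`,
#'   variance components `vc` (`sigma2_horse`, `sigma2_resid`), centering
#'   values and bookkeeping.
#' @export
fit_variability_model <- function(devs, parameter = NULL,
                                  with_speed = FALSE) {
  pars <- unique(devs$parameter)
  if (is.null(parameter)) {
    if (length(pars) != 1) {
      stop("devs contains ", length(pars),
           " parameters; supply `parameter`")
    }
    parameter <- pars
  }
  d <- devs[devs$parameter == parameter & !is.na(devs$y), , drop = FALSE]
  if (length(unique(d$horse)) < 2) {
    stop("variability model needs at least 2 horses")
  }
  d$day <- droplevels(factor(d$day, levels = c("1", "2", "recheck")))
  d$path <- droplevels(factor(d$path, levels = c("straight", "lunge_left",
                                                 "lunge_right")))
  d$surface <- droplevels(factor(d$surface, levels = c("soft", "hard")))
  d$rep_index <- as.numeric(d$rep_index)

  terms <- c("day", "rep_index", "path", "surface")
  keep <- vapply(terms, function(tm) {
    v <- d[[tm]]
    length(unique(v[!is.na(v)])) > 1
  }, logical(1))
  if (any(!keep)) {
    message("dropping constant fixed effect(s): ",
            paste(terms[!keep], collapse = ", "))
  }
  terms <- terms[keep]
  if (with_speed) {
    if (!"speed_cov" %in% names(d) || all(is.na(d$speed_cov))) {
      stop("with_speed = TRUE but no speed covariate in the records")
    }
    terms <- c(terms, "speed_cov")
  }
  rep_center <- if ("rep_index" %in% terms) mean(d$rep_index) else NA_real_
  speed_center <- if (with_speed) mean(d$speed_cov, na.rm = TRUE) else NA_real_

  out <- list(parameter = parameter, with_speed = with_speed,
              n = nrow(d), data = d, terms = terms,
              rep_center = rep_center, speed_center = speed_center)
  if (stats::var(d$y) == 0) {
    # constant response: all variance components are exactly zero
    out$model <- NULL
    out$beta <- c(`(Intercept)` = d$y[1])
    out$vc <- c(sigma2_horse = 0, sigma2_resid = 0)
    class(out) <- "variability_fit"
    return(out)
  }
  rhs <- paste(c(if (length(terms) > 0) terms else "1", "(1 | horse)"),
               collapse = " + ")
  form <- stats::as.formula(paste("y ~", rhs))
  X <- stats::model.matrix(stats::as.formula(
    paste("~", paste(if (length(terms) > 0) terms else "1",
                     collapse = " + "))), d)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("fixed-effect design is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  model <- suppressMessages(
    lmerTest::lmer(form, data = d, REML = TRUE,
                   control = lme4::lmerControl(
                     check.conv.singular = "ignore"))
  )
  vc <- as.data.frame(lme4::VarCorr(model))
  out$model <- model
  out$beta <- lme4::fixef(model)
  out$vc <- c(sigma2_horse = vc$vcov[vc$grp == "horse"],
              sigma2_resid = vc$vcov[vc$grp == "Residual"])
  class(out) <- "variability_fit"
  out
}

#' @export
print.variability_fit <- function(x, ...) {
  cat(sprintf("<variability_fit> %s (n = %d)\n", x$parameter, x$n))
  cat(sprintf("  sigma2_horse = %.5g, sigma2_resid = %.5g\n",
              x$vc[["sigma2_horse"]], x$vc[["sigma2_resid"]]))
  print(round(x$beta, 4))
  invisible(x)
}

#' Wald tests of the variability-model fixed effects
#'
#' Per-coefficient t statistics with Satterthwaite denominator degrees of
#' freedom (the default), or normal-approximation z tests. Two-sided
#' p-values; the study's significance threshold is 0.05.
#'
#' @param fit A `variability_fit`.
#' @param ddf `"satterthwaite"` or `"z"`.
#' @return Tibble: `term`, `estimate`, `se`, `df`, `statistic`, `p_value`.
#' @export
fixed_effect_tests <- function(fit, ddf = c("satterthwaite", "z")) {
  ddf <- match.arg(ddf)
  stopifnot(inherits(fit, "variability_fit"))
  if (is.null(fit$model)) {
    return(tibble::tibble(term = names(fit$beta), estimate = unname(fit$beta),
                          se = 0, df = NA_real_, statistic = NA_real_,
                          p_value = NA_real_))
  }
  if (ddf == "satterthwaite") {
    ct <- stats::coef(summary(fit$model, ddf = "Satterthwaite"))
    tibble::tibble(term = rownames(ct),
                   estimate = unname(ct[, "Estimate"]),
                   se = unname(ct[, "Std. Error"]),
                   df = unname(ct[, "df"]),
                   statistic = unname(ct[, "t value"]),
                   p_value = unname(ct[, "Pr(>|t|)"]))
  } else {
    est <- lme4::fixef(fit$model)
    se <- sqrt(diag(as.matrix(stats::vcov(fit$model))))
    z <- unname(est / se)
    tibble::tibble(term = names(est), estimate = unname(est),
                   se = unname(se), df = Inf, statistic = unname(z),
                   p_value = 2 * stats::pnorm(-abs(z)))
  }
}

#' Back-transformed 95% prediction upper limits per condition
#'
#' Marginal prediction limit for the absolute deviation of a new measurement
#' in each path-surface condition. On the square-root scale the limit is
#' `x'beta + q * sqrt(sigma2_horse + sigma2_resid)` with `x` encoding the
#' condition at the reference day (day one) and the mean repetition index
#' (and mean speed when the model includes it), and `q` the upper quantile
#' of the standard normal by default. Back-transformation squares the limit,
#' so it is reported on the original scale (degrees, mm or m/s). Because
#' deviations are zero-centered and their distribution symmetric, only the
#' upper limit is meaningful. The arithmetic mean over the four conditions
#' summarises a parameter's between-measurement variation in one number.
#'
#' @param fit A `variability_fit`.
#' @param level Prediction level (default 0.95).
#' @param quantile `"z"` (normal, default) or `"t"` (Student t with
#'   residual-style df `n - p`).
#' @return List with `limits` (tibble: `condition`, `upper_limit`) and
#'   `mean_variation` (arithmetic mean of the per-condition limits).
#' @export
prediction_upper_limits <- function(fit, level = 0.95,
                                    quantile = c("z", "t")) {
  quantile <- match.arg(quantile)
  stopifnot(inherits(fit, "variability_fit"))
  conds <- intersect(conditions_all(), unique(fit$data$condition))
  p <- 1 - (1 - level) / 2
  q <- if (quantile == "z") {
    stats::qnorm(p)
  } else {
    stats::qt(p, df = max(fit$n - length(fit$beta), 1))
  }
  tot_sd <- sqrt(sum(fit$vc))
  xb <- vapply(conds, function(cn) {
    x <- stats::setNames(numeric(length(fit$beta)), names(fit$beta))
    x["(Intercept)"] <- 1
    if ("rep_index" %in% names(x)) x["rep_index"] <- fit$rep_center
    if ("speed_cov" %in% names(x)) x["speed_cov"] <- fit$speed_center
    if (cn == "hard_straight" && "surfacehard" %in% names(x)) {
      x["surfacehard"] <- 1
    }
    if (cn == "soft_left" && "pathlunge_left" %in% names(x)) {
      x["pathlunge_left"] <- 1
    }
    if (cn == "soft_right" && "pathlunge_right" %in% names(x)) {
      x["pathlunge_right"] <- 1
    }
    sum(x * fit$beta)
  }, numeric(1))
  lim <- pmax(xb + q * tot_sd, 0)^2
  limits <- tibble::tibble(condition = conds, upper_limit = unname(lim))
  list(limits = limits, mean_variation = mean(limits$upper_limit))
}

#' Variability analysis of a whole measurement table
#'
#' Offset-adjusts the records and, for each parameter, fits the variability
#' model and computes fixed-effect tests and back-transformed prediction
#' limits.
#'
#' @param records Measurement-record tibble.
#' @param parameters Parameters to model; defaults to every non-identifier
#'   numeric column.
#' @param with_speed Add speed as a linear covariate to each model.
#' @param ... Passed to [prediction_upper_limits()].
#' @return List with `coefficients` (long tibble of per-parameter Wald
#'   tests), `limits` (tibble: parameter, condition, upper_limit),
#'   `mean_variation` (tibble: parameter, mean_variation) and `fits` (named
#'   list of `variability_fit`s).
#' @export
variability_summary <- function(records, parameters = NULL,
                                with_speed = FALSE, ...) {
  devs <- offset_adjust(records, parameters)
  pars <- unique(devs$parameter)
  fits <- lapply(pars, function(p) {
    fit_variability_model(devs, parameter = p, with_speed = with_speed)
  })
  names(fits) <- pars
  coefs <- dplyr::bind_rows(lapply(pars, function(p) {
    dplyr::mutate(fixed_effect_tests(fits[[p]]), parameter = p,
                  .before = 1)
  }))
  lims <- lapply(pars, function(p) prediction_upper_limits(fits[[p]], ...))
  limits <- dplyr::bind_rows(lapply(seq_along(pars), function(i) {
    dplyr::mutate(lims[[i]]$limits, parameter = pars[i], .before = 1)
  }))
  mv <- tibble::tibble(parameter = pars,
                       mean_variation = vapply(lims, `[[`, numeric(1),
                                               "mean_variation"))
  list(coefficients = coefs, limits = limits, mean_variation = mv,
       fits = fits)
}
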