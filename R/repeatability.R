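#' Intraclass correlation coefficients per parameter and condition
#'
#' Repeatability of each kinematic parameter within each path-surface
#' condition, with horse as the grouping factor: a one-way random-effects
#' model `value ~ 1 + (1 | horse)` is fitted by REML to the (non-offset-
#' adjusted) measurement means, and ICC(1) = sigma2_horse / (sigma2_horse +
#' sigma2_resid). ICC near 1 means horses are well separated relative to
#' their within-horse measurement scatter, i.e. repeated trot-ups are highly
#' repeatable.
#'
#' Estimates are reported in `[0, 1]`; a boundary fit (between-horse variance
#' estimated at zero) is flagged. Conditions with fewer than 2 horses having
#' at least 2 repetitions are marked unavailable.
#'
#' @param records Measurement-record tibble.
#' @param parameters Parameter columns; defaults to every non-identifier
#'   numeric column.
#' @return Tibble: `parameter`, `condition`, `icc`, `n_horses`, `n_records`,
#'   `flag` (`""`, `"boundary"`, `"unavailable"`).
#' @export
icc_per_condition <- function(records, parameters = NULL) {
  records <- validate_measurement_records(records)
  if (is.null(parameters)) {
    parameters <- setdiff(names(records)[vapply(records, is.numeric,
                                                logical(1))],
                          record_id_cols())
  }
  records$condition <- condition_label(records$path, records$surface)
  grid <- expand.grid(parameter = parameters,
                      condition = intersect(conditions_all(),
                                            unique(records$condition)),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- grid$parameter[i]
    cn <- grid$condition[i]
    d <- records[records$condition == cn & !is.na(records[[p]]),
                 c("horse", p)]
    names(d)[2] <- "value"
    reps <- table(d$horse)
    base <- tibble::tibble(parameter = p, condition = cn, icc = NA_real_,
                           n_horses = length(reps), n_records = nrow(d),
                           flag = "unavailable")
    if (sum(reps >= 2) < 2 || length(reps) < 2) return(base)
    base$flag <- ""
    within_var <- sum(vapply(split(d$value, d$horse), function(v) {
      if (length(v) < 2) 0 else stats::var(v) * (length(v) - 1)
    }, numeric(1)))
    if (stats::var(d$value) == 0) {
      base$icc <- NA_real_
      base$flag <- "unavailable" # no variance at all: ICC undefined
      return(base)
    }
    if (within_var == 0) {
      # horses perfectly constant but distinct: all variance is between
      base$icc <- 1
      return(base)
    }
    model <- suppressMessages(
      lme4::lmer(value ~ 1 + (1 | horse), data = d, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))
    )
    vc <- as.data.frame(lme4::VarCorr(model))
    vh <- vc$vcov[vc$grp == "horse"]
    ve <- vc$vcov[vc$grp == "Residual"]
    base$icc <- min(max(vh / (vh + ve), 0), 1)
    if (vh <= 0) base$flag <- "boundary"
    base
  })
  dplyr::bind_rows(rows)
}

#' ICC table in wide, condition-per-column layout
#'
#' Pivots [icc_per_condition()] output to one row per parameter with a final
#' row of per-condition column means (the mean of the available entries).
#'
#' @param icc_long Output of [icc_per_condition()].
#' @return Tibble: `parameter` then one column per condition; last row
#'   `column_mean`.
#' @export
icc_table <- function(icc_long) {
  wide <- tidyr::pivot_wider(icc_long[, c("parameter", "condition", "icc")],
                             names_from = "condition", values_from = "icc")
  means <- dplyr::summarise(wide, dplyr::across(-"parameter",
                                                ~mean(.x, na.rm = TRUE)))
  means$parameter <- "column_mean"
  dplyr::bind_rows(wide, means)
}
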