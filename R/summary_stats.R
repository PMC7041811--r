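#' Percentile summary of measurement means per condition
#'
#' For each kinematic parameter and path-surface condition, the 5th
#' percentile, median and 95th percentile of the measurement means, pooled
#' over all horses and all available repetitions. Quantiles use linear
#' interpolation of order statistics (R's default type 7); the rule is
#' configurable.
#'
#' @param records Measurement-record tibble (identifier columns plus
#'   parameter columns), e.g. from [analyze_trial()] or
#'   [read_measurement_table()].
#' @param probs Probabilities to report (default 0.05, 0.50, 0.95).
#' @param parameters Parameter columns to summarise; defaults to every
#'   non-identifier numeric column.
#' @param type Quantile type passed to [stats::quantile()] (default 7).
#' @return Tibble with columns `parameter`, `condition`, then one column per
#'   probability (`p5`, `p50`, `p95` for the defaults). Conditions with no
#'   records are omitted with a warning.
#' @export
percentile_summary <- function(records, probs = c(0.05, 0.5, 0.95),
                               parameters = NULL, type = 7) {
  records <- validate_measurement_records(records)
  if (is.null(parameters)) {
    parameters <- setdiff(names(records)[vapply(records, is.numeric,
                                                logical(1))],
                          record_id_cols())
  }
  if (nrow(records) == 0) stop("no records to summarise")
  records$condition <- condition_label(records$path, records$surface)
  absent <- setdiff(conditions_all(), unique(records$condition))
  if (length(absent) > 0) {
    warning("no records for condition(s): ", paste(absent, collapse = ", "))
  }
  pn <- paste0("p", round(probs * 100))
  out <- records |>
    tidyr::pivot_longer(dplyr::all_of(parameters), names_to = "parameter",
                        values_to = "value") |>
    dplyr::group_by(.data$parameter, .data$condition) |>
    dplyr::summarise(
      q = list(stats::quantile(.data$value, probs = probs, type = type,
                               na.rm = TRUE)),
      .groups = "drop"
    )
  qm <- do.call(rbind, out$q)
  colnames(qm) <- pn
  out <- dplyr::bind_cols(out[c("parameter", "condition")],
                          tibble::as_tibble(qm))
  out$parameter <- factor(out$parameter, levels = parameters)
  out <- dplyr::arrange(out, .data$parameter,
                        match(.data$condition, conditions_all()))
  out$parameter <- as.character(out$parameter)
  out
}
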