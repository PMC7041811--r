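#' Marker roles required by the kinematic pipeline
#'
#' The pipeline needs 13 anatomical landmarks: the reference (lowest) head
#' marker, the withers triad (highest point plus one marker 20 cm to each
#' side), the dorsal spinous processes T12, T15, T18, L3, L5 and S5, and the
#' pelvic T-strip (tuber sacrale plus left and right tubera coxae).
#'
#' @return Character vector of role names.
#' @export
marker_roles <- function() {
  c("head_ref", "withers_mid", "withers_left", "withers_right",
    "tuber_sacrale", "tuber_coxae_left", "tuber_coxae_right",
    "T12", "T15", "T18", "L3", "L5", "S5")
}

#' Map anatomical roles to marker labels
#'
#' A marker configuration maps each required anatomical role to the label the
#' motion-capture export uses for that marker. All 13 roles must be mapped and
#' labels must be unique.
#'
#' @param labels Named character vector or list: names are roles (see
#'   [marker_roles()]), values are marker labels. Defaults to the identity
#'   mapping (labels equal role names), which is what the trot simulator
#'   emits.
#' @return A `marker_config` object (named character vector).
#' @export
marker_config <- function(labels = NULL) {
  roles <- marker_roles()
  if (is.null(labels)) {
    labels <- stats::setNames(roles, roles)
  }
  labels <- unlist(labels)
  missing <- setdiff(roles, names(labels))
  if (length(missing) > 0) {
    stop("marker_config: unmapped roles: ", paste(missing, collapse = ", "))
  }
  labels <- labels[roles]
  if (anyDuplicated(labels)) {
    stop("marker_config: duplicated labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  structure(labels, class = "marker_config")
}

#' Read a marker configuration from a YAML file
#'
#' The file holds a flat `role: label` mapping.
#'
#' @param path Path to a YAML file.
#' @return A `marker_config`.
#' @export
read_marker_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML marker configs requires the 'yaml' package")
  }
  marker_config(yaml::read_yaml(path))
}

#' Construct a marker frame series
#'
#' Container for labelled 3D marker trajectories: time-indexed positions in a
#' right-handed world frame with the vertical axis up (+z), in millimetres, at
#' a fixed sampling rate. Frames where a marker was not tracked carry `NA`
#' positions and are flagged in the gap mask; they are never interpolated by
#' this package — downstream strides touching a gap in a needed marker are
#' dropped instead.
#'
#' @param markers Named list of numeric matrices, one per marker, each with
#'   `n_frames` rows and columns x, y, z (mm). `NA` rows mark untracked
#'   frames.
#' @param rate Sampling rate in Hz (> 0).
#' @return A `marker_series` object: list with elements `markers` (list of
#'   n x 3 matrices), `gap` (n x n_markers logical matrix) and `rate`.
#' @export
marker_series <- function(markers, rate) {
  stopifnot(is.list(markers), length(markers) > 0, !is.null(names(markers)),
            is.numeric(rate), length(rate) == 1, rate > 0)
  n <- unique(vapply(markers, nrow, integer(1)))
  if (length(n) != 1) {
    stop("all markers must have the same frame count")
  }
  if (n == 0) {
    stop("marker series has zero frames")
  }
  markers <- lapply(markers, function(m) {
    m <- as.matrix(m)
    stopifnot(ncol(m) == 3)
    colnames(m) <- c("x", "y", "z")
    # a frame is a gap if any coordinate is missing
    m[rowSums(is.na(m)) > 0, ] <- NA_real_
    m
  })
  gap <- vapply(markers, function(m) is.na(m[, 1]), logical(n))
  gap <- matrix(gap, nrow = n, dimnames = list(NULL, names(markers)))
  finite_ok <- vapply(markers, function(m) {
    ok <- !is.na(m[, 1])
    all(is.finite(m[ok, , drop = FALSE]))
  }, logical(1))
  if (!all(finite_ok)) {
    stop("non-finite positions in tracked frames for marker(s): ",
         paste(names(markers)[!finite_ok], collapse = ", "))
  }
  structure(list(markers = markers, gap = gap, rate = rate),
            class = "marker_series")
}

#' @export
print.marker_series <- function(x, ...) {
  cat(sprintf("<marker_series> %d markers, %d frames @ %g Hz (%.2f s)\n",
              length(x$markers), n_frames(x), x$rate, duration(x)))
  gaps <- colSums(x$gap)
  if (any(gaps > 0)) {
    g <- gaps[gaps > 0]
    cat("  gaps:", paste(sprintf("%s=%d", names(g), g), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of frames / duration of a marker series
#' @param series A `marker_series`.
#' @return Integer frame count / duration in seconds.
#' @export
n_frames <- function(series) nrow(series$markers[[1]])

#' @rdname n_frames
#' @export
duration <- function(series) n_frames(series) / series$rate

#' Write marker trajectories as tab-separated text
#'
#' Plain-text trajectory dialect: line 1 is `sampling_rate<TAB><Hz>`, line 2 a
#' header with three columns per marker (`<label>_X`, `<label>_Y`,
#' `<label>_Z`), then one row per frame with positions in mm and `NA` for
#' untracked frames.
#'
#' @param series A `marker_series`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(series, path) {
  stopifnot(inherits(series, "marker_series"))
  labs <- names(series$markers)
  mat <- do.call(cbind, series$markers)
  colnames(mat) <- paste0(rep(labs, each = 3), "_", c("X", "Y", "Z"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("sampling_rate\t%.10g", series$rate), con)
  utils::write.table(mat, con, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' Read labelled marker trajectories
#'
#' Reads the tab-separated trajectory dialect written by
#' [write_trajectories()]. Untracked frames (`NA`) are flagged in the gap
#' mask, never interpolated.
#'
#' @param path Input file path.
#' @param format `"tsv"`. The binary C3D container is not supported by this
#'   package; export trajectories to the TSV dialect instead.
#' @return A `marker_series`.
#' @export
read_trajectories <- function(path, format = c("tsv", "c3d")) {
  format <- match.arg(format)
  if (format == "c3d") {
    stop("C3D input is not supported; export trajectories as TSV ",
         "(see ?write_trajectories for the dialect)")
  }
  if (!file.exists(path)) {
    stop("trajectory file not found: ", path)
  }
  header <- readLines(path, n = 1)
  parts <- strsplit(header, "\t", fixed = TRUE)[[1]]
  if (length(parts) != 2 || parts[1] != "sampling_rate") {
    stop("not a trajectory TSV: first line must be 'sampling_rate<TAB><Hz>'")
  }
  rate <- as.numeric(parts[2])
  if (!is.finite(rate) || rate <= 0) {
    stop("invalid sampling rate in header: ", parts[2])
  }
  tab <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1,
                           na.strings = "NA", check.names = FALSE)
  if (nrow(tab) == 0) {
    stop("trajectory file has zero frames: ", path)
  }
  cols <- colnames(tab)
  ok <- grepl("_[XYZ]$", cols)
  if (!all(ok)) {
    stop("malformed trajectory columns: ", paste(cols[!ok], collapse = ", "))
  }
  labs <- unique(sub("_[XYZ]$", "", cols))
  markers <- lapply(labs, function(lb) {
    need <- paste0(lb, "_", c("X", "Y", "Z"))
    if (!all(need %in% cols)) {
      stop("marker ", lb, " is missing one of its X/Y/Z columns")
    }
    as.matrix(tab[, need])
  })
  names(markers) <- labs
  marker_series(markers, rate)
}

#' Validate a marker series against a marker configuration
#'
#' Report-based check (never mutates or errors): lists roles whose label is
#' absent from the series and the gap fraction of every mapped marker. The
#' check passes iff all 13 roles are present and every mapped marker's gap
#' fraction is at or below `max_gap_fraction`.
#'
#' @param series A `marker_series`.
#' @param config A `marker_config`.
#' @param max_gap_fraction Maximum tolerated fraction of untracked frames per
#'   marker (default 0.05).
#' @return List with `pass` (logical), `missing_roles` (character),
#'   `gaps` (tibble: role, label, gap_fraction, ok).
#' @export
validate_marker_set <- function(series, config = marker_config(),
                                max_gap_fraction = 0.05) {
  stopifnot(inherits(series, "marker_series"),
            inherits(config, "marker_config"))
  present <- names(series$markers)
  missing_roles <- names(config)[!config %in% present]
  mapped <- config[config %in% present]
  gaps <- tibble::tibble(
    role = names(mapped),
    label = unname(mapped),
    gap_fraction = vapply(mapped, function(lb) mean(series$gap[, lb]),
                          numeric(1), USE.NAMES = FALSE)
  )
  gaps$ok <- gaps$gap_fraction <= max_gap_fraction
  list(pass = length(missing_roles) == 0 && all(gaps$ok),
       missing_roles = missing_roles,
       gaps = gaps)
}

#' Read a measurement-mean table
#'
#' One row per trot-up (horse x day x measurement number x path x surface)
#' with one column per kinematic parameter, as produced by
#' [aggregate_measurement()] or exported from other gait software. CSV and
#' XLSX are accepted (XLSX requires the readxl package).
#'
#' @param path CSV or XLSX file.
#' @param mapping Optional named character vector renaming file columns to the
#'   canonical names: names are canonical (e.g. `"horse"`,
#'   `"back_flexext_rom"`), values are the file's column names.
#' @return A tibble of measurement records with identifier columns `horse`,
#'   `day` (`"1"`, `"2"`, `"recheck"`), `measurement` (1-12), `path`,
#'   `surface`, `n_strides`, plus parameter columns.
#' @export
read_measurement_table <- function(path, mapping = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading XLSX requires the 'readxl' package")
    }
    tab <- readxl::read_excel(path)
  } else {
    tab <- readr::read_csv(path, show_col_types = FALSE)
  }
  if (!is.null(mapping)) {
    for (canon in names(mapping)) {
      if (!mapping[[canon]] %in% names(tab)) {
        stop("mapped column not in file: ", mapping[[canon]])
      }
      names(tab)[names(tab) == mapping[[canon]]] <- canon
    }
  }
  validate_measurement_records(tab)
}

# Shared invariants of a measurement-record table.
validate_measurement_records <- function(tab) {
  need <- c("horse", "day", "path", "surface")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    stop("measurement table lacks column(s): ", paste(missing, collapse = ", "))
  }
  tab$horse <- as.character(tab$horse)
  tab$day <- as.character(tab$day)
  if (!all(tab$day %in% c("1", "2", "recheck"))) {
    stop("day must be one of '1', '2', 'recheck'")
  }
  if ("measurement" %in% names(tab) &&
      !all(tab$measurement %in% 1:12)) {
    stop("measurement number must be in 1..12")
  }
  if (!all(tab$path %in% c("straight", "lunge_left", "lunge_right"))) {
    stop("path must be straight, lunge_left or lunge_right")
  }
  if (!all(tab$surface %in% c("hard", "soft"))) {
    stop("surface must be hard or soft")
  }
  if (any(tab$path != "straight" & tab$surface == "hard")) {
    stop("invalid records: lunge on hard surface is not part of the design")
  }
  if ("n_strides" %in% names(tab) && any(tab$n_strides < 0)) {
    stop("n_strides must be >= 0")
  }
  tibble::as_tibble(tab)
}
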