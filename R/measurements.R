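#' Read a morphometric measurement table
#'
#' Reads a CSV of linear measurements with one row per specimen. The file must
#' have a header `specimen_id,group,<var1>,<var2>,...`; every measurement
#' column is a strictly positive length (the measurement unit, typically mm,
#' is irrelevant to all downstream ratio analyses).
#'
#' @param path Path to a CSV file.
#' @return A tibble with columns `specimen_id`, `group` and one numeric column
#'   per measured variable.
#' @export
read_measurements <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  validate_measurements(data)
  data
}

#' List the measurement variables of a table
#'
#' All columns other than `specimen_id` and `group` are treated as measured
#' variables, in their column order.
#'
#' @param data A measurement table (see [read_measurements()]).
#' @return Character vector of variable names.
#' @export
measurement_vars <- function(data) {
  setdiff(names(data), c("specimen_id", "group"))
}

# Checks the measurement-table contract: id/group columns present, >= 2
# numeric variables, no missing cells, all values strictly positive. The
# offending cell is named on failure because a single mistyped 0 otherwise
# surfaces only as -Inf deep inside the log-ratio machinery.
validate_measurements <- function(data, min_vars = 2L) {
  if (!all(c("specimen_id", "group") %in% names(data))) {
    stop("measurement table needs `specimen_id` and `group` columns",
         call. = FALSE)
  }
  vars <- measurement_vars(data)
  if (length(vars) < min_vars) {
    stop("measurement table needs at least ", min_vars, " variables",
         call. = FALSE)
  }
  if (anyDuplicated(data$specimen_id)) {
    stop("duplicated specimen_id values", call. = FALSE)
  }
  for (v in vars) {
    col <- data[[v]]
    if (!is.numeric(col)) {
      stop("variable `", v, "` is not numeric", call. = FALSE)
    }
    bad <- which(is.na(col) | col <= 0)
    if (length(bad)) {
      stop("non-positive or missing measurement: specimen `",
           data$specimen_id[bad[1]], "`, variable `", v, "`", call. = FALSE)
    }
  }
  invisible(data)
}

log_matrix <- function(data, vars = measurement_vars(data)) {
  m <- log(as.matrix(data[vars]))
  rownames(m) <- data$specimen_id
  m
}

#' Isometric size (geometric mean of measurements)
#'
#' Appends per-specimen `isosize` (the geometric mean of all measurement
#' columns, same unit as the measurements) and `log_isosize` (its natural
#' log, equal to the mean of the log measurements). Isosize is the isometric
#' size proxy of multivariate ratio analysis: rescaling every measurement of
#' a specimen by a constant c multiplies its isosize by c and leaves its
#' shape (log-ratio) coordinates untouched.
#'
#' @param data A measurement table.
#' @param vars Variables to use; defaults to all measurement columns.
#' @return `data` with `isosize` and `log_isosize` columns appended.
#' @export
#' @examples
#' tbl <- tibble::tibble(specimen_id = "s1", group = "A", a = 2, b = 8)
#' add_isosize(tbl)$isosize  # 4
add_isosize <- function(data, vars = NULL) {
  vars <- vars %||% measurement_vars(data)
  validate_measurements(data[c("specimen_id", "group", vars)])
  lm_ <- log_matrix(data, vars)
  data$log_isosize <- unname(rowMeans(lm_))
  data$isosize <- exp(data$log_isosize)
  data
}

#' Shape-space (centered log-ratio) coordinates
#'
#' Projects log measurements into shape space by subtracting each specimen's
#' mean log measurement (its log isosize). The result is the centered
#' log-ratio transform: rows sum to zero, and specimens that are scalar
#' multiples of one another get identical shape rows. Changing the unit of a
#' single variable shifts that column by a constant before centering, so all
#' between-specimen shape contrasts are unit invariant.
#'
#' @inheritParams add_isosize
#' @return A numeric matrix (specimens x variables) of shape coordinates,
#'   with specimen ids as row names.
#' @export
shape_values <- function(data, vars = NULL) {
  vars <- vars %||% measurement_vars(data)
  validate_measurements(data[c("specimen_id", "group", vars)])
  lm_ <- log_matrix(data, vars)
  sweep(lm_, 1, rowMeans(lm_))
}
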