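#' Two-group sample
#'
#' The unit all hypothesis tests in the package consume: a binary group label
#' (0/1) and one numeric value per record.
#'
#' @param labels integer vector of 0/1 group labels.
#' @param values numeric vector, same length as `labels`.
#' @return an object of class `two_group_sample` with derived group sizes
#'   `n1` (label 0) and `n2` (label 1).
#' @export
two_group_sample <- function(labels, values) {
  labels <- as.integer(labels)
  values <- as.numeric(values)
  if (length(labels) != length(values))
    stop("labels and values must have the same length")
  if (length(labels) && !all(labels %in% c(0L, 1L)))
    stop("labels must be 0 or 1")
  structure(list(labels = labels, values = values,
                 n1 = sum(labels == 0L), n2 = sum(labels == 1L)),
            class = "two_group_sample")
}

#' @export
print.two_group_sample <- function(x, ...) {
  cat(sprintf("two_group_sample: %d records (group 0: %d, group 1: %d)\n",
              length(x$labels), x$n1, x$n2))
  invisible(x)
}

#' Extract the values of one group
#' @param sample a [two_group_sample()].
#' @param group 0 or 1.
#' @return numeric vector.
#' @export
group_values <- function(sample, group) {
  stopifnot(inherits(sample, "two_group_sample"), group %in% c(0L, 1L))
  sample$values[sample$labels == group]
}

#' Read a two-group sample from CSV
#'
#' Expects a header and (at least) a 0/1 group column and a numeric value
#' column.  Rows that fail to parse are reported with their line numbers; if
#' more than 1% of data rows are bad the load aborts.
#'
#' @param path CSV file path.
#' @param value_col,group_col column names (defaults `"value"`, `"group"`).
#' @return a [two_group_sample()].
#' @export
read_two_group_csv <- function(path, value_col = "value", group_col = "group") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c(value_col, group_col) %in% names(df)))
    stop("missing required columns: expected '", group_col, "' and '",
         value_col, "'")
  if (nrow(df) == 0L) stop("empty sample: file has a header but no data rows")
  g <- suppressWarnings(as.numeric(df[[group_col]]))
  v <- suppressWarnings(as.numeric(df[[value_col]]))
  bad <- is.na(g) | is.na(v) | !(g %in% c(0, 1))
  if (any(bad)) {
    lines <- which(bad) + 1L  # +1 for the header line
    if (mean(bad) > 0.01)
      stop(sprintf("%d malformed rows (>1%%), e.g. lines %s", sum(bad),
                   paste(utils::head(lines, 5L), collapse = ", ")))
    warning(sprintf("dropping %d malformed rows at lines %s", sum(bad),
                    paste(utils::head(lines, 5L), collapse = ", ")))
  }
  two_group_sample(g[!bad], v[!bad])
}

#' Write a two-group sample to CSV
#' @param sample a [two_group_sample()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_two_group_csv <- function(sample, path) {
  stopifnot(inherits(sample, "two_group_sample"))
  utils::write.csv(data.frame(group = sample$labels, value = sample$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' Body mass index from weight and height
#' @param weight_kg weight in kilograms.
#' @param height_cm height in centimetres.
#' @return BMI in kg/m^2.
#' @export
bmi_from <- function(weight_kg, height_cm) weight_kg / (height_cm / 100)^2
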