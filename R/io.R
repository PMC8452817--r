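# CSV input/output.  Fixed dialect: UTF-8, comma-separated, header
# required.  Dataset files carry `diameter_um,eta_app_rel[,weight]`; curve
# files carry `diameter_um,eta_app_rel,layer_thickness_um`.  Numbers are
# written with 15 significant digits so a write -> read round trip is
# lossless well past 12 significant digits.

.fmt_num <- function(x) sprintf("%.15g", x)

.write_table <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- .fmt_num(out[[j]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.read_checked <- function(path, required, optional = character(0)) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  tab <- read.csv(path, stringsAsFactors = FALSE, check.names = TRUE)
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  for (col in intersect(c(required, optional), names(tab))) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]))
    if (length(bad))
      stop(sprintf("%s: non-numeric value in column '%s', row %d",
                   path, col, bad[1]), call. = FALSE)
    if (anyNA(v))
      stop(sprintf("%s: missing value in column '%s', row %d",
                   path, col, which(is.na(v))[1]), call. = FALSE)
    tab[[col]] <- v
  }
  tab
}

#' Read a viscosity-diameter dataset from CSV
#'
#' Expects a header with columns `diameter_um,eta_app_rel` and optionally
#' `weight`.  Malformed input (missing header columns, non-numeric cells)
#' is an error naming the offending row and column.
#'
#' @param path Path to a CSV file.
#' @return A [viscosity_dataset()].
#' @export
read_viscosity_dataset <- function(path) {
  tab <- .read_checked(path, c("diameter_um", "eta_app_rel"), "weight")
  viscosity_dataset(tab$diameter_um, tab$eta_app_rel,
                    weight = tab$weight, label = basename(path))
}

#' Write a viscosity-diameter dataset to CSV
#'
#' @param dataset A [viscosity_dataset()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_viscosity_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "fl_dataset"))
  .write_table(as.data.frame(dataset), path)
}

#' Read / write a model viscosity curve
#'
#' Curve files use the header `diameter_um,eta_app_rel,layer_thickness_um`.
#'
#' @param curve An `fl_curve` from [viscosity_curve()].
#' @param path CSV path.
#' @return `write_curve` returns the path invisibly; `read_curve` returns
#'   an `fl_curve` data frame.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "fl_curve"))
  .write_table(as.data.frame(curve), path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  tab <- .read_checked(path, c("diameter_um", "eta_app_rel",
                               "layer_thickness_um"))
  class(tab) <- c("fl_curve", "data.frame")
  tab
}
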