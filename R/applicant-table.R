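#' Validate an applicant table
#'
#' An applicant table is a data frame with numeric columns `x1`, `x2`
#' (complete for every applicant), an outcome column `y` that is missing
#' exactly for rejected applicants, and optionally a composite `z` and a
#' logical `selected` flag.  When `selected` is absent it is inferred as
#' "y observed"; when present, `y` must be observed if and only if
#' `selected` is `TRUE`.
#'
#' @param data a data frame.
#' @return the validated table as a tibble with columns
#'   `x1, x2, (z,) selected, y`.
#' @export
as_applicant_table <- function(data) {
  if (!is.data.frame(data)) abort_data("`data` must be a data frame.")
  for (col in c("x1", "x2")) {
    if (!col %in% names(data)) {
      abort_data(sprintf("Mandatory column `%s` is missing.", col),
        column = col
      )
    }
  }
  if (!"y" %in% names(data)) data$y <- NA_real_
  for (col in intersect(c("x1", "x2", "z", "y"), names(data))) {
    if (!is.numeric(data[[col]])) {
      abort_data(sprintf("Column `%s` must be numeric.", col), column = col)
    }
  }
  for (col in c("x1", "x2")) {
    bad <- which(!is.finite(data[[col]]))
    if (length(bad)) {
      abort_data(
        sprintf(
          "Predictor column `%s` must be complete; missing/non-finite at row(s) %s.",
          col, paste(utils::head(bad, 5), collapse = ", ")
        ),
        column = col, rows = bad
      )
    }
  }
  if (!"selected" %in% names(data)) {
    data$selected <- !is.na(data$y)
  } else {
    if (!is.logical(data$selected)) {
      abort_data("Column `selected` must be logical.", column = "selected")
    }
    mismatch <- which(data$selected != !is.na(data$y))
    if (length(mismatch)) {
      abort_data(
        sprintf(
          "`y` must be observed iff `selected` is TRUE; violated at row(s) %s.",
          paste(utils::head(mismatch, 5), collapse = ", ")
        ),
        rows = mismatch
      )
    }
  }
  keep <- intersect(c("x1", "x2", "z", "selected", "y"), names(data))
  as_tibble(data[keep])
}

#' Read an applicant table from a delimited text file
#'
#' Expects a header row with at least `x1`, `x2`; optional `y`, `z`,
#' `selected`.  Empty fields and `"NA"` in `y` mark rejected applicants
#' (outcome unobserved).  Lines starting with `#` are treated as metadata
#' comments and skipped.
#'
#' @param path file path.
#' @param delim field delimiter, default comma.
#' @return an applicant table (tibble), see [as_applicant_table()].
#' @export
read_applicants <- function(path, delim = ",") {
  if (!file.exists(path)) abort_data(sprintf("File not found: %s", path))
  raw <- readr::read_delim(
    path,
    delim = delim, na = c("", "NA"), comment = "#",
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  for (col in c("x1", "x2")) {
    if (!col %in% names(raw)) {
      abort_data(sprintf("Mandatory column `%s` is missing from %s.", col, path),
        column = col
      )
    }
  }
  num <- raw
  for (col in intersect(c("x1", "x2", "z", "y"), names(raw))) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(vals))
    if (length(bad)) {
      abort_data(
        sprintf(
          "Non-numeric value in column `%s` at data row(s) %s.",
          col, paste(utils::head(bad, 5), collapse = ", ")
        ),
        column = col, rows = bad
      )
    }
    num[[col]] <- vals
  }
  if ("selected" %in% names(raw)) {
    sel <- toupper(trimws(raw$selected))
    if (!all(sel %in% c("TRUE", "FALSE", "T", "F", "0", "1"))) {
      abort_data("Column `selected` must contain logical values.",
        column = "selected"
      )
    }
    num$selected <- sel %in% c("TRUE", "T", "1")
  }
  tab <- as_applicant_table(num)
  message(sprintf(
    "Read %d applicants from %s (%d with observed outcome, %d missing).",
    nrow(tab), path, sum(!is.na(tab$y)), sum(is.na(tab$y))
  ))
  tab
}

#' Write an applicant table to a delimited text file
#'
#' Missing outcomes are written as empty fields.
#'
#' @param data an applicant table.
#' @param path destination path.
#' @param delim field delimiter, default comma.
#' @param header optional character vector of metadata lines to prepend,
#'   written as `#`-prefixed comments.
#' @return `path`, invisibly.
#' @export
write_applicants <- function(data, path, delim = ",", header = NULL) {
  data <- as_applicant_table(data)
  if (!is.null(header)) {
    writeLines(paste0("# ", header), path)
    readr::write_delim(data, path, delim = delim, na = "", append = TRUE,
      col_names = TRUE)
  } else {
    readr::write_delim(data, path, delim = delim, na = "")
  }
  invisible(path)
}
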