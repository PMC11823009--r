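#' Load a field book CSV
#'
#' A field book is the tabular per-plot record breeding programs keep: plot
#' number, line name, pedigree, phenotypes. The file must have a header row
#' and one column holding plot numbers, which must be unique; any subset of
#' the remaining columns can be copied onto the plot features.
#'
#' @param path Path to a CSV file (RFC 4180, UTF-8, header row mandatory).
#' @param plot_column Name of the column holding plot numbers
#'   (default `"plot"`).
#' @param selected_columns Character vector of columns to carry onto
#'   features; defaults to every non-plot column.
#' @return An object of class `fieldbook`: a list with `records` (data
#'   frame; the plot column parsed to integer), `plot_column` and
#'   `selected_columns`.
#' @examples
#' csv <- tempfile(fileext = ".csv")
#' write.csv(data.frame(plot = 101:103, name = c("A", "B", "C")),
#'           csv, row.names = FALSE)
#' fb <- load_fieldbook(csv)
#' fb$selected_columns
#' @export
load_fieldbook <- function(path, plot_column = "plot", selected_columns = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("Field book file not found: '%s'.", path), call. = FALSE)
  }
  records <- utils::read.csv(path, check.names = FALSE,
                             colClasses = "character",
                             fileEncoding = "UTF-8")
  fieldbook(records, plot_column = plot_column,
            selected_columns = selected_columns)
}

#' Construct a field book from an in-memory data frame
#'
#' The programmatic counterpart of [load_fieldbook()], used by the built-in
#' case-study fixtures and by callers that already hold the table.
#'
#' @param records A data frame with one row per plot.
#' @inheritParams load_fieldbook
#' @return An object of class `fieldbook`.
#' @export
fieldbook <- function(records, plot_column = "plot", selected_columns = NULL) {
  if (!is.data.frame(records)) {
    stop("'records' must be a data frame.", call. = FALSE)
  }
  if (!plot_column %in% names(records)) {
    stop(sprintf("Field book has no column '%s' (columns: %s).",
                 plot_column, paste(names(records), collapse = ", ")),
         call. = FALSE)
  }
  plots_raw <- records[[plot_column]]
  plots <- suppressWarnings(as.integer(as.character(plots_raw)))
  if (anyNA(plots)) {
    bad <- unique(as.character(plots_raw)[is.na(plots)])
    stop(sprintf("Field book plot column '%s' has non-integer values: %s.",
                 plot_column, paste(utils::head(bad, 5), collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(plots)) {
    dup <- sort(unique(plots[duplicated(plots)]))
    stop(sprintf("Field book plot numbers must be unique; duplicated: %s.",
                 paste(utils::head(dup, 10), collapse = ", ")), call. = FALSE)
  }
  records[[plot_column]] <- plots
  if (is.null(selected_columns)) {
    selected_columns <- setdiff(names(records), plot_column)
  } else {
    missing <- setdiff(selected_columns, names(records))
    if (length(missing)) {
      stop(sprintf("Selected column(s) not in the field book: %s.",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    selected_columns <- setdiff(selected_columns, plot_column)
  }
  structure(
    list(records = records, plot_column = plot_column,
         selected_columns = as.character(selected_columns)),
    class = "fieldbook"
  )
}

#' @export
print.fieldbook <- function(x, ...) {
  cat(sprintf("Field book: %d records, plot column '%s', selected: %s\n",
              nrow(x$records), x$plot_column,
              if (length(x$selected_columns))
                paste(x$selected_columns, collapse = ", ") else "(none)"))
  invisible(x)
}

#' Join field-book columns onto plot features
#'
#' Matches by plot number (numeric match, so a zero-padded "0101" in the CSV
#' matches plot 101) and copies the book's selected columns onto the feature
#' table. Geometry, feature order and feature count are unchanged. Every
#' feature's plot number must be present in the book -- a book that misses
#' layout plots is an error. Extra book rows whose plots are not in the
#' layout are ignored with a warning, so one book can serve an experiment
#' split across several layers.
#'
#' @param features A `plot_feature_table` from [build_feature_table()].
#' @param book A `fieldbook` from [load_fieldbook()] or [fieldbook()].
#' @return The feature table with one extra column per selected book column.
#' @export
join_attributes <- function(features, book) {
  stopifnot(inherits(features, "plot_feature_table"), inherits(book, "fieldbook"))
  book_plots <- book$records[[book$plot_column]]
  missing <- setdiff(features$plot, book_plots)
  if (length(missing)) {
    stop(sprintf(
      "Field book does not cover %d layout plot number(s): %s.",
      length(missing),
      paste(utils::head(sort(missing), 10), collapse = ", ")), call. = FALSE)
  }
  extra <- setdiff(book_plots, features$plot)
  if (length(extra)) {
    warning(sprintf(
      "Ignoring %d field-book row(s) whose plots are not in the layout (e.g. %s).",
      length(extra), paste(utils::head(sort(extra), 5), collapse = ", ")),
      call. = FALSE)
  }
  if (length(book$selected_columns) == 0L) {
    return(features)
  }
  idx <- match(features$plot, book_plots)
  out <- features
  geometry <- out$geometry
  out$geometry <- NULL
  for (col in book$selected_columns) {
    out[[col]] <- book$records[[col]][idx]
  }
  out$geometry <- geometry
  out
}
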