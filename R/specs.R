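#' Define a replicated serpentine trial layout
#'
#' A replicated layout places `reps` replicates of `plots_per_rep`
#' experimental plots each into a `rows` x `ranges` rectangular footprint,
#' walked in serpentine order from the bottom-left cell. Each replicate may
#' be trailed by fill plots (planted but non-experimental), and whole ranges
#' may be given over to lateral-irrigation wheel tracks. The footprint must
#' be filled exactly: `reps * plots_per_rep + sum(fills_after_reps) +
#' rows * length(wheel_track_ranges)` must equal `rows * ranges`.
#'
#' @param plots_per_rep Number of experimental plots in every replicate
#'   (replicates are assumed balanced).
#' @param reps Number of replicates.
#' @param rows Plots across each range (the width of the footprint).
#' @param ranges Number of ranges front to back, counting wheel-track ranges.
#' @param fills_after_reps Integer vector, one entry per replicate: the number
#'   of fill plots placed immediately after that replicate's last plot.
#' @param wheel_track_ranges Integer vector of 1-based range positions
#'   (counted from the front) occupied by irrigation wheel tracks; may be
#'   empty. Wheel-track ranges are skipped by the numbering and removed from
#'   the output layer.
#' @param right_to_left If `TRUE`, plot numbers increase right to left in the
#'   front range (the serpentine mirror image of the default).
#' @param experiment_name Optional label; used for default output file names.
#'
#' @return An object of class `replicated_spec`.
#' @seealso [validate_spec()], [build_matrix()], [unreplicated_spec()]
#' @examples
#' spec <- replicated_spec(plots_per_rep = 30, reps = 3, rows = 4, ranges = 26,
#'                         fills_after_reps = c(2, 2, 2),
#'                         wheel_track_ranges = c(9, 18))
#' validate_spec(spec)
#' @export
replicated_spec <- function(plots_per_rep, reps, rows, ranges,
                            fills_after_reps = rep(0L, reps),
                            wheel_track_ranges = integer(0),
                            right_to_left = FALSE,
                            experiment_name = NULL) {
  spec <- structure(
    list(
      experiment_name = if (is.null(experiment_name)) NULL else as.character(experiment_name)[1],
      plots_per_rep = as_count(plots_per_rep, "plots_per_rep"),
      reps = as_count(reps, "reps"),
      rows = as_count(rows, "rows"),
      ranges = as_count(ranges, "ranges"),
      fills_after_reps = as_int_vector(fills_after_reps, "fills_after_reps"),
      wheel_track_ranges = as_int_vector(wheel_track_ranges, "wheel_track_ranges"),
      right_to_left = isTRUE(right_to_left)
    ),
    class = c("replicated_spec", "layout_spec")
  )
  spec
}

#' Define an unreplicated serpentine trial layout
#'
#' Unreplicated trials (e.g. early-generation nurseries) are numbered
#' sequentially from `start_plot` to `end_plot` along the serpentine walk.
#' `plot_indent` skips cells at the start of the first range, for the case
#' where a preceding experiment ends mid-range; any cells left after the
#' last plot are likewise excluded from the output.
#'
#' @param start_plot First plot number.
#' @param end_plot Last plot number (`end_plot >= start_plot`).
#' @param rows Plots across each range.
#' @param ranges Number of ranges; `plot_indent + (end_plot - start_plot + 1)`
#'   must fit in `rows * ranges`.
#' @param plot_indent Number of skipped cells in the first range before the
#'   first plot; must be smaller than `rows`.
#' @inheritParams replicated_spec
#'
#' @return An object of class `unreplicated_spec`.
#' @examples
#' nursery <- unreplicated_spec(start_plot = 1, end_plot = 701,
#'                              rows = 52, ranges = 14)
#' validate_spec(nursery)
#' @export
unreplicated_spec <- function(start_plot, end_plot, rows, ranges,
                              plot_indent = 0L,
                              right_to_left = FALSE,
                              experiment_name = NULL) {
  structure(
    list(
      experiment_name = if (is.null(experiment_name)) NULL else as.character(experiment_name)[1],
      start_plot = as_count(start_plot, "start_plot"),
      end_plot = as_count(end_plot, "end_plot"),
      rows = as_count(rows, "rows"),
      ranges = as_count(ranges, "ranges"),
      plot_indent = as_int_scalar(plot_indent, "plot_indent", min = 0L),
      right_to_left = isTRUE(right_to_left)
    ),
    class = c("unreplicated_spec", "layout_spec")
  )
}

#' Validate a layout specification
#'
#' Checks every invariant of a layout spec and returns the problems as a
#' character vector of human-readable messages (empty when the spec is
#' valid), mirroring the warnings a layout dialog would display. Counts are
#' reported as specified vs total-possible plots so a user can see how far
#' off a mismatched design is.
#'
#' @param spec A [replicated_spec()] or [unreplicated_spec()].
#' @return Character vector of issues; `character(0)` if the spec is valid.
#' @examples
#' bad <- replicated_spec(plots_per_rep = 30, reps = 3, rows = 4, ranges = 26,
#'                        fills_after_reps = c(2, 2))
#' validate_spec(bad)
#' @export
validate_spec <- function(spec) {
  UseMethod("validate_spec")
}

#' @export
validate_spec.replicated_spec <- function(spec) {
  issues <- character(0)
  if (length(spec$fills_after_reps) != spec$reps) {
    issues <- c(issues, sprintf(
      "'Fills after reps' has %d entries but must have one per replicate ('Reps' = %d).",
      length(spec$fills_after_reps), spec$reps))
  }
  if (any(spec$fills_after_reps < 0)) {
    issues <- c(issues, "'Fills after reps' entries must be non-negative.")
  }
  wt <- spec$wheel_track_ranges
  if (length(wt)) {
    if (any(wt < 1L | wt > spec$ranges)) {
      issues <- c(issues, sprintf(
        "'Wheel track ranges' entries must be between 1 and 'Ranges' (%d); got: %s.",
        spec$ranges, paste(wt[wt < 1L | wt > spec$ranges], collapse = ", ")))
    }
    if (anyDuplicated(wt)) {
      issues <- c(issues, sprintf(
        "'Wheel track ranges' entries must be unique; duplicated: %s.",
        paste(unique(wt[duplicated(wt)]), collapse = ", ")))
    }
  }
  # Only meaningful when the per-field checks above pass
  if (length(spec$fills_after_reps) == spec$reps && all(spec$fills_after_reps >= 0)) {
    specified <- specified_plots(spec)
    possible <- total_possible_plots(spec)
    if (specified != possible) {
      issues <- c(issues, sprintf(
        "Specified plots (%d) must match total possible plots (%d = %d rows x %d ranges).",
        specified, possible, spec$rows, spec$ranges))
    }
  }
  d <- numbering_digits(spec$plots_per_rep)
  if (length(spec$fills_after_reps) == spec$reps &&
      any(spec$plots_per_rep + spec$fills_after_reps > 10^d - 1)) {
    issues <- c(issues, sprintf(
      "Fill numbering would overflow into the next replicate's series: plots_per_rep + fills must stay below 10^%d.",
      d))
  }
  issues
}

#' @export
validate_spec.unreplicated_spec <- function(spec) {
  issues <- character(0)
  if (spec$end_plot < spec$start_plot) {
    issues <- c(issues, sprintf(
      "'End plot' (%d) must be at least 'Start plot' (%d).",
      spec$end_plot, spec$start_plot))
  }
  if (spec$plot_indent >= spec$rows) {
    issues <- c(issues, sprintf(
      "'Plot indent' (%d) must be smaller than 'Rows' (%d).",
      spec$plot_indent, spec$rows))
  }
  specified <- specified_plots(spec)
  possible <- total_possible_plots(spec)
  if (spec$end_plot >= spec$start_plot && specified > possible) {
    issues <- c(issues, sprintf(
      "Specified plots (%d, including the %d-plot indent) exceed total possible plots (%d = %d rows x %d ranges).",
      specified, spec$plot_indent, possible, spec$rows, spec$ranges))
  }
  issues
}

#' Specified and total-possible plot counts
#'
#' `specified_plots()` is the number of cells a spec claims: experimental +
#' fill + wheel-track plots for replicated designs, indent + experimental
#' plots for unreplicated ones. `total_possible_plots()` is the footprint
#' capacity `rows * ranges`. A replicated spec is valid only when the two
#' are equal; an unreplicated spec when specified <= possible.
#'
#' @inheritParams validate_spec
#' @return A single integer count.
#' @export
specified_plots <- function(spec) {
  UseMethod("specified_plots")
}

#' @export
specified_plots.replicated_spec <- function(spec) {
  spec$reps * spec$plots_per_rep + sum(spec$fills_after_reps) +
    spec$rows * length(spec$wheel_track_ranges)
}

#' @export
specified_plots.unreplicated_spec <- function(spec) {
  spec$plot_indent + (spec$end_plot - spec$start_plot + 1L)
}

#' @rdname specified_plots
#' @export
total_possible_plots <- function(spec) {
  spec$rows * spec$ranges
}

#' @export
print.replicated_spec <- function(x, ...) {
  cat("Replicated serpentine layout",
      if (!is.null(x$experiment_name)) paste0(" '", x$experiment_name, "'"),
      "\n", sep = "")
  cat(sprintf("  %d reps x %d plots, footprint %d rows x %d ranges\n",
              x$reps, x$plots_per_rep, x$rows, x$ranges))
  cat(sprintf("  fills after reps: %s; wheel-track ranges: %s; direction: %s\n",
              paste(x$fills_after_reps, collapse = ","),
              if (length(x$wheel_track_ranges)) paste(x$wheel_track_ranges, collapse = ",") else "none",
              if (x$right_to_left) "right-to-left" else "left-to-right"))
  cat(sprintf("  specified plots: %d / total possible: %d\n",
              specified_plots(x), total_possible_plots(x)))
  invisible(x)
}

#' @export
print.unreplicated_spec <- function(x, ...) {
  cat("Unreplicated serpentine layout",
      if (!is.null(x$experiment_name)) paste0(" '", x$experiment_name, "'"),
      "\n", sep = "")
  cat(sprintf("  plots %d-%d, footprint %d rows x %d ranges, indent %d, direction: %s\n",
              x$start_plot, x$end_plot, x$rows, x$ranges, x$plot_indent,
              if (x$right_to_left) "right-to-left" else "left-to-right"))
  cat(sprintf("  specified plots: %d / total possible: %d (excluded in final range: %d)\n",
              specified_plots(x), total_possible_plots(x),
              total_possible_plots(x) - specified_plots(x)))
  invisible(x)
}

# -- input coercion helpers ---------------------------------------------------

as_count <- function(x, what) {
  as_int_scalar(x, what, min = 1L)
}

as_int_scalar <- function(x, what, min = -.Machine$integer.max) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x)) {
    stop(sprintf("'%s' must be a single whole number.", what), call. = FALSE)
  }
  x <- as.integer(x)
  if (x < min) {
    stop(sprintf("'%s' must be at least %d (got %d).", what, min, x), call. = FALSE)
  }
  x
}

as_int_vector <- function(x, what) {
  if (length(x) == 0L) return(integer(0))
  if (!is.numeric(x) || anyNA(x) || any(x != as.integer(x))) {
    stop(sprintf("'%s' must be a vector of whole numbers.", what), call. = FALSE)
  }
  as.integer(x)
}

numbering_digits <- function(plots_per_rep) {
  max(2L, nchar(as.character(as.integer(plots_per_rep))))
}
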