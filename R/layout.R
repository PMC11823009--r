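#' Serpentine traversal order of a rows-by-ranges grid
#'
#' Enumerates every cell of the grid in the order plots are numbered: start
#' at the bottom-left cell, walk across the front range, then reverse
#' direction on each successive range (boustrophedon). Cells are identified
#' by 0-based `(row, range)` indices with row 0 on the left and range 0 at
#' the front of the experiment.
#'
#' @param rows,ranges Grid dimensions (positive integers).
#' @param right_to_left If `TRUE`, the walk starts at the bottom-right cell
#'   instead, mirroring every range's direction.
#' @return A data frame with integer columns `row` and `range`, one line per
#'   cell, in traversal order (`rows * ranges` lines).
#' @examples
#' serpentine_cell_sequence(4, 2)
#' @export
serpentine_cell_sequence <- function(rows, ranges, right_to_left = FALSE) {
  rows <- as_count(rows, "rows")
  ranges <- as_count(ranges, "ranges")
  forward <- seq_len(rows) - 1L
  row <- unlist(lapply(seq_len(ranges) - 1L, function(g) {
    if (g %% 2L == 0L) forward else rev(forward)
  }), use.names = FALSE)
  if (isTRUE(right_to_left)) {
    row <- rows - 1L - row
  }
  data.frame(
    row = row,
    range = rep(seq_len(ranges) - 1L, each = rows)
  )
}

#' Replicate-prefixed plot number
#'
#' Replicated trials are numbered so that the trailing digits give the plot's
#' position within its replicate and the leading digit(s) give the replicate:
#' `rep * 10^d + within_rep_index`, where `d` is the number of digits reserved
#' for the within-replicate part -- two for replicates of fewer than 100
#' plots, three for 100-999, and so on. A 3-replicate trial of 20 plots is
#' numbered 101-120, 201-220, 301-320; with 200 plots per replicate,
#' 1001-1200, 2001-2200, 3001-3200.
#'
#' @param rep Replicate number (1-based).
#' @param within_rep_index Plot position within the replicate (1-based, at
#'   most `plots_per_rep`).
#' @param plots_per_rep Number of plots per replicate; sets the digit width.
#' @return The plot number (integer).
#' @examples
#' replicated_plot_number(3, 20, plots_per_rep = 20)   # 320
#' replicated_plot_number(1, 1, plots_per_rep = 200)   # 1001
#' @export
replicated_plot_number <- function(rep, within_rep_index, plots_per_rep) {
  rep <- as_count(rep, "rep")
  within_rep_index <- as_count(within_rep_index, "within_rep_index")
  plots_per_rep <- as_count(plots_per_rep, "plots_per_rep")
  if (within_rep_index > plots_per_rep) {
    stop(sprintf(
      "'within_rep_index' (%d) exceeds 'plots_per_rep' (%d).",
      within_rep_index, plots_per_rep), call. = FALSE)
  }
  d <- numbering_digits(plots_per_rep)
  as.integer(rep * 10^d + within_rep_index)
}

#' Build the field matrix for a layout specification
#'
#' Walks the serpentine cell sequence and assigns every cell of the footprint
#' a role and, where applicable, a plot number:
#'
#' * **replicated** designs: cells in wheel-track ranges get role
#'   `"wheel_track"` and consume no plot number; the remaining cells are
#'   consumed in serpentine order as replicate 1's experimental plots
#'   (numbered with [replicated_plot_number()]), then replicate 1's fills,
#'   then replicate 2, and so on. Fill plots continue the replicate's number
#'   series past `plots_per_rep`.
#' * **unreplicated** designs: the first `plot_indent` cells are
#'   `"excluded"`, the next `end_plot - start_plot + 1` cells are
#'   experimental with sequential numbers, and any remaining cells in the
#'   final range(s) are `"excluded"`.
#'
#' The spec is validated first; any issue from [validate_spec()] is raised
#' as an error.
#'
#' @param spec A [replicated_spec()] or [unreplicated_spec()].
#' @return A `field_matrix`: a data frame in serpentine traversal order with
#'   columns `row`, `range` (0-based integers), `role` (one of
#'   `"experimental"`, `"fill"`, `"wheel_track"`, `"excluded"`), `plot`
#'   (integer, `NA` for wheel-track/excluded cells) and `rep` (integer, `NA`
#'   for unreplicated designs and non-plot cells), plus attributes `rows`,
#'   `ranges`, `design` and `experiment_name`.
#' @examples
#' m <- build_matrix(replicated_spec(2, 2, rows = 2, ranges = 3,
#'                                   fills_after_reps = c(1, 1),
#'                                   wheel_track_ranges = 2))
#' table(m$role)
#' @export
build_matrix <- function(spec) {
  UseMethod("build_matrix")
}

#' @export
build_matrix.replicated_spec <- function(spec) {
  issues <- validate_spec(spec)
  if (length(issues)) {
    stop(paste(c("Invalid replicated layout:", issues), collapse = "\n  "),
         call. = FALSE)
  }
  cells <- serpentine_cell_sequence(spec$rows, spec$ranges, spec$right_to_left)
  n <- nrow(cells)
  role <- rep("experimental", n)
  plot <- rep(NA_integer_, n)
  repno <- rep(NA_integer_, n)

  # Stream of plot assignments consumed by non-wheel-track cells, in order:
  # rep 1 experimentals, rep 1 fills, rep 2 experimentals, ...
  d <- numbering_digits(spec$plots_per_rep)
  stream_role <- character(0)
  stream_plot <- integer(0)
  stream_rep <- integer(0)
  for (k in seq_len(spec$reps)) {
    nf <- spec$fills_after_reps[k]
    stream_role <- c(stream_role, rep("experimental", spec$plots_per_rep),
                     rep("fill", nf))
    stream_plot <- c(stream_plot,
                     as.integer(k * 10^d + seq_len(spec$plots_per_rep)),
                     as.integer(k * 10^d + spec$plots_per_rep + seq_len(nf)))
    stream_rep <- c(stream_rep, rep(as.integer(k), spec$plots_per_rep + nf))
  }

  in_wheel_track <- (cells$range + 1L) %in% spec$wheel_track_ranges
  role[in_wheel_track] <- "wheel_track"
  consumed <- which(!in_wheel_track)
  stopifnot(length(consumed) == length(stream_role))  # guaranteed by validation
  role[consumed] <- stream_role
  plot[consumed] <- stream_plot
  repno[consumed] <- stream_rep

  new_field_matrix(cells, role, plot, repno, spec, design = "replicated")
}

#' @export
build_matrix.unreplicated_spec <- function(spec) {
  issues <- validate_spec(spec)
  if (length(issues)) {
    stop(paste(c("Invalid unreplicated layout:", issues), collapse = "\n  "),
         call. = FALSE)
  }
  cells <- serpentine_cell_sequence(spec$rows, spec$ranges, spec$right_to_left)
  n <- nrow(cells)
  n_plots <- spec$end_plot - spec$start_plot + 1L
  role <- rep("excluded", n)
  plot <- rep(NA_integer_, n)
  idx <- spec$plot_indent + seq_len(n_plots)
  role[idx] <- "experimental"
  plot[idx] <- seq.int(spec$start_plot, spec$end_plot)
  new_field_matrix(cells, role, plot, rep(NA_integer_, n), spec,
                   design = "unreplicated")
}

new_field_matrix <- function(cells, role, plot, repno, spec, design) {
  m <- data.frame(
    row = cells$row,
    range = cells$range,
    role = role,
    plot = plot,
    rep = repno
  )
  structure(m,
            rows = spec$rows,
            ranges = spec$ranges,
            design = design,
            experiment_name = spec$experiment_name,
            class = c("field_matrix", "data.frame"))
}

#' @export
print.field_matrix <- function(x, ...) {
  cat(sprintf("Field matrix (%s design): %d rows x %d ranges\n",
              attr(x, "design"), attr(x, "rows"), attr(x, "ranges")))
  counts <- table(factor(x$role, levels = c("experimental", "fill",
                                            "wheel_track", "excluded")))
  cat(sprintf("  experimental %d | fill %d | wheel-track %d | excluded %d\n",
              counts[["experimental"]], counts[["fill"]],
              counts[["wheel_track"]], counts[["excluded"]]))
  cat(render_preview(x), sep = "\n")
  invisible(x)
}
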