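#' Plot dimensions and region-of-interest buffers
#'
#' `plot_length` and `plot_width` are the *total* footprint of one plot --
#' the full fishnet cell, including all crop rows and alleyways. The region
#' of interest written to the output layer is trimmed symmetrically by the
#' buffers, so each final dimension is the total dimension reduced by twice
#' its buffer; this keeps the rectangle centred on the plot and excludes
#' alleyways and vegetation from neighbouring plots.
#'
#' @param plot_length Along-range depth of a cell (the direction ranges
#'   stack in), in `units`.
#' @param plot_width Across-range span of a cell, in `units`.
#' @param length_buffer,width_buffer Per-side trim on each axis
#'   (non-negative); the final dimension `plot_* - 2 * *_buffer` must stay
#'   positive.
#' @param units `"english"` (feet) or `"metric"` (metres).
#' @return An object of class `plot_dimensions`.
#' @examples
#' dims <- plot_dimensions(20, 10, length_buffer = 5, width_buffer = 2.5,
#'                         units = "english")
#' final_dimensions(dims)  # 10 x 5 ft
#' @export
plot_dimensions <- function(plot_length, plot_width,
                            length_buffer = 0, width_buffer = 0,
                            units = c("english", "metric")) {
  units <- match.arg(units)
  check_positive_real <- function(x, what, strict = TRUE) {
    if (length(x) != 1L || !is.numeric(x) || is.na(x) ||
        (if (strict) x <= 0 else x < 0)) {
      stop(sprintf("'%s' must be a single %s number.", what,
                   if (strict) "positive" else "non-negative"), call. = FALSE)
    }
    as.numeric(x)
  }
  dims <- structure(
    list(
      plot_length = check_positive_real(plot_length, "plot_length"),
      plot_width = check_positive_real(plot_width, "plot_width"),
      length_buffer = check_positive_real(length_buffer, "length_buffer", strict = FALSE),
      width_buffer = check_positive_real(width_buffer, "width_buffer", strict = FALSE),
      units = units
    ),
    class = "plot_dimensions"
  )
  final_dimensions(dims)  # errors early if a buffer consumes its axis
  dims
}

#' Final (buffered) plot dimensions
#'
#' Each total dimension is reduced by twice its respective buffer.
#'
#' @param dims A [plot_dimensions()] object.
#' @return Named numeric vector `c(length = ..., width = ...)` in the
#'   dimensions' own units.
#' @export
final_dimensions <- function(dims) {
  stopifnot(inherits(dims, "plot_dimensions"))
  len <- dims$plot_length - 2 * dims$length_buffer
  wid <- dims$plot_width - 2 * dims$width_buffer
  if (len <= 0) {
    stop(sprintf(
      "Length buffer %g leaves a non-positive final plot length (%g - 2*%g).",
      dims$length_buffer, dims$plot_length, dims$length_buffer), call. = FALSE)
  }
  if (wid <= 0) {
    stop(sprintf(
      "Width buffer %g leaves a non-positive final plot width (%g - 2*%g).",
      dims$width_buffer, dims$plot_width, dims$width_buffer), call. = FALSE)
  }
  c(length = len, width = wid)
}

#' @export
print.plot_dimensions <- function(x, ...) {
  u <- if (x$units == "english") "ft" else "m"
  fin <- final_dimensions(x)
  cat(sprintf("Plot dimensions: %g x %g %s (length x width), buffers %g / %g %s\n",
              x$plot_length, x$plot_width, u, x$length_buffer, x$width_buffer, u))
  cat(sprintf("  final plot size: %g x %g %s\n", fin["length"], fin["width"], u))
  invisible(x)
}

#' Placement of the layout in a coordinate reference system
#'
#' Positions the field matrix: `origin` is the coordinate of the outside
#' corner of the first cell of the front range (the bottom-left cell for
#' left-to-right layouts), rows extend along +x and ranges stack along +y,
#' and `rotation` then rotates the whole layer counter-clockwise about the
#' origin. Alignment against aerial imagery is expected to be done
#' downstream in a GIS; choose `origin`/`rotation` to pre-position the layer
#' when the field coordinates are known.
#'
#' @param origin Numeric length-2 vector `c(x, y)` in CRS units.
#' @param rotation Counter-clockwise rotation in degrees about `origin`.
#' @param crs CRS identifier passed to [resolve_crs()]; defaults to a local
#'   metre-unit engineering CRS.
#' @return An object of class `placement`.
#' @export
placement <- function(origin = c(0, 0), rotation = 0, crs = local_crs("metre")) {
  if (length(origin) != 2L || !is.numeric(origin) || anyNA(origin)) {
    stop("'origin' must be a numeric c(x, y) pair.", call. = FALSE)
  }
  if (length(rotation) != 1L || !is.numeric(rotation) || !is.finite(rotation)) {
    stop("'rotation' must be a single finite number of degrees.", call. = FALSE)
  }
  wkt <- resolve_crs(crs)
  crs_linear_unit(wkt)  # errors on geographic / unsupported-unit CRSs
  structure(
    list(origin = as.numeric(origin), rotation = as.numeric(rotation), crs = wkt),
    class = "placement"
  )
}

#' Convert a plot dimension into CRS linear units
#'
#' Applies the exact international-foot factor (0.3048 m/ft) when the
#' dimension unit system and the CRS linear unit differ; identity otherwise.
#'
#' @param value Numeric value(s) in the unit system's units.
#' @param units `"english"` (feet) or `"metric"` (metres).
#' @param crs_unit `"metre"` or `"foot"` (see [crs_linear_unit()]).
#' @return Numeric value(s) in CRS units.
#' @examples
#' convert_units(20, "english", "metre")  # 6.096
#' @export
convert_units <- function(value, units = c("english", "metric"),
                          crs_unit = c("metre", "foot")) {
  units <- match.arg(units)
  crs_unit <- match.arg(crs_unit)
  if (units == "english" && crs_unit == "metre") return(value * 0.3048)
  if (units == "metric" && crs_unit == "foot") return(value / 0.3048)
  value
}

#' Buffered polygon of a single grid cell
#'
#' Builds the region-of-interest rectangle for cell `(row, range)`: the
#' buffered rectangle is centred in its fishnet cell, then the whole layout
#' rotation is applied about the placement origin.
#'
#' @param row,range 0-based cell indices (row 0 left, range 0 front).
#' @param dims A [plot_dimensions()] object.
#' @param place A [placement()] object.
#' @return A 5 x 2 numeric matrix (columns `x`, `y`): a closed
#'   counter-clockwise ring in CRS units.
#' @examples
#' dims <- plot_dimensions(20, 10, 5, 2.5, units = "english")
#' cell_polygon(0, 0, dims, placement(crs = local_crs("foot")))
#' @export
cell_polygon <- function(row, range, dims, place) {
  stopifnot(inherits(dims, "plot_dimensions"), inherits(place, "placement"))
  row <- as_int_scalar(row, "row", min = 0L)
  range <- as_int_scalar(range, "range", min = 0L)
  unit <- crs_linear_unit(place$crs)
  W <- convert_units(dims$plot_width, dims$units, unit)
  L <- convert_units(dims$plot_length, dims$units, unit)
  wb <- convert_units(dims$width_buffer, dims$units, unit)
  lb <- convert_units(dims$length_buffer, dims$units, unit)
  final_dimensions(dims)  # re-assert positivity
  x0 <- place$origin[1] + row * W + wb
  x1 <- place$origin[1] + (row + 1) * W - wb
  y0 <- place$origin[2] + range * L + lb
  y1 <- place$origin[2] + (range + 1) * L - lb
  ring <- cbind(
    x = c(x0, x1, x1, x0, x0),
    y = c(y0, y0, y1, y1, y0)
  )
  rotate_ring(ring, place$rotation, place$origin)
}

rotate_ring <- function(ring, rotation_deg, about) {
  if (rotation_deg == 0) return(ring)
  theta <- rotation_deg * pi / 180
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  centred <- sweep(ring, 2, about)
  out <- centred %*% rot
  out <- sweep(out, 2, about, `+`)
  colnames(out) <- c("x", "y")
  out
}

#' Build the plot feature table from a field matrix
#'
#' Produces one polygon feature per *experimental* cell; fill, wheel-track
#' and excluded cells are dropped, which is how non-experimental plots are
#' removed from the output layer. Features are ordered by plot traversal
#' (serpentine) order and carry the plot number and, for replicated designs,
#' the replicate number.
#'
#' @param matrix A `field_matrix` from [build_matrix()].
#' @param dims A [plot_dimensions()] object.
#' @param place A [placement()] object (default: origin `(0,0)`, no
#'   rotation, local metre CRS).
#' @return A `plot_feature_table`: a data frame with columns `plot`, `rep`
#'   (replicated designs only) and a `geometry` list-column of closed 5 x 2
#'   rings, plus attributes `crs` (WKT) and `experiment_name`.
#' @examples
#' spec <- replicated_spec(2, 1, rows = 2, ranges = 1)
#' tab <- build_feature_table(build_matrix(spec),
#'                            plot_dimensions(20, 10, units = "english"))
#' tab$plot
#' @export
build_feature_table <- function(matrix, dims, place = placement()) {
  stopifnot(inherits(matrix, "field_matrix"),
            inherits(dims, "plot_dimensions"),
            inherits(place, "placement"))
  keep <- matrix$role == "experimental"
  cells <- matrix[keep, , drop = FALSE]
  geometry <- lapply(seq_len(nrow(cells)), function(i) {
    cell_polygon(cells$row[i], cells$range[i], dims, place)
  })
  tab <- data.frame(plot = cells$plot)
  if (identical(attr(matrix, "design"), "replicated")) {
    tab$rep <- cells$rep
  }
  tab$geometry <- I(geometry)
  rownames(tab) <- NULL
  structure(tab,
            crs = place$crs,
            experiment_name = attr(matrix, "experiment_name"),
            class = c("plot_feature_table", "data.frame"))
}

#' @export
print.plot_feature_table <- function(x, ...) {
  cat(sprintf("Plot feature table: %d features (%s)\n", nrow(x),
              paste(setdiff(names(x), "geometry"), collapse = ", ")))
  cat("CRS:", substr(attr(x, "crs"), 1, 60), "...\n")
  invisible(x)
}

#' Polygon ring area (shoelace formula)
#'
#' Absolute area of a closed ring; used to check that every feature's area
#' equals the product of the final plot dimensions regardless of rotation.
#'
#' @param ring An n x 2 matrix whose last vertex repeats the first.
#' @return The enclosed area in squared ring units.
#' @export
ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}
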