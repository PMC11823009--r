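#' Render an ASCII preview of a field matrix
#'
#' Draws the field map as text, one line per range with the front range at
#' the bottom (the orientation a scout standing at the front of the field
#' would see). Experimental cells show their plot number, fill cells `F`,
#' wheel-track cells `W` and excluded cells `.`; columns are aligned.
#'
#' @param matrix A `field_matrix` from [build_matrix()].
#' @return Character vector, one element per range (top range first).
#' @examples
#' m <- build_matrix(unreplicated_spec(1, 4, rows = 2, ranges = 2))
#' cat(render_preview(m), sep = "\n")
#' @export
render_preview <- function(matrix) {
  stopifnot(inherits(matrix, "field_matrix"))
  rows <- attr(matrix, "rows")
  ranges <- attr(matrix, "ranges")
  token <- ifelse(matrix$role == "experimental", as.character(matrix$plot),
           ifelse(matrix$role == "fill", "F",
           ifelse(matrix$role == "wheel_track", "W", ".")))
  width <- max(nchar(token))
  grid <- matrix(NA_character_, nrow = rows, ncol = ranges)
  grid[cbind(matrix$row + 1L, matrix$range + 1L)] <-
    formatC(token, width = width)
  # back range (last column) printed first so the front range lands at the bottom
  vapply(rev(seq_len(ranges)), function(g) {
    paste(grid[, g], collapse = " ")
  }, character(1))
}
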