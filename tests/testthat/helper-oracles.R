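# Independent oracles and generators shared across test files.

# Brute-force serpentine enumeration by sorting cells on an explicit order
# key (a different route than the package's per-range construction).
serpentine_bruteforce <- function(rows, ranges, right_to_left = FALSE) {
  cells <- expand.grid(row = 0:(rows - 1L), range = 0:(ranges - 1L))
  walk_pos <- ifelse(cells$range %% 2L == 0L, cells$row, rows - 1L - cells$row)
  if (right_to_left) walk_pos <- rows - 1L - walk_pos
  key <- cells$range * rows + walk_pos
  out <- cells[order(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random valid replicated spec: choose a footprint and wheel tracks, then
# split the remaining cells into balanced reps plus fills.
random_replicated_spec <- function() {
  repeat {
    rows <- sample(2:8, 1)
    ranges <- sample(2:12, 1)
    n_wt <- sample(0:min(3, ranges - 1L), 1)
    wheel <- if (n_wt > 0) sort(sample(seq_len(ranges), n_wt)) else integer(0)
    remaining <- rows * (ranges - n_wt)
    reps <- sample(1:3, 1)
    total_fills <- sample(0:min(6, remaining - reps), 1)
    if ((remaining - total_fills) %% reps != 0) next
    ppr <- (remaining - total_fills) %/% reps
    if (ppr < 1) next
    fills <- as.integer(stats::rmultinom(1, total_fills, rep(1, reps)))
    d <- max(2L, nchar(as.character(ppr)))
    if (any(ppr + fills > 10^d - 1)) next
    return(replicated_spec(
      plots_per_rep = ppr, reps = reps, rows = rows, ranges = ranges,
      fills_after_reps = fills, wheel_track_ranges = wheel,
      right_to_left = sample(c(TRUE, FALSE), 1)
    ))
  }
}

random_unreplicated_spec <- function() {
  rows <- sample(2:10, 1)
  ranges <- sample(1:10, 1)
  indent <- sample(0:(rows - 1L), 1)
  capacity <- rows * ranges - indent
  n_plots <- sample(seq_len(capacity), 1)
  start <- sample(1:500, 1)
  unreplicated_spec(
    start_plot = start, end_plot = start + n_plots - 1L,
    rows = rows, ranges = ranges, plot_indent = indent,
    right_to_left = sample(c(TRUE, FALSE), 1)
  )
}

# Overlap area of two axis-aligned rectangles given as (xmin,ymin,xmax,ymax).
rect_overlap_area <- function(a, b) {
  max(0, min(a[3], b[3]) - max(a[1], b[1])) *
    max(0, min(a[4], b[4]) - max(a[2], b[2]))
}

ring_bbox <- function(ring) {
  c(min(ring[, 1]), min(ring[, 2]), max(ring[, 1]), max(ring[, 2]))
}

centroid <- function(ring) {
  colMeans(ring[-nrow(ring), , drop = FALSE])
}
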