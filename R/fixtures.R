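#' Built-in case study: a replicated yield trial
#'
#' Regenerates, entirely in code, a typical late-stage yield trial: three
#' replicates of 30 plots each, every replicate trailed by two fill plots,
#' with irrigation wheel tracks occupying ranges 9 and 18, in a 4-row by
#' 26-range footprint. Plots are four 2.5-ft crop rows on 20-ft beds (20 x
#' 10 ft total) trimmed by 5-ft and 2.5-ft buffers to a 10 x 5 ft region of
#' interest. A synthetic field book with line name and pedigree for all 90
#' experimental plots is generated deterministically (no RNG), so repeated
#' calls are identical.
#'
#' @return A list with elements `spec` ([replicated_spec()]), `dims`
#'   ([plot_dimensions()]), `book` ([fieldbook()]) and `expected` (a list of
#'   the counts the design implies: `features`, `fills`, `wheel_track_cells`,
#'   `footprint`, `final_size_ft`).
#' @examples
#' cs1 <- case_study_1()
#' validate_spec(cs1$spec)
#' @export
case_study_1 <- function() {
  spec <- replicated_spec(
    plots_per_rep = 30, reps = 3, rows = 4, ranges = 26,
    fills_after_reps = c(2, 2, 2),
    wheel_track_ranges = c(9, 18),
    experiment_name = "yield_trial"
  )
  dims <- plot_dimensions(plot_length = 20, plot_width = 10,
                          length_buffer = 5, width_buffer = 2.5,
                          units = "english")
  plots <- unlist(lapply(1:3, function(k) k * 100L + 1:30))
  book <- fieldbook(synthetic_book_records(plots))
  list(
    spec = spec, dims = dims, book = book,
    expected = list(
      features = 90L, fills = 6L, wheel_track_cells = 8L,
      footprint = c(rows = 4L, ranges = 26L),
      final_size_ft = c(length = 10, width = 5)
    )
  )
}

#' Built-in case study: unreplicated nurseries
#'
#' Regenerates a pair of early-generation plant-row nurseries laid out as
#' single 2.5-ft rows on 12-ft beds, 52 plots wide:
#'
#' * **set #1** -- 701 plots (numbered 1-701) over 14 ranges, left to right;
#' * **set #2 part 1** -- starts 25 plots into its first range (where set #1
#'   ended mid-range) and runs right-to-left for 1,067 plots (1-1,067) over
#'   34 ranges;
#' * **set #2 part 2** -- continues for 1,716 plots (1,068-2,783), exactly
#'   filling a 52 x 33 footprint, planted across a washed-out gap from
#'   part 1.
#'
#' One synthetic field book covers set #1; a second, shared book covers
#' both parts of set #2, since a single book serves an experiment split
#' across layers. Generation is deterministic.
#'
#' @return A list with elements `set1`, `set2_part1`, `set2_part2` (each a
#'   list of `spec`, `dims`, `book`, `expected`); the two set-#2 entries
#'   share one `book` object.
#' @examples
#' cs2 <- case_study_2()
#' vapply(cs2, function(p) length(validate_spec(p$spec)), integer(1))
#' @export
case_study_2 <- function() {
  dims <- plot_dimensions(plot_length = 12, plot_width = 2.5,
                          units = "english")
  set1_spec <- unreplicated_spec(
    start_plot = 1, end_plot = 701, rows = 52, ranges = 14,
    experiment_name = "plant_rows_set1"
  )
  part1_spec <- unreplicated_spec(
    start_plot = 1, end_plot = 1067, rows = 52, ranges = 34,
    plot_indent = 25, right_to_left = TRUE,
    experiment_name = "plant_rows_set2_part1"
  )
  part2_spec <- unreplicated_spec(
    start_plot = 1068, end_plot = 2783, rows = 52, ranges = 33,
    experiment_name = "plant_rows_set2_part2"
  )
  set1_book <- fieldbook(synthetic_book_records(1:701))
  set2_book <- fieldbook(synthetic_book_records(1:2783))
  list(
    set1 = list(
      spec = set1_spec, dims = dims, book = set1_book,
      expected = list(features = 701L, excluded = 52L * 14L - 701L)
    ),
    set2_part1 = list(
      spec = part1_spec, dims = dims, book = set2_book,
      expected = list(features = 1067L, indent = 25L,
                      excluded = 52L * 34L - 25L - 1067L)
    ),
    set2_part2 = list(
      spec = part2_spec, dims = dims, book = set2_book,
      expected = list(features = 1716L, excluded = 0L)
    )
  )
}

# Deterministic synthetic field book: line names and pedigrees derived
# arithmetically from the plot number, so no RNG state is involved and
# regenerated books are identical byte for byte.
synthetic_book_records <- function(plots) {
  parents <- c("AMBER", "BASIN", "CREST", "DELTA", "ESTER",
               "FJORD", "GALE", "HARVEST", "IRIS", "JUNIPER")
  i <- seq_along(plots)
  data.frame(
    plot = as.integer(plots),
    name = sprintf("LINE_%04d", i),
    pedigree = paste0(parents[(i - 1L) %% 10L + 1L], "/",
                      parents[(i * 3L) %% 10L + 1L]),
    stringsAsFactors = FALSE
  )
}

#' Write a case-study field book to a CSV file
#'
#' Convenience wrapper used by the examples and the command-line interface
#' tests: writes a [fieldbook()]'s records as a standard header-row CSV.
#'
#' @param book A `fieldbook`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_fieldbook_csv <- function(book, path) {
  stopifnot(inherits(book, "fieldbook"))
  utils::write.csv(book$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
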