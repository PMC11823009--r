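test_that("serpentine order matches hand-enumerated small grids", {
  expect_equal(serpentine_cell_sequence(1, 1),
               data.frame(row = 0L, range = 0L))
  s <- serpentine_cell_sequence(4, 2)
  expect_equal(s$row, c(0L, 1L, 2L, 3L, 3L, 2L, 1L, 0L))
  expect_equal(s$range, c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L))
  # right-to-left is the mirror: row r becomes rows-1-r
  s_rtl <- serpentine_cell_sequence(4, 2, right_to_left = TRUE)
  expect_equal(s_rtl$row, 3L - s$row)
  expect_equal(s_rtl$range, s$range)
  expect_error(serpentine_cell_sequence(0, 3), "rows")
})

test_that("serpentine equals brute-force enumeration for all grids up to 8x8", {
  for (rows in 1:8) {
    for (ranges in 1:8) {
      for (rtl in c(FALSE, TRUE)) {
        got <- serpentine_cell_sequence(rows, ranges, rtl)
        want <- serpentine_bruteforce(rows, ranges, rtl)
        expect_equal(got$row, want$row,
                     info = sprintf("rows=%d ranges=%d rtl=%s", rows, ranges, rtl))
        expect_equal(got$range, want$range)
      }
    }
  }
})

test_that("consecutive serpentine cells are grid-adjacent and cover the grid", {
  for (rows in c(1, 3, 5)) {
    for (ranges in c(1, 4, 7)) {
      s <- serpentine_cell_sequence(rows, ranges)
      expect_equal(nrow(s), rows * ranges)
      expect_false(anyDuplicated(s) > 0)
      expect_true(all(diff(s$range) >= 0))
      d <- abs(diff(s$row)) + abs(diff(s$range))
      expect_true(all(d == 1))
    }
  }
})

test_that("replicate-prefixed numbering uses 2+ digits for the within-rep part", {
  expect_identical(replicated_plot_number(3, 20, plots_per_rep = 20), 320L)
  expect_identical(replicated_plot_number(1, 1, plots_per_rep = 200), 1001L)
  expect_identical(replicated_plot_number(1, 1, plots_per_rep = 1), 101L)
  expect_identical(replicated_plot_number(2, 150, plots_per_rep = 200), 2150L)
  # natural extension: 1000-plot reps get four digits
  expect_identical(replicated_plot_number(2, 1000, plots_per_rep = 1000), 21000L)
  expect_error(replicated_plot_number(1, 21, plots_per_rep = 20), "exceeds")
})

test_that("replicated matrix places reps, fills and wheel tracks along the walk", {
  # 2x4 grid, wheel track in range 2, one fill after each of two 2-plot reps;
  # cell-by-cell expectation derived by hand from the serpentine walk.
  m <- build_matrix(replicated_spec(
    plots_per_rep = 2, reps = 2, rows = 2, ranges = 4,
    fills_after_reps = c(1, 1), wheel_track_ranges = 2
  ))
  key <- paste(m$row, m$range)
  expect_equal(m$plot[match(c("0 0", "1 0"), key)], c(101L, 102L))
  expect_equal(m$role[m$range == 1L], rep("wheel_track", 2))
  expect_true(all(is.na(m$plot[m$range == 1L])))
  expect_equal(m$role[match(c("0 2", "1 2", "1 3", "0 3"), key)],
               c("fill", "experimental", "experimental", "fill"))
  expect_equal(m$plot[match(c("1 2", "1 3"), key)], c(201L, 202L))
  expect_equal(m$rep[match(c("0 2", "0 3"), key)], c(1L, 2L))
})

test_that("the replicated yield-trial case study fills its 4x26 footprint", {
  cs1 <- case_study_1()
  m <- build_matrix(cs1$spec)
  counts <- table(m$role)
  expect_equal(unname(counts[["experimental"]]), 90L)
  expect_equal(unname(counts[["fill"]]), 6L)
  expect_equal(unname(counts[["wheel_track"]]), 8L)
  expect_equal(nrow(m), 4L * 26L)
  # wheel-track ranges 9 and 18 (1-based from the front) carry no numbers
  expect_true(all(m$role[m$range %in% c(8L, 17L)] == "wheel_track"))
  # per-replicate numbering is exactly {k*100+1 ... k*100+30}
  for (k in 1:3) {
    expect_setequal(m$plot[m$role == "experimental" & m$rep == k],
                    k * 100L + 1:30)
  }
})

test_that("three-digit numbering engages at 100 plots per replicate", {
  m <- build_matrix(replicated_spec(plots_per_rep = 200, reps = 3,
                                    rows = 4, ranges = 150))
  plots <- m$plot[m$role == "experimental"]
  expect_setequal(plots, c(1000L + 1:200, 2000L + 1:200, 3000L + 1:200))
})

test_that("unreplicated matrices handle indents and trailing exclusions", {
  m <- build_matrix(unreplicated_spec(1, 701, rows = 52, ranges = 14))
  expect_equal(sum(m$role == "experimental"), 701L)
  expect_equal(sum(m$role == "excluded"), 27L)
  expect_setequal(m$plot[m$role == "experimental"], 1:701)

  m2 <- build_matrix(unreplicated_spec(1, 1067, rows = 52, ranges = 34,
                                       plot_indent = 25, right_to_left = TRUE))
  expect_equal(m2$role[1:25], rep("excluded", 25))
  expect_equal(sum(m2$role == "experimental"), 1067L)
  # right-to-left: the first indent cell is at the right edge of the front range
  expect_equal(m2$row[1], 51L)

  m3 <- build_matrix(unreplicated_spec(5, 5, rows = 1, ranges = 1))
  expect_equal(m3$plot, 5L)
  expect_equal(m3$role, "experimental")

  expect_error(build_matrix(unreplicated_spec(1, 10, rows = 3, ranges = 3)),
               "exceed")
})

test_that("validation reports each dialog-style issue with counts", {
  cs1 <- case_study_1()
  expect_length(validate_spec(cs1$spec), 0)

  bad_fills <- replicated_spec(30, 3, rows = 4, ranges = 26,
                               fills_after_reps = c(2, 2))
  issues <- validate_spec(bad_fills)
  expect_true(any(grepl("Reps", issues)))

  mismatch <- replicated_spec(25, 4, rows = 4, ranges = 26,
                              fills_after_reps = c(0, 0, 0, 0))
  issues <- validate_spec(mismatch)
  expect_length(issues, 1)
  expect_match(issues, "100")
  expect_match(issues, "104")

  wt_bad <- replicated_spec(2, 1, rows = 2, ranges = 2,
                            fills_after_reps = 0, wheel_track_ranges = 5)
  expect_true(any(grepl("Wheel track", validate_spec(wt_bad))))

  indent_bad <- unreplicated_spec(1, 4, rows = 3, ranges = 3, plot_indent = 3)
  expect_true(any(grepl("Plot indent", validate_spec(indent_bad))))

  # equality with the footprint is allowed: a nursery may exactly fill it
  exact <- unreplicated_spec(1, 52 * 33, rows = 52, ranges = 33)
  expect_length(validate_spec(exact), 0)
})

test_that("counts are conserved and numbers contiguous for random valid specs", {
  set.seed(4822)
  for (i in 1:100) {
    spec <- random_replicated_spec()
    m <- build_matrix(spec)
    expect_equal(nrow(m), spec$rows * spec$ranges)
    expect_equal(sum(m$role == "experimental"), spec$reps * spec$plots_per_rep)
    expect_equal(sum(m$role == "fill"), sum(spec$fills_after_reps))
    expect_equal(sum(m$role == "wheel_track"),
                 spec$rows * length(spec$wheel_track_ranges))
    plots <- m$plot[!is.na(m$plot)]
    expect_false(anyDuplicated(plots) > 0)
    d <- max(2L, nchar(as.character(spec$plots_per_rep)))
    for (k in seq_len(spec$reps)) {
      expect_setequal(m$plot[m$role == "experimental" & m$rep == k],
                      as.integer(k * 10^d + seq_len(spec$plots_per_rep)))
    }
  }
  for (i in 1:100) {
    spec <- random_unreplicated_spec()
    m <- build_matrix(spec)
    expect_equal(sum(m$role == "experimental") + sum(m$role == "excluded"),
                 spec$rows * spec$ranges)
    expect_setequal(m$plot[m$role == "experimental"],
                    seq.int(spec$start_plot, spec$end_plot))
  }
})

test_that("mirroring a layout reflects every numbered cell across the rows", {
  set.seed(91)
  for (i in 1:10) {
    spec <- random_replicated_spec()
    spec_ltr <- spec; spec_ltr$right_to_left <- FALSE
    spec_rtl <- spec; spec_rtl$right_to_left <- TRUE
    a <- build_matrix(spec_ltr)
    b <- build_matrix(spec_rtl)
    key_a <- paste(a$row, a$range)
    key_b <- paste(spec$rows - 1L - b$row, b$range)
    expect_equal(b$plot[order(key_b)], a$plot[order(key_a)])
    expect_equal(b$role[order(key_b)], a$role[order(key_a)])
  }
})

test_that("removing wheel-track ranges leaves the numbering walk unchanged", {
  set.seed(77)
  for (i in 1:10) {
    spec <- random_replicated_spec()
    if (length(spec$wheel_track_ranges) == 0) next
    reduced <- spec
    reduced$wheel_track_ranges <- integer(0)
    reduced$ranges <- spec$ranges - length(spec$wheel_track_ranges)
    a <- build_matrix(spec)
    b <- build_matrix(reduced)
    # the consumed stream (plots + fills in walk order) is identical
    expect_equal(a$plot[a$role != "wheel_track"], b$plot)
    expect_equal(a$role[a$role != "wheel_track"], b$role)
  }
})
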