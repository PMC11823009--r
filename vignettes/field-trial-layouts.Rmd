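---
title: "Serpentine field-trial layouts as polygon layers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serpentine field-trial layouts as polygon layers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fieldplotr)
```

## The problem

UAV high-throughput phenotyping and plot-level remote sensing both need a
polygon layer that demarcates every experimental plot so per-plot statistics
can be extracted from imagery. Building that layer by hand -- fishnet grid,
manual serpentine renumbering, spreadsheet joins, deleting non-experimental
cells -- is slow and error-prone, especially for breeding programs with many
trials. `fieldplotr` generates the layer directly from the way agronomists
already describe a trial: a rows-by-ranges footprint walked in serpentine
order, with fill plots, irrigation wheel-track ranges, and per-plot canopy
buffers.

## The layout model

A trial footprint is a grid of `rows * ranges` fishnet cells: `rows` counts
plots across each *range* (a band of plots running across the field) and
`ranges` counts bands from the *front* of the experiment backwards. Plots
are numbered along a serpentine (boustrophedon) walk that starts at the
bottom-left cell, crosses the front range, and reverses direction on each
successive range; `right_to_left = TRUE` mirrors every range, for trials
planted from the other side.

Every cell receives exactly one role:

* **experimental** -- carries a plot number and becomes one output polygon;
* **fill** -- a non-experimental plot planted (with a generic variety) to
  complete the rectangle; dropped from the output;
* **wheel_track** -- a whole range under the wheels of a lateral irrigation
  system; planted with fills, skipped by the numbering, dropped from the
  output;
* **excluded** -- indent cells before an unreplicated trial's first plot, or
  unused cells after its last plot.

**Replicated designs** number plots so the trailing digits give the
within-replicate position and the leading digits the replicate:
`rep * 10^d + i`, with `d = max(2, digits(plots_per_rep))`. Three replicates
of 20 are numbered 101--120, 201--220, 301--320; of 200, 1001--1200,
2001--2200, 3001--3200. We extend the same rule upwards (1000-plot
replicates get `d = 4`), which keeps numbers collision-free for any size.
Fills after replicate `k` continue that replicate's series
(`k*10^d + plots_per_rep + j`); the numbers never reach the output layer --
fills are removed -- but keeping them unique lets the preview and matrix
invariants stay simple. A design where `plots_per_rep + fills` would
overflow into the next replicate's series is rejected at validation.

Replicates are assumed balanced. An unbalanced trial is better laid out with
the unreplicated workflow per replicate, or as a balanced layout trimmed
afterwards in a GIS.

**Unreplicated designs** (nurseries, generation advances) number cells
sequentially from `start_plot` to `end_plot`. `plot_indent` skips cells at
the start of the first range -- the case where the preceding experiment
ended mid-range -- and must be smaller than `rows`. Cells after the last
plot are excluded. We allow the design to fill its footprint *exactly*
(`indent + plots == rows * ranges`); requiring strict inequality would
reject perfectly valid nurseries that end flush with their last range, and
one of the built-in case studies does exactly that.

**Validation** (`validate_spec()`) returns human-readable issues rather than
raising, mirroring the warnings panel of a layout dialog: the fills list
must have one entry per replicate, wheel-track ranges must lie within
`1..ranges` and be unique, and the specified plot count
(`reps*plots_per_rep + fills + rows*wheel_tracks`, or `indent + plots`) must
match (replicated) or fit within (unreplicated) the `rows * ranges`
footprint. Both counts are named in the message so the user can see the
imbalance at a glance.

### A decision the sources leave open

Whether the serpentine direction parity counts wheel-track ranges is not
observable from plot numbers alone (wheel-track cells carry none). We use
the *physical* range index -- range `g` (0-based) is reversed iff `g` is
odd, wheel tracks included -- because wheel-track ranges are physically
planted and walked through; a scout's direction alternates per physical
pass, not per numbered range.

## Geometry

`plot_length` and `plot_width` are the **total** cell dimensions, including
alleyways and all crop rows; rows extend along +x (one `plot_width` per
step) and ranges stack along +y (one `plot_length` per step), with the
front range at `y = 0`. The exported rectangle is the region of interest
for canopy extraction: each total dimension is reduced by **twice** its
buffer (equal trim on both sides), so the rectangle stays centred in its
cell. `final = total - 2 * buffer` must remain positive on both axes.

Dimensions may be given in feet (`units = "english"`) or metres
(`"metric"`); they are converted to the CRS linear unit with the exact
international-foot factor 0.3048 m/ft. Geographic (degree-unit) CRSs are
rejected -- plots are metre-scale rectangles, and degrees are not a length.
The package resolves WGS84/UTM EPSG codes and EPSG:3857 from built-in WKT
templates, passes WKT through verbatim, and provides `local_crs()` (a WKT
`LOCAL_CS` in metres or feet) for layouts that will be dragged onto imagery
later. Placement is explicit -- origin at the outside corner of the first
cell, counter-clockwise rotation about that origin -- because aligning the
layer to aerial imagery is deliberately left to the user's GIS; there is no
canvas to centre on.

Numerical choices: rings are closed 5-vertex rectangles, counter-clockwise
in memory, and rotation is applied as an exact 2-D rotation matrix, so a
feature's shoelace area equals the product of the final dimensions to
floating-point accuracy (the tests assert 1e-9 relative) at any rotation.

## Field-book join

A field book is the breeder's per-plot CSV: a header row, one column of
plot numbers (unique, integer-parseable), and any other columns. The join
is by *numeric* plot value, so a spreadsheet's zero-padded `"0101"` matches
plot 101. Coverage is one-sided by design: every layout plot must appear in
the book (a miss is an error naming the plots), while extra book rows are
ignored with a warning -- that asymmetry is what lets a single book serve an
experiment split across several layers. The join never touches geometry,
feature order or feature count.

## Export

The default output is an ESRI Shapefile (`.shp`/`.shx`/`.dbf`/`.prj`, the
`.prj` holding the CRS WKT), written by the package's own writer for the
single-ring polygon subset it needs; attribute tables go through
`foreign::write.dbf`. DBF limits field names to 10 ASCII characters, so
names pass through `sanitize_field_names()` (truncation, with deterministic
`8-char + 2-digit` suffixes on collision). `plot` and `rep` are written as
integers; field-book columns as text unless every value parses as a number.
Outer rings are stored clockwise as the format requires and normalised back
on read.

GeoJSON output is available for dependency-light pipelines. Because
RFC 7946 reserves coordinates for WGS84 degrees and plot layers live in
projected CRSs, the file carries a non-standard `"crs"` member naming the
CRS -- consumers that assume WGS84 should use the shapefile instead. The
writer is deterministic (fixed key order, coordinates printed with exactly
six decimals), so identical tables give byte-identical files; round-trip
tests rely on this.

## Built-in case studies

Two complete worked examples regenerate themselves in code, synthetic field
books included (line names and pedigrees are derived arithmetically from
the plot number -- no RNG, so regeneration is byte-identical):

* `case_study_1()` -- a replicated yield trial: 3 replicates x 30 plots,
  two fills after each replicate, wheel tracks in ranges 9 and 18, a
  4 x 26 footprint; 20 x 10 ft plots trimmed by 5 / 2.5 ft buffers to a
  10 x 5 ft region of interest; 90 output features.
* `case_study_2()` -- two plant-row nurseries on 12-ft beds of single
  2.5-ft rows, 52 plots wide: set #1 with 701 plots over 14 ranges; set #2
  part 1 starting 25 plots into its first range, right-to-left, 1,067
  plots over 34 ranges; set #2 part 2 with 1,716 plots exactly filling
  52 x 33. Set #2 is numbered continuously across the split (1--1,067,
  then 1,068--2,783) and one shared book joins onto both parts. Part 1's
  stated 34 ranges exceed what 25 + 1,067 plots occupy; we treat `ranges`
  as capacity and leave the trailing cells excluded rather than guess.

The synthetic books emulate the *structure* of real field books (header,
plot column, text attributes), not their content: no missing values,
mixed encodings, or messy headers. Passing tests therefore demonstrate the
layout/join/export contracts, not robustness to arbitrary real-world CSVs.

## Scope and limitations

* Unbalanced replicates are rejected, not approximated.
* Serpentine across *rows* (walking parallel to rows rather than ranges) is
  not a native mode: generate the layout with rows/ranges and length/width
  swapped, then rotate the exported layer 90 degrees.
* Randomization and experimental design are out of scope -- this package
  lays out a design it is given.
* Georeferencing against imagery and per-plot nudging belong to the user's
  GIS after export.

## Verification

The test suite checks the serpentine order against an independent
brute-force enumeration on every grid up to 8 x 8, the mirror identity, and
count conservation with per-replicate number contiguity on 200 randomly
generated valid specifications (fixed seed); polygon areas under random
rotations; shapefile and GeoJSON round trips; and join permutation
invariance. The case-study problem sizes above (90, 701, 1,067 and 1,716
features) run end to end, including file round trips, in a few seconds.
`scripts/acceptance.R` recomputes the numbering endpoints of the 3 x 20 and
3 x 200 replicated examples from freshly built layouts.
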