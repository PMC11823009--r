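Package: fieldplotr
Title: Serpentine Field-Trial Plot Layouts as Georeferenced Polygon Layers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generates georeferenced polygon layers of plot regions of
    interest for replicated and unreplicated field trials laid out in a
    serpentine (boustrophedon) pattern, as used in plant breeding and
    UAV high-throughput phenotyping. Builds the rows-by-ranges cell matrix
    with replicate-prefixed plot numbering, removes fill plots and
    irrigation wheel-track ranges, shrinks plot rectangles by per-axis
    buffers, joins field-book CSV attributes by plot number, and exports
    ESRI Shapefile or deterministic GeoJSON. Includes a command-line
    interface with an ASCII field-map preview.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    foreign,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
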