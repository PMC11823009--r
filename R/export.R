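#' Make attribute names DBF-safe
#'
#' The shapefile attribute table (DBF) limits field names to 10 ASCII
#' characters. Names are cleaned to alphanumerics/underscore and truncated;
#' collisions are resolved deterministically by truncating to 8 characters
#' and appending a 2-digit suffix in input order.
#'
#' @param names Character vector of attribute names (non-empty).
#' @return Named character vector mapping each original name to its
#'   DBF-safe name; the mapping depends only on the input order.
#' @examples
#' sanitize_field_names(c("pedigree_information", "pedigree_infos"))
#' @export
sanitize_field_names <- function(names) {
  if (length(names) == 0L || !is.character(names)) {
    stop("'names' must be a non-empty character vector.", call. = FALSE)
  }
  out <- character(length(names))
  taken <- character(0)
  for (i in seq_along(names)) {
    clean <- gsub("[^A-Za-z0-9_]", "_", names[i])
    if (!nzchar(clean)) clean <- "field"
    clean <- substr(clean, 1, 10)
    if (clean %in% taken) {
      base <- substr(clean, 1, 8)
      for (k in 1:99) {
        candidate <- sprintf("%s%02d", base, k)
        if (!candidate %in% taken) {
          clean <- candidate
          break
        }
      }
    }
    taken <- c(taken, clean)
    out[i] <- clean
  }
  stats::setNames(out, names)
}

#' Write a plot feature table to disk
#'
#' Writes the polygon layer as an ESRI Shapefile (the default; emits
#' `.shp`, `.shx`, `.dbf` and a `.prj` holding the CRS WKT) or as GeoJSON
#' (one file; RFC 7946 layout with a non-standard `"crs"` member naming the
#' projected CRS, since coordinates are in CRS units rather than WGS84
#' degrees -- see the package vignette). GeoJSON output is deterministic:
#' fixed key order and 6-decimal coordinates, so identical tables produce
#' byte-identical files.
#'
#' `plot` and `rep` are written as integer fields; field-book columns are
#' written as text unless every value parses as a number. Attribute names
#' are passed through [sanitize_field_names()] for shapefile output.
#'
#' @param table A `plot_feature_table`.
#' @param path Output path; the extension may be omitted (shapefile mode
#'   always writes the four sidecar extensions). `NULL` or `""` writes to a
#'   temporary-directory default name derived from the experiment name.
#' @param format `"shapefile"` or `"geojson"`.
#' @return Invisibly, the character vector of files written.
#' @seealso [read_layer()] for reading either format back.
#' @export
write_layer <- function(table, path = NULL, format = c("shapefile", "geojson")) {
  stopifnot(inherits(table, "plot_feature_table"))
  format <- match.arg(format)
  if (is.null(path) || !nzchar(path)) {
    nm <- attr(table, "experiment_name")
    if (is.null(nm) || !nzchar(nm)) nm <- "plots"
    nm <- gsub("[^A-Za-z0-9_-]", "_", nm)
    path <- file.path(tempdir(), nm)
  }
  base <- sub("\\.(shp|geojson|json)$", "", path, ignore.case = TRUE)
  dir <- dirname(base)
  if (!dir.exists(dir)) {
    stop(sprintf("Output directory does not exist: '%s'.", dir), call. = FALSE)
  }
  attrs <- type_attributes(table)
  if (format == "shapefile") {
    files <- write_shapefile(table$geometry, attrs, attr(table, "crs"), base)
  } else {
    files <- write_geojson(table$geometry, attrs, attr(table, "crs"),
                           paste0(base, ".geojson"))
  }
  invisible(files)
}

#' Read a plot layer back from disk
#'
#' Reads a layer written by [write_layer()] (either format) back into a
#' `plot_feature_table`. Intended for round-trip verification and for
#' re-opening generated layers; it reads the subset of each format that
#' `write_layer()` emits (single-ring polygon features).
#'
#' @param path Path to a `.shp` or `.geojson` file (shapefile extension
#'   optional).
#' @param format `"shapefile"` or `"geojson"`; inferred from the extension
#'   when missing.
#' @return A `plot_feature_table` with attributes and geometry.
#' @export
read_layer <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE))
      "geojson" else "shapefile"
  }
  format <- match.arg(format, c("shapefile", "geojson"))
  if (format == "shapefile") read_shapefile(path) else read_geojson(path)
}

# Apply the attribute typing policy and drop geometry: plot/rep integer,
# other columns text unless every value parses as a number.
type_attributes <- function(table) {
  attrs <- as.data.frame(table)[, setdiff(names(table), "geometry"), drop = FALSE]
  for (col in names(attrs)) {
    if (col %in% c("plot", "rep")) {
      attrs[[col]] <- as.integer(attrs[[col]])
    } else if (!is.numeric(attrs[[col]])) {
      v <- as.character(attrs[[col]])
      num <- suppressWarnings(as.numeric(v))
      if (!anyNA(num[!is.na(v) & nzchar(v)]) && any(nzchar(v[!is.na(v)]))) {
        attrs[[col]] <- num
      } else {
        attrs[[col]] <- v
      }
    }
  }
  attrs
}

# -- ESRI Shapefile ----------------------------------------------------------
# Binary .shp/.shx writer for single-ring polygon (type 5) records. The
# attribute table goes through foreign::write.dbf; the CRS WKT goes in .prj.
# Outer rings are stored clockwise as the format requires; the in-memory
# convention is counter-clockwise, so rings are reversed on write and again
# on read (reversal of a closed ring keeps its start vertex).

write_shapefile <- function(geometry, attrs, crs_wkt, base) {
  n <- length(geometry)
  rings_cw <- lapply(geometry, function(g) g[rev(seq_len(nrow(g))), , drop = FALSE])
  bboxes <- lapply(rings_cw, function(g) {
    c(min(g[, 1]), min(g[, 2]), max(g[, 1]), max(g[, 2]))
  })
  global_bbox <- if (n > 0) {
    bb <- do.call(rbind, bboxes)
    c(min(bb[, 1]), min(bb[, 2]), max(bb[, 3]), max(bb[, 4]))
  } else {
    c(0, 0, 0, 0)
  }

  content_words <- vapply(rings_cw, function(g) {
    (4L + 32L + 4L + 4L + 4L + 16L * nrow(g)) %/% 2L
  }, integer(1))
  shp_words <- 50L + sum(8L %/% 2L + content_words)
  shx_words <- 50L + 4L * n

  shp_path <- paste0(base, ".shp")
  shx_path <- paste0(base, ".shx")
  con <- file(shp_path, "wb")
  conx <- file(shx_path, "wb")
  on.exit({ close(con); close(conx) }, add = TRUE)

  write_shp_header(con, shp_words, global_bbox)
  write_shp_header(conx, shx_words, global_bbox)

  offset <- 50L
  for (i in seq_len(n)) {
    ring <- rings_cw[[i]]
    # .shx index entry
    writeBin(as.integer(offset), conx, size = 4, endian = "big")
    writeBin(as.integer(content_words[i]), conx, size = 4, endian = "big")
    # .shp record header + content
    writeBin(as.integer(i), con, size = 4, endian = "big")
    writeBin(as.integer(content_words[i]), con, size = 4, endian = "big")
    writeBin(5L, con, size = 4, endian = "little")
    writeBin(as.numeric(bboxes[[i]]), con, size = 8, endian = "little")
    writeBin(1L, con, size = 4, endian = "little")           # NumParts
    writeBin(nrow(ring), con, size = 4, endian = "little")   # NumPoints
    writeBin(0L, con, size = 4, endian = "little")           # part start
    writeBin(as.numeric(t(ring)), con, size = 8, endian = "little")
    offset <- offset + 4L + content_words[i]
  }
  close(con); close(conx)
  on.exit(NULL)

  dbf_path <- paste0(base, ".dbf")
  dbf <- attrs
  names(dbf) <- unname(sanitize_field_names(names(attrs)))
  suppressWarnings(foreign::write.dbf(dbf, dbf_path))

  prj_path <- paste0(base, ".prj")
  writeLines(crs_wkt, prj_path, useBytes = TRUE)

  c(shp_path, shx_path, dbf_path, prj_path)
}

write_shp_header <- function(con, file_length_words, bbox) {
  writeBin(9994L, con, size = 4, endian = "big")
  writeBin(integer(5), con, size = 4, endian = "big")
  writeBin(as.integer(file_length_words), con, size = 4, endian = "big")
  writeBin(1000L, con, size = 4, endian = "little")
  writeBin(5L, con, size = 4, endian = "little")
  writeBin(as.numeric(c(bbox, 0, 0, 0, 0)), con, size = 8, endian = "little")
}

read_shapefile <- function(path) {
  base <- sub("\\.shp$", "", path, ignore.case = TRUE)
  shp_path <- paste0(base, ".shp")
  if (!file.exists(shp_path)) {
    stop(sprintf("No shapefile at '%s'.", shp_path), call. = FALSE)
  }
  con <- file(shp_path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (magic != 9994L) {
    stop(sprintf("'%s' is not a shapefile (bad file code %d).", shp_path, magic),
         call. = FALSE)
  }
  readBin(con, "integer", 5, size = 4, endian = "big")
  file_words <- readBin(con, "integer", 1, size = 4, endian = "big")
  readBin(con, "integer", 2, size = 4, endian = "little")  # version, shape type
  readBin(con, "numeric", 8, size = 8, endian = "little")  # bbox
  geometry <- list()
  words_read <- 50L
  while (words_read < file_words) {
    readBin(con, "integer", 1, size = 4, endian = "big")   # record number
    clen <- readBin(con, "integer", 1, size = 4, endian = "big")
    stype <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (stype != 5L) {
      stop(sprintf("Unsupported shape type %d (only polygons are read).", stype),
           call. = FALSE)
    }
    readBin(con, "numeric", 4, size = 8, endian = "little")  # bbox
    nparts <- readBin(con, "integer", 1, size = 4, endian = "little")
    npoints <- readBin(con, "integer", 1, size = 4, endian = "little")
    readBin(con, "integer", nparts, size = 4, endian = "little")
    pts <- readBin(con, "numeric", 2L * npoints, size = 8, endian = "little")
    ring_cw <- matrix(pts, ncol = 2, byrow = TRUE, dimnames = list(NULL, c("x", "y")))
    geometry[[length(geometry) + 1L]] <-
      ring_cw[rev(seq_len(nrow(ring_cw))), , drop = FALSE]
    words_read <- words_read + 4L + clen
  }
  attrs <- suppressWarnings(foreign::read.dbf(paste0(base, ".dbf"), as.is = TRUE))
  prj_path <- paste0(base, ".prj")
  crs <- if (file.exists(prj_path)) readLines(prj_path, warn = FALSE)[1] else NA_character_
  as_feature_table(attrs, geometry, crs)
}

# -- GeoJSON -----------------------------------------------------------------
# Hand-formatted for determinism: fixed key order, coordinates printed with
# exactly six decimals, attribute values printed with a fixed numeric format.

write_geojson <- function(geometry, attrs, crs_wkt, path) {
  features <- vapply(seq_along(geometry), function(i) {
    props <- vapply(names(attrs), function(col) {
      paste0(json_string(col), ":", json_value(attrs[[col]][i]))
    }, character(1))
    coords <- apply(geometry[[i]], 1, function(p) {
      sprintf("[%.6f,%.6f]", p[1], p[2])
    })
    paste0('{"type":"Feature","properties":{', paste(props, collapse = ","),
           '},"geometry":{"type":"Polygon","coordinates":[[',
           paste(coords, collapse = ","), ']]}}')
  }, character(1))
  txt <- paste0(
    '{"type":"FeatureCollection",',
    '"crs":{"type":"name","properties":{"name":', json_string(crs_wkt), '}},',
    '"features":[', paste(features, collapse = ","), ']}')
  writeLines(txt, path, useBytes = TRUE)
  path
}

read_geojson <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- doc$features
  geometry <- lapply(feats, function(f) {
    ring <- f$geometry$coordinates[[1]]
    m <- matrix(unlist(ring), ncol = 2, byrow = TRUE,
                dimnames = list(NULL, c("x", "y")))
    m
  })
  prop_names <- if (length(feats)) names(feats[[1]]$properties) else character(0)
  attrs <- as.data.frame(
    stats::setNames(lapply(prop_names, function(col) {
      vals <- lapply(feats, function(f) {
        v <- f$properties[[col]]
        if (is.null(v)) NA else v
      })
      unlist(vals, use.names = FALSE)
    }), prop_names),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  crs <- if (!is.null(doc$crs)) doc$crs$properties$name else NA_character_
  as_feature_table(attrs, geometry, crs)
}

as_feature_table <- function(attrs, geometry, crs) {
  if (is.null(attrs) || nrow(attrs) == 0L) {
    attrs <- data.frame(plot = integer(0))
  }
  if ("plot" %in% names(attrs)) attrs$plot <- as.integer(attrs$plot)
  if ("rep" %in% names(attrs)) attrs$rep <- as.integer(attrs$rep)
  attrs$geometry <- I(geometry)
  rownames(attrs) <- NULL
  structure(attrs, crs = crs,
            class = c("plot_feature_table", "data.frame"))
}

json_string <- function(x) {
  x <- gsub("\\\\", "\\\\\\\\", x)
  x <- gsub('"', '\\\\"', x)
  x <- gsub("\n", "\\\\n", x)
  x <- gsub("\r", "\\\\r", x)
  x <- gsub("\t", "\\\\t", x)
  paste0('"', x, '"')
}

json_value <- function(v) {
  if (length(v) != 1L || is.na(v)) return("null")
  if (is.integer(v)) return(sprintf("%d", v))
  if (is.numeric(v)) return(sprintf("%.10g", v))
  json_string(as.character(v))
}
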