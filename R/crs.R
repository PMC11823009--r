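#' Coordinate reference systems for plot layers
#'
#' `resolve_crs()` turns a user-supplied CRS identifier into a WKT1 string
#' for the layer's `.prj` file. Accepted forms:
#'
#' * a WKT1 string (anything containing a `[`), used verbatim;
#' * `"EPSG:326xx"` / `"EPSG:327xx"` (WGS 84 / UTM zone xx, north/south) or
#'   `"EPSG:3857"` (Web Mercator), generated from built-in templates;
#' * the output of [local_crs()].
#'
#' Geographic (degree-unit) systems are rejected: plots are metre/foot-scale
#' rectangles and require a projected or local engineering CRS.
#'
#' `local_crs()` builds a local engineering CRS (WKT `LOCAL_CS`) in metres or
#' feet, for layouts that are positioned against imagery later rather than
#' georeferenced up front.
#'
#' @param crs CRS identifier: WKT1 text or an `"EPSG:nnnn"` code (a bare
#'   number is taken as an EPSG code).
#' @return `resolve_crs()`: a WKT1 string. `crs_linear_unit()`: `"metre"` or
#'   `"foot"`. `local_crs()`: a WKT1 `LOCAL_CS` string.
#' @examples
#' crs_linear_unit(resolve_crs("EPSG:32614"))
#' local_crs("foot")
#' @export
resolve_crs <- function(crs) {
  if (is.numeric(crs)) crs <- paste0("EPSG:", as.integer(crs))
  if (!is.character(crs) || length(crs) != 1L || is.na(crs) || !nzchar(crs)) {
    stop("'crs' must be a single WKT string or EPSG code.", call. = FALSE)
  }
  if (grepl("\\[", crs)) {
    return(crs)
  }
  code_txt <- sub("^(EPSG|epsg):", "", crs)
  if (!grepl("^[0-9]+$", code_txt)) {
    stop(sprintf("Unrecognized CRS identifier '%s': supply WKT or an EPSG code.",
                 crs), call. = FALSE)
  }
  code <- as.integer(code_txt)
  if (code >= 32601L && code <= 32660L) {
    return(utm_wkt(zone = code - 32600L, north = TRUE, code = code))
  }
  if (code >= 32701L && code <= 32760L) {
    return(utm_wkt(zone = code - 32700L, north = FALSE, code = code))
  }
  if (code == 3857L) {
    return(paste0(
      'PROJCS["WGS 84 / Pseudo-Mercator",', wgs84_geogcs(),
      ',PROJECTION["Mercator_1SP"],PARAMETER["central_meridian",0],',
      'PARAMETER["scale_factor",1],PARAMETER["false_easting",0],',
      'PARAMETER["false_northing",0],UNIT["metre",1],',
      'AUTHORITY["EPSG","3857"]]'))
  }
  if (code == 4326L) {
    stop("EPSG:4326 is geographic (degrees); use a projected CRS such as a UTM zone.",
         call. = FALSE)
  }
  stop(sprintf(
    "EPSG:%d has no built-in definition; supply the CRS as a WKT string.",
    code), call. = FALSE)
}

#' @rdname resolve_crs
#' @param unit Linear unit of the local CRS: `"metre"` or `"foot"`
#'   (international foot, 0.3048 m).
#' @export
local_crs <- function(unit = c("metre", "foot")) {
  unit <- match.arg(unit)
  u <- if (unit == "metre") 'UNIT["metre",1]' else 'UNIT["foot",0.3048]'
  paste0('LOCAL_CS["Local engineering CRS (', unit,
         ')",LOCAL_DATUM["Local datum",32767],', u,
         ',AXIS["Easting",EAST],AXIS["Northing",NORTH]]')
}

#' @rdname resolve_crs
#' @param wkt A WKT1 string, as returned by `resolve_crs()`.
#' @export
crs_linear_unit <- function(wkt) {
  root <- sub("^\\s*([A-Za-z_]+)\\[.*$", "\\1", wkt)
  if (toupper(root) %in% c("GEOGCS", "GEOGCRS", "GEOGRAPHICCRS")) {
    stop("Geographic (degree-unit) CRS: plot layers require a projected or local CRS.",
         call. = FALSE)
  }
  hits <- regmatches(wkt, gregexpr('UNIT\\s*\\[\\s*"[^"]*"\\s*,\\s*[0-9eE.+-]+', wkt))[[1]]
  if (length(hits) == 0L) {
    stop("Could not find a UNIT[] entry in the CRS WKT.", call. = FALSE)
  }
  # The projected/local unit is the last UNIT[] (a PROJCS's inner GEOGCS
  # lists its degree unit first).
  last <- hits[length(hits)]
  factor <- as.numeric(sub('.*,\\s*([0-9eE.+-]+)$', "\\1", last))
  if (abs(factor - 1) < 1e-9) return("metre")
  if (abs(factor - 0.3048) < 1e-4) return("foot")
  stop(sprintf(
    "Unsupported CRS linear unit (factor %g m); only metre- and foot-unit CRSs are supported.",
    factor), call. = FALSE)
}

wgs84_geogcs <- function() {
  paste0('GEOGCS["WGS 84",DATUM["WGS_1984",SPHEROID["WGS 84",6378137,',
         '298.257223563]],PRIMEM["Greenwich",0],',
         'UNIT["degree",0.0174532925199433]]')
}

utm_wkt <- function(zone, north, code) {
  paste0(
    'PROJCS["WGS 84 / UTM zone ', zone, if (north) "N" else "S", '",',
    wgs84_geogcs(),
    ',PROJECTION["Transverse_Mercator"],PARAMETER["latitude_of_origin",0],',
    'PARAMETER["central_meridian",', -183L + 6L * zone, '],',
    'PARAMETER["scale_factor",0.9996],PARAMETER["false_easting",500000],',
    'PARAMETER["false_northing",', if (north) 0L else 10000000L, '],',
    'UNIT["metre",1],AUTHORITY["EPSG","', code, '"]]')
}
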