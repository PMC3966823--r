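# Grids are plain matrices plus metadata. File interchange uses the ESRI
# ASCII grid format (single band, NODATA tag) so that fixtures and pipeline
# outputs remain text.

#' Crop classification grid
#'
#' A gridded crop map: a rectangular matrix of integer crop codes at a fixed
#' metric resolution. Non-cropland cells carry `nodata_code`.
#'
#' @param codes Integer matrix of crop codes (rows = northing, cols = easting).
#' @param resolution_m Pixel edge length in metres (e.g. 30, 56, 100).
#' @param year Calendar year of the classification (optional).
#' @param nodata_code Integer code marking non-cropland pixels.
#' @return An object of class `crop_grid`.
#' @examples
#' g <- crop_grid(matrix(1L, 4, 4), resolution_m = 100, year = 2012)
#' @export
crop_grid <- function(codes, resolution_m, year = NA_integer_, nodata_code = 0L) {
  if (!is.matrix(codes) || length(codes) == 0) {
    abort_invalid("`codes` must be a non-empty matrix of integer crop codes.")
  }
  if (any(!is.finite(codes))) {
    abort_config(paste0("`codes` contains missing values; recode non-cropland ",
                        "to `nodata_code` before building a grid."))
  }
  check_number(resolution_m, "resolution_m", min = 0, min_open = TRUE)
  codes_int <- codes
  storage.mode(codes_int) <- "integer"
  if (any(codes_int != codes)) {
    abort_invalid("`codes` must be whole numbers (crop classification codes).")
  }
  structure(
    list(codes = codes_int,
         resolution_m = as.numeric(resolution_m),
         year = if (is.na(year)) NA_integer_ else as.integer(year),
         nodata_code = as.integer(nodata_code)),
    class = "crop_grid"
  )
}

#' @export
print.crop_grid <- function(x, ...) {
  cat(sprintf("<crop_grid> %d x %d pixels @ %g m (year %s, nodata code %d)\n",
              nrow(x$codes), ncol(x$codes), x$resolution_m,
              ifelse(is.na(x$year), "?", x$year), x$nodata_code))
  invisible(x)
}

#' Expected-use raster
#'
#' Per-pixel expected application rate (g active ingredient / ha) together
#' with the per-pixel treated fraction. Untreated and non-cropland pixels
#' carry rate 0 and fraction 0.
#'
#' @param rates Numeric matrix of expected rates in g AI/ha (>= 0).
#' @param fractions Numeric matrix of treated fractions in \[0, 1\], same
#'   shape as `rates`.
#' @param resolution_m Pixel edge length in metres.
#' @param year Calendar year (optional).
#' @param ai_label Active-ingredient label, or `"total"` for merged rasters.
#' @return An object of class `use_raster`.
#' @export
use_raster <- function(rates, fractions, resolution_m, year = NA_integer_,
                       ai_label = "total") {
  if (!is.matrix(rates) || !is.matrix(fractions) ||
      !identical(dim(rates), dim(fractions))) {
    abort_invalid("`rates` and `fractions` must be matrices of identical shape.")
  }
  if (any(!is.finite(rates)) || any(rates < 0)) {
    abort_invalid("`rates` must be finite and >= 0 everywhere.")
  }
  if (any(!is.finite(fractions)) || any(fractions < 0) || any(fractions > 1)) {
    abort_invalid("`fractions` must lie in [0, 1] everywhere.")
  }
  check_number(resolution_m, "resolution_m", min = 0, min_open = TRUE)
  structure(
    list(rates = rates, fractions = fractions,
         resolution_m = as.numeric(resolution_m),
         year = if (is.na(year)) NA_integer_ else as.integer(year),
         ai_label = as.character(ai_label)),
    class = "use_raster"
  )
}

#' @export
print.use_raster <- function(x, ...) {
  cat(sprintf("<use_raster> %s: %d x %d pixels @ %g m, rate range [%g, %g] g/ha\n",
              x$ai_label, nrow(x$rates), ncol(x$rates), x$resolution_m,
              min(x$rates), max(x$rates)))
  invisible(x)
}

# ---- ESRI ASCII grid read/write -------------------------------------------

format_grid_value <- function(x) {
  formatC(x, format = "g", digits = 15)
}

write_ascii_grid <- function(m, path, cellsize, nodata = -9999) {
  header <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    "xllcorner 0",
    "yllcorner 0",
    sprintf("cellsize %s", format_grid_value(cellsize)),
    sprintf("NODATA_value %s", format_grid_value(nodata))
  )
  body <- apply(m, 1, function(r) paste(format_grid_value(r), collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

read_ascii_grid <- function(path) {
  if (!file.exists(path)) {
    abort_io(sprintf("grid file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1
  while (i <= length(lines) && grepl("^\\s*[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2) {
      abort_format(sprintf("malformed header in %s at line %d: '%s'",
                           path, i, lines[i]))
    }
    hdr[[tolower(parts[1])]] <- suppressWarnings(as.numeric(parts[2]))
    i <- i + 1
  }
  for (key in c("ncols", "nrows", "cellsize")) {
    if (is.null(hdr[[key]]) || is.na(hdr[[key]])) {
      abort_format(sprintf("grid %s is missing a numeric '%s' header", path, key))
    }
  }
  tokens <- unlist(strsplit(trimws(lines[i:length(lines)]), "\\s+"))
  tokens <- tokens[nzchar(tokens)]
  vals <- suppressWarnings(as.numeric(tokens))
  n_expect <- hdr$nrows * hdr$ncols
  if (length(vals) != n_expect || any(is.na(vals))) {
    abort_format(sprintf(
      "grid %s: expected %d values (%d rows x %d cols) from line %d, got %d",
      path, n_expect, hdr$nrows, hdr$ncols, i, length(vals)))
  }
  list(values = matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE),
       cellsize = hdr$cellsize,
       nodata = hdr[["nodata_value"]] %||% -9999)
}

#' Read and write crop grids as ASCII rasters
#'
#' Single-band plain-text raster interchange (ESRI ASCII grid). The file's
#' `NODATA_value` tag becomes the grid's `nodata_code`.
#'
#' @param path File path (conventionally `.asc`).
#' @param year Calendar year to attach to the grid (not stored in the file).
#' @return `read_crop_grid()` returns a [crop_grid()]; `write_crop_grid()`
#'   returns `path` invisibly.
#' @export
read_crop_grid <- function(path, year = NA_integer_) {
  g <- read_ascii_grid(path)
  m <- g$values
  if (any(m != round(m))) {
    abort_format(sprintf("crop grid %s contains non-integer codes", path))
  }
  crop_grid(matrix(as.integer(m), nrow(m), ncol(m)),
            resolution_m = g$cellsize, year = year,
            nodata_code = as.integer(g$nodata))
}

#' @rdname read_crop_grid
#' @param grid A [crop_grid()].
#' @export
write_crop_grid <- function(grid, path) {
  stopifnot(inherits(grid, "crop_grid"))
  write_ascii_grid(grid$codes, path, grid$resolution_m, grid$nodata_code)
}

#' Write a use raster layer as an ASCII raster
#'
#' @param raster A [use_raster()].
#' @param path Output file path.
#' @param layer `"rate"` (g AI/ha) or `"fraction"` (treated fraction).
#' @return `path`, invisibly.
#' @export
write_use_raster <- function(raster, path, layer = c("rate", "fraction")) {
  stopifnot(inherits(raster, "use_raster"))
  layer <- match.arg(layer)
  m <- if (layer == "rate") raster$rates else raster$fractions
  write_ascii_grid(m, path, raster$resolution_m, -9999)
}
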