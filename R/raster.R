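# Habitat-suitability rasters. The pipeline consumes a gridded logistic
# habitat-suitability surface (each pixel scored in [0, 1], here 10 km^2
# pixels by default) produced upstream by a presence-only distribution
# model; training that model is outside this package.
#
# No binary raster package is available in the build environment, so the
# container is a plain matrix plus geometry metadata, serialised as the
# text ESRI ASCII grid dialect. Rows of `values` run south to north
# (row 1 = southernmost), columns west to east.

#' Construct a suitability raster
#'
#' @param values Numeric matrix of logistic suitability scores in \[0, 1\]
#'   (NA = no data). Row 1 is the southernmost row.
#' @param origin Lower-left corner of the grid (x, y), km.
#' @param pixel_area Pixel area in km^2 (default 10, i.e. pixel side
#'   sqrt(10) km).
#' @return An object of class `suit_raster`.
#' @export
suit_raster <- function(values, origin = c(0, 0), pixel_area = 10) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (pixel_area <= 0) abort("pixel_area must be > 0")
  if (all(is.na(values))) abort("raster has no data values")
  bad <- !is.na(values) & (values < -1e-9 | values > 1 + 1e-9)
  if (any(bad)) {
    abort(sprintf("suitability scores outside [0, 1]: e.g. %.6g", values[bad][1]))
  }
  # scores within 1e-9 of the bounds are numerical spill: clamp
  values[!is.na(values)] <- pmin(1, pmax(0, values[!is.na(values)]))
  structure(
    list(values = values, origin = as.numeric(origin),
         pixel_area = as.numeric(pixel_area),
         cellsize = sqrt(as.numeric(pixel_area))),
    class = "suit_raster"
  )
}

#' @export
print.suit_raster <- function(x, ...) {
  cat(sprintf("<suit_raster> %d x %d pixels of %.3g km^2, origin (%.4g, %.4g) km\n",
              nrow(x$values), ncol(x$values), x$pixel_area, x$origin[1], x$origin[2]))
  v <- x$values[!is.na(x$values)]
  cat(sprintf("  values: [%.4g, %.4g], %d missing\n",
              min(v), max(v), sum(is.na(x$values))))
  invisible(x)
}

#' Pixel centres of a raster as a tibble
#'
#' @param r A `suit_raster` (or abundance surface built on one).
#' @param drop_na Drop pixels with missing values (default TRUE).
#' @return Tibble with columns `x`, `y` (pixel centres, km) and `value`.
#' @export
raster_centres <- function(r, drop_na = TRUE) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  cs <- r$cellsize
  xs <- r$origin[1] + (seq_len(nc) - 0.5) * cs
  ys <- r$origin[2] + (seq_len(nr) - 0.5) * cs
  out <- tibble::tibble(
    x = rep(xs, each = nr),
    y = rep(ys, times = nc),
    value = as.vector(r$values)
  )
  if (drop_na) out <- dplyr::filter(out, !is.na(.data$value))
  out
}

#' Read a suitability raster from an ESRI ASCII grid
#'
#' The only supported raster dialect is the plain-text ESRI ASCII grid
#' (`ncols`/`nrows`/`xllcorner`/`yllcorner`/`cellsize` header). Scores more
#' than 1e-9 outside \[0, 1\] raise an error; smaller excursions are clamped.
#'
#' @param path Path to an `.asc` file. Header coordinates are km.
#' @return A [suit_raster].
#' @export
read_suitability <- function(path) {
  if (!file.exists(path)) abort(sprintf("cannot read raster: '%s' does not exist", path))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    abort("GeoTIFF input is not supported in this build; supply an ESRI ASCII grid (.asc)")
  }
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    abort(sprintf("'%s' is not an ESRI ASCII grid (missing header keys)", path))
  }
  nodata <- hdr[["nodata_value"]] %||% -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    abort(sprintf("raster '%s': expected %d values, found %d",
                  path, hdr$ncols * hdr$nrows, length(vals)))
  }
  # file rows run north to south; flip into south-to-north storage
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  m[m == nodata] <- NA_real_
  suit_raster(m, origin = c(hdr$xllcorner, hdr$yllcorner),
              pixel_area = hdr$cellsize^2)
}

#' Write a raster as an ESRI ASCII grid
#'
#' Values are written with 17 significant digits so that a write/read
#' round trip reproduces the doubles bit for bit.
#'
#' @param r A [suit_raster] or abundance surface.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raster_ascii <- function(r, path) {
  m <- r$values
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]  # north row first on disk
  m[is.na(m)] <- -9999
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.17g", r$origin[1]),
    sprintf("yllcorner %.17g", r$origin[2]),
    sprintf("cellsize %.17g", r$cellsize),
    "NODATA_value -9999"
  )
  body <- apply(m, 1, function(row) paste(formatC(row, format = "g", digits = 17),
                                          collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
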