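# Readers and writers for the tabular survey inputs: camera-trap detector
# layouts with per-occasion usage, binary capture histories with sex, and
# kill (mortality permit) records. All files are comma-separated with a
# header row; coordinates are projected kilometres.

#' Construct a detector array
#'
#' A camera-trap array: one proximity detector per row plus a binary usage
#' matrix saying which detectors were active on which sampling occasions
#' (surveys here rotate camera blocks, so usage is rarely all-ones).
#'
#' @param detectors Tibble/data frame with columns `detector` (id), `x`,
#'   `y` (km).
#' @param usage Binary matrix, occasions x detectors. Column names, if
#'   present, must match detector ids.
#' @return An object of class `detector_array`.
#' @export
detector_array <- function(detectors, usage) {
  detectors <- tibble::as_tibble(detectors)
  stopifnot(all(c("detector", "x", "y") %in% names(detectors)))
  detectors$detector <- as.character(detectors$detector)
  if (anyDuplicated(detectors$detector)) abort("duplicate detector ids")
  usage <- as.matrix(usage)
  if (ncol(usage) != nrow(detectors)) {
    abort(sprintf("usage has %d columns but there are %d detectors",
                  ncol(usage), nrow(detectors)))
  }
  if (!all(usage %in% c(0, 1))) {
    abort(sprintf("usage entries must be 0/1 (found %s)",
                  paste(unique(usage[!usage %in% c(0, 1)])[1], collapse = ", ")))
  }
  colnames(usage) <- detectors$detector
  structure(list(detectors = detectors, usage = usage), class = "detector_array")
}

#' @export
print.detector_array <- function(x, ...) {
  cat(sprintf("<detector_array> %d detectors, %d occasions, %d active detector-occasions\n",
              nrow(x$detectors), nrow(x$usage), sum(x$usage)))
  invisible(x)
}

n_occasions <- function(da) nrow(da$usage)

#' Detector coordinates as a matrix
#' @param da A [detector_array].
#' @return Two-column (x, y) matrix, km.
#' @export
detector_coords <- function(da) as.matrix(da$detectors[, c("x", "y")])

#' Read a detector layout with usage columns
#'
#' Expects a CSV with columns `detector`, `x`, `y` and one `u<k>` usage
#' column per occasion (`u1`, `u2`, ...), all usage entries 0/1.
#'
#' @param path CSV path.
#' @return A [detector_array].
#' @export
read_detectors <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE,
                        progress = FALSE, name_repair = "minimal")
  if (!all(c("detector", "x", "y") %in% names(tb))) {
    abort(sprintf("'%s': need columns detector, x, y plus usage columns u1..", path))
  }
  ucols <- grep("^u[0-9]+$", names(tb), value = TRUE)
  if (length(ucols) == 0) abort(sprintf("'%s': no usage columns (u1, u2, ...)", path))
  ucols <- ucols[order(as.integer(sub("^u", "", ucols)))]
  bad <- which(!stats::complete.cases(tb[, c("detector", "x", "y")]))
  if (length(bad)) {
    abort(sprintf("'%s': malformed row at data line %d", path, bad[1]))
  }
  usage <- t(as.matrix(tb[, ucols]))  # occasions x detectors
  rownames(usage) <- NULL
  detector_array(tb[, c("detector", "x", "y")], usage)
}

#' Write a detector layout
#'
#' @param da A [detector_array].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_detectors <- function(da, path) {
  u <- t(da$usage)
  colnames(u) <- paste0("u", seq_len(ncol(u)))
  readr::write_csv(dplyr::bind_cols(da$detectors, tibble::as_tibble(u)), path,
                   progress = FALSE)
  invisible(path)
}

#' Construct capture data
#'
#' Binary proximity-detector capture histories: at most one detection per
#' (individual, occasion, detector); duplicates collapse. Every captured
#' individual must have a known sex because the density model conditions
#' on sex.
#'
#' @param captures Tibble with columns `individual`, `sex` ("M"/"F"),
#'   `occasion` (integer), `detector` (id present in `detectors`).
#' @param detectors A [detector_array].
#' @return Object of class `capture_data`.
#' @export
capture_data <- function(captures, detectors) {
  stopifnot(inherits(detectors, "detector_array"))
  captures <- tibble::as_tibble(captures)
  need <- c("individual", "sex", "occasion", "detector")
  stopifnot(all(need %in% names(captures)))
  captures$individual <- as.character(captures$individual)
  captures$detector <- as.character(captures$detector)
  captures$occasion <- as.integer(captures$occasion)
  if (nrow(captures)) {
    if (any(is.na(captures$sex)) || !all(captures$sex %in% c("M", "F"))) {
      abort("every capture needs sex 'M' or 'F' (the model conditions on sex)")
    }
    unknown <- setdiff(captures$detector, detectors$detectors$detector)
    if (length(unknown)) {
      abort(sprintf("capture at unknown detector id: %s", unknown[1]))
    }
    if (any(captures$occasion < 1 | captures$occasion > n_occasions(detectors))) {
      abort("capture occasion outside the survey's occasion range")
    }
    # sex must be consistent within individual
    chk <- dplyr::summarise(dplyr::group_by(captures, .data$individual),
                            nsex = dplyr::n_distinct(.data$sex), .groups = "drop")
    if (any(chk$nsex > 1)) {
      abort(sprintf("individual '%s' recorded with more than one sex",
                    chk$individual[chk$nsex > 1][1]))
    }
    off <- !mapply(function(o, d) detectors$usage[o, d] == 1,
                   captures$occasion, captures$detector)
    if (any(off)) {
      abort(sprintf("detection at detector '%s' on occasion %d where usage is 0",
                    captures$detector[off][1], captures$occasion[off][1]))
    }
    captures <- dplyr::distinct(captures, .data$individual, .data$sex,
                                .data$occasion, .data$detector)
  }
  structure(list(captures = captures, detectors = detectors),
            class = "capture_data")
}

#' @export
print.capture_data <- function(x, ...) {
  byx <- table(dplyr::distinct(x$captures, .data$individual, .data$sex)$sex)
  cat(sprintf("<capture_data> %d detections, %d individuals (%d M, %d F)\n",
              nrow(x$captures), dplyr::n_distinct(x$captures$individual),
              byx["M"] %||% 0L, byx["F"] %||% 0L))
  invisible(x)
}

#' Read capture histories
#'
#' CSV with columns `individual`, `sex`, `occasion`, `detector`. Duplicate
#' (individual, occasion, detector) rows collapse to one binary detection.
#'
#' @param path CSV path.
#' @param detectors The [detector_array] the captures refer to.
#' @return A [capture_data].
#' @export
read_captures <- function(path, detectors) {
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          individual = readr::col_character(),
                          sex = readr::col_character(),
                          occasion = readr::col_integer(),
                          detector = readr::col_character()
                        ))
  capture_data(tb, detectors)
}

#' Write capture histories
#' @param cd A [capture_data].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_captures <- function(cd, path) {
  readr::write_csv(cd$captures, path, progress = FALSE)
  invisible(path)
}

kill_causes <- c("retaliatory", "hunt")

#' Read kill records
#'
#' One row per killed animal: `record_id`, `date`, `x`, `y` (km), `cause`
#' (`retaliatory` or `hunt`). Each damage-causing-animal permit row is
#' taken to be exactly one retaliatory death; locations are single points
#' (kills are georeferenced to a farm centroid upstream). Counts by cause
#' are reported via `message()` and attached as attribute `counts`.
#'
#' @param path CSV path.
#' @param window Optional length-2 `Date` vector; records outside it are an
#'   error (the analysis window, e.g. a 2002--2010 permit registry).
#' @param quiet Suppress the count message.
#' @return Tibble of kill records with attribute `counts`.
#' @export
read_kill_records <- function(path, window = NULL, quiet = FALSE) {
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          record_id = readr::col_character(),
                          date = readr::col_date(),
                          x = readr::col_double(),
                          y = readr::col_double(),
                          cause = readr::col_character()
                        ))
  if (nrow(tb) && !all(tb$cause %in% kill_causes)) {
    abort(sprintf("unknown kill cause '%s' (expected %s)",
                  setdiff(tb$cause, kill_causes)[1],
                  paste(kill_causes, collapse = ", ")))
  }
  if (!is.null(window) && nrow(tb)) {
    out <- tb$date < window[1] | tb$date > window[2]
    if (any(out)) {
      abort(sprintf("kill record '%s' dated %s outside the analysis window",
                    tb$record_id[out][1], tb$date[out][1]))
    }
  }
  counts <- vapply(kill_causes, function(cz) sum(tb$cause == cz), integer(1))
  if (!quiet) {
    inform(sprintf("read %d kill records (%s)", nrow(tb),
                   paste(sprintf("%s: %d", names(counts), counts), collapse = ", ")))
  }
  attr(tb, "counts") <- counts
  tb
}

#' Write kill records
#' @param records Kill-record tibble.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_kill_records <- function(records, path) {
  readr::write_csv(records[, c("record_id", "date", "x", "y", "cause")], path,
                   progress = FALSE)
  invisible(path)
}

#' Write analysis-cell geometries as GeoJSON
#'
#' Each cell becomes a MultiPolygon feature carrying its id and raw area.
#' Coordinates stay in the projected km system of the analysis (documented
#' in the `crs_note` property).
#'
#' @param cells An analysis-cell tibble from [build_grid()] /
#'   [merge_small_cells()].
#' @param path Output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_cells_geojson <- function(cells, path) {
  features <- purrr::map(seq_len(nrow(cells)), function(i) {
    polys <- cells$geometry[[i]]
    coords <- purrr::map(polys, function(p) {
      p <- rbind(p, p[1, , drop = FALSE])  # close ring
      list(purrr::map(seq_len(nrow(p)), function(k) c(p[k, 1], p[k, 2])))
    })
    list(
      type = "Feature",
      properties = list(cell_id = cells$cell_id[i],
                        raw_area_km2 = cells$raw_area[i],
                        crs_note = "planar km, projected upstream"),
      geometry = list(type = "MultiPolygon", coordinates = coords)
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
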