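# The coarse analysis grid: square cells (nominal 2,500 km^2) tiled over
# the region, clipped to the region outline, with undersized border cells
# merged into their neighbours so that no analysis cell is smaller than
# half the nominal size, and cropped cells scaled up to full-cell
# equivalents for the response regression.

grid_cell_tbl <- function(cell_id, members, geometry, raw_area) {
  tibble::tibble(cell_id = cell_id, members = members,
                 geometry = geometry, raw_area = raw_area)
}

# row-major lattice id from column/row indices (0-based), lower-left first
lattice_id <- function(col, row, ncols) row * ncols + col + 1L

# lattice indices of a point, with the half-open tie-break: a point
# exactly on a shared edge belongs to the lower-index (south/west) cell.
lattice_index <- function(x, y, origin, side, tol = 1e-9) {
  fx <- (x - origin[1]) / side
  fy <- (y - origin[2]) / side
  col <- floor(fx + tol)
  row <- floor(fy + tol)
  on_x <- abs(fx - round(fx)) < tol & round(fx) > 0
  on_y <- abs(fy - round(fy)) < tol & round(fy) > 0
  col[on_x] <- round(fx[on_x]) - 1
  row[on_y] <- round(fy[on_y]) - 1
  cbind(col = col, row = row)
}

#' Build the analysis grid over a region
#'
#' Tiles a square lattice of side `sqrt(cell_area)` over the region's
#' bounding box (lower-left corner = grid origin by default) and clips
#' every lattice cell to the region polygon. Cells with no overlap are
#' dropped; `raw_area` is the clipped area.
#'
#' @param region Region polygon (matrix/data frame of x, y, km).
#' @param cell_area Nominal cell area, km^2 (default 2500).
#' @param origin Optional grid origin (x, y); defaults to the bounding-box
#'   lower-left corner. Shift it for sensitivity analyses.
#' @return An `analysis_grid` tibble: `cell_id`, `members` (list of lattice
#'   cell indices), `geometry` (list of clipped polygons), `raw_area`; the
#'   region, side and origin travel as attributes.
#' @export
build_grid <- function(region, cell_area = 2500, origin = NULL) {
  region <- as_polygon(region)
  area_region <- polygon_area(region)
  if (!is.finite(area_region) || area_region <= cell_area) {
    abort("degenerate region: area must exceed one grid cell")
  }
  side <- sqrt(cell_area)
  if (is.null(origin)) origin <- c(min(region[, 1]), min(region[, 2]))
  ncols <- ceiling((max(region[, 1]) - origin[1]) / side)
  nrows <- ceiling((max(region[, 2]) - origin[2]) / side)
  rows <- list(); ids <- integer(0); areas <- numeric(0); members <- list()
  geoms <- list()
  for (row in 0:(nrows - 1)) {
    for (col in 0:(ncols - 1)) {
      xmin <- origin[1] + col * side
      ymin <- origin[2] + row * side
      clip <- clip_polygon_rect(region, xmin, xmin + side, ymin, ymin + side)
      if (nrow(clip) < 3) next
      a <- polygon_area(clip)
      if (a <= 1e-9) next
      id <- lattice_id(col, row, ncols)
      ids <- c(ids, id)
      areas <- c(areas, a)
      members <- c(members, list(cbind(col = col, row = row)))
      geoms <- c(geoms, list(list(clip)))
    }
  }
  out <- grid_cell_tbl(ids, members, geoms, areas)
  attr(out, "side") <- side
  attr(out, "origin") <- origin
  attr(out, "ncols") <- ncols
  attr(out, "region") <- region
  attr(out, "cell_area") <- cell_area
  class(out) <- c("analysis_grid", class(out))
  out
}

# shared clipped boundary length between two cells (sums over adjacent
# member-rectangle pairs)
shared_boundary <- function(cells, i, j, side, origin) {
  mi <- cells$members[[i]]; mj <- cells$members[[j]]
  gi <- cells$geometry[[i]]; gj <- cells$geometry[[j]]
  total <- 0
  for (a in seq_len(nrow(mi))) {
    for (b in seq_len(nrow(mj))) {
      dc <- mj[b, "col"] - mi[a, "col"]
      dr <- mj[b, "row"] - mi[a, "row"]
      if (abs(dc) + abs(dr) != 1) next
      if (dc != 0) {
        xline <- origin[1] + max(mi[a, "col"], mj[b, "col"]) * side
        iva <- edges_on_line(gi[[a]], 1, xline)
        ivb <- edges_on_line(gj[[b]], 1, xline)
      } else {
        yline <- origin[2] + max(mi[a, "row"], mj[b, "row"]) * side
        iva <- edges_on_line(gi[[a]], 2, yline)
        ivb <- edges_on_line(gj[[b]], 2, yline)
      }
      total <- total + interval_overlap_length(iva, ivb)
    }
  }
  total
}

#' Merge undersized border cells
#'
#' Any cell whose clipped area is below `min_area` (half the nominal size
#' by default) is merged into the adjacent cell with which it shares the
#' longest boundary, ties broken by lower cell id; the merged cell keeps
#' the lower id. Repeats, smallest first, until every cell passes. Total
#' area is conserved.
#'
#' @param cells An `analysis_grid` from [build_grid()].
#' @param min_area Minimum admissible raw area, km^2 (default
#'   `cell_area / 2`).
#' @return The merged `analysis_grid`.
#' @export
merge_small_cells <- function(cells, min_area = attr(cells, "cell_area") / 2) {
  side <- attr(cells, "side"); origin <- attr(cells, "origin")
  grid_attrs <- attributes(cells)[c("side", "origin", "ncols", "region", "cell_area")]
  repeat {
    small <- which(cells$raw_area < min_area)
    if (length(small) == 0) break
    i <- small[which.min(cells$raw_area[small])]
    lens <- vapply(seq_len(nrow(cells)), function(j) {
      if (j == i) return(0)
      shared_boundary(cells, i, j, side, origin)
    }, numeric(1))
    if (max(lens) <= 1e-9) {
      abort(sprintf("cell %d (%.1f km^2) is an isolated fragment: no neighbour to merge with",
                    cells$cell_id[i], cells$raw_area[i]))
    }
    j <- which(lens == max(lens))
    if (length(j) > 1) j <- j[which.min(cells$cell_id[j])]
    keep <- min(i, j); drop <- max(i, j)
    new_id <- min(cells$cell_id[c(i, j)])
    cells$members[[keep]] <- rbind(cells$members[[i]], cells$members[[j]])
    cells$geometry[[keep]] <- c(cells$geometry[[i]], cells$geometry[[j]])
    cells$raw_area[keep] <- cells$raw_area[i] + cells$raw_area[j]
    cells$cell_id[keep] <- new_id
    cells <- cells[-drop, ]
    for (nm in names(grid_attrs)) attr(cells, nm) <- grid_attrs[[nm]]
    if (!inherits(cells, "analysis_grid")) {
      class(cells) <- c("analysis_grid", class(cells))
    }
  }
  cells
}

# map points to analysis-cell row index (NA when outside all cells)
points_to_cells <- function(x, y, cells) {
  side <- attr(cells, "side"); origin <- attr(cells, "origin")
  ncols <- attr(cells, "ncols"); region <- attr(cells, "region")
  idx <- lattice_index(x, y, origin, side)
  lat <- lattice_id(idx[, "col"], idx[, "row"], ncols)
  lookup <- integer(0)
  for (r in seq_len(nrow(cells))) {
    m <- cells$members[[r]]
    lookup[lattice_id(m[, "col"], m[, "row"], ncols)] <- r
  }
  row <- rep(NA_integer_, length(x))
  ok <- lat >= 1 & lat <= length(lookup)
  row[ok] <- lookup[lat[ok]]  # unassigned lookup slots are NA
  # a lattice hit still needs to be inside the region outline
  inr <- point_in_polygon(x, y, region)
  row[!inr] <- NA_integer_
  row
}

#' Count kill records per cell and cause
#'
#' Assigns each record's point to the analysis cell containing it
#' (half-open edges: a point on a shared edge goes to the lower-id cell)
#' and tallies counts per cause. Records falling outside every cell are
#' excluded and reported.
#'
#' @param records Kill-record tibble ([read_kill_records()] output or the
#'   synthetic equivalent).
#' @param cells An `analysis_grid`.
#' @param quiet Suppress the excluded-record message.
#' @return `cells` with integer columns `kills_<cause>_raw` added; the
#'   number of excluded records is attached as attribute `n_excluded`.
#' @export
assign_kills <- function(records, cells, quiet = FALSE) {
  row <- points_to_cells(records$x, records$y, cells)
  excluded <- sum(is.na(row))
  if (excluded > 0 && !quiet) {
    inform(sprintf("%d kill record(s) fall outside all analysis cells and are excluded",
                   excluded))
  }
  for (cz in kill_causes) {
    cnt <- integer(nrow(cells))
    hit <- !is.na(row) & records$cause == cz
    if (any(hit)) {
      tab <- table(row[hit])
      cnt[as.integer(names(tab))] <- as.integer(tab)
    }
    cells[[paste0("kills_", cz, "_raw")]] <- cnt
  }
  attr(cells, "n_excluded") <- excluded
  cells
}

#' Sum expected abundance into cells
#'
#' Per-cell sum of the abundance surface over pixels whose centres fall in
#' the cell (and inside the region outline).
#'
#' @param surface An abundance surface from [extrapolate()].
#' @param cells An `analysis_grid`.
#' @return `cells` with an `abundance_raw` column added.
#' @export
cell_abundance <- function(surface, cells) {
  ctr <- raster_centres(surface)
  row <- points_to_cells(ctr$x, ctr$y, cells)
  ab <- numeric(nrow(cells))
  ok <- !is.na(row)
  if (any(ok)) {
    s <- tapply(ctr$value[ok], row[ok], sum)
    ab[as.integer(names(s))] <- as.numeric(s)
  }
  npix <- integer(nrow(cells))
  tb <- table(row[ok])
  npix[as.integer(names(tb))] <- as.integer(tb)
  if (any(npix == 0)) {
    abort(sprintf("cell %d contains no abundance pixels",
                  cells$cell_id[npix == 0][1]))
  }
  cells$abundance_raw <- ab
  cells
}

#' Scale cropped cells to full-cell equivalents
#'
#' Multiplies raw abundance and kill counts by `cell_area / raw_area` so
#' every cell reads as a nominal full-size cell; full cells are unchanged
#' and scaling preserves per-km^2 rates. Scaled kill counts may be
#' fractional; raw counts are retained.
#'
#' @param cells An `analysis_grid` carrying `abundance_raw` and/or
#'   `kills_*_raw` columns.
#' @param cell_area Nominal full-cell area (default the grid's own).
#' @return `cells` with `abundance_full` / `kills_<cause>_full` columns.
#' @export
scale_to_full_cell <- function(cells, cell_area = attr(cells, "cell_area")) {
  f <- cell_area / cells$raw_area
  if ("abundance_raw" %in% names(cells)) {
    cells$abundance_full <- cells$abundance_raw * f
  }
  for (cz in kill_causes) {
    rawcol <- paste0("kills_", cz, "_raw")
    if (rawcol %in% names(cells)) {
      cells[[paste0("kills_", cz, "_full")]] <- cells[[rawcol]] * f
    }
  }
  cells
}

#' Write the per-cell analysis table
#'
#' @param cells Analysis grid with abundance/kill columns.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  keep <- setdiff(names(cells), c("members", "geometry"))
  readr::write_csv(tibble::as_tibble(cells[, keep]), path, progress = FALSE)
  invisible(path)
}
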