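# Synthetic stand-ins for every field input: a smoothed habitat
# suitability surface, animals placed proportional to suitability,
# rotating-block camera surveys, Bernoulli capture histories under the
# half-normal model, and per-cell kills generated from a chosen
# functional-response form with additive Gaussian noise. All generators
# are deterministic given their seed.

#' Simulation configuration
#'
#' Defaults state a leopard-like world: ~50,000 km^2 region, 10 km^2
#' suitability pixels, about one animal per ideal-habitat pixel, modest
#' camera-trap detectability (g0 = 0.15, sigma = 1.5 km for both sexes),
#' three rotating blocks of 14 cameras run for 20 days each (within the
#' 13-15 cells / 18-21 days rotation the survey design emulates, 60 days
#' total), a nominal 2,500 km^2 analysis grid, and response truths of
#' Table-1 magnitude: a sigmoidal (type III) retaliatory response
#' (k = 13, x = 67, r = 12) and a linear (type I) sport-hunting response
#' (a = -5, b = 0.14), each with additive Gaussian noise (sd = 2).
#'
#' @param seed Integer root seed; every stage derives its own stream.
#' @param region_radius Radius scale of the random region outline, km.
#' @param pixel_area Suitability pixel area, km^2.
#' @param A_star True expected animals per ideal pixel.
#' @param g0,sigma Detection truth (scalars or `c(M=,F=)`).
#' @param n_blocks,detectors_per_block,days_per_block Rotating survey design.
#' @param detector_spacing Camera spacing inside a block, km.
#' @param cell_area,min_area Analysis-grid geometry, km^2.
#' @param response_truth Named list of [fr_model()]s per cause.
#' @param noise_sd Kill-count noise standard deviation.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       region_radius = 126,
                       pixel_area = 10,
                       A_star = 1.06,
                       g0 = 0.15, sigma = 1.5,
                       n_blocks = 3, detectors_per_block = 14,
                       days_per_block = 20, detector_spacing = 2.5,
                       cell_area = 2500, min_area = cell_area / 2,
                       response_truth = list(
                         retaliatory = fr_model("III", k = 13, x = 67, r = 12),
                         hunt = fr_model("I", a = -5, b = 0.14)
                       ),
                       noise_sd = 2) {
  stopifnot(A_star > 0, pixel_area > 0, noise_sd >= 0)
  structure(list(
    seed = as.integer(seed), region_radius = region_radius,
    pixel_area = pixel_area, A_star = A_star, g0 = g0, sigma = sigma,
    n_blocks = n_blocks, detectors_per_block = detectors_per_block,
    days_per_block = days_per_block, detector_spacing = detector_spacing,
    cell_area = cell_area, min_area = min_area,
    response_truth = response_truth, noise_sd = noise_sd
  ), class = "sim_config")
}

# deterministic sub-seed per named stage, kept under 2^31
stage_seed <- function(seed, stage) {
  (as.integer(seed) * 1009L + utf8ToInt(substr(stage, 1, 1)) * 131L +
     nchar(stage)) %% 2147483587L
}

#' Generate a synthetic habitat-suitability raster
#'
#' A Gaussian random field (white noise smoothed by repeated 3x3 local
#' averaging) rescaled to \[0.05, 1\]: spatially autocorrelated, never
#' exactly zero, deterministic given the seed.
#'
#' @param config A [sim_config()].
#' @param smoothing Number of smoothing passes (default 12).
#' @return A [suit_raster] covering the region bounding box; an attribute
#'   `region` carries the region outline polygon.
#' @export
gen_suitability <- function(config, smoothing = 12) {
  set.seed(stage_seed(config$seed, "suitability"))
  region <- random_region_polygon(centre = c(config$region_radius,
                                             config$region_radius),
                                  radius = config$region_radius)
  cs <- sqrt(config$pixel_area)
  nc <- ceiling((max(region[, 1])) / cs) + 1
  nr <- ceiling((max(region[, 2])) / cs) + 1
  m <- matrix(rnorm(nr * nc), nr, nc)
  for (k in seq_len(smoothing)) {
    padded <- rbind(m[1, ], m, m[nr, ])
    padded <- cbind(padded[, 1], padded, padded[, nc])
    m <- (padded[1:nr, 1:nc] + padded[1:nr, 2:(nc + 1)] + padded[1:nr, 3:(nc + 2)] +
          padded[2:(nr + 1), 1:nc] + padded[2:(nr + 1), 2:(nc + 1)] +
          padded[2:(nr + 1), 3:(nc + 2)] +
          padded[3:(nr + 2), 1:nc] + padded[3:(nr + 2), 2:(nc + 1)] +
          padded[3:(nr + 2), 3:(nc + 2)]) / 9
  }
  m <- 0.05 + 0.95 * (m - min(m)) / (max(m) - min(m))
  r <- suit_raster(m, origin = c(0, 0), pixel_area = config$pixel_area)
  attr(r, "region") <- region
  r
}

#' Simulate activity centres over an abundance surface
#'
#' Inhomogeneous Poisson: each pixel gets `rpois(a')` animals placed
#' uniformly within the pixel; sex is a fair Bernoulli draw.
#'
#' @param surface An abundance surface from [extrapolate()].
#' @param seed Integer seed.
#' @return Tibble `x`, `y`, `sex`.
#' @export
sim_activity_centers <- function(surface, seed = 1) {
  set.seed(seed)
  ctr <- raster_centres(surface)
  half <- surface$cellsize / 2
  counts <- rpois(nrow(ctr), ctr$value)
  idx <- rep(seq_len(nrow(ctr)), counts)
  n <- length(idx)
  tibble::tibble(
    x = ctr$x[idx] + runif(n, -half, half),
    y = ctr$y[idx] + runif(n, -half, half),
    sex = ifelse(rbinom(n, 1, 0.5) == 1, "M", "F")
  )
}

#' Rotating-block usage matrix
#'
#' Block-diagonal usage: block b's detectors are active only during its
#' `days_per_block`-day window. Emulates a camera shortage survey that
#' rotates one set of cameras through the site.
#'
#' @param n_blocks Number of blocks.
#' @param detectors_per_block Detectors in each block.
#' @param days_per_block Occasions (days) per block.
#' @return Binary usage matrix, occasions x detectors; warns when the
#'   total duration exceeds 90 days (population-closure strain).
#' @export
sim_rotating_usage <- function(n_blocks, detectors_per_block, days_per_block) {
  total_days <- n_blocks * days_per_block
  if (total_days > 90) {
    warn(sprintf("survey spans %d days; population closure is doubtful beyond 90",
                 total_days))
  }
  n_det <- n_blocks * detectors_per_block
  usage <- matrix(0L, total_days, n_det)
  for (b in seq_len(n_blocks)) {
    occ <- (b - 1) * days_per_block + seq_len(days_per_block)
    det <- (b - 1) * detectors_per_block + seq_len(detectors_per_block)
    usage[occ, det] <- 1L
  }
  usage
}

#' Lay out a camera-trap site
#'
#' Detectors on a compact rectangular grid (one per surveyed cell),
#' assigned to rotating blocks column-wise, with a rotating usage matrix.
#'
#' @param config A [sim_config()].
#' @param origin Lower-left corner of the site, km.
#' @param site_id Prefix for detector ids.
#' @return A [detector_array].
#' @export
sim_detectors <- function(config, origin = c(0, 0), site_id = "S") {
  n_det <- config$n_blocks * config$detectors_per_block
  ncol_grid <- ceiling(sqrt(n_det))
  xy <- tibble::tibble(
    detector = sprintf("%s%02d", site_id, seq_len(n_det)),
    x = origin[1] + ((seq_len(n_det) - 1) %% ncol_grid) * config$detector_spacing,
    y = origin[2] + ((seq_len(n_det) - 1) %/% ncol_grid) * config$detector_spacing
  )
  usage <- sim_rotating_usage(config$n_blocks, config$detectors_per_block,
                              config$days_per_block)
  detector_array(xy, usage)
}

#' Simulate binary capture histories
#'
#' Every (animal, occasion, active detector) triple is an independent
#' Bernoulli trial with probability `halfnormal(distance, g0, sigma)` for
#' the animal's sex. Animals never detected are absent from the output,
#' as in real capture data.
#'
#' @param centres Tibble `x`, `y`, `sex` of true activity centres.
#' @param detectors A [detector_array].
#' @param g0,sigma Detection truth; scalars or `c(M=,F=)`.
#' @param seed Integer seed.
#' @return A [capture_data].
#' @export
sim_captures <- function(centres, detectors, g0, sigma, seed = 1) {
  set.seed(seed)
  usage <- detectors$usage
  det_xy <- detector_coords(detectors)
  ids <- detectors$detectors$detector
  rows <- list()
  for (i in seq_len(nrow(centres))) {
    sx <- centres$sex[i]
    g <- if (length(g0) > 1) g0[[sx]] else g0
    s <- if (length(sigma) > 1) sigma[[sx]] else sigma
    if (g <= 0) next
    d <- sqrt((det_xy[, 1] - centres$x[i])^2 + (det_xy[, 2] - centres$y[i])^2)
    p <- halfnormal(d, g, s)
    # skip animals far outside detection range
    if (all(p < 1e-12)) next
    P <- usage * matrix(p, nrow(usage), ncol(usage), byrow = TRUE)
    hits <- which(matrix(rbinom(length(P), 1, as.vector(P)),
                         nrow(P), ncol(P)) == 1, arr.ind = TRUE)
    if (nrow(hits)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        individual = sprintf("A%04d", i), sex = sx,
        occasion = hits[, 1], detector = ids[hits[, 2]]
      )
    }
  }
  caps <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(individual = character(), sex = character(),
                   occasion = integer(), detector = character())
  capture_data(caps, detectors)
}

#' Simulate per-cell kill counts under a response truth
#'
#' `kills = max(0, fr_predict(truth, abundance) + N(0, noise_sd))`;
#' the number of zero-truncation events is attached as an attribute.
#'
#' @param abundance Vector of per-full-cell abundances.
#' @param truth An [fr_model()].
#' @param noise_sd Gaussian noise sd (>= 0).
#' @param seed Integer seed.
#' @return Numeric kills vector with attribute `n_truncated`.
#' @export
sim_kills <- function(abundance, truth, noise_sd = 2, seed = 1) {
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  set.seed(seed)
  raw <- fr_predict(truth, abundance) + rnorm(length(abundance), 0, noise_sd)
  truncated <- raw < 0
  out <- pmax(0, raw)
  attr(out, "n_truncated") <- sum(truncated)
  out
}

#' Scatter per-cell kill counts into point records
#'
#' Turns integer per-cell counts into kill-record rows with points drawn
#' uniformly inside each cell (inside the region outline), so the
#' point-in-cell assignment path can be exercised end to end.
#'
#' @param cells An `analysis_grid`.
#' @param counts Named list of integer vectors per cause
#'   (`list(retaliatory = , hunt = )`), one count per cell.
#' @param seed Integer seed.
#' @param year_range Years stamped on the synthetic dates.
#' @return Kill-record tibble (`record_id`, `date`, `x`, `y`, `cause`).
#' @export
sim_kill_records <- function(cells, counts, seed = 1,
                             year_range = c(2002, 2010)) {
  set.seed(seed)
  side <- attr(cells, "side"); origin <- attr(cells, "origin")
  region <- attr(cells, "region")
  rows <- list()
  rid <- 0L
  for (cz in names(counts)) {
    for (r in seq_len(nrow(cells))) {
      n <- counts[[cz]][r]
      if (n == 0) next
      m <- cells$members[[r]]
      pts <- matrix(numeric(0), ncol = 2)
      guard <- 0
      while (nrow(pts) < n && guard < 1000) {
        k <- sample.int(nrow(m), n - nrow(pts), replace = TRUE)
        px <- origin[1] + (m[k, "col"] + runif(length(k))) * side
        py <- origin[2] + (m[k, "row"] + runif(length(k))) * side
        keep <- point_in_polygon(px, py, region)
        pts <- rbind(pts, cbind(px[keep], py[keep]))
        guard <- guard + 1
      }
      if (nrow(pts) < n) abort(sprintf("could not place kills inside cell %d",
                                       cells$cell_id[r]))
      pts <- pts[seq_len(n), , drop = FALSE]
      rows[[length(rows) + 1]] <- tibble::tibble(
        record_id = sprintf("K%05d", rid + seq_len(n)),
        date = as.Date(sprintf("%d-06-15",
                               sample(year_range[1]:year_range[2], n, TRUE))),
        x = pts[, 1], y = pts[, 2], cause = cz
      )
      rid <- rid + n
    }
  }
  if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(record_id = character(), date = as.Date(character()),
                   x = numeric(), y = numeric(), cause = character())
}
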