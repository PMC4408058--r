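# Extrapolating site densities across a region through the habitat
# suitability surface. Two steps: (1) estimate A, the expected number of
# animals in one pixel of ideal habitat (suitability 1), by averaging
# suitability-deflated per-pixel abundances over the camera-trap sites;
# (2) multiply A back onto the suitability score of every pixel to get a
# per-pixel expected-abundance surface a' = A * hs.

#' Pixel table for a camera-trap site
#'
#' Extracts the suitability pixels whose centres fall inside a site
#' polygon, as one row per pixel.
#'
#' @param raster A [suit_raster].
#' @param site_polygon Site boundary polygon (matrix/data frame of x, y km).
#' @param site_id Identifier stored in the `site` column.
#' @return Tibble with columns `site`, `x`, `y`, `hs`.
#' @export
site_pixels <- function(raster, site_polygon, site_id = "site") {
  ctr <- raster_centres(raster)
  inside <- point_in_polygon(ctr$x, ctr$y, site_polygon)
  if (!any(inside)) abort(sprintf("site '%s': no raster pixels in footprint", site_id))
  dplyr::mutate(ctr[inside, ], site = site_id, hs = .data$value,
                .keep = "unused", .before = 1)
}

#' Per-pixel expected abundance for a site from its SECR density
#'
#' Spreads the site's density uniformly over its pixels:
#' `a = density * pixel_area / 100` expected animals per pixel.
#'
#' @param pixels Tibble from [site_pixels()] (columns `site`, `hs`, ...).
#' @param density Site density, animals per 100 km^2 (>= 0).
#' @param pixel_area Pixel area, km^2 (default 10).
#' @param density_se Optional SE of the density; propagated into an `a_se`
#'   column for downstream uncertainty in the ideal abundance.
#' @return `pixels` with columns `a` (and `a_se` if requested) added.
#' @export
pixels_from_density <- function(pixels, density, pixel_area = 10,
                                density_se = NULL) {
  if (nrow(pixels) == 0) abort("empty site footprint")
  if (density < 0) abort("density must be >= 0")
  pixels$a <- density * pixel_area / 100
  if (!is.null(density_se)) pixels$a_se <- density_se * pixel_area / 100
  pixels
}

#' Expected abundance of an ideal-habitat pixel
#'
#' Averages suitability-corrected per-pixel abundance, first within then
#' across sites:
#' `A = (1/K) * sum_i (1/n_i) * sum_j a_ij / hs_ij`.
#' Within a site the per-pixel abundances share one density estimate, so
#' the within-site SE terms add linearly; across sites they add in
#' quadrature.
#'
#' @param sites Tibble with columns `site`, `a`, `hs` (one row per pixel),
#'   optionally `a_se`.
#' @return List with `A` (> 0 expected), `se` (NA without `a_se`) and `K`.
#' @export
ideal_abundance <- function(sites) {
  stopifnot(all(c("site", "a", "hs") %in% names(sites)))
  if (nrow(sites) == 0) abort("no site pixels")
  zero <- sites$hs <= 0
  if (any(zero)) {
    abort(sprintf("site '%s' contains a pixel with suitability 0 at (%.4g, %.4g)",
                  sites$site[zero][1], sites$x[zero][1] %||% NA,
                  sites$y[zero][1] %||% NA))
  }
  per_site <- dplyr::summarise(
    dplyr::group_by(sites, .data$site),
    term = mean(.data$a / .data$hs),
    term_se = if ("a_se" %in% names(sites)) mean(.data$a_se / .data$hs) else NA_real_,
    .groups = "drop"
  )
  K <- nrow(per_site)
  list(A = mean(per_site$term),
       se = if (all(is.na(per_site$term_se))) NA_real_ else
         sqrt(sum(per_site$term_se^2)) / K,
       K = K)
}

#' Extrapolate ideal abundance over the suitability raster
#'
#' Per-pixel expected abundance `a' = A * hs`; missing pixels stay missing.
#'
#' @param A Ideal-pixel abundance (the `A` element of [ideal_abundance()],
#'   or a positive scalar).
#' @param raster A [suit_raster].
#' @return An `abundance_surface`: same geometry, values `a'`, with the
#'   scalar `A` attached.
#' @export
extrapolate <- function(A, raster) {
  if (is.list(A)) A <- A$A
  if (!is.numeric(A) || A <= 0) abort("A must be a positive scalar")
  out <- raster
  out$values <- A * raster$values
  out$A <- A
  class(out) <- c("abundance_surface", "suit_raster")
  out
}

#' @export
print.abundance_surface <- function(x, ...) {
  cat(sprintf("<abundance_surface> A = %.4g per ideal pixel; total %.4g animals\n",
              x$A, sum(x$values, na.rm = TRUE)))
  NextMethod()
}

#' Expected number of animals in a region
#'
#' Sums per-pixel expected abundance over pixels whose centres fall in the
#' region polygon.
#'
#' @param surface An abundance surface from [extrapolate()].
#' @param region Region polygon (x, y km).
#' @return Expected count (scalar).
#' @export
region_abundance <- function(surface, region) {
  ctr <- raster_centres(surface)
  inside <- point_in_polygon(ctr$x, ctr$y, region)
  if (!any(inside)) abort("region overlaps no raster pixels")
  sum(ctr$value[inside])
}
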