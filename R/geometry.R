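# Planar geometry primitives for the analysis grid. All coordinates are
# projected kilometres; the package does no geodesy. Polygons are two-column
# (x, y) matrices, implicitly closed, vertices in any consistent orientation.

as_polygon <- function(p) {
  if (is.data.frame(p)) p <- cbind(p$x, p$y)
  p <- as.matrix(p)
  if (ncol(p) != 2 || nrow(p) < 3) {
    abort("a polygon needs at least 3 (x, y) vertices")
  }
  storage.mode(p) <- "double"
  colnames(p) <- c("x", "y")
  # drop an explicitly repeated closing vertex
  n <- nrow(p)
  if (all(p[1, ] == p[n, ])) p <- p[-n, , drop = FALSE]
  p
}

#' Area of a planar polygon
#'
#' Shoelace formula; orientation-independent.
#'
#' @param poly Two-column matrix or data frame of vertices (x, y), km.
#' @return Area in km^2.
#' @export
polygon_area <- function(poly) {
  p <- as_polygon(poly)
  x <- p[, 1]; y <- p[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

# Sutherland-Hodgman clip of an arbitrary subject polygon against one
# half-plane keep(v) >= 0 with intersection rule inter(v1, v2).
clip_halfplane <- function(p, inside, intersect_fn) {
  n <- nrow(p)
  if (n == 0) return(p)
  out <- matrix(numeric(0), ncol = 2)
  prev <- p[n, ]
  prev_in <- inside(prev)
  for (i in seq_len(n)) {
    cur <- p[i, ]
    cur_in <- inside(cur)
    if (cur_in) {
      if (!prev_in) out <- rbind(out, intersect_fn(prev, cur))
      out <- rbind(out, cur)
    } else if (prev_in) {
      out <- rbind(out, intersect_fn(prev, cur))
    }
    prev <- cur
    prev_in <- cur_in
  }
  out
}

# Clip a polygon to the axis-aligned rectangle [xmin, xmax] x [ymin, ymax].
# Returns a (possibly empty) vertex matrix. Correct area for concave
# subjects; degenerate connecting edges have zero area.
clip_polygon_rect <- function(poly, xmin, xmax, ymin, ymax) {
  p <- as_polygon(poly)
  lerp <- function(a, b, t) a + t * (b - a)
  cuts <- list(
    list(function(v) v[1] >= xmin,
         function(a, b) { t <- (xmin - a[1]) / (b[1] - a[1]); c(xmin, lerp(a[2], b[2], t)) }),
    list(function(v) v[1] <= xmax,
         function(a, b) { t <- (xmax - a[1]) / (b[1] - a[1]); c(xmax, lerp(a[2], b[2], t)) }),
    list(function(v) v[2] >= ymin,
         function(a, b) { t <- (ymin - a[2]) / (b[2] - a[2]); c(lerp(a[1], b[1], t), ymin) }),
    list(function(v) v[2] <= ymax,
         function(a, b) { t <- (ymax - a[2]) / (b[2] - a[2]); c(lerp(a[1], b[1], t), ymax) })
  )
  for (cut in cuts) {
    p <- clip_halfplane(p, cut[[1]], cut[[2]])
    if (nrow(p) < 3) return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y"))))
  }
  colnames(p) <- c("x", "y")
  p
}

#' Test whether points fall inside a polygon
#'
#' Even-odd ray casting, vectorised over points. Points exactly on the
#' boundary may fall on either side; downstream tie-breaks are handled at
#' the grid-index level, not here.
#'
#' @param x,y Numeric vectors of point coordinates, km.
#' @param poly Polygon vertex matrix or data frame.
#' @return Logical vector.
#' @export
point_in_polygon <- function(x, y, poly) {
  p <- as_polygon(poly)
  px <- p[, 1]; py <- p[, 2]
  n <- nrow(p)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > y) != (py[j] > y))
    if (any(crosses)) {
      xin <- (px[j] - px[i]) * (y[crosses] - py[i]) / (py[j] - py[i]) + px[i]
      flip <- x[crosses] < xin
      inside[crosses][flip] <- !inside[crosses][flip]
    }
    j <- i
  }
  inside
}

# Intervals (as a 2-column matrix of [lo, hi]) where the polygon boundary
# runs along the line {axis == value}. `axis` is 1 for x, 2 for y; the
# interval is measured along the other axis.
edges_on_line <- function(poly, axis, value, tol = 1e-9) {
  p <- as_polygon(poly)
  other <- 3 - axis
  n <- nrow(p)
  iv <- matrix(numeric(0), ncol = 2)
  j <- n
  for (i in seq_len(n)) {
    if (abs(p[i, axis] - value) < tol && abs(p[j, axis] - value) < tol) {
      lo <- min(p[i, other], p[j, other])
      hi <- max(p[i, other], p[j, other])
      if (hi - lo > tol) iv <- rbind(iv, c(lo, hi))
    }
    j <- i
  }
  iv
}

# Total length of the pairwise overlap between two interval sets.
interval_overlap_length <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  total <- 0
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a[i, 1], b[, 1])
    hi <- pmin(a[i, 2], b[, 2])
    total <- total + sum(pmax(0, hi - lo))
  }
  total
}

# A reasonably general random "blob" polygon: star-shaped around a centre
# with smoothly varying radius. Used by the synthetic module and tests.
random_region_polygon <- function(n_vertices = 24, centre = c(0, 0),
                                  radius = 100, roughness = 0.35) {
  stopifnot(n_vertices >= 3, radius > 0, roughness >= 0, roughness < 1)
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  # low-order harmonics keep the outline smooth but irregular
  a1 <- runif(1, -1, 1); a2 <- runif(1, -1, 1)
  b1 <- runif(1, -1, 1); b2 <- runif(1, -1, 1)
  r <- radius * (1 + roughness * (a1 * cos(theta) + b1 * sin(theta) +
                                    0.5 * (a2 * cos(2 * theta) + b2 * sin(2 * theta))) / 2)
  r <- pmax(r, 0.2 * radius)
  cbind(x = centre[1] + r * cos(theta), y = centre[2] + r * sin(theta))
}
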