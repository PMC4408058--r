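# Independent oracles and small fixture builders shared across tests.
# Oracles are deliberately naive (explicit loops, no shared code with the
# package internals beyond exported constructors).

# a 2x2-detector array, all usage 1
toy_detectors <- function(n_occ = 3) {
  detector_array(
    data.frame(detector = paste0("d", 1:4), x = c(0, 1, 0, 1), y = c(0, 0, 1, 1)),
    matrix(1, n_occ, 4)
  )
}

toy_captures <- function(det, n_occ = 3) {
  caps <- tibble::tibble(
    individual = rep(c("a", "b", "c", "d", "e"), times = c(2, 1, 3, 1, 2)),
    sex = rep(c("M", "F", "M", "F", "M"), times = c(2, 1, 3, 1, 2)),
    occasion = c(1, 2, 1, 1, 2, 3, 2, 1, 3),
    detector = c("d1", "d2", "d1", "d3", "d3", "d4", "d2", "d1", "d4")
  )
  capture_data(caps, det)
}

# a free-standing mask tibble (same contract as build_mask output)
manual_mask <- function(xs, ys, cell_area) {
  m <- tibble::tibble(x = rep(xs, times = length(ys)),
                      y = rep(ys, each = length(xs)))
  attr(m, "cell_area") <- cell_area
  m
}

# brute-force conditional SECR log-likelihood: nested loops over
# individuals, mask points, occasions and detectors
brute_conditional_loglik <- function(cd, params, mask) {
  caps <- cd$captures
  det <- cd$detectors$detectors
  usage <- cd$detectors$usage
  n_occ <- nrow(usage); n_det <- nrow(det)
  cell <- attr(mask, "cell_area")
  total <- 0
  for (id in unique(caps$individual)) {
    sub <- caps[caps$individual == id, ]
    sx <- sub$sex[1]
    g0 <- if (length(params$g0) > 1) params$g0[[sx]] else params$g0
    sg <- if (length(params$sigma) > 1) params$sigma[[sx]] else params$sigma
    hist <- matrix(0, n_occ, n_det)
    for (r in seq_len(nrow(sub))) {
      hist[sub$occasion[r], match(sub$detector[r], det$detector)] <- 1
    }
    num <- 0; den <- 0
    for (s in seq_len(nrow(mask))) {
      ph <- 1; psurv <- 1
      for (k in seq_len(n_occ)) {
        for (dd in seq_len(n_det)) {
          if (usage[k, dd] == 0) next
          dist <- sqrt((det$x[dd] - mask$x[s])^2 + (det$y[dd] - mask$y[s])^2)
          p <- g0 * exp(-dist^2 / (2 * sg^2))
          ph <- ph * if (hist[k, dd] == 1) p else (1 - p)
          psurv <- psurv * (1 - p)
        }
      }
      num <- num + ph * cell
      den <- den + (1 - psurv) * cell
    }
    total <- total + log(num / den)
  }
  total
}

# brute-force p_dot at one centre
brute_p_dot <- function(centre, det, g0, sigma) {
  usage <- det$usage
  xy <- det$detectors
  prod_surv <- 1
  for (k in seq_len(nrow(usage))) {
    for (dd in seq_len(ncol(usage))) {
      if (usage[k, dd] == 0) next
      dist <- sqrt((xy$x[dd] - centre[1])^2 + (xy$y[dd] - centre[2])^2)
      prod_surv <- prod_surv * (1 - g0 * exp(-dist^2 / (2 * sigma^2)))
    }
  }
  1 - prod_surv
}

# independently coded AICc (different algebraic arrangement)
oracle_aicc <- function(rss, n, p_curve) {
  p <- p_curve + 1
  aic <- n * log(rss / n) + 2 * p
  aic + (2 * p^2 + 2 * p) / (n - p - 1)
}

# dense grid-search minimiser of type II rss
grid_search_type2 <- function(abundance, kills, k_range, x_range, n_grid = 200) {
  ks <- seq(k_range[1], k_range[2], length.out = n_grid)
  xs <- seq(x_range[1], x_range[2], length.out = n_grid)
  best <- c(Inf, NA, NA)
  for (k in ks) {
    for (x in xs) {
      rss <- sum((kills - k * abundance / (x + abundance))^2)
      if (rss < best[1]) best <- c(rss, k, x)
    }
  }
  list(rss = best[1], k = best[2], x = best[3])
}

# uniform raster fixture
uniform_raster <- function(value = 0.5, nr = 10, nc = 10, pixel_area = 10) {
  suit_raster(matrix(value, nr, nc), origin = c(0, 0), pixel_area = pixel_area)
}

rect_poly <- function(xmin, xmax, ymin, ymax) {
  cbind(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax))
}
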