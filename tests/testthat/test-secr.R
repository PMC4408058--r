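test_that("half-normal detection function obeys its closed forms", {
  expect_equal(halfnormal(0, 0.3, 1.5), 0.3)
  expect_equal(halfnormal(1.5 * sqrt(2 * log(2)), 0.3, 1.5), 0.15)
  expect_lt(halfnormal(15, 0.3, 1.5), 1e-20 * 0.3)
  d <- seq(0, 10, by = 0.1)
  expect_true(all(diff(halfnormal(d, 0.2, 2)) <= 0))
  expect_error(halfnormal(-1, 0.2, 1), "distances")
  expect_error(halfnormal(1, 1.2, 1), "g0")
  expect_error(halfnormal(1, 0.2, 0), "sigma")
})

test_that("mask construction counts points and covers the buffered box", {
  da <- detector_array(data.frame(detector = "d1", x = 0, y = 0),
                       matrix(1, 1, 1))
  m1 <- build_mask(da, buffer = 1, spacing = 1)
  expect_equal(nrow(m1), 9)
  m2 <- build_mask(da, buffer = 1, spacing = 0.5)
  expect_gt(nrow(m2) / nrow(m1), 2.5)  # halving spacing ~ 4x points

  da2 <- detector_array(data.frame(detector = c("a", "b"), x = c(0, 3), y = c(0, 2)),
                        matrix(1, 1, 2))
  m3 <- build_mask(da2, buffer = 2, spacing = 0.25)
  want <- (3 + 4) * (2 + 4)
  got <- nrow(m3) * attr(m3, "cell_area")
  expect_lt(abs(got - want) / want, 0.15)  # geometric oracle within a spacing
  expect_warning(build_mask(da, buffer = 1, spacing = 2), "coarse")
})

test_that("history probability multiplies Bernoulli factors", {
  da <- detector_array(data.frame(detector = "d1", x = 0, y = 0),
                       matrix(1, 1, 1))
  g0 <- 0.3
  expect_equal(history_prob(matrix(0, 1, 1), c(0, 0), da, g0, 1), 0.7)
  expect_equal(history_prob(matrix(1, 1, 1), c(0, 0), da, g0, 1), 0.3)
  expect_error(
    history_prob(matrix(1, 2, 1), c(0, 0),
                 detector_array(data.frame(detector = "d1", x = 0, y = 0),
                                matrix(c(1, 0), 2, 1)),
                 g0, 1),
    "usage is 0")

  # 2 detectors x 2 occasions, mixed history, hand-computed product
  da2 <- detector_array(data.frame(detector = c("a", "b"), x = c(0, 2), y = 0),
                        matrix(1, 2, 2))
  centre <- c(0.5, 0.5)
  p_a <- halfnormal(sqrt(0.5), 0.25, 1.2)
  p_b <- halfnormal(sqrt(1.5^2 + 0.5^2), 0.25, 1.2)
  hist <- rbind(c(1, 0), c(0, 1))
  expect_equal(history_prob(hist, centre, da2, 0.25, 1.2),
               p_a * (1 - p_b) * (1 - p_a) * p_b)
})

test_that("p_dot matches the exhaustive product and its limits", {
  det <- toy_detectors(n_occ = 2)
  centre <- c(0.3, 0.7)
  expect_equal(p_dot(centre, det, 0.2, 1.1),
               brute_p_dot(centre, det, 0.2, 1.1))
  # single detector, single occasion: p_dot is the half-normal itself
  da1 <- detector_array(data.frame(detector = "d", x = 0, y = 0),
                        matrix(1, 1, 1))
  expect_equal(p_dot(c(1, 1), da1, 0.4, 2), halfnormal(sqrt(2), 0.4, 2))
  # g0 -> 0 limit
  expect_lt(p_dot(centre, det, 1e-9, 1.1), 1e-6)
  # monotone in g0
  expect_gt(p_dot(centre, det, 0.3, 1.1), p_dot(centre, det, 0.1, 1.1))
})

test_that("effective area integrates p_dot and refines stably", {
  det <- toy_detectors()
  # large g0 and sigma: p_dot ~ 1 over a small mask near the detectors
  m <- manual_mask(c(0.4, 0.6), c(0.4, 0.6), cell_area = 4)
  a <- effective_area(det, m, 0.9, 50)
  expect_lt(abs(a - 16) / 16, 1e-4)
  # refinement oracle: quadrupling resolution changes a by < 1%
  m1 <- build_mask(det, buffer = 5, spacing = 0.5)
  m2 <- build_mask(det, buffer = 5, spacing = 0.125)
  a1 <- effective_area(det, m1, 0.2, 1.3)
  a2 <- effective_area(det, m2, 0.2, 1.3)
  expect_lt(abs(a1 - a2) / a2, 0.01)
})

test_that("conditional likelihood equals the brute-force double loop", {
  det <- toy_detectors()
  cd <- toy_captures(det)
  mask <- manual_mask(seq(-1.5, 2.5, 1), seq(-1.5, 2.5, 1), cell_area = 1)
  expect_equal(nrow(mask), 25)
  params <- list(g0 = c(M = 0.2, F = 0.3), sigma = c(M = 1.0, F = 0.8))
  expect_equal(conditional_loglik(cd, params, mask),
               brute_conditional_loglik(cd, params, mask),
               tolerance = 1e-10)
})

test_that("likelihood is invariant to area scaling, ordering and translation", {
  det <- toy_detectors()
  cd <- toy_captures(det)
  mask <- manual_mask(seq(-1.5, 2.5, 1), seq(-1.5, 2.5, 1), cell_area = 1)
  params <- list(g0 = 0.25, sigma = 1.1)
  base <- conditional_loglik(cd, params, mask)

  # doubling cell_area cancels between numerator and denominator
  mask2 <- mask
  attr(mask2, "cell_area") <- 2
  expect_equal(conditional_loglik(cd, params, mask2), base)

  # mask point order is irrelevant
  set.seed(1)
  mask3 <- mask[sample.int(nrow(mask)), ]
  attr(mask3, "cell_area") <- 1
  expect_equal(conditional_loglik(cd, params, mask3), base)

  # uniform translation of all coordinates
  shift <- c(13.7, -4.2)
  det_s <- detector_array(
    dplyr::mutate(det$detectors, x = x + shift[1], y = y + shift[2]),
    det$usage)
  cd_s <- capture_data(cd$captures, det_s)
  mask_s <- manual_mask(seq(-1.5, 2.5, 1) + shift[1],
                        seq(-1.5, 2.5, 1) + shift[2], cell_area = 1)
  expect_equal(conditional_loglik(cd_s, params, mask_s), base)

  # conditioning identity: single animal, single detector, single occasion
  da1 <- detector_array(data.frame(detector = "d", x = 0, y = 0),
                        matrix(1, 1, 1))
  cd1 <- capture_data(tibble::tibble(individual = "i", sex = "F",
                                     occasion = 1L, detector = "d"), da1)
  m1 <- manual_mask(seq(-2, 2, 0.5), seq(-2, 2, 0.5), cell_area = 0.25)
  expect_equal(conditional_loglik(cd1, list(g0 = 0.3, sigma = 1), m1), 0)
})

test_that("density estimator does Horvitz-Thompson arithmetic", {
  expect_equal(density_estimate(50)$estimate, 2.0)
  expect_equal(density_estimate(c(50, 100))$estimate, 3.0)
  expect_error(density_estimate(c(50, 0)), "> 0")
})

test_that("fitting recovers truth on one simulated survey and is stable", {
  cfg <- sim_config(seed = 21)
  det <- sim_detectors(cfg)
  xy <- detector_coords(det)
  set.seed(22)
  buf <- 6
  N <- rpois(1, 0.08 * (diff(range(xy[, 1])) + 2 * buf) *
               (diff(range(xy[, 2])) + 2 * buf))
  centres <- tibble::tibble(
    x = runif(N, min(xy[, 1]) - buf, max(xy[, 1]) + buf),
    y = runif(N, min(xy[, 2]) - buf, max(xy[, 2]) + buf),
    sex = sample(c("M", "F"), N, TRUE))
  cd <- sim_captures(centres, det, g0 = 0.2, sigma = 1.5, seed = 23)
  mask <- build_mask(det, buffer = 6, spacing = 1)
  fit <- fit_secr(cd, mask, sex_specific = FALSE)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$g0 - 0.2), 0.15)
  expect_lt(abs(fit$params$sigma - 1.5), 0.8)
  expect_gt(fit$density, 0)
  expect_gt(fit$density_se, 0)
  expect_equal(fit$loglik,
               conditional_loglik(cd, list(g0 = fit$params$g0,
                                           sigma = fit$params$sigma), mask))

  # two distant starting points reach the same optimum
  fit_a <- fit_secr(cd, mask, init = list(g0 = 0.05, sigma = 4),
                    sex_specific = FALSE)
  fit_b <- fit_secr(cd, mask, init = list(g0 = 0.45, sigma = 0.6),
                    sex_specific = FALSE)
  expect_lt(abs(fit_a$params$g0 - fit_b$params$g0), 1e-3)
  expect_lt(abs(fit_a$params$sigma - fit_b$params$sigma), 1e-3)

  # sexes sharing true parameters give near-equal per-sex estimates
  fit_sex <- fit_secr(cd, mask, sex_specific = TRUE)
  expect_lt(abs(diff(fit_sex$params$sigma)), 1.0)
})

test_that("a buffer beyond 4 sigma no longer moves the density estimate", {
  cfg <- sim_config(seed = 61, n_blocks = 2, detectors_per_block = 10,
                    days_per_block = 10)
  det <- sim_detectors(cfg)
  xy <- detector_coords(det)
  set.seed(62)
  centres <- tibble::tibble(
    x = runif(60, min(xy[, 1]) - 8, max(xy[, 1]) + 8),
    y = runif(60, min(xy[, 2]) - 8, max(xy[, 2]) + 8),
    sex = sample(c("M", "F"), 60, TRUE))
  cd <- sim_captures(centres, det, g0 = 0.25, sigma = 1.5, seed = 63)
  f4 <- fit_secr(cd, build_mask(det, buffer = 6, spacing = 0.75),
                 sex_specific = FALSE)   # 4 sigma
  f6 <- fit_secr(cd, build_mask(det, buffer = 9, spacing = 0.75),
                 sex_specific = FALSE)   # 6 sigma
  expect_lt(abs(f6$density - f4$density) / f4$density, 0.01)
})

test_that("a design with no spatial information is flagged, not trusted", {
  da <- detector_array(data.frame(detector = "d1", x = 0, y = 0),
                       matrix(1, 5, 1))
  caps <- tibble::tibble(individual = c("a", "b", "c"), sex = "M",
                         occasion = c(1L, 2L, 3L), detector = "d1")
  cd <- capture_data(caps, da)
  mask <- manual_mask(seq(-3, 3, 0.5), seq(-3, 3, 0.5), cell_area = 0.25)
  fit <- suppressWarnings(fit_secr(cd, mask, init = list(g0 = 0.2, sigma = 1),
                                   sex_specific = FALSE))
  expect_false(fit$converged)
  expect_true(fit$degenerate)
})

test_that("tidy and glance summarise a fit", {
  det <- toy_detectors()
  cd <- toy_captures(det)
  mask <- build_mask(det, buffer = 3, spacing = 0.5)
  fit <- fit_secr(cd, mask, sex_specific = FALSE)
  td <- tidy(fit)
  expect_setequal(td$term, c("g0", "sigma"))
  gl <- glance(fit)
  expect_equal(gl$n_individuals, 5)
  expect_named(gl, c("density", "density_se", "logLik", "n_individuals",
                     "converged"))
})
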