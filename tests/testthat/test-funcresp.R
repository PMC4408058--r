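test_that("response curves evaluate their closed forms", {
  m2 <- fr_model("II", k = 12, x = 60)
  expect_equal(fr_predict(m2, 60), 6)  # half-saturation
  m1 <- fr_model("I", a = 0, b = 0.1)
  expect_equal(fr_predict(m1, 50), 5.0)
  # type III with r = 1 is type II everywhere
  m3 <- fr_model("III", k = 12, x = 60, r = 1)
  ab <- seq(0, 300, by = 7.5)
  expect_equal(fr_predict(m3, ab), fr_predict(m2, ab))
  # a type I line may go negative and is reported as-is
  neg <- fr_model("I", a = -5, b = 0.14)
  expect_lt(fr_predict(neg, 0), 0)
  expect_error(fr_model("II", k = -1, x = 5), "k > 0")
  expect_error(fr_model("III", k = 1, x = 5, r = 0), "r > 0")
  expect_error(fr_predict(m2, -3), ">= 0")
})

test_that("AICc matches its closed form and an independent coding", {
  expect_equal(fr_aicc(30, 30, 2), 6.923077, tolerance = 1e-6)
  expect_equal(fr_aicc(30, 30, 2), 0 + 6 + 24 / 26)
  # doubling rss adds n log 2
  expect_equal(fr_aicc(60, 30, 2) - fr_aicc(30, 30, 2), 30 * log(2))
  set.seed(4)
  for (i in 1:100) {
    rss <- runif(1, 0.1, 500); n <- sample(8:60, 1); p <- sample(1:4, 1)
    expect_equal(fr_aicc(rss, n, p), oracle_aicc(rss, n, p))
  }
  expect_error(fr_aicc(0, 30, 2), "perfect")
  expect_error(fr_aicc(10, 4, 2), "n > p")
  # monotone in rss at fixed n, p
  r1 <- sort(runif(20, 1, 100))
  expect_true(all(diff(vapply(r1, fr_aicc, numeric(1), n = 25, p_curve = 3)) > 0))
})

test_that("noise-free data recover exact parameters for every form", {
  ab <- seq(5, 300, length.out = 30)
  # type I on an exact line: rss 0 and closed-form coefficients
  d1 <- tibble::tibble(abundance = ab, kills = 2 + 0.12 * ab)
  f1 <- fit_model("I", d1)
  expect_equal(unname(f1$model$params), c(2, 0.12), tolerance = 1e-10)
  expect_lt(f1$rss, 1e-18)
  expect_true(f1$perfect_fit)

  truth2 <- fr_model("II", k = 12, x = 60)
  f2 <- fit_model("II", tibble::tibble(abundance = ab,
                                       kills = fr_predict(truth2, ab)))
  expect_equal(unname(f2$model$params), c(12, 60), tolerance = 1e-4)

  truth3 <- fr_model("III", k = 13, x = 67, r = 12)
  f3 <- fit_model("III", tibble::tibble(abundance = ab,
                                        kills = fr_predict(truth3, ab)))
  expect_equal(unname(f3$model$params), c(13, 67, 12), tolerance = 1e-4)
})

test_that("the optimiser matches a dense grid search on a toy instance", {
  set.seed(10)
  ab <- seq(10, 200, length.out = 12)
  kills <- fr_predict(fr_model("II", k = 9, x = 45), ab) + rnorm(12, 0, 0.4)
  fit <- fit_model("II", tibble::tibble(abundance = ab, kills = kills))
  gs <- grid_search_type2(ab, kills, k_range = c(5, 15), x_range = c(20, 90),
                          n_grid = 300)
  expect_lt(fit$rss, gs$rss + 1e-9)  # never worse than the grid
  expect_equal(unname(fit$model$params["k"]), gs$k, tolerance = 1e-2)
  expect_equal(unname(fit$model$params["x"]), gs$x, tolerance = 2e-2)
})

test_that("type III never fits worse than type II (nesting)", {
  set.seed(20)
  ab <- seq(5, 300, length.out = 30)
  for (i in 1:5) {
    kills <- pmax(0, 4 + 0.05 * ab + rnorm(30, 0, 2))
    d <- tibble::tibble(abundance = ab, kills = kills)
    f2 <- fit_model("II", d)
    f3 <- fit_model("III", d)
    expect_lte(f3$rss, f2$rss + 1e-6 * (1 + f2$rss))
  }
})

test_that("comparison reproduces published AICc support sets", {
  # retaliatory: all three response types within 2 units
  ret <- compare_models(c(I = 138.77, II = 138.45, III = 137.91))
  expect_setequal(equal_support(ret), c("I", "II", "III"))
  expect_equal(min(ret$delta_aicc), 0)
  expect_equal(sum(ret$delta_aicc == 0), 1)
  # sport hunting: the linear response alone
  hunt <- compare_models(c(I = 132.41, II = 135.66, III = 135.02))
  expect_setequal(equal_support(hunt), "I")
  # exact ties: all deltas zero, all supported
  tie <- compare_models(c(I = 100, II = 100, III = 100))
  expect_equal(tie$delta_aicc, c(0, 0, 0))
  expect_setequal(equal_support(tie), c("I", "II", "III"))
})

test_that("comparison excludes unconverged fits and needs at least one", {
  ab <- seq(5, 300, length.out = 30)
  set.seed(2)
  d <- tibble::tibble(abundance = ab, kills = pmax(0, 3 + 0.1 * ab + rnorm(30)))
  f1 <- fit_model("I", d); f2 <- fit_model("II", d)
  f2$converged <- FALSE
  expect_warning(cmp <- compare_models(list(f1, f2)), "unconverged")
  expect_equal(cmp$form, "I")
  f1$converged <- FALSE
  expect_error(suppressWarnings(compare_models(list(f1, f2))), "no converged")
})

test_that("diagnostics flag injected outliers and respect relabelling", {
  set.seed(33)
  ab <- seq(5, 300, length.out = 30)
  kills <- fr_predict(fr_model("II", k = 12, x = 60), ab) + rnorm(30, 0, 0.5)
  kills[17] <- kills[17] + 10 * 0.5  # a 10-sd bump
  f <- fit_model("II", tibble::tibble(abundance = ab, kills = kills))
  dg <- fr_diagnostics(f)
  expect_true(dg$outlier[17])
  expect_equal(sum(dg$outlier), 1)

  # residuals all ~zero: nothing flagged
  f0 <- fit_model("I", tibble::tibble(abundance = ab, kills = 1 + 0.1 * ab))
  expect_false(any(fr_diagnostics(f0)$outlier))

  # permutation invariance of the flag set
  perm <- sample.int(30)
  fp <- fit_model("II", tibble::tibble(abundance = ab[perm], kills = kills[perm]))
  dgp <- fr_diagnostics(fp)
  expect_equal(sum(dgp$outlier), 1)
  expect_equal(dgp$abundance[dgp$outlier], ab[17])
})

test_that("tidy, glance and autoplot give Table-1-shaped output", {
  set.seed(41)
  ab <- seq(5, 300, length.out = 30)
  d <- tibble::tibble(abundance = ab,
                      kills = pmax(0, -5 + 0.14 * ab + rnorm(30, 0, 2)))
  fits <- lapply(c("I", "II", "III"), fit_model, data = d)
  cmp <- compare_models(fits)
  expect_named(cmp, c("form", "aicc", "delta_aicc", "equal_support"))
  td <- tidy(fits[[3]])
  expect_equal(td$term, c("k", "x", "r"))
  expect_true(all(is.finite(td$estimate)))
  gl <- glance(fits[[1]])
  expect_named(gl, c("form", "rss", "n", "AICc", "converged"))
  p <- ggplot2::autoplot(cmp)
  expect_s3_class(p, "ggplot")
})
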