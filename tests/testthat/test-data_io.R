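test_that("detector reader validates usage and round-trips", {
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "det.csv")
  writeLines(c("detector,x,y,u1,u2",
               "a,0,0,1,1", "b,1,0,1,1", "c,0,1,1,1"), p)
  da <- read_detectors(p)
  expect_equal(nrow(da$detectors), 3)
  expect_equal(dim(da$usage), c(2, 3))
  expect_true(all(da$usage == 1))

  writeLines(c("detector,x,y,u1", "a,0,0,2"), p)
  expect_error(read_detectors(p), "0/1")

  # write/read roundtrip on a rotating-survey layout
  cfg <- sim_config(seed = 4, n_blocks = 2, detectors_per_block = 3,
                    days_per_block = 4)
  da2 <- sim_detectors(cfg)
  p2 <- file.path(tmp, "det2.csv")
  write_detectors(da2, p2)
  back <- read_detectors(p2)
  expect_equal(back$detectors, da2$detectors)
  expect_equal(unname(back$usage), unname(da2$usage))
})

test_that("capture reader collapses duplicates and enforces the contract", {
  tmp <- withr::local_tempdir()
  da <- detector_array(data.frame(detector = c("a", "b"), x = 0:1, y = 0),
                       rbind(c(1, 1), c(1, 0)))
  p <- file.path(tmp, "cap.csv")
  writeLines(c("individual,sex,occasion,detector",
               "i1,M,1,a", "i1,M,1,a"), p)
  cd <- read_captures(p, da)
  expect_equal(nrow(cd$captures), 1)

  writeLines(c("individual,sex,occasion,detector", "i1,M,1,zz"), p)
  expect_error(read_captures(p, da), "unknown detector")

  writeLines(c("individual,sex,occasion,detector", "i1,M,2,b"), p)
  expect_error(read_captures(p, da), "usage is 0")

  writeLines(c("individual,sex,occasion,detector", "i1,,1,a"), p)
  expect_error(read_captures(p, da), "sex")
})

test_that("synthetic captures round-trip with the generator's bookkeeping", {
  cfg <- sim_config(seed = 12)
  det <- sim_detectors(cfg)
  set.seed(31)
  centres <- tibble::tibble(x = runif(60, -5, 20), y = runif(60, -5, 18),
                            sex = sample(c("M", "F"), 60, TRUE))
  cd <- sim_captures(centres, det, g0 = 0.3, sigma = 2, seed = 32)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_captures(cd, tmp)
  back <- read_captures(tmp, det)
  expect_equal(dplyr::arrange(back$captures, individual, occasion, detector),
               dplyr::arrange(cd$captures, individual, occasion, detector))
  expect_equal(dplyr::n_distinct(back$captures$individual),
               dplyr::n_distinct(cd$captures$individual))
})

test_that("kill-record reader counts causes and rejects bad input", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("record_id,date,x,y,cause",
               "k1,2004-05-01,10,10,retaliatory",
               "k2,2005-06-01,20,10,retaliatory",
               "k3,2006-07-01,30,10,hunt"), tmp)
  rec <- read_kill_records(tmp, quiet = TRUE)
  expect_equal(nrow(rec), 3)
  expect_equal(attr(rec, "counts"), c(retaliatory = 2L, hunt = 1L))

  writeLines(c("record_id,date,x,y,cause", "k1,2004-05-01,1,1,poached"), tmp)
  expect_error(read_kill_records(tmp, quiet = TRUE), "unknown kill cause")

  writeLines("record_id,date,x,y,cause", tmp)
  rec0 <- read_kill_records(tmp, quiet = TRUE)
  expect_equal(nrow(rec0), 0)
  expect_equal(unname(attr(rec0, "counts")), c(0L, 0L))

  # analysis-window enforcement
  writeLines(c("record_id,date,x,y,cause", "k1,2014-05-01,1,1,hunt"), tmp)
  expect_error(
    read_kill_records(tmp, window = as.Date(c("2002-01-01", "2010-12-31")),
                      quiet = TRUE),
    "analysis window")
})

test_that("a permit-registry-sized fixture keeps its 200/133 cause split", {
  # one registry row per permit; each row is exactly one death
  set.seed(77)
  rec <- tibble::tibble(
    record_id = sprintf("K%03d", 1:333),
    date = as.Date("2002-01-01") + sample.int(3200, 333, TRUE),
    x = runif(333, 0, 250), y = runif(333, 0, 200),
    cause = rep(c("retaliatory", "hunt"), times = c(200, 133))
  )
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_kill_records(rec, tmp)
  back <- read_kill_records(tmp, quiet = TRUE)
  expect_equal(attr(back, "counts"), c(retaliatory = 200L, hunt = 133L))
  expect_equal(nrow(back), 333)
})

test_that("suitability raster reader validates, clamps, and round-trips bitwise", {
  tmp <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 3.1622776601683795", "NODATA_value -9999",
               "0 0.5", "1 1"), tmp)
  r <- read_suitability(tmp)
  expect_equal(sort(as.vector(r$values)), c(0, 0.5, 1, 1))

  writeLines(c("ncols 1", "nrows 1", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "NODATA_value -9999", "1.2"), tmp)
  expect_error(read_suitability(tmp), "outside")

  # a hair over 1 is clamped, not rejected
  writeLines(c("ncols 1", "nrows 1", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "NODATA_value -9999",
               sprintf("%.17g", 1 + 1e-12)), tmp)
  expect_equal(read_suitability(tmp)$values[1, 1], 1)

  expect_error(read_suitability("nope.tif"), "does not exist")

  # synthetic surface bitwise roundtrip
  r2 <- gen_suitability(sim_config(seed = 5))
  p2 <- withr::local_tempfile(fileext = ".asc")
  write_raster_ascii(r2, p2)
  back <- read_suitability(p2)
  expect_identical(back$values, r2$values)
  expect_identical(back$origin, r2$origin)
})

test_that("cell geometries serialise to valid GeoJSON", {
  g <- merge_small_cells(build_grid(rect_poly(0, 120, 0, 100), 2500))
  p <- withr::local_tempfile(fileext = ".geojson")
  write_cells_geojson(g, p)
  gj <- jsonlite::read_json(p)
  expect_equal(gj$type, "FeatureCollection")
  expect_equal(length(gj$features), nrow(g))
  expect_equal(gj$features[[1]]$geometry$type, "MultiPolygon")
})
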