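test_that("crown polygons join to field records, tolerating missing matches", {
  dir <- withr::local_tempdir()
  crowns <- data.frame(individual_id = c("A1", "A2", "A3"),
                       xmin = c(1, 5, 10), ymin = c(1, 5, 10),
                       xmax = c(3, 8, 12), ymax = c(2, 7, 13))
  gj <- file.path(dir, "crowns.geojson")
  write_crowns_geojson(crowns, gj)
  field <- data.frame(individual_id = c("A1", "A2", "A3"),
                      taxon_code = c("PIPA2", "QURU", "ACRU"),
                      site_id = "OSBS", plot_id = "P1")
  fcsv <- file.path(dir, "field.csv")
  write.csv(field, fcsv, row.names = FALSE)

  rec <- load_crowns(gj, fcsv)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$taxon_code, c("PIPA2", "QURU", "ACRU"))
  expect_equal(rec$xmax - rec$xmin, c(2, 3, 2))

  # a polygon with no field match is retained with NA taxon, with a warning
  write.csv(field[1:2, ], fcsv, row.names = FALSE)
  expect_warning(rec2 <- load_crowns(gj, fcsv), "no field-data match")
  expect_equal(nrow(rec2), 3)
  expect_true(is.na(rec2$taxon_code[3]))

  # empty vector file yields an empty collection, not an error
  write_crowns_geojson(crowns[0, ], gj)
  expect_equal(nrow(load_crowns(gj, fcsv)), 0)
})

test_that("raster clipping covers exactly the cells with centers in the box", {
  tile <- raster_tile(array(runif(200 * 200 * 3), c(200, 200, 3)),
                      origin = c(0, 20), res = 0.1)
  expect_equal(dim(clip_raster(tile, c(1, 1, 4, 3))$values), c(20, 30, 3))
  # a box covering a single cell center
  expect_equal(dim(clip_raster(tile, c(0.51, 0.51, 0.59, 0.59))$values), c(1, 1, 3))
  expect_error(clip_raster(tile, c(30, 30, 35, 35)), "does not cover")
})

test_that("centroid pixel follows the half-open row-north-down convention", {
  tile <- raster_tile(array(0, c(20, 20, 1)), origin = c(0, 20), res = 1)
  # centroid (5.4, 12.1): 5.4 m east, 7.9 m south of the NW corner ->
  # 1-based cell (8, 6) (the 0-based oracle arithmetic gives row 7, col 5)
  expect_equal(centroid_pixel(tile, c(4.9, 11.6, 5.9, 12.6)),
               c(row = 8L, col = 6L))
  # box centered exactly on a cell center
  expect_equal(centroid_pixel(tile, c(2, 16, 3, 17)), c(row = 4L, col = 3L))
  # centroid on a cell edge belongs to the larger index along that axis
  expect_equal(centroid_pixel(tile, c(1, 17, 3, 19)), c(row = 3L, col = 3L))
  expect_error(centroid_pixel(tile, c(25, 25, 27, 27)), "outside")
})

test_that("clipping then locating the centroid matches the unclipped tile", {
  tile <- raster_tile(array(runif(50 * 50), c(50, 50, 1)),
                      origin = c(100, 250), res = 0.5)
  withr::with_seed(42, {
    for (i in 1:20) {
      x0 <- runif(1, 100.5, 120); y0 <- runif(1, 226, 245)
      bb <- c(x0, y0, x0 + runif(1, 1, 4), y0 + runif(1, 1, 4))
      full <- centroid_pixel(tile, bb)
      clipped <- clip_raster(tile, bb)
      sub <- centroid_pixel(clipped, bb)
      off_r <- round((tile$origin[2] - clipped$origin[2]) / tile$res)
      off_c <- round((clipped$origin[1] - tile$origin[1]) / tile$res)
      expect_equal(sub + c(off_r, off_c), full, ignore_attr = TRUE)
    }
  })
})

test_that("individual splits are exhaustive, disjoint and deterministic", {
  rec <- data.frame(individual_id = sprintf("I%03d", 1:100))
  sp <- split_individuals(rec, 0.75, seed = 3)
  expect_equal(nrow(sp$train), 75)
  expect_equal(nrow(sp$holdout), 25)
  expect_identical(sp, split_individuals(rec, 0.75, seed = 3))
  expect_equal(nrow(split_individuals(rec[1:10, , drop = FALSE], 0.8, seed = 1)$train), 8)
  withr::with_seed(8, {
    for (i in 1:10) {
      n <- sample(5:60, 1); f <- runif(1, 0.1, 0.9)
      r <- data.frame(individual_id = sprintf("I%03d", seq_len(n)))
      s <- split_individuals(r, f, seed = i)
      ids <- c(s$train$individual_id, s$holdout$individual_id)
      expect_setequal(ids, r$individual_id)
      expect_equal(length(ids), n)  # disjoint cover
      expect_equal(nrow(s$train), round(f * n))
    }
  })
  expect_error(split_individuals(rec, 1.2), "fraction")
})

test_that("raster tiles and point clouds round-trip through disk", {
  dir <- withr::local_tempdir()
  hs <- raster_tile(array(round(runif(5 * 5 * 30) * 10000), c(5, 5, 30)),
                    origin = c(0, 5), res = 1)
  pth <- file.path(dir, "hs.csv")
  write_raster_tile(hs, pth, metadata = list(wavelengths_nm = 1:30))
  back <- read_raster_tile(pth)
  expect_equal(back$values, hs$values)
  expect_equal(back$origin, hs$origin)
  expect_equal(attr(back, "metadata")$wavelengths_nm, 1:30)

  rgb <- raster_tile(array(runif(8 * 8 * 3), c(8, 8, 3)), origin = c(0, 8), res = 1)
  tp <- file.path(dir, "rgb.tif")
  write_raster_tile(rgb, tp)
  expect_equal(read_raster_tile(tp)$values, rgb$values, tolerance = 1e-4)

  pts <- data.frame(x = runif(20), y = runif(20), h = rnorm(20, 10))
  xp <- file.path(dir, "p.xyz")
  write_xyz(pts, xp)
  expect_equal(read_xyz(xp), pts, tolerance = 1e-12, ignore_attr = TRUE)
})
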