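test_that("affine transforms invert exactly", {
  tr <- c(origin_x = 0, origin_y = 0, px_w = 1, px_h = 1)
  expect_equal(world_to_pixel(tr, c(0, 0)), c(col = 0, row = 0))

  tr <- c(origin_x = 0, origin_y = 0, px_w = 0.00418, px_h = 0.00418)
  expect_equal(world_to_pixel(tr, c(1, 0))[["col"]], 1 / 0.00418, tolerance = 1e-12)

  set.seed(11)
  tr <- c(origin_x = -310.2, origin_y = 5123.7, px_w = 0.00418, px_h = 0.00418)
  pts <- cbind(stats::runif(200, -500, 500), stats::runif(200, 4000, 6000))
  back <- pixel_to_world(tr, world_to_pixel(tr, pts))
  expect_lt(max(abs(back - pts)), 1e-9)
})

test_that("circular masks follow pixel-center containment", {
  r <- geo_raster(array(0L, c(5, 5, 3)), c(0, 5, 1, 1))
  m <- circular_mask(r, c(2.5, 2.5), 2)          # radius 1 m: plus-shape
  expect_equal(sum(m), 5L)
  expect_true(m[3, 3] && m[2, 3] && m[4, 3] && m[3, 2] && m[3, 4])

  expect_equal(sum(circular_mask(r, c(2.5, 2.5), 0.5)), 1L)  # sub-pixel circle
  expect_true(all(circular_mask(r, c(2.5, 2.5), 20)))        # covers everything
  expect_warning(circular_mask(r, c(100, 100), 1), "does not cover")

  # brute-force oracle on random rasters/circles
  set.seed(12)
  for (i in 1:20) {
    H <- sample(3:12, 1); W <- sample(3:12, 1)
    gsd <- stats::runif(1, 0.05, 2)
    r <- geo_raster(array(0L, c(H, W, 1)),
                    c(stats::runif(1, -5, 5), stats::runif(1, -5, 5), gsd, gsd))
    ctr <- pixel_to_world(r$transform, c(stats::runif(1, 0, W), stats::runif(1, 0, H)))
    d <- stats::runif(1, 0.5, 6) * gsd
    expect_identical(suppressWarnings(circular_mask(r, ctr, d)),
                     mask_oracle(r, ctr, d))
  }
})

test_that("per-tree tiles crop, mask and georeference correctly", {
  r <- geo_raster(array(7L, c(40, 40, 3)), c(0, 4, 0.1, 0.1))
  tree <- list(tree_id = "t1", x = 2, y = 2)
  tile <- crop_tree_tile(r, tree, 1)
  expect_equal(sum(tile$raster$pixels), 7 * sum(tile$mask) * 3)
  expect_true(all(dim(tile$mask) %in% (ceiling(1 / 0.1) + c(-1, 0, 1))))

  # window offset preserves world position of the tile origin
  off_world <- pixel_to_world(r$transform, as.numeric(tile$window_offset))
  expect_equal(unname(off_world),
               unname(tile$raster$transform[c("origin_x", "origin_y")]))

  # masking is idempotent: cropping the tile with the same circle changes nothing
  tile2 <- crop_tree_tile(tile$raster, tree, 1)
  expect_identical(tile$raster$pixels, tile2$raster$pixels)
  expect_identical(tile$raster$transform, tile2$raster$transform)

  expect_error(crop_tree_tile(r, list(tree_id = "far", x = 99, y = 99), 1), "far")
})

test_that("raster I/O round-trips pixels, transform and crs", {
  r <- geo_raster(array(sample(0:255, 18 * 25 * 3, TRUE), c(18, 25, 3)),
                  c(12.5, -40, 0.25, 0.25), crs = "EPSG:32631")
  path <- file.path(withr::local_tempdir(), "r.tif")
  write_raster(r, path)
  r2 <- read_raster(path)
  expect_identical(r$pixels, r2$pixels)
  expect_equal(r$transform, r2$transform)
  expect_identical(r$crs, r2$crs)
  expect_error(read_raster(file.path(tempdir(), "nope.tif")), "not found")
})

test_that("vector I/O round-trips geometries and attributes in both formats", {
  tmp <- withr::local_tempdir()
  pts <- geo_features(
    cbind(x = c(1.25, -2.5, 7), y = c(3, -4, 0.5)),
    data.frame(tree_id = c("a", "b", "c"), fruit_count = c(10L, 0L, 312L),
               stringsAsFactors = FALSE),
    "point", crs = "EPSG:32631"
  )
  for (ext in c("geojson", "shp")) {
    p <- file.path(tmp, paste0("pts.", ext))
    res <- write_vector(pts, p)
    back <- read_vector(p)
    # shapefiles truncate names > 10 chars; the mapping is returned on write
    nm <- if (ext == "shp") attr(res, "name_map") else
      stats::setNames(names(pts$attributes), names(pts$attributes))
    expect_equal(unname(back$geometry), unname(pts$geometry))
    expect_equal(back$attributes[[nm[["tree_id"]]]], pts$attributes$tree_id)
    expect_equal(as.integer(back$attributes[[nm[["fruit_count"]]]]),
                 pts$attributes$fruit_count)
    expect_identical(back$crs, pts$crs)
  }

  poly <- geo_features(
    list(rbind(c(0, 0), c(2, 0), c(2, 1), c(0, 1)),
         rbind(c(5, 5), c(6, 5), c(6, 7), c(5, 7))),
    data.frame(row_index = 1:2, fruit_count = c(12L, 40L)),
    "polygon"
  )
  p <- file.path(tmp, "poly.shp")
  res <- write_vector(poly, p)
  back <- read_vector(p)
  nm <- attr(res, "name_map")
  expect_equal(back$geometry, poly$geometry)
  expect_equal(back$attributes[[nm[["fruit_count"]]]], poly$attributes$fruit_count)

  expect_error(write_vector(pts, file.path(tmp, "x.kml")), "unknown vector extension")
})

test_that("shapefile field names obey the 10-character limit with a mapping", {
  nm <- shapefile_field_names(c("tree_id", "a_very_long_attribute", "a_very_long_attr2"))
  expect_true(all(nchar(nm) <= 10))
  expect_false(anyDuplicated(nm) > 0)
  expect_equal(names(nm), c("tree_id", "a_very_long_attribute", "a_very_long_attr2"))
  expect_equal(nm[["tree_id"]], "tree_id")

  tmp <- withr::local_tempdir()
  f <- geo_features(cbind(x = 1, y = 2),
                    data.frame(an_extremely_long_count_name = 5L),
                    "point")
  res <- write_vector(f, file.path(tmp, "t.shp"))
  map <- attr(res, "name_map")
  expect_equal(unname(nchar(map)), 10L)
  back <- read_vector(file.path(tmp, "t.shp"))
  expect_equal(names(back$attributes), unname(map))
})
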