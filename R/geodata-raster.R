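#' Georeferenced 8-bit raster
#'
#' A minimal in-memory raster container: an H x W x C integer pixel array
#' (values 0-255) bound to world coordinates by a shear-free, north-up affine
#' transform. World x increases with pixel column, world y decreases with pixel
#' row. Continuous pixel coordinates are 0-based with (0, 0) at the outer
#' corner of the top-left pixel, so pixel centers sit at half-integers.
#'
#' @param pixels numeric or integer array, H x W (greyscale) or H x W x C;
#'   values are clamped/rounded to 0-255.
#' @param transform numeric, `c(origin_x, origin_y, px_w, px_h)`: world
#'   coordinates of the raster's top-left corner and pixel size in meters.
#'   Both pixel sizes are positive magnitudes; rotation/shear is not supported.
#' @param crs opaque coordinate reference system tag (character), carried
#'   through I/O unchanged. Empty string means "unspecified planar meters".
#' @return an object of class `geo_raster` with fields `pixels`, `transform`,
#'   `crs`.
#' @export
geo_raster <- function(pixels, transform, crs = "") {
  if (length(dim(pixels)) == 2L) dim(pixels) <- c(dim(pixels), 1L)
  if (length(dim(pixels)) != 3L) stopf("pixels must be an H x W or H x W x C array")
  if (any(dim(pixels)[1:2] < 1L)) stopf("raster must have H >= 1 and W >= 1")
  transform <- as.numeric(transform)
  if (length(transform) != 4L) {
    stopf("transform must be c(origin_x, origin_y, px_w, px_h)")
  }
  if (transform[3] <= 0 || transform[4] <= 0) stopf("pixel sizes must be > 0")
  names(transform) <- c("origin_x", "origin_y", "px_w", "px_h")
  structure(
    list(pixels = as_uint8(pixels), transform = transform, crs = as.character(crs)),
    class = "geo_raster"
  )
}

#' @export
print.geo_raster <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<geo_raster> %d x %d px, %d band(s), %.6g m/px, origin (%.3f, %.3f)%s\n",
    d[1], d[2], d[3], x$transform[["px_w"]],
    x$transform[["origin_x"]], x$transform[["origin_y"]],
    if (nzchar(x$crs)) paste0(", crs: ", x$crs) else ""
  ))
  invisible(x)
}

raster_dim <- function(raster) dim(raster$pixels)[1:2]

#' World to pixel coordinates
#'
#' Invert the raster affine: world (x, y) to continuous 0-based pixel
#' (col, row). The exact inverse of [pixel_to_world()].
#'
#' @param transform affine as in [geo_raster()] (a `geo_raster` is also
#'   accepted).
#' @param xy numeric length-2 vector or an n x 2 matrix of world coordinates.
#' @return matching shape of continuous (col, row) coordinates.
#' @export
world_to_pixel <- function(transform, xy) {
  tr <- if (inherits(transform, "geo_raster")) transform$transform else transform
  m <- matrix(as.numeric(xy), ncol = 2)
  out <- cbind(
    col = (m[, 1] - tr[["origin_x"]]) / tr[["px_w"]],
    row = (tr[["origin_y"]] - m[, 2]) / tr[["px_h"]]
  )
  if (is.null(dim(xy)) && length(xy) == 2L) drop(out) else out
}

#' Pixel to world coordinates
#'
#' @param transform affine as in [geo_raster()].
#' @param colrow continuous 0-based (col, row), vector or n x 2 matrix.
#' @return world (x, y), matching shape.
#' @export
pixel_to_world <- function(transform, colrow) {
  tr <- if (inherits(transform, "geo_raster")) transform$transform else transform
  m <- matrix(as.numeric(colrow), ncol = 2)
  out <- cbind(
    x = tr[["origin_x"]] + m[, 1] * tr[["px_w"]],
    y = tr[["origin_y"]] - m[, 2] * tr[["px_h"]]
  )
  if (is.null(dim(colrow)) && length(colrow) == 2L) drop(out) else out
}

# World coordinates of pixel centers for 0-based rows/cols (vectors).
pixel_center_xy <- function(transform, cols, rows) {
  list(
    x = transform[["origin_x"]] + (cols + 0.5) * transform[["px_w"]],
    y = transform[["origin_y"]] - (rows + 0.5) * transform[["px_h"]]
  )
}

#' Circular mask over a raster
#'
#' Rasterize a circle: a pixel belongs to the mask iff the world distance from
#' its center to `center_world` is at most `diameter_m / 2` (pixel-center
#' containment, the common zonal-statistics convention).
#'
#' @param raster a [geo_raster()].
#' @param center_world world (x, y) of the circle center.
#' @param diameter_m circle diameter in meters.
#' @return logical H x W matrix. Warns if the circle misses the raster
#'   entirely (all-FALSE mask).
#' @export
circular_mask <- function(raster, center_world, diameter_m) {
  if (diameter_m <= 0) stopf("diameter_m must be > 0")
  d <- raster_dim(raster)
  tr <- raster$transform
  cx <- tr[["origin_x"]] + (seq_len(d[2]) - 0.5) * tr[["px_w"]]
  cy <- tr[["origin_y"]] - (seq_len(d[1]) - 0.5) * tr[["px_h"]]
  r2 <- (diameter_m / 2)^2
  dx2 <- (cx - center_world[1])^2
  dy2 <- (cy - center_world[2])^2
  mask <- outer(dy2, dx2, `+`) <= r2
  if (!any(mask)) warnf("circle at (%g, %g) does not cover any pixel center", center_world[1], center_world[2])
  mask
}

#' Crop a circular per-tree tile from a raster
#'
#' The per-tree pre-processing step: a circular mask of `diameter_m` centered
#' on the tree's coordinates selects canopy pixels while avoiding canopy
#' edges; the tile is the tight bounding window of that mask with all
#' out-of-circle pixels set to 0 (black) in every channel. The tile keeps a
#' shifted affine so its georeference is exact, plus the (col, row) offset of
#' its origin in the parent raster.
#'
#' @param raster a [geo_raster()].
#' @param tree a list or one-row data frame with `tree_id`, `x`, `y` (world
#'   meters).
#' @param diameter_m mask diameter in meters (default 1).
#' @return a `tree_tile`: list with `tree_id`, `raster` (cropped
#'   [geo_raster()]), `mask` (logical, tile-sized), `window_offset`
#'   (0-based c(col, row) in the parent).
#' @export
crop_tree_tile <- function(raster, tree, diameter_m = 1) {
  mask <- suppressWarnings(circular_mask(raster, c(tree$x, tree$y), diameter_m))
  if (!any(mask)) stopf("tree '%s' does not intersect the raster", tree$tree_id)
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  sub <- raster$pixels[rows[1]:rows[2], cols[1]:cols[2], , drop = FALSE]
  m <- mask[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  sub <- sub * as.integer(rep(m, times = dim(sub)[3]))
  tr <- raster$transform
  tile_tr <- c(
    tr[["origin_x"]] + (cols[1] - 1) * tr[["px_w"]],
    tr[["origin_y"]] - (rows[1] - 1) * tr[["px_h"]],
    tr[["px_w"]], tr[["px_h"]]
  )
  structure(
    list(
      tree_id = tree$tree_id,
      raster = geo_raster(sub, tile_tr, raster$crs),
      mask = m,
      window_offset = c(col = cols[1] - 1L, row = rows[1] - 1L)
    ),
    class = "tree_tile"
  )
}

#' Write a georeferenced raster
#'
#' Pixels go to an 8-bit TIFF; the affine goes to an ESRI world file (`.tfw`)
#' whose 6 lines are the pixel sizes and the world coordinates of the CENTER
#' of the top-left pixel; a non-empty CRS tag goes to a `.prj` sidecar,
#' verbatim.
#'
#' @param raster a [geo_raster()].
#' @param path output path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path) {
  tr <- raster$transform
  tiff::writeTIFF(raster$pixels / 255, path, bits.per.sample = 8L)
  tfw <- c(
    tr[["px_w"]], 0, 0, -tr[["px_h"]],
    tr[["origin_x"]] + tr[["px_w"]] / 2,
    tr[["origin_y"]] - tr[["px_h"]] / 2
  )
  writeLines(sprintf("%.12g", tfw), sidecar_path(path, "tfw"))
  if (nzchar(raster$crs)) writeLines(raster$crs, sidecar_path(path, "prj"))
  invisible(path)
}

#' Read a georeferenced raster written by [write_raster()]
#'
#' @param path path to a `.tif` with a `.tfw` world file alongside.
#' @return a [geo_raster()].
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stopf("raster file not found: %s", path)
  px <- tiff::readTIFF(path)
  tfw_path <- sidecar_path(path, "tfw")
  if (!file.exists(tfw_path)) stopf("world file not found: %s", tfw_path)
  tfw <- as.numeric(readLines(tfw_path))
  if (length(tfw) != 6 || anyNA(tfw)) stopf("malformed world file: %s", tfw_path)
  if (tfw[2] != 0 || tfw[3] != 0) stopf("rotated rasters are not supported: %s", tfw_path)
  prj <- sidecar_path(path, "prj")
  crs <- if (file.exists(prj)) paste(readLines(prj), collapse = "\n") else ""
  transform <- c(tfw[5] - tfw[1] / 2, tfw[6] - tfw[4] / 2, tfw[1], -tfw[4])
  geo_raster(px * 255, transform, crs)
}

sidecar_path <- function(path, ext) {
  paste0(tools::file_path_sans_ext(path), ".", ext)
}
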