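# Minimal ESRI Shapefile codec (point / polyline / polygon, 2-D, no M/Z).
#
# The .shp/.shx pair is written and read directly (the format is a fixed
# binary layout: a 100-byte header, then per-record headers in big-endian and
# record contents in little-endian); the .dbf attribute table is delegated to
# foreign::write.dbf / read.dbf, and a non-empty CRS tag is carried in a .prj
# sidecar verbatim. Only shape types 1 (Point), 3 (PolyLine) and 5 (Polygon)
# are supported, which covers every layer this package emits.

SHP_TYPE <- c(point = 1L, polyline = 3L, polygon = 5L)

#' Truncate attribute names to the shapefile 10-character limit
#'
#' DBF field names are at most 10 bytes. Longer names are truncated and made
#' unique by replacing the tail with a counter when truncation collides.
#'
#' @param nms character vector of attribute names.
#' @return named character vector: `names()` are the original names, values
#'   the (possibly truncated) written names.
#' @export
shapefile_field_names <- function(nms) {
  out <- substr(nms, 1L, 10L)
  while (anyDuplicated(out)) {
    dup <- duplicated(out) | duplicated(out, fromLast = TRUE)
    idx <- which(dup)
    for (k in seq_along(idx)) {
      i <- idx[k]
      suffix <- as.character(k)
      out[i] <- paste0(substr(out[i], 1L, 10L - nchar(suffix)), suffix)
    }
  }
  stats::setNames(out, nms)
}

write_shapefile <- function(features, path) {
  type <- SHP_TYPE[[features$geom_type]]
  n <- n_features(features)
  geoms <- if (features$geom_type == "point") {
    lapply(seq_len(n), function(i) features$geometry[i, , drop = FALSE])
  } else {
    features$geometry
  }

  # per-record content bytes (shape type int32 included)
  content_bytes <- vapply(geoms, function(g) {
    if (type == 1L) 20L else 44L + 4L + 16L * nrow(g)
  }, integer(1))
  content_words <- content_bytes %/% 2L
  offsets_words <- cumsum(c(50L, utils::head(content_words, -1L) + 4L))  # record starts
  total_words <- 50L + sum(content_words + 4L)

  all_xy <- do.call(rbind, geoms)
  box <- c(min(all_xy[, 1]), min(all_xy[, 2]), max(all_xy[, 1]), max(all_xy[, 2]))

  write_header <- function(con, length_words) {
    writeBin(c(9994L, 0L, 0L, 0L, 0L, 0L, length_words), con, size = 4, endian = "big")
    writeBin(c(1000L, type), con, size = 4, endian = "little")
    writeBin(c(box, 0, 0, 0, 0), con, size = 8, endian = "little")
  }

  shp <- file(path, "wb")
  on.exit(close(shp), add = TRUE)
  write_header(shp, total_words)
  for (i in seq_len(n)) {
    g <- geoms[[i]]
    writeBin(c(i, content_words[i]), shp, size = 4, endian = "big")
    writeBin(type, shp, size = 4, endian = "little")
    if (type == 1L) {
      writeBin(as.numeric(g[1, ]), shp, size = 8, endian = "little")
    } else {
      writeBin(c(min(g[, 1]), min(g[, 2]), max(g[, 1]), max(g[, 2])),
               shp, size = 8, endian = "little")
      writeBin(c(1L, nrow(g), 0L), shp, size = 4L, endian = "little")
      writeBin(as.numeric(t(g)), shp, size = 8, endian = "little")
    }
  }

  shx <- file(sidecar_path(path, "shx"), "wb")
  on.exit(close(shx), add = TRUE)
  write_header(shx, 50L + 4L * n)
  for (i in seq_len(n)) {
    writeBin(as.integer(c(offsets_words[i], content_words[i])), shx, size = 4, endian = "big")
  }

  name_map <- shapefile_field_names(names(features$attributes))
  attrs <- features$attributes
  names(attrs) <- unname(name_map)
  foreign::write.dbf(attrs, sidecar_path(path, "dbf"))
  if (nzchar(features$crs)) writeLines(features$crs, sidecar_path(path, "prj"))
  invisible(structure(path, name_map = name_map))
}

read_shapefile <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (!identical(magic, 9994L)) stopf("%s: not a shapefile (bad magic %d)", path, magic)
  readBin(con, "integer", 5, size = 4, endian = "big")
  length_words <- readBin(con, "integer", 1, size = 4, endian = "big")
  version <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!identical(version, 1000L)) stopf("%s: unsupported shapefile version %d", path, version)
  type <- readBin(con, "integer", 1, size = 4, endian = "little")
  geom_type <- names(SHP_TYPE)[match(type, SHP_TYPE)]
  if (is.na(geom_type)) stopf("%s: unsupported shape type %d", path, type)
  readBin(con, "numeric", 8, size = 8, endian = "little")  # bbox + zm ranges

  geoms <- list()
  remaining <- length_words - 50L
  while (remaining > 0L) {
    readBin(con, "integer", 1, size = 4, endian = "big")  # record number
    clen <- readBin(con, "integer", 1, size = 4, endian = "big")
    rtype <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (rtype != type) stopf("%s: mixed shape types (%d vs %d)", path, rtype, type)
    if (type == 1L) {
      xy <- readBin(con, "numeric", 2, size = 8, endian = "little")
      geoms[[length(geoms) + 1L]] <- matrix(xy, ncol = 2)
    } else {
      readBin(con, "numeric", 4, size = 8, endian = "little")  # box
      counts <- readBin(con, "integer", 2, size = 4, endian = "little")
      nparts <- counts[1]; npts <- counts[2]
      if (nparts != 1L) stopf("%s: multi-part records are not supported", path)
      readBin(con, "integer", nparts, size = 4, endian = "little")
      pts <- readBin(con, "numeric", 2 * npts, size = 8, endian = "little")
      geoms[[length(geoms) + 1L]] <- matrix(pts, ncol = 2, byrow = TRUE)
    }
    remaining <- remaining - 4L - clen
  }

  attrs <- foreign::read.dbf(sidecar_path(path, "dbf"), as.is = TRUE)
  prj <- sidecar_path(path, "prj")
  crs <- if (file.exists(prj)) paste(readLines(prj), collapse = "\n") else ""
  geometry <- if (geom_type == "point") do.call(rbind, geoms) else geoms
  geo_features(geometry, attrs, geom_type, crs)
}
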