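#' Vector feature collection
#'
#' A lightweight container for the vector layers the pipeline reads and
#' writes: tree points, per-tree yield points, per-row yield polygons. All
#' features in one collection share a geometry type.
#'
#' @param geometry for `"point"`, an n x 2 matrix (or data frame) of (x, y);
#'   for `"polyline"`/`"polygon"`, a list of n_i x 2 coordinate matrices (one
#'   per feature; polygon rings must be closed, first vertex == last vertex).
#' @param attributes data frame with one row per feature.
#' @param geom_type `"point"`, `"polyline"` or `"polygon"`.
#' @param crs opaque CRS tag carried to outputs (empty = unspecified).
#' @return an object of class `geo_features`.
#' @export
geo_features <- function(geometry, attributes,
                         geom_type = c("point", "polyline", "polygon"),
                         crs = "") {
  geom_type <- match.arg(geom_type)
  if (geom_type == "point") {
    geometry <- as.matrix(as.data.frame(geometry))
    storage.mode(geometry) <- "double"
    if (ncol(geometry) != 2L) stopf("point geometry must be n x 2")
    n <- nrow(geometry)
  } else {
    if (!is.list(geometry)) stopf("%s geometry must be a list of coordinate matrices", geom_type)
    geometry <- lapply(geometry, function(g) {
      g <- as.matrix(g)
      storage.mode(g) <- "double"
      if (ncol(g) != 2L) stopf("coordinate matrices must be n x 2")
      if (geom_type == "polygon" && !all(g[1, ] == g[nrow(g), ])) {
        g <- rbind(g, g[1, , drop = FALSE])  # close the ring
      }
      g
    })
    n <- length(geometry)
  }
  attributes <- as.data.frame(attributes, stringsAsFactors = FALSE)
  if (nrow(attributes) != n) stopf("attributes (%d rows) do not match geometry (%d features)", nrow(attributes), n)
  structure(
    list(geom_type = geom_type, geometry = geometry, attributes = attributes, crs = as.character(crs)),
    class = "geo_features"
  )
}

#' @export
print.geo_features <- function(x, ...) {
  n <- if (x$geom_type == "point") nrow(x$geometry) else length(x$geometry)
  cat(sprintf("<geo_features> %d %s feature(s); attributes: %s\n",
              n, x$geom_type, paste(names(x$attributes), collapse = ", ")))
  invisible(x)
}

n_features <- function(x) if (x$geom_type == "point") nrow(x$geometry) else length(x$geometry)

#' Write a vector layer (GeoJSON or ESRI Shapefile)
#'
#' The format is chosen by extension: `.geojson`/`.json` or `.shp`.
#' Shapefile attribute names longer than 10 characters are truncated (made
#' unique) as the format requires; the mapping is returned as the
#' `name_map` attribute of the result.
#'
#' @param features a [geo_features()].
#' @param path output path.
#' @return `path` invisibly, with a `name_map` attribute (named character
#'   vector, original -> written) for shapefiles.
#' @export
write_vector <- function(features, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    geojson = ,
    json = write_geojson(features, path),
    shp = write_shapefile(features, path),
    stopf("unknown vector extension '.%s' (use .geojson or .shp)", ext)
  )
}

#' Read a vector layer (GeoJSON or ESRI Shapefile)
#'
#' @param path input path (`.geojson`/`.json` or `.shp`).
#' @return a [geo_features()].
#' @export
read_vector <- function(path) {
  if (!file.exists(path)) stopf("vector file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    geojson = ,
    json = read_geojson(path),
    shp = read_shapefile(path),
    stopf("unknown vector extension '.%s' (use .geojson or .shp)", ext)
  )
}

# ---- GeoJSON ----------------------------------------------------------------

write_geojson <- function(features, path) {
  n <- n_features(features)
  feats <- lapply(seq_len(n), function(i) {
    geom <- switch(features$geom_type,
      point = list(type = "Point", coordinates = as.numeric(features$geometry[i, ])),
      polyline = list(type = "LineString", coordinates = features$geometry[[i]]),
      polygon = list(type = "Polygon", coordinates = list(features$geometry[[i]]))
    )
    props <- lapply(features$attributes[i, , drop = FALSE], function(v) v[[1]])
    list(type = "Feature", geometry = geom, properties = props)
  })
  fc <- list(type = "FeatureCollection", features = feats)
  if (nzchar(features$crs)) {
    fc$crs <- list(type = "name", properties = list(name = features$crs))
  }
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

read_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  if (is.null(fc$type) || fc$type != "FeatureCollection") stopf("%s: not a GeoJSON FeatureCollection", path)
  crs <- if (!is.null(fc$crs$properties$name)) fc$crs$properties$name else ""
  feats <- fc$features
  if (length(feats) == 0L) stopf("%s: empty FeatureCollection", path)
  gtype <- feats[[1]]$geometry$type
  geom_type <- switch(gtype,
    Point = "point", LineString = "polyline", Polygon = "polygon",
    stopf("%s: unsupported geometry type '%s'", path, gtype)
  )
  coords <- lapply(feats, function(f) {
    cc <- f$geometry$coordinates
    switch(geom_type,
      point = as.numeric(unlist(cc)),
      polyline = do.call(rbind, lapply(cc, function(p) as.numeric(unlist(p)))),
      polygon = do.call(rbind, lapply(cc[[1]], function(p) as.numeric(unlist(p))))
    )
  })
  attrs <- do.call(rbind, lapply(feats, function(f) {
    as.data.frame(lapply(f$properties, function(v) if (is.null(v)) NA else v),
                  stringsAsFactors = FALSE)
  }))
  geometry <- if (geom_type == "point") do.call(rbind, coords) else coords
  geo_features(geometry, attrs, geom_type, crs)
}
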