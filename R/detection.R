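#' Reference detector parameters
#'
#' Thresholds for the deterministic colour-blob reference detector that
#' stands behind the pluggable detector contract. The detector selects
#' red-hued, sufficiently saturated pixels, labels connected components, and
#' keeps components whose area and compactness look fruit-like.
#'
#' @param hue_window `c(lo, hi)` in degrees on the colour wheel; `lo > hi`
#'   wraps through 0 (the default selects reds).
#' @param min_saturation,min_value HSV thresholds in [0, 1].
#' @param area_range_px `c(min, max)` component area in pixels.
#' @param min_circularity minimum compactness `4 * pi * A / P^2`, with the
#'   perimeter P counted as exposed pixel edges; in [0, 1-ish].
#' @param nms_iou IoU above which a lower-scored box is suppressed.
#' @param score_floor default score threshold used when counting.
#' @return a `detector_params` list.
#' @export
detector_params <- function(hue_window = c(330, 30),
                            min_saturation = 0.35,
                            min_value = 0.15,
                            area_range_px = c(3, 5000),
                            min_circularity = 0.3,
                            nms_iou = 0.3,
                            score_floor = 0.5) {
  if (area_range_px[1] > area_range_px[2]) stopf("area_range_px must be ordered")
  for (v in c(min_saturation, min_value, min_circularity, nms_iou, score_floor)) {
    if (v < 0 || v > 1) stopf("thresholds must lie in [0, 1]")
  }
  structure(
    list(hue_window = hue_window, min_saturation = min_saturation,
         min_value = min_value, area_range_px = area_range_px,
         min_circularity = min_circularity, nms_iou = nms_iou,
         score_floor = score_floor),
    class = "detector_params"
  )
}

#' Detection set
#'
#' Scored boxes for one image, sorted by descending score with ties broken
#' by (ymin, xmin) — the canonical ordering every detector implementation
#' must produce.
#'
#' @param image_id image identifier.
#' @param width,height image size.
#' @param boxes data frame of boxes with a `score` column in [0, 1].
#' @return an [annotation_set()] with class `detection_set` prepended.
#' @export
detection_set <- function(image_id, width, height, boxes = NULL) {
  if (!is.null(boxes) && nrow(boxes) > 0L) {
    if (any(is.na(boxes$score)) || any(boxes$score < 0) || any(boxes$score > 1)) {
      stopf("detection scores must be in [0, 1]")
    }
    boxes <- boxes[order(-boxes$score, boxes$ymin, boxes$xmin), , drop = FALSE]
  }
  out <- annotation_set(image_id, width, height, boxes)
  class(out) <- c("detection_set", class(out))
  out
}

# Component perimeter as exposed pixel edges (4-neighbourhood), per label.
component_perimeters <- function(lab) {
  H <- nrow(lab); W <- ncol(lab)
  pad <- matrix(0L, H + 2L, W + 2L)
  pad[2:(H + 1), 2:(W + 1)] <- lab
  core <- pad[2:(H + 1), 2:(W + 1)]
  exposed <- (core != pad[1:H, 2:(W + 1)]) + (core != pad[3:(H + 2), 2:(W + 1)]) +
    (core != pad[2:(H + 1), 1:W]) + (core != pad[2:(H + 1), 3:(W + 2)])
  sel <- core > 0
  as.numeric(rowsum(as.numeric(exposed[sel]), core[sel]))
}

#' Deterministic colour-blob reference detector
#'
#' The classical pipeline standing in for a learned detector: RGB to HSV,
#' binary mask by hue/saturation/value thresholds, connected components,
#' filtering by area and compactness, one tight box per surviving component
#' with `score = min(1, circularity)`, then greedy [nms()]. Deterministic:
#' the same tile and parameters always give the same detections. The score
#' is a bounded shape-compactness index, not a calibrated probability.
#'
#' @param tile a [geo_raster()], `tree_tile`, or H x W x 3 array.
#' @param params a [detector_params()].
#' @return a [detection_set()].
#' @export
reference_blob_detect <- function(tile, params = detector_params()) {
  img <- tile_pixels(tile)
  H <- dim(img)[1]; W <- dim(img)[2]
  rgb <- matrix(as.numeric(img), ncol = 3L)
  hsv <- grDevices::rgb2hsv(t(rgb), maxColorValue = 255)
  hue <- hsv[1, ] * 360
  lo <- params$hue_window[1]; hi <- params$hue_window[2]
  in_hue <- if (lo <= hi) hue >= lo & hue <= hi else hue >= lo | hue <= hi
  mask <- in_hue & hsv[2, ] >= params$min_saturation & hsv[3, ] >= params$min_value
  mask_m <- matrix(mask, nrow = H, ncol = W)
  id <- tile_id(tile)
  if (!any(mask_m)) return(detection_set(id, W, H))

  lab <- EBImage::bwlabel(mask_m)
  areas <- tabulate(lab[lab > 0])
  perims <- component_perimeters(lab)
  circ <- 4 * pi * areas / perims^2
  keep <- which(areas >= params$area_range_px[1] & areas <= params$area_range_px[2] &
                  circ >= params$min_circularity)
  if (length(keep) == 0L) return(detection_set(id, W, H))

  idx <- which(lab > 0, arr.ind = TRUE)
  lv <- lab[lab > 0]
  boxes <- do.call(rbind, lapply(keep, function(k) {
    sel <- lv == k
    data.frame(
      xmin = min(idx[sel, 2]) - 1, ymin = min(idx[sel, 1]) - 1,
      xmax = max(idx[sel, 2]), ymax = max(idx[sel, 1]),
      label = "apple", score = min(1, circ[k]),
      stringsAsFactors = FALSE
    )
  }))
  nms(detection_set(id, W, H, boxes), params$nms_iou)
}

tile_pixels <- function(tile) {
  if (inherits(tile, "tree_tile")) tile$raster$pixels
  else if (inherits(tile, "geo_raster")) tile$pixels
  else tile
}

tile_id <- function(tile) {
  if (inherits(tile, "tree_tile")) as.character(tile$tree_id) else "tile"
}

#' Greedy non-maximum suppression
#'
#' Boxes are visited in descending score order (ties by ymin then xmin); a
#' box is suppressed iff its IoU with an already-kept box exceeds
#' `iou_thresh`.
#'
#' @param detections a [detection_set()] or a data frame of scored boxes.
#' @param iou_thresh suppression threshold in [0, 1].
#' @return same type as the input, with suppressed boxes removed.
#' @export
nms <- function(detections, iou_thresh) {
  is_set <- inherits(detections, "detection_set")
  b <- if (is_set) detections$boxes else detections
  if (nrow(b) > 1L) {
    b <- b[order(-b$score, b$ymin, b$xmin), , drop = FALSE]
    kept <- logical(nrow(b))
    for (i in seq_len(nrow(b))) {
      ok <- TRUE
      for (j in which(kept)) {
        if (iou(b[i, ], b[j, ]) > iou_thresh) {
          ok <- FALSE
          break
        }
      }
      kept[i] <- ok
    }
    b <- b[kept, , drop = FALSE]
  }
  if (is_set) detection_set(detections$image_id, detections$width, detections$height, b) else b
}

#' Count fruits per tree over a raster
#'
#' For each tree: crop its circular tile ([crop_tree_tile()]), run the
#' detector, and count boxes with `score >= score_floor`. A tree whose crop
#' fails (e.g. it misses the raster) gets an `NA` count and a warning; the
#' batch continues. Detections are reported in parent-raster pixel
#' coordinates.
#'
#' @param raster a [geo_raster()].
#' @param trees tree data frame (`tree_id`, `x`, `y`).
#' @param detector function mapping a tile to a [detection_set()]; defaults
#'   to [reference_blob_detect()] with default parameters.
#' @param diameter_m circular mask diameter (default 1 m).
#' @param score_floor minimum score for a detection to be counted.
#' @return list with `counts` (data frame `tree_id`, `count`) and
#'   `detections` (named list of [detection_set()] per tree, boxes offset to
#'   parent coordinates).
#' @export
count_per_tree <- function(raster, trees, detector = reference_blob_detect,
                           diameter_m = 1, score_floor = 0.5) {
  counts <- integer(nrow(trees))
  dets <- vector("list", nrow(trees))
  names(dets) <- trees$tree_id
  for (i in seq_len(nrow(trees))) {
    tile <- tryCatch(crop_tree_tile(raster, trees[i, ], diameter_m), error = identity)
    if (inherits(tile, "error")) {
      warnf("tree '%s': %s", trees$tree_id[i], conditionMessage(tile))
      counts[i] <- NA_integer_
      next
    }
    ds <- detector(tile)
    if (nrow(ds$boxes) > 0L) {
      ds$boxes$xmin <- ds$boxes$xmin + tile$window_offset[["col"]]
      ds$boxes$xmax <- ds$boxes$xmax + tile$window_offset[["col"]]
      ds$boxes$ymin <- ds$boxes$ymin + tile$window_offset[["row"]]
      ds$boxes$ymax <- ds$boxes$ymax + tile$window_offset[["row"]]
    }
    dets[[i]] <- ds
    counts[i] <- sum(ds$boxes$score >= score_floor)
  }
  list(
    counts = data.frame(tree_id = trees$tree_id, count = counts, stringsAsFactors = FALSE),
    detections = dets
  )
}

#' Write detections as CSV
#'
#' @param detections a [detection_set()] or named list of them.
#' @param path output CSV path (`image_id, xmin, ymin, xmax, ymax, score`).
#' @return `path`, invisibly.
#' @export
write_detections_csv <- function(detections, path) {
  if (inherits(detections, "detection_set")) detections <- list(detections)
  rows <- do.call(rbind, lapply(detections, function(d) {
    if (is.null(d) || nrow(d$boxes) == 0L) return(NULL)
    data.frame(image_id = d$image_id, d$boxes[, c("xmin", "ymin", "xmax", "ymax", "score")],
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(image_id = character(), xmin = numeric(), ymin = numeric(),
                       xmax = numeric(), ymax = numeric(), score = numeric())
  }
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
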