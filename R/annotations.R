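#' Bounding-box annotation set for one image
#'
#' Boxes use 0-based, half-open pixel coordinates: a box covers columns
#' `[xmin, xmax)` and rows `[ymin, ymax)`, so its area is
#' `(xmax - xmin) * (ymax - ymin)`. PASCAL VOC's 1-based inclusive
#' convention is converted at the I/O boundary only.
#'
#' @param image_id identifier of the image the boxes belong to.
#' @param width,height image size in pixels.
#' @param boxes data frame with `xmin`, `ymin`, `xmax`, `ymax` and optional
#'   `label` (default `"apple"`) and `score` columns; extra columns are kept.
#' @return an object of class `annotation_set`.
#' @export
annotation_set <- function(image_id, width, height, boxes = NULL) {
  if (is.null(boxes) || nrow(boxes) == 0L) {
    boxes <- data.frame(xmin = numeric(), ymin = numeric(), xmax = numeric(),
                        ymax = numeric(), label = character(), score = numeric(),
                        stringsAsFactors = FALSE)
  } else {
    boxes <- as.data.frame(boxes, stringsAsFactors = FALSE)
    if (is.null(boxes$label)) boxes$label <- "apple"
    if (is.null(boxes$score)) boxes$score <- NA_real_
    if (any(boxes$xmax <= boxes$xmin) || any(boxes$ymax <= boxes$ymin)) {
      stopf("degenerate box: xmax > xmin and ymax > ymin required")
    }
    if (any(boxes$xmin < 0) || any(boxes$ymin < 0) ||
        any(boxes$xmax > width) || any(boxes$ymax > height)) {
      stopf("box outside image bounds [0,%d) x [0,%d)", width, height)
    }
  }
  rownames(boxes) <- NULL
  structure(
    list(image_id = as.character(image_id), width = as.integer(width),
         height = as.integer(height), boxes = boxes),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> '%s' %d x %d px, %d box(es)\n",
              x$image_id, x$width, x$height, nrow(x$boxes)))
  invisible(x)
}

#' Write annotations as PASCAL VOC XML
#'
#' Internal 0-based half-open boxes become VOC's 1-based inclusive `bndbox`
#' (xmin+1, ymin+1, xmax, ymax). A non-missing score is written as a
#' non-standard `<score>` element so detections round-trip too.
#'
#' @param ann an [annotation_set()].
#' @param path output `.xml` path.
#' @return `path`, invisibly.
#' @export
write_voc <- function(ann, path) {
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "folder", "images")
  xml2::xml_add_child(doc, "filename", ann$image_id)
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(ann$width))
  xml2::xml_add_child(size, "height", as.character(ann$height))
  xml2::xml_add_child(size, "depth", "3")
  for (i in seq_len(nrow(ann$boxes))) {
    b <- ann$boxes[i, ]
    obj <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(obj, "name", b$label)
    xml2::xml_add_child(obj, "pose", "Unspecified")
    xml2::xml_add_child(obj, "truncated", "0")
    xml2::xml_add_child(obj, "difficult", "0")
    bb <- xml2::xml_add_child(obj, "bndbox")
    xml2::xml_add_child(bb, "xmin", format(b$xmin + 1L, scientific = FALSE))
    xml2::xml_add_child(bb, "ymin", format(b$ymin + 1L, scientific = FALSE))
    xml2::xml_add_child(bb, "xmax", format(b$xmax, scientific = FALSE))
    xml2::xml_add_child(bb, "ymax", format(b$ymax, scientific = FALSE))
    if (!is.na(b$score)) xml2::xml_add_child(obj, "score", sprintf("%.6f", b$score))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a PASCAL VOC XML annotation file
#'
#' @param path path to a VOC `.xml`.
#' @return an [annotation_set()] (0-based half-open coordinates).
#' @export
read_voc <- function(path) {
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  doc <- xml2::read_xml(path)
  size <- xml2::xml_find_first(doc, "./size")
  if (inherits(size, "xml_missing")) stopf("%s: missing <size> element", path)
  width <- as.integer(xml2::xml_text(xml2::xml_find_first(size, "./width")))
  height <- as.integer(xml2::xml_text(xml2::xml_find_first(size, "./height")))
  if (is.na(width) || is.na(height)) stopf("%s: malformed <size> element", path)
  image_id <- xml2::xml_text(xml2::xml_find_first(doc, "./filename"))
  objs <- xml2::xml_find_all(doc, "./object")
  boxes <- lapply(objs, function(o) {
    bb <- xml2::xml_find_first(o, "./bndbox")
    if (inherits(bb, "xml_missing")) stopf("%s: <object> without <bndbox>", path)
    num <- function(tag) {
      v <- as.numeric(xml2::xml_text(xml2::xml_find_first(bb, paste0("./", tag))))
      if (is.na(v)) stopf("%s: missing or malformed <%s> in bndbox", path, tag)
      v
    }
    sc <- xml2::xml_find_first(o, "./score")
    data.frame(
      xmin = num("xmin") - 1, ymin = num("ymin") - 1,
      xmax = num("xmax"), ymax = num("ymax"),
      label = xml2::xml_text(xml2::xml_find_first(o, "./name")),
      score = if (inherits(sc, "xml_missing")) NA_real_ else as.numeric(xml2::xml_text(sc)),
      stringsAsFactors = FALSE
    )
  })
  boxes <- if (length(boxes)) do.call(rbind, boxes) else NULL
  annotation_set(image_id, width, height, boxes)
}

#' Tile an image and its annotations on a regular grid
#'
#' Cuts non-overlapping `tile_size` tiles left-to-right, top-to-bottom;
#' remainder tiles at the right/bottom edges keep their native (smaller)
#' size — nothing is resized. Every box is assigned to each tile it
#' intersects, clipped to the tile, and dropped from a tile when the clipped
#' area is less than `min_visibility` of the original box area.
#'
#' @param image H x W x C pixel array.
#' @param annotations an [annotation_set()] for the image.
#' @param tile_size tile edge in pixels (default 416).
#' @param min_visibility minimum clipped/original area ratio for a box to be
#'   kept in a tile (default 0.25).
#' @return list of `list(image =, annotations =)` pairs; tile ids are
#'   `<image_id>_r<i>_c<j>` and each tile's annotation set records its size.
#' @export
tile_image <- function(image, annotations, tile_size = 416L, min_visibility = 0.25) {
  H <- dim(image)[1]; W <- dim(image)[2]
  if (H < 1 || W < 1) stopf("image must be at least 1 x 1")
  x_starts <- seq.int(0L, W - 1L, by = tile_size)
  y_starts <- seq.int(0L, H - 1L, by = tile_size)
  b <- annotations$boxes
  out <- list()
  for (yi in seq_along(y_starts)) {
    for (xi in seq_along(x_starts)) {
      x0 <- x_starts[xi]; y0 <- y_starts[yi]
      tw <- min(tile_size, W - x0)
      th <- min(tile_size, H - y0)
      tile_px <- image[(y0 + 1):(y0 + th), (x0 + 1):(x0 + tw), , drop = FALSE]
      keep <- NULL
      if (nrow(b) > 0L) {
        cx1 <- pmax(b$xmin, x0); cx2 <- pmin(b$xmax, x0 + tw)
        cy1 <- pmax(b$ymin, y0); cy2 <- pmin(b$ymax, y0 + th)
        w <- pmax(0, cx2 - cx1); h <- pmax(0, cy2 - cy1)
        frac <- (w * h) / ((b$xmax - b$xmin) * (b$ymax - b$ymin))
        sel <- w > 0 & h > 0 & !(frac < min_visibility)
        if (any(sel)) {
          keep <- b[sel, , drop = FALSE]
          keep$xmin <- cx1[sel] - x0; keep$xmax <- cx2[sel] - x0
          keep$ymin <- cy1[sel] - y0; keep$ymax <- cy2[sel] - y0
        }
      }
      tid <- sprintf("%s_r%d_c%d", annotations$image_id, yi, xi)
      out[[length(out) + 1L]] <- list(
        image = tile_px,
        annotations = annotation_set(tid, tw, th, keep)
      )
    }
  }
  out
}

#' Rotate an image and its boxes by a multiple of 90 degrees
#'
#' 90 degrees is clockwise: pixel (x, y) of a W x H image maps to
#' (H - 1 - y, x); 180 and 270 are compositions. Boxes are remapped exactly
#' (a rotated box is still axis-aligned) and area is preserved.
#'
#' @param image H x W x C pixel array.
#' @param annotations an [annotation_set()].
#' @param angle one of 90, 180, 270.
#' @return list with rotated `image` and `annotations`.
#' @export
rotate_annotated <- function(image, annotations, angle) {
  if (!angle %in% c(90, 180, 270)) stopf("angle must be 90, 180 or 270")
  rot90_img <- function(img) {
    H <- dim(img)[1]
    aperm(img[H:1, , , drop = FALSE], c(2, 1, 3))
  }
  rot90_boxes <- function(b, H) {
    data.frame(
      xmin = H - b$ymax, ymin = b$xmin, xmax = H - b$ymin, ymax = b$xmax,
      b[, setdiff(names(b), c("xmin", "ymin", "xmax", "ymax")), drop = FALSE],
      stringsAsFactors = FALSE
    )
  }
  img <- image
  ann <- annotations
  for (k in seq_len(angle / 90)) {
    H <- dim(img)[1]; W <- dim(img)[2]
    b <- ann$boxes
    nb <- if (nrow(b)) rot90_boxes(b, H) else NULL
    img <- rot90_img(img)
    ann <- annotation_set(ann$image_id, H, W, nb)
  }
  list(image = img, annotations = ann)
}

#' Linear brightness/contrast adjustment
#'
#' Per pixel and channel, `out = clip(round(alpha * in + beta), 0, 255)`
#' (half-up rounding), applied uniformly to all channels. Annotations are
#' unaffected by a photometric transform.
#'
#' @param image H x W x C pixel array (8-bit values).
#' @param alpha contrast gain, > 0.
#' @param beta brightness offset in intensity units.
#' @return adjusted integer pixel array.
#' @export
brightness_contrast <- function(image, alpha, beta) {
  if (alpha <= 0) stopf("alpha must be > 0")
  as_uint8(alpha * image + beta)
}

#' Augmentation parameters
#'
#' @param rotations subset of c(90, 180, 270) degrees.
#' @param color_settings list of `c(alpha, beta)` pairs for
#'   [brightness_contrast()] variants.
#' @return an `augment_params` list; its `factor` field is the dataset
#'   expansion factor `1 + length(rotations) + length(color_settings)`.
#' @export
augment_params <- function(rotations = c(90, 180, 270), color_settings = list()) {
  if (!all(rotations %in% c(90, 180, 270))) stopf("rotations must be within {90, 180, 270}")
  for (cs in color_settings) {
    if (length(cs) != 2L || cs[1] <= 0) stopf("each color setting must be c(alpha > 0, beta)")
  }
  structure(
    list(rotations = rotations, color_settings = color_settings,
         factor = 1L + length(rotations) + length(color_settings)),
    class = "augment_params"
  )
}

#' Expand an annotated dataset by deterministic augmentation
#'
#' Outputs the originals followed by each configured rotation and each
#' brightness/contrast variant of every input, so `n` inputs become
#' `n * params$factor` outputs (e.g. 1,000 tiles with a factor-3
#' configuration give 3,000 annotated images).
#'
#' @param dataset list of `list(image =, annotations =)` pairs (as produced
#'   by [tile_image()]).
#' @param params an [augment_params()].
#' @return expanded dataset in the same shape, with suffixed image ids; the
#'   `expansion_factor` attribute records `params$factor`.
#' @export
augment_dataset <- function(dataset, params = augment_params()) {
  out <- vector("list", length(dataset) * params$factor)
  k <- 0L
  add <- function(item) {
    k <<- k + 1L
    out[[k]] <<- item
  }
  relabel <- function(ann, suffix) {
    annotation_set(paste0(ann$image_id, suffix), ann$width, ann$height,
                   if (nrow(ann$boxes)) ann$boxes else NULL)
  }
  for (item in dataset) {
    add(item)
    for (a in params$rotations) {
      r <- rotate_annotated(item$image, item$annotations, a)
      add(list(image = r$image, annotations = relabel(r$annotations, sprintf("_rot%d", a))))
    }
    for (cs in params$color_settings) {
      add(list(
        image = brightness_contrast(item$image, cs[1], cs[2]),
        annotations = relabel(item$annotations, sprintf("_a%gb%g", cs[1], cs[2]))
      ))
    }
  }
  structure(out, expansion_factor = params$factor)
}
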