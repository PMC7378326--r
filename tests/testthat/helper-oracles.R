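# Shared fixtures and independent oracles used by the property suites.

# Random axis-aligned boxes with scores, fully inside a canvas.
rand_boxes <- function(n, canvas = 100, smin = 8, smax = 35) {
  w <- stats::runif(n, smin, smax)
  h <- stats::runif(n, smin, smax)
  x <- stats::runif(n, 0, canvas - w)
  y <- stats::runif(n, 0, canvas - h)
  data.frame(
    xmin = x, ymin = y, xmax = x + w, ymax = y + h,
    label = "apple", score = stats::runif(n),
    stringsAsFactors = FALSE
  )
}

# Exhaustive maximum bipartite matching (boxes matchable iff IoU >= thr):
# recursive branch over each detection's choices. Independent of the greedy
# matcher it checks; feasible for <= ~8 boxes.
optimal_tp <- function(det, truth, thr = 0.5) {
  nd <- nrow(det)
  nt <- nrow(truth)
  if (nd == 0L || nt == 0L) return(0L)
  m <- outer(seq_len(nd), seq_len(nt),
             Vectorize(function(i, j) iou(det[i, ], truth[j, ])))
  rec <- function(i, used) {
    if (i > nd) return(0L)
    best <- rec(i + 1L, used)
    for (j in seq_len(nt)) {
      if (!used[j] && m[i, j] >= thr) {
        used[j] <- TRUE
        best <- max(best, 1L + rec(i + 1L, used))
        used[j] <- FALSE
      }
    }
    best
  }
  rec(1L, logical(nt))
}

# Brute-force NMS: walk boxes in canonical order, keep a box iff it clears
# every previously kept box; quadratic and index-based, no shortcuts shared
# with the implementation under test.
nms_oracle <- function(boxes, thr) {
  b <- boxes[order(-boxes$score, boxes$ymin, boxes$xmin), , drop = FALSE]
  keep <- integer(0)
  for (i in seq_len(nrow(b))) {
    clears <- TRUE
    for (j in keep) {
      if (iou(b[i, ], b[j, ]) > thr) {
        clears <- FALSE
        break
      }
    }
    if (clears) keep <- c(keep, i)
  }
  b[keep, , drop = FALSE]
}

# Pixel-center containment oracle for circular masks: loop over every pixel.
mask_oracle <- function(raster, center, diameter_m) {
  d <- dim(raster$pixels)
  tr <- raster$transform
  out <- matrix(FALSE, d[1], d[2])
  for (r in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      cx <- tr[["origin_x"]] + (c - 0.5) * tr[["px_w"]]
      cy <- tr[["origin_y"]] - (r - 0.5) * tr[["px_h"]]
      out[r, c] <- (cx - center[1])^2 + (cy - center[2])^2 <= (diameter_m / 2)^2
    }
  }
  out
}

# Rotate a W x H binary mask of a box by 90 deg clockwise at pixel level and
# read the extents back -- the oracle for the box-coordinate remap.
rotated_bbox_oracle <- function(box, W, H, angle) {
  m <- matrix(FALSE, H, W)
  m[(box$ymin + 1):box$ymax, (box$xmin + 1):box$xmax] <- TRUE
  rotcw <- function(mm) t(mm[nrow(mm):1, , drop = FALSE])
  for (k in seq_len(angle / 90)) m <- rotcw(m)
  idx <- which(m, arr.ind = TRUE)
  c(xmin = min(idx[, 2]) - 1, ymin = min(idx[, 1]) - 1,
    xmax = max(idx[, 2]), ymax = max(idx[, 1]))
}

# Small clean scene used across detection/pipeline tests: separated fruits,
# no pixel noise, coarse-but-adequate resolution.
clean_scene_config <- function(n_rows = 3, trees_per_row = 4, seed = 7,
                               total_count_range = c(8, 12)) {
  orchard_config(
    n_rows = n_rows, trees_per_row = trees_per_row,
    inter_row_m = 3, intra_row_m = 1.5,
    total_count_range = total_count_range,
    gsd_m = 0.01, canopy_diameter_m = 0.8,
    noise_sd = 0, min_separation_m = 0.12, seed = seed
  )
}

# Calibration pairs straight from the generator (no rendering): detected =
# number of visible fruits per tree, reference = true total.
gen_calibration_pairs <- function(n_trees, seed, config = orchard_config()) {
  config$n_rows <- 1L
  config$trees_per_row <- as.integer(n_trees)
  trees <- build_layout(config)
  s <- sample_fruit_counts(trees, config, seed = seed)
  fr <- assign_visibility(s$fruits, config, seed = seed + 5e5)
  det <- table(factor(fr$tree_id[fr$visible], levels = s$trees$tree_id))
  data.frame(detected = as.integer(det), reference = s$trees$total)
}

# sample() treats a length-1 numeric as 1:n; this always samples the vector.
pick <- function(v) v[sample.int(length(v), 1)]

extdata <- function(name) {
  system.file("extdata", name, package = "orchardyield", mustWork = TRUE)
}
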