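#' Synthetic orchard configuration
#'
#' Parameters of the synthetic orchard scene generator. Defaults emulate the
#' study field the package is benchmarked on: a 14-row apple orchard with
#' about 41 trees per row at 3 x 1 m (inter-row x intra-row) spacing,
#' per-tree totals averaging ~255 fruits in the 175-308 range, canopy
#' strata (top / middle / underside) holding on average 27.31% / 37.63% /
#' 35.06% of a tree's fruit, and 4.18 mm/pixel imagery.
#'
#' @param n_rows number of tree rows.
#' @param trees_per_row trees in each row.
#' @param inter_row_m distance between rows (m).
#' @param intra_row_m distance between trees within a row (m).
#' @param row_bearing_deg compass bearing of the row direction, degrees
#'   clockwise from world +y; 0 means rows run along +y.
#' @param origin_world world (x, y) of the first tree, meters in a planar
#'   projected frame.
#' @param total_count_range integer (min, max); per-tree totals are drawn
#'   uniformly on this range. The default (202, 308) keeps the observed
#'   maximum of 308 while centring the uniform mean on ~255.
#' @param stratum_mean_fractions mean (top, middle, underside) fractions,
#'   summing to 1.
#' @param stratum_concentration Dirichlet concentration governing per-tree
#'   scatter of the stratum fractions; `Inf` pins every tree to the mean.
#'   The default 40 reproduces the ~7-point per-tree spread of top-stratum
#'   percentages seen in field surveys of this layout.
#' @param visibility_probs probability that a (top, middle, underside) fruit
#'   is visible in a nadir (top-down) image. The default (0.9, 0.3, 0)
#'   yields an expected visible fraction of ~0.36, consistent with only part
#'   of the crop being observable from above.
#' @param gsd_m ground sample distance, m/pixel (default 0.00418).
#' @param canopy_diameter_m rendered canopy disk diameter (m).
#' @param fruit_diameter_m rendered fruit disk diameter (m); 0.07 is a
#'   typical apple.
#' @param noise_sd Gaussian pixel-noise standard deviation in 8-bit units.
#' @param min_separation_m minimum center-to-center distance enforced between
#'   fruits (0 = overlaps allowed, the realistic default).
#' @param seed integer seed making every generated scene reproducible.
#' @return a validated `orchard_config` list.
#' @export
orchard_config <- function(n_rows = 14L,
                           trees_per_row = 41L,
                           inter_row_m = 3,
                           intra_row_m = 1,
                           row_bearing_deg = 0,
                           origin_world = c(0, 0),
                           total_count_range = c(202L, 308L),
                           stratum_mean_fractions = c(0.2731, 0.3763, 0.3506),
                           stratum_concentration = 40,
                           visibility_probs = c(0.9, 0.3, 0),
                           gsd_m = 0.00418,
                           canopy_diameter_m = 1,
                           fruit_diameter_m = 0.07,
                           noise_sd = 2,
                           min_separation_m = 0,
                           seed = 1L) {
  cfg <- list(
    n_rows = n_rows, trees_per_row = trees_per_row,
    inter_row_m = inter_row_m, intra_row_m = intra_row_m,
    row_bearing_deg = row_bearing_deg, origin_world = as.numeric(origin_world),
    total_count_range = as.integer(total_count_range),
    stratum_mean_fractions = as.numeric(stratum_mean_fractions),
    stratum_concentration = stratum_concentration,
    visibility_probs = as.numeric(visibility_probs),
    gsd_m = gsd_m, canopy_diameter_m = canopy_diameter_m,
    fruit_diameter_m = fruit_diameter_m, noise_sd = noise_sd,
    min_separation_m = min_separation_m, seed = as.integer(seed)
  )
  validate_orchard_config(cfg)
  structure(cfg, class = "orchard_config")
}

validate_orchard_config <- function(cfg) {
  if (!is_count(cfg$n_rows) || !is_count(cfg$trees_per_row)) {
    stopf("n_rows and trees_per_row must be nonnegative integers")
  }
  f <- cfg$stratum_mean_fractions
  if (length(f) != 3L || any(f < 0) || any(f > 1) || abs(sum(f) - 1) > 1e-9) {
    stopf("stratum_mean_fractions must be 3 values in [0,1] summing to 1")
  }
  v <- cfg$visibility_probs
  if (length(v) != 3L || any(v < 0) || any(v > 1)) {
    stopf("visibility_probs must be 3 probabilities in [0,1]")
  }
  r <- cfg$total_count_range
  if (length(r) != 2L || r[1] > r[2] || r[1] < 0) stopf("total_count_range must be ordered nonnegative (min, max)")
  if (cfg$gsd_m <= 0) stopf("gsd_m must be > 0")
  if (cfg$stratum_concentration <= 0) stopf("stratum_concentration must be > 0")
  if (cfg$canopy_diameter_m <= 0 || cfg$fruit_diameter_m <= 0) stopf("diameters must be > 0")
  if (cfg$noise_sd < 0) stopf("noise_sd must be >= 0")
  invisible(cfg)
}

STRATA <- c("top", "middle", "underside")

#' Build the tree layout of an orchard grid
#'
#' Places `n_rows` x `trees_per_row` trees on a regular grid: row i sits
#' `(i-1) * inter_row_m` along the cross-row axis, tree j within a row
#' `(j-1) * intra_row_m` along the row axis, both rotated by the row bearing
#' and offset by the world origin. Tree ids are deterministic in
#' (row, position).
#'
#' @param config an [orchard_config()].
#' @return data frame of tree records: `tree_id`, `row_index`,
#'   `position_in_row`, `x`, `y` (fruit counts unset).
#' @export
build_layout <- function(config) {
  validate_orchard_config(config)
  if (config$n_rows == 0L || config$trees_per_row == 0L) {
    return(data.frame(
      tree_id = character(), row_index = integer(), position_in_row = integer(),
      x = numeric(), y = numeric(), stringsAsFactors = FALSE
    ))
  }
  grid <- expand.grid(
    position_in_row = seq_len(config$trees_per_row),
    row_index = seq_len(config$n_rows)
  )
  u <- (grid$row_index - 1) * config$inter_row_m     # cross-row axis (+x at bearing 0)
  v <- (grid$position_in_row - 1) * config$intra_row_m  # row axis (+y at bearing 0)
  th <- config$row_bearing_deg * pi / 180
  # compass rotation: bearing turns the row axis clockwise from +y
  x <- config$origin_world[1] + u * cos(th) + v * sin(th)
  y <- config$origin_world[2] - u * sin(th) + v * cos(th)
  data.frame(
    tree_id = sprintf("r%02dt%02d", grid$row_index, grid$position_in_row),
    row_index = grid$row_index,
    position_in_row = grid$position_in_row,
    x = x, y = y,
    stringsAsFactors = FALSE
  )
}

# Largest-remainder apportionment of `total` into integer parts with target
# `fractions` (deterministic, sum-exact; ties broken by index order).
apportion_counts <- function(total, fractions) {
  exact <- total * fractions
  base <- floor(exact)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(exact - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# One Dirichlet draw per row with mean `mean_frac` and concentration `conc`.
rdirichlet_mean <- function(n, mean_frac, conc) {
  if (is.infinite(conc)) {
    return(matrix(mean_frac, nrow = n, ncol = length(mean_frac), byrow = TRUE))
  }
  g <- matrix(
    stats::rgamma(n * length(mean_frac), shape = rep(mean_frac * conc, each = n)),
    nrow = n
  )
  # a zero mean fraction gives a degenerate (all-zero) gamma column; keep it 0
  sums <- rowSums(g)
  sums[sums == 0] <- 1
  g / sums
}

#' Sample per-tree fruit counts and fruit positions
#'
#' Per tree: a total drawn uniformly on `total_count_range`; stratum
#' fractions drawn from a Dirichlet distribution with the configured mean and
#' concentration, converted to integers that sum exactly to the total by
#' largest-remainder apportionment; one fruit instance per fruit with a
#' position uniform in the canopy disk (optionally respecting
#' `min_separation_m` between fruit centers, rejection-sampled).
#'
#' @param trees layout from [build_layout()].
#' @param config an [orchard_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return list with `trees` (layout plus `count_top`, `count_middle`,
#'   `count_underside`, `total`) and `fruits` (data frame `fruit_id`,
#'   `tree_id`, `stratum`, `x`, `y`, `radius_m`).
#' @export
sample_fruit_counts <- function(trees, config, seed = config$seed) {
  validate_orchard_config(config)
  n <- nrow(trees)
  with_seed(seed, {
    totals <- if (n == 0L) integer() else {
      r <- config$total_count_range
      vals <- seq.int(r[1], r[2])  # explicit indexing: safe when min == max
      as.integer(vals[sample.int(length(vals), n, replace = TRUE)])
    }
    fracs <- rdirichlet_mean(n, config$stratum_mean_fractions, config$stratum_concentration)
    counts <- t(vapply(seq_len(n), function(i) apportion_counts(totals[i], fracs[i, ]),
                       integer(3)))
    if (n == 0L) counts <- matrix(integer(), ncol = 3)
    trees$count_top <- counts[, 1]
    trees$count_middle <- counts[, 2]
    trees$count_underside <- counts[, 3]
    trees$total <- totals

    fruit_r <- config$fruit_diameter_m / 2
    canopy_r <- config$canopy_diameter_m / 2
    tree_of <- rep.int(seq_len(n), totals)
    stratum <- unlist(lapply(seq_len(n), function(i) rep(STRATA, times = counts[i, ])),
                      use.names = FALSE)
    if (is.null(stratum)) stratum <- character()
    m <- length(tree_of)
    if (config$min_separation_m <= 0) {
      rr <- canopy_r * sqrt(stats::runif(m))
      th <- 2 * pi * stats::runif(m)
      xs <- trees$x[tree_of] + rr * cos(th)
      ys <- trees$y[tree_of] + rr * sin(th)
    } else {
      xs <- numeric(m); ys <- numeric(m)
      for (j in seq_len(m)) {
        ok <- FALSE
        for (attempt in 1:200) {
          rr <- canopy_r * sqrt(stats::runif(1))
          th <- 2 * pi * stats::runif(1)
          px <- trees$x[tree_of[j]] + rr * cos(th)
          py <- trees$y[tree_of[j]] + rr * sin(th)
          if (j == 1L ||
              all((xs[seq_len(j - 1L)] - px)^2 + (ys[seq_len(j - 1L)] - py)^2 >=
                    config$min_separation_m^2)) {
            ok <- TRUE
            break
          }
        }
        if (!ok) stopf("could not place a fruit of tree '%s' at min_separation_m = %g",
                       trees$tree_id[tree_of[j]], config$min_separation_m)
        xs[j] <- px; ys[j] <- py
      }
    }
    fruits <- data.frame(
      fruit_id = if (m == 0L) character() else
        sprintf("%s_f%03d", trees$tree_id[tree_of], sequence(totals)),
      tree_id = trees$tree_id[tree_of],
      stratum = stratum,
      x = xs, y = ys,
      radius_m = rep(fruit_r, m),
      stringsAsFactors = FALSE
    )
    list(trees = trees, fruits = fruits)
  })
}

#' Assign top-view visibility to fruits
#'
#' Each fruit is independently visible with the probability configured for
#' its canopy stratum, so the expected visible fraction of a tree's crop is
#' the stratum-fraction-weighted sum of the visibility probabilities.
#'
#' @param fruits fruit data frame from [sample_fruit_counts()].
#' @param config an [orchard_config()].
#' @param seed RNG seed (defaults to `config$seed + 1`, so counts and
#'   visibility use distinct streams).
#' @return `fruits` with a logical `visible` column.
#' @export
assign_visibility <- function(fruits, config, seed = config$seed + 1L) {
  validate_orchard_config(config)
  p <- config$visibility_probs[match(fruits$stratum, STRATA)]
  fruits$visible <- with_seed(seed, stats::runif(nrow(fruits)) < p)
  fruits
}

# Paint a filled world-space disk onto an integer H x W x 3 array; returns the
# array and the painted pixel bbox (0-based half-open), or NULL bbox if the
# disk misses the raster. A disk always paints at least the pixel containing
# its center (so sub-pixel fruits still carry a truth box).
paint_disk <- function(px, transform, cx, cy, radius_m, color) {
  H <- dim(px)[1]; W <- dim(px)[2]
  c0 <- world_to_pixel(transform, c(cx, cy))
  rad_px <- radius_m / transform[["px_w"]]
  cols <- clamp(floor(c0[1] - rad_px - 1):ceiling(c0[1] + rad_px + 1), 0, W - 1)
  rows <- clamp(floor(c0[2] - rad_px - 1):ceiling(c0[2] + rad_px + 1), 0, H - 1)
  cols <- unique(cols); rows <- unique(rows)
  ctr <- pixel_center_xy(transform, cols, rows)
  inside <- outer((ctr$y - cy)^2, (ctr$x - cx)^2, `+`) <= radius_m^2
  # guarantee the center pixel
  ccol <- floor(c0[1]); crow <- floor(c0[2])
  if (ccol >= 0 && ccol < W && crow >= 0 && crow < H) {
    inside[match(crow, rows), match(ccol, cols)] <- TRUE
  }
  if (!any(inside)) return(list(px = px, bbox = NULL))
  idx <- which(inside, arr.ind = TRUE)
  r1 <- rows[idx[, 1]] + 1L  # 1-based rows
  c1 <- cols[idx[, 2]] + 1L
  for (ch in 1:3) px[cbind(r1, c1, ch)] <- color[ch]
  list(px = px, bbox = c(
    xmin = min(c1) - 1L, ymin = min(r1) - 1L, xmax = max(c1), ymax = max(r1)
  ))
}

#' Render a synthetic orchard scene
#'
#' Rasterizes the orchard at the configured ground sample distance: a soil
#' background, a green canopy disk per tree, and a red disk per VISIBLE
#' fruit, with optional Gaussian pixel noise. Each visible fruit yields one
#' ground-truth bounding box, the tight pixel box of its rendered disk. The
#' affine is set so world/pixel mapping is exact.
#'
#' @param trees tree data frame with counts (from [sample_fruit_counts()]).
#' @param fruits fruit data frame with `visible` (from [assign_visibility()]).
#' @param config an [orchard_config()].
#' @param margin_m blank margin around the layout bounding box (m).
#' @param max_pixels guard against accidental huge renders (H x W limit);
#'   exceeding it is an error, not a silent downscale.
#' @return a `scene_bundle`: list with `raster` ([geo_raster()]), `trees`,
#'   `fruits`, `truth` (an [annotation_set()] of visible-fruit boxes, with a
#'   `fruit_id` column), `tree_layer` ([geo_features()] points), `config`.
#' @export
render_scene <- function(trees, fruits, config, margin_m = 1, max_pixels = 2.5e7) {
  validate_orchard_config(config)
  if (is.null(fruits$visible)) stopf("fruits must carry a 'visible' flag; run assign_visibility() first")
  pad <- margin_m + config$canopy_diameter_m / 2
  xr <- range(trees$x) + c(-pad, pad)
  yr <- range(trees$y) + c(-pad, pad)
  W <- ceiling(diff(xr) / config$gsd_m)
  H <- ceiling(diff(yr) / config$gsd_m)
  if (H * W > max_pixels) {
    stopf("render of %d x %d px exceeds the pixel budget (%g); coarsen gsd_m or raise max_pixels",
          H, W, max_pixels)
  }
  transform <- c(xr[1], yr[2], config$gsd_m, config$gsd_m)
  names(transform) <- c("origin_x", "origin_y", "px_w", "px_h")

  soil <- c(96L, 78L, 56L)
  canopy <- c(44L, 108L, 46L)
  fruit_col <- c(205L, 32L, 34L)
  px <- array(rep(soil, each = H * W), dim = c(H, W, 3))

  for (i in seq_len(nrow(trees))) {
    px <- paint_disk(px, transform, trees$x[i], trees$y[i],
                     config$canopy_diameter_m / 2, canopy)$px
  }

  vis <- fruits[fruits$visible, , drop = FALSE]
  boxes <- vector("list", nrow(vis))
  for (i in seq_len(nrow(vis))) {
    res <- paint_disk(px, transform, vis$x[i], vis$y[i], vis$radius_m[i], fruit_col)
    px <- res$px
    if (is.null(res$bbox)) stopf("visible fruit '%s' fell outside the raster", vis$fruit_id[i])
    boxes[[i]] <- res$bbox
  }
  boxes_df <- if (nrow(vis) == 0L) {
    data.frame(xmin = numeric(), ymin = numeric(), xmax = numeric(), ymax = numeric(),
               label = character(), score = numeric(), fruit_id = character(),
               stringsAsFactors = FALSE)
  } else {
    b <- do.call(rbind, boxes)
    data.frame(xmin = b[, "xmin"], ymin = b[, "ymin"], xmax = b[, "xmax"], ymax = b[, "ymax"],
               label = "apple", score = NA_real_, fruit_id = vis$fruit_id,
               stringsAsFactors = FALSE)
  }

  if (config$noise_sd > 0) {
    px <- with_seed(config$seed + 2L, {
      as_uint8(px + stats::rnorm(length(px), sd = config$noise_sd))
    })
  }

  raster <- geo_raster(px, transform)
  tree_layer <- geo_features(
    trees[, c("x", "y")],
    trees[, c("tree_id", "row_index", "position_in_row"), drop = FALSE],
    "point"
  )
  structure(
    list(
      raster = raster, trees = trees, fruits = fruits,
      truth = annotation_set("scene", W, H, boxes_df),
      tree_layer = tree_layer, config = config
    ),
    class = "scene_bundle"
  )
}

#' Generate a complete synthetic scene in one call
#'
#' Convenience wrapper: layout, counts, visibility, render.
#'
#' @inheritParams render_scene
#' @param config an [orchard_config()].
#' @return a `scene_bundle` (see [render_scene()]).
#' @export
simulate_orchard <- function(config, margin_m = 1, max_pixels = 2.5e7) {
  trees <- build_layout(config)
  sampled <- sample_fruit_counts(trees, config)
  fruits <- assign_visibility(sampled$fruits, config)
  render_scene(sampled$trees, fruits, config, margin_m = margin_m, max_pixels = max_pixels)
}

#' Write the files of a synthetic scene bundle
#'
#' Raster as TIFF + world file, tree layer as GeoJSON and Shapefile, truth
#' boxes as a PASCAL VOC XML, and the per-tree truth table as CSV.
#'
#' @param bundle a `scene_bundle` from [render_scene()].
#' @param dir output directory (created if missing).
#' @return named character vector of the written paths, invisibly.
#' @export
write_scene <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    raster = file.path(dir, "scene.tif"),
    trees_geojson = file.path(dir, "trees.geojson"),
    trees_shp = file.path(dir, "trees.shp"),
    truth_xml = file.path(dir, "scene_truth.xml"),
    truth_csv = file.path(dir, "tree_truth.csv")
  )
  write_raster(bundle$raster, paths[["raster"]])
  write_vector(bundle$tree_layer, paths[["trees_geojson"]])
  write_vector(bundle$tree_layer, paths[["trees_shp"]])
  write_voc(bundle$truth, paths[["truth_xml"]])
  vis_by_tree <- table(bundle$fruits$tree_id[bundle$fruits$visible])
  truth <- bundle$trees
  truth$n_visible <- as.integer(vis_by_tree[truth$tree_id])
  truth$n_visible[is.na(truth$n_visible)] <- 0L
  utils::write.csv(truth, paths[["truth_csv"]], row.names = FALSE)
  invisible(paths)
}
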