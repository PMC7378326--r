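#' Per-tree yield map layer
#'
#' One point feature per tree at its world position, carrying the tree's
#' fruit count and the half-open count bin `[e_k, e_{k+1})` it falls in.
#' Features are ordered by (row_index, position_in_row).
#'
#' @param trees tree data frame (`tree_id`, `row_index`, `position_in_row`,
#'   `x`, `y`).
#' @param counts data frame `tree_id`, `count` (e.g. from
#'   [count_per_tree()]); every tree must be covered.
#' @param bin_edges increasing numeric bin edges; counts at or above the
#'   last finite edge fall in the top bin. The default keeps a `[30,40)`
#'   class among its bins.
#' @param crs CRS tag written to outputs.
#' @return a [geo_features()] point layer with attributes `tree_id`,
#'   `row_index`, `fruit_count`, `class_bin`.
#' @export
per_tree_layer <- function(trees, counts,
                           bin_edges = c(0, 20, 30, 40, 60, 80, 120, Inf),
                           crs = "") {
  idx <- match(trees$tree_id, counts$tree_id)
  if (anyNA(idx)) {
    stopf("no count for tree '%s'", trees$tree_id[which(is.na(idx))[1]])
  }
  cnt <- counts$count[idx]
  if (anyNA(cnt)) stopf("count for tree '%s' is missing (NA)", trees$tree_id[which(is.na(cnt))[1]])
  ord <- order(trees$row_index, trees$position_in_row)
  trees <- trees[ord, , drop = FALSE]
  cnt <- cnt[ord]
  bin_idx <- findInterval(cnt, bin_edges)  # half-open [e_k, e_{k+1})
  if (any(bin_idx == 0)) stopf("count %g below the lowest bin edge", min(cnt))
  labels <- paste0("[", bin_edges[-length(bin_edges)], ",", bin_edges[-1], ")")
  geo_features(
    trees[, c("x", "y")],
    data.frame(
      tree_id = trees$tree_id, row_index = trees$row_index,
      fruit_count = as.integer(cnt), class_bin = labels[bin_idx],
      stringsAsFactors = FALSE
    ),
    "point", crs = crs
  )
}

#' Per-row yield map layer
#'
#' Aggregates a per-tree layer to one feature per row: the row's fruit
#' count is the sum of its trees' counts; the geometry is the line from the
#' row's first to last tree, buffered to a thin rectangle for display
#' (a small square for single-tree rows).
#'
#' @param tree_layer output of [per_tree_layer()].
#' @param buffer_m half-width of the row polygon in meters.
#' @return a [geo_features()] polygon layer with attributes `row_index`,
#'   `fruit_count`.
#' @export
per_row_layer <- function(tree_layer, buffer_m = 0.5) {
  at <- tree_layer$attributes
  xy <- tree_layer$geometry
  rows <- sort(unique(at$row_index))
  geoms <- vector("list", length(rows))
  totals <- integer(length(rows))
  for (k in seq_along(rows)) {
    sel <- at$row_index == rows[k]
    totals[k] <- sum(at$fruit_count[sel])
    p <- xy[sel, , drop = FALSE]
    a <- p[1, ]; b <- p[nrow(p), ]
    v <- b - a
    len <- sqrt(sum(v^2))
    u <- if (len > 0) v / len else c(0, 1)
    nrm <- c(-u[2], u[1]) * buffer_m
    ends <- rbind(a - u * buffer_m, b + u * buffer_m)  # extend past end trees
    ring <- rbind(
      ends[1, ] + nrm, ends[2, ] + nrm, ends[2, ] - nrm, ends[1, ] - nrm,
      ends[1, ] + nrm
    )
    geoms[[k]] <- ring
  }
  geo_features(
    geoms,
    data.frame(row_index = rows, fruit_count = totals),
    "polygon", crs = tree_layer$crs
  )
}

#' Fraction of trees with counts in a half-open bin
#'
#' `100 * |{count : lo <= count < hi}| / n`, unrounded; round half-up to 2
#' decimals for presentation. Set `closed = TRUE` for a closed upper bound.
#'
#' @param counts nonempty numeric vector of per-tree counts.
#' @param lo,hi bin bounds.
#' @param closed include `hi` in the bin (default FALSE: half-open).
#' @return percentage of trees in the bin.
#' @export
bin_fraction <- function(counts, lo, hi, closed = FALSE) {
  if (length(counts) == 0L) stopf("counts must be nonempty")
  inside <- counts >= lo & (if (closed) counts <= hi else counts < hi)
  100 * sum(inside) / length(counts)
}
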