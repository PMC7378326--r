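#' Intersection over union of two boxes
#'
#' Areas follow the half-open convention: a box covers
#' `(xmax - xmin) * (ymax - ymin)` pixels.
#'
#' @param a,b boxes: lists/one-row data frames with `xmin`, `ymin`, `xmax`,
#'   `ymax`.
#' @return IoU in [0, 1].
#' @export
iou <- function(a, b) {
  iw <- min(a$xmax, b$xmax) - max(a$xmin, b$xmin)
  ih <- min(a$ymax, b$ymax) - max(a$ymin, b$ymin)
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  union <- (a$xmax - a$xmin) * (a$ymax - a$ymin) +
    (b$xmax - b$xmin) * (b$ymax - b$ymin) - inter
  inter / union
}

# All-pairs IoU matrix: detections in rows, truths in columns.
iou_matrix <- function(det, truth) {
  nd <- nrow(det); nt <- nrow(truth)
  m <- matrix(0, nd, nt)
  for (i in seq_len(nd)) {
    for (j in seq_len(nt)) m[i, j] <- iou(det[i, ], truth[j, ])
  }
  m
}

#' Match detections to ground-truth boxes
#'
#' Greedy one-to-one matching, the standard detection-benchmark rule:
#' detections are visited in descending score order (ties by ymin, xmin);
#' each takes the unmatched truth box of highest IoU, provided
#' IoU >= `iou_min`, with IoU ties between truth boxes broken by the truth
#' box's (ymin, xmin). Matched pairs are true positives; unmatched
#' detections are false positives; unmatched truths are false negatives.
#'
#' @param detections a [detection_set()] or data frame of scored boxes.
#' @param truth an [annotation_set()] or data frame of boxes.
#' @param iou_min TP criterion (default 0.5, the community standard).
#' @return a `match_result`: list with `pairs` (data frame `det`, `truth`,
#'   `iou`; indices refer to the score-sorted detections and the input truth
#'   order), `tp`, `fp`, `fn`.
#' @export
match_detections <- function(detections, truth, iou_min = 0.5) {
  det <- if (inherits(detections, "annotation_set")) detections$boxes else detections
  tb <- if (inherits(truth, "annotation_set")) truth$boxes else truth
  if (nrow(det) > 1L) {
    sc <- if (is.null(det$score)) rep(0, nrow(det)) else det$score
    det <- det[order(-sc, det$ymin, det$xmin), , drop = FALSE]
  }
  nd <- nrow(det); nt <- nrow(tb)
  taken <- logical(nt)
  pairs <- list()
  if (nd > 0L && nt > 0L) {
    m <- iou_matrix(det, tb)
    for (i in seq_len(nd)) {
      cand <- which(!taken & m[i, ] >= iou_min)
      if (length(cand) == 0L) next
      best <- cand[order(-m[i, cand], tb$ymin[cand], tb$xmin[cand])][1]
      taken[best] <- TRUE
      pairs[[length(pairs) + 1L]] <- data.frame(det = i, truth = best, iou = m[i, best])
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(det = integer(), truth = integer(), iou = numeric())
  structure(
    list(pairs = pairs, tp = nrow(pairs), fp = nd - nrow(pairs), fn = nt - nrow(pairs)),
    class = "match_result"
  )
}

#' Detection metrics for one image
#'
#' The per-picture evaluation tuple: precision `TP / (TP + FP)`, recall
#' `TP / (TP + FN)`, their harmonic mean F1, and accuracy `TP / Nfp` where
#' `Nfp` is the manually counted number of fruits in the picture. With no
#' detections at all, precision and F1 are reported as `NA` (undefined),
#' never silently 0. All values are unrounded; round only for presentation.
#'
#' @param match a `match_result` from [match_detections()], or any list /
#'   one-row data frame carrying `tp`, `fp`, `fn` counts.
#' @param nfp manually counted fruits in the picture (>= 0).
#' @param picture_id identifier for the row.
#' @return one-row data frame: `picture_id`, `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`, `nfp`, `accuracy`.
#' @export
detection_metrics <- function(match, nfp, picture_id = NA) {
  tp <- match$tp; fp <- match$fp; fn <- match$fn
  if (nfp < 0) stopf("nfp must be >= 0")
  if (nfp == 0 && tp > 0) stopf("inconsistent: tp = %d but nfp = 0", tp)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else if (!is.na(precision) && !is.na(recall)) {
    0
  } else {
    NA_real_
  }
  accuracy <- if (nfp > 0) tp / nfp else NA_real_
  data.frame(
    picture_id = as.character(picture_id), tp = tp, fp = fp, fn = fn,
    precision = precision, recall = recall, f1 = f1, nfp = nfp,
    accuracy = accuracy, stringsAsFactors = FALSE
  )
}

#' Metrics table with an average row
#'
#' Stacks per-picture metric rows and appends an `Avg` row holding the
#' arithmetic column means, computed on the unrounded values. Use
#' `digits` (half-up) only when presenting or exporting.
#'
#' @param rows data frame of rows from [detection_metrics()] (or the same
#'   columns), one per picture.
#' @param digits optional presentation rounding for the metric columns.
#' @return data frame in the column order TP, FP, FN, P, R, F1, Nfp, A with
#'   a final `Avg` row.
#' @export
metrics_table <- function(rows, digits = NULL) {
  if (nrow(rows) < 1L) stopf("metrics_table needs at least one row")
  num_cols <- c("tp", "fp", "fn", "precision", "recall", "f1", "nfp", "accuracy")
  avg <- rows[1, , drop = FALSE]
  avg$picture_id <- "Avg"
  for (cl in num_cols) avg[[cl]] <- mean(rows[[cl]])
  out <- rbind(rows[, c("picture_id", num_cols)], avg[, c("picture_id", num_cols)])
  rownames(out) <- NULL
  if (!is.null(digits)) {
    for (cl in c("precision", "recall", "f1", "accuracy")) {
      out[[cl]] <- round_half_up(out[[cl]], digits)
    }
    for (cl in c("tp", "fp", "fn", "nfp")) out[[cl]] <- round_half_up(out[[cl]], digits)
  }
  out
}

#' Mean absolute error
#'
#' `MAE = mean(|actual - forecast|)` over paired series.
#'
#' @param actual,forecast equal-length nonempty numeric vectors.
#' @return nonnegative real.
#' @export
mae <- function(actual, forecast) {
  check_paired(actual, forecast)
  mean(abs(actual - forecast))
}

#' Root mean square error
#'
#' `RMSE = sqrt(mean((actual - forecast)^2))`; always >= [mae()] on the same
#' pair of series.
#'
#' @inheritParams mae
#' @return nonnegative real.
#' @export
rmse <- function(actual, forecast) {
  check_paired(actual, forecast)
  sqrt(mean((actual - forecast)^2))
}

check_paired <- function(actual, forecast) {
  if (length(actual) == 0L) stopf("series must be nonempty")
  if (length(actual) != length(forecast)) {
    stopf("series lengths differ: %d vs %d", length(actual), length(forecast))
  }
}

#' Ordinary least-squares fit with fit-quality summaries
#'
#' Simple OLS of y on x with intercept, reporting the coefficient of
#' determination `R^2 = 1 - SSres / SStot` (for simple OLS with intercept
#' this equals the squared Pearson correlation) plus MAE and RMSE of fitted
#' versus observed y.
#'
#' @param x predictor (not constant, length >= 3).
#' @param y response, same length.
#' @return a `regression_fit`: list with `slope`, `intercept`, `r_squared`,
#'   `mae`, `rmse`, `n`.
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y lengths differ")
  if (length(x) < 3L) stopf("linear_fit needs n >= 3 points")
  if (stats::sd(x) == 0) stopf("x is constant; no regression possible")
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  fitted_y <- stats::fitted(fit)
  ss_res <- sum((y - fitted_y)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(
    list(
      slope = unname(co[2]), intercept = unname(co[1]),
      r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
      mae = mae(y, fitted_y), rmse = rmse(y, fitted_y),
      n = length(x)
    ),
    class = "regression_fit"
  )
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> y = %.4f x + %.4f, R^2 = %.4f, MAE = %.3f, RMSE = %.3f, n = %d\n",
              x$slope, x$intercept, x$r_squared, x$mae, x$rmse, x$n))
  invisible(x)
}

#' Export a metrics table as CSV
#'
#' Columns follow the standard report order (Picture, TP, FP, FN, P, R, F1,
#' Nfp, A), metric cells rounded half-up to 2 decimals.
#'
#' @param table output of [metrics_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(table, path) {
  out <- metrics_if_needed(table)
  names(out) <- c("Picture", "TP", "FP", "FN", "P", "R", "F1", "Nfp", "A")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

metrics_if_needed <- function(table) {
  for (cl in c("precision", "recall", "f1", "accuracy", "tp", "fp", "fn", "nfp")) {
    table[[cl]] <- round_half_up(table[[cl]], 2)
  }
  table
}
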