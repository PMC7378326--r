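#' Canopy stratum distribution table
#'
#' From per-tree visual counts in the three canopy strata (top, middle,
#' underside), compute each tree's total and stratum percentages, plus an
#' `Average` row of unrounded column means. This is the summary used to
#' judge how much of a tree's crop a nadir image can possibly show.
#'
#' @param counts data frame with `tree_id` and the per-stratum counts
#'   `count_top`, `count_middle`, `count_underside` (the Nfcvt / Nfcvm /
#'   Nfcvun visual counts).
#' @param digits optional half-up presentation rounding for the percentage
#'   and average cells.
#' @return data frame `tree_id`, `count_top`, `count_middle`,
#'   `count_underside`, `total`, `pct_top`, `pct_middle`, `pct_underside`
#'   with a final `Average` row.
#' @export
canopy_distribution <- function(counts, digits = NULL) {
  req <- c("tree_id", "count_top", "count_middle", "count_underside")
  if (!all(req %in% names(counts))) {
    stopf("counts must have columns %s", paste(req, collapse = ", "))
  }
  total <- counts$count_top + counts$count_middle + counts$count_underside
  if (any(total <= 0)) {
    stopf("tree '%s' has zero total fruits; percentages undefined",
          counts$tree_id[which(total <= 0)[1]])
  }
  out <- data.frame(
    tree_id = as.character(counts$tree_id),
    count_top = counts$count_top,
    count_middle = counts$count_middle,
    count_underside = counts$count_underside,
    total = total,
    pct_top = 100 * counts$count_top / total,
    pct_middle = 100 * counts$count_middle / total,
    pct_underside = 100 * counts$count_underside / total,
    stringsAsFactors = FALSE
  )
  avg <- out[1, , drop = FALSE]
  avg$tree_id <- "Average"
  for (cl in names(out)[-1]) avg[[cl]] <- mean(out[[cl]])
  out <- rbind(out, avg)
  rownames(out) <- NULL
  if (!is.null(digits)) {
    for (cl in c("count_top", "count_middle", "count_underside", "total",
                 "pct_top", "pct_middle", "pct_underside")) {
      out[[cl]] <- round_half_up(out[[cl]], digits)
    }
  }
  out
}

#' Fit a visible-to-total calibration regression
#'
#' Links counts detected on top-view imagery (the noisy, partial
#' measurement) to reference totals (harvested or field-counted), producing
#' a fit usable by [predict_total()]. Two estimators:
#'
#' * `"classical"` (default): calibration-curve regression. The forward
#'   model `detected ~ visible_fraction * reference` is fit through the
#'   origin by weighted least squares with weights `1 / reference^2`
#'   (equivalently, the mean of per-tree `detected / reference` ratios —
#'   appropriate because detection noise scales with tree size), then
#'   inverted to the prediction scale: `slope = 1 / fraction_hat`,
#'   `intercept = 0`. Immune to the attenuation that regressing on the
#'   noisy variable induces.
#' * `"inverse"`: plain OLS of `reference` on `detected` via
#'   [linear_fit()] — the direct prediction-direction regression.
#'
#' Both report slope/intercept on the prediction scale (total per detected),
#' `r_squared` as the squared Pearson correlation of the pairs, and
#' MAE/RMSE of predicted versus reference totals over the calibration set.
#'
#' @param pairs data frame with `detected` and `reference` counts (>= 3
#'   rows, `detected` not constant).
#' @param method `"classical"` or `"inverse"`.
#' @return a `regression_fit` (see [linear_fit()]) with an extra
#'   `method` field.
#' @export
fit_calibration <- function(pairs, method = c("classical", "inverse")) {
  method <- match.arg(method)
  if (!all(c("detected", "reference") %in% names(pairs))) {
    stopf("pairs must have 'detected' and 'reference' columns")
  }
  d <- pairs$detected; r <- pairs$reference
  if (any(d < 0) || any(r < 0)) stopf("counts must be nonnegative")
  if (length(d) < 3L) stopf("calibration needs at least 3 pairs")
  if (stats::sd(d) == 0) stopf("detected counts are constant; no calibration possible")
  if (method == "classical") {
    if (any(r == 0)) stopf("classical calibration needs reference > 0 for every pair")
    frac_hat <- mean(d / r)
    if (frac_hat <= 0) stopf("no fruit detected anywhere; cannot calibrate")
    fit <- list(slope = 1 / frac_hat, intercept = 0)
  } else {
    lf <- linear_fit(d, r)
    fit <- list(slope = lf$slope, intercept = lf$intercept)
  }
  pred <- fit$slope * d + fit$intercept
  structure(
    list(
      slope = fit$slope, intercept = fit$intercept,
      r_squared = stats::cor(d, r)^2,
      mae = mae(r, pred), rmse = rmse(r, pred),
      n = length(d), method = method
    ),
    class = "regression_fit"
  )
}

#' Predict a tree's total fruit count from its detected count
#'
#' `round(slope * detected + intercept)` (half-up), clamped at zero —
#' totals are counts.
#'
#' @param fit a `regression_fit` from [fit_calibration()] or [linear_fit()].
#' @param detected detected count(s), vectorized.
#' @return nonnegative integer vector of estimated totals.
#' @export
predict_total <- function(fit, detected) {
  raw <- fit$slope * detected + fit$intercept
  as.integer(pmax(0, round_half_up(raw, 0)))
}
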