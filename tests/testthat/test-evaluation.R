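box <- function(x1, y1, x2, y2, score = NA_real_) {
  data.frame(xmin = x1, ymin = y1, xmax = x2, ymax = y2, label = "apple",
             score = score, stringsAsFactors = FALSE)
}

test_that("IoU follows half-open box areas", {
  a <- box(0, 0, 2, 2)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, box(5, 5, 7, 7)), 0)
  expect_equal(iou(a, box(1, 0, 3, 2)), 2 / 6)
  expect_equal(iou(a, box(2, 0, 4, 2)), 0)  # touching edges do not intersect
})

test_that("greedy matching is one-to-one and bounded by the optimal assignment", {
  truths <- rbind(box(0, 0, 10, 10), box(20, 0, 30, 10), box(40, 0, 50, 10))
  m0 <- match_detections(truths[0, ], truths)
  expect_equal(c(m0$tp, m0$fp, m0$fn), c(0, 0, 3))

  dets <- truths
  dets$score <- c(0.9, 0.8, 0.7)
  m1 <- match_detections(dets, truths)
  expect_equal(c(m1$tp, m1$fp, m1$fn), c(3, 0, 0))
  expect_equal(sort(m1$pairs$truth), 1:3)

  # interlocked configuration where greedy is one short of optimal
  tr <- rbind(box(0, 0, 12, 10), box(7, 0, 19, 10))
  de <- rbind(box(3, 0, 15, 10, score = 0.9), box(1, 0, 13, 10, score = 0.8))
  g <- match_detections(de, tr)
  expect_equal(g$tp, 1L)
  opt <- optimal_tp(de, tr)
  expect_equal(opt, 2L)
  expect_gte(g$tp, opt - 1L)

  # bookkeeping identities hold on random instances
  set.seed(51)
  for (i in 1:50) {
    nd <- pick(0:6); nt <- pick(0:6)
    de <- rand_boxes(max(nd, 1))[seq_len(nd), , drop = FALSE]
    tr <- rand_boxes(max(nt, 1))[seq_len(nt), , drop = FALSE]
    m <- match_detections(de, tr)
    expect_equal(m$tp + m$fp, nd)
    expect_equal(m$tp + m$fn, nt)
    expect_false(anyDuplicated(m$pairs$truth) > 0)
  }
})

test_that("per-picture metrics follow the precision/recall/F1/accuracy formulas", {
  r1 <- detection_metrics(list(tp = 70, fp = 2, fn = 8), nfp = 78, picture_id = 1)
  expect_equal(round_half_up(r1[, c("precision", "recall", "f1", "accuracy")], 2),
               data.frame(precision = 0.97, recall = 0.90, f1 = 0.93, accuracy = 0.90),
               ignore_attr = TRUE)
  r13 <- detection_metrics(list(tp = 75, fp = 4, fn = 1), nfp = 76)
  expect_equal(round_half_up(r13[, c("precision", "recall", "f1", "accuracy")], 2),
               data.frame(precision = 0.95, recall = 0.99, f1 = 0.97, accuracy = 0.99),
               ignore_attr = TRUE)

  r0 <- detection_metrics(list(tp = 0, fp = 0, fn = 5), nfp = 5)
  expect_true(is.na(r0$precision) && is.na(r0$f1))
  expect_equal(r0$recall, 0)
  expect_equal(r0$accuracy, 0)

  expect_error(detection_metrics(list(tp = 3, fp = 0, fn = 0), nfp = 0), "inconsistent")
})

test_that("the metrics table averages unrounded columns and is order-invariant", {
  rows <- rbind(
    detection_metrics(list(tp = 10, fp = 1, fn = 2), nfp = 12, picture_id = "a"),
    detection_metrics(list(tp = 20, fp = 0, fn = 5), nfp = 25, picture_id = "b"),
    detection_metrics(list(tp = 7, fp = 3, fn = 1), nfp = 8, picture_id = "c")
  )
  tab <- metrics_table(rows)
  avg <- tab[tab$picture_id == "Avg", ]
  expect_equal(avg$tp, mean(rows$tp))
  expect_equal(avg$f1, mean(rows$f1))
  perm <- metrics_table(rows[c(3, 1, 2), ])
  expect_equal(perm[perm$picture_id == "Avg", -1], avg[, -1], ignore_attr = TRUE)

  one <- metrics_table(rows[1, ])
  expect_equal(one[2, -1], one[1, -1], ignore_attr = TRUE)
})

test_that("MAE and RMSE evaluate their defining formulas", {
  expect_equal(mae(1:5, 1:5), 0)
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(mae(c(1, 2, 3), c(2, 2, 5)), 1)
  expect_equal(rmse(c(1, 2, 3), c(2, 2, 5)), sqrt(5 / 3))
  expect_equal(mae(1:4, 1:4 + 2.5), 2.5)
  expect_equal(rmse(1:4, 1:4 + 2.5), 2.5)
  expect_error(mae(1:3, 1:4), "lengths differ")
  expect_error(rmse(numeric(), numeric()), "nonempty")

  set.seed(52)
  for (i in 1:1000) {
    n <- pick(2:30)
    a <- stats::rnorm(n); f <- stats::rnorm(n)
    expect_gte(rmse(a, f) + 1e-12, mae(a, f))
  }
})

test_that("linear_fit reproduces hand-computed OLS", {
  f <- linear_fit(0:10, 2 * (0:10) + 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r_squared, 1)

  g <- linear_fit(c(0, 1, 2), c(0, 1, 3))
  expect_equal(g$slope, 1.5)
  expect_equal(g$intercept, -1 / 6)
  expect_equal(g$r_squared, 27 / 28)

  # R^2 invariant under affine rescaling of y
  set.seed(53)
  x <- stats::runif(20); y <- 3 * x + stats::rnorm(20, sd = 0.3)
  expect_equal(linear_fit(x, 5 * y - 2)$r_squared, linear_fit(x, y)$r_squared)

  expect_error(linear_fit(1:2, 1:2), "n >= 3")
  expect_error(linear_fit(rep(1, 5), 1:5), "constant")
})
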