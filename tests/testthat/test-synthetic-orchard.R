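test_that("layout places trees on the rotated grid with deterministic ids", {
  cfg <- orchard_config(n_rows = 0, trees_per_row = 5)
  expect_equal(nrow(build_layout(cfg)), 0L)

  cfg <- orchard_config(n_rows = 2, trees_per_row = 2, inter_row_m = 3, intra_row_m = 1)
  lay <- build_layout(cfg)
  expect_equal(nrow(lay), 4L)
  expect_setequal(paste(lay$x, lay$y), c("0 0", "0 1", "3 0", "3 1"))
  expect_false(anyDuplicated(lay$tree_id) > 0)
  expect_equal(lay$tree_id, lay$tree_id[order(lay$row_index, lay$position_in_row)])

  # a 90-degree bearing turns the row axis from +y onto +x
  cfg90 <- orchard_config(n_rows = 1, trees_per_row = 3, row_bearing_deg = 90)
  lay90 <- build_layout(cfg90)
  expect_equal(lay90$x, c(0, 1, 2))
  expect_equal(lay90$y, c(0, 0, 0), tolerance = 1e-12)

  full <- build_layout(orchard_config())
  expect_equal(nrow(full), 14L * 41L)  # 574 trees at the default field layout
})

test_that("fruit counts apportion exactly and reproduce configured statistics", {
  cfg <- orchard_config(
    n_rows = 2, trees_per_row = 3, total_count_range = c(5, 5),
    stratum_mean_fractions = c(0.2, 0.4, 0.4), stratum_concentration = Inf
  )
  s <- sample_fruit_counts(build_layout(cfg), cfg, seed = 1)
  expect_true(all(s$trees$total == 5L))
  expect_true(all(s$trees$count_top == 1L & s$trees$count_middle == 2L &
                    s$trees$count_underside == 2L))

  # conservation holds for arbitrary configs and seeds
  for (seed in c(3, 99)) {
    cfg <- orchard_config(n_rows = 4, trees_per_row = 10, seed = seed)
    s <- sample_fruit_counts(build_layout(cfg), cfg)
    expect_equal(s$trees$count_top + s$trees$count_middle + s$trees$count_underside,
                 s$trees$total)
    expect_equal(nrow(s$fruits), sum(s$trees$total))
  }

  # 1000 trees at defaults: sample means recover the configured targets
  cfg <- orchard_config(n_rows = 25, trees_per_row = 40)
  s <- sample_fruit_counts(build_layout(cfg), cfg, seed = 42)
  expect_lt(abs(mean(s$trees$total) - 255.16) / 255.16, 0.03)
  expect_lt(abs(100 * mean(s$trees$count_top / s$trees$total) - 27.31), 2)
})

test_that("visibility flags follow the per-stratum probabilities", {
  cfg <- orchard_config(n_rows = 1, trees_per_row = 5, visibility_probs = c(1, 0, 0))
  s <- sample_fruit_counts(build_layout(cfg), cfg, seed = 2)
  fr <- assign_visibility(s$fruits, cfg)
  vis <- tapply(fr$visible, fr$tree_id, sum)
  expect_equal(as.integer(vis[s$trees$tree_id]), s$trees$count_top)

  cfg0 <- orchard_config(n_rows = 1, trees_per_row = 2, visibility_probs = c(0, 0, 0))
  s0 <- sample_fruit_counts(build_layout(cfg0), cfg0, seed = 2)
  fr0 <- assign_visibility(s0$fruits, cfg0)
  expect_false(any(fr0$visible))

  # closed form: E[visible fraction] = sum(fraction * prob) ~ 0.359
  cfg <- orchard_config(n_rows = 10, trees_per_row = 5, visibility_probs = c(0.9, 0.3, 0))
  s <- sample_fruit_counts(build_layout(cfg), cfg, seed = 5)
  expect_gt(nrow(s$fruits), 1e4)
  fr <- assign_visibility(s$fruits, cfg, seed = 6)
  expected <- sum(cfg$visibility_probs * cfg$stratum_mean_fractions)
  expect_lt(abs(mean(fr$visible) - expected), 0.02)
})

test_that("rendered scenes carry exact truth geometry", {
  cfg <- orchard_config(
    n_rows = 1, trees_per_row = 1, total_count_range = c(1, 1),
    visibility_probs = c(1, 1, 1), gsd_m = 0.01, canopy_diameter_m = 0.8,
    noise_sd = 0, seed = 3
  )
  b <- simulate_orchard(cfg)
  expect_equal(nrow(b$truth$boxes), 1L)
  ctr_px <- c((b$truth$boxes$xmin + b$truth$boxes$xmax) / 2,
              (b$truth$boxes$ymin + b$truth$boxes$ymax) / 2)
  ctr_world <- pixel_to_world(b$raster$transform, ctr_px)
  expect_lt(max(abs(ctr_world - c(b$fruits$x, b$fruits$y))) / cfg$gsd_m, 1)

  cfg0 <- orchard_config(n_rows = 1, trees_per_row = 2, visibility_probs = c(0, 0, 0),
                         gsd_m = 0.01, noise_sd = 0, seed = 3)
  b0 <- simulate_orchard(cfg0)
  expect_equal(nrow(b0$truth$boxes), 0L)

  # one truth box per visible fruit, all inside the raster
  b2 <- simulate_orchard(clean_scene_config())
  expect_equal(nrow(b2$truth$boxes), sum(b2$fruits$visible))
  expect_true(all(b2$truth$boxes$xmin >= 0 & b2$truth$boxes$ymin >= 0 &
                    b2$truth$boxes$xmax <= b2$truth$width &
                    b2$truth$boxes$ymax <= b2$truth$height))
})

test_that("identical config and seed give bit-identical scenes", {
  cfg <- clean_scene_config(seed = 21)
  b1 <- simulate_orchard(cfg)
  b2 <- simulate_orchard(cfg)
  expect_identical(b1$raster$pixels, b2$raster$pixels)
  expect_identical(b1$trees, b2$trees)
  expect_identical(b1$fruits, b2$fruits)
  expect_identical(b1$truth$boxes, b2$truth$boxes)
})

test_that("oversized renders hit the pixel budget guard", {
  cfg <- orchard_config(n_rows = 2, trees_per_row = 2)  # 4.18 mm/px default
  expect_error(simulate_orchard(cfg, max_pixels = 1e5), "pixel budget")
})

test_that("invalid orchard configurations are rejected", {
  expect_error(orchard_config(stratum_mean_fractions = c(0.5, 0.4, 0.2)), "summing to 1")
  expect_error(orchard_config(visibility_probs = c(1.2, 0, 0)), "probabilities")
  expect_error(orchard_config(total_count_range = c(10, 5)), "ordered")
  expect_error(orchard_config(gsd_m = 0), "gsd_m")
})
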