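test_that("VOC I/O converts between 1-based inclusive and half-open boxes", {
  tmp <- withr::local_tempdir()
  voc <- c(
    "<annotation><filename>fix1</filename>",
    "<size><width>20</width><height>15</height><depth>3</depth></size>",
    "<object><name>apple</name><bndbox>",
    "<xmin>1</xmin><ymin>1</ymin><xmax>10</xmax><ymax>10</ymax>",
    "</bndbox></object></annotation>"
  )
  p <- file.path(tmp, "fix.xml")
  writeLines(voc, p)
  ann <- read_voc(p)
  expect_equal(as.numeric(ann$boxes[1, c("xmin", "ymin", "xmax", "ymax")]),
               c(0, 0, 10, 10))

  # write -> read identity, including empty sets and scores
  ann2 <- annotation_set("img", 50, 40, data.frame(
    xmin = c(0, 12), ymin = c(5, 0), xmax = c(7, 50), ymax = c(9, 40),
    label = "apple", score = c(NA, 0.75)
  ))
  p2 <- file.path(tmp, "rt.xml")
  write_voc(ann2, p2)
  back <- read_voc(p2)
  expect_equal(back$boxes[, c("xmin", "ymin", "xmax", "ymax", "label", "score")],
               ann2$boxes[, c("xmin", "ymin", "xmax", "ymax", "label", "score")])
  expect_equal(back$width, 50L)

  empty <- annotation_set("none", 10, 10)
  p3 <- file.path(tmp, "empty.xml")
  write_voc(empty, p3)
  expect_equal(nrow(read_voc(p3)$boxes), 0L)

  writeLines("<annotation><filename>x</filename></annotation>", file.path(tmp, "bad.xml"))
  expect_error(read_voc(file.path(tmp, "bad.xml")), "<size>")
})

test_that("tiling clips boxes with the min-visibility rule and loses no area", {
  img1 <- array(0L, c(416, 416, 3))
  ann1 <- annotation_set("a", 416, 416,
                         data.frame(xmin = 10, ymin = 10, xmax = 60, ymax = 50))
  tiles <- tile_image(img1, ann1)
  expect_length(tiles, 1L)
  expect_equal(tiles[[1]]$annotations$boxes$xmax, 60)

  img2 <- array(0L, c(416, 832, 3))
  ann2 <- annotation_set("b", 832, 416,
                         data.frame(xmin = 400, ymin = 100, xmax = 432, ymax = 132))
  tiles2 <- tile_image(img2, ann2, min_visibility = 0.25)
  expect_length(tiles2, 2L)
  b1 <- tiles2[[1]]$annotations$boxes
  b2 <- tiles2[[2]]$annotations$boxes
  expect_equal(as.numeric(b1[1, c("xmin", "ymin", "xmax", "ymax")]), c(400, 100, 416, 132))
  expect_equal(as.numeric(b2[1, c("xmin", "ymin", "xmax", "ymax")]), c(0, 100, 16, 132))

  # min_visibility = 1: straddling boxes survive in no tile
  tiles3 <- tile_image(img2, ann2, min_visibility = 1)
  expect_equal(sum(vapply(tiles3, function(t) nrow(t$annotations$boxes), integer(1))), 0L)

  # partition property: clipped areas of every box sum to its original area
  set.seed(31)
  img <- array(0L, c(200, 300, 3))
  b <- rand_boxes(12, canvas = 180)
  b$box_id <- seq_len(nrow(b))
  ann <- annotation_set("c", 300, 200, b)
  tiles4 <- tile_image(img, ann, tile_size = 64, min_visibility = 0)
  clipped <- do.call(rbind, lapply(tiles4, function(t) t$annotations$boxes))
  area <- function(bb) (bb$xmax - bb$xmin) * (bb$ymax - bb$ymin)
  by_id <- tapply(area(clipped), clipped$box_id, sum)
  expect_equal(as.numeric(by_id[as.character(b$box_id)]), area(b), tolerance = 1e-9)

  # remainder tiles keep native size
  sizes <- vapply(tiles4, function(t) dim(t$image)[2], integer(1))
  expect_true(all(sizes %in% c(64L, 300L %% 64L)))
})

test_that("rotations remap boxes exactly and preserve area", {
  img <- array(seq_len(200 * 100 * 3) %% 256L, c(200, 100, 3))  # H=200, W=100
  ann <- annotation_set("r", 100, 200,
                        data.frame(xmin = 10, ymin = 20, xmax = 30, ymax = 40))
  r90 <- rotate_annotated(img, ann, 90)
  expect_equal(as.numeric(r90$annotations$boxes[1, c("xmin", "ymin", "xmax", "ymax")]),
               c(160, 10, 180, 30))
  expect_equal(dim(r90$image)[1:2], c(100L, 200L))

  r180 <- rotate_annotated(img, ann, 180)
  back <- rotate_annotated(r180$image, r180$annotations, 180)
  expect_identical(back$image, img)
  expect_equal(back$annotations$boxes, ann$boxes)

  expect_error(rotate_annotated(img, ann, 45), "90, 180 or 270")

  # pixel-level mask oracle over random boxes and all three angles
  set.seed(32)
  for (i in 1:200) {
    W <- sample(10:40, 1); H <- sample(10:40, 1)
    x1 <- pick(0:(W - 2)); x2 <- pick((x1 + 1):(W - 1)) + 1L
    y1 <- pick(0:(H - 2)); y2 <- pick((y1 + 1):(H - 1)) + 1L
    box <- data.frame(xmin = x1, ymin = y1, xmax = x2, ymax = y2)
    angle <- sample(c(90, 180, 270), 1)
    small <- array(0L, c(H, W, 3))
    got <- rotate_annotated(small, annotation_set("o", W, H, box), angle)$annotations$boxes
    want <- rotated_bbox_oracle(box, W, H, angle)
    expect_equal(as.numeric(got[1, c("xmin", "ymin", "xmax", "ymax")]), unname(want))
    expect_equal((got$xmax - got$xmin) * (got$ymax - got$ymin),
                 (x2 - x1) * (y2 - y1))
  }
})

test_that("brightness/contrast applies the clipped linear map", {
  img <- array(100L, c(4, 4, 3))
  expect_identical(brightness_contrast(img, 1, 0), img)
  expect_true(all(brightness_contrast(img, 1.2, 10) == 130L))
  expect_true(all(brightness_contrast(array(250L, c(2, 2, 3)), 1.1, 0) == 255L))
  expect_true(all(brightness_contrast(array(10L, c(2, 2, 3)), 1, -50) == 0L))
  expect_error(brightness_contrast(img, 0, 1), "alpha")
})

test_that("augmentation expands the dataset by the configured factor", {
  set.seed(33)
  mk_tile <- function(i) {
    list(
      image = array(sample(0:255, 16 * 16 * 3, TRUE), c(16, 16, 3)),
      annotations = annotation_set(paste0("t", i), 16, 16,
                                   data.frame(xmin = 2, ymin = 3, xmax = 9, ymax = 12))
    )
  }
  ds <- lapply(1:10, mk_tile)
  p3 <- augment_params(rotations = c(90, 180), color_settings = list())
  expect_equal(p3$factor, 3L)
  out <- augment_dataset(ds, p3)
  expect_length(out, 30L)
  expect_length(augment_dataset(list(), p3), 0L)

  # every output annotation satisfies the set invariants (constructor-checked)
  for (item in out) {
    a <- item$annotations
    expect_s3_class(annotation_set(a$image_id, a$width, a$height,
                                   if (nrow(a$boxes)) a$boxes else NULL),
                    "annotation_set")
    expect_equal(dim(item$image)[1:2], c(a$height, a$width))
  }

  p4 <- augment_params(color_settings = list(c(1.2, 10)))
  expect_equal(p4$factor, 5L)
  expect_length(augment_dataset(ds[1:2], p4), 10L)
  expect_error(augment_params(rotations = 45), "90, 180, 270")
})
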