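make_three_class_image <- function() {
  # left third berry-ish, middle rachis-ish, right background-ish
  px <- array(0, dim = c(9, 9, 3))
  px[, 1:3, 1] <- 0.1; px[, 1:3, 2] <- 0.1; px[, 1:3, 3] <- 0.8
  px[, 4:6, 1] <- 0.4; px[, 4:6, 2] <- 0.2; px[, 4:6, 3] <- 0.1
  px[, 7:9, ] <- 1
  rgb_image(px, id = "tri")
}

tri_picks <- data.frame(row = c(4, 4, 4), col = c(1, 4, 7),
                        label = c("berry", "rachis", "background"))

test_that("training patches store block means as prototypes", {
  img <- make_three_class_image()
  ts <- build_training_set(img, tri_picks)
  expect_length(ts$patches, 3)
  expect_equal(ts$patches[[1]]$prototype, c(0.1, 0.1, 0.8))
  expect_equal(ts$patches[[2]]$prototype, c(0.4, 0.2, 0.1))
  # prototype is the mean of the 9 stored pixel colors
  for (p in ts$patches) {
    expect_equal(p$prototype, colMeans(p$pixel_colors))
  }
  # two picks with the same label are both retained
  ts2 <- build_training_set(img, rbind(tri_picks,
                                       data.frame(row = 2, col = 1,
                                                  label = "berry")))
  expect_length(ts2$patches, 4)
})

test_that("training-set preconditions are enforced", {
  img <- make_three_class_image()
  expect_error(build_training_set(img, tri_picks[1:2, ]),
               "incomplete training set.*background")
  border <- rbind(tri_picks, data.frame(row = 0, col = 4, label = "berry"))
  expect_error(build_training_set(img, border), "outside the image")
})

test_that("segmentation assigns nearest prototypes, matching brute force", {
  img <- make_three_class_image()
  ts <- build_training_set(img, tri_picks)
  mask <- segment_image(img, ts)
  expect_equal(unique(as.vector(mask$labels[, 1:3])), 1L)
  expect_equal(unique(as.vector(mask$labels[, 4:6])), 2L)
  expect_equal(unique(as.vector(mask$labels[, 7:9])), 3L)

  # exhaustive-distance oracle on random pixels
  set.seed(5)
  px <- array(runif(12 * 12 * 3), dim = c(12, 12, 3))
  rimg <- rgb_image(px)
  rmask <- segment_image(rimg, ts)
  proto <- do.call(rbind, lapply(ts$patches, `[[`, "prototype"))
  for (i in sample.int(144, 25)) {
    r <- (i - 1) %% 12 + 1; cc <- (i - 1) %/% 12 + 1
    d <- colSums((t(proto) - px[r, cc, ])^2)
    expect_equal(rmask$labels[r, cc], which.min(d))
  }

  # near-white pixel goes to background
  one <- rgb_image(array(0.9, dim = c(1, 1, 3)))
  expect_equal(as.vector(segment_image(one, ts)$labels), 3L)
})

test_that("distance ties break toward berry, and duplicates change nothing", {
  # training image: left half R = 0.2, right half R = 0.8
  px <- array(0, dim = c(6, 6, 3))
  px[, 1:3, 1] <- 0.2
  px[, 4:6, 1] <- 0.8
  img <- rgb_image(px)
  # rachis shares the background prototype exactly; classification of a 0.8
  # pixel ties between them and must go to rachis (higher priority)
  picks <- data.frame(row = c(2, 2, 2), col = c(1, 4, 4),
                      label = c("berry", "background", "rachis"))
  ts <- build_training_set(img, picks)
  probe <- array(0, dim = c(1, 3, 3))
  probe[1, , 1] <- c(0.2, 0.5, 0.8)  # berry color, halfway, shared color
  pimg <- rgb_image(probe)
  mask <- segment_image(pimg, ts)
  expect_equal(as.vector(mask$labels), c(1L, 1L, 2L))  # tie 0.5 -> berry

  # permuting patch order leaves the mask unchanged
  ts_perm <- build_training_set(img, picks[c(3, 1, 2), ])
  expect_identical(segment_image(pimg, ts_perm)$labels, mask$labels)

  # adding a duplicate prototype never changes the mask
  ts_dup <- build_training_set(img, rbind(picks, picks[1, ]))
  expect_identical(segment_image(pimg, ts_dup)$labels, mask$labels)

  # segmenting twice is identical (deterministic)
  expect_identical(segment_image(pimg, ts)$labels, mask$labels)
})

test_that("export keeps foreground colors, whitens background, round-trips labels", {
  set.seed(9)
  out <- generate_cluster_image(small_cluster_spec(seed = 3))
  seg_path <- withr::local_tempfile(fileext = ".png")
  lab_path <- withr::local_tempfile(fileext = ".png")
  export_segmented(out$image, out$mask, seg_path, lab_path)

  seg <- read_image(seg_path)
  bg <- out$mask$labels == 3L
  for (ch in 1:3) {
    plane <- seg$pixels[, , ch]
    expect_true(all(plane[bg] == 1))
    orig <- out$image$pixels[, , ch]
    expect_true(max(abs(plane[!bg] - orig[!bg])) <= 1 / 255)
  }
  expect_identical(read_label_mask(lab_path)$labels, out$mask$labels)

  bad <- label_mask(matrix(3L, 2, 2))
  expect_error(export_segmented(out$image, bad, seg_path), "dimensions")
})

test_that("all-background masks export as pure white", {
  img <- uniform_image(c(0.3, 0.6, 0.2), 4, 4)
  mask <- label_mask(matrix(3L, 4, 4))
  p <- withr::local_tempfile(fileext = ".png")
  export_segmented(img, mask, p)
  expect_true(all(read_image(p)$pixels == 1))
})

test_that("evaluation metrics match a hand-computed confusion matrix", {
  truth <- label_mask(matrix(c(1L, 1L, 2L, 3L), 2, 2))
  pred <- label_mask(matrix(c(1L, 2L, 2L, 1L), 2, 2))
  ev <- evaluate_segmentation(pred, truth)
  expect_equal(ev$accuracy, 0.5)
  pc <- ev$per_class
  expect_equal(pc$precision[pc$class == "berry"], 1 / 2)
  expect_equal(pc$recall[pc$class == "berry"], 1 / 2)
  expect_equal(pc$precision[pc$class == "rachis"], 1 / 2)
  expect_equal(pc$recall[pc$class == "rachis"], 1)
  expect_true(is.na(pc$precision[pc$class == "background"]))
  expect_equal(pc$recall[pc$class == "background"], 0)

  expect_equal(evaluate_segmentation(truth, truth)$accuracy, 1)
  # complementary two-class masks: zero accuracy
  a <- label_mask(matrix(1L, 3, 3)); b <- label_mask(matrix(2L, 3, 3))
  expect_equal(evaluate_segmentation(a, b)$accuracy, 0)
  # absent classes in truth are reported as undefined, not zero
  ev2 <- evaluate_segmentation(a, b)
  expect_true(is.na(ev2$per_class$precision[1]))
  expect_error(evaluate_segmentation(a, label_mask(matrix(1L, 2, 2))),
               "dimensions")
})
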