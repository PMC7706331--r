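test_that("HSI follows the arccos formulation", {
  h <- rgb_to_hsi(c(1, 0, 0))
  expect_equal(as.numeric(h), c(0, 1, 1 / 3))
  expect_false(attr(h, "achromatic"))

  # theta = 120 with B > G takes the 360 - theta branch
  h2 <- rgb_to_hsi(c(0, 0, 1))
  expect_equal(h2[1, "H"][[1]], 240)
  expect_equal(h2[1, "S"][[1]], 1)

  # achromatic pixels: S = 0, H = 0 and flagged
  for (g in c(0.2, 0.5, 1)) {
    hg <- rgb_to_hsi(c(g, g, g))
    expect_equal(as.numeric(hg), c(0, 0, g))
    expect_true(attr(hg, "achromatic"))
  }
  expect_equal(as.numeric(rgb_to_hsi(c(0, 0, 0))), c(0, 0, 0))

  # hexcone cross-check at primaries and secondaries, where the two hue
  # definitions coincide
  cols <- rbind(c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                c(0, 1, 1), c(0, 0, 1), c(1, 0, 1))
  got <- rgb_to_hsi(cols)[, "H"]
  hexcone <- grDevices::rgb2hsv(t(cols * 255))["h", ] * 360
  expect_equal(unname(got), unname(hexcone), tolerance = 1e-9)

  expect_error(rgb_to_hsi(c(1.2, 0, 0)), "\\[0, 1\\]")
})

test_that("CIELAB conversion hits the D65 white point and is monotone in L", {
  lab_white <- rgb_to_lab(c(1, 1, 1))
  expect_equal(lab_white[1, "L"][[1]], 100, tolerance = 1e-4)
  expect_lt(abs(lab_white[1, "a"]), 0.01)
  expect_lt(abs(lab_white[1, "b"]), 0.01)
  expect_equal(as.numeric(rgb_to_lab(c(0, 0, 0))), c(0, 0, 0))

  greys <- rgb_to_lab(rbind(c(0.4, 0.4, 0.4), c(0.5, 0.5, 0.5),
                            c(0.6, 0.6, 0.6)))
  expect_true(all(abs(greys[, c("a", "b")]) < 0.01))
  expect_true(greys[1, "L"] < greys[2, "L"] && greys[2, "L"] < greys[3, "L"])

  # independent oracle: grDevices sRGB -> Lab conversion (its primaries are
  # derived from chromaticities, so agreement is to ~0.3 Lab units)
  set.seed(13)
  cols <- matrix(runif(30), ncol = 3)
  ours <- rgb_to_lab(cols)
  oracle <- grDevices::convertColor(cols, from = "sRGB", to = "Lab")
  expect_lt(max(abs(ours - oracle)), 0.5)
})

test_that("greyscale values apply the stated weights", {
  expect_equal(as.numeric(grey_values(c(255, 255, 255))), c(255, 255))
  expect_equal(as.numeric(grey_values(c(255, 0, 0))), c(76.245, 85))
  expect_equal(grey_values(c(60, 120, 180))[1, "weighted_grey"][[1]],
               0.299 * 60 + 0.587 * 120 + 0.114 * 180)
  # weighted grey of any achromatic color equals its channel value
  for (v in c(0, 17, 128.5, 255)) {
    expect_equal(grey_values(c(v, v, v))[1, "weighted_grey"][[1]], v)
  }
})

test_that("cluster summaries convert the mean berry color", {
  img <- uniform_image(c(0.2, 0.2, 0.6), 4, 4)
  mask <- label_mask(matrix(1L, 4, 4))
  s <- summarize_cluster(img, mask, unit_id = "u")
  expect_equal(c(s$R, s$G, s$B), c(51, 51, 153))
  expect_equal(s$I, 85)
  expect_equal(s$n_berry_pixels, 16)
  one <- grapecolor:::color_traits_from_rgb01(c(0.2, 0.2, 0.6))
  expect_equal(s[, COLOR_TRAITS], one[, COLOR_TRAITS], ignore_attr = TRUE)

  # two berry pixels, black and white: summary equals conversion of the mean
  px <- array(0, dim = c(1, 2, 3)); px[1, 2, ] <- 1
  s2 <- summarize_cluster(rgb_image(px), label_mask(matrix(1L, 1, 2)))
  expect_equal(c(s2$R, s2$G, s2$B), c(127.5, 127.5, 127.5))

  # non-berry pixels do not affect the summary
  set.seed(3)
  px3 <- array(rep(c(0.3, 0.4, 0.5), each = 16), dim = c(4, 4, 3))
  labs <- matrix(3L, 4, 4); labs[2:3, 2:3] <- 1L
  base <- summarize_cluster(rgb_image(px3), label_mask(labs))
  px4 <- px3
  px4[1, , ] <- runif(12)   # perturb background row
  pert <- summarize_cluster(rgb_image(px4), label_mask(labs))
  expect_equal(base[, COLOR_TRAITS], pert[, COLOR_TRAITS])

  expect_error(summarize_cluster(rgb_image(px3),
                                 label_mask(matrix(3L, 4, 4))),
               "no berry pixels")
})

test_that("intensity and average grey are identical, and scale linearly", {
  set.seed(21)
  for (i in 1:20) {
    rgb01 <- runif(3)
    s <- grapecolor:::color_traits_from_rgb01(rgb01)
    expect_identical(s$I, s$average_grey)
    # scaling a chromatic color scales I and the greys, leaves H unchanged
    if (max(rgb01) - min(rgb01) > 1e-6) {
      cf <- runif(1, 0.1, 1)
      sc <- grapecolor:::color_traits_from_rgb01(cf * rgb01)
      expect_equal(sc$I, cf * s$I)
      expect_equal(sc$average_grey, cf * s$average_grey)
      expect_equal(sc$weighted_grey, cf * s$weighted_grey)
      expect_equal(sc$H, s$H, tolerance = 1e-9)
    }
  }
})

test_that("genotype aggregation averages traits and sums pixel counts", {
  img <- uniform_image(c(0.2, 0.2, 0.6), 4, 4)
  mask <- label_mask(matrix(1L, 4, 4))
  s <- summarize_cluster(img, mask, unit_id = "g1")

  twelve <- do.call(rbind, replicate(12, s, simplify = FALSE))
  agg <- aggregate_genotype(twelve)
  expect_equal(agg[, COLOR_TRAITS], s[, COLOR_TRAITS])
  expect_equal(agg$n_berry_pixels, 12 * 16)

  s2 <- s; s2$R <- 120; s$R <- 100
  pair <- aggregate_genotype(rbind(s, s2))
  expect_equal(pair$R, 110)

  expect_error(aggregate_genotype(list()), "no summaries")
})
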