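test_that("write/read round trip is bit-exact at matching depth", {
  set.seed(11)
  img <- rgb_image(array(runif(5 * 7 * 3), dim = c(5, 7, 3)), id = "rt")

  p8 <- withr::local_tempfile(fileext = ".png")
  write_image(img, p8, depth = 8)
  back8 <- read_image(p8)
  expect_equal(back8$bit_depth, 8L)
  expect_equal(back8$pixels * 255,
               array(grapecolor:::round_half_away(img$pixels * 255),
                     dim = dim(img$pixels)))
  # writing the read-back image reproduces the file pixels exactly
  p8b <- withr::local_tempfile(fileext = ".png")
  write_image(back8, p8b, depth = 8)
  expect_identical(read_image(p8b)$pixels, back8$pixels)

  p16 <- withr::local_tempfile(fileext = ".tiff")
  write_image(img, p16, depth = 16)
  back16 <- read_image(p16)
  expect_equal(back16$bit_depth, 16L)
  expect_true(max(abs(back16$pixels - img$pixels)) <= 1 / 65535)
  expect_equal(back16$pixels * 65535,
               array(grapecolor:::round_half_away(img$pixels * 65535),
                     dim = dim(img$pixels)))
})

test_that("scaling and quantization follow the stated conventions", {
  white <- uniform_image(c(1, 1, 1), 2, 2)
  p <- withr::local_tempfile(fileext = ".png")
  write_image(white, p, depth = 8)
  expect_true(all(read_image(p)$pixels == 1))

  # round-half-away-from-zero: 0.5 * 255 = 127.5 stores as 128
  mid <- uniform_image(c(0.5, 0.5, 0.5), 2, 2)
  write_image(mid, p, depth = 8)
  expect_true(all(read_image(p)$pixels * 255 == 128))

  # 16-bit scale definition: stored k reads back as k / 65535
  t16 <- withr::local_tempfile(fileext = ".tif")
  write_image(uniform_image(rep(32767 / 65535, 3), 2, 2), t16, depth = 16)
  expect_equal(unique(as.vector(read_image(t16)$pixels)), 32767 / 65535)
})

test_that("channel handling: alpha dropped, 1/2-channel rejected", {
  p <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(runif(3 * 3 * 4), dim = c(3, 3, 4)), p)
  expect_warning(img <- read_image(p), "alpha")
  expect_equal(dim(img$pixels)[3], 3L)

  png::writePNG(matrix(runif(9), 3, 3), p)
  expect_error(read_image(p), "1 channel")
  png::writePNG(array(runif(3 * 3 * 2), dim = c(3, 3, 2)), p)
  expect_error(read_image(p), "2 channels")
  expect_error(read_image("no/such/file.png"), "not found")
})

test_that("measure_patches averages boxes and validates geometry", {
  img <- uniform_image(c(0.2, 0.4, 0.6), 8, 8)
  m <- measure_patches(img, data.frame(x0 = 1, y0 = 1, x1 = 5, y1 = 4))
  expect_equal(as.numeric(m), c(0.2, 0.4, 0.6))

  # 2-pixel patch mixing black and white
  px <- array(0, dim = c(1, 2, 3)); px[1, 2, ] <- 1
  img2 <- rgb_image(px)
  m2 <- measure_patches(img2, data.frame(x0 = 0, y0 = 0, x1 = 2, y1 = 1))
  expect_equal(as.numeric(m2), c(0.5, 0.5, 0.5))

  # checkerboard red channel 0.1/0.3 averages to 0.2
  px <- array(0.5, dim = c(4, 4, 3))
  px[, , 1] <- matrix(c(0.1, 0.3), 4, 4)[, ]  # alternating rows
  img3 <- rgb_image(px)
  m3 <- measure_patches(img3, data.frame(x0 = 0, y0 = 0, x1 = 4, y1 = 4))
  expect_equal(m3[1, "R"][[1]], 0.2)

  expect_error(measure_patches(img, data.frame(x0 = 0, y0 = 0, x1 = 9, y1 = 2)),
               "box 1")
  expect_error(measure_patches(img, data.frame(x0 = 3, y0 = 0, x1 = 3, y1 = 2)),
               "empty")
})

test_that("fit_color_correction recovers exact affine relations", {
  ref <- colorchecker_classic()$reference_rgb
  # measured == reference: identity map, zero offset, zero rmse
  t0 <- fit_color_correction(ref, ref)
  expect_equal(t0$matrix, diag(3), tolerance = 1e-10)
  expect_equal(t0$offset, rep(0, 3), tolerance = 1e-10)
  expect_lt(t0$fit_rmse, 1e-12)

  # measured = 0.5 * reference: matrix 2 I
  t2 <- fit_color_correction(0.5 * ref, ref)
  expect_equal(t2$matrix, 2 * diag(3), tolerance = 1e-8)
  expect_equal(t2$offset, rep(0, 3), tolerance = 1e-8)
})

test_that("fit matches the normal-equations oracle on a random affine map", {
  set.seed(41)
  M <- diag(3) + matrix(rnorm(9, 0, 0.15), 3)
  b <- rnorm(3, 0, 0.04)
  ref <- colorchecker_classic()$reference_rgb
  measured <- t(solve(M) %*% (t(ref) - b))  # so that M x + b = ref exactly
  fit <- fit_color_correction(measured, ref)
  expect_equal(fit$matrix, M, tolerance = 1e-8)
  expect_equal(fit$offset, b, tolerance = 1e-8)

  # independent oracle: direct normal-equations solve
  X <- cbind(1, measured)
  beta <- solve(t(X) %*% X, t(X) %*% ref)
  expect_equal(fit$matrix, t(beta[-1, ]), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(fit$offset, as.numeric(beta[1, ]), tolerance = 1e-10)
})

test_that("degenerate correction fits are rejected", {
  ref <- colorchecker_classic()$reference_rgb
  expect_error(fit_color_correction(ref[1:3, ], ref[1:3, ]), "at least 4")
  grey <- matrix(rep(seq(0.1, 0.8, length.out = 6), 3), ncol = 3)
  expect_error(fit_color_correction(grey, grey), "singular")
})

test_that("apply_correction maps pixels affinely and clips to [0, 1]", {
  img <- uniform_image(c(0.3, 0.5, 0.7), 3, 3)
  ident <- fit_color_correction(colorchecker_classic()$reference_rgb,
                                colorchecker_classic()$reference_rgb)
  expect_equal(apply_correction(img, ident)$pixels, img$pixels,
               tolerance = 1e-10)

  shift <- ident
  shift$offset <- c(0.1, 0.1, 0.1)
  out <- apply_correction(uniform_image(c(0, 0, 0), 2, 2), shift)
  expect_true(all(abs(out$pixels - 0.1) < 1e-12))

  # out-of-gamut results clipped
  big <- ident
  big$matrix <- 5 * diag(3)
  clipped <- apply_correction(img, big)
  expect_true(max(clipped$pixels) <= 1 && min(clipped$pixels) >= 0)
  expect_true(all(clipped$pixels[, , 2] == 1))
})
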