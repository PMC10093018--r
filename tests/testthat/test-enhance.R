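test_that("dark channel handles constant images and propagates minima", {
  img <- intensity_image(matrix(0.5, 6, 6))
  expect_equal(dark_channel(img, 3), matrix(0.5, 6, 6))

  m <- matrix(0.8, 7, 7)
  m[4, 4] <- 0
  dc <- dark_channel(intensity_image(m), 3)
  expect_equal(sum(dc == 0), 9)          # the pixel and its 8 neighbours
  expect_true(all(dc[3:5, 3:5] == 0))
})

test_that("dark channel and atmospheric light match brute-force oracles", {
  for (seed in 1:3) {
    img <- random_image(8, 8, 3, seed = seed)
    a <- unclass(img)
    dc <- dark_channel(img, 3)
    expect_equal(dc, oracle_dark_channel(a, 3))
    expect_true(all(dc <= pmin(a[, , 1], a[, , 2], a[, , 3]) + 1e-12))
    expect_equal(atmospheric_light(img, dc, 0.1),
                 oracle_atmospheric_light(a, dc, 0.1))
  }
  # larger grayscale instance
  img <- random_image(16, 16, 1, seed = 9)
  expect_equal(dark_channel(img, 5), oracle_dark_channel(unclass(img), 5))
})

test_that("atmospheric light selects the brightest haze-opaque pixels", {
  img <- intensity_image(matrix(0.7, 5, 5))
  dc <- dark_channel(img, 3)
  expect_equal(atmospheric_light(img, dc, 0.5), 0.7)

  m <- matrix(0.2, 5, 5)
  m[3, 3] <- 1.0
  img <- intensity_image(m)
  dc <- dark_channel(img, 1)  # unit window keeps the bright pixel isolated
  expect_equal(atmospheric_light(img, dc, 1 / 25), 1.0)
  expect_error(atmospheric_light(img, dc, 0), "fraction")
})

test_that("transmission map obeys its limits and composes the oracles", {
  black <- intensity_image(matrix(0, 6, 6))
  expect_equal(transmission_map(black, 0.9, 0.95, 3), matrix(1, 6, 6))

  flat <- intensity_image(matrix(0.8, 6, 6))
  expect_equal(transmission_map(flat, 0.8, 0.95, 3),
               matrix(0.05, 6, 6))

  img <- random_image(8, 8, 3, seed = 4)
  a <- unclass(img)
  light <- c(0.9, 0.85, 0.95)
  norm <- a
  for (cc in 1:3) norm[, , cc] <- a[, , cc] / light[cc]
  expected <- pmin(pmax(1 - 0.95 * oracle_dark_channel(norm, 3), 0), 1)
  expect_equal(transmission_map(img, light, 0.95, 3), expected)

  # monotone: larger omega never increases transmission
  t1 <- transmission_map(img, light, 0.7, 3)
  t2 <- transmission_map(img, light, 0.95, 3)
  expect_true(all(t2 <= t1 + 1e-12))
  expect_error(transmission_map(img, c(0, 0.5, 0.5), 0.95, 3), "zero")
})

test_that("radiance recovery inverts the haze model", {
  img <- random_image(6, 6, 1, seed = 2)
  t1 <- matrix(1, 6, 6)
  expect_equal(unclass(recover_radiance(img, t1, 0.9, 0.1)), unclass(img))

  flat <- intensity_image(matrix(0.6, 6, 6))
  t <- matrix(runif(36), 6, 6)
  expect_equal(unclass(recover_radiance(flat, t, 0.6, 0.1))[, , 1],
               matrix(0.6, 6, 6))

  one <- intensity_image(matrix(0.8, 1, 1))
  y <- recover_radiance(one, matrix(0.5, 1, 1), 1.0, 0.1)
  expect_equal(as.vector(unclass(y)), 0.6)  # (0.8 - 1)/0.5 + 1
})

test_that("global contrast enhancement follows the adopted parenthesization", {
  const <- intensity_image(matrix(0.4, 4, 4))
  expect_equal(unclass(global_contrast_enhance(const, 0.5))[, , 1],
               matrix(0, 4, 4))

  img <- random_image(6, 6, 1, seed = 3)
  raw <- global_contrast_enhance(img, 0, clip_output = FALSE)
  v <- as.vector(unclass(img))
  sigma <- sqrt(mean((v - mean(v))^2))
  expect_equal(mean(raw), sigma, tolerance = 1e-12)

  # half 0.2 / half 0.8, Ck = 1: kmean = 0.5, sigma = 0.3; clipped
  # outputs are exactly {0, 0.9}
  two <- matrix(c(rep(0.2, 8), rep(0.8, 8)), 4, 4)
  clipped <- unclass(global_contrast_enhance(intensity_image(two), 1))
  expect_equal(sort(unique(round(as.vector(clipped), 10))), c(0.0, 0.9))
})

test_that("local contrast enhancement matches windowed-statistics oracle", {
  const <- intensity_image(matrix(0.3, 5, 5))
  expect_equal(unclass(local_contrast_enhance(const, 0.5, 0.01, 3))[, , 1],
               matrix(0.3, 5, 5))

  img <- random_image(5, 5, 1, seed = 5)
  expect_equal(unclass(local_contrast_enhance(img, 0, 0.01, 3))[, , 1],
               unclass(img)[, , 1])

  step <- matrix(0.2, 5, 5); step[, 4:5] <- 0.8
  st <- oracle_local_stats(step, 3)
  expected <- pmin(pmax(step + (0.1 / (st$sd + 0.01)) * (step - st$mean),
                        0), 1)
  got <- unclass(local_contrast_enhance(intensity_image(step), 0.1, 0.01,
                                        3))[, , 1]
  expect_equal(got, expected)
  expect_error(local_contrast_enhance(img, 0.1, 0, 3), "local_alpha")
})

test_that("HRLG enhancement is deterministic, shape-preserving and bounded", {
  img <- random_image(24, 20, 1, seed = 7)
  p <- enhance_params(patch_size = 7, local_window = 5)
  e1 <- hrlg_enhance(img, p)
  e2 <- hrlg_enhance(img, p)
  expect_identical(unclass(e1), unclass(e2))
  expect_equal(dim(unclass(e1)), dim(unclass(img)))
  expect_true(all(unclass(e1) >= 0 & unclass(e1) <= 1))

  # 3-channel input comes back 3-channel
  img3 <- random_image(12, 12, 3, seed = 8)
  e3 <- hrlg_enhance(img3, p)
  expect_equal(dim(unclass(e3))[3], 3)

  stages <- hrlg_enhance(img, p, keep_stages = TRUE)
  expect_named(stages, c("enhanced", "dehazed", "global", "local",
                         "transmission", "light"))
  # fusion identity: g = L = I pointwise implies CF = I
  I <- unclass(img)[, , 1]
  expect_equal(pmin(pmax(I + I - I, 0), 1), I)
})

test_that("enhancement raises RMS contrast of hazed lesion images", {
  sim <- make_synthetic_mammograms(image_synthesis_spec(
    n_per_class = 2, side = 64, seed = 0))
  p <- enhance_params()
  gains <- vapply(sim$images, function(im)
    rms_contrast(hrlg_enhance(im, p)) - rms_contrast(im), numeric(1))
  expect_true(mean(gains > 0) >= 0.75)
})

test_that("PNG and TIFF round-trips preserve pixel data", {
  img <- random_image(9, 7, 1, seed = 11)
  for (ext in c("png", "tiff")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_image(img, f)
    back <- read_image(f)
    expect_equal(unclass(back)[, , 1], unclass(img)[, , 1],
                 tolerance = 1 / 255)
    unlink(f)
  }
})
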