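# Image containers, file I/O, phantom generation, noise simulators.

test_that("PNG and TIFF round trips preserve pixel content and bit depth", {
  px <- matrix(sample(0:255, 24 * 16, replace = TRUE), 24, 16)
  img <- csImage(px, 8L)
  fp <- withr::local_tempfile(fileext = ".png")
  writeImageFile(img, fp)
  back <- readImageFile(fp)
  expect_equal(pixels(back), px)
  expect_identical(bitDepth(back), 8L)

  # constant-image round trip
  fc <- withr::local_tempfile(fileext = ".png")
  writeImageFile(csImage(matrix(128, 8, 8)), fc)
  expect_true(all(pixels(readImageFile(fc)) == 128))

  # 16-bit TIFF keeps the full range
  px16 <- matrix(sample(0:65535, 64, replace = TRUE), 8, 8)
  ft <- withr::local_tempfile(fileext = ".tif")
  writeImageFile(csImage(px16, 16L), ft)
  b16 <- readImageFile(ft)
  expect_identical(bitDepth(b16), 16L)
  expect_identical(dynamicRange(b16), 65535)
  expect_equal(pixels(b16), px16)

  # RGB round trip
  arr <- array(sample(0:255, 3 * 64, replace = TRUE), c(8, 8, 3))
  fr <- withr::local_tempfile(fileext = ".png")
  writeImageFile(csImage(arr), fr)
  expect_equal(pixels(readImageFile(fr)), arr)
})

test_that("export clips to the representable range and rounds half away from zero", {
  px <- matrix(c(300, -4.2, 127.5, 127.49, 254.5, 0.5, 10, 20), 2, 4)
  fp <- withr::local_tempfile(fileext = ".png")
  writeImageFile(csImage(px), fp)
  out <- pixels(readImageFile(fp))
  expect_equal(out[1, 1], 255)   # clipped high
  expect_equal(out[2, 1], 0)     # clipped low
  expect_equal(out[1, 2], 128)   # .5 rounds away from zero
  expect_equal(out[2, 2], 127)
  expect_equal(out[1, 3], 255)
  expect_equal(out[2, 3], 1)
})

test_that("unreadable files and unsupported formats are rejected", {
  expect_error(readImageFile(file.path(tempdir(), "nope-missing.png")),
               "no such file")
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines("x", f)
  expect_error(readImageFile(f), "unsupported")
  expect_error(writeImageFile(csImage(matrix(0, 4, 4), 16L),
                              withr::local_tempfile(fileext = ".png")),
               "8-bit")
})

test_that("phantom is deterministic, in range, and degenerates to a constant", {
  a <- makePhantom(64, 64, seed = 3)
  b <- makePhantom(64, 64, seed = 3)
  expect_identical(pixels(a), pixels(b))
  expect_true(all(pixels(a) >= 0 & pixels(a) <= 255))
  expect_false(identical(pixels(a), pixels(makePhantom(64, 64, seed = 4))))

  flat <- makePhantom(64, 64, texturePeriod = 0, nShapes = 0, seed = 1)
  expect_equal(stats::sd(pixels(flat)), 0)
  expect_equal(totalVariation(pixels(flat)), 0)
  expect_error(makePhantom(16, 64), "32")
})

test_that("phantom texture strips contain many exact duplicate blocks (seeds 0-9)", {
  # brute-force scan for pairwise-identical disjoint period-sized blocks
  for (seed in 0:9) {
    ph <- makePhantom(128, 128, texturePeriod = 8, seed = seed)
    px <- pixels(ph)
    keys <- character(0)
    for (r in seq(65, 121, by = 8))
      for (cc in seq(1, 121, by = 8))
        keys <- c(keys, paste(px[r:(r + 7), cc:(cc + 7)], collapse = ","))
    counts <- table(keys)
    expect_gte(max(counts), 16)
  }
})

test_that("Gaussian noise has the declared moments and exact degenerate limits", {
  ph <- makePhantom(64, 64, seed = 1)
  expect_identical(pixels(addGaussianNoise(ph, 0, 0, seed = 5)), pixels(ph))
  shifted <- addGaussianNoise(ph, 0, 5, seed = 5)
  expect_equal(pixels(shifted), pixels(ph) + 5)
  expect_error(addGaussianNoise(ph, -1), "sigma")

  big <- makePhantom(256, 256, seed = 2)
  noisy <- addGaussianNoise(big, 20, seed = 7)
  diffs <- pixels(noisy) - pixels(big)
  # sample sd of 65536 N(0, 20) draws: chi-distribution concentration
  expect_lt(abs(stats::sd(diffs) - 20), 3 * 20 / sqrt(2 * 65535))
  expect_lt(abs(mean(diffs)), 4 * 20 / sqrt(65536))
  # determinism
  expect_identical(pixels(addGaussianNoise(big, 20, seed = 7)), pixels(noisy))
})

test_that("salt-and-pepper corrupts the declared fraction and nothing else", {
  ph <- makePhantom(64, 64, seed = 1)
  expect_identical(pixels(addSaltPepperNoise(ph, q = 0, seed = 1)), pixels(ph))
  sat <- addSaltPepperNoise(ph, q1 = 0.5, q2 = 0.5, seed = 2)
  expect_true(all(pixels(sat) %in% c(0, 255)))
  expect_error(addSaltPepperNoise(ph, q1 = 0.6, q2 = 0.6), "<= 1")

  big <- makePhantom(256, 256, seed = 2)
  # shift so clean pixels can never equal the salt/pepper values
  base <- csImage(pmin(pmax(pixels(big), 3), 252))
  noisy <- addSaltPepperNoise(base, q1 = 0.1, q2 = 0.1, seed = 3)
  changed <- pixels(noisy) != pixels(base)
  expect_true(all(pixels(noisy)[changed] %in% c(0, 255)))
  # untouched pixels are bit-identical
  expect_identical(pixels(noisy)[!changed], pixels(base)[!changed])
  # binomial concentration of the corrupted fraction
  expect_lt(abs(mean(changed) - 0.2), 3 * sqrt(0.2 * 0.8 / 65536))
})
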