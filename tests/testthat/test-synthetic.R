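test_that("sample generation is bit-deterministic given a seed", {
  p <- scene_params(101, "easy")
  s1 <- generate_sample(p)
  s2 <- generate_sample(scene_params(101, "easy"))
  expect_identical(s1$image, s2$image)
  expect_identical(s1$mask, s2$mask)
})

test_that("masks are a single connected ellipse with the analytic area", {
  skip_if_not_installed("EBImage")
  for (seed in c(1, 2, 3, 4, 5)) {
    s <- generate_sample(scene_params(seed, "easy"))
    lab <- EBImage::bwlabel(s$mask)
    expect_equal(max(lab), 1)                  # exactly one component
    p <- s$params
    analytic <- pi * p$disc_axes[1] * p$disc_axes[2] /
      (480 * 640) * 256 * 256                  # area survives the resize
    expect_lt(abs(sum(s$mask) - analytic) / analytic, 0.10)
  }
})

test_that("images and masks are valid across many seeds and difficulties", {
  for (seed in 1:25) {
    diff <- if (seed %% 2 == 0) "easy" else "blurred"
    s <- generate_sample(scene_params(seed, diff))
    expect_true(all(s$mask %in% c(0, 1)))
    expect_true(all(s$image >= 0 & s$image <= 1))
    expect_true(all(is.finite(s$image)))
    frac <- mean(s$mask)
    expect_gt(frac, 0.003)
    expect_lt(frac, 0.06)
  }
})

test_that("the contrast knob monotonically separates disc from background", {
  wins <- 0L
  for (seed in 1:20) {
    p_hi <- scene_params(seed, "easy"); p_hi$disc_contrast <- 0.8
    p_lo <- scene_params(seed, "easy"); p_lo$disc_contrast <- 0.2
    contrast_of <- function(s) {
      inside <- s$mask == 1
      mean(s$image[, , 2][inside]) - mean(s$image[, , 2][!inside])
    }
    if (contrast_of(generate_sample(p_hi)) > contrast_of(generate_sample(p_lo)))
      wins <- wins + 1L
  }
  expect_identical(wins, 20L)
})

test_that("dataset generation writes complete, reproducible trees", {
  d1 <- file.path(tempdir(), "dsA")
  d2 <- file.path(tempdir(), "dsB")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- generate_dataset(12, c(easy = 0.5, blurred = 0.5), seed = 5, out_dir = d1)
  m2 <- generate_dataset(12, c(easy = 0.5, blurred = 0.5), seed = 5, out_dir = d2)
  expect_equal(nrow(m1), 12L)
  imgs <- list.files(file.path(d1, "images"), recursive = TRUE)
  msks <- list.files(file.path(d1, "masks"), recursive = TRUE)
  expect_length(imgs, 12L)
  expect_identical(imgs, msks)
  expect_identical(m1, m2)
  h1 <- tools::md5sum(list.files(d1, recursive = TRUE, full.names = TRUE))
  h2 <- tools::md5sum(list.files(d2, recursive = TRUE, full.names = TRUE))
  expect_identical(unname(h1), unname(h2))
  expect_identical(sum(m1$difficulty == "easy"), 6L)
})

test_that("split sizes follow the floor-then-distribute rule", {
  expect_identical(odseg:::apportion(10, c(train = 0.6, val = 0.2, test = 0.2)),
                   c(6L, 2L, 2L))
  expect_identical(odseg:::apportion(7, c(a = 0.5, b = 0.5)), c(4L, 3L))
  expect_identical(sum(odseg:::apportion(11, c(0.34, 0.33, 0.33))), 11L)
  d <- file.path(tempdir(), "dsSplit")
  unlink(d, recursive = TRUE)
  mf <- generate_dataset(10, c(easy = 1), seed = 2, out_dir = d)
  expect_identical(as.integer(table(mf$split)[c("train", "val", "test")]),
                   c(6L, 2L, 2L))
})

test_that("horizontal flip is an involution and reflects the mask centroid", {
  s <- generate_sample(scene_params(42, "easy"))
  f1 <- augment(s, seed = 1, p_flip = 1, p_rot = 0, p_affine = 0)
  f2 <- augment(f1, seed = 2, p_flip = 1, p_rot = 0, p_affine = 0)
  expect_identical(f2$image, s$image)
  expect_identical(f2$mask, s$mask)
  W <- ncol(s$mask)
  col0 <- mean(which(s$mask == 1, arr.ind = TRUE)[, 2])
  col1 <- mean(which(f1$mask == 1, arr.ind = TRUE)[, 2])
  expect_lt(abs(col1 - (W + 1 - col0)), 1)
})

test_that("rotation keeps the mask binary and nearly area-preserving", {
  s <- generate_sample(scene_params(17, "easy"))
  area0 <- sum(s$mask)
  for (seed in 1:20) {
    a <- augment(s, seed = seed, p_flip = 0, p_rot = 1, p_affine = 0)
    expect_true(all(a$mask %in% c(0, 1)))
    expect_lt(abs(sum(a$mask) - area0) / area0, 0.05)
    expect_true(all(a$image >= 0 & a$image <= 1))
  }
})

test_that("augmentation draws are reproducible and leave the input untouched", {
  s <- generate_sample(scene_params(23, "blurred"))
  before <- s$mask
  a1 <- augment(s, seed = 9)
  a2 <- augment(s, seed = 9)
  expect_identical(a1$image, a2$image)
  expect_identical(a1$mask, a2$mask)
  expect_identical(s$mask, before)
})
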