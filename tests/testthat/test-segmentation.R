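test_that("RGB to XYZ follows the CIE matrix and is linear", {
  px <- function(r, g, b) array(c(r, g, b), c(1, 1, 3))
  expect_equal(as.vector(rgb_to_xyz(px(0, 0, 0))), c(0, 0, 0))
  w <- as.vector(rgb_to_xyz(px(1, 1, 1)))
  expect_equal(w, rep(1 / 0.17697, 3), tolerance = 1e-3)  # rows sum to 1
  r <- as.vector(rgb_to_xyz(px(1, 0, 0)))
  expect_equal(r, c(0.49, 0.17697, 0) / 0.17697, tolerance = 1e-12)
  set.seed(2)
  p <- array(runif(3), c(1, 1, 3))
  expect_equal(rgb_to_xyz(p * 0.37), rgb_to_xyz(p) * 0.37)
})

test_that("channel normalization handles pure, gray and black pixels", {
  px <- function(r, g, b) array(c(r, g, b), c(1, 1, 3))
  nz <- function(p) normalize_channels(p, rgb_to_xyz(p))
  expect_equal(as.vector(nz(px(1, 0, 0))$Rhat), 1)
  expect_equal(as.vector(nz(px(0.42, 0.42, 0.42))$Rhat), 1 / sqrt(3),
               tolerance = 1e-12)
  expect_equal(as.vector(nz(px(0.9, 0.9, 0.9))$Rhat), 1 / sqrt(3),
               tolerance = 1e-12)
  expect_equal(as.vector(nz(px(0, 0, 0))$Rhat), 0)
  set.seed(3)
  img <- array(runif(25 * 25 * 3), c(25, 25, 3))
  ch <- nz(img)
  expect_true(all(ch$Rhat >= 0 & ch$Rhat <= 1))
  expect_true(all(ch$Xhat >= 0 & ch$Xhat <= 1))
})

test_that("Otsu separates a bimodal channel and rejects constants", {
  ch <- matrix(rep(c(0.1, 0.9), each = 50), 10)
  t <- otsu_threshold(ch)
  expect_gt(t, 0.1); expect_lt(t, 0.9)
  expect_true(all((ch <= t) == (ch == 0.1)))
  expect_error(otsu_threshold(matrix(1, 5, 5)), "degenerate")
})

test_that("incremental Otsu equals the exhaustive between-class-variance scan", {
  set.seed(10)
  for (i in 1:20) {
    n <- sample(c(100, 400, 900), 1)
    ch <- switch(sample(3, 1),
                 matrix(runif(n), ncol = 10),
                 matrix(c(rnorm(n / 2, 0.3, 0.05), rnorm(n / 2, 0.7, 0.1)),
                        ncol = 10),
                 matrix(rbeta(n, 2, 5), ncol = 10))
    nb <- sample(c(32, 64, 256), 1)
    expect_equal(otsu_threshold(ch, nb), otsu_bruteforce(ch, nb))
  }
  # two-point histogram with unequal masses
  ch <- matrix(c(rep(0.2, 25), rep(0.8, 75)), 10)
  expect_equal(otsu_threshold(ch, 16), otsu_bruteforce(ch, 16))
})

test_that("Otsu class split is invariant to positive linear rebinning", {
  set.seed(11)
  ch <- matrix(rnorm(400, 0.5, 0.2), 20)
  t1 <- otsu_threshold(ch)
  t2 <- otsu_threshold(3 * ch + 10)
  expect_equal((ch <= t1), (3 * ch + 10 <= t2))
})

test_that("morphological fill, open and close behave canonically", {
  m <- matrix(FALSE, 20, 20); m[5:15, 5:15] <- TRUE
  holed <- m; holed[9:10, 9:10] <- FALSE
  filled <- morphology(holed, "fill", "disk5")
  expect_equal(sum(filled), sum(holed) + 4)
  expect_equal(filled, m)

  lone <- matrix(FALSE, 9, 9); lone[5, 5] <- TRUE
  expect_false(any(morphology(lone, "open", matrix(TRUE, 3, 3))))

  set.seed(12)
  for (i in 1:5) {
    r <- matrix(runif(400) < 0.4, 20)
    for (se in list("identity5", "disk5")) {
      once <- morphology(r, "close", se)
      expect_identical(morphology(once, "close", se), once)
    }
  }
})

test_that("segmentation recovers a dark disk and keeps the largest blob", {
  mask <- disk_mask(96, 22)
  img <- skin_image(96, mask = mask)
  seg <- segment_lesion(img)
  expect_s3_class(seg, "lesion_mask")
  expect_gte(dice_coefficient(seg$mask, mask), 0.95)
  lab <- EBImage::bwlabel(EBImage::Image(seg$mask * 1))
  expect_equal(max(lab), 1)  # single connected component

  # small blob off the main diagonal so the diagonal fill cannot bridge them
  two <- disk_mask(96, 13) | disk_mask(96, 4, cx = 24, cy = 80)
  seg2 <- segment_lesion(skin_image(96, mask = two))
  expect_gte(dice_coefficient(seg2$mask, disk_mask(96, 13)), 0.9)
  expect_equal(sum(seg2$mask & disk_mask(96, 4, cx = 24, cy = 80)), 0)

  flat <- array(rep(c(0.85, 0.6, 0.5), each = 64 * 64), c(64, 64, 3))
  expect_error(segment_lesion(flat), "empty|degenerate")
})
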