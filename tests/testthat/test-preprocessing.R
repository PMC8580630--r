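test_that("contrast stretch maps observed range onto [0,1] via the 8-bit LUT", {
  m <- matrix(c(50, 150, 150, 50), 2)
  out <- contrast_stretch(m)
  expect_equal(out, matrix(c(0, 1, 1, 0), 2))
  full <- matrix(0:255, 16)
  sf <- contrast_stretch(full)
  expect_equal(range(sf), c(0, 1))
  expect_warning(z <- contrast_stretch(matrix(3, 4, 4)), "degenerate")
  expect_true(all(z == 0))
})

test_that("contrast stretch is invariant to positive affine rescaling", {
  set.seed(1)
  x <- matrix(runif(400, 10, 90), 20)
  expect_equal(contrast_stretch(2.5 * x + 7), contrast_stretch(x))
  expect_equal(contrast_stretch(x / 1000 - 3), contrast_stretch(x))
})

test_that("rule base training keeps one max-degree rule per cell", {
  nb1 <- matrix(0.5, 1, 9)
  rb <- train_wm_rulebase(nb1, 0.9, n_partitions = 3)
  expect_s3_class(rb, "wm_rulebase")
  expect_equal(nrow(rb$rules), 1)
  expect_equal(rb$rules$consequent, 0.9)

  # two pairs landing in the same cell: degrees 1.0 (all at the partition
  # center) vs 0.8^3 (all off-center); the high-degree consequent wins
  nb <- rbind(matrix(0.5, 1, 9), matrix(0.4, 1, 9))
  rb2 <- train_wm_rulebase(nb, c(0.9, 0.1), n_partitions = 3)
  expect_equal(nrow(rb2$rules), 1)
  expect_equal(rb2$rules$consequent, 0.9)

  expect_error(train_wm_rulebase(matrix(numeric(0), 0, 9), numeric(0)),
               "no training pairs")
  expect_error(train_wm_rulebase(matrix(2, 1, 9), 0.5), "\\[0, 1\\]")
})

test_that("an identity-task rule base reproduces inputs within a partition", {
  set.seed(4)
  img <- matrix(runif(32 * 32, 0.1, 0.9), 32)
  img <- denoise(img)  # smooth it so neighborhoods are coherent
  nbs <- t(sapply(sample(which(row(img) %in% 2:31 & col(img) %in% 2:31), 300),
                  function(ix) {
                    r <- ((ix - 1) %% 32) + 1; cc <- ((ix - 1) %/% 32) + 1
                    as.vector(img[(r - 1):(r + 1), (cc - 1):(cc + 1)])
                  }))
  rb <- train_wm_rulebase(nbs, nbs[, 5], n_partitions = 7)
  out <- denoise(img, rb)
  expect_lt(max(abs(out - img)), 1 / 6 + 1e-3)  # about one partition width
})

test_that("the 3x3 median filter matches a brute-force median oracle", {
  set.seed(41)
  img <- matrix(runif(18 * 15), 18, 15)
  pad <- img[c(1, 1:18, 18), c(1, 1:15, 15)]  # replicate border
  oracle <- matrix(0, 18, 15)
  for (r in 1:18) for (cc in 1:15)
    oracle[r, cc] <- median(pad[r:(r + 2), cc:(cc + 2)])
  expect_equal(denoise(img), oracle)
})

test_that("median fallback removes impulse noise and fixes constants", {
  const <- matrix(0.4, 12, 12)
  expect_equal(denoise(const), const)
  salt <- const; salt[6, 6] <- 1
  expect_equal(denoise(salt), const)
})

test_that("denoising reduces error on Gaussian-corrupted images", {
  set.seed(8)
  clean <- outer(seq(0.2, 0.8, length.out = 48), seq(0.3, 0.7, length.out = 48),
                 function(a, b) (a + b) / 2)
  noisy <- pmin(pmax(clean + matrix(rnorm(48^2, 0, 0.05), 48), 0), 1)
  den <- denoise(noisy)
  expect_lt(mean(abs(den - clean)), mean(abs(noisy - clean)))
  expect_gte(min(den), 0)
  expect_lte(max(den), 1)
})

test_that("denoising is idempotent within tolerance on noiseless images", {
  img <- outer(seq(0, 1, length.out = 40), seq(0, 1, length.out = 40),
               function(a, b) (a + b) / 2)
  once <- denoise(img)
  twice <- denoise(once)
  # replicate-padding biases the four corner medians on a diagonal
  # gradient, and that bias walks inward one pixel per pass; away from
  # that 2-pixel corner margin the filter is an exact fixed point
  core <- 3:38
  expect_lt(max(abs(twice[core, core] - once[core, core])), 1e-3)
  expect_lt(mean(abs(twice - once)), 1e-3)
  const <- matrix(0.7, 30, 30)
  expect_identical(denoise(denoise(const)), denoise(const))
  ramp <- matrix(seq(0, 1, length.out = 40), 40, 40)  # 1-D gradient
  expect_equal(denoise(denoise(ramp)), denoise(ramp))
})
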