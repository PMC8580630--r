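test_that("co-occurrence matrix normalizes and counts adjacencies", {
  g <- matrix(0.5, 8, 8)
  m <- matrix(TRUE, 8, 8)
  G <- glcm(g, m, levels = 8)
  expect_equal(sum(G$matrix), 1)
  expect_equal(sum(G$matrix != 0), 1)  # constant region: single entry

  cb <- matrix(rep(c(0, 1), 32), 8)   # checkerboard columns alternate by row
  G2 <- glcm(cb, m, levels = 2, offset = c(1L, 0L))
  expect_equal(sum(diag(G2$matrix)), 0)
  expect_equal(sum(G2$matrix), 1)

  set.seed(5)
  G3 <- glcm(matrix(runif(100), 10), matrix(TRUE, 10, 10), levels = 16)
  expect_lt(abs(sum(G3$matrix) - 1), 1e-12)
  expect_equal(G3$matrix, t(G3$matrix))  # symmetrized
  expect_error(glcm(g, matrix(FALSE, 8, 8)), "empty")
})

test_that("moment invariants are symmetric, translation- and scale-invariant", {
  d <- disk_mask(101, 30)
  phi <- hu_invariants(d)
  expect_lt(phi["phi2"], 1e-6)   # rotational symmetry

  big <- matrix(FALSE, 160, 160)
  big[31:131, 31:131] <- disk_mask(101, 30)
  shifted <- matrix(FALSE, 160, 160)
  shifted[8:108, 45:145] <- disk_mask(101, 30)
  expect_equal(hu_invariants(big), hu_invariants(shifted), tolerance = 1e-9)

  small <- disk_mask(101, 20)
  scaled <- disk_mask(201, 40)
  expect_equal(hu_invariants(small)[["phi1"]], hu_invariants(scaled)[["phi1"]],
               tolerance = 1e-3)
  expect_error(hu_invariants(matrix(0, 4, 4)), "zero-mass")
})

test_that("a 10x10 solid square yields the hand-counted geometry", {
  m <- matrix(FALSE, 20, 20); m[6:15, 6:15] <- TRUE
  img <- array(0.5, c(20, 20, 3))
  f <- extract_features(img, m)
  expect_equal(f[["area"]], 100)
  expect_equal(f[["perimeter"]], 36)
  expect_equal(f[["solidity"]], 1)
  expect_equal(f[["irregularity_index"]], 4 * pi * 100 / 36^2, tolerance = 1e-12)
  expect_equal(f[["eccentricity"]], 0)        # a = b for a square
  expect_equal(f[["entropy"]], 0)             # constant intensity
  expect_equal(f[["variance"]], 0)
})

test_that("a disk is rounder than an equal-area star", {
  d <- disk_mask(101, 30)
  s <- star_mask(101, 30, amp = 0.3, k = 8)
  img <- array(0.4, c(101, 101, 3))
  expect_gt(extract_features(img, d)[["irregularity_index"]],
            extract_features(img, s)[["irregularity_index"]])
})

test_that("literal mode reproduces the printed contrast/energy duplication", {
  set.seed(6)
  img <- array(runif(40 * 40 * 3), c(40, 40, 3))
  m <- disk_mask(40, 15)
  lit <- extract_features(img, m, mode = "literal")
  expect_identical(lit[["contrast"]], lit[["energy"]])
  std <- extract_features(img, m, mode = "standard")
  expect_false(identical(std[["contrast"]], std[["energy"]]))
})

test_that("features are translation-invariant and scale-covariant", {
  set.seed(7)
  base <- matrix(FALSE, 120, 120)
  base[31:71, 26:66] <- star_mask(41, 14, amp = 0.2, k = 5)
  tex <- matrix(runif(120 * 120), 120)
  img <- array(rep(tex, 3), c(120, 120, 3))
  sh <- matrix(FALSE, 120, 120)
  sh[36:76, 33:73] <- star_mask(41, 14, amp = 0.2, k = 5)
  tex_sh <- matrix(0.5, 120, 120)
  tex_sh[36:76, 33:73] <- tex[31:71, 26:66]
  img_sh <- array(rep(tex_sh, 3), c(120, 120, 3))
  f1 <- extract_features(img, base)
  f2 <- extract_features(img_sh, sh)
  expect_equal(f1, f2, tolerance = 1e-9)

  d1 <- extract_features(img, disk_mask(120, 20))
  d2 <- extract_features(img, disk_mask(120, 40))
  expect_equal(d2[["area"]] / d1[["area"]], 4, tolerance = 0.05)
  expect_equal(d2[["perimeter"]] / d1[["perimeter"]], 2, tolerance = 0.1)
})

test_that("every feature is finite on generator output", {
  set.seed(9)
  for (i in 1:4) {
    sp <- lesion_spec(image_size = 96,
                      irregularity = runif(1, 0, 0.3),
                      asymmetry = runif(1, 0, 0.3),
                      color_variance = runif(1, 0, 0.1),
                      hair_count = sample(0:2, 1))
    g <- generate_image(sp)
    f <- extract_features(g$image, g$mask)
    expect_true(all(is.finite(f)))
    expect_length(f, 19)
    expect_gt(f[["solidity"]], 0); expect_lte(f[["solidity"]], 1)
    expect_gt(f[["homogeneity"]], 0); expect_lte(f[["homogeneity"]], 1)
  }
})
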