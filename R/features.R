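#' Gray-level co-occurrence matrix over a masked region
#'
#' Counts pairs of quantized gray levels at a fixed pixel offset where both
#' pixels belong to the mask; the matrix is symmetrized and normalized to
#' sum to one.
#'
#' @param gray 2-D numeric matrix.
#' @param mask Logical matrix of the same shape.
#' @param levels Number of quantization levels (>= 2).
#' @param offset Integer `(drow, dcol)` displacement.
#' @return Object of class `"glcm"`: `levels`, `offset`, `matrix`.
#' @export
glcm <- function(gray, mask, levels = 32L, offset = c(0L, 1L)) {
  stopifnot(identical(dim(gray), dim(mask)))
  levels <- as.integer(levels)
  if (levels < 2L) stop("levels must be >= 2", call. = FALSE)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  vals <- gray[mask]
  lo <- min(vals); hi <- max(vals)
  q <- if (hi > lo) {
    pmin(levels, 1L + floor((gray - lo) / (hi - lo) * levels))
  } else {
    array(1L, dim = dim(gray))
  }
  dim(q) <- dim(gray)
  nr <- nrow(gray); nc <- ncol(gray)
  dr <- offset[1]; dc <- offset[2]
  r1 <- seq_len(nr - abs(dr)); c1 <- seq_len(nc - abs(dc))
  if (dr < 0) r1 <- r1 - dr
  if (dc < 0) c1 <- c1 - dc
  a_idx <- cbind(rep(r1, times = length(c1)), rep(c1, each = length(r1)))
  b_idx <- cbind(a_idx[, 1] + dr, a_idx[, 2] + dc)
  ok <- mask[a_idx] & mask[b_idx]
  if (sum(ok) < 1L) stop("mask has too few paired pixels", call. = FALSE)
  ia <- q[a_idx][ok]; ib <- q[b_idx][ok]
  m <- matrix(0, levels, levels)
  tab <- table(factor(ia, levels = seq_len(levels)),
               factor(ib, levels = seq_len(levels)))
  m <- unclass(tab) + t(unclass(tab))    # symmetric
  m <- m / sum(m)
  structure(list(levels = levels, offset = as.integer(offset), matrix = m),
            class = "glcm")
}

#' Invariant moments of a region
#'
#' Central image moments normalized for scale give `eta_pq`; the first three
#' moment invariants are `phi1 = eta20 + eta02`,
#' `phi2 = (eta20 - eta02)^2 + 4 eta11^2`,
#' `phi3 = (eta30 - 3 eta12)^2 + (3 eta21 - eta03)^2`. Invariant to
#' translation and (for phi1 especially) to scale.
#'
#' @param region Numeric or logical matrix of pixel weights (a binary mask
#'   or masked gray values); total mass must be positive.
#' @return Named numeric vector `c(phi1, phi2, phi3)`.
#' @export
hu_invariants <- function(region) {
  w <- region * 1
  m00 <- sum(w)
  if (m00 <= 0) stop("zero-mass region", call. = FALSE)
  rows <- row(w); cols <- col(w)
  xc <- sum(cols * w) / m00; yc <- sum(rows * w) / m00
  dx <- cols - xc; dy <- rows - yc
  mu <- function(p, q) sum(dx^p * dy^q * w)
  eta <- function(p, q) mu(p, q) / m00^(1 + (p + q) / 2)
  e20 <- eta(2, 0); e02 <- eta(0, 2); e11 <- eta(1, 1)
  e30 <- eta(3, 0); e03 <- eta(0, 3); e21 <- eta(2, 1); e12 <- eta(1, 2)
  c(phi1 = e20 + e02,
    phi2 = (e20 - e02)^2 + 4 * e11^2,
    phi3 = (e30 - 3 * e12)^2 + (3 * e21 - e03)^2)
}

#' Luminance of an RGB array
#'
#' Rec. 709 weights: `0.2126 R + 0.7152 G + 0.0722 B`.
#'
#' @param image H x W x 3 RGB array (a 2-D matrix is returned unchanged).
#' @return 2-D matrix.
#' @export
luminance <- function(image) {
  if (length(dim(image)) == 2L) return(image)
  0.2126 * image[, , 1] + 0.7152 * image[, , 2] + 0.0722 * image[, , 3]
}

# Convex-hull pixel count of a mask (union with the mask itself so solidity
# can never exceed 1 on degenerate/collinear regions).
.convex_area <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) < 3L) return(nrow(pts))
  h <- grDevices::chull(pts[, 2], pts[, 1])
  if (length(h) < 3L) return(nrow(pts))
  bnd <- list(x = pts[h, 2], y = pts[h, 1])
  rr <- range(pts[, 1]); cr <- range(pts[, 2])
  grid <- expand.grid(r = rr[1]:rr[2], cc = cr[1]:cr[2])
  inside <- mgcv::in.out(cbind(c(bnd$x, bnd$x[1]), c(bnd$y, bnd$y[1])),
                         cbind(grid$cc, grid$r))
  conv <- matrix(FALSE, nrow(mask), ncol(mask))
  conv[cbind(grid$r, grid$cc)] <- inside
  sum(conv | mask)
}

# Perimeter as the count of region pixels 4-adjacent to background (image
# border counts as background).
.perimeter <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  up <- pad[1:nr, 2:(nc + 1L)]; down <- pad[3:(nr + 2L), 2:(nc + 1L)]
  left <- pad[2:(nr + 1L), 1:nc]; right <- pad[2:(nr + 1L), 3:(nc + 2L)]
  sum(core & !(up & down & left & right))
}

.glcm_stats <- function(P, mode) {
  i <- row(P); j <- col(P)
  if (mode == "literal") {
    # the printed table duplicates the energy formula for contrast and
    # places mu_r mu_c / sigma_r sigma_c outside the sum for correlation
    contrast <- sum(P^2)
    energy <- sum(P^2)
    mu_r <- sum(i * P); mu_c <- sum(j * P)
    s_r <- sqrt(sum((i - mu_r)^2 * P)); s_c <- sqrt(sum((j - mu_c)^2 * P))
    correlation <- if (s_r > 0 && s_c > 0) (sum(P) - mu_r * mu_c) / (s_r * s_c) else 0
  } else {
    contrast <- sum((i - j)^2 * P)
    energy <- sum(P^2)
    mu_r <- sum(i * P); mu_c <- sum(j * P)
    s_r <- sqrt(sum((i - mu_r)^2 * P)); s_c <- sqrt(sum((j - mu_c)^2 * P))
    correlation <- if (s_r > 0 && s_c > 0)
      sum((i - mu_r) * (j - mu_c) * P) / (s_r * s_c) else 0
  }
  homogeneity <- sum(P / (1 + abs(i - j)))
  c(contrast = contrast, energy = energy, correlation = correlation,
    homogeneity = homogeneity)
}

#' Extract the lesion feature vector
#'
#' Computes the statistical (mean, variance, standard deviation, entropy),
#' geometric (area, perimeter, rectangularity, irregularity index, form
#' factor, eccentricity, elongation, solidity), co-occurrence texture
#' (contrast, energy, correlation, homogeneity) and invariant-moment
#' (phi1-phi3) features of a segmented lesion.
#'
#' Geometric descriptors use the second-moment ellipse axis lengths `a >= b`
#' (four times the square roots of the coordinate-covariance eigenvalues):
#' rectangularity = Area/(a b), irregularity = 4 pi Area / Perimeter^2,
#' form factor = Area/a^2, eccentricity = (2/a) sqrt(a^2 - b^2) (as printed;
#' it can exceed 1 for elongated shapes), elongation = 2 sqrt(Area/pi) / a,
#' solidity = Area / ConvexArea. Entropy is the natural-log Shannon entropy
#' of the 256-bin gray histogram of the region, with `0 log 0 := 0`.
#'
#' @param image H x W x 3 RGB array (or gray matrix) in `[0, 1]`.
#' @param mask Logical lesion mask, or a `"lesion_mask"` object.
#' @param glcm_levels Quantization levels of the co-occurrence matrix.
#' @param mode `"standard"` for the canonical co-occurrence texture
#'   definitions, `"literal"` to reproduce the printed (degenerate) contrast
#'   and correlation formulas.
#' @return Named numeric vector of 19 features.
#' @export
extract_features <- function(image, mask, glcm_levels = 32L,
                             mode = c("standard", "literal")) {
  mode <- match.arg(mode)
  if (inherits(mask, "lesion_mask")) mask <- mask$mask
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  gray <- luminance(image)
  stopifnot(identical(dim(gray), dim(mask)))
  px <- gray[mask]

  mean_v <- mean(px)
  var_v <- mean((px - mean_v)^2)
  std_v <- sqrt(var_v)
  hcounts <- tabulate(pmin(256L, 1L + as.integer(floor(px * 256))), 256L)
  ph <- hcounts / sum(hcounts)
  ph <- ph[ph > 0]
  entropy <- -sum(ph * log(ph))

  area <- sum(mask)
  perim <- .perimeter(mask)
  pts <- which(mask, arr.ind = TRUE)
  ctr <- colMeans(pts)
  cov <- crossprod(sweep(pts, 2, ctr)) / area
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  a_ax <- 4 * sqrt(max(ev[1], 0)); b_ax <- 4 * sqrt(max(ev[2], 0))
  if (a_ax == 0) stop("degenerate region: zero major axis", call. = FALSE)

  g1 <- .glcm_stats(glcm(gray, mask, glcm_levels, c(0L, 1L))$matrix, mode)
  g2 <- .glcm_stats(glcm(gray, mask, glcm_levels, c(1L, 0L))$matrix, mode)
  g <- (g1 + g2) / 2

  phi <- hu_invariants(mask)

  c(mean = mean_v, variance = var_v, std = std_v, area = area,
    rectangularity = area / (a_ax * b_ax),
    irregularity_index = 4 * pi * area / perim^2,
    form_factor = area / a_ax^2,
    eccentricity = (2 / a_ax) * sqrt(max(a_ax^2 - b_ax^2, 0)),
    elongation = 2 * sqrt(area / pi) / a_ax,
    contrast = unname(g["contrast"]), perimeter = perim, entropy = entropy,
    solidity = area / .convex_area(mask),
    correlation = unname(g["correlation"]), energy = unname(g["energy"]),
    homogeneity = unname(g["homogeneity"]),
    phi1 = unname(phi["phi1"]), phi2 = unname(phi["phi2"]),
    phi3 = unname(phi["phi3"]))
}
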