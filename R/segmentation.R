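#' Convert RGB to CIE XYZ
#'
#' Per-pixel linear map `(X,Y,Z)' = (1/0.17697) M (R,G,B)'` with the classic
#' CIE 1931 matrix rows (0.49, 0.31, 0.20), (0.17697, 0.81240, 0.01063),
#' (0, 0.01, 0.99). X and Z carry chromatic information, Y luminance.
#'
#' @param image H x W x 3 RGB array in `[0, 1]`.
#' @return H x W x 3 XYZ array.
#' @export
rgb_to_xyz <- function(image) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L)
    stop("image must be an H x W x 3 RGB array", call. = FALSE)
  M <- rbind(c(0.49, 0.31, 0.20),
             c(0.17697, 0.81240, 0.01063),
             c(0, 0.01, 0.99)) / 0.17697
  flat <- matrix(image, ncol = 3L)
  out <- flat %*% t(M)
  array(out, dim = d)
}

#' Normalized red and X channels for segmentation
#'
#' Computes the chromatically normalized channels used for lesion
#' thresholding: `Rhat = R / sqrt(R^2 + G^2 + B^2)` and
#' `Xhat = X / sqrt(X^2 + Y^2 + Z^2)` per pixel; zero-norm (black) pixels
#' map to 0 by convention.
#'
#' @param rgb H x W x 3 RGB array.
#' @param xyz H x W x 3 XYZ array (e.g. from [rgb_to_xyz()]).
#' @return List with matrices `Rhat` and `Xhat`.
#' @export
normalize_channels <- function(rgb, xyz) {
  stopifnot(identical(dim(rgb), dim(xyz)))
  nr <- sqrt(rgb[, , 1]^2 + rgb[, , 2]^2 + rgb[, , 3]^2)
  nx <- sqrt(xyz[, , 1]^2 + xyz[, , 2]^2 + xyz[, , 3]^2)
  Rhat <- ifelse(nr > 0, rgb[, , 1] / nr, 0)
  Xhat <- ifelse(nx > 0, xyz[, , 1] / nx, 0)
  dim(Rhat) <- dim(rgb)[1:2]; dim(Xhat) <- dim(rgb)[1:2]
  list(Rhat = Rhat, Xhat = Xhat)
}

#' Otsu threshold maximizing between-class variance
#'
#' Histogram-based global threshold: bins the channel over its observed
#' range and returns the bin edge maximizing the between-class variance
#' `sigma_b^2(t) = w1 w2 (m1 - m2)^2`, computed by the incremental
#' cumulative-histogram update. Ties resolve to the lowest threshold.
#'
#' @param channel 2-D numeric array, non-constant.
#' @param n_bins Number of histogram bins.
#' @return The threshold (a bin edge); pixels `<= t` form class 1.
#' @export
otsu_threshold <- function(channel, n_bins = 256L) {
  v <- as.vector(channel)
  lo <- min(v); hi <- max(v)
  if (hi == lo)
    stop("degenerate histogram: channel is constant", call. = FALSE)
  n_bins <- as.integer(n_bins)
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  bin <- pmin(n_bins, pmax(1L, findInterval(v, edges, rightmost.closed = TRUE)))
  p <- tabulate(bin, n_bins) / length(v)
  mid <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  w1 <- cumsum(p)                      # class-1 weight after bin k
  mu1 <- cumsum(p * mid)               # unnormalized class-1 mean
  mt <- mu1[n_bins]                    # global mean
  valid <- w1 > 0 & w1 < 1
  sb2 <- rep(-Inf, n_bins)
  sb2[valid] <- (mt * w1[valid] - mu1[valid])^2 / (w1[valid] * (1 - w1[valid]))
  k <- which.max(sb2)                  # which.max takes the first (lowest) tie
  edges[k + 1L]
}

.make_se <- function(se) {
  if (is.matrix(se)) return(se != 0)
  switch(se,
         identity5 = diag(5) != 0,
         disk5 = EBImage::makeBrush(5, shape = "disc") != 0,
         stop("unknown structuring element: ", se, call. = FALSE))
}

#' Binary morphology: hole filling, opening, closing
#'
#' `fill` performs iterative conditional dilation of the border-connected
#' background until a fixed point, then fills every background pixel the
#' dilation never reached (the interior holes). `open` is erosion followed
#' by dilation (removes small spurious foreground); `close` is dilation
#' followed by erosion (bridges narrow gaps).
#'
#' @param mask Logical matrix.
#' @param op One of `"fill"`, `"open"`, `"close"`.
#' @param se Structuring element: a logical/numeric matrix, or `"identity5"`
#'   (the 5 x 5 identity matrix, i.e. a diagonal line) or `"disk5"`.
#' @return Logical matrix.
#' @export
morphology <- function(mask, op = c("fill", "open", "close"),
                       se = "identity5") {
  op <- match.arg(op)
  se <- .make_se(se)
  if (!any(se)) stop("structuring element must be non-empty", call. = FALSE)
  kern <- se * 1
  img <- EBImage::Image(mask * 1)
  if (op == "open") {
    out <- EBImage::dilate(EBImage::erode(img, kern), kern)
  } else if (op == "close") {
    out <- EBImage::erode(EBImage::dilate(img, kern), kern)
  } else {
    comp <- !mask
    marker <- matrix(FALSE, nrow(mask), ncol(mask))
    marker[1, ] <- comp[1, ]; marker[nrow(mask), ] <- comp[nrow(mask), ]
    marker[, 1] <- comp[, 1]; marker[, ncol(mask)] <- comp[, ncol(mask)]
    repeat {
      grown <- EBImage::dilate(EBImage::Image(marker * 1), kern)
      grown <- (as.matrix(grown) > 0.5) & comp
      grown <- grown | marker
      if (identical(grown, marker)) break
      marker <- grown
    }
    return(mask | (comp & !marker))
  }
  m <- as.matrix(out) > 0.5
  dim(m) <- dim(mask)
  m
}

#' Segment the lesion in a dermoscopy image
#'
#' Implements the thresholding chain: normalized red and X channels, an
#' Otsu threshold per channel (the lesion class being the one with the
#' lower channel mean, lesions being darker and less red-saturated than
#' skin), channel combination, hole filling, opening and closing with the
#' configured structuring element, and retention of the largest connected
#' component.
#'
#' @param image Preprocessed H x W x 3 RGB array in `[0, 1]`.
#' @param combine Channel combination rule: `"and"` (default), `"or"`,
#'   `"r_only"`, `"x_only"`.
#' @param se Structuring element for the morphology (see [morphology()]);
#'   the default honors the printed 5 x 5 identity matrix, but `"disk5"` is
#'   recommended for real images.
#' @param n_bins Histogram bins for [otsu_threshold()].
#' @return Object of class `"lesion_mask"`: logical `mask`, `threshold_r`,
#'   `threshold_x`, `combine_rule`.
#' @export
segment_lesion <- function(image, combine = c("and", "or", "r_only", "x_only"),
                           se = "identity5", n_bins = 256L) {
  combine <- match.arg(combine)
  ch <- normalize_channels(image, rgb_to_xyz(image))
  lesion_side <- function(channel) {
    t <- otsu_threshold(channel, n_bins)
    low <- channel <= t
    m_low <- mean(channel[low]); m_high <- mean(channel[!low])
    list(mask = if (m_low <= m_high) low else !low, threshold = t)
  }
  sr <- lesion_side(ch$Rhat)
  sx <- lesion_side(ch$Xhat)
  mask <- switch(combine,
                 and = sr$mask & sx$mask,
                 or = sr$mask | sx$mask,
                 r_only = sr$mask,
                 x_only = sx$mask)
  if (!any(mask))
    stop("empty lesion mask before morphology; try combine = \"or\"",
         call. = FALSE)
  mask <- morphology(mask, "fill", se)
  mask <- morphology(mask, "open", se)
  mask <- morphology(mask, "close", se)
  if (!any(mask))
    stop("empty lesion mask after morphology; try combine = \"or\" or se = \"disk5\"",
         call. = FALSE)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- round(as.matrix(lab))
  sizes <- tabulate(lab[lab > 0])
  mask <- lab == which.max(sizes)
  structure(list(mask = mask, threshold_r = sr$threshold,
                 threshold_x = sx$threshold, combine_rule = combine),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf(
    "lesion mask: %d px (%.1f%% of frame), thresholds Rhat %.4f / Xhat %.4f, combine '%s'\n",
    sum(x$mask), 100 * mean(x$mask), x$threshold_r, x$threshold_x,
    x$combine_rule))
  invisible(x)
}

#' Dice overlap between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; 1 for identical non-empty masks.
#'
#' @param a,b Logical matrices of equal shape.
#' @return Dice coefficient in `[0, 1]` (`NaN` if both masks are empty).
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}
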