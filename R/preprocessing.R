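#' Global contrast stretch through an 8-bit lookup table
#'
#' Linearly rescales a channel to `[0, 1]` via a 256-entry lookup table:
#' pixel values are quantized by floor into 256 bins spanning the observed
#' range and mapped through the table entry `bin / 255`. A constant channel
#' is degenerate and maps to all zeros with a warning.
#'
#' @param channel 2-D numeric array (any finite range).
#' @return Array of the same shape with values in `[0, 1]`.
#' @examples
#' contrast_stretch(matrix(c(50, 150, 150, 50), 2))
#' @export
contrast_stretch <- function(channel) {
  if (any(!is.finite(channel))) stop("channel must be finite", call. = FALSE)
  lo <- min(channel); hi <- max(channel)
  if (hi == lo) {
    warning("degenerate contrast: channel is constant, returning zeros",
            call. = FALSE)
    return(array(0, dim = dim(channel)))
  }
  idx <- pmin(255L, as.integer(floor((channel - lo) / (hi - lo) * 256)))
  lut <- (0:255) / 255
  out <- lut[idx + 1L]
  dim(out) <- dim(channel)
  out
}

# --- 3x3 neighborhood machinery -------------------------------------------

# Shifted copies of `m` with replicated borders, as a P x 9 matrix
# (columns in raster order of the 3x3 window; column 5 is the center).
.neigh9 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- function(dr) pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- function(dc) pmin(pmax(seq_len(nc) + dc, 1L), nc)
  cols <- vector("list", 9L)
  k <- 0L
  for (dc in -1:1) for (dr in -1:1) {
    k <- k + 1L
    cols[[k]] <- as.vector(m[ri(dr), ci(dc)])
  }
  do.call(cbind, cols)
}

# Vectorized median of each row of a P x 9 matrix (Paeth sorting network).
.median9 <- function(nb) {
  p <- lapply(seq_len(9L), function(j) nb[, j])
  op <- function(a, b) list(lo = pmin(p[[a]], p[[b]]), hi = pmax(p[[a]], p[[b]]))
  sw <- function(a, b) { s <- op(a, b); p[[a]] <<- s$lo; p[[b]] <<- s$hi }
  sw(2,3); sw(5,6); sw(8,9)
  sw(1,2); sw(4,5); sw(7,8)
  sw(2,3); sw(5,6); sw(8,9)
  sw(1,4); sw(6,9); sw(5,8)
  sw(4,7); sw(2,5); sw(3,6)
  sw(5,8); sw(5,3); sw(7,5)
  sw(5,3)
  p[[5]]
}

# --- Wang-Mendel style fuzzy denoiser --------------------------------------

# Triangular membership matrix: length(x) x n_partitions over [0, 1].
.wm_membership <- function(x, n_partitions) {
  centers <- seq(0, 1, length.out = n_partitions)
  w <- 1 / (n_partitions - 1)
  mu <- vapply(centers, function(cc) pmax(0, 1 - abs(x - cc) / w),
               numeric(length(x)))
  if (is.null(dim(mu))) mu <- matrix(mu, nrow = length(x))
  mu
}

#' Train a fuzzy rule base for image denoising
#'
#' Learns a Wang-Mendel style rule base from (noisy 3x3 neighborhood, clean
#' center) training pairs. Each neighborhood is summarized by three
#' antecedents - its center value, median and mean - fuzzified over
#' `n_partitions` triangular sets covering `[0, 1]`. Every pair generates one
#' candidate rule whose degree is the product of its maximal memberships;
#' within each occupied antecedent cell only the maximum-degree rule is
#' retained, its consequent being that pair's clean value.
#'
#' @param neighborhoods Numeric matrix, one row per pair, 9 columns in raster
#'   order (column 5 = center), values in `[0, 1]`.
#' @param clean Numeric vector of clean center values in `[0, 1]`.
#' @param n_partitions Number of triangular partitions per antecedent (>= 3).
#' @return Object of class `"wm_rulebase"`.
#' @export
train_wm_rulebase <- function(neighborhoods, clean, n_partitions = 7L) {
  neighborhoods <- as.matrix(neighborhoods)
  if (nrow(neighborhoods) == 0L) stop("no training pairs", call. = FALSE)
  if (ncol(neighborhoods) != 9L)
    stop("neighborhoods must have 9 columns (3x3 window)", call. = FALSE)
  if (length(clean) != nrow(neighborhoods))
    stop("one clean value per neighborhood required", call. = FALSE)
  rng_ok <- function(v) all(v >= 0 & v <= 1)
  if (!rng_ok(neighborhoods) || !rng_ok(clean))
    stop("all values must lie in [0, 1]", call. = FALSE)
  n_partitions <- as.integer(n_partitions)
  if (n_partitions < 3L) stop("n_partitions must be >= 3", call. = FALSE)

  ante <- cbind(center = neighborhoods[, 5L],
                median = .median9(neighborhoods),
                mean = rowMeans(neighborhoods))
  cells <- matrix(0L, nrow(ante), 3L)
  degs <- rep(1, nrow(ante))
  for (a in 1:3) {
    mu <- .wm_membership(ante[, a], n_partitions)
    cells[, a] <- max.col(mu, ties.method = "first")
    degs <- degs * mu[cbind(seq_len(nrow(mu)), cells[, a])]
  }
  key <- paste(cells[, 1], cells[, 2], cells[, 3], sep = "-")
  best <- tapply(seq_along(key), key, function(ix) ix[which.max(degs[ix])])
  best <- unlist(best, use.names = FALSE)
  rules <- data.frame(i = cells[best, 1], j = cells[best, 2],
                      k = cells[best, 3], consequent = clean[best],
                      degree = degs[best])
  structure(list(n_partitions = n_partitions, rules = rules),
            class = "wm_rulebase")
}

#' @export
print.wm_rulebase <- function(x, ...) {
  cat(sprintf("Wang-Mendel rule base: %d rules over %d^3 antecedent cells\n",
              nrow(x$rules), x$n_partitions))
  invisible(x)
}

#' Noise reduction for dermoscopy images
#'
#' With a trained rule base: every pixel's (center, median, mean)
#' neighborhood summary fires all rules under product inference and the
#' output is the firing-strength-weighted average of rule consequents;
#' pixels firing no rule fall back to their 3x3 neighborhood median.
#' Without a rule base the filter is a plain 3x3 median (the documented
#' fallback). RGB images are processed per channel.
#'
#' @param image 2-D gray matrix or H x W x 3 RGB array with values in
#'   `[0, 1]`.
#' @param rulebase Optional `"wm_rulebase"` from [train_wm_rulebase()].
#' @return Denoised array of the same shape, values in `[0, 1]`.
#' @export
denoise <- function(image, rulebase = NULL) {
  if (min(image) < 0 || max(image) > 1)
    stop("image values must lie in [0, 1]", call. = FALSE)
  if (length(dim(image)) == 3L) {
    out <- image
    for (ch in seq_len(dim(image)[3]))
      out[, , ch] <- denoise(image[, , ch], rulebase)
    return(out)
  }
  nb <- .neigh9(image)
  med <- .median9(nb)
  if (is.null(rulebase)) {
    out <- med
  } else {
    stopifnot(inherits(rulebase, "wm_rulebase"))
    np <- rulebase$n_partitions
    mu_c <- .wm_membership(nb[, 5L], np)
    mu_m <- .wm_membership(med, np)
    mu_n <- .wm_membership(rowMeans(nb), np)
    num <- numeric(nrow(nb)); den <- numeric(nrow(nb))
    r <- rulebase$rules
    for (q in seq_len(nrow(r))) {
      s <- mu_c[, r$i[q]] * mu_m[, r$j[q]] * mu_n[, r$k[q]]
      num <- num + s * r$consequent[q]
      den <- den + s
    }
    out <- ifelse(den > 1e-12, num / pmax(den, 1e-12), med)
  }
  out <- pmin(pmax(out, 0), 1)
  dim(out) <- dim(image)
  out
}

#' Full image preprocessing: denoise then stretch contrast
#'
#' Convenience wrapper applying [denoise()] followed by per-channel
#' [contrast_stretch()], the two preprocessing stages preceding
#' segmentation.
#'
#' @inheritParams denoise
#' @return Preprocessed array in `[0, 1]`.
#' @export
preprocess_image <- function(image, rulebase = NULL) {
  image <- denoise(image, rulebase)
  if (length(dim(image)) == 3L) {
    for (ch in seq_len(dim(image)[3]))
      image[, , ch] <- contrast_stretch(image[, , ch])
  } else {
    image <- contrast_stretch(image)
  }
  image
}
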