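#' Specification of a synthetic dermoscopy lesion image
#'
#' Describes one generated image: a skin-toned background with a smooth
#' illumination gradient and Gaussian sensor noise, one darker lesion blob
#' whose boundary is a radial-harmonic perturbation of a circle
#' (`r(theta) = r0 (1 + irregularity * sum_{k=2..6} a_k cos(k theta + phi_k)
#' + asymmetry * cos(theta + phi_1))`), per-pixel color jitter inside the
#' lesion, and optional dark hair arcs. Tones were chosen so the lesion is
#' darker, less red-saturated and lower in normalized CIE-X than the skin,
#' matching the physical premise of the segmentation rule.
#'
#' @param image_size Side length in pixels.
#' @param skin_tone,lesion_tone RGB triples in `[0, 1]`; the lesion must be
#'   darker (lower luminance).
#' @param radius_frac Base lesion radius as a fraction of the side, in
#'   `(0, 0.45)`.
#' @param irregularity Radial-harmonic amplitude (border jaggedness), >= 0.
#' @param asymmetry First-harmonic amplitude (shape asymmetry), >= 0.
#' @param color_variance Relative per-pixel tone jitter inside the lesion.
#' @param hair_count Number of dark hair arcs.
#' @param noise_sigma Gaussian noise standard deviation.
#' @param label `"benign"` or `"melanoma"`.
#' @return Object of class `"lesion_spec"`.
#' @export
lesion_spec <- function(image_size = 256L,
                        skin_tone = c(0.85, 0.60, 0.50),
                        lesion_tone = c(0.30, 0.26, 0.24),
                        radius_frac = 0.18,
                        irregularity = 0.05, asymmetry = 0.05,
                        color_variance = 0.02, hair_count = 0L,
                        noise_sigma = 0.02,
                        label = c("benign", "melanoma")) {
  label <- match.arg(label)
  lum <- function(v) sum(c(0.2126, 0.7152, 0.0722) * v)
  if (lum(lesion_tone) >= lum(skin_tone))
    stop("lesion tone must be darker than skin tone", call. = FALSE)
  if (radius_frac <= 0 || radius_frac >= 0.45)
    stop("radius_frac must lie in (0, 0.45)", call. = FALSE)
  if (irregularity < 0 || asymmetry < 0 || color_variance < 0 ||
      noise_sigma < 0 || hair_count < 0)
    stop("amplitudes and counts must be non-negative", call. = FALSE)
  structure(list(image_size = as.integer(image_size),
                 skin_tone = skin_tone, lesion_tone = lesion_tone,
                 radius_frac = radius_frac, irregularity = irregularity,
                 asymmetry = asymmetry, color_variance = color_variance,
                 hair_count = as.integer(hair_count),
                 noise_sigma = noise_sigma, label = label),
            class = "lesion_spec")
}

#' Generate one synthetic dermoscopy image with ground truth
#'
#' Rasterizes the lesion described by a [lesion_spec()] onto a noisy
#' skin-toned background and returns the image together with the exact
#' binary ground-truth mask and the class label. The generated lesion is
#' star-shaped around its center (the total boundary perturbation is capped
#' below 0.9), hence always a single connected component.
#'
#' @param spec A [lesion_spec()].
#' @return List with `image` (H x W x 3 in `[0, 1]`), `mask` (logical),
#'   `label`.
#' @export
generate_image <- function(spec) {
  stopifnot(inherits(spec, "lesion_spec"))
  n <- spec$image_size
  r0 <- spec$radius_frac * n
  cx <- n / 2 + stats::runif(1, -0.05, 0.05) * n
  cy <- n / 2 + stats::runif(1, -0.05, 0.05) * n

  # boundary harmonics, normalized so the relative perturbation is bounded
  ks <- 2:6
  ak <- stats::runif(length(ks), -1, 1)
  ak <- ak / max(sum(abs(ak)), 1e-9)
  phik <- stats::runif(length(ks), 0, 2 * pi)
  phi1 <- stats::runif(1, 0, 2 * pi)
  amp_total <- spec$irregularity + spec$asymmetry
  scale_amp <- if (amp_total > 0.9) 0.9 / amp_total else 1

  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  dx <- cols - cx; dy <- rows - cy
  theta <- atan2(dy, dx)
  pert <- spec$asymmetry * cos(theta + phi1)
  for (i in seq_along(ks))
    pert <- pert + spec$irregularity * ak[i] * cos(ks[i] * theta + phik[i])
  rtheta <- r0 * (1 + scale_amp * pert)
  mask <- (dx^2 + dy^2) <= rtheta^2

  # illumination gradient
  gdir <- stats::runif(1, 0, 2 * pi)
  grad <- 0.03 * ((cols - n / 2) * cos(gdir) + (rows - n / 2) * sin(gdir)) / n

  img <- array(0, dim = c(n, n, 3))
  jit <- matrix(stats::rnorm(n * n), n, n)
  for (ch in 1:3) {
    plane <- matrix(spec$skin_tone[ch], n, n) + grad
    lesion_plane <- spec$lesion_tone[ch] *
      (1 + spec$color_variance * jit +
         0.3 * spec$color_variance * matrix(stats::rnorm(n * n), n, n))
    plane[mask] <- lesion_plane[mask]
    img[, , ch] <- plane
  }

  # hair arcs: quadratic Bezier strokes, darkened
  if (spec$hair_count > 0L) {
    for (h in seq_len(spec$hair_count)) {
      p <- matrix(stats::runif(6, 1, n), 3, 2)
      tt <- seq(0, 1, length.out = 4L * n)
      bez <- outer((1 - tt)^2, p[1, ]) + outer(2 * tt * (1 - tt), p[2, ]) +
        outer(tt^2, p[3, ])
      rr <- pmin(pmax(round(bez[, 2]), 1L), n)
      cc <- pmin(pmax(round(bez[, 1]), 1L), n)
      for (ch in 1:3) {
        pl <- img[, , ch]
        pl[cbind(rr, cc)] <- pl[cbind(rr, cc)] * 0.25
        img[, , ch] <- pl
      }
    }
  }

  if (spec$noise_sigma > 0)
    img <- img + array(stats::rnorm(length(img), 0, spec$noise_sigma),
                       dim = dim(img))
  img <- pmin(pmax(img, 0), 1)
  list(image = img, mask = mask, label = spec$label)
}

#' Generate a labeled synthetic dermoscopy dataset
#'
#' Draws `n/2` benign and `n/2` melanoma images; the default melanoma
#' specification has higher border irregularity, asymmetry and color
#' variance than the benign one, so the extracted features separate the
#' classes the way clinical ABCD criteria would.
#'
#' @param n Total number of images (>= 2; odd n is rounded up per class).
#' @param benign_spec,melanoma_spec [lesion_spec()] objects for the two
#'   classes.
#' @param extract Compute the feature table from the ground-truth masks.
#' @return List with `images`, `masks`, `labels` (factor), and `features`
#'   (data frame, when `extract = TRUE`).
#' @export
generate_dataset <- function(n,
                             benign_spec = lesion_spec(label = "benign"),
                             melanoma_spec = lesion_spec(
                               irregularity = 0.25, asymmetry = 0.30,
                               color_variance = 0.08, label = "melanoma"),
                             extract = TRUE) {
  n <- as.integer(n)
  if (n < 2L) stop("n must be >= 2", call. = FALSE)
  per <- ceiling(n / 2)
  specs <- c(rep(list(benign_spec), per), rep(list(melanoma_spec), per))
  images <- vector("list", 2L * per)
  masks <- vector("list", 2L * per)
  labels <- character(2L * per)
  feats <- vector("list", 2L * per)
  for (i in seq_along(specs)) {
    g <- generate_image(specs[[i]])
    images[[i]] <- g$image
    masks[[i]] <- g$mask
    labels[i] <- g$label
    if (extract) feats[[i]] <- extract_features(g$image, g$mask)
  }
  out <- list(images = images, masks = masks,
              labels = factor(labels, levels = c("benign", "melanoma")))
  if (extract) out$features <- as.data.frame(do.call(rbind, feats))
  out
}
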