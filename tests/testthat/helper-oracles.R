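# Brute-force Otsu oracle: exhaustive between-class variance scan over the
# same histogram bins as otsu_threshold, with class statistics recomputed
# from scratch at every candidate split (no incremental updates).
otsu_bruteforce <- function(channel, n_bins = 256L) {
  v <- as.vector(channel)
  edges <- seq(min(v), max(v), length.out = n_bins + 1L)
  bin <- pmin(n_bins, pmax(1L, findInterval(v, edges, rightmost.closed = TRUE)))
  p <- tabulate(bin, n_bins) / length(v)
  mid <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  best <- -Inf; best_k <- NA_integer_
  for (k in seq_len(n_bins)) {
    w1 <- sum(p[1:k]); w2 <- 1 - w1
    if (w1 <= 0 || w2 <= 0) next
    m1 <- sum(p[1:k] * mid[1:k]) / w1
    m2 <- sum(p[(k + 1):n_bins] * mid[(k + 1):n_bins]) / w2
    sb <- w1 * w2 * (m1 - m2)^2
    if (sb > best) { best <- sb; best_k <- k }   # strict: first (lowest) max
  }
  edges[best_k + 1L]
}

# Disk mask centered in an n x n frame.
disk_mask <- function(n, r, cx = (n + 1) / 2, cy = (n + 1) / 2) {
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  (cols - cx)^2 + (rows - cy)^2 <= r^2
}

# Star-shaped mask: radius modulated by a cosine harmonic.
star_mask <- function(n, r, amp = 0.3, k = 8) {
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  cx <- (n + 1) / 2
  th <- atan2(rows - cx, cols - cx)
  rr <- sqrt((cols - cx)^2 + (rows - cx)^2)
  rr <= r * (1 + amp * cos(k * th))
}

# Flat skin-toned image with additive gray disks, mild gradient for
# non-degenerate histograms.
skin_image <- function(n, skin = c(0.85, 0.6, 0.5), lesion = c(0.3, 0.26, 0.24),
                       mask = NULL) {
  img <- array(0, c(n, n, 3))
  grad <- 0.02 * matrix(seq_len(n), n, n) / n
  for (ch in 1:3) {
    pl <- matrix(skin[ch], n, n) + grad
    if (!is.null(mask)) pl[mask] <- lesion[ch] + grad[mask]
    img[, , ch] <- pl
  }
  img
}

# Mean k-fold cross-validated MCC of an ELM on a feature table: the
# selection module's inner criterion, recomputed independently for null and
# separability calibrations.
cv_elm_fitness <- function(x, y, k = 5, hidden = 30, seed = 1) {
  set.seed(seed)
  y <- as.factor(y)
  fold <- integer(length(y))
  for (lv in levels(y)) {
    ix <- sample(which(y == lv))
    fold[ix] <- rep_len(seq_len(k), length(ix))
  }
  pos <- levels(y)[2]
  fits <- sapply(seq_len(k), function(f) {
    m <- elm(x[fold != f, , drop = FALSE], y[fold != f], hidden = hidden,
             seed = seed + f)
    pred <- predict(m, x[fold == f, , drop = FALSE])
    truth <- y[fold == f]
    selection_fitness(tp = sum(pred == pos & truth == pos),
                      tn = sum(pred != pos & truth != pos),
                      fp = sum(pred == pos & truth != pos),
                      fn = sum(pred != pos & truth == pos))
  })
  mean(fits)
}
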