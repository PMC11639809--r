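# Independent brute-force oracles used to validate the package's
# implementations. These deliberately avoid the code paths they check.

# Exhaustive FAST segment test: per-pixel loop over the 16-pixel Bresenham
# circle, arc length 9. Returns 1-based (x, y) of every corner.
fast_oracle <- function(img, threshold) {
  circ_x <- c(0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3, -3, -3, -2, -1)
  circ_y <- c(-3, -3, -2, -1, 0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3)
  h <- nrow(img)
  w <- ncol(img)
  out <- NULL
  for (y in 4:(h - 3)) {
    for (x in 4:(w - 3)) {
      c0 <- img[y, x]
      vals <- img[cbind(y + circ_y, x + circ_x)]
      flags <- ifelse(vals > c0 + threshold, 1L,
                      ifelse(vals < c0 - threshold, -1L, 0L))
      is_corner <- FALSE
      for (s in 1:16) {
        f <- flags[s]
        if (f == 0L) next
        run <- 1L
        while (run < 9L && flags[((s - 1L + run) %% 16L) + 1L] == f) run <- run + 1L
        if (run >= 9L) { is_corner <- TRUE; break }
      }
      if (is_corner) out <- rbind(out, c(x, y))
    }
  }
  out
}

# Explicit-sum DFT magnitude at bin k (0-based) of a signal.
dft_bin_mag <- function(x, k) {
  n <- length(x)
  j <- 0:(n - 1)
  re <- sum(x * cos(-2 * pi * k * j / n))
  im <- sum(x * sin(-2 * pi * k * j / n))
  sqrt(re^2 + im^2)
}

# Brute-force windowed dominant-frequency RR: explicit linear detrend,
# explicit DFT sums over the zero-padded in-band bins, exhaustive argmax.
estimate_rr_oracle <- function(x, fps, window_s = 10, pad_len = 256,
                               low = 0.33, high = 0.67) {
  wf <- round(window_s * fps)
  nw <- length(x) - wf + 1
  bins <- which((0:(pad_len - 1)) * fps / pad_len >= low &
                  (0:(pad_len - 1)) * fps / pad_len <= high) - 1L
  tt <- seq_len(wf)
  vapply(seq_len(nw), function(i) {
    w <- x[i:(i + wf - 1)]
    fit <- stats::lm.fit(cbind(1, tt), w)
    w <- fit$residuals
    padded <- c(w, rep(0, pad_len - wf))
    mags <- vapply(bins, function(k) dft_bin_mag(padded, k), numeric(1))
    60 * bins[which.max(mags)] * fps / pad_len
  }, numeric(1))
}

# Closed-form magnitude response of the bilinear-transform Butterworth
# band-pass (prewarped edges); filtfilt applies the square of this.
butter_bp_gain <- function(f, fs, low = 0.33, high = 0.67, order = 2) {
  w1 <- tan(pi * low / fs)
  w2 <- tan(pi * high / fs)
  w0sq <- w1 * w2
  b <- w2 - w1
  wf <- tan(pi * f / fs)
  1 / sqrt(1 + ((wf^2 - w0sq) / (b * wf))^(2 * order))
}

# Pixel-by-pixel IoU counting loop.
iou_oracle <- function(a, b) {
  inter <- 0L
  uni <- 0L
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(ncol(a))) {
      af <- a[i, j] != 0
      bf <- b[i, j] != 0
      if (af && bf) inter <- inter + 1L
      if (af || bf) uni <- uni + 1L
    }
  }
  inter / uni
}

# Random blob mask: union of a few filled discs on an h x w grid.
random_blob_mask <- function(h, w, n_discs = 3) {
  m <- matrix(0L, h, w)
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), times = w), h, w)
  for (k in seq_len(n_discs)) {
    cx <- runif(1, 4, w - 3)
    cy <- runif(1, 4, h - 3)
    r <- runif(1, 2, min(h, w) / 3)
    m[(xs - cx)^2 + (ys - cy)^2 <= r^2] <- 1L
  }
  m
}
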