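# Internal helpers shared across modules.

# Evaluate `code` with a private RNG stream seeded at `seed`, restoring any
# pre-existing global RNG state afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Vectorised bilinear interpolation into matrix `img` (H x W) at fractional
# 1-based coordinates (y, x); coordinates are clamped to the image.
bilinear_sample <- function(img, y, x) {
  h <- nrow(img)
  w <- ncol(img)
  x <- pmin(pmax(x, 1), w)
  y <- pmin(pmax(y, 1), h)
  x0 <- pmin(floor(x), w - 1L)
  y0 <- pmin(floor(y), h - 1L)
  ax <- x - x0
  ay <- y - y0
  i00 <- (x0 - 1) * h + y0
  v00 <- img[i00]
  v01 <- img[i00 + h]
  v10 <- img[i00 + 1]
  v11 <- img[i00 + h + 1]
  (1 - ay) * ((1 - ax) * v00 + ax * v01) + ay * ((1 - ax) * v10 + ax * v11)
}

# Separable binomial blur (1,4,6,4,1)/16 applied along rows then columns,
# with replicated edges. Used to give the synthetic speckle a wool-like grain.
binomial_blur <- function(m, passes = 1L) {
  k <- c(1, 4, 6, 4, 1) / 16
  pad_filter <- function(v) {
    n <- length(v)
    vp <- c(v[c(2, 1)], v, v[c(n, n - 1)])
    stats::filter(vp, k, sides = 2)[3:(n + 2)]
  }
  for (p in seq_len(passes)) {
    m <- apply(m, 2, pad_filter)
    m <- t(apply(m, 1, pad_filter))
  }
  m
}

stop_input <- function(msg, class) {
  stop(structure(class = c(class, "ovirr_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

is_binary_mask <- function(mask) {
  is.matrix(mask) && all(mask %in% c(0, 1) | mask >= 0)
}
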