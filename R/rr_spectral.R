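#' Band-pass configuration for the ovine breathing band
#'
#' Resting sheep breathe at roughly 20-30 breaths/min; the filter band is
#' specified in hertz as 0.33-0.67 Hz (0.67 Hz corresponds to 40.2
#' breaths/min, which accommodates the elevated rates seen in practice).
#'
#' @param low_hz,high_hz cut-off frequencies in Hz.
#' @param order Butterworth prototype order (2 gives a 4-pole band-pass).
#' @return An object of class `bandpass_config`.
#' @export
bandpass_config <- function(low_hz = 0.33, high_hz = 0.67, order = 2L) {
  if (!(low_hz > 0 && low_hz < high_hz)) {
    stop_input("need 0 < low_hz < high_hz", "ovirr_parameter_error")
  }
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order)),
            class = "bandpass_config")
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth band-pass (default second order, 0.33-0.67 Hz)
#' forward and backward (`signal::filtfilt`), so the output is band-limited
#' without phase lag. Removes the DC level and out-of-band motion artefacts
#' before source separation.
#'
#' @param x numeric signal sampled at `fps`.
#' @param fps sampling rate, frames/s.
#' @param cfg a [bandpass_config].
#' @return Filtered signal, same length.
#' @export
bandpass <- function(x, fps, cfg = bandpass_config()) {
  if (cfg$high_hz >= fps / 2) {
    stop_input("high_hz must be below the Nyquist frequency fps/2",
               "ovirr_parameter_error")
  }
  if (length(x) < 3 * cfg$order) {
    stop_input("signal too short for this filter order", "ovirr_parameter_error")
  }
  bf <- signal::butter(cfg$order, c(cfg$low_hz, cfg$high_hz) / (fps / 2),
                       type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' PCA blind source separation of motion signals
#'
#' Stacks the horizontal and vertical derivative signals (2M rows) and
#' decomposes them with principal component analysis (per-signal mean
#' centering, singular value decomposition). The component scores are
#' candidate respiratory time courses, ordered by decreasing explained
#' variance.
#'
#' @param motion a [motion_signals] object, or a plain matrix with one
#'   signal per row.
#' @param n_components number of components to retain (default 6); when
#'   fewer signals are available all of them are returned.
#' @return A list with `scores` (T x k matrix of component time series),
#'   `sdev`, `explained_var` (eigenvalues, summing to the total variance),
#'   and `fps`.
#' @export
pca_decompose <- function(motion, n_components = 6L) {
  if (inherits(motion, "motion_signals")) {
    x <- rbind(motion$dx, motion$dy)
    fps <- motion$fps
  } else {
    x <- as.matrix(motion)
    fps <- attr(motion, "fps") %||% NA_real_
  }
  if (nrow(x) < 2L) stop_input("need at least 2 signals", "ovirr_parameter_error")
  k <- min(n_components, nrow(x), ncol(x) - 1L)
  if (k < n_components) {
    message("pca_decompose: only ", k, " components available")
  }
  p <- prcomp(t(x), center = TRUE, scale. = FALSE)
  list(scores = p$x[, seq_len(min(k, ncol(p$x))), drop = FALSE],
       sdev = p$sdev, explained_var = p$sdev^2, fps = fps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select the respiratory component
#'
#' `strategy = "first"` (the default, matching the observation that chest
#' contraction/relaxation is already evident in the first component) returns
#' component 1. `strategy = "best_inband"` applies an FFT to the first six
#' components and returns the one with the largest ratio of in-band spectral
#' peak to total spectral power.
#'
#' @param comps result of [pca_decompose()] (or a plain score matrix).
#' @param fps sampling rate.
#' @param cfg a [bandpass_config] defining the breathing band.
#' @param strategy `"first"` or `"best_inband"`.
#' @return An object of class `respiratory_signal` with fields `samples`
#'   (zero-mean), `fps`, and `component_index`.
#' @export
select_component <- function(comps, fps = NULL, cfg = bandpass_config(),
                             strategy = c("first", "best_inband")) {
  strategy <- match.arg(strategy)
  scores <- if (is.list(comps) && !is.null(comps$scores)) comps$scores else as.matrix(comps)
  if (is.null(fps)) fps <- comps$fps
  n_avail <- ncol(scores)
  idx <- 1L
  if (strategy == "best_inband" && n_avail > 1L) {
    n <- nrow(scores)
    freqs <- (seq_len(n) - 1) * fps / n
    inband <- freqs >= cfg$low_hz & freqs <= cfg$high_hz
    ratio <- vapply(seq_len(min(6L, n_avail)), function(j) {
      mag2 <- Mod(fft(scores[, j] - mean(scores[, j])))^2
      tot <- sum(mag2[-1])
      if (tot <= 0) return(0)
      max(mag2[inband]) / tot
    }, numeric(1))
    idx <- which.max(ratio)
  }
  s <- scores[, idx] - mean(scores[, idx])
  structure(list(samples = as.numeric(s), fps = fps,
                 component_index = as.integer(idx)),
            class = "respiratory_signal")
}

#' Respiratory-rate series
#'
#' @param times_s window-end times, seconds.
#' @param rr_bpm per-window respiratory rate, breaths/min.
#' @param rr_smoothed_bpm optional smoothed curve (same length).
#' @param window_s analysis window length, seconds.
#' @param fps sampling rate of the series (one estimate per frame step).
#' @return An object of class `rr_series`.
#' @export
rr_series <- function(times_s, rr_bpm, rr_smoothed_bpm = NULL,
                      window_s = 10, fps = NA_real_) {
  stopifnot(length(times_s) == length(rr_bpm))
  if (!is.null(rr_smoothed_bpm)) stopifnot(length(rr_smoothed_bpm) == length(rr_bpm))
  structure(list(times_s = times_s, rr_bpm = rr_bpm,
                 rr_smoothed_bpm = rr_smoothed_bpm, window_s = window_s,
                 fps = fps),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %d windows (%g s each)", length(x$rr_bpm), x$window_s))
  if (length(x$rr_bpm)) {
    cat(sprintf(", median RR %.2f bpm", stats::median(
      if (is.null(x$rr_smoothed_bpm)) x$rr_bpm else x$rr_smoothed_bpm)))
  }
  cat("\n")
  invisible(x)
}

#' Estimate the respiratory rate with a sliding spectral window
#'
#' A 10 s window slides over the respiratory signal one frame at a time
#' (200-frame windows at 20 fps, 100-frame windows at 10 fps). Each window
#' is linearly detrended, zero-padded to `pad_len`, Fourier transformed,
#' and the dominant frequency is taken as the magnitude-spectrum argmax
#' restricted to the breathing band; RR = 60 * f_peak. Ties break toward
#' the lower frequency.
#'
#' @param sig a [respiratory_signal] (or numeric vector with `fps` given
#'   via `fps`).
#' @param window_s window length, seconds.
#' @param pad_len FFT length after zero padding (default 4096, i.e. a
#'   frequency resolution of 20/4096 = 0.005 Hz, about 0.3 breaths/min, at
#'   20 fps).
#' @param cfg a [bandpass_config] defining the admissible band.
#' @param fps sampling rate, used when `sig` is a plain vector.
#' @return An [rr_series] with `length(signal) - window + 1` entries, all
#'   within `[60 * low_hz, 60 * high_hz]` breaths/min.
#' @export
estimate_rr <- function(sig, window_s = 10, pad_len = 4096L,
                        cfg = bandpass_config(), fps = NULL) {
  if (inherits(sig, "respiratory_signal")) {
    x <- sig$samples
    fps <- sig$fps
  } else {
    x <- as.numeric(sig)
    if (is.null(fps)) stop_input("fps required for a plain signal vector",
                                 "ovirr_parameter_error")
  }
  wf <- round(window_s * fps)
  n <- length(x)
  if (n < wf) stop_input("signal shorter than one analysis window",
                         "ovirr_degenerate_input")
  if (pad_len < wf) stop_input("pad_len must be at least the window length",
                               "ovirr_parameter_error")
  nw <- n - wf + 1L
  # all windows as a wf x nw matrix
  idx <- outer(seq_len(wf), seq_len(nw) - 1L, `+`)
  w <- matrix(x[idx], wf, nw)
  # closed-form linear detrend of every column
  tt <- seq_len(wf)
  tc <- tt - mean(tt)
  denom <- sum(tc^2)
  slope <- as.numeric(crossprod(tc, w)) / denom
  meanw <- colMeans(w)
  w <- w - outer(rep(1, wf), meanw) - outer(tc, slope)
  padded <- rbind(w, matrix(0, pad_len - wf, nw))
  mag <- Mod(mvfft(padded))
  freqs <- (seq_len(pad_len) - 1) * fps / pad_len
  band <- which(freqs >= cfg$low_hz & freqs <= cfg$high_hz)
  # which.max returns the first maximum; bins ascend, so ties go low
  peak <- band[apply(mag[band, , drop = FALSE], 2, which.max)]
  rr <- 60 * freqs[peak]
  times <- (seq_len(nw) + wf - 1) / fps
  rr_series(times_s = times, rr_bpm = rr, window_s = window_s, fps = fps)
}

#' Smooth a respiratory-rate series by moving-average convolution
#'
#' Convolves the per-window RR estimates with a uniform kernel of one
#' analysis window's length (default 10 s), yielding the average RR curve.
#' The kernel length is made odd and the series is padded by half-sample
#' mirroring at both ends, so a constant series is a fixed point and the
#' series mean is conserved exactly.
#'
#' @param series an [rr_series].
#' @param kernel_s kernel length in seconds.
#' @return The series with `rr_smoothed_bpm` filled in.
#' @export
smooth_rr <- function(series, kernel_s = 10) {
  stopifnot(inherits(series, "rr_series"))
  x <- series$rr_bpm
  n <- length(x)
  if (n == 0L) stop_input("empty RR series", "ovirr_degenerate_input")
  k <- round(kernel_s * series$fps)
  if (is.na(k) || k < 1) k <- 1L
  k <- min(k, n)
  if (k %% 2 == 0) k <- k - 1L
  if (k <= 1L) {
    series$rr_smoothed_bpm <- x
    return(series)
  }
  h <- (k - 1L) %/% 2L
  padded <- c(rev(x[seq_len(h)]), x, rev(x[seq.int(n - h + 1L, n)]))
  sm <- stats::filter(padded, rep(1 / k, k), sides = 2)
  series$rr_smoothed_bpm <- as.numeric(sm[(h + 1L):(h + n)])
  series
}
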