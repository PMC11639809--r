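#' Agreement between reference and video-derived respiratory rates
#'
#' For each pair, the absolute error is `|rr_ref - rr_video|` (breaths/min)
#' and the relative error is `100 * abs_err / rr_ref` (percent, denominated
#' by the expert reference). Means are computed at full precision; round
#' only for display.
#'
#' @param rr_ref,rr_video paired rates, breaths/min (`rr_ref > 0`).
#' @param video_id,region optional labels recycled across pairs.
#' @return A list with `mean_abs_err`, `mean_rel_err_pct`, and `records`
#'   (a per-pair data frame with columns
#'   `video_id,region,rr_ref,rr_video,abs_err,rel_err_pct`).
#' @export
agreement <- function(rr_ref, rr_video, video_id = seq_along(rr_ref),
                      region = "total") {
  if (length(rr_ref) == 0L) stop_input("no pairs supplied", "ovirr_degenerate_input")
  if (length(rr_ref) != length(rr_video)) {
    stop_input("rr_ref and rr_video must have equal length", "ovirr_parameter_error")
  }
  if (any(rr_ref <= 0)) stop_input("rr_ref must be positive", "ovirr_parameter_error")
  abs_err <- abs(rr_ref - rr_video)
  rel_err <- 100 * abs_err / rr_ref
  records <- data.frame(video_id = rep_len(video_id, length(rr_ref)),
                        region = rep_len(region, length(rr_ref)),
                        rr_ref = rr_ref, rr_video = rr_video,
                        abs_err = abs_err, rel_err_pct = rel_err)
  list(mean_abs_err = mean(abs_err), mean_rel_err_pct = mean(rel_err),
       records = records)
}

#' Pearson correlation between paired rates
#'
#' @param rr_ref,rr_video paired rates (at least 3 pairs, both with nonzero
#'   variance).
#' @return The product-moment correlation in `[-1, 1]`.
#' @export
pearson <- function(rr_ref, rr_video) {
  if (length(rr_ref) < 3L || length(rr_ref) != length(rr_video)) {
    stop_input("need at least 3 complete pairs", "ovirr_parameter_error")
  }
  if (sd(rr_ref) == 0 || sd(rr_video) == 0) {
    stop_input("correlation undefined: zero variance", "ovirr_undefined_input")
  }
  cor(rr_ref, rr_video)
}

#' Bland-Altman agreement analysis
#'
#' Differences are taken as `d = rr_ref - rr_video`; the limits of agreement
#' are `mean(d) +/- 1.96 * sd(d)` with the sample standard deviation
#' (denominator n - 1).
#'
#' @param rr_ref,rr_video paired rates (at least 2 pairs).
#' @return An object of class `bland_altman` with `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, and `n`.
#' @export
bland_altman <- function(rr_ref, rr_video) {
  if (length(rr_ref) < 2L || length(rr_ref) != length(rr_video)) {
    stop_input("need at least 2 complete pairs", "ovirr_degenerate_input")
  }
  d <- rr_ref - rr_video
  m <- mean(d)
  s <- sd(d)
  structure(list(mean_diff = m, sd_diff = s,
                 loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
                 n = length(d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n=%d, mean diff %.2f bpm, LoA [%.2f, %.2f]\n",
              x$n, x$mean_diff, x$loa_low, x$loa_high))
  invisible(x)
}

#' Parse a duration string to seconds
#'
#' Accepts `"HH:MM:SS"` or `"MM:SS"`.
#'
#' @param x character vector of duration strings.
#' @return Numeric vector of seconds.
#' @export
parse_hms <- function(x) {
  vapply(x, function(tok) {
    parts <- strsplit(tok, ":", fixed = TRUE)[[1]]
    nums <- suppressWarnings(as.numeric(parts))
    if (anyNA(nums) || !(length(parts) %in% 2:3) || any(nums < 0)) {
      stop_input(paste0("malformed duration string: '", tok, "'"),
                 "ovirr_parse_error")
    }
    if (length(nums) == 2L) nums <- c(0, nums)
    sum(nums * c(3600, 60, 1))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Rest-coverage accounting
#'
#' Sums total and at-rest recording durations exactly in seconds and
#' reports the percentage of footage usable for RR estimation.
#'
#' @param durations_total,durations_rest character vectors of `"HH:MM:SS"`
#'   (or `"MM:SS"`) durations.
#' @return An object of class `coverage_report` with `total_duration_s`,
#'   `rest_duration_s`, and `coverage_pct`.
#' @export
coverage <- function(durations_total, durations_rest) {
  total <- sum(parse_hms(durations_total))
  rest <- sum(parse_hms(durations_rest))
  if (rest > total) stop_input("rest duration exceeds total duration",
                               "ovirr_parameter_error")
  if (total <= 0) stop_input("total duration must be positive",
                             "ovirr_parameter_error")
  structure(list(total_duration_s = total, rest_duration_s = rest,
                 coverage_pct = 100 * rest / total),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("<coverage_report> %.0f s of %.0f s at rest (%.2f%%)\n",
              x$rest_duration_s, x$total_duration_s, x$coverage_pct))
  invisible(x)
}
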