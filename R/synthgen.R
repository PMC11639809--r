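#' Specification for a synthetic breathing video
#'
#' Describes a speckle-textured elliptical "thorax" whose boundary expands
#' and contracts radially at a known respiratory frequency, over a static
#' dimmer background. The boundary displacement at angle-position `x` along
#' the long axis is `A(x) * sin(2 pi (rr_bpm/60) t)`, with `A(x)` tapering
#' linearly from `amplitude_px` at the abdominal end to
#' `amplitude_px * amplitude_gradient` at the cranial end. This reproduces
#' the empirical ordering in which the abdominal third of the thorax (R1)
#' carries a stronger breathing signal than the cranial third (R3).
#'
#' @param duration_s clip length in seconds.
#' @param fps frame rate (20 emulates the RGB stage, 10 the NIR stage).
#' @param rr_bpm true respiratory rate, breaths/min. In-band fixtures keep
#'   `rr_bpm/60` within 0.33-0.67 Hz; out-of-band values are allowed for
#'   rejection tests.
#' @param amplitude_px peak boundary displacement, pixels.
#' @param amplitude_gradient fraction of the amplitude retained at the
#'   cranial end, in `[0, 1]`.
#' @param noise_sd additive Gaussian sensor noise, gray levels. Default 2
#'   for RGB; NIR defaults to 4 (night footage is noisier).
#' @param drift_per_s slow illumination drift, gray levels per second.
#' @param seed integer; fully determines the output.
#' @param modality `"rgb"` (3-plane) or `"nir"` (single-channel, lower
#'   contrast).
#' @param image_size `c(height, width)` in pixels.
#' @param center ellipse center `c(y, x)`; default = image center.
#' @param semiaxes ellipse semi-axes `c(b, a)` (vertical, horizontal);
#'   default 0.30 * height and 0.38 * width.
#' @param abdominal_end which end of the long axis breathes hardest;
#'   `"left"` (default) or `"right"`.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(duration_s = 30, fps = 20, rr_bpm = 27,
                           amplitude_px = 3, amplitude_gradient = 0.5,
                           noise_sd = NULL, drift_per_s = 0, seed = 1L,
                           modality = c("rgb", "nir"),
                           image_size = c(120L, 160L),
                           center = NULL, semiaxes = NULL,
                           abdominal_end = c("left", "right")) {
  modality <- match.arg(modality)
  abdominal_end <- match.arg(abdominal_end)
  if (is.null(noise_sd)) noise_sd <- if (modality == "nir") 4 else 2
  if (fps <= 2 * (rr_bpm / 60)) {
    stop_input("fps must exceed twice the breathing frequency (Nyquist)",
               "ovirr_parameter_error")
  }
  if (amplitude_gradient < 0 || amplitude_gradient > 1) {
    stop_input("amplitude_gradient must lie in [0, 1]", "ovirr_parameter_error")
  }
  if (duration_s <= 0 || amplitude_px < 0 || noise_sd < 0) {
    stop_input("duration_s must be positive; amplitude_px and noise_sd non-negative",
               "ovirr_parameter_error")
  }
  if (is.null(center)) center <- c(image_size[1] / 2, image_size[2] / 2)
  if (is.null(semiaxes)) semiaxes <- c(0.30 * image_size[1], 0.38 * image_size[2])
  structure(list(duration_s = duration_s, fps = fps, rr_bpm = rr_bpm,
                 amplitude_px = amplitude_px,
                 amplitude_gradient = amplitude_gradient, noise_sd = noise_sd,
                 drift_per_s = drift_per_s, seed = as.integer(seed),
                 modality = modality, image_size = as.integer(image_size),
                 center = center, semiaxes = semiaxes,
                 abdominal_end = abdominal_end),
            class = "synthetic_spec")
}

# Speckle texture for one instance: smoothed uniform noise rescaled to a
# modality-dependent gray-level range.
make_texture <- function(h, w, modality, seed) {
  with_seed(seed, {
    u <- matrix(runif(h * w), h, w)
    u <- binomial_blur(u, passes = 1L)
    u <- (u - mean(u)) / stats::sd(u)
    if (modality == "nir") 110 + 25 * u else 130 + 45 * u
  })
}

# Geometry tables reused for every frame of one instance.
instance_geometry <- function(spec) {
  h <- spec$image_size[1]; w <- spec$image_size[2]
  cy <- spec$center[1]; cx <- spec$center[2]
  b <- spec$semiaxes[1]; a <- spec$semiaxes[2]
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), times = w), h, w)
  dx <- xs - cx; dy <- ys - cy
  rho <- sqrt((dx / a)^2 + (dy / b)^2)
  dist <- sqrt(dx^2 + dy^2)
  # amplitude profile along the long axis, clamped to the ellipse extent
  u <- pmin(pmax((xs - (cx - a)) / (2 * a), 0), 1)
  if (spec$abdominal_end == "right") u <- 1 - u
  amp <- spec$amplitude_px * (1 - (1 - spec$amplitude_gradient) * u)
  # radial scale increment per unit sin(): A * rho / |p - c|
  afac <- ifelse(dist > 1e-9, amp * rho / dist, 0)
  list(dx = dx, dy = dy, rho = rho, afac = afac, cx = cx, cy = cy)
}

render_instance <- function(frame, texture, geo, delta) {
  s <- 1 + delta * geo$afac
  qx <- geo$cx + geo$dx / s
  qy <- geo$cy + geo$dy / s
  h <- nrow(frame); w <- ncol(frame)
  cxn <- geo$cx; cyn <- geo$cy
  # inside the moving region iff the source point lies inside the ellipse
  rho_src <- sqrt(((qx - cxn) / attr(geo, "a"))^2 + ((qy - cyn) / attr(geo, "b"))^2)
  inside <- rho_src <= 1
  frame[inside] <- bilinear_sample(texture, qy[inside], qx[inside])
  frame
}

#' Generate a synthetic breathing video with known ground truth
#'
#' Renders the breathing ellipse described by `spec` over a static textured
#' background, adds illumination drift and Gaussian sensor noise, and
#' quantises to 8 bits. Output is bitwise deterministic for a fixed seed.
#'
#' @param spec a [synthetic_spec].
#' @return A list with elements `frames` ([frame_sequence]), `mask`
#'   ([instance_mask], the region at mid-expansion), `truth` (data frame
#'   `time_s`, `rr_bpm`, `boundary_displacement_px` sampled per frame), and
#'   `spec`.
#' @export
generate_breathing_video <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  h <- spec$image_size[1]; w <- spec$image_size[2]
  n_frames <- round(spec$duration_s * spec$fps)
  f_hz <- spec$rr_bpm / 60
  texture <- make_texture(h, w, spec$modality, spec$seed)
  background <- with_seed(spec$seed + 7919L, {
    u <- binomial_blur(matrix(runif(h * w), h, w), passes = 1L)
    70 + 12 * (u - mean(u)) / stats::sd(u)
  })
  geo <- instance_geometry(spec)
  attr(geo, "a") <- spec$semiaxes[2]
  attr(geo, "b") <- spec$semiaxes[1]
  t_s <- (seq_len(n_frames) - 1) / spec$fps
  delta <- sin(2 * pi * f_hz * t_s)
  noise <- with_seed(spec$seed + 104729L,
                     matrix(rnorm(h * w * n_frames, 0, spec$noise_sd), h * w, n_frames))
  frames <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    fr <- render_instance(background, texture, geo, delta[i])
    fr <- fr + spec$drift_per_s * t_s[i] + matrix(noise[, i], h, w)
    fr <- round(pmin(pmax(fr, 0), 255))
    frames[[i]] <- if (spec$modality == "rgb") {
      array(c(fr, round(fr * 0.97), round(fr * 0.90)), dim = c(h, w, 3))
    } else {
      fr
    }
  }
  mask <- instance_mask((geo$rho <= 1) * 1L, class_label = "thorax",
                        certainty = 1.0, instance_id = 1L)
  truth <- data.frame(time_s = t_s, rr_bpm = rep(spec$rr_bpm, n_frames),
                      boundary_displacement_px = spec$amplitude_px * delta)
  list(frames = frame_sequence(frames, fps = spec$fps, modality = spec$modality,
                               source_id = sprintf("synth_rr%g_seed%d",
                                                   spec$rr_bpm, spec$seed)),
       mask = mask, truth = truth, spec = spec)
}

#' Generate a scene with two independently breathing instances
#'
#' Both specs must agree on duration, frame rate, modality, and image size,
#' and their (amplitude-dilated) elliptical regions must be disjoint. When
#' both specs use the default geometry, the instances are placed side by
#' side automatically.
#'
#' @param spec_a,spec_b [synthetic_spec]s for the two instances.
#' @return A list with `frames`, `masks` (list of two [instance_mask]s),
#'   `truth` (list of two truth data frames), and the two specs.
#' @export
generate_two_instance_scene <- function(spec_a, spec_b) {
  stopifnot(inherits(spec_a, "synthetic_spec"), inherits(spec_b, "synthetic_spec"))
  if (!identical(spec_a$image_size, spec_b$image_size) ||
      spec_a$fps != spec_b$fps || spec_a$duration_s != spec_b$duration_s ||
      !identical(spec_a$modality, spec_b$modality)) {
    stop_input("the two specs must share image size, fps, duration, and modality",
               "ovirr_parameter_error")
  }
  h <- spec_a$image_size[1]; w <- spec_a$image_size[2]
  default_center <- c(h / 2, w / 2)
  if (isTRUE(all.equal(spec_a$center, default_center)) &&
      isTRUE(all.equal(spec_b$center, default_center))) {
    spec_a$center <- c(h / 2, 0.27 * w)
    spec_b$center <- c(h / 2, 0.73 * w)
    spec_a$semiaxes <- spec_b$semiaxes <- c(0.28 * h, 0.19 * w)
  }
  geo_a <- instance_geometry(spec_a)
  geo_b <- instance_geometry(spec_b)
  grow_a <- 1 + spec_a$amplitude_px / min(spec_a$semiaxes)
  grow_b <- 1 + spec_b$amplitude_px / min(spec_b$semiaxes)
  if (any(geo_a$rho <= grow_a & geo_b$rho <= grow_b)) {
    stop_input("instance regions overlap (including breathing excursion)",
               "ovirr_parameter_error")
  }
  attr(geo_a, "a") <- spec_a$semiaxes[2]; attr(geo_a, "b") <- spec_a$semiaxes[1]
  attr(geo_b, "a") <- spec_b$semiaxes[2]; attr(geo_b, "b") <- spec_b$semiaxes[1]
  tex_a <- make_texture(h, w, spec_a$modality, spec_a$seed)
  tex_b <- make_texture(h, w, spec_b$modality, spec_b$seed + 1L)
  background <- with_seed(spec_a$seed + 7919L, {
    u <- binomial_blur(matrix(runif(h * w), h, w), passes = 1L)
    70 + 12 * (u - mean(u)) / stats::sd(u)
  })
  n_frames <- round(spec_a$duration_s * spec_a$fps)
  t_s <- (seq_len(n_frames) - 1) / spec_a$fps
  delta_a <- sin(2 * pi * spec_a$rr_bpm / 60 * t_s)
  delta_b <- sin(2 * pi * spec_b$rr_bpm / 60 * t_s)
  noise <- with_seed(spec_a$seed + 104729L,
                     matrix(rnorm(h * w * n_frames, 0, spec_a$noise_sd), h * w, n_frames))
  frames <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    fr <- render_instance(background, tex_a, geo_a, delta_a[i])
    fr <- render_instance(fr, tex_b, geo_b, delta_b[i])
    fr <- fr + spec_a$drift_per_s * t_s[i] + matrix(noise[, i], h, w)
    fr <- round(pmin(pmax(fr, 0), 255))
    frames[[i]] <- if (spec_a$modality == "rgb") {
      array(c(fr, round(fr * 0.97), round(fr * 0.90)), dim = c(h, w, 3))
    } else {
      fr
    }
  }
  masks <- list(instance_mask((geo_a$rho <= 1) * 1L, instance_id = 1L),
                instance_mask((geo_b$rho <= 1) * 1L, instance_id = 2L))
  truth <- list(
    data.frame(time_s = t_s, rr_bpm = spec_a$rr_bpm,
               boundary_displacement_px = spec_a$amplitude_px * delta_a),
    data.frame(time_s = t_s, rr_bpm = spec_b$rr_bpm,
               boundary_displacement_px = spec_b$amplitude_px * delta_b))
  list(frames = frame_sequence(frames, fps = spec_a$fps,
                               modality = spec_a$modality,
                               source_id = "synth_two_instance"),
       masks = masks, truth = truth, spec_a = spec_a, spec_b = spec_b)
}

#' Write a synthetic scene to disk (frames, mask, truth, spec)
#'
#' Writes the frame directory, the mask PNG, a truth CSV, and the spec as
#' YAML alongside, mirroring the on-disk dialects read by [read_frame_sequence]
#' and [read_instance_masks].
#'
#' @param scene result of [generate_breathing_video].
#' @param dir output directory.
#' @return Invisibly, `dir`.
#' @export
write_synthetic_scene <- function(scene, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_frame_sequence(scene$frames, file.path(dir, "frames"))
  write_instance_mask(scene$mask, file.path(dir, "mask.png"))
  write.csv(scene$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  sp <- scene$spec
  yaml::write_yaml(unclass(sp), file.path(dir, "spec.yaml"))
  invisible(dir)
}
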