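# Shared synthetic fixtures, memoised so several test files can reuse the
# same generated scene and pipeline run without paying for regeneration.

.fixture_cache <- new.env(parent = emptyenv())

std_scene <- function() {
  if (is.null(.fixture_cache$scene)) {
    .fixture_cache$scene <- generate_breathing_video(
      synthetic_spec(rr_bpm = 27, fps = 20, duration_s = 30,
                     modality = "nir", seed = 101))
  }
  .fixture_cache$scene
}

std_run <- function() {
  if (is.null(.fixture_cache$run)) {
    sc <- std_scene()
    .fixture_cache$run <- run_pipeline(sc$frames, sc$mask)
  }
  .fixture_cache$run
}

# A small textured frame (2-D sinusoid grid plus speckle) for tracking tests.
textured_image <- function(h, w, seed = 7) {
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), times = w), h, w)
  base <- 120 + 40 * sin(xs / 2.1) * cos(ys / 2.7)
  set.seed(seed)
  pmin(pmax(base + matrix(rnorm(h * w, 0, 6), h, w), 0), 255)
}
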