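#' Published validation measurements shipped with the package
#'
#' Two small tables of published per-video agreement measurements from a
#' sheep respiratory-rate monitoring experiment, used for the worked-example
#' reproduction of the method's evaluation statistics.
#'
#' `rgb_validation_table()` holds the daytime RGB stage (one sheep, four
#' videos at 20 fps): the expert reference rate and the video-derived rate
#' for the whole thorax and for its three bands (R1 deepest abdominal, R2
#' middle, R3 nearest the head), with per-video absolute (breaths/min) and
#' relative (%) errors.
#'
#' `nir_validation_table()` holds the nighttime NIR stage (five sheep over
#' five nights at 10 fps, whole-thorax analysis only): 36 reference/video
#' rate pairs with durations and errors.
#'
#' @return A data frame.
#' @export
rgb_validation_table <- function() {
  read.csv(system.file("extdata", "rgb_stage_agreement.csv", package = "ovirr"),
           stringsAsFactors = FALSE)
}

#' @rdname rgb_validation_table
#' @export
nir_validation_table <- function() {
  read.csv(system.file("extdata", "nir_stage_agreement.csv", package = "ovirr"),
           stringsAsFactors = FALSE)
}
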