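#' Frame sequences
#'
#' A frame sequence is the package's in-memory representation of a video:
#' an ordered list of frames sharing one geometry, together with the frame
#' rate and the imaging modality. Frames are stored as numeric matrices
#' (grayscale, `H x W`) or arrays (`H x W x 3`, RGB) with 8-bit intensities
#' in `[0, 255]`; the raster origin is top-left, `x` indexes columns and `y`
#' indexes rows.
#'
#' @param frames list of frames, all with identical height and width.
#' @param fps frames per second (positive). The RGB acquisition stage of the
#'   reference setup ran at 20 fps, the NIR stage at 10 fps.
#' @param modality `"rgb"` or `"nir"`.
#' @param source_id free-text label identifying the recording.
#'
#' @return An object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, fps, modality = c("rgb", "nir"),
                           source_id = "") {
  modality <- match.arg(modality)
  if (!is.list(frames) || length(frames) < 2L) {
    stop_input("a frame sequence needs at least 2 frames", "ovirr_format_error")
  }
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0) {
    stop_input("fps must be a positive number", "ovirr_parameter_error")
  }
  dims <- lapply(frames, function(f) dim(f)[1:2])
  if (length(unique(dims)) != 1L) {
    stop_input("all frames must share identical dimensions", "ovirr_format_error")
  }
  structure(list(frames = frames, fps = fps, modality = modality,
                 source_id = source_id),
            class = "frame_sequence")
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_sequence> %d frames, %dx%d px, %g fps, %s%s\n",
              length(x$frames), d[1], d[2], x$fps, x$modality,
              if (nzchar(x$source_id)) paste0(", '", x$source_id, "'") else ""))
  invisible(x)
}

#' Read a frame sequence from a directory of images
#'
#' Frames are read from a directory of PNG (or TIFF) files. Ordering follows
#' the numeric value embedded in the file name when every file carries one
#' (so `frame_2.png` precedes `frame_10.png`); otherwise plain lexicographic
#' order is used with a warning. Video containers are not decoded; extract
#' frames to images first.
#'
#' @param path directory containing the frame images.
#' @param fps frame rate to attach (metadata supplied by the caller; no
#'   resampling is performed).
#' @param modality `"rgb"` or `"nir"`.
#' @return A [frame_sequence].
#' @export
read_frame_sequence <- function(path, fps, modality = c("rgb", "nir")) {
  modality <- match.arg(modality)
  if (!dir.exists(path)) {
    if (file.exists(path)) {
      stop_input(paste0("'", path, "' is a file, not a frame directory; ",
                        "video containers are not decoded - extract frames ",
                        "to PNG first"), "ovirr_input_error")
    }
    stop_input(paste0("no such directory: '", path, "'"), "ovirr_input_error")
  }
  files <- list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE)
  if (length(files) == 0L) {
    stop_input(paste0("no frame images found in '", path, "'"),
               "ovirr_input_error")
  }
  nums <- suppressWarnings(as.numeric(gsub("\\D", "", tools::file_path_sans_ext(files))))
  if (!anyNA(nums) && !any(duplicated(nums))) {
    files <- files[order(nums)]
  } else {
    warning("frame file names carry no unique number; using lexicographic order")
    files <- sort(files)
  }
  frames <- lapply(files, function(f) {
    fp <- file.path(path, f)
    img <- tryCatch(read_image_file(fp),
                    error = function(e) stop_input(
                      paste0("unreadable frame file '", fp, "': ",
                             conditionMessage(e)), "ovirr_input_error"))
    img
  })
  frame_sequence(frames, fps = fps, modality = modality,
                 source_id = basename(path))
}

read_image_file <- function(fp) {
  ext <- tolower(tools::file_ext(fp))
  img <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(fp)
  } else {
    png::readPNG(fp)
  }
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] >= 3L) img <- img[, , 1:3, drop = FALSE] else img <- img[, , 1]
  }
  round(img * 255)
}

#' Write a frame sequence as zero-padded PNG files
#'
#' @param fs a [frame_sequence].
#' @param path output directory (created when missing).
#' @return Invisibly, the written file paths.
#' @export
write_frame_sequence <- function(fs, path) {
  stopifnot(inherits(fs, "frame_sequence"))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  n <- length(fs$frames)
  width <- max(4L, nchar(as.character(n)))
  paths <- character(n)
  for (i in seq_len(n)) {
    fp <- file.path(path, sprintf(paste0("frame_%0", width, "d.png"), i))
    png::writePNG(fs$frames[[i]] / 255, fp)
    paths[i] <- fp
  }
  invisible(paths)
}

#' Convert a frame (or whole sequence) to grayscale luminance
#'
#' RGB frames are converted with ITU-R BT.601 weights
#' (0.299 R + 0.587 G + 0.114 B); grayscale frames pass through unchanged.
#'
#' @param x a frame matrix/array or a [frame_sequence].
#' @return A grayscale matrix, or a list of matrices for a sequence.
#' @export
as_gray <- function(x) {
  if (inherits(x, "frame_sequence")) return(lapply(x$frames, as_gray))
  if (is.matrix(x)) return(x)
  if (length(dim(x)) == 3L) {
    return(0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3])
  }
  stop_input("expected a 2-D or 3-plane frame", "ovirr_format_error")
}

#' Instance masks
#'
#' A binary region-of-interest mask for one detected instance (typically the
#' sheep thorax), with the detector's class label and certainty score.
#'
#' @param mask binary matrix (nonzero = foreground) matching the frame
#'   geometry.
#' @param class_label one of `"sheep"`, `"face"`, `"thorax"`.
#' @param certainty detector confidence in `[0, 1]`.
#' @param instance_id integer identifier.
#' @return An object of class `instance_mask`.
#' @export
instance_mask <- function(mask, class_label = c("thorax", "sheep", "face"),
                          certainty = 1.0, instance_id = 1L) {
  class_label <- match.arg(class_label)
  if (!is.matrix(mask)) stop_input("mask must be a matrix", "ovirr_format_error")
  if (!is.numeric(certainty) || certainty < 0 || certainty > 1) {
    stop_input("certainty must lie in [0, 1]", "ovirr_parameter_error")
  }
  structure(list(mask = (mask != 0) * 1L, class_label = class_label,
                 certainty = certainty, instance_id = as.integer(instance_id)),
            class = "instance_mask")
}

#' @export
print.instance_mask <- function(x, ...) {
  cat(sprintf("<instance_mask> #%d %s, certainty %.2f, %d foreground px\n",
              x$instance_id, x$class_label, x$certainty, sum(x$mask)))
  invisible(x)
}

#' Read instance masks from PNG files with an optional CSV sidecar
#'
#' Masks are 8-bit single-channel PNGs, nonzero = foreground. A sidecar CSV
#' with columns `instance_id,class_label,certainty,mask_file` attaches
#' detection metadata; without one, certainty defaults to 1.0 and the class
#' label to `"thorax"`.
#'
#' @param path a mask PNG file or a directory of mask PNGs.
#' @param sidecar optional path to the sidecar CSV.
#' @return A list of [instance_mask] objects.
#' @export
read_instance_masks <- function(path, sidecar = NULL) {
  files <- if (dir.exists(path)) {
    file.path(path, sort(list.files(path, pattern = "\\.png$", ignore.case = TRUE)))
  } else if (file.exists(path)) {
    path
  } else {
    stop_input(paste0("no such mask path: '", path, "'"), "ovirr_input_error")
  }
  if (length(files) == 0L) {
    stop_input(paste0("no mask PNGs found in '", path, "'"), "ovirr_input_error")
  }
  meta <- NULL
  if (!is.null(sidecar)) {
    meta <- read.csv(sidecar, stringsAsFactors = FALSE)
    needed <- c("instance_id", "class_label", "certainty", "mask_file")
    if (!all(needed %in% names(meta))) {
      stop_input("sidecar must have columns instance_id,class_label,certainty,mask_file",
                 "ovirr_format_error")
    }
  }
  out <- vector("list", length(files))
  for (i in seq_along(files)) {
    m <- png::readPNG(files[i])
    if (length(dim(m)) == 3L) m <- m[, , 1]
    bin <- (m > 0) * 1L
    if (!is.null(meta)) {
      row <- meta[meta$mask_file == basename(files[i]), , drop = FALSE]
      if (nrow(row) == 1L) {
        out[[i]] <- instance_mask(bin, class_label = row$class_label,
                                  certainty = row$certainty,
                                  instance_id = row$instance_id)
        next
      }
    }
    out[[i]] <- instance_mask(bin, instance_id = i)
  }
  out
}

#' Write an instance mask as an 8-bit PNG (foreground = 255)
#'
#' @param mask an [instance_mask] or binary matrix.
#' @param path output PNG path.
#' @export
write_instance_mask <- function(mask, path) {
  m <- if (inherits(mask, "instance_mask")) mask$mask else mask
  png::writePNG((m != 0) * 1.0, path)
  invisible(path)
}

#' Write / read a respiratory-rate series as CSV
#'
#' The dialect is a header plus columns `time_s,rr_bpm,rr_smoothed_bpm`
#' (times in seconds, rates in breaths/min). An empty series writes a
#' header-only file.
#'
#' @param series an [rr_series].
#' @param path output CSV path.
#' @export
write_rr_series <- function(series, path) {
  stopifnot(inherits(series, "rr_series"))
  df <- data.frame(time_s = series$times_s, rr_bpm = series$rr_bpm,
                   rr_smoothed_bpm = if (is.null(series$rr_smoothed_bpm))
                     rep(NA_real_, length(series$rr_bpm)) else series$rr_smoothed_bpm)
  tryCatch(write.csv(df, path, row.names = FALSE),
           error = function(e) stop_input(
             paste0("cannot write '", path, "': ", conditionMessage(e)),
             "ovirr_io_error"))
  invisible(path)
}

#' @rdname write_rr_series
#' @export
read_rr_series <- function(path) {
  df <- read.csv(path)
  rr_series(times_s = df$time_s, rr_bpm = df$rr_bpm,
            rr_smoothed_bpm = if (all(is.na(df$rr_smoothed_bpm))) NULL
            else df$rr_smoothed_bpm)
}

#' Write an agreement table as CSV
#'
#' Columns: `video_id,region,rr_ref,rr_video,abs_err,rel_err_pct`.
#'
#' @param records a data frame of per-pair agreement records, e.g. the
#'   `records` element returned by [agreement()].
#' @param path output CSV path.
#' @export
write_agreement_table <- function(records, path) {
  cols <- c("video_id", "region", "rr_ref", "rr_video", "abs_err", "rel_err_pct")
  if (!all(cols %in% names(records))) {
    stop_input(paste("agreement table needs columns", paste(cols, collapse = ",")),
               "ovirr_format_error")
  }
  tryCatch(write.csv(records[, cols], path, row.names = FALSE),
           error = function(e) stop_input(
             paste0("cannot write '", path, "': ", conditionMessage(e)),
             "ovirr_io_error"))
  invisible(path)
}
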