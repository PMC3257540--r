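#' Trial image stacks
#'
#' An `image_stack` holds one trial's frames together with the acquisition
#' metadata the analysis needs: frame rate, spatial scale, the index of the
#' first post-stimulus frame (acquisition is time-locked to respiration, so
#' stimulus onset always falls on a known frame), the stimulus delivered and
#' a trial identifier.
#'
#' Frames are stored as a numeric array with dimensions
#' `height x width x n_frames` (rows are the dorsoventral axis, columns the
#' anteroposterior axis). Frame `i` covers acquisition time
#' `[(i-1)/rate, i/rate)` seconds, with `t = 0` at the start of the trial.
#'
#' @param frames numeric array, `height x width x n_frames`, finite and
#'   non-negative fluorescence in arbitrary units.
#' @param frame_rate_hz acquisition frame rate in Hz.
#' @param mm_per_px spatial scale of one pixel in millimetres.
#' @param stimulus_onset_frame 1-based index of the first post-stimulus
#'   frame.
#' @param stimulus a [stimulus_spec][electrical_stimulus] (possibly blank).
#' @param trial_id character trial identifier.
#' @param replicate integer replicate (animal/session) identifier used when
#'   several experiments are analysed together.
#' @return An `image_stack` object.
#' @seealso [generate_trial()], [bleach_correct()], [differential_image()]
#' @export
image_stack <- function(frames, frame_rate_hz, mm_per_px,
                        stimulus_onset_frame, stimulus, trial_id,
                        replicate = 1L) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stopf("`frames` must be a height x width x n_frames array")
  if (!all(is.finite(frames)))
    stopf("`frames` must be finite")
  if (any(frames < 0))
    stopf("`frames` must be non-negative")
  if (!is_scalar_num(frame_rate_hz) || frame_rate_hz <= 0)
    stopf("`frame_rate_hz` must be a positive scalar")
  if (!is_scalar_num(mm_per_px) || mm_per_px <= 0)
    stopf("`mm_per_px` must be a positive scalar")
  nf <- dim(frames)[3L]
  if (!is_count(stimulus_onset_frame) || stimulus_onset_frame > nf)
    stopf("`stimulus_onset_frame` must lie within the stack (1..%d)", nf)
  if (!inherits(stimulus, "stimulus_spec"))
    stopf("`stimulus` must be a stimulus_spec")
  structure(list(frames = frames,
                 frame_rate_hz = frame_rate_hz,
                 mm_per_px = mm_per_px,
                 stimulus_onset_frame = as.integer(stimulus_onset_frame),
                 stimulus = stimulus,
                 trial_id = as.character(trial_id),
                 replicate = as.integer(replicate)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<image_stack> %s: %d x %d px, %d frames @ %g Hz, onset frame %d [%s]\n",
    x$trial_id, d[1L], d[2L], d[3L], x$frame_rate_hz,
    x$stimulus_onset_frame, x$stimulus$label))
  invisible(x)
}

# shared-geometry check used before any cross-trial arithmetic
check_same_geometry <- function(stacks) {
  ref <- stacks[[1L]]
  for (s in stacks[-1L]) {
    if (!identical(dim(s$frames), dim(ref$frames)))
      stopf("stacks differ in shape (%s vs %s)",
            paste(dim(s$frames), collapse = "x"),
            paste(dim(ref$frames), collapse = "x"))
    if (s$frame_rate_hz != ref$frame_rate_hz)
      stopf("stacks differ in frame rate")
    if (s$stimulus_onset_frame != ref$stimulus_onset_frame)
      stopf("stacks differ in stimulus onset frame")
    if (s$mm_per_px != ref$mm_per_px)
      stopf("stacks differ in spatial scale")
  }
  invisible(TRUE)
}

#' Read and write image stacks as multi-frame TIFF plus JSON sidecar
#'
#' Stacks are written as a multi-frame 32-bit TIFF next to a JSON sidecar
#' (`<prefix>.tif`, `<prefix>.json`) that carries the acquisition metadata.
#' Because TIFF samples are stored on a normalized scale, the maximum
#' fluorescence value is recorded in the sidecar (`scale`) and restored on
#' read.
#'
#' @param stack an [image_stack()].
#' @param prefix file path without extension.
#' @return `write_stack()` returns `prefix` invisibly; `read_stack()`
#'   returns an [image_stack()].
#' @export
write_stack <- function(stack, prefix) {
  if (!inherits(stack, "image_stack")) stopf("`stack` must be an image_stack")
  scale <- max(stack$frames, 1e-12)
  frames <- lapply(seq_len(dim(stack$frames)[3L]),
                   function(i) stack$frames[, , i] / scale)
  tiff::writeTIFF(frames, paste0(prefix, ".tif"), bits.per.sample = 32L)
  meta <- list(frame_rate_hz = stack$frame_rate_hz,
               mm_per_px = stack$mm_per_px,
               stimulus_onset_frame = stack$stimulus_onset_frame,
               stimulus = unclass(stack$stimulus),
               blank = is_blank(stack$stimulus),
               trial_id = stack$trial_id,
               replicate = stack$replicate,
               scale = scale)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_stack
#' @export
read_stack <- function(prefix) {
  tif <- paste0(prefix, ".tif")
  js <- paste0(prefix, ".json")
  if (!file.exists(tif) || !file.exists(js))
    stopf("missing %s or %s", tif, js)
  frames <- tiff::readTIFF(tif, all = TRUE)
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  arr <- array(0, dim = c(dim(frames[[1L]]), length(frames)))
  for (i in seq_along(frames)) arr[, , i] <- frames[[i]] * meta$scale
  stim <- structure(as.list(meta$stimulus), class = "stimulus_spec")
  image_stack(arr, meta$frame_rate_hz, meta$mm_per_px,
              meta$stimulus_onset_frame, stim, meta$trial_id,
              meta$replicate)
}
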