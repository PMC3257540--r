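#' Analysis windows for the differential image
#'
#' The stimulus window is a half-open interval after stimulus onset
#' (`[0.5, 1.5)` s for electrical stimulation, `[0.5, 2.0)` s for
#' odourants); the baseline is the 2-s temporal average acquired
#' immediately before stimulation. Windows are converted to frames with a
#' fixed rounding rule: floor for the start, ceiling for the end, half-open
#' in frames, and the baseline ends at the onset frame.
#'
#' @param stim_start_s,stim_end_s stimulus window bounds, seconds after
#'   onset.
#' @param baseline_s baseline duration before onset, seconds.
#' @return An `analysis_windows` object.
#' @export
analysis_windows <- function(stim_start_s = 0.5, stim_end_s = 1.5,
                             baseline_s = 2) {
  if (stim_end_s <= stim_start_s || stim_start_s < 0)
    stopf("stimulus window must be a non-empty interval after onset")
  if (baseline_s <= 0) stopf("`baseline_s` must be positive")
  structure(list(stim_start_s = stim_start_s, stim_end_s = stim_end_s,
                 baseline_s = baseline_s), class = "analysis_windows")
}

#' @rdname analysis_windows
#' @export
odour_windows <- function() analysis_windows(stim_end_s = 2)

# frame indices (1-based) for the stimulus and baseline windows
window_frames <- function(windows, onset, rate, n_frames) {
  s0 <- onset + as.integer(floor(windows$stim_start_s * rate))
  s1 <- onset + as.integer(ceiling(windows$stim_end_s * rate)) - 1L
  b0 <- onset - as.integer(floor(windows$baseline_s * rate))
  b1 <- onset - 1L
  if (s1 < s0 || s0 < 1L || s1 > n_frames)
    stopf("stimulus window is empty or outside the stack after rounding")
  if (b1 < b0 || b0 < 1L)
    stopf("baseline window is empty or outside the stack after rounding")
  list(stim = s0:s1, base = b0:b1)
}

#' Spatial band-pass filter parameters
#'
#' Cutoffs are frequency-domain standard deviations, in cycles/mm, of
#' Gaussian transfer functions composed multiplicatively: a low-pass
#' `exp(-f^2 / (2 sigma_hi^2))` removing high-frequency shot noise and a
#' complementary high-pass `1 - exp(-f^2 / (2 sigma_lo^2))` removing
#' nonspecific global fluctuation, with `f` the radial spatial frequency.
#' The product lies in `[0, 1]` and vanishes at DC.
#'
#' @param sigma_hi_per_mm upper cutoff, cycles/mm.
#' @param sigma_lo_per_mm lower cutoff, cycles/mm.
#' @return A `filter_params` object.
#' @export
filter_params <- function(sigma_hi_per_mm = 50, sigma_lo_per_mm = 0.1) {
  if (!(sigma_lo_per_mm > 0 && sigma_hi_per_mm > sigma_lo_per_mm))
    stopf("need 0 < sigma_lo < sigma_hi")
  structure(list(sigma_hi_per_mm = sigma_hi_per_mm,
                 sigma_lo_per_mm = sigma_lo_per_mm),
            class = "filter_params")
}

#' Photobleaching correction by blank-trial subtraction
#'
#' Subtracts the frame-wise mean of the blank (no-stimulus) trials from a
#' trial and restores the blank grand mean as an offset, so that the
#' deterministic bleaching decay common to all trials cancels while the
#' baseline stays positive for the subsequent ratio. All stacks must share
#' geometry, frame rate and onset frame.
#'
#' @param stack the trial to correct (an [image_stack()]).
#' @param blank_stacks non-empty list of blank-trial [image_stack()]s.
#' @return The corrected [image_stack()] with metadata preserved.
#' @export
bleach_correct <- function(stack, blank_stacks) {
  if (!inherits(stack, "image_stack")) stopf("`stack` must be an image_stack")
  if (!is.list(blank_stacks) || length(blank_stacks) < 1L)
    stopf("at least one blank stack is required")
  check_same_geometry(c(list(stack), blank_stacks))
  blank_mean <- Reduce(`+`, lapply(blank_stacks, `[[`, "frames")) /
    length(blank_stacks)
  grand <- mean(blank_mean)
  out <- stack$frames - blank_mean + grand
  out[out < 0] <- 0
  stack$frames <- out
  stack
}

#' Windowed differential image (deltaF/F)
#'
#' Divides the stimulus-window temporal average by the pre-stimulus
#' baseline average, reported as `dff = ratio - 1` so that non-responding
#' pixels sit at zero. Pixels whose baseline mean is non-positive are set
#' to 0 and flagged in the `invalid` attribute.
#'
#' @param stack an [image_stack()].
#' @param windows an [analysis_windows()].
#' @return A `differential_image`: the deltaF/F matrix with attributes
#'   `windows`, `trial_id`, `stimulus`, `mm_per_px`, `filtered`, `n` and
#'   `invalid`.
#' @export
differential_image <- function(stack, windows = analysis_windows()) {
  if (!inherits(stack, "image_stack")) stopf("`stack` must be an image_stack")
  if (!inherits(windows, "analysis_windows"))
    stopf("`windows` must be an analysis_windows object")
  nf <- dim(stack$frames)[3L]
  wf <- window_frames(windows, stack$stimulus_onset_frame,
                      stack$frame_rate_hz, nf)
  mean_frames <- function(idx) {
    if (length(idx) == 1L) stack$frames[, , idx]
    else rowMeans(stack$frames[, , idx, drop = FALSE], dims = 2L)
  }
  m_stim <- mean_frames(wf$stim)
  m_base <- mean_frames(wf$base)
  invalid <- m_base <= 0
  dff <- matrix(0, nrow(m_stim), ncol(m_stim))
  dff[!invalid] <- m_stim[!invalid] / m_base[!invalid] - 1
  structure(dff, class = c("differential_image", "matrix"),
            windows = windows, trial_id = stack$trial_id,
            stimulus = stack$stimulus, mm_per_px = stack$mm_per_px,
            filtered = FALSE, n = 1L, invalid = invalid)
}

#' Gaussian spatial band-pass filter
#'
#' Filters a differential image in the frequency domain with the band-pass
#' transfer function `H(f) = exp(-f^2/(2 sigma_hi^2)) *
#' (1 - exp(-f^2/(2 sigma_lo^2)))`, `f` in cycles/mm (see
#' [filter_params()]). The image is mean-padded to the next power of two in
#' each dimension before the FFT to suppress wrap-around artefacts, and
#' cropped back afterwards; the output is real-valued with the DC component
#' removed.
#'
#' @param dff a `differential_image` or plain numeric matrix.
#' @param params a [filter_params()].
#' @param mm_per_px pixel size in mm; taken from the `differential_image`
#'   attribute when omitted.
#' @return The filtered image, same class and attributes as the input with
#'   `filtered = TRUE`.
#' @export
bandpass_filter <- function(dff, params = filter_params(),
                            mm_per_px = attr(dff, "mm_per_px")) {
  if (!inherits(params, "filter_params"))
    stopf("`params` must be a filter_params object")
  if (is.null(mm_per_px) || !is_scalar_num(mm_per_px) || mm_per_px <= 0)
    stopf("`mm_per_px` must be a positive scalar")
  x <- unclass(dff)
  if (!all(is.finite(x))) stopf("input image contains non-finite values")
  h <- nrow(x); w <- ncol(x)
  ph <- next_pow2(h); pw <- next_pow2(w)
  padded <- matrix(mean(x), ph, pw)
  padded[seq_len(h), seq_len(w)] <- x
  fy <- fft_freq(ph) / mm_per_px                 # cycles/mm
  fx <- fft_freq(pw) / mm_per_px
  f2 <- outer(fy^2, fx^2, "+")
  H <- exp(-f2 / (2 * params$sigma_hi_per_mm^2)) *
    (1 - exp(-f2 / (2 * params$sigma_lo_per_mm^2)))
  out <- Re(fft(fft(padded) * H, inverse = TRUE)) / (ph * pw)
  out <- out[seq_len(h), seq_len(w)]
  attrs <- attributes(dff)
  if (inherits(dff, "differential_image")) {
    attrs$filtered <- TRUE
    attrs$dim <- dim(out)
    attributes(out) <- attrs
  }
  out
}

#' Average differential images across trials
#'
#' Pixel-wise arithmetic mean of same-shape differential images; the
#' number of averaged trials is recorded in the `n` attribute.
#'
#' @param dffs non-empty list of `differential_image`s (or matrices) of
#'   identical shape.
#' @return A `differential_image` carrying the attributes of the first
#'   input and `n = length(dffs)`.
#' @export
average_trials <- function(dffs) {
  if (!is.list(dffs) || length(dffs) < 1L)
    stopf("`dffs` must be a non-empty list")
  d1 <- dim(unclass(dffs[[1L]]))
  for (d in dffs)
    if (!identical(dim(unclass(d)), d1)) stopf("images differ in shape")
  out <- Reduce(`+`, lapply(dffs, unclass)) / length(dffs)
  attrs <- attributes(dffs[[1L]])
  attrs$dim <- dim(out)
  attrs$n <- length(dffs)
  attributes(out) <- attrs
  if (!inherits(out, "differential_image"))
    class(out) <- c("differential_image", "matrix")
  out
}

#' Pixel-wise two-sample t-test response map
#'
#' Compares stimulus-trial with blank-trial differential images pixel by
#' pixel using a two-tailed two-sample t-test (pooled-variance Student test
#' by default, matching the balanced 10-versus-10 design; Welch available
#' as a switch). No multiple-testing correction is applied by default,
#' mirroring the original analysis; `p_adjust` enables one.
#'
#' Pixels where both groups have zero variance and equal means get
#' `p = 1`; zero variance with unequal means gives `p = 0`.
#'
#' @param stim_dffs,blank_dffs lists (each of length >= 2) of
#'   `differential_image`s for the stimulus and blank groups.
#' @param alpha significance level of the map (two-tailed).
#' @param var_equal pooled-variance Student test (`TRUE`, default) or
#'   Welch (`FALSE`).
#' @param p_adjust multiple-testing correction passed to
#'   [stats::p.adjust()]; `"none"` by default.
#' @return A `response_map` with per-pixel `mean_dff` (mean over stimulus
#'   trials), `diff_dff` (stimulus minus blank group means), `t_stat`,
#'   `p_value`, the two-sided `sig_mask` (`p < alpha`) and the
#'   `responsive_mask` (significant pixels with positive response, the
#'   "significantly responsive areas" shown in overlays), plus `alpha`,
#'   `n_stim_trials` and `n_blank_trials`.
#' @export
pixel_ttest <- function(stim_dffs, blank_dffs, alpha = 0.01,
                        var_equal = TRUE, p_adjust = "none") {
  if (length(stim_dffs) < 2L || length(blank_dffs) < 2L)
    stopf("each group needs at least 2 images")
  if (!is_scalar_num(alpha) || alpha <= 0 || alpha >= 1)
    stopf("`alpha` must be in (0, 1)")
  d1 <- dim(unclass(stim_dffs[[1L]]))
  for (d in c(stim_dffs, blank_dffs))
    if (!identical(dim(unclass(d)), d1)) stopf("images differ in shape")
  X1 <- matrix(vapply(stim_dffs, function(d) as.vector(unclass(d)),
                      numeric(prod(d1))), nrow = prod(d1))
  X2 <- matrix(vapply(blank_dffs, function(d) as.vector(unclass(d)),
                      numeric(prod(d1))), nrow = prod(d1))
  n1 <- ncol(X1); n2 <- ncol(X2)
  m1 <- rowMeans(X1); m2 <- rowMeans(X2)
  v1 <- rowSums((X1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((X2 - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  diff <- m1 - m2
  tt <- diff / se
  degenerate <- se == 0
  tt[degenerate] <- ifelse(diff[degenerate] == 0, 0,
                           sign(diff[degenerate]) * Inf)
  p <- 2 * pt(-abs(tt), df)
  p[degenerate] <- ifelse(diff[degenerate] == 0, 1, 0)
  if (!identical(p_adjust, "none")) p <- p.adjust(p, method = p_adjust)
  shape <- function(v) matrix(v, d1[1L], d1[2L])
  sig <- shape(p < alpha)
  structure(list(mean_dff = shape(m1),
                 diff_dff = shape(diff),
                 t_stat = shape(tt),
                 p_value = shape(p),
                 sig_mask = sig,
                 responsive_mask = sig & shape(diff > 0),
                 alpha = alpha,
                 n_stim_trials = n1,
                 n_blank_trials = n2,
                 var_equal = var_equal,
                 p_adjust = p_adjust),
            class = "response_map")
}

#' @export
print.response_map <- function(x, ...) {
  cat(sprintf(
    "<response_map> %d x %d px, %d stim vs %d blank trials, alpha = %g\n",
    nrow(x$mean_dff), ncol(x$mean_dff), x$n_stim_trials, x$n_blank_trials,
    x$alpha))
  cat(sprintf("  significant pixels: %d (%.2f%%), responsive: %d\n",
              sum(x$sig_mask), 100 * mean(x$sig_mask),
              sum(x$responsive_mask)))
  invisible(x)
}

#' Overlay significant pixels on an anatomical image
#'
#' Renders the anatomy (typically the blood-vessel image, here the mean
#' baseline frame) in greyscale and colorizes significantly responsive
#' pixels from yellow to red with increasing deltaF/F magnitude.
#'
#' @param map a [pixel_ttest()] response map.
#' @param anatomy numeric matrix of the same shape as the map.
#' @param mask which mask to colorize: the positive `"responsive"` mask
#'   (default, as plotted) or the full two-sided `"significant"` mask.
#' @param max_dff deltaF/F mapped to pure red; defaults to the maximum
#'   magnitude over the mask.
#' @return An `height x width x 3` RGB array in `[0, 1]`.
#' @export
make_overlay <- function(map, anatomy,
                         mask = c("responsive", "significant"),
                         max_dff = NULL) {
  mask <- match.arg(mask)
  if (!inherits(map, "response_map")) stopf("`map` must be a response_map")
  if (!identical(dim(anatomy), dim(map$mean_dff)))
    stopf("anatomy shape does not match the map")
  rng <- range(anatomy)
  grey <- if (diff(rng) > 0) (anatomy - rng[1L]) / diff(rng)
  else matrix(0.5, nrow(anatomy), ncol(anatomy))
  rgb <- array(rep(grey, 3L), dim = c(dim(grey), 3L))
  sel <- if (mask == "responsive") map$responsive_mask else map$sig_mask
  if (any(sel)) {
    mag <- abs(map$mean_dff[sel])
    if (is.null(max_dff)) max_dff <- max(mag)
    frac <- if (max_dff > 0) pmin(mag / max_dff, 1) else rep(1, sum(sel))
    r <- rgb[, , 1L]; g <- rgb[, , 2L]; b <- rgb[, , 3L]
    r[sel] <- 1
    g[sel] <- 1 - frac   # yellow (low) to red (high)
    b[sel] <- 0
    rgb <- array(c(r, g, b), dim = dim(rgb))
  }
  rgb
}
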