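#' Configuration of the synthetic imaging experiment
#'
#' The generator emulates the statistical structure the analysis chain
#' assumes: a spatially smooth baseline fluorescence field, multiplicative
#' exponential photobleaching, additive Gaussian shot noise, a slow
#' large-scale multiplicative fluctuation (the component the low-frequency
#' cutoff of the band-pass is meant to remove), and respiration-locked
#' evoked responses that are spatial Gaussians entering multiplicatively on
#' the bleached baseline so that ratio-based deltaF/F recovery is
#' scale-free.
#'
#' All temporal parameters are converted to whole frames by flooring at
#' `frame_rate_hz`. The amplitude gain mapping stimulus strength (pulse
#' count scaled by relative current, or relative odourant dilution) to the
#' realized peak deltaF/F is saturating and monotone,
#' `g(s) = (s/(s+k)) / (s0/(s0+k))` with half-saturation `k =
#' amplitude_halfsat` and reference strength `s0 = amplitude_ref_strength`,
#' so the default stimulus realizes exactly the configured blob peak.
#'
#' @param height_px,width_px frame size in pixels (512 x 672 field halved
#'   twice gives the default camera format 256 x 336).
#' @param frame_rate_hz acquisition rate, Hz.
#' @param mm_per_px pixel size, mm. The acquisition optics do not pin this
#'   value down; it is carried in stack metadata and never assumed
#'   downstream.
#' @param n_frames frames per trial.
#' @param stimulus_onset_s time of stimulus onset from trial start, s.
#' @param n_trials_per_condition trials per condition (and blank trials).
#' @param baseline_F0 mean baseline fluorescence, arbitrary units. The
#'   actual field is `baseline_F0 * (1 + 0.1 sin(pi r/H) sin(pi c/W))`,
#'   a smooth bump emulating uneven illumination/expression.
#' @param bleach_tau_s exponential photobleaching time constant, s
#'   (`Inf` disables bleaching).
#' @param shot_noise_sd additive Gaussian noise SD per frame per pixel,
#'   arbitrary units.
#' @param global_fluct_amplitude peak multiplicative amplitude of the slow
#'   large-scale fluctuation (0 disables it).
#' @param global_fluct_spatial_sigma_mm spatial correlation scale of the
#'   fluctuation field, mm.
#' @param global_fluct_period_s period of the slow temporal modulation, s.
#' @param response_latency_s delay from stimulus onset to response onset, s.
#' @param response_duration_s duration of the evoked plateau, s.
#' @param blobs named list (by condition label) of evoked-response
#'   definitions, each `list(center = c(x, y), sigma_px, peak_dFF)` with
#'   `center` in (column, row) pixel coordinates. Conditions without an
#'   entry evoke no response.
#' @param amplitude_halfsat,amplitude_ref_strength saturating gain
#'   parameters (pulse-equivalent units).
#' @param rng_seed optional default seed recorded in the configuration.
#' @return A validated `synthetic_config` object.
#' @seealso [generate_trial()], [generate_experiment()]
#' @export
synthetic_config <- function(height_px = 256, width_px = 336,
                             frame_rate_hz = 5, mm_per_px = 0.02,
                             n_frames = 25, stimulus_onset_s = 2,
                             n_trials_per_condition = 10,
                             baseline_F0 = 1000, bleach_tau_s = 50,
                             shot_noise_sd = 19,
                             global_fluct_amplitude = 0.01,
                             global_fluct_spatial_sigma_mm = 2,
                             global_fluct_period_s = 8,
                             response_latency_s = 0.5,
                             response_duration_s = 2,
                             blobs = list(),
                             amplitude_halfsat = 2,
                             amplitude_ref_strength = 5,
                             rng_seed = NULL) {
  cfg <- structure(as.list(environment()), class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  if (!is_count(cfg$height_px) || !is_count(cfg$width_px))
    stopf("frame dimensions must be positive integers")
  if (!is_count(cfg$n_frames))
    stopf("`n_frames` must be a positive integer")
  if (!is_scalar_num(cfg$frame_rate_hz) || cfg$frame_rate_hz <= 0)
    stopf("`frame_rate_hz` must be positive")
  if (!is_scalar_num(cfg$mm_per_px) || cfg$mm_per_px <= 0)
    stopf("`mm_per_px` must be positive")
  if (!(is_scalar_num(cfg$bleach_tau_s) || identical(cfg$bleach_tau_s, Inf)) ||
      cfg$bleach_tau_s <= 0)
    stopf("`bleach_tau_s` must be positive (Inf allowed)")
  if (!is_count(cfg$n_trials_per_condition) || cfg$n_trials_per_condition < 2)
    stopf("`n_trials_per_condition` must be at least 2")
  if (cfg$shot_noise_sd < 0 || cfg$global_fluct_amplitude < 0)
    stopf("noise and fluctuation amplitudes must be non-negative")
  onset <- onset_frame(cfg)
  if (onset < 1L || onset > cfg$n_frames)
    stopf("stimulus onset falls outside the stack")
  for (nm in names(cfg$blobs)) {
    b <- cfg$blobs[[nm]]
    if (!all(c("center", "sigma_px", "peak_dFF") %in% names(b)))
      stopf("blob '%s' needs fields center, sigma_px, peak_dFF", nm)
    if (b$peak_dFF < 0) stopf("blob '%s': peak_dFF must be >= 0", nm)
    if (b$sigma_px <= 0) stopf("blob '%s': sigma_px must be > 0", nm)
    if (length(b$center) != 2L)
      stopf("blob '%s': center must be c(x, y)", nm)
  }
  invisible(cfg)
}

# first post-stimulus frame, 1-based; temporal rounding rule is floor
onset_frame <- function(cfg) {
  as.integer(floor(cfg$stimulus_onset_s * cfg$frame_rate_hz)) + 1L
}

# smooth deterministic baseline field
baseline_field <- function(cfg) {
  h <- cfg$height_px; w <- cfg$width_px
  bump <- outer(sin(pi * (seq_len(h) - 0.5) / h),
                sin(pi * (seq_len(w) - 0.5) / w))
  cfg$baseline_F0 * (1 + 0.1 * bump)
}

# unit-pointwise-SD Gaussian random field with spatial scale sigma_px,
# built by spectral shaping of white noise (periodic boundary)
smooth_noise_field <- function(h, w, sigma_px) {
  z <- matrix(rnorm(h * w), h, w)
  if (sigma_px <= 0) return(z)
  sigma_f <- 1 / (2 * pi * sigma_px)            # cycles/px
  f2 <- outer(fft_freq(h)^2, fft_freq(w)^2, "+")
  H <- exp(-f2 / (2 * sigma_f^2))
  out <- Re(fft(fft(z) * H, inverse = TRUE)) / (h * w)
  out / sqrt(mean(H^2))
}

gaussian_blob <- function(h, w, center_xy, sigma_px) {
  d2 <- outer((seq_len(h) - center_xy[2L])^2,
              (seq_len(w) - center_xy[1L])^2, "+")
  exp(-d2 / (2 * sigma_px^2))
}

amplitude_gain <- function(cfg, stimulus) {
  s <- stimulus_strength(stimulus, ref_strength = cfg$amplitude_ref_strength)
  if (s <= 0) return(0)
  k <- cfg$amplitude_halfsat
  (s / (s + k)) / (cfg$amplitude_ref_strength /
                     (cfg$amplitude_ref_strength + k))
}

#' Generate one synthetic trial
#'
#' Frames follow
#' `F(x,y,t) = F0(x,y) exp(-t/tau) (1 + g(x,y,t)) (1 + e(x,y,t)) + noise`,
#' where `g` is the slow large-scale multiplicative fluctuation and `e` the
#' evoked response: a spatial Gaussian blob scaled by the saturating
#' amplitude gain, active from `response_latency_s` after stimulus onset for
#' `response_duration_s`. Blank trials and conditions without a configured
#' blob have `e = 0`. Output is bit-identical for identical
#' configuration and seed.
#'
#' @param config a [synthetic_config()].
#' @param stimulus a [stimulus_spec][electrical_stimulus]; blank trials
#'   carry no evoked response.
#' @param seed integer RNG seed for this trial.
#' @param trial_id,replicate identifiers stored in the stack metadata.
#' @return An [image_stack()].
#' @export
generate_trial <- function(config, stimulus, seed,
                           trial_id = stimulus$label, replicate = 1L) {
  validate_synthetic_config(config)
  if (!inherits(stimulus, "stimulus_spec"))
    stopf("`stimulus` must be a stimulus_spec")
  h <- config$height_px; w <- config$width_px; nf <- config$n_frames
  rate <- config$frame_rate_hz
  tvec <- (seq_len(nf) - 1) / rate
  f0 <- baseline_field(config)
  decay <- if (is.infinite(config$bleach_tau_s)) rep(1, nf) else
    exp(-tvec / config$bleach_tau_s)

  blob <- NULL
  gain <- 0
  if (!is_blank(stimulus) && stimulus$label %in% names(config$blobs)) {
    b <- config$blobs[[stimulus$label]]
    gain <- amplitude_gain(config, stimulus)
    if (gain > 0 && b$peak_dFF > 0)
      blob <- b$peak_dFF * gain * gaussian_blob(h, w, b$center, b$sigma_px)
  }
  first_active <- as.integer(floor((config$stimulus_onset_s +
                                      config$response_latency_s) * rate)) + 1L
  n_active <- as.integer(floor(config$response_duration_s * rate))
  active <- if (n_active < 1L) integer(0) else
    intersect(first_active:(first_active + n_active - 1L), seq_len(nf))

  with_rng_seed(seed, {
    fluct_spatial <- NULL
    fluct_t <- rep(0, nf)
    if (config$global_fluct_amplitude > 0) {
      fluct_spatial <- smooth_noise_field(
        h, w, config$global_fluct_spatial_sigma_mm / config$mm_per_px)
      phase <- runif(1, 0, 2 * pi)
      fluct_t <- sin(2 * pi * tvec / config$global_fluct_period_s + phase)
    }
    frames <- array(0, dim = c(h, w, nf))
    for (i in seq_len(nf)) {
      fr <- f0 * decay[i]
      if (!is.null(fluct_spatial))
        fr <- fr * (1 + config$global_fluct_amplitude * fluct_t[i] *
                      fluct_spatial)
      if (!is.null(blob) && i %in% active)
        fr <- fr * (1 + blob)
      frames[, , i] <- fr
    }
    if (config$shot_noise_sd > 0)
      frames <- frames + array(rnorm(length(frames),
                                     sd = config$shot_noise_sd),
                               dim = dim(frames))
    frames[frames < 0] <- 0
    image_stack(frames, rate, config$mm_per_px, onset_frame(config),
                stimulus, trial_id, replicate)
  })
}

#' Generate a full synthetic experiment with ground truth
#'
#' Produces `n_trials_per_condition` stacks for every condition plus the
#' same number of blank stacks, together with a `synthetic_truth` record:
#' per-condition true active masks (pixels whose noiseless peak deltaF/F is
#' at least half the blob peak), blob centres and the realized per-trial
#' amplitudes. Per-trial seeds are drawn deterministically from `seed`.
#'
#' @param config a [synthetic_config()].
#' @param conditions list of [stimulus_spec][electrical_stimulus] objects
#'   with distinct labels.
#' @param seed integer experiment seed.
#' @param replicate replicate identifier stamped on every stack.
#' @return A list with elements `stacks` (list of [image_stack()]) and
#'   `truth` (class `synthetic_truth`).
#' @export
generate_experiment <- function(config, conditions, seed, replicate = 1L) {
  validate_synthetic_config(config)
  if (!is.list(conditions) || length(conditions) < 1L)
    stopf("`conditions` must be a non-empty list of stimulus_spec objects")
  labels <- vapply(conditions, function(s) s$label, character(1))
  if (anyDuplicated(labels))
    stopf("duplicate condition labels: %s",
          paste(unique(labels[duplicated(labels)]), collapse = ", "))
  n <- config$n_trials_per_condition
  n_total <- n * (length(conditions) + 1L)
  trial_seeds <- with_rng_seed(seed,
                               sample.int(.Machine$integer.max, n_total))
  stacks <- vector("list", n_total)
  k <- 0L
  for (ci in seq_along(conditions)) {
    for (i in seq_len(n)) {
      k <- k + 1L
      stacks[[k]] <- generate_trial(
        config, conditions[[ci]], trial_seeds[k],
        trial_id = sprintf("%s_trial%02d", labels[ci], i),
        replicate = replicate)
    }
  }
  for (i in seq_len(n)) {
    k <- k + 1L
    stacks[[k]] <- generate_trial(
      config, blank_stimulus(), trial_seeds[k],
      trial_id = sprintf("blank_trial%02d", i), replicate = replicate)
  }

  truth_cond <- list()
  for (ci in seq_along(conditions)) {
    stim <- conditions[[ci]]
    lab <- labels[ci]
    if (!is_blank(stim) && lab %in% names(config$blobs)) {
      b <- config$blobs[[lab]]
      gain <- amplitude_gain(config, stim)
      mask <- gaussian_blob(config$height_px, config$width_px,
                            b$center, b$sigma_px) >= 0.5
      if (gain <= 0 || b$peak_dFF <= 0)
        mask <- matrix(FALSE, config$height_px, config$width_px)
      amp <- rep(b$peak_dFF * gain, n)
      truth_cond[[lab]] <- list(center = b$center, sigma_px = b$sigma_px,
                                active_mask = mask, amplitude_per_trial = amp)
    } else {
      truth_cond[[lab]] <- list(
        center = NULL, sigma_px = NULL,
        active_mask = matrix(FALSE, config$height_px, config$width_px),
        amplitude_per_trial = rep(0, n))
    }
  }
  truth <- structure(list(conditions = truth_cond, seed = seed,
                          replicate = replicate),
                     class = "synthetic_truth")
  list(stacks = stacks, truth = truth)
}

#' Generate a synthetic pairwise alignment with planted structure
#'
#' Emits a gap-free aligned pair whose per-column match probability equals
#' `background_identity` outside planted blocks and the block identity
#' inside them. Consensus motif instances (default the T-box site
#' `TCACACCT`) are written into the reference with exactly the requested
#' number of substitutions.
#'
#' @param length_bp alignment length.
#' @param background_identity per-column match probability outside blocks.
#' @param planted_blocks list of `list(start, width, identity)` blocks
#'   (1-based, non-overlapping, within bounds).
#' @param planted_motifs list of `list(position, n_mismatch)` motif
#'   plantings on the reference.
#' @param seed integer seed.
#' @param motif consensus motif planted by `planted_motifs`.
#' @return A list with `pair` (an [alignment_pair()]) and `truth`
#'   (planted blocks and realized motif instances).
#' @export
generate_alignment <- function(length_bp, background_identity,
                               planted_blocks = list(),
                               planted_motifs = list(), seed,
                               motif = "TCACACCT") {
  if (!is_count(length_bp)) stopf("`length_bp` must be a positive integer")
  if (!is_scalar_num(background_identity) || background_identity < 0 ||
      background_identity > 1)
    stopf("`background_identity` must be in [0, 1]")
  blocks <- lapply(planted_blocks, function(b) {
    b <- as.list(b)
    names(b) <- c("start", "width", "identity")[seq_along(b)]
    b
  })
  if (length(blocks)) {
    ord <- order(vapply(blocks, `[[`, numeric(1), "start"))
    blocks <- blocks[ord]
    last_end <- 0
    for (b in blocks) {
      if (b$start < 1 || b$start + b$width - 1 > length_bp)
        stopf("planted block (%d, %d) out of bounds", b$start, b$width)
      if (b$start <= last_end)
        stopf("planted blocks overlap")
      last_end <- b$start + b$width - 1
    }
  }
  bases <- c("A", "C", "G", "T")
  mot <- strsplit(toupper(motif), "")[[1L]]
  m <- length(mot)

  with_rng_seed(seed, {
    ref <- sample(bases, length_bp, replace = TRUE)
    motif_truth <- list()
    for (pm in planted_motifs) {
      pm <- as.list(pm)
      names(pm) <- c("position", "n_mismatch")[seq_along(pm)]
      if (pm$position < 1 || pm$position + m - 1 > length_bp)
        stopf("planted motif at %d out of bounds", pm$position)
      inst <- mot
      if (pm$n_mismatch > 0) {
        at <- sample.int(m, pm$n_mismatch)
        for (j in at) inst[j] <- sample(setdiff(bases, inst[j]), 1L)
      }
      ref[pm$position:(pm$position + m - 1L)] <- inst
      motif_truth[[length(motif_truth) + 1L]] <-
        list(position = pm$position, n_mismatch = pm$n_mismatch,
             instance = paste(inst, collapse = ""))
    }
    p_match <- rep(background_identity, length_bp)
    for (b in blocks)
      p_match[b$start:(b$start + b$width - 1L)] <- b$identity
    match <- runif(length_bp) < p_match
    partner <- ref
    idx <- which(!match)
    if (length(idx)) {
      # substitute a uniformly drawn different base at mismatch columns
      shift <- sample.int(3L, length(idx), replace = TRUE)
      base_i <- match(ref[idx], bases)
      partner[idx] <- bases[((base_i - 1L + shift) %% 4L) + 1L]
    }
    pair <- alignment_pair(paste(ref, collapse = ""),
                           paste(partner, collapse = ""),
                           name = "synthetic")
    list(pair = pair,
         truth = list(blocks = blocks, motifs = motif_truth, seed = seed))
  })
}
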