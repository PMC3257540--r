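#' Stimulus descriptions
#'
#' A `stimulus_spec` describes the stimulus delivered on one trial: focal
#' electrical microstimulation of an olfactory bulb glomerulus, an odourant
#' applied to the nostril, or a blank (pure air / no stimulus) trial. Blank
#' trials serve both as the photobleaching reference and as the comparison
#' group of the pixel-wise t-test.
#'
#' Electrical defaults follow the standard glomerular microstimulation
#' protocol (100 uA, 60 Hz, 5 pulses of 0.2 ms).
#'
#' @param current_uA stimulation current in microamperes.
#' @param frequency_hz pulse-train frequency in Hz.
#' @param n_pulses number of pulses in the train.
#' @param pulse_width_ms single-pulse width in milliseconds.
#' @param label condition label; derived from the parameters when `NULL`.
#'
#' @return A `stimulus_spec` object with fields `kind`
#'   (`"electrical"`, `"odourant"` or `"blank"`), the kind-specific
#'   parameters, and a `label` used to group trials into conditions.
#' @examples
#' electrical_stimulus(n_pulses = 10)
#' odourant_stimulus("TMT", dilution = 0.10)
#' blank_stimulus()
#' @export
electrical_stimulus <- function(current_uA = 100, frequency_hz = 60,
                                n_pulses = 5, pulse_width_ms = 0.2,
                                label = NULL) {
  for (v in c(current_uA, frequency_hz, n_pulses, pulse_width_ms))
    if (!is_scalar_num(v) || v <= 0)
      stopf("electrical stimulus parameters must be positive scalars")
  if (is.null(label))
    label <- sprintf("elec_%gp_%guA", n_pulses, current_uA)
  structure(list(kind = "electrical", current_uA = current_uA,
                 frequency_hz = frequency_hz, n_pulses = n_pulses,
                 pulse_width_ms = pulse_width_ms, label = label),
            class = "stimulus_spec")
}

#' @param name odourant name (for example `"TMT"` or `"HA"`).
#' @param dilution volumetric dilution in mineral oil (0.10 = 10%).
#' @rdname electrical_stimulus
#' @export
odourant_stimulus <- function(name, dilution = 0.10, label = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stopf("`name` must be a non-empty string")
  if (!is_scalar_num(dilution) || dilution <= 0)
    stopf("`dilution` must be a positive scalar")
  if (is.null(label)) label <- name
  structure(list(kind = "odourant", name = name, dilution = dilution,
                 label = label),
            class = "stimulus_spec")
}

#' @rdname electrical_stimulus
#' @export
blank_stimulus <- function() {
  structure(list(kind = "blank", label = "blank"), class = "stimulus_spec")
}

#' @param x object to test or print.
#' @rdname electrical_stimulus
#' @export
is_blank <- function(x) inherits(x, "stimulus_spec") && x$kind == "blank"

#' @export
print.stimulus_spec <- function(x, ...) {
  desc <- switch(x$kind,
    electrical = sprintf("electrical %g uA, %g Hz, %g pulses of %g ms",
                         x$current_uA, x$frequency_hz, x$n_pulses,
                         x$pulse_width_ms),
    odourant = sprintf("odourant %s at %g%% dilution", x$name,
                       100 * x$dilution),
    blank = "blank (no stimulus)")
  cat(sprintf("<stimulus_spec> %s [%s]\n", desc, x$label))
  invisible(x)
}

# scalar stimulus strength on the pulse-equivalent scale used by the
# synthetic amplitude gain; blank trials have strength 0
stimulus_strength <- function(stimulus, ref_current = 100,
                              ref_dilution = 0.10, ref_strength = 5) {
  if (!inherits(stimulus, "stimulus_spec"))
    stopf("`stimulus` must be a stimulus_spec")
  switch(stimulus$kind,
    blank = 0,
    electrical = stimulus$n_pulses * (stimulus$current_uA / ref_current),
    odourant = ref_strength * (stimulus$dilution / ref_dilution))
}
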