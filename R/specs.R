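#' Recording-condition specification
#'
#' Captures how an experimental condition (healthy control vs DSS-colitis-like
#' inflammation) modifies neural activity in the generator: the rate and
#' amplitude of spontaneous transients, per-stimulus scaling of evoked
#' amplitudes, and the white-noise level of the DFF traces.
#'
#' @param name Condition label, `"control"` or `"dss"`.
#' @param spont_rate Spontaneous transient rate, events/min per neuron (>= 0).
#' @param spont_amplitude_mean Mean spontaneous transient amplitude, %DFF.
#' @param evoked_amplitude_scale Named numeric map stimulus -> multiplicative
#'   scale applied to the kernel's `amplitude_mean` (all > 0).
#' @param noise_sd SD of additive Gaussian noise, %DFF (>= 0).
#' @return An object of class `condition_spec`.
#' @seealso [control_condition()], [dss_condition()]
#' @export
condition_spec <- function(name, spont_rate, spont_amplitude_mean,
                           evoked_amplitude_scale, noise_sd) {
  if (!is.character(name) || !nzchar(name))
    stopf("'name' must be a nonempty label")
  if (spont_rate < 0) stopf("spont_rate must be >= 0")
  if (spont_amplitude_mean <= 0) stopf("spont_amplitude_mean must be > 0")
  if (is.null(names(evoked_amplitude_scale)) ||
      any(!nzchar(names(evoked_amplitude_scale))))
    stopf("evoked_amplitude_scale must be a named numeric vector")
  if (any(evoked_amplitude_scale <= 0))
    stopf("all evoked amplitude scales must be > 0")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  structure(
    list(name = name, spont_rate = spont_rate,
         spont_amplitude_mean = spont_amplitude_mean,
         evoked_amplitude_scale = evoked_amplitude_scale,
         noise_sd = noise_sd),
    class = "condition_spec")
}

#' @export
print.condition_spec <- function(x, ...) {
  cat(sprintf(
    "<condition_spec> %s: spont %.2f/min at %.2f %%DFF, noise sd %.2f %%DFF\n",
    x$name, x$spont_rate, x$spont_amplitude_mean, x$noise_sd))
  cat("  evoked scales:",
      paste(sprintf("%s=%.3f", names(x$evoked_amplitude_scale),
                    x$evoked_amplitude_scale), collapse = ", "), "\n")
  invisible(x)
}

#' Default healthy-control condition
#'
#' Spontaneous amplitude 42.66 %DFF (printed control baseline mean); evoked
#' scales all 1. The spontaneous rate (0.2 events/min) and noise SD
#' (2 %DFF) are generator defaults.
#'
#' @param ... Overrides passed to [condition_spec()] fields.
#' @return A `condition_spec`.
#' @export
control_condition <- function(...) {
  args <- list(name = "control", spont_rate = 0.2,
               spont_amplitude_mean = 42.66,
               evoked_amplitude_scale = c("IL-1b" = 1, "TNF" = 1, "IL-10" = 1),
               noise_sd = 2)
  over <- list(...)
  args[names(over)] <- over
  do.call(condition_spec, args)
}

#' Default DSS-colitis-like condition
#'
#' Encodes the inflammation phenotype: more spontaneously active neurons
#' (rate tripled), reduced spontaneous amplitude (29.08 vs 42.66 %DFF),
#' and cytokine-specific reduction of evoked amplitudes
#' (TNF 44.27/56.62, IL-10 55.59/95.70, IL-1b unchanged), with noise SD
#' raised 1.5x relative to control.
#'
#' @param ... Overrides passed to [condition_spec()] fields.
#' @return A `condition_spec`.
#' @export
dss_condition <- function(...) {
  args <- list(name = "dss", spont_rate = 0.6,
               spont_amplitude_mean = 29.08,
               evoked_amplitude_scale = c("IL-1b" = 1,
                                          "TNF" = 44.27 / 56.62,
                                          "IL-10" = 55.59 / 95.70),
               noise_sd = 3)
  over <- list(...)
  args[names(over)] <- over
  do.call(condition_spec, args)
}

#' Build a stimulus event log
#'
#' @param time_s Application times in seconds (>= 0, strictly increasing).
#' @param stimulus Stimulus labels.
#' @param concentration_ng_per_ml Concentrations in ng/mL.
#' @return A data.frame with columns `time_s`, `stimulus`,
#'   `concentration_ng_per_ml`.
#' @export
stimulus_events <- function(time_s, stimulus, concentration_ng_per_ml) {
  if (length(time_s)) {
    if (any(time_s < 0)) stopf("event times must be >= 0")
    if (any(diff(time_s) <= 0)) stopf("event times must be strictly increasing")
    if (any(!nzchar(stimulus))) stopf("stimulus labels must be nonempty")
  }
  data.frame(time_s = as.numeric(time_s), stimulus = as.character(stimulus),
             concentration_ng_per_ml = as.numeric(concentration_ng_per_ml),
             stringsAsFactors = FALSE)
}

#' Default two-cytokine application schedule
#'
#' Sequential IL-1b (200 ng/mL) and TNF (50 ng/mL) applications, the design
#' under which the four responder subpopulations were defined.
#' @return Event data.frame (see [stimulus_events()]).
#' @export
two_cytokine_events <- function() {
  stimulus_events(c(150, 450), c("IL-1b", "TNF"), c(200, 50))
}

#' Default three-cytokine application schedule
#'
#' IL-1b (200 ng/mL), TNF (50 ng/mL) and IL-10 (50 ng/mL), the design behind
#' the cluster-separability comparison.
#' @return Event data.frame (see [stimulus_events()]).
#' @export
three_cytokine_events <- function() {
  stimulus_events(c(150, 450, 750), c("IL-1b", "TNF", "IL-10"), c(200, 50, 50))
}

#' Synthetic population specification
#'
#' Defines a simulated imaging session: how many neurons, their responder-class
#' mix, the recording grid, and the stimulus schedule. Default class
#' proportions follow the printed responder breakdown from the two-cytokine
#' experiments (TNF 40.7%, multi-cytokine 28.6%, IL-1b 17.1%, non-cytokine
#' 13.6%); the default sampling rate is 20 Hz.
#'
#' @param n_neurons Number of neurons.
#' @param class_proportions Named fractions over the responder classes
#'   (see [responder_classes()]); must sum to 1. Realised class counts use
#'   largest-remainder apportionment with ties broken by class order.
#' @param sampling_rate Frames per second (> 0).
#' @param duration Recording length, seconds.
#' @param event_schedule Data.frame from [stimulus_events()]; all event times
#'   must lie in `[0, duration)`.
#' @param seed Integer RNG seed: simulation is fully deterministic given the
#'   spec.
#' @param latency_max Maximum latency of an evoked transient after its event,
#'   seconds. Defaults to 100 s, matching the response-assignment window so
#'   ground truth is recoverable by the 100-s rule.
#' @param n_animals Number of animals the neurons are attributed to
#'   (round-robin), for per-animal summaries.
#' @param active_noncytokine If TRUE (default), each non-cytokine neuron is
#'   guaranteed one spontaneous transient placed outside all assignment
#'   windows, emulating the activity-based selection of the imaging pipeline
#'   (only active neurons yield ROIs).
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_neurons = 100,
                            class_proportions = c(il1b_specific = 0.171,
                                                  tnf_specific = 0.407,
                                                  il10_responsive = 0,
                                                  multi_cytokine = 0.286,
                                                  non_cytokine = 0.136),
                            sampling_rate = 20,
                            duration = 700,
                            event_schedule = two_cytokine_events(),
                            seed = 1L,
                            latency_max = 100,
                            n_animals = 10,
                            active_noncytokine = TRUE) {
  if (n_neurons < 1) stopf("n_neurons must be >= 1")
  if (sampling_rate <= 0) stopf("sampling_rate must be > 0")
  if (duration <= 0) stopf("duration must be > 0")
  if (latency_max <= 0) stopf("latency_max must be > 0")
  if (is.null(names(class_proportions)) ||
      !all(names(class_proportions) %in% .classes))
    stopf("class_proportions must be named with responder class labels")
  if (any(class_proportions < 0) || abs(sum(class_proportions) - 1) > 1e-8)
    stopf("class proportions must be nonnegative and sum to 1")
  if (nrow(event_schedule)) {
    if (any(event_schedule$time_s < 0) ||
        any(event_schedule$time_s >= duration))
      stopf("event times must lie within [0, duration)")
    if (any(diff(event_schedule$time_s) <= 0))
      stopf("event times must be strictly increasing")
  }
  structure(
    list(n_neurons = as.integer(n_neurons),
         class_proportions = class_proportions,
         sampling_rate = sampling_rate, duration = duration,
         event_schedule = event_schedule, seed = as.integer(seed),
         latency_max = latency_max, n_animals = as.integer(n_animals),
         active_noncytokine = isTRUE(active_noncytokine)),
    class = "population_spec")
}

#' Three-cytokine population specification
#'
#' Convenience wrapper for simulated sessions in which all three cytokines
#' are applied; the class mix adds an IL-10-responsive subpopulation.
#'
#' @param n_neurons Number of neurons.
#' @param seed RNG seed.
#' @param ... Further overrides passed to [population_spec()].
#' @return A `population_spec`.
#' @export
three_cytokine_population <- function(n_neurons = 120, seed = 1L, ...) {
  population_spec(
    n_neurons = n_neurons,
    class_proportions = c(il1b_specific = 0.15, tnf_specific = 0.25,
                          il10_responsive = 0.20, multi_cytokine = 0.25,
                          non_cytokine = 0.15),
    duration = 1000,
    event_schedule = three_cytokine_events(),
    seed = seed, ...)
}

# Stimuli a responder class reacts to, restricted to the scheduled stimuli
class_stimuli <- function(class, scheduled) {
  stim <- switch(class,
                 il1b_specific = "IL-1b",
                 tnf_specific = "TNF",
                 il10_responsive = "IL-10",
                 multi_cytokine = .cytokines,
                 non_cytokine = character(0),
                 saline_responder = "saline",
                 character(0))
  intersect(stim, scheduled)
}
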