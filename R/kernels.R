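#' Stereotyped response kernel specification
#'
#' Describes the shape of the calcium transient a stimulus evokes: a product of
#' exponentials \eqn{g(t) = (1 - e^{-t/\tau_r})\, e^{-t/\tau_d}} rescaled to a
#' target peak amplitude, with optional delayed sub-peaks. Each cytokine gets
#' its own kernel, which is what makes responses separable in feature space.
#'
#' @param stimulus Stimulus label (e.g. `"TNF"`).
#' @param amplitude_mean Mean peak amplitude, %DFF. Must be > 0.
#' @param amplitude_sd Between-transient SD of the peak amplitude, %DFF.
#' @param rise_tau Rise time constant, seconds (> 0).
#' @param decay_tau Decay time constant, seconds (> `rise_tau`).
#' @param duration_mean Nominal response support, seconds; also sets the
#'   spacing of sub-peaks in multi-peak transients (`duration_mean / 4`).
#' @param n_peaks_weights Probability vector over 1, 2 or 3 peaks.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(stimulus, amplitude_mean, amplitude_sd, rise_tau,
                        decay_tau, duration_mean,
                        n_peaks_weights = c(1, 0, 0)) {
  if (!is.character(stimulus) || !nzchar(stimulus))
    stopf("'stimulus' must be a nonempty label")
  if (amplitude_mean <= 0) stopf("amplitude_mean must be > 0")
  if (amplitude_sd < 0) stopf("amplitude_sd must be >= 0")
  if (rise_tau <= 0) stopf("rise_tau must be > 0")
  if (decay_tau <= rise_tau) stopf("decay_tau must exceed rise_tau")
  if (duration_mean <= 0) stopf("duration_mean must be > 0")
  if (length(n_peaks_weights) != 3L || any(n_peaks_weights < 0) ||
      abs(sum(n_peaks_weights) - 1) > 1e-8)
    stopf("n_peaks_weights must be 3 nonnegative values summing to 1")
  structure(
    list(stimulus = stimulus, amplitude_mean = amplitude_mean,
         amplitude_sd = amplitude_sd, rise_tau = rise_tau,
         decay_tau = decay_tau, duration_mean = duration_mean,
         n_peaks_weights = n_peaks_weights),
    class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf(
    "<kernel_spec> %s: amplitude %.2f +/- %.2f %%DFF, rise %.1f s, decay %.1f s, support %.0f s\n",
    x$stimulus, x$amplitude_mean, x$amplitude_sd, x$rise_tau, x$decay_tau,
    x$duration_mean))
  invisible(x)
}

#' Default cytokine response kernels
#'
#' Mean amplitudes follow the printed control-condition group means for each
#' cytokine (IL-1b 22.9, TNF 56.62, IL-10 95.70 %DFF); shape parameters
#' (rise/decay time constants, support, peak-count weights) are generator
#' defaults chosen to give each cytokine a distinct stereotyped time course.
#' The `"spontaneous"` kernel is used for baseline (non-evoked) transients;
#' its amplitude is overridden by the [condition_spec()] in use.
#'
#' @return Named list of [kernel_spec()] objects
#'   (`IL-1b`, `TNF`, `IL-10`, `spontaneous`).
#' @export
default_kernels <- function() {
  list(
    "IL-1b" = kernel_spec("IL-1b", 22.9, 4.5, rise_tau = 2, decay_tau = 10,
                          duration_mean = 40, n_peaks_weights = c(0.7, 0.2, 0.1)),
    "TNF" = kernel_spec("TNF", 56.62, 9, rise_tau = 4, decay_tau = 18,
                        duration_mean = 60, n_peaks_weights = c(0.6, 0.3, 0.1)),
    "IL-10" = kernel_spec("IL-10", 95.70, 14, rise_tau = 3, decay_tau = 28,
                          duration_mean = 80, n_peaks_weights = c(0.7, 0.25, 0.05)),
    "spontaneous" = kernel_spec("spontaneous", 42.66, 8.5, rise_tau = 1.5,
                                decay_tau = 8, duration_mean = 25,
                                n_peaks_weights = c(0.85, 0.12, 0.03)))
}

# Kernel evaluated at arbitrary nonnegative offsets from onset (no grid
# assumptions); sub-peaks are delayed copies with geometrically decaying
# amplitude, and the whole segment is rescaled so its maximum equals
# `amplitude` exactly.
kernel_values <- function(spec, amplitude, rel_t, n_peaks = 1L) {
  g <- function(t) {
    v <- numeric(length(t))
    pos <- t >= 0
    v[pos] <- (1 - exp(-t[pos] / spec$rise_tau)) * exp(-t[pos] / spec$decay_tau)
    v
  }
  gap <- spec$duration_mean / 4
  v <- numeric(length(rel_t))
  for (j in seq_len(n_peaks) - 1L) v <- v + 0.6^j * g(rel_t - j * gap)
  m <- max(v)
  if (m > 0 && amplitude > 0) {
    v <- v * (amplitude / m)
    v[which.max(v)] <- amplitude   # exact, not just within rounding
    v
  } else v * 0
}

#' Render a response kernel on a time grid
#'
#' Evaluates the transient shape model on a uniform grid starting at the
#' transient onset and rescales it so the sampled maximum equals `amplitude`.
#'
#' @param spec A [kernel_spec()].
#' @param amplitude Peak amplitude in %DFF (>= 0; 0 yields an all-zero
#'   segment).
#' @param t Uniform time grid in seconds starting at 0 (the onset).
#' @param n_peaks Number of sub-peaks to superpose (1-3).
#' @return Numeric vector of DFF values, same length as `t`; nonnegative,
#'   with `max(.) == amplitude`.
#' @examples
#' t <- seq(0, 30, by = 0.05)
#' seg <- render_kernel(default_kernels()$TNF, amplitude = 50, t = t)
#' max(seg)  # exactly 50
#' @export
render_kernel <- function(spec, amplitude, t, n_peaks = 1L) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (!is.numeric(amplitude) || length(amplitude) != 1L || amplitude < 0)
    stopf("'amplitude' must be a single nonnegative number")
  if (!is_uniform_grid(t)) stopf("'t' must be a strictly increasing uniform grid")
  if (abs(t[1L]) > 1e-9) stopf("'t' must start at the transient onset (t[1] == 0)")
  if (!(n_peaks %in% 1:3)) stopf("'n_peaks' must be 1, 2 or 3")
  kernel_values(spec, amplitude, t, as.integer(n_peaks))
}
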