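# Local maxima of y with their prominences. A plateau counts once, at its
# first sample (deterministic tie-break). Prominence follows the usual
# topographic definition: height minus the higher of the two valley minima
# separating the peak from the nearest strictly higher terrain (or the signal
# edge).
find_peaks <- function(y) {
  r <- rle(y)
  K <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  v <- r$values
  prev_lower <- c(TRUE, v[-K] < v[-1L])
  next_lower <- c(v[-1L] < v[-K], TRUE)
  idx <- starts[prev_lower & next_lower]
  if (!length(idx))
    return(data.frame(index = integer(0), height = numeric(0),
                      prominence = numeric(0)))
  height <- y[idx]
  prom <- peak_prominences_cpp(as.numeric(y), idx)
  data.frame(index = idx, height = height, prominence = prom)
}

# Shared feature computation given onset/offset sample indices
features_from_indices <- function(trace, i_on, i_off, peak_prominence_frac,
                                  censored = FALSE) {
  y <- trace$dff
  t <- trace$time
  seg <- y[i_on:i_off]
  i_peak_rel <- which.max(seg)          # first maximum: plateau tie-break
  i_peak <- i_on + i_peak_rel - 1L
  amplitude <- seg[i_peak_rel]
  if (amplitude <= 0)
    stopf("segment has nonpositive amplitude for neuron '%s'", trace$neuron_id)
  if (i_peak == i_on)
    stopf("peak at onset: rise slope undefined for neuron '%s'",
          trace$neuron_id)
  if (i_peak == i_off && !censored)
    stopf("peak at offset: decay slope undefined for neuron '%s'",
          trace$neuron_id)

  peaks <- find_peaks(seg)
  n_peaks <- sum(peaks$prominence >= peak_prominence_frac * amplitude)
  n_peaks <- max(1L, as.integer(n_peaks))   # the global maximum always counts

  decay <- if (i_peak == i_off) NA_real_ else
    (y[i_off] - amplitude) / (t[i_off] - t[i_peak])
  data.frame(
    neuron_id = trace$neuron_id,
    t_onset = t[i_on], t_peak = t[i_peak], t_offset = t[i_off],
    amplitude = amplitude,
    duration = t[i_off] - t[i_on],
    rise_slope = (amplitude - y[i_on]) / (t[i_peak] - t[i_on]),
    decay_slope = decay,
    integral = max(0, trapz(t[i_on:i_off], seg)),
    n_peaks = n_peaks,
    censored = censored,
    stringsAsFactors = FALSE)
}

#' Extract the six response features from a trace segment
#'
#' Given a transient's onset and offset (on the trace's grid), computes
#' amplitude (maximum DFF in the segment; first sample of a plateau is the
#' peak), duration (`t_offset - t_onset`), rise slope
#' (`(amplitude - dff(t_onset)) / (t_peak - t_onset)`), decay slope
#' (`(dff(t_offset) - amplitude) / (t_offset - t_peak)`), trapezoidal
#' integral over the segment, and the number of peaks (local maxima with
#' prominence at least `peak_prominence_frac` of the amplitude; the global
#' maximum always counts). All features are computed on the raw, unsmoothed
#' trace. Amplitude, slopes and integral scale linearly with the DFF signal;
#' duration and peak count do not.
#'
#' @param trace A [dff_trace()].
#' @param t_onset,t_offset Segment boundaries in seconds; must coincide with
#'   grid samples and satisfy `t_onset < t_offset`.
#' @param peak_prominence_frac Prominence threshold as a fraction of the
#'   amplitude.
#' @return One-row data.frame as in [detect_transients()].
#' @examples
#' # triangle: 0 -> 60 %DFF over 2 s, back to 0 over 4 s, at 20 Hz
#' t <- seq(0, 6, by = 0.05)
#' y <- ifelse(t <= 2, 30 * t, 60 - 15 * (t - 2))
#' extract_features(dff_trace("n1", t, y), 0, 6)
#' @export
extract_features <- function(trace, t_onset, t_offset,
                             peak_prominence_frac = 0.2) {
  stopifnot(inherits(trace, "dff_trace"))
  if (t_onset >= t_offset) stopf("t_onset must precede t_offset")
  dt <- trace$time[2L] - trace$time[1L]
  to_index <- function(tt, what) {
    i <- round((tt - trace$time[1L]) / dt) + 1
    if (i < 1 || i > length(trace$time) ||
        abs(trace$time[i] - tt) > 1e-6 * max(1, abs(tt)))
      stopf("%s = %g is not on the trace grid of neuron '%s'", what, tt,
            trace$neuron_id)
    as.integer(i)
  }
  features_from_indices(trace, to_index(t_onset, "t_onset"),
                        to_index(t_offset, "t_offset"), peak_prominence_frac)
}
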