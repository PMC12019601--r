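#' Transient detection parameters
#'
#' Thresholds for event detection in DFF traces. Detection runs on a smoothed
#' copy of the trace; feature extraction uses the raw trace. None of these
#' thresholds are prescribed by the underlying experimental analysis, so all
#' are exposed here with robust defaults.
#'
#' @param noise_sd_estimator `"mad"` (1.4826 x median absolute deviation of
#'   the full trace; robust to sparse transients) or `"low_activity"` (SD of
#'   samples within 3 MAD of the median).
#' @param onset_k Onset threshold in multiples of the noise SD.
#' @param offset_frac Offset threshold as a fraction of the transient's peak
#'   (< 1); the transient ends when the smoothed trace falls below both this
#'   and the onset threshold.
#' @param min_duration Minimum transient duration in seconds; shorter
#'   excursions are discarded.
#' @param smoothing_window Moving-average window in samples (detection only).
#' @param peak_k Minimum smoothed peak height in multiples of the noise SD:
#'   a segment is kept only when its smoothed maximum reaches
#'   `max(peak_k * noise_sd, abs_floor)`. Screens out the brief
#'   threshold-flicker segments that noise produces on the slowly decaying
#'   tail of a real transient.
#' @param peak_prominence_frac Minimum peak prominence, as a fraction of the
#'   transient amplitude, for a local maximum to count in `n_peaks`.
#' @param abs_floor Absolute onset floor in %DFF; the onset threshold is
#'   `max(onset_k * noise_sd, abs_floor)`.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(noise_sd_estimator = c("mad", "low_activity"),
                             onset_k = 3, offset_frac = 0.2,
                             min_duration = 0.5, smoothing_window = 5,
                             peak_k = 5, peak_prominence_frac = 0.2,
                             abs_floor = 5) {
  noise_sd_estimator <- match.arg(noise_sd_estimator)
  if (onset_k <= 0 || offset_frac <= 0 || min_duration <= 0 ||
      smoothing_window <= 0 || peak_prominence_frac <= 0 || abs_floor <= 0 ||
      peak_k <= 0)
    stopf("all detection parameters must be positive")
  if (offset_frac >= 1) stopf("offset_frac must be < 1")
  structure(list(noise_sd_estimator = noise_sd_estimator, onset_k = onset_k,
                 offset_frac = offset_frac, min_duration = min_duration,
                 smoothing_window = as.integer(smoothing_window),
                 peak_k = peak_k,
                 peak_prominence_frac = peak_prominence_frac,
                 abs_floor = abs_floor),
            class = "detection_params")
}

estimate_noise_sd <- function(y, estimator = "mad") {
  m <- stats::mad(y)
  if (estimator == "mad") return(m)
  if (m == 0) return(0)
  low <- y[abs(y - stats::median(y)) < 3 * m]
  if (length(low) < 2L) m else stats::sd(low)
}

empty_transients <- function() {
  data.frame(neuron_id = character(0), t_onset = numeric(0),
             t_peak = numeric(0), t_offset = numeric(0),
             amplitude = numeric(0), duration = numeric(0),
             rise_slope = numeric(0), decay_slope = numeric(0),
             integral = numeric(0), n_peaks = integer(0),
             censored = logical(0), stringsAsFactors = FALSE)
}

#' Detect calcium transients in a DFF trace
#'
#' Detection runs on a moving-average smoothed copy of the trace. A transient
#' starts at the first sample where the smoothed DFF exceeds
#' `max(onset_k * noise_sd, abs_floor)` and ends at the first later sample
#' where it has fallen below both that threshold and `offset_frac` times the
#' transient's (smoothed) running maximum -- so a trace that re-rises before
#' decaying fully stays one transient, and detected transients are disjoint
#' and time-ordered. Excursions shorter than `min_duration` are discarded.
#' Transients truncated by the end of the recording are kept with
#' `censored = TRUE` (their duration, decay slope and integral are lower
#' bounds and are excluded from feature statistics by default downstream).
#' Features are computed on the unsmoothed trace via [extract_features()].
#'
#' @param trace A [dff_trace()].
#' @param params A [detection_params()].
#' @return Data.frame with one row per transient: `neuron_id`, `t_onset`,
#'   `t_peak`, `t_offset`, `amplitude`, `duration`, `rise_slope`,
#'   `decay_slope`, `integral`, `n_peaks`, `censored`. Attributes `noise_sd`
#'   and `threshold` record the detection state.
#' @export
detect_transients <- function(trace, params = detection_params()) {
  stopifnot(inherits(trace, "dff_trace"))
  y <- trace$dff
  t <- trace$time
  n <- length(y)
  if (n < params$smoothing_window)
    stopf("trace '%s' is shorter than the smoothing window", trace$neuron_id)

  s <- moving_average(y, params$smoothing_window)
  sigma <- estimate_noise_sd(y, params$noise_sd_estimator)
  thr <- max(params$onset_k * sigma, params$abs_floor)

  above <- s > thr
  starts <- which(above & !c(FALSE, above[-n]))   # rising edges, computed once
  out <- list()
  cursor <- 1L
  si <- 1L
  repeat {
    while (si <= length(starts) && starts[si] < cursor) si <- si + 1L
    if (si > length(starts)) break
    i_on <- starts[si]
    # scan forward in chunks for the offset: first j with
    # s[j] < min(offset_frac * runmax, thr)
    i_off <- NA_integer_
    censored <- FALSE
    runmax <- s[i_on]
    j0 <- i_on + 1L
    while (is.na(i_off)) {
      if (j0 > n) { i_off <- n; censored <- TRUE; break }
      j1 <- min(n, j0 + 1999L)
      seg <- s[j0:j1]
      cm <- cummax(seg)
      cm[cm < runmax] <- runmax
      hit <- which(seg < pmin(params$offset_frac * cm, thr))
      if (length(hit)) {
        i_off <- j0 + hit[1L] - 1L
        runmax <- max(runmax, cm[hit[1L]])   # peak up to the offset only
      } else runmax <- max(runmax, cm[length(cm)])
      j0 <- j1 + 1L
      if (j1 == n && is.na(i_off)) { i_off <- n; censored <- TRUE }
    }
    cursor <- i_off + 1L
    peak_ok <- runmax >= max(params$peak_k * sigma, params$abs_floor)
    if (peak_ok && t[i_off] - t[i_on] >= params$min_duration) {
      row <- tryCatch(
        features_from_indices(trace, i_on, i_off,
                              params$peak_prominence_frac, censored),
        error = function(e) NULL)
      if (!is.null(row)) out[[length(out) + 1L]] <- row
    }
    if (cursor > n) break
  }
  res <- if (length(out)) do.call(rbind, out) else empty_transients()
  rownames(res) <- NULL
  attr(res, "noise_sd") <- sigma
  attr(res, "threshold") <- thr
  res
}

#' Detect transients across a dataset
#'
#' Applies [detect_transients()] to every trace and binds the per-transient
#' feature rows, annotated with the animal and ground-truth class when the
#' input is a simulated `ca_dataset`.
#'
#' @param x A `ca_dataset` or a list of [dff_trace()] objects.
#' @param params A [detection_params()].
#' @return Combined transient feature data.frame.
#' @export
detect_all <- function(x, params = detection_params()) {
  traces <- if (inherits(x, "ca_dataset")) x$traces else x
  res <- do.call(rbind, lapply(traces, detect_transients, params = params))
  if (is.null(res)) res <- empty_transients()
  rownames(res) <- NULL
  if (inherits(x, "ca_dataset")) {
    map <- x$truth$neurons
    res$animal_id <- map$animal_id[match(res$neuron_id, map$neuron_id)]
  }
  res
}
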