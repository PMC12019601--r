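#' Construct a DFF trace
#'
#' One neuron's DFF time series (\% units) on a uniform time grid.
#'
#' @param neuron_id Neuron label.
#' @param time Time in seconds, strictly increasing uniform grid (length >= 2).
#' @param dff DFF values in percent; must be finite.
#' @return An object of class `dff_trace` (list with `neuron_id`, `time`,
#'   `dff`).
#' @export
dff_trace <- function(neuron_id, time, dff) {
  if (length(time) != length(dff)) stopf("time and dff lengths differ")
  if (length(time) < 2L) stopf("a trace needs at least 2 samples")
  if (!is_uniform_grid(time))
    stopf("time grid for neuron '%s' is not strictly increasing and uniform",
          neuron_id)
  if (!all(is.finite(dff)))
    stopf("non-finite DFF values for neuron '%s'", neuron_id)
  structure(list(neuron_id = as.character(neuron_id),
                 time = as.numeric(time), dff = as.numeric(dff)),
            class = "dff_trace")
}

#' @export
print.dff_trace <- function(x, ...) {
  cat(sprintf("<dff_trace> %s: %d samples @ %.3g Hz, range [%.2f, %.2f] %%DFF\n",
              x$neuron_id, length(x$time), 1 / diff(x$time[1:2]),
              min(x$dff), max(x$dff)))
  invisible(x)
}

sampling_rate_of <- function(trace) 1 / (trace$time[2L] - trace$time[1L])

# Add a rendered kernel to a trace vector starting at continuous time `onset`;
# returns the modified vector. Support is 1.5x the kernel's nominal duration.
add_kernel_at <- function(y, t, spec, amplitude, onset, n_peaks, fs) {
  support <- 1.5 * spec$duration_mean
  i0 <- findInterval(onset, t) + 1L        # first sample with t >= onset
  if (i0 > length(y)) return(y)
  i1 <- min(length(y), i0 + as.integer(round(support * fs)))
  rel <- t[i0:i1] - onset
  y[i0:i1] <- y[i0:i1] + kernel_values(spec, amplitude, rel, n_peaks)
  y
}

#' Simulate a population of DFF traces with known ground truth
#'
#' Generates per-neuron DFF traces under a [population_spec()] and a
#' [condition_spec()]. Each neuron belongs to a responder class (realised
#' counts follow largest-remainder apportionment of the class proportions);
#' for every scheduled stimulus its class responds to, the neuron emits one
#' evoked transient with onset uniform in `(event_time, event_time +
#' latency_max]` and amplitude drawn from the kernel's distribution scaled by
#' the condition. Spontaneous transients arrive as a Poisson process at the
#' condition's rate; white Gaussian noise is added last. The full generation
#' is deterministic given `pop$seed`.
#'
#' @param pop A [population_spec()].
#' @param cond A [condition_spec()].
#' @param kernels Named list of [kernel_spec()] objects covering every
#'   scheduled stimulus, plus a `"spontaneous"` kernel.
#' @return An object of class `ca_dataset`: list with `traces` (list of
#'   [dff_trace()]), `events` (data.frame), `truth` (list with `neurons` --
#'   neuron_id, animal_id, class -- and `transients` -- one row per
#'   ground-truth transient with kind, event_index, stimulus, onset,
#'   amplitude, n_peaks), `condition`, and `population`.
#' @examples
#' pop <- population_spec(n_neurons = 10, duration = 400,
#'                        event_schedule = stimulus_events(100, "TNF", 50))
#' ds <- simulate_population(pop, control_condition())
#' ds
#' @export
simulate_population <- function(pop, cond, kernels = default_kernels()) {
  stopifnot(inherits(pop, "population_spec"), inherits(cond, "condition_spec"))
  events <- pop$event_schedule
  scheduled <- unique(events$stimulus)
  missing_k <- setdiff(scheduled, names(kernels))
  if (length(missing_k))
    stopf("no kernel_spec for scheduled stimulus: %s",
          paste(missing_k, collapse = ", "))
  if (is.null(kernels$spontaneous))
    stopf("kernels must include a 'spontaneous' entry")

  fs <- pop$sampling_rate
  n_samp <- as.integer(round(pop$duration * fs))
  t <- (seq_len(n_samp) - 1L) / fs

  counts <- largest_remainder(pop$n_neurons, pop$class_proportions)
  classes <- rep(names(counts), counts)

  # spontaneous kernel with condition-specific amplitude distribution
  spont <- kernels$spontaneous
  spont_mean <- cond$spont_amplitude_mean
  spont_sd <- 0.2 * spont_mean

  # intervals a "guaranteed" non-cytokine transient must avoid: anything that
  # could be assigned to an event ((t_k, t_k + latency_max]) or span t_k
  spont_support <- 1.5 * spont$duration_mean
  forbidden <- if (nrow(events)) {
    cbind(events$time_s - spont_support - 1, events$time_s + pop$latency_max + 1)
  } else matrix(numeric(0), ncol = 2)

  with_seed(pop$seed, {
    traces <- vector("list", pop$n_neurons)
    truth_rows <- vector("list", pop$n_neurons)
    neuron_ids <- sprintf("n%04d", seq_len(pop$n_neurons))
    animal_ids <- paste0("m", ((seq_len(pop$n_neurons) - 1L) %% pop$n_animals) + 1L)

    for (i in seq_len(pop$n_neurons)) {
      cls <- classes[i]
      y <- numeric(n_samp)
      rows <- list()

      # evoked transients
      respond_to <- class_stimuli(cls, scheduled)
      if (nrow(events)) {
        for (k in seq_len(nrow(events))) {
          stim <- events$stimulus[k]
          if (!(stim %in% respond_to)) next
          ks <- kernels[[stim]]
          scale <- unname(cond$evoked_amplitude_scale[stim])
          if (is.na(scale)) scale <- 1
          onset <- events$time_s[k] + stats::runif(1, 0, pop$latency_max)
          amp <- truncnorm_pos(1, ks$amplitude_mean * scale,
                               ks$amplitude_sd * scale)
          npk <- sample.int(3L, 1L, prob = ks$n_peaks_weights)
          y <- add_kernel_at(y, t, ks, amp, onset, npk, fs)
          rows[[length(rows) + 1L]] <- data.frame(
            neuron_id = neuron_ids[i], kind = "evoked", event_index = k,
            stimulus = stim, onset = onset, amplitude = amp, n_peaks = npk,
            stringsAsFactors = FALSE)
        }
      }

      # Poisson spontaneous transients
      m <- stats::rpois(1, cond$spont_rate * pop$duration / 60)
      if (m > 0) {
        onsets <- stats::runif(m, 0, max(pop$duration - 5, 1))
        amps <- truncnorm_pos(m, spont_mean, spont_sd)
        npks <- sample.int(3L, m, replace = TRUE, prob = spont$n_peaks_weights)
        for (j in seq_len(m)) {
          y <- add_kernel_at(y, t, spont, amps[j], onsets[j], npks[j], fs)
          rows[[length(rows) + 1L]] <- data.frame(
            neuron_id = neuron_ids[i], kind = "spontaneous",
            event_index = NA_integer_, stimulus = "spontaneous",
            onset = onsets[j], amplitude = amps[j], n_peaks = npks[j],
            stringsAsFactors = FALSE)
        }
      }

      # activity-conditioning of the non-cytokine class: one transient placed
      # outside every assignment window (see vignette)
      if (cls == "non_cytokine" && pop$active_noncytokine) {
        onset <- NA_real_
        hi <- max(pop$duration - spont_support - 1, 1)
        for (try in 1:200) {
          cand <- stats::runif(1, 0, hi)
          ok <- !nrow(forbidden) ||
            all(cand < forbidden[, 1] | cand > forbidden[, 2])
          if (ok) { onset <- cand; break }
        }
        if (is.na(onset)) onset <- 1   # deterministic fallback
        amp <- truncnorm_pos(1, spont_mean, spont_sd)
        npk <- sample.int(3L, 1L, prob = spont$n_peaks_weights)
        y <- add_kernel_at(y, t, spont, amp, onset, npk, fs)
        rows[[length(rows) + 1L]] <- data.frame(
          neuron_id = neuron_ids[i], kind = "spontaneous",
          event_index = NA_integer_, stimulus = "spontaneous",
          onset = onset, amplitude = amp, n_peaks = npk,
          stringsAsFactors = FALSE)
      }

      if (cond$noise_sd > 0) y <- y + stats::rnorm(n_samp, 0, cond$noise_sd)
      traces[[i]] <- dff_trace(neuron_ids[i], t, y)
      truth_rows[[i]] <- if (length(rows)) do.call(rbind, rows) else NULL
    }

    transients <- do.call(rbind, truth_rows[!vapply(truth_rows, is.null, TRUE)])
    if (is.null(transients))
      transients <- data.frame(neuron_id = character(0), kind = character(0),
                               event_index = integer(0), stimulus = character(0),
                               onset = numeric(0), amplitude = numeric(0),
                               n_peaks = integer(0), stringsAsFactors = FALSE)
    rownames(transients) <- NULL

    structure(
      list(traces = traces, events = events,
           truth = list(
             neurons = data.frame(neuron_id = neuron_ids,
                                  animal_id = animal_ids,
                                  class = classes, stringsAsFactors = FALSE),
             transients = transients),
           condition = cond, population = pop),
      class = "ca_dataset")
  })
}

#' @export
print.ca_dataset <- function(x, ...) {
  cat(sprintf("<ca_dataset> %d neurons, %.0f s @ %.3g Hz, condition '%s'\n",
              length(x$traces), x$population$duration,
              x$population$sampling_rate, x$condition$name))
  if (nrow(x$events))
    cat("  events:", paste(sprintf("%s@%gs", x$events$stimulus,
                                   x$events$time_s), collapse = ", "), "\n")
  tab <- table(x$truth$neurons$class)
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  cat(sprintf("  ground-truth transients: %d\n", nrow(x$truth$transients)))
  invisible(x)
}

#' Score transient detection against ground truth
#'
#' Greedy one-to-one matching in time order: a detected transient matches a
#' ground-truth transient of the same neuron when its onset falls within
#' `[truth_onset - tol_pre, truth_onset + tol_post]` (detection onsets lag the
#' true onset by the rise to threshold, hence the asymmetric window).
#'
#' @param truth Ground-truth transient table (from a `ca_dataset`'s
#'   `truth$transients`).
#' @param detected Detected transient table (from [detect_transients()]).
#' @param tol_pre,tol_post Matching tolerances, seconds.
#' @return List with `recall`, `precision`, `n_truth`, `n_detected`,
#'   `n_matched`.
#' @export
detection_performance <- function(truth, detected, tol_pre = 2, tol_post = 15) {
  n_truth <- nrow(truth)
  n_det <- nrow(detected)
  n_matched <- 0L
  for (id in unique(truth$neuron_id)) {
    tr <- sort(truth$onset[truth$neuron_id == id])
    de <- sort(detected$t_onset[detected$neuron_id == id])
    used <- logical(length(de))
    for (o in tr) {
      j <- which(!used & de >= o - tol_pre & de <= o + tol_post)
      if (length(j)) { used[j[1L]] <- TRUE; n_matched <- n_matched + 1L }
    }
  }
  list(recall = if (n_truth) n_matched / n_truth else NA_real_,
       precision = if (n_det) n_matched / n_det else NA_real_,
       n_truth = n_truth, n_detected = n_det, n_matched = n_matched)
}
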