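#' Response-assignment parameters
#'
#' @param window_s Response window after each application, seconds. A
#'   transient is a candidate response to event k when its onset lies in
#'   `(t_k, t_k + window_s]` (half-open at the event, inclusive at the far
#'   boundary).
#' @param exclude_if_active_at_event If TRUE (default), an event gets no
#'   response from a neuron whose earlier transient is still ongoing at the
#'   application time (onset <= t_k < offset).
#' @param exclude_saline_responders If TRUE, saline responders are dropped
#'   from responder proportions.
#' @param baseline_window_s Baseline window for spontaneous-activity counts,
#'   seconds from recording start.
#' @param min_traces_per_animal Minimum per-animal transient count before a
#'   per-animal mean is considered well-supported (under-min animals are
#'   flagged, not dropped).
#' @return An object of class `assignment_params`.
#' @export
assignment_params <- function(window_s = 100, exclude_if_active_at_event = TRUE,
                              exclude_saline_responders = FALSE,
                              baseline_window_s = 50,
                              min_traces_per_animal = 10) {
  if (window_s <= 0) stopf("window_s must be > 0")
  if (baseline_window_s <= 0) stopf("baseline_window_s must be > 0")
  structure(list(window_s = window_s,
                 exclude_if_active_at_event = isTRUE(exclude_if_active_at_event),
                 exclude_saline_responders = isTRUE(exclude_saline_responders),
                 baseline_window_s = baseline_window_s,
                 min_traces_per_animal = min_traces_per_animal),
            class = "assignment_params")
}

#' Assign detected transients to stimulus applications
#'
#' For each neuron and each event (in time order), the earliest unassigned
#' transient with onset in `(t_k, t_k + window_s]` becomes the response to
#' event k -- one response per trace per event, and each transient can answer
#' at most one event (the earlier event wins when windows overlap). With
#' `exclude_if_active_at_event`, an event whose application time falls inside
#' an ongoing transient gets no response from that neuron.
#'
#' @param transients Transient feature table (one or more neurons), as from
#'   [detect_transients()]/[detect_all()].
#' @param events Event data.frame (see [stimulus_events()]).
#' @param params An [assignment_params()].
#' @return The transient rows that are responses, with added columns
#'   `event_index`, `stimulus`, and `latency_s` (onset minus application
#'   time).
#' @export
assign_responses <- function(transients, events, params = assignment_params()) {
  out <- list()
  if (nrow(transients) && nrow(events)) {
    ord_ev <- order(events$time_s)
    for (id in unique(transients$neuron_id)) {
      tr <- transients[transients$neuron_id == id, , drop = FALSE]
      tr <- tr[order(tr$t_onset), , drop = FALSE]
      assigned <- logical(nrow(tr))
      for (k in ord_ev) {
        tk <- events$time_s[k]
        if (params$exclude_if_active_at_event &&
            any(tr$t_onset <= tk & tr$t_offset > tk)) next
        cand <- which(!assigned & tr$t_onset > tk &
                        tr$t_onset <= tk + params$window_s)
        if (!length(cand)) next
        j <- cand[1L]
        assigned[j] <- TRUE
        row <- tr[j, , drop = FALSE]
        row$event_index <- k
        row$stimulus <- events$stimulus[k]
        row$latency_s <- row$t_onset - tk
        out[[length(out) + 1L]] <- row
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    cbind(empty_transients(),
          data.frame(event_index = integer(0), stimulus = character(0),
                     latency_s = numeric(0), stringsAsFactors = FALSE))
  rownames(res) <- NULL
  res
}

#' Classify neurons into responder subpopulations
#'
#' A neuron's label follows the set S of cytokines it responded to:
#' S = (IL-1b) -> `il1b_specific`; S = (TNF) -> `tnf_specific`;
#' S = (IL-10) -> `il10_responsive`; |S| >= 2 -> `multi_cytokine`;
#' S empty with at least one transient -> `non_cytokine` (or
#' `saline_responder` when the only responses were to saline). Neurons with
#' no transients at all get `NA` and are excluded from proportions, mirroring
#' the activity-based selection of the imaging pipeline.
#'
#' @param transients Transient feature table.
#' @param events Event data.frame.
#' @param params An [assignment_params()].
#' @param neuron_ids Optional character vector of all neurons in the
#'   recording (so zero-transient neurons appear with `NA` class); defaults
#'   to the neurons present in `transients`.
#' @return Data.frame `neuron_id`, `class`, `n_transients`, `n_responses`,
#'   with the response table in attribute `"responses"`.
#' @export
classify_neurons <- function(transients, events, params = assignment_params(),
                             neuron_ids = NULL) {
  responses <- assign_responses(transients, events, params)
  if (is.null(neuron_ids)) neuron_ids <- unique(transients$neuron_id)
  res <- data.frame(neuron_id = neuron_ids, class = NA_character_,
                    n_transients = 0L, n_responses = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(res))) {
    id <- res$neuron_id[i]
    nt <- sum(transients$neuron_id == id)
    resp <- responses[responses$neuron_id == id, , drop = FALSE]
    res$n_transients[i] <- nt
    res$n_responses[i] <- nrow(resp)
    if (nt == 0L) next
    s <- setdiff(unique(resp$stimulus), "saline")
    res$class[i] <-
      if (length(s) >= 2L) "multi_cytokine"
      else if (length(s) == 1L) switch(s, "IL-1b" = "il1b_specific",
                                       "TNF" = "tnf_specific",
                                       "IL-10" = "il10_responsive",
                                       "non_cytokine")
      else if ("saline" %in% resp$stimulus) "saline_responder"
      else "non_cytokine"
  }
  attr(res, "responses") <- responses
  res
}

#' Responder-class proportions
#'
#' Fractions of each responder class over the classified (transient-bearing)
#' neurons; zero-transient neurons (`NA` class) are excluded from the
#' denominator.
#'
#' @param classification Output of [classify_neurons()], or a character
#'   vector of class labels (possibly with `NA`).
#' @param exclude_saline If TRUE, saline responders are removed before
#'   computing fractions.
#' @return Named numeric vector over [responder_classes()] (saline omitted
#'   unless present), summing to 1.
#' @export
responder_proportions <- function(classification, exclude_saline = FALSE) {
  cls <- if (is.data.frame(classification)) classification$class
         else as.character(classification)
  cls <- cls[!is.na(cls)]
  if (exclude_saline) cls <- cls[cls != "saline_responder"]
  if (!length(cls)) stopf("no classified neurons: cannot compute proportions")
  lev <- .classes[.classes %in% c(setdiff(.classes, "saline_responder"), cls)]
  tab <- table(factor(cls, levels = lev))
  tab / sum(tab)
}

#' Onset-aligned mean response trace
#'
#' Re-times each response segment so its onset is t = 0 and averages
#' pointwise over responses on `[-pre_s, post_s]`, the way stereotyped
#' cytokine responses are summarised across experiments. Segments shorter
#' than the window contribute missing values that are excluded pointwise.
#'
#' @param traces List of [dff_trace()] objects (all sharing one sampling
#'   rate), or a `ca_dataset`.
#' @param onsets Data.frame with columns `neuron_id` and `t_onset` (e.g. the
#'   output of [assign_responses()]).
#' @param pre_s,post_s Window before/after onset, seconds.
#' @return Data.frame `time`, `mean`, `sem`, `n` on the aligned grid.
#' @export
aligned_mean_trace <- function(traces, onsets, pre_s = 10, post_s = 60) {
  if (inherits(traces, "ca_dataset")) traces <- traces$traces
  if (!nrow(onsets)) stopf("at least one response is required")
  fs <- vapply(traces, sampling_rate_of, numeric(1))
  if (max(abs(fs - fs[1L])) > 1e-6 * fs[1L])
    stopf("traces have mixed sampling rates")
  fs <- fs[1L]
  by_id <- stats::setNames(traces, vapply(traces, `[[`, "", "neuron_id"))
  rel <- seq(-round(pre_s * fs), round(post_s * fs)) / fs
  mat <- matrix(NA_real_, nrow = length(rel), ncol = nrow(onsets))
  for (j in seq_len(nrow(onsets))) {
    tr <- by_id[[onsets$neuron_id[j]]]
    if (is.null(tr)) stopf("no trace for neuron '%s'", onsets$neuron_id[j])
    i_on <- round((onsets$t_onset[j] - tr$time[1L]) * fs) + 1
    idx <- i_on + round(rel * fs)
    ok <- idx >= 1 & idx <= length(tr$dff)
    mat[ok, j] <- tr$dff[idx[ok]]
  }
  n <- rowSums(!is.na(mat))
  mu <- rowMeans(mat, na.rm = TRUE)
  mu[n == 0L] <- NA_real_
  sem <- apply(mat, 1L, function(r) {
    r <- r[!is.na(r)]
    if (length(r) >= 2L) stats::sd(r) / sqrt(length(r)) else NA_real_
  })
  data.frame(time = rel, mean = mu, sem = sem, n = n)
}

#' Per-animal feature summary
#'
#' Averages a transient feature within each animal, the unit on which group
#' statistics operate (per-mouse n). Animals contributing fewer than
#' `min_traces` transients are flagged, not dropped.
#'
#' @param features Transient/response table with an `animal_id` column.
#' @param feature Feature column name (e.g. `"amplitude"`).
#' @param min_traces Minimum transients per animal.
#' @param drop_censored Exclude censored transients first (default TRUE).
#' @return Data.frame `animal_id`, `mean`, `n`, `flagged`.
#' @export
per_animal_summary <- function(features, feature = "amplitude",
                               min_traces = 10, drop_censored = TRUE) {
  if (!("animal_id" %in% names(features)))
    stopf("features must have an 'animal_id' column")
  if (!(feature %in% names(features)))
    stopf("no feature column '%s'", feature)
  if (drop_censored && "censored" %in% names(features))
    features <- features[!features$censored, , drop = FALSE]
  ids <- sort(unique(features$animal_id))
  out <- data.frame(animal_id = ids, mean = NA_real_, n = 0L,
                    flagged = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    v <- features[[feature]][features$animal_id == ids[i]]
    v <- v[!is.na(v)]
    out$mean[i] <- mean(v)
    out$n[i] <- length(v)
    out$flagged[i] <- length(v) < min_traces
  }
  out
}

#' Count spontaneously active neurons at baseline
#'
#' Number of neurons with at least one transient onset in
#' `[0, baseline_window_s)`, the per-recording baseline-activity measure that
#' rises under colitis-like conditions.
#'
#' @param transients Transient feature table for one recording.
#' @param baseline_window_s Baseline window length, seconds.
#' @param events Optional event data.frame; if any application occurs before
#'   the window closes the count is refused.
#' @return Integer count.
#' @export
count_active_baseline <- function(transients, baseline_window_s = 50,
                                  events = NULL) {
  if (!is.null(events) && nrow(events) &&
      min(events$time_s) < baseline_window_s)
    stopf("baseline window [0, %g) overlaps an event at %g s",
          baseline_window_s, min(events$time_s))
  sel <- transients$t_onset >= 0 & transients$t_onset < baseline_window_s
  length(unique(transients$neuron_id[sel]))
}
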