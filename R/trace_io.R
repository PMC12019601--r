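#' Compute DFF from a raw fluorescence series
#'
#' DFF = 100 * (F - F0) / F0, in percent. The baseline F0 is either the q-th
#' percentile of the whole series (default q = 10, quantile convention with
#' linear interpolation at index (n-1)q) or the mean over a designated
#' pre-event window.
#'
#' @param f Raw fluorescence values (finite).
#' @param time Time grid in seconds (uniform, strictly increasing).
#' @param neuron_id Neuron label (used in error messages and the result).
#' @param baseline_method `"percentile"` or `"pre_event_mean"`.
#' @param q Percentile (0-100) for the percentile baseline.
#' @param pre_event_window Numeric `c(start, end)` in seconds for the
#'   pre-event-mean baseline.
#' @return A [dff_trace()].
#' @examples
#' compute_dff(c(10, 10, 10, 20), time = (0:3) / 20, neuron_id = "n1")$dff
#' @export
compute_dff <- function(f, time, neuron_id = "neuron",
                        baseline_method = c("percentile", "pre_event_mean"),
                        q = 10, pre_event_window = NULL) {
  baseline_method <- match.arg(baseline_method)
  if (!all(is.finite(f)))
    stopf("non-finite fluorescence values for neuron '%s'", neuron_id)
  f0 <- switch(baseline_method,
    percentile = stats::quantile(f, q / 100, names = FALSE, type = 7),
    pre_event_mean = {
      if (is.null(pre_event_window) || length(pre_event_window) != 2L)
        stopf("pre_event_window must be c(start, end) in seconds")
      sel <- time >= pre_event_window[1L] & time < pre_event_window[2L]
      if (!any(sel)) stopf("pre_event_window contains no samples")
      mean(f[sel])
    })
  if (f0 <= 0)
    stopf("baseline F0 = %g is not positive for neuron '%s'", f0, neuron_id)
  dff_trace(neuron_id, time, 100 * (f - f0) / f0)
}

#' Write DFF traces to a long-format CSV
#'
#' Columns `neuron_id`, `time_s`, `dff`; values are written with full
#' (round-trip) precision so write -> read is lossless.
#'
#' @param traces List of [dff_trace()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  dt <- data.table::rbindlist(lapply(traces, function(tr) {
    data.table::data.table(neuron_id = tr$neuron_id, time_s = tr$time,
                           dff = tr$dff)
  }))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read DFF traces from a long-format CSV
#'
#' @param path CSV path with columns `neuron_id`, `time_s`, `dff`.
#' @return List of [dff_trace()] objects (order of first appearance). An
#'   empty file yields an empty list with a warning.
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stopf("trace file not found: %s", path)
  if (file.size(path) == 0L) {
    warnf("trace file '%s' is empty", path)
    return(list())
  }
  dt <- data.table::fread(path)
  if (nrow(dt) == 0L) {
    warnf("trace file '%s' has no rows", path)
    return(list())
  }
  need <- c("neuron_id", "time_s", "dff")
  if (!all(need %in% names(dt)))
    stopf("trace file must have columns %s", paste(need, collapse = ", "))
  dt$..row <- seq_len(nrow(dt)) + 1L   # file row numbers (header = row 1)
  ids <- unique(dt$neuron_id)
  lapply(ids, function(id) {
    sub <- dt[dt$neuron_id == id, ]
    dup <- duplicated(sub$time_s)
    if (any(dup))
      stopf("duplicate (neuron_id, time) for neuron '%s' at file row %d",
            id, sub$..row[which(dup)[1L]])
    if (!is_uniform_grid(sub$time_s))
      stopf("non-uniform time grid for neuron '%s' (first row %d)",
            id, sub$..row[1L])
    dff_trace(id, sub$time_s, sub$dff)
  })
}

#' Write a stimulus event log to CSV
#' @param events Event data.frame (see [stimulus_events()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  data.table::fwrite(data.table::as.data.table(events), path)
  invisible(path)
}

#' Read a stimulus event log from CSV
#' @param path CSV path with columns `time_s`, `stimulus`,
#'   `concentration_ng_per_ml`.
#' @return Event data.frame.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stopf("event file not found: %s", path)
  if (file.size(path) == 0L) {
    warnf("event file '%s' is empty", path)
    return(stimulus_events(numeric(0), character(0), numeric(0)))
  }
  dt <- as.data.frame(data.table::fread(path))
  if (nrow(dt) == 0L) {
    warnf("event file '%s' has no rows", path)
    return(stimulus_events(numeric(0), character(0), numeric(0)))
  }
  need <- c("time_s", "stimulus", "concentration_ng_per_ml")
  if (!all(need %in% names(dt)))
    stopf("event file must have columns %s", paste(need, collapse = ", "))
  bad <- which(dt$time_s < 0)
  if (length(bad))
    stopf("negative event time at file row %d", bad[1L] + 1L)
  bad <- which(!nzchar(dt$stimulus))
  if (length(bad))
    stopf("empty stimulus label at file row %d", bad[1L] + 1L)
  dt[need]
}

#' Write the ground-truth record of a simulated dataset to JSON
#' @param truth The `truth` element of a `ca_dataset`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a ground-truth record written by [write_truth()]
#' @param path JSON path.
#' @return List with `neurons` and `transients` data.frames.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(neurons = as.data.frame(x$neurons, stringsAsFactors = FALSE),
       transients = as.data.frame(x$transients, stringsAsFactors = FALSE))
}

#' Write a per-transient feature table to CSV
#' @param features Data.frame from [detect_transients()] (plus any added
#'   columns).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  data.table::fwrite(data.table::as.data.table(features), path)
  invisible(path)
}

#' Read a per-transient feature table written by [write_features()]
#' @param path CSV path.
#' @return Data.frame.
#' @export
read_features <- function(path) {
  as.data.frame(data.table::fread(path))
}

#' Write an arbitrary results list to JSON
#'
#' Numbers are written unrounded; scalars are unboxed.
#'
#' @param x List of results.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", force = TRUE)
  invisible(path)
}
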