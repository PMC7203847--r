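# Core containers: continuous recordings and event tables.

#' Construct a continuous EEG recording
#'
#' The central container of the pipeline: a channels-by-time matrix in
#' microvolts plus sampling rate, ordered channel labels, an event table and
#' an append-only provenance trail. Flagging operations never mutate a
#' recording; they return annotations (see [annotations()]).
#'
#' @param samples numeric matrix, channels x time, in microvolts.
#' @param sfreq sampling frequency in Hz (> 0).
#' @param labels character vector of unique channel labels, one per row.
#' @param events event table from [event_table()] (optional).
#' @param montage an `eeg_montage` (optional).
#' @param provenance character vector of applied-operation descriptors.
#' @return an object of class `eeg_recording`.
#' @export
new_recording <- function(samples, sfreq, labels, events = event_table(),
                          montage = NULL, provenance = character(0)) {
  samples <- as.matrix(samples)
  labels <- as.character(labels)
  if (nrow(samples) != length(labels))
    stopf("recording: %d sample rows but %d labels", nrow(samples), length(labels))
  if (anyDuplicated(labels)) stopf("recording: duplicate channel labels")
  if (!is.numeric(sfreq) || length(sfreq) != 1L || sfreq <= 0)
    stopf("recording: sfreq must be a positive scalar")
  validate_event_table(events, ncol(samples) / sfreq)
  rownames(samples) <- labels
  structure(
    list(samples = samples, sfreq = as.numeric(sfreq), labels = labels,
         events = events, montage = montage, provenance = provenance),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$samples), ncol(x$samples), x$sfreq,
              recording_duration(x), nrow(x$events)))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an `eeg_recording`.
#' @export
recording_duration <- function(rec) ncol(rec$samples) / rec$sfreq

n_channels <- function(rec) nrow(rec$samples)
n_samples <- function(rec) ncol(rec$samples)

# return a modified copy with a provenance entry appended
with_provenance <- function(rec, op) {
  rec$provenance <- c(rec$provenance, op)
  rec
}

has_provenance <- function(rec, op) any(startsWith(rec$provenance, op))

#' Construct an event table
#'
#' @param onset event onsets in seconds (>= 0, non-decreasing).
#' @param duration event durations in seconds (>= 0).
#' @param code event code strings.
#' @param hed optional hierarchical event descriptor (HED) strings.
#' @return a data.frame with class `event_table`.
#' @export
event_table <- function(onset = numeric(0), duration = numeric(0),
                        code = character(0), hed = NULL) {
  n <- length(onset)
  hed <- if (is.null(hed)) rep(NA_character_, n) else as.character(hed)
  ev <- data.frame(onset = as.numeric(onset), duration = as.numeric(duration),
                   code = as.character(code), hed = hed,
                   stringsAsFactors = FALSE)
  class(ev) <- c("event_table", "data.frame")
  ev
}

validate_event_table <- function(ev, duration_s = NULL) {
  if (!nrow(ev)) return(invisible(ev))
  if (any(ev$onset < 0) || any(ev$duration < 0))
    stopf("events: onsets and durations must be >= 0")
  if (is.unsorted(ev$onset)) stopf("events: onsets must be non-decreasing")
  if (!is.null(duration_s) && any(ev$onset + ev$duration > duration_s + 1e-9))
    stopf("events: event extends past the end of the recording")
  invisible(ev)
}

#' Translate event codes to HED strings
#'
#' Populates the `hed` column of an event table from a code-to-HED mapping,
#' leaving onsets, durations and codes untouched. Under the `"strict"` policy
#' every code present in the table must be mapped; under `"keep"` unmapped
#' rows pass through with `hed` unset.
#'
#' @param ev an [event_table()].
#' @param mapping named character vector (names = codes, values = HED strings).
#' @param policy `"keep"` (default) or `"strict"`.
#' @return the translated event table.
#' @export
translate_events <- function(ev, mapping = character(0), policy = c("keep", "strict")) {
  policy <- match.arg(policy)
  if (!nrow(ev)) return(ev)
  unmapped <- setdiff(unique(ev$code), names(mapping))
  if (policy == "strict" && length(unmapped))
    stopf("translate_events: unmapped codes under strict policy: %s",
          paste(sort(unmapped), collapse = ", "))
  hit <- ev$code %in% names(mapping)
  ev$hed[hit] <- unname(mapping[ev$code[hit]])
  ev
}
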