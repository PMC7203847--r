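# AnnotationSet: the pipeline's entire output. Purely additive; holds no
# signal data. Channel flags, labeled time intervals, IC flags, review state.

CHANNEL_FLAG_LABELS <- c("ch_s_sd", "ch_sd", "low_r", "bridge", "manual")
TIME_FLAG_LABELS <- c("ch_s_sd", "ch_sd", "low_r", "ic_sd1", "ic_sd2", "gap", "manual")
IC_FLAG_LABELS <- c("blink", "lateral_eye", "emg", "line", "heart",
                    "low_power", "nonstationary", "manual")

#' Construct an annotation set
#'
#' Holds every quality decision of the pipeline as pure metadata: per-channel
#' flag labels, labeled time intervals (half-open, seconds), per-component
#' flag labels, and a review state. Raw data is never touched.
#'
#' @param channel_flags named list mapping channel label to a character vector
#'   of flag labels (subset of `ch_s_sd, ch_sd, low_r, bridge, manual`).
#' @param time_flags data.frame with columns onset, duration, label
#'   (labels among `ch_s_sd, ch_sd, low_r, ic_sd1, ic_sd2, gap, manual`).
#' @param ic_flags named list mapping IC index (as character) to a character
#'   vector of reason labels.
#' @param review_state `"unreviewed"` (default) or `"reviewed"`.
#' @return an object of class `annotation_set`.
#' @export
annotations <- function(channel_flags = list(), time_flags = empty_intervals(),
                        ic_flags = list(), review_state = "unreviewed") {
  stopifnot(review_state %in% c("unreviewed", "reviewed"))
  bad <- setdiff(unlist(channel_flags, use.names = FALSE), CHANNEL_FLAG_LABELS)
  if (length(bad)) stopf("annotations: unknown channel flag label(s): %s",
                         paste(unique(bad), collapse = ", "))
  bad <- setdiff(time_flags$label, TIME_FLAG_LABELS)
  if (length(bad)) stopf("annotations: unknown time flag label(s): %s",
                         paste(unique(bad), collapse = ", "))
  bad <- setdiff(unlist(ic_flags, use.names = FALSE), IC_FLAG_LABELS)
  if (length(bad)) stopf("annotations: unknown IC flag label(s): %s",
                         paste(unique(bad), collapse = ", "))
  structure(list(channel_flags = channel_flags,
                 time_flags = time_flags,
                 ic_flags = ic_flags,
                 review_state = review_state),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d flagged channels, %d time flags, %d flagged ICs [%s]\n",
              length(x$channel_flags), nrow(x$time_flags), length(x$ic_flags),
              x$review_state))
  invisible(x)
}

# append flag labels; duplicates collapsed, order normalized
add_channel_flags <- function(ann, labels, flag) {
  for (lb in labels) {
    ann$channel_flags[[lb]] <- sort(unique(c(ann$channel_flags[[lb]], flag)))
  }
  ann
}

add_time_flags <- function(ann, iv) {
  if (nrow(iv)) ann$time_flags <- rbind(ann$time_flags, iv)
  ann
}

add_ic_flags <- function(ann, idx, flags) {
  key <- as.character(idx)
  ann$ic_flags[[key]] <- sort(unique(c(ann$ic_flags[[key]], flags)))
  ann
}

flagged_channels <- function(ann, labels = CHANNEL_FLAG_LABELS) {
  hit <- vapply(ann$channel_flags, function(f) any(f %in% labels), logical(1))
  names(ann$channel_flags)[hit]
}

time_flags_of <- function(ann, labels) {
  ann$time_flags[ann$time_flags$label %in% labels, , drop = FALSE]
}

flagged_ics <- function(ann) as.integer(names(ann$ic_flags))

# check an annotation set against a recording (flags refer to real channels,
# intervals lie inside the recording)
validate_annotations <- function(ann, rec) {
  missing <- setdiff(names(ann$channel_flags), rec$labels)
  if (length(missing))
    stopf("annotations: flagged channel(s) not in recording: %s",
          paste(missing, collapse = ", "))
  dur <- recording_duration(rec)
  tf <- ann$time_flags
  if (nrow(tf) && any(tf$onset < -1e-9 | tf$onset + tf$duration > dur + 1e-9))
    stopf("annotations: time flag outside recording [0, %g)", dur)
  invisible(ann)
}

#' Structural equality of two annotation sets
#'
#' Field-by-field comparison after canonical ordering (channels by label,
#' time flags by onset then label, ICs by index); used by the serialization
#' round-trip contract.
#'
#' @param a,b annotation sets.
#' @param tol numeric tolerance on onsets/durations (seconds).
#' @return TRUE/FALSE.
#' @export
annotations_equal <- function(a, b, tol = 1e-9) {
  canon_cf <- function(x) x$channel_flags[order(names(x$channel_flags))]
  canon_ic <- function(x) x$ic_flags[order(as.integer(names(x$ic_flags)))]
  canon_tf <- function(x) {
    tf <- x$time_flags
    tf[order(tf$onset, tf$label, tf$duration), , drop = FALSE]
  }
  if (!identical(canon_cf(a), canon_cf(b))) return(FALSE)
  if (!identical(canon_ic(a), canon_ic(b))) return(FALSE)
  ta <- canon_tf(a); tb <- canon_tf(b)
  if (nrow(ta) != nrow(tb)) return(FALSE)
  if (nrow(ta)) {
    if (!identical(ta$label, tb$label)) return(FALSE)
    if (max(abs(ta$onset - tb$onset), abs(ta$duration - tb$duration)) > tol)
      return(FALSE)
  }
  identical(a$review_state, b$review_state)
}

#' Mark an annotation set as reviewed
#' @param ann an annotation set.
#' @export
mark_reviewed <- function(ann) { ann$review_state <- "reviewed"; ann }
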