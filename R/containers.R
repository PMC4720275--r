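#' Epoched EEG container
#'
#' A light container for trials x channels x time voltage data (microvolts)
#' with a millisecond time axis relative to stimulus onset and one stimulus
#' label per trial.  The canonical epoch window is the half-open interval
#' \[-50, 350) ms at 1000 Hz: 400 samples, time axis -50..349, with t = 0 the
#' first poststimulus sample.
#'
#' @param data numeric array, trials x channels x time
#' @param time_ms integer/numeric time axis, one entry per time sample
#' @param channels character channel labels, one per channel
#' @param labels data.frame with columns `frequency_hz`, `modality`, one row
#'   per trial
#' @param montage optional montage data.frame (`label,x,y,z`)
#' @param bad_channels,rejected_trials optional bookkeeping carried along by
#'   the preprocessing chain
#' @return object of class `eeg_epochs`
#' @export
eeg_epochs <- function(data, time_ms, channels, labels, montage = NULL,
                       bad_channels = character(0),
                       rejected_trials = integer(0)) {
  stopifnot(length(dim(data)) == 3,
            dim(data)[2] == length(channels),
            dim(data)[3] == length(time_ms),
            dim(data)[1] == nrow(labels),
            !anyDuplicated(channels))
  structure(list(data = data, time_ms = as.numeric(time_ms),
                 channels = as.character(channels), labels = labels,
                 montage = montage, bad_channels = bad_channels,
                 rejected_trials = rejected_trials),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d trials x %d channels x %d samples (%g..%g ms)\n",
              d[1], d[2], d[3], min(x$time_ms), max(x$time_ms)))
  tab <- table(.type_key(x$labels$frequency_hz, x$labels$modality))
  cat(sprintf("  %d condition(s); trials per condition: %s\n",
              length(tab), paste(range(tab), collapse = "-")))
  invisible(x)
}

#' @export
dim.eeg_epochs <- function(x) dim(x$data)

#' Number of trials in an epoch set
#' @param ep an `eeg_epochs`
#' @return integer
#' @export
n_trials <- function(ep) dim(ep$data)[1]

#' Subset epochs by trial index
#' @param ep an `eeg_epochs`
#' @param idx trial indices (logical or integer)
#' @return an `eeg_epochs`
#' @export
subset_trials <- function(ep, idx) {
  eeg_epochs(ep$data[idx, , , drop = FALSE], ep$time_ms, ep$channels,
             ep$labels[idx, , drop = FALSE], montage = ep$montage,
             bad_channels = ep$bad_channels)
}

#' Continuous EEG recording container
#'
#' @param data numeric matrix, channels x samples, microvolts; sample s is
#'   at time (s - 1) / fs_hz seconds from recording start
#' @param fs_hz sampling frequency, Hz
#' @param channels character channel labels (unique)
#' @param events data.frame with columns `onset_ms`, `frequency_hz`,
#'   `modality`
#' @param montage optional montage data.frame
#' @return object of class `eeg_recording`
#' @export
eeg_recording <- function(data, fs_hz, channels, events, montage = NULL) {
  stopifnot(is.matrix(data), fs_hz > 0, nrow(data) == length(channels),
            !anyDuplicated(channels))
  structure(list(data = data, fs_hz = fs_hz,
                 channels = as.character(channels), events = events,
                 montage = montage),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$data), ncol(x$data), x$fs_hz,
              if (is.null(x$events)) 0L else nrow(x$events)))
  invisible(x)
}
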