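#' Zero-phase Butterworth filters used by the pipeline
#'
#' `bandstop_45_55()` applies an order-2 Butterworth band-stop (notch)
#' eliminating the 45--55 Hz interval that contains power-line artifacts;
#' `lowpass_30()` applies an order-2 Butterworth low-pass at 30 Hz.  Both
#' run forward-backward (`signal::filtfilt`) so the net phase is zero and
#' component latencies are preserved; the effective magnitude response is
#' the square of the single-pass response.
#'
#' @param x an `eeg_recording`, an `eeg_epochs`, a channels x samples
#'   matrix, or a numeric vector
#' @param fs_hz sampling frequency (taken from the object when available)
#' @return the same type as `x`, filtered along time.
#' @export
bandstop_45_55 <- function(x, fs_hz = 1000) {
  flt <- signal::butter(2, c(45, 55) / (fs_hz / 2), type = "stop")
  .apply_filter(x, flt, fs_hz, settle_samples = ceiling(3 * fs_hz / 45))
}

#' @rdname bandstop_45_55
#' @export
lowpass_30 <- function(x, fs_hz = 1000) {
  flt <- signal::butter(2, 30 / (fs_hz / 2), type = "low")
  .apply_filter(x, flt, fs_hz, settle_samples = ceiling(3 * fs_hz / 30))
}

# forward-backward filtering with odd-reflection padding and steady-state
# initial history, so edge transients die inside the pad and a constant
# signal passes through a unit-DC-gain filter exactly
.filtfilt_padded <- function(flt, v, padlen) {
  n <- length(v)
  p <- min(padlen, n - 1)
  ext <- c(2 * v[1] - v[(p + 1):2], v, 2 * v[n] - v[(n - 1):(n - p)])
  nord <- length(flt$a) - 1
  dc <- sum(flt$b) / sum(flt$a)
  run <- function(x) as.numeric(signal::filter(
    flt$b, flt$a, x,
    init.x = rep(x[1], nord), init.y = rep(x[1] * dc, nord)))
  y <- rev(run(rev(run(ext))))
  y[(p + 1):(p + n)]
}

.apply_filter <- function(x, flt, fs_hz, settle_samples) {
  filt1 <- function(v) {
    if (length(v) < settle_samples)
      stop("signal too short for stable zero-phase filtering (need >= ",
           settle_samples, " samples, got ", length(v), ")")
    .filtfilt_padded(flt, v, settle_samples)
  }
  if (inherits(x, "eeg_recording")) {
    x$data <- t(apply(x$data, 1, filt1))
    return(x)
  }
  if (inherits(x, "eeg_epochs")) {
    d <- x$data
    for (i in seq_len(dim(d)[1]))
      for (j in seq_len(dim(d)[2]))
        d[i, j, ] <- filt1(d[i, j, ])
    x$data <- d
    return(x)
  }
  if (is.matrix(x)) return(t(apply(x, 1, filt1)))
  filt1(x)
}

#' Extract stimulus-locked epochs from a continuous recording
#'
#' Cuts one epoch per event over the half-open window \[-50, 350) ms
#' relative to stimulus onset (400 samples at 1000 Hz; the sample at t = 0
#' is the first poststimulus sample).  Events whose window would cross the
#' recording bounds are dropped with a warning.
#'
#' @param rec an `eeg_recording` (fs 1000 Hz) with an `events` table
#' @param pre_ms,post_ms window bounds (defaults 50 and 350)
#' @return an `eeg_epochs`; attribute `n_dropped` counts dropped events.
#' @export
extract_epochs <- function(rec, pre_ms = 50, post_ms = 350) {
  stopifnot(inherits(rec, "eeg_recording"), !is.null(rec$events))
  fs <- rec$fs_hz
  rel <- seq.int(-pre_ms * fs / 1000, post_ms * fs / 1000 - 1)
  onset_idx <- round(rec$events$onset_ms * fs / 1000) + 1L
  lo <- onset_idx + rel[1]
  hi <- onset_idx + rel[length(rel)]
  ok <- lo >= 1 & hi <= ncol(rec$data)
  if (any(!ok))
    warning(sum(!ok), " event(s) dropped: epoch window outside recording")
  onset_idx <- onset_idx[ok]
  data <- array(0, dim = c(length(onset_idx), nrow(rec$data), length(rel)))
  for (i in seq_along(onset_idx))
    data[i, , ] <- rec$data[, onset_idx[i] + rel]
  ep <- eeg_epochs(data, time_ms = rel * 1000 / fs, channels = rec$channels,
                   labels = rec$events[ok, c("frequency_hz", "modality"),
                                       drop = FALSE],
                   montage = rec$montage)
  attr(ep, "n_dropped") <- sum(!ok)
  ep
}

#' Screen epochs for amplitude artifacts
#'
#' Flags every (trial, channel) whose absolute voltage exceeds
#' `threshold_uV` anywhere in the epoch.  A channel flagged in more than
#' `bad_channel_fraction` of trials is declared globally bad (to be
#' interpolated); a trial is marked for rejection if any *non-bad* channel
#' is flagged in it.
#'
#' @param ep an `eeg_epochs`
#' @param threshold_uV rejection threshold, microvolts (default 100)
#' @param bad_channel_fraction fraction of flagged trials above which a
#'   channel is globally bad (default 0.2)
#' @return list of class `artifact_report`: `flags` (trials x channels
#'   logical), `bad_channels`, `rejected_trials`,
#'   `interpolated_fraction` (bad channels / all channels), `threshold_uV`.
#' @export
detect_artifacts <- function(ep, threshold_uV = 100,
                             bad_channel_fraction = 0.2) {
  stopifnot(inherits(ep, "eeg_epochs"))
  peak <- apply(abs(ep$data), c(1, 2), max)
  flags <- peak > threshold_uV
  bad <- colMeans(flags) > bad_channel_fraction
  rejected <- which(rowSums(flags[, !bad, drop = FALSE]) > 0)
  structure(list(flags = flags,
                 bad_channels = ep$channels[bad],
                 rejected_trials = rejected,
                 interpolated_fraction = mean(bad),
                 threshold_uV = threshold_uV),
            class = "artifact_report")
}

#' @export
print.artifact_report <- function(x, ...) {
  cat(sprintf(paste0("<artifact_report> threshold +/-%g uV: %d flagged ",
                     "(trial,channel) pairs, %d bad channel(s) [%.1f%%], ",
                     "%d rejected trial(s)\n"),
              x$threshold_uV, sum(x$flags), length(x$bad_channels),
              100 * x$interpolated_fraction, length(x$rejected_trials)))
  invisible(x)
}

#' Spherical-spline interpolation of bad channels
#'
#' Replaces the listed channels by Perrin-style spherical-spline estimates
#' (stiffness m = 4, 50 Legendre terms, regularization 1e-5) computed from
#' the remaining channels on their unit-sphere montage positions.  The
#' interpolation operator depends only on the montage, so it is built once
#' and applied to every trial and time sample.
#'
#' @param ep an `eeg_epochs` with a montage
#' @param bad character vector of channel labels to reconstruct
#' @param m spline stiffness (order), default 4
#' @param n_legendre number of Legendre terms, default 50
#' @param lambda ridge regularization added to the spline system
#' @return the `eeg_epochs` with bad channels replaced and recorded in
#'   `$bad_channels`.
#' @export
interpolate_bad_channels <- function(ep, bad, m = 4, n_legendre = 50,
                                     lambda = 1e-5) {
  stopifnot(inherits(ep, "eeg_epochs"))
  if (length(bad) == 0) return(ep)
  stopifnot(all(bad %in% ep$channels), !is.null(ep$montage))
  good <- setdiff(ep$channels, bad)
  if (length(bad) >= length(good))
    stop("cannot interpolate: a majority of channels is bad")
  if (length(good) < 4)
    stop("cannot interpolate: fewer than 4 good channels")
  pos <- as.matrix(ep$montage[match(ep$channels, ep$montage$label),
                              c("x", "y", "z")])
  pos <- pos / sqrt(rowSums(pos^2))
  gi <- match(good, ep$channels)
  bi <- match(bad, ep$channels)
  A <- .spline_interp_matrix(pos[gi, , drop = FALSE],
                             pos[bi, , drop = FALSE], m, n_legendre, lambda)
  d <- ep$data
  nt <- dim(d)[1]
  for (i in seq_len(nt)) {
    G <- d[i, gi, , drop = TRUE]
    if (is.null(dim(G))) G <- matrix(G, nrow = length(gi))
    d[i, bi, ] <- A %*% G
  }
  ep$data <- d
  ep$bad_channels <- union(ep$bad_channels, bad)
  ep
}

# g(cos angle) kernel of the spherical spline (Legendre recurrence)
.spline_g <- function(cosang, m, n_legendre) {
  p_prev <- rep(1, length(cosang))      # P_0
  p_cur <- cosang                       # P_1
  acc <- numeric(length(cosang))
  for (n in seq_len(n_legendre)) {
    if (n > 1) {
      p_new <- ((2 * n - 1) * cosang * p_cur - (n - 1) * p_prev) / n
      p_prev <- p_cur
      p_cur <- p_new
    }
    acc <- acc + (2 * n + 1) / (n^m * (n + 1)^m) * p_cur
  }
  acc / (4 * pi)
}

# linear operator mapping good-channel values to bad-channel estimates
.spline_interp_matrix <- function(pos_good, pos_bad, m, n_legendre, lambda) {
  ng <- nrow(pos_good)
  cg <- pmin(1, pmax(-1, tcrossprod(pos_good)))
  Ggg <- matrix(.spline_g(as.numeric(cg), m, n_legendre), ng, ng)
  cb <- pmin(1, pmax(-1, pos_bad %*% t(pos_good)))
  Gbg <- matrix(.spline_g(as.numeric(cb), m, n_legendre), nrow(pos_bad), ng)
  # solve [Ggg + lambda I, 1; 1', 0] [c; d] = [v; 0]
  S <- rbind(cbind(Ggg + lambda * diag(ng), rep(1, ng)),
             c(rep(1, ng), 0))
  Sinv <- solve(S)
  # interpolated = Gbg c + d = [Gbg, 1] Sinv[, 1:ng] v
  cbind(Gbg, rep(1, nrow(pos_bad))) %*% Sinv[, seq_len(ng), drop = FALSE]
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean voltage over the 50 ms
#' prestimulus window \[-50, 0).
#'
#' @param ep an `eeg_epochs` whose time axis covers \[-50, 0)
#' @param window_ms baseline window (half-open), default `c(-50, 0)`
#' @return the baseline-corrected `eeg_epochs`.
#' @export
baseline_correct <- function(ep, window_ms = c(-50, 0)) {
  stopifnot(inherits(ep, "eeg_epochs"))
  sel <- ep$time_ms >= window_ms[1] & ep$time_ms < window_ms[2]
  if (!any(sel)) stop("baseline window not covered by the epoch time axis")
  bl <- apply(ep$data[, , sel, drop = FALSE], c(1, 2), mean)
  ep$data <- ep$data - array(bl, dim = dim(ep$data))
  ep
}

#' Full preprocessing pipeline
#'
#' Runs the standard chain on a continuous recording, in this order:
#' epoch extraction, 45--55 Hz band-stop, amplitude artifact screening,
#' spherical-spline interpolation of globally bad channels, rejection of
#' residual artifact trials, 30 Hz low-pass, baseline correction.
#'
#' @param rec an `eeg_recording`
#' @param threshold_uV artifact threshold (default 100)
#' @param bad_channel_fraction see [detect_artifacts()]
#' @param exclude_trials optional integer vector of trials to drop a priori
#'   (e.g. a manual ocular-artifact list)
#' @param verbose print stage-by-stage counts?
#' @return list with `epochs` (clean `eeg_epochs`) and `report`
#'   (`artifact_report`).
#' @export
preprocess_pipeline <- function(rec, threshold_uV = 100,
                                bad_channel_fraction = 0.2,
                                exclude_trials = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  ep <- extract_epochs(rec)
  say("epoching: %d trials (%d dropped)", n_trials(ep), attr(ep, "n_dropped"))
  if (!is.null(exclude_trials) && length(exclude_trials)) {
    ep <- subset_trials(ep, setdiff(seq_len(n_trials(ep)), exclude_trials))
    say("manual exclusion: %d trials remain", n_trials(ep))
  }
  ep <- bandstop_45_55(ep, fs_hz = rec$fs_hz)
  report <- detect_artifacts(ep, threshold_uV, bad_channel_fraction)
  say("artifacts: %d bad channel(s), %d trial(s) to reject",
      length(report$bad_channels), length(report$rejected_trials))
  if (length(report$bad_channels))
    ep <- interpolate_bad_channels(ep, report$bad_channels)
  if (length(report$rejected_trials)) {
    keep <- setdiff(seq_len(n_trials(ep)), report$rejected_trials)
    ep <- subset_trials(ep, keep)
    ep$rejected_trials <- report$rejected_trials
  }
  ep <- lowpass_30(ep, fs_hz = rec$fs_hz)
  ep <- baseline_correct(ep)
  say("final: %d clean trials", n_trials(ep))
  list(epochs = ep, report = report)
}
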