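# Threshold-based seizure-onset detection.
#
# Per channel: band-pass filter, z-normalise, rectify; build an envelope
# by cubic-spline interpolation over local maxima separated by at least
# `min_peak_sep` samples; onset is the first time the processed signal
# exceeds mean(envelope) + s * sd(envelope).

#' Recording container
#'
#' A multichannel recording: channels x samples matrix plus sampling
#' rate, channel labels and free-form epoch metadata.
#'
#' @param samples numeric matrix, one row per channel.
#' @param fs sampling rate in Hz.
#' @param labels channel names (unique); defaults to `ch01`, `ch02`, ...
#' @param meta list of epoch annotations (e.g. clinician onset time).
#' @return object of class `recording`.
#' @export
recording <- function(samples, fs, labels = NULL, meta = list()) {
  samples <- as.matrix(samples)
  stopifnot(is.numeric(samples), is.numeric(fs), fs > 0)
  if (is.null(labels))
    labels <- sprintf("ch%02d", seq_len(nrow(samples)))
  if (length(labels) != nrow(samples) || anyDuplicated(labels))
    stop("labels must be unique, one per channel")
  rownames(samples) <- labels
  structure(list(samples = samples, fs = fs, labels = labels, meta = meta),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat("Recording:", nrow(x$samples), "channels x", ncol(x$samples),
      "samples @", x$fs, "Hz (",
      signif(ncol(x$samples) / x$fs, 4), "s )\n")
  invisible(x)
}

#' Detection parameters and data-type presets
#'
#' `detection_params()` validates a parameter set; `detection_preset()`
#' returns the published settings for the two recording types: scalp EEG
#' (band 4-20 Hz, peak separation 60 samples, s = 0.6) and mEC LFP
#' (band 15-35 Hz, peak separation 22000 samples, s = 1).
#'
#' @param band length-2 numeric, band-pass corner frequencies in Hz.
#' @param min_peak_sep minimum separation between envelope knots, in
#'   samples (the algorithm's `np`).
#' @param s threshold multiplier on the envelope standard deviation.
#' @return object of class `detection_params`.
#' @export
detection_params <- function(band, min_peak_sep, s) {
  stopifnot(length(band) == 2, band[1] > 0, band[2] > band[1],
            min_peak_sep >= 1, s > 0)
  structure(list(band = as.numeric(band),
                 min_peak_sep = as.integer(min_peak_sep), s = s),
            class = "detection_params")
}

#' @rdname detection_params
#' @param preset `"eeg"` or `"mec"`.
#' @export
detection_preset <- function(preset = c("eeg", "mec")) {
  preset <- match.arg(preset)
  switch(preset,
         eeg = detection_params(band = c(4, 20), min_peak_sep = 60, s = 0.6),
         mec = detection_params(band = c(15, 35), min_peak_sep = 22000, s = 1))
}

#' Preprocess one channel for onset detection
#'
#' Zero-phase band-pass filter (4th-order Butterworth run forward and
#' backward), z-normalisation over the epoch, then rectification.
#'
#' @param x numeric sample vector.
#' @param fs sampling rate (Hz).
#' @param band length-2 band in Hz; must lie below Nyquist.
#' @return nonnegative processed signal, same length as `x`.
#' @export
preprocess_channel <- function(x, fs, band) {
  stopifnot(is.numeric(x), fs > 0, length(band) == 2)
  if (band[2] >= fs / 2 || band[1] <= 0)
    stop("band must lie strictly inside (0, fs/2)")
  if (length(x) < 2 * fs / band[1])
    stop("signal too short for the requested band")
  if (var(x) == 0) stop("degenerate signal: zero variance")
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bf, x)
  if (sd(xf) == 0) stop("degenerate signal after filtering")
  abs((xf - mean(xf)) / sd(xf))
}

# strict local maxima of v with minimum index separation, conflicts
# resolved greedily by descending height
.local_maxima <- function(v, min_sep) {
  n <- length(v)
  idx <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]) + 1L
  if (!length(idx)) return(integer(0))
  ord <- idx[order(v[idx], decreasing = TRUE)]
  keep <- logical(0)
  chosen <- integer(0)
  for (i in ord) {
    if (!length(chosen) || all(abs(chosen - i) >= min_sep))
      chosen <- c(chosen, i)
  }
  sort(chosen)
}

#' Spline envelope over separated local maxima
#'
#' Cubic spline through the retained peaks of the processed signal,
#' evaluated at every sample.  Outside the span of the first and last
#' retained peak the envelope is clamped to the respective peak value,
#' avoiding extrapolation overshoot.  With fewer than two retained peaks
#' a constant envelope at `max(x)` is returned with a warning.
#'
#' @param x nonnegative processed signal.
#' @param min_peak_sep minimum inter-peak distance in samples.
#' @return envelope vector, same length as `x`.
#' @export
spline_envelope <- function(x, min_peak_sep) {
  stopifnot(is.numeric(x), min_peak_sep >= 1)
  n <- length(x)
  if (n <= 2 * min_peak_sep + 2) {
    pk <- integer(0)
  } else {
    pk <- .local_maxima(x, as.integer(min_peak_sep))
  }
  if (length(pk) < 2) {
    warning("fewer than 2 envelope knots; falling back to constant envelope")
    return(rep(max(x), n))
  }
  sf <- splinefun(pk, x[pk], method = "fmm")
  u <- sf(seq_len(n))
  u[seq_len(n) < pk[1]] <- x[pk[1]]
  u[seq_len(n) > pk[length(pk)]] <- x[pk[length(pk)]]
  u
}

#' Onset time of one processed channel
#'
#' Threshold \eqn{\theta = \mathrm{mean}(u) + s\,\mathrm{sd}(u)} on the
#' envelope; the onset is the time of the first sample of the processed
#' signal exceeding \eqn{\theta}, in seconds from epoch start, or `NA`
#' if there is no crossing.
#'
#' @param x processed signal (from [preprocess_channel()]).
#' @param envelope envelope vector (from [spline_envelope()]).
#' @param s threshold multiplier.
#' @param fs sampling rate (Hz).
#' @return onset time in seconds, or `NA_real_`.
#' @export
detect_channel_onset <- function(x, envelope, s, fs) {
  if (length(x) != length(envelope))
    stop("signal and envelope lengths differ")
  theta <- mean(envelope) + s * sd(envelope)
  idx <- which(x > theta)
  if (!length(idx)) return(NA_real_)
  (idx[1] - 1) / fs
}

#' Detect onsets in every channel of a recording
#'
#' Runs the three-step threshold algorithm per channel.  Channels that
#' fail (flat signal, no crossing) get an `NA` onset; `all_detected`
#' records whether every channel produced one, which callers use to
#' filter epochs before pattern analysis.
#'
#' @param rec a [recording()].
#' @param params a [detection_params()] or preset.
#' @return object of class `channel_onsets`: `tau` (named seconds,
#'   `NA` = not detected), `all_detected`, `messages` (per-channel
#'   diagnostics), `fs`.
#' @examples
#' tau <- make_onset_times("fast", n_channels = 6, spread = 0.3, seed = 1)
#' rec <- synthesize_recording(tau$tau, fs = 256, duration = 15,
#'                             band = c(4, 20), snr = 8, seed = 2)
#' detect_recording(rec, detection_preset("eeg"))
#' @export
detect_recording <- function(rec, params) {
  stopifnot(inherits(rec, "recording"), inherits(params, "detection_params"))
  n_ch <- nrow(rec$samples)
  tau <- rep(NA_real_, n_ch)
  msgs <- character(n_ch)
  for (i in seq_len(n_ch)) {
    res <- tryCatch({
      x <- preprocess_channel(rec$samples[i, ], rec$fs, params$band)
      u <- suppressWarnings(spline_envelope(x, params$min_peak_sep))
      detect_channel_onset(x, u, params$s, rec$fs)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      msgs[i] <- conditionMessage(res)
    } else {
      tau[i] <- res
      if (is.na(res)) msgs[i] <- "no threshold crossing"
    }
  }
  names(tau) <- rec$labels
  structure(list(tau = tau, all_detected = !anyNA(tau),
                 messages = msgs, fs = rec$fs),
            class = "channel_onsets")
}

#' @export
print.channel_onsets <- function(x, ...) {
  cat("Channel onsets (s):\n")
  print(signif(x$tau, 4))
  cat("all detected:", x$all_detected, "\n")
  invisible(x)
}
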