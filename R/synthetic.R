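# Synthetic inputs with known ground truth: surrogate EEG / mEC-LFP
# epochs with prescribed onset structure, coupled series for the
# association index, and a chain-cascade fixture set.
#
# The seizure-state surrogate is a mid-band sinusoid with a short ramped
# envelope rather than simulator output, so detection ground truth stays
# sharp and independent of the network model under test.

#' Generate per-channel onset times with a prescribed domino class
#'
#' Onsets are spread evenly over `spread` seconds starting at
#' `base_onset`; for multi-domino patterns additional lags from `gaps`
#' are inserted before the named channel positions, splitting the
#' cascade into subgroups.  Uniform jitter on [0, `jitter`] is added per
#' channel.  The pre-jitter geometry is validated against the class
#' thresholds (0.5 s total recruitment, 0.4 s lag), so the returned
#' label is the ground truth by construction.
#'
#' @param class `"fast"`, `"slow"` or `"multi"`.
#' @param n_channels number of channels.
#' @param base_onset time of the earliest onset, seconds.
#' @param spread total recruitment target excluding gaps, seconds.
#'   Defaults: 0.3 (fast), 1.5 (slow), 0.6 (multi).
#' @param gaps for multi: list of `c(position, lag)` pairs; channels at
#'   or beyond `position` are delayed by `lag` (>= 0.4 s for at least
#'   one gap).
#' @param jitter uniform jitter amplitude, seconds.
#' @param seed RNG seed.
#' @return list with `tau` (onset times, seconds) and `class`.
#' @export
make_onset_times <- function(class = c("fast", "slow", "multi"),
                             n_channels = 19, base_onset = 5,
                             spread = NULL, gaps = NULL, jitter = 0,
                             seed = 1L) {
  class <- match.arg(class)
  if (is.null(spread))
    spread <- switch(class, fast = 0.3, slow = 1.5, multi = 0.6)
  if (class == "multi" && is.null(gaps))
    gaps <- list(c(ceiling(n_channels / 2), 0.8))
  stopifnot(n_channels >= 2, spread >= 0, jitter >= 0)

  step <- spread / (n_channels - 1)
  tau <- base_onset + (seq_len(n_channels) - 1) * step
  if (!is.null(gaps)) {
    if (!is.list(gaps)) gaps <- list(gaps)
    for (g in gaps) {
      stopifnot(length(g) == 2, g[1] >= 2, g[1] <= n_channels)
      tau[seq(g[1], n_channels)] <- tau[seq(g[1], n_channels)] + g[2]
    }
  }
  # validate pre-jitter geometry against the grouping thresholds
  srt <- sort(tau)
  r0 <- max(srt) - min(srt)
  l0 <- max(diff(srt))
  ok <- switch(class,
               fast = r0 < 0.5 && l0 < 0.4,
               slow = r0 >= 0.5 && l0 < 0.4,
               multi = l0 >= 0.4)
  if (!ok)
    stop("spread/gaps are inconsistent with class '", class, "'",
         " (r = ", signif(r0, 3), ", l = ", signif(l0, 3), ")")
  if (jitter > 0) {
    set.seed(seed)
    tau <- tau + stats::runif(n_channels, 0, jitter)
  }
  list(tau = tau, class = class)
}

#' Synthesize a multichannel recording with known onsets
#'
#' Each channel carries stationary background (white Gaussian noise
#' band-passed to the detection band, scaled to unit standard
#' deviation); from its onset time onward a sinusoid at the band's
#' centre frequency with amplitude `snr` is added, its envelope ramped
#' linearly over 50 ms so the prescribed onset is sharp.
#'
#' @param tau per-channel onset times in seconds, all inside
#'   (0, `duration`); `snr = 0` yields pure stationary background.
#' @param fs sampling rate, Hz.
#' @param duration epoch length, seconds.
#' @param band Hz pair; background is limited to, and the oscillation
#'   centred in, this band.
#' @param snr oscillation amplitude relative to the unit-sd background.
#' @param burst_duration how long each channel's oscillation lasts,
#'   seconds.  Seizure-like events terminate, and keeping the
#'   oscillation to a minority of the epoch mirrors real epochs, where
#'   the envelope threshold sits between background and seizure
#'   amplitude.  The default, 40% of the epoch, keeps that property for
#'   any epoch length; `Inf` sustains the oscillation to the end.
#' @param seed RNG seed (identical seeds give identical recordings).
#' @param labels optional channel names.
#' @return a [recording()]; ground truth in `meta$tau_true`.
#' @export
synthesize_recording <- function(tau, fs, duration, band, snr = 8,
                                 burst_duration = 0.4 * duration,
                                 seed = 1L, labels = NULL) {
  stopifnot(all(tau > 0), all(tau < duration), snr >= 0,
            length(band) == 2)
  n_ch <- length(tau)
  n_s <- round(duration * fs)
  set.seed(seed)
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  f_mid <- mean(band)
  ramp_n <- round(0.05 * fs)
  tt <- (seq_len(n_s) - 1) / fs
  X <- matrix(0, n_ch, n_s)
  for (i in seq_len(n_ch)) {
    bg <- signal::filtfilt(bf, stats::rnorm(n_s))
    bg <- bg / sd(bg)
    env <- pmin(pmax((tt - tau[i]) * fs / ramp_n, 0), 1)
    env[tt >= tau[i] + burst_duration] <- 0
    X[i, ] <- bg + snr * env * sin(2 * pi * f_mid * (tt - tau[i]))
  }
  recording(X, fs, labels = labels,
            meta = list(tau_true = tau, band = band, snr = snr,
                        burst_duration = burst_duration))
}

#' Coupled series pair for association-index validation
#'
#' @param relation `"identity"`, `"quadratic"` or `"independent"`.
#' @param n sample count (>= 100).
#' @param noise_sd noise standard deviation as a fraction of the signal
#'   standard deviation.
#' @param seed RNG seed.
#' @return list with `x` (source) and `y` (target).
#' @export
make_coupled_pair <- function(relation = c("identity", "quadratic",
                                           "independent"),
                              n = 10000, noise_sd = 0.05, seed = 1L) {
  relation <- match.arg(relation)
  stopifnot(n >= 100, noise_sd >= 0)
  set.seed(seed)
  x <- stats::rnorm(n)
  y <- switch(relation,
              identity = x,
              quadratic = x^2,
              independent = stats::rnorm(n))
  if (relation != "independent" && noise_sd > 0)
    y <- y + stats::rnorm(n, sd = noise_sd * sd(y))
  list(x = x, y = y)
}

#' Synthetic mEC-style cascade event set
#'
#' Six events (by default) of 16-channel local-field-potential-like
#' recordings at 2 kHz in which onset advances from channel 1 (ventral)
#' to channel 16 (dorsal) over roughly 20 seconds plus per-channel
#' jitter -- the slow ventral-to-dorsal domino cascade.  Tuned so the
#' mEC detection preset (15-35 Hz, peak separation 22000 samples, s = 1)
#' detects every channel of every event.
#'
#' @param seed RNG seed.
#' @param n_events number of events.
#' @param cascade cascade duration from channel 1 to 16, seconds.
#' @param snr oscillation-to-background amplitude ratio.
#' @return list of [recording()] objects; each carries its true onsets
#'   in `meta$tau_true`.
#' @export
make_mec_fixture <- function(seed = 1L, n_events = 6, cascade = 20,
                             snr = 8) {
  # 100-s epochs with the cascade starting 35 s in and 25-s bursts keep
  # the seizure fraction low enough for the long-window (np = 22000)
  # envelope threshold on every channel
  lapply(seq_len(n_events), function(ev) {
    set.seed(seed + 1000L * ev)
    jit <- stats::runif(16, 0, 0.04 * cascade)
    tau <- 35 + (0:15) / 15 * cascade + jit
    synthesize_recording(tau, fs = 2000, duration = 100,
                         band = c(15, 35), snr = snr,
                         burst_duration = 25,
                         seed = seed + 1000L * ev + 1L)
  })
}
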