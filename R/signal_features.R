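# Per-modality preprocessing: EEG band-pass and band power, pupillary
# velocity filtering, peak-based heart and respiration rates, EMG RMS,
# and mean/slope summaries.

#' EEG band-pass filter (1-50 Hz, zero-phase)
#'
#' Cascade of a 2nd-order Butterworth high-pass at 1 Hz and an 8th-order
#' Butterworth low-pass at 50 Hz, applied as a zero-phase (two-pass) filter:
#' the squared Butterworth magnitude response is applied to the signal
#' spectrum, which is the response a forward-backward time-domain pass
#' produces, without its boundary transients.  Attenuation one octave
#' beyond either edge exceeds 20 dB.
#'
#' @param series numeric vector.
#' @param fs sampling rate in Hz; must exceed 100.
#' @return filtered series, same length.
#' @examples
#' t <- seq(0, 2, by = 1/500)
#' x <- sin(2 * pi * 10 * t) + sin(2 * pi * 60 * t)
#' y <- bandpass_eeg(x, 500)  # 60 Hz component suppressed
#' @export
bandpass_eeg <- function(series, fs) {
  if (fs <= 100) stop_input("input error: fs must exceed 100 Hz")
  n <- length(series)
  if (n < fs)
    stop_input("input error: series shorter than filter warm-up (1 s)")
  f <- (seq_len(n) - 1) * fs / n
  fol <- pmin(f, fs - f)                 # two-sided frequency axis
  # |H_hp|^2 * |H_lp|^2 of the Butterworth cascade, i.e. the two-pass gain
  g <- ifelse(fol == 0, 0, 1 / (1 + (1 / fol)^4)) / (1 + (fol / 50)^16)
  Re(fft(fft(series) * g, inverse = TRUE)) / n
}

# One-sided Welch PSD: 2-s Hann segments, 50% overlap, segment means
# removed, scaled so sum(psd) * df = signal variance.
welch_psd <- function(series, fs) {
  L <- round(2 * fs)
  if (length(series) < L)
    stop_input("input error: series shorter than 2 s")
  step <- L %/% 2
  nseg <- 1 + (length(series) - L) %/% step
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))   # Hann
  U <- mean(win^2)
  psd <- numeric(L)
  for (s in seq_len(nseg)) {
    seg <- series[(s - 1) * step + seq_len(L)]
    seg <- (seg - mean(seg)) * win
    psd <- psd + Mod(fft(seg))^2
  }
  psd <- psd / (nseg * fs * L * U)
  f <- (seq_len(L) - 1) * fs / L
  half <- f <= fs / 2
  list(f = f[half],
       psd = psd[half] * ifelse(f[half] %in% c(0, fs / 2), 1, 2),
       df = fs / L)
}

integrate_band <- function(spec, lo, hi) {
  sum(spec$psd[spec$f >= lo & spec$f < hi]) * spec$df
}

check_band <- function(band) {
  stopifnot(is.list(band) || is.data.frame(band))
  if (!(band$lo < band$hi)) stop_input("input error: band lo must be < hi")
  invisible(band)
}

#' Integrated spectral power in a frequency band
#'
#' Welch's averaged modified periodogram: 2-s Hann-windowed segments with
#' 50% overlap, segment means removed, one-sided PSD scaled so that the
#' integral over all frequencies equals the signal variance (Parseval).
#' Returns the PSD integrated over `[lo, hi)`, in signal-variance units.
#'
#' @param series numeric vector, at least 2 s long.
#' @param fs sampling rate in Hz.
#' @param band a list or one-row data frame with elements `lo` and `hi` (Hz),
#'   e.g. one row of [eeg_bands()].
#' @return nonnegative scalar power.
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 20, by = 1/500))
#' band_power(x, 500, list(lo = 8, hi = 13))  # ~0.5, the sinusoid variance
#' @export
band_power <- function(series, fs, band) {
  check_band(band)
  if (band$lo < 0 || band$hi > fs / 2)
    stop_input("input error: band outside [0, fs/2)")
  integrate_band(welch_psd(series, fs), band$lo, band$hi)
}

#' The five canonical EEG bands
#'
#' delta 1-3, theta 4-8, alpha 8-13, beta 13-30, gamma 30-50 Hz, half-open
#' `[lo, hi)`.  The 3-4 Hz gap between delta and theta belongs to no band.
#'
#' @return data frame with columns `name`, `lo`, `hi`.
#' @export
eeg_bands <- function() EEG_BANDS

#' Channel-by-band EEG power matrix for one window
#'
#' Applies [bandpass_eeg()] per channel, then [band_power()] per band.
#'
#' @param window samples x channels numeric matrix with channel names.
#' @param fs sampling rate in Hz.
#' @param bands band definition table (default [eeg_bands()]).
#' @param channels channels to use (default: all columns); an absent channel
#'   is an error.
#' @return channels x bands named matrix of powers.
#' @export
eeg_session_powers <- function(window, fs, bands = eeg_bands(),
                               channels = colnames(window)) {
  if (!all(channels %in% colnames(window)))
    stop_input("input error: missing EEG channel(s): %s",
               paste(setdiff(channels, colnames(window)), collapse = ", "))
  out <- matrix(NA_real_, length(channels), nrow(bands),
                dimnames = list(channels, bands$name))
  for (ch in channels) {
    spec <- welch_psd(bandpass_eeg(window[, ch], fs), fs)
    for (bi in seq_len(nrow(bands)))
      out[ch, bi] <- integrate_band(spec, bands$lo[bi], bands$hi[bi])
  }
  out
}

#' Pupillary-velocity artifact filter
#'
#' Flags samples adjacent to any first-difference velocity exceeding `vmax`
#' (plus one neighbor on each side) and replaces them by linear
#' interpolation from the nearest unflagged samples.  Blink and tracking
#' dropouts produce implausible diameter velocities; physiological pupil
#' change does not.
#'
#' @param series pupil diameter in mm.
#' @param fs sampling rate in Hz.
#' @param vmax velocity threshold in mm/s (default 10).
#' @return repaired series, same length.
#' @export
pupil_velocity_filter <- function(series, fs, vmax = 10) {
  if (fs <= 0 || vmax <= 0) stop_input("input error: fs and vmax must be > 0")
  n <- length(series)
  if (n < 3) return(series)
  v <- diff(series) * fs
  bad_diff <- which(abs(v) > vmax)
  if (length(bad_diff) == 0) return(series)
  flagged <- unique(c(bad_diff - 1L, bad_diff, bad_diff + 1L, bad_diff + 2L))
  flagged <- flagged[flagged >= 1L & flagged <= n]
  if (length(flagged) > n / 2)
    stop_input("data-quality error: >50%% of pupil samples flagged")
  good <- setdiff(seq_len(n), flagged)
  series[flagged] <- approx(good, series[good], xout = flagged, rule = 2)$y
  series
}

rate_from_peaks <- function(window, fs, min_dist_s, what) {
  peaks <- find_peaks(window, fs, min_dist_s)
  if (length(peaks) < 2)
    stop_input("data-quality error: fewer than 2 %s peaks detected", what)
  60 * (length(peaks) - 1) / ((peaks[length(peaks)] - peaks[1]) / fs)
}

#' Heart rate from a blood-volume-pulse window
#'
#' Detects pulse peaks (minimum inter-peak distance 0.33 s) and converts the
#' mean inter-peak interval to beats per minute.
#'
#' @param window BVP samples, at least 10 s.
#' @param fs sampling rate in Hz.
#' @return heart rate in bpm.
#' @export
heart_rate_from_bvp <- function(window, fs) {
  if (length(window) < 10 * fs)
    stop_input("input error: BVP window shorter than 10 s")
  rate_from_peaks(window, fs, 0.33, "pulse")
}

#' Respiration rate from a respiration-belt window
#'
#' Peak detection with minimum inter-peak distance 1.5 s; breaths per minute.
#'
#' @param window respiration samples, at least 20 s.
#' @param fs sampling rate in Hz.
#' @return breaths per minute.
#' @export
respiration_rate <- function(window, fs) {
  if (length(window) < 20 * fs)
    stop_input("input error: respiration window shorter than 20 s")
  rate_from_peaks(window, fs, 1.5, "respiration")
}

#' RMS amplitude of a mean-removed EMG window
#'
#' @param window EMG samples in µV.
#' @return root-mean-square of the mean-removed window.
#' @export
emg_rms <- function(window) {
  if (length(window) == 0) stop_input("input error: empty EMG window")
  sqrt(mean((window - mean(window))^2))
}

#' Mean and least-squares slope of a window
#'
#' @param window numeric samples.
#' @param fs sampling rate in Hz (slope is per second, time origin at
#'   window start).
#' @return named numeric `c(mean, slope)`.
#' @export
mean_slope <- function(window, fs) {
  n <- length(window)
  if (n < 2) stop_input("input error: window must have >= 2 samples")
  t <- (seq_len(n) - 1) / fs
  tc <- t - mean(t)
  slope <- sum(tc * window) / sum(tc^2)
  c(mean = mean(window), slope = slope)
}

#' Mean action-unit probabilities for one facial-expression window
#'
#' @param fe_window frames x 17 matrix of AU probabilities, columns in the
#'   fixed AU order (AU01 ... AU45).
#' @return named vector of 17 columnwise means, each in `[0, 1]`.
#' @export
au_session_features <- function(fe_window) {
  fe_window <- as.matrix(fe_window)
  if (ncol(fe_window) != 17)
    stop_input("schema error: expected 17 AU columns, got %d", ncol(fe_window))
  m <- colMeans(fe_window)
  names(m) <- if (!is.null(colnames(fe_window))) colnames(fe_window) else AU_NAMES
  m
}

#' Pain-class label from window kind and VRS rating
#'
#' Baseline windows are `B`; session ratings 1-5 are `LP`, 6-10 `HP`.  A
#' session rated 0 ("no pain" on the VRS) is labeled `B`.
#'
#' @param window_kind `"baseline"` or `"session"`.
#' @param rating integer VRS in 0-10 (ignored for baseline windows).
#' @return factor with levels `B`, `LP`, `HP`.
#' @export
label_from_vrs <- function(window_kind, rating = NA_integer_) {
  window_kind <- match.arg(window_kind, c("baseline", "session"))
  if (window_kind == "baseline") return(factor("B", levels = PAIN_LEVELS))
  if (is.na(rating) || rating < 0 || rating > 10)
    stop_input("input error: session rating must be in [0, 10]")
  lab <- if (rating == 0) "B" else if (rating <= 5) "LP" else "HP"
  factor(lab, levels = PAIN_LEVELS)
}
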