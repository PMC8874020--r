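test_that("the 1-50 Hz band-pass passes the band and rejects outside it", {
  fs <- 500
  t <- (0:(20 * fs - 1)) / fs
  in_band <- sin(2 * pi * 10 * t)
  out60 <- sin(2 * pi * 60 * t)
  octave_lo <- sin(2 * pi * 0.5 * t)
  octave_hi <- sin(2 * pi * 100 * t)
  expect_lt(abs(sd(bandpass_eeg(in_band, fs)) / sd(in_band) - 1), 0.05)
  expect_lt(sd(bandpass_eeg(out60, fs)) / sd(out60), 0.1)
  expect_lt(sd(bandpass_eeg(octave_lo, fs)) / sd(octave_lo), 0.1)   # >20 dB
  expect_lt(sd(bandpass_eeg(octave_hi, fs)) / sd(octave_hi), 0.1)
  expect_equal(bandpass_eeg(rep(0, fs), fs), rep(0, fs))
  expect_error(bandpass_eeg(rnorm(100), fs), "warm-up")
  expect_error(bandpass_eeg(rnorm(500), 50), "fs")
})

test_that("band power matches the Parseval closed form for a sinusoid", {
  fs <- 500
  x <- sin(2 * pi * 10 * (0:(20 * fs - 1)) / fs)
  alpha <- band_power(x, fs, list(lo = 8, hi = 13))
  expect_lt(abs(alpha - 0.5), 0.025)                   # variance = 1/2
  expect_lt(band_power(x, fs, list(lo = 30, hi = 50)), 0.01)
  zero <- rep(0, 20 * fs)
  for (bi in seq_len(nrow(eeg_bands())))
    expect_equal(band_power(zero, fs, eeg_bands()[bi, ]), 0)
  expect_error(band_power(x, fs, list(lo = 30, hi = 400)), "fs/2")
  expect_error(band_power(x[1:100], fs, list(lo = 8, hi = 13)), "2 s")
})

test_that("band definitions partition power as printed", {
  b <- eeg_bands()
  expect_identical(b$name, c("delta", "theta", "alpha", "beta", "gamma"))
  expect_equal(b$lo, c(1, 4, 8, 13, 30))
  expect_equal(b$hi, c(3, 8, 13, 30, 50))
  # band-limited noise stays in its own band
  set.seed(4)
  fs <- 500
  x <- painfuse:::band_limited_noise(20 * fs, fs, 8, 13, 1)
  powers <- vapply(seq_len(5), function(bi)
    band_power(x, fs, b[bi, ]), numeric(1))
  expect_gt(powers[3] / sum(powers), 0.9)
  # Parseval: five band powers of a band-passed signal sum to ~ its variance
  set.seed(5)
  y <- bandpass_eeg(rnorm(20 * fs), fs)
  total <- sum(vapply(seq_len(5), function(bi)
    band_power(y, fs, b[bi, ]), numeric(1)))
  expect_lt(abs(total - var(y)) / var(y), 0.1)
})

test_that("session power matrices control per-band variance", {
  fs <- 250
  set.seed(6)
  mk_win <- function(gamma_var) {
    cbind(Pz = painfuse:::band_limited_noise(20 * fs, fs, 8, 13, sqrt(2)) +
            painfuse:::band_limited_noise(20 * fs, fs, 30, 50,
                                          sqrt(gamma_var)),
          Cz = painfuse:::band_limited_noise(20 * fs, fs, 8, 13, sqrt(2)))
  }
  p1 <- vapply(1:50, function(i) eeg_session_powers(mk_win(1), fs)["Pz", "gamma"],
               numeric(1))
  p2 <- vapply(1:50, function(i) eeg_session_powers(mk_win(2), fs)["Pz", "gamma"],
               numeric(1))
  expect_lt(abs(mean(p2) / mean(p1) - 2), 0.4)          # ratio 2 within 20%
  pw <- eeg_session_powers(mk_win(1), fs)
  expect_equal(dim(pw), c(2, 5))
  expect_identical(rownames(pw), c("Pz", "Cz"))
  expect_identical(colnames(pw), eeg_bands()$name)
  dc <- cbind(Pz = rep(3, 20 * fs))
  expect_true(all(eeg_session_powers(dc, fs) < 1e-6))
  expect_error(eeg_session_powers(mk_win(1), fs, channels = c("Pz", "Oz")),
               "missing EEG channel")
})

test_that("pupillary velocity filter repairs dropouts and nothing else", {
  fs <- 50
  const <- rep(4, 200)
  expect_equal(pupil_velocity_filter(const, fs), const)
  spike <- const; spike[100] <- 0.5
  expect_equal(pupil_velocity_filter(spike, fs), const)
  drift <- 4 + 0.01 * (0:199) / fs
  expect_equal(pupil_velocity_filter(drift, fs), drift)
  # idempotence on a noisy series with several blink-like dropouts
  set.seed(7)
  x <- 4 + cumsum(rnorm(500, 0, 0.01))
  x[c(50, 150, 300)] <- 0.3
  once <- pupil_velocity_filter(x, fs)
  expect_equal(pupil_velocity_filter(once, fs), once)
  bad <- rep(c(1, 8), 100)
  expect_error(pupil_velocity_filter(bad, fs), "50%")
})

test_that("pulse and respiration rates recover constructed periodicities", {
  fs <- 2048
  tt <- (0:(20 * fs - 1)) / fs
  pulse <- function(period) exp(1.5 * (cos(2 * pi * tt / period) - 1))
  expect_lt(abs(heart_rate_from_bvp(pulse(1 / 1.2), fs) - 72), 1)
  expect_lt(abs(heart_rate_from_bvp(pulse(1.0), fs) - 60), 1)
  expect_error(heart_rate_from_bvp(rep(1, 20 * fs), fs), "peaks")
  expect_error(heart_rate_from_bvp(pulse(1)[1:fs], fs), "10 s")
  expect_lt(abs(respiration_rate(sin(2 * pi * 0.25 * tt), fs) - 15), 1)
  expect_lt(abs(respiration_rate(sin(2 * pi * 0.20 * tt), fs) - 12), 1)
  expect_error(respiration_rate(rep(2, 20 * fs), fs), "peaks")
})

test_that("EMG RMS and mean/slope summaries are exact on closed forms", {
  expect_equal(emg_rms(rep(2, 100)), 0)
  expect_lt(abs(emg_rms(sin(2 * pi * 5 * (0:9999) / 1000)) - 1 / sqrt(2)),
            1e-3)
  expect_equal(emg_rms(rep(0, 10)), 0)
  expect_error(emg_rms(numeric(0)), "empty")

  fs <- 2048
  tt <- (0:(20 * fs - 1)) / fs
  ms <- mean_slope(3 + 0.05 * tt, fs)
  expect_equal(unname(ms["slope"]), 0.05, tolerance = 1e-10)
  expect_equal(unname(ms["mean"]), mean(3 + 0.05 * tt))
  expect_equal(unname(mean_slope(rep(31.5, 100), fs)), c(31.5, 0))
  set.seed(8)
  x <- rnorm(40960)
  se <- sd(x) / sqrt(sum(((seq_along(x) - 1) / fs -
                            mean((seq_along(x) - 1) / fs))^2))
  expect_lt(abs(unname(mean_slope(x, fs)["slope"])), 3 * se)
  expect_error(mean_slope(1, fs), "2 samples")
})

test_that("AU summaries and the VRS labeling rule are exact", {
  m <- matrix(0.5, 60, 17)
  expect_equal(unname(au_session_features(m)), rep(0.5, 17))
  m2 <- matrix(0, 60, 17, dimnames = list(NULL, painfuse:::AU_NAMES))
  m2[, "AU45"] <- 1
  f <- au_session_features(m2)
  expect_equal(unname(f[17]), 1)
  expect_identical(names(f)[17], "AU45")
  expect_equal(sum(f), 1)
  one <- matrix(runif(17), 1, 17)
  expect_equal(unname(au_session_features(one)), as.vector(one))
  expect_error(au_session_features(matrix(0, 10, 16)), "17")

  expect_equal(as.character(label_from_vrs("session", 5)), "LP")
  expect_equal(as.character(label_from_vrs("session", 6)), "HP")
  expect_equal(as.character(label_from_vrs("baseline")), "B")
  expect_equal(as.character(label_from_vrs("session", 0)), "B")
  expect_equal(as.character(label_from_vrs("session", 10)), "HP")
  expect_error(label_from_vrs("session", 11), "0, 10")
  # toy rating vector maps as the partition rule dictates
  labs <- c(as.character(label_from_vrs("baseline")),
            vapply(c(2, 5, 6, 10), function(v)
              as.character(label_from_vrs("session", v)), character(1)))
  expect_identical(labs, c("B", "LP", "LP", "HP", "HP"))
})

test_that("session feature assembly is complete, labeled and configurable", {
  cfg <- fast_cfg(n_subjects = 1, seed = 9)
  p <- generate_subject(1, cfg, "S01")
  sim <- simulate_subject_day(p, 1, cfg, 3)
  f <- session_features_day(sim$recordings, "S01", 1)
  expect_equal(nrow(f), sim$timeline$n_sessions + 1)
  expect_equal(f$kind[1], "baseline")
  expect_equal(f$session[1], 0)
  expect_identical(levels(f$label), c("B", "LP", "HP"))
  expect_true(all(is.finite(feature_matrix(f))))
  expect_length(feature_columns(f, "FE"), 17)
  expect_length(feature_columns(f, "EEG"), 4 * 5)
  expect_length(feature_columns(f, "BP"), 2)
  # BP deltas broadcast within the day
  expect_equal(length(unique(f$bp.sys_delta)), 1)

  cfg2 <- fast_cfg(n_subjects = 1, seed = 9,
                   modalities = setdiff(painfuse:::MODALITIES, "EM"))
  f2 <- simulate_cohort_features(cfg2)
  expect_length(feature_columns(f2, "EM"), 0)
  expect_gt(length(feature_columns(f2, "SC")), 0)
})
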