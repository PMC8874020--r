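# Synthetic cohort generation: subject profiles, stimulus timelines and
# per-modality recordings with the statistical structure the downstream
# analysis assumes (window-level class effects plus subject random effects).

#' Draw a subject profile
#'
#' Samples the latent per-subject parameters that drive signal generation:
#' a lognormal pain-sensitivity multiplier, a uniform tolerance (the VRS
#' level above which early withdrawal becomes possible), and baseline
#' physiological levels offset from the population means by Gaussian random
#' effects with the configured between-subject SDs.
#'
#' @param seed integer seed; the profile is a pure function of (seed, config).
#' @param config a [generator_config()] object.
#' @param subject_id identifier stored in the profile (default derived from
#'   the seed).
#' @return a `painfuse_subject` list with fields `subject_id`, `sensitivity`,
#'   `tolerance`, `baseline_means` and `random_effect_sd`.
#' @export
generate_subject <- function(seed, config, subject_id = NULL) {
  validate_config(config)
  set.seed(derive_seed(seed, 104729L))
  if (is.null(subject_id)) subject_id <- sprintf("S%d", seed)
  sensitivity <- rlnorm(1, config$sensitivity_meanlog, config$sensitivity_sdlog)
  tolerance <- runif(1, config$tolerance_range[1], config$tolerance_range[2])
  pop <- config$baseline_pop
  ssd <- config$subject_sd
  off <- function(m) rnorm(1, 0, ssd[[m]])
  ch <- config$eeg_channels
  # Subject offsets for EEG and FE are coherent along the pain-effect
  # pattern (one scalar per modality, plus small independent jitter):
  # a high-arousal subject's band powers and an expressive subject's pain
  # AUs shift together, which is what limits cross-subject generalization.
  dirs <- eeg_effect_directions(ch)
  u_eeg <- rnorm(1, 0, ssd[["EEG"]])
  eeg_base <- outer(rep(0, length(ch)), pop$EEG, "+") + u_eeg * dirs +
    matrix(rnorm(length(ch) * 5, 0, 0.3 * ssd[["EEG"]]), length(ch), 5)
  dimnames(eeg_base) <- list(ch, EEG_BANDS$name)
  u_fe <- rnorm(1, 0, ssd[["FE"]])
  fe_base <- rep(pop$FE, 17) + rnorm(17, 0, 0.3 * ssd[["FE"]])
  names(fe_base) <- AU_NAMES
  fe_base[config$fe_pain_aus] <- fe_base[config$fe_pain_aus] + u_fe
  baseline_means <- list(
    EM  = max(pop$EM + off("EM"), 1.5),
    SC  = max(pop$SC + off("SC"), 0.5),
    BVP = max(pop$BVP + off("BVP"), 45),
    EMG = max(pop$EMG + off("EMG"), 0.5),
    RR  = max(pop$RR + off("RR"), 6),
    ST  = max(pop$ST + off("ST"), 25),
    BP  = pmax(pop$BP + rnorm(2, 0, ssd[["BP"]]), c(85, 50)),
    FE  = clamp(fe_base, 0.01, 0.6),
    EEG = eeg_base
  )
  structure(list(subject_id = subject_id, sensitivity = sensitivity,
                 tolerance = tolerance, baseline_means = baseline_means,
                 random_effect_sd = ssd),
            class = "painfuse_subject")
}

#' Simulate one day's stimulus timeline and VRS ratings
#'
#' The latent pain state follows a logistic rise toward VRS 10 across
#' sessions, at a rate proportional to the subject's sensitivity, with
#' session-level noise on the logistic argument.  Day-1 latent pain is
#' shifted up by `day1_rating_shift` (acclimatization effect).  Ratings are
#' the rounded latent state clipped to \[0, 10\].  After any session whose
#' rating exceeds the subject's tolerance the subject withdraws with
#' logistic probability; otherwise the day runs the full `max_sessions`.
#'
#' @param profile a [generate_subject()] profile.
#' @param day day index in `1:config$n_days`.
#' @param config a [generator_config()] object.
#' @param seed integer seed.
#' @return a `painfuse_timeline` list with `day`, `n_sessions`, `vrs`,
#'   `baseline_window`, `session_windows` (n x 2 matrix of half-open
#'   \[t0, t1) intervals in seconds) and `withdrew_early`.
#' @export
generate_timeline <- function(profile, day, config, seed) {
  if (!day %in% seq_len(config$n_days))
    stop_input("input error: day must be in 1..%d", config$n_days)
  set.seed(derive_seed(seed, 15485863L, day))
  a <- config$vrs_growth_rate * profile$sensitivity
  vrs <- integer(0)
  n <- 0L
  withdrew <- FALSE
  for (k in seq_len(config$max_sessions)) {
    arg <- a * k - config$vrs_offset + rnorm(1, 0, config$vrs_latent_sd)
    latent <- 10 / (1 + exp(-arg))
    if (day == 1L) latent <- latent + config$day1_rating_shift
    vrs[k] <- as.integer(clamp(round(latent), 0, 10))
    n <- k
    if (vrs[k] > profile$tolerance) {
      p_stop <- plogis(config$withdrawal_slope * (vrs[k] - profile$tolerance))
      if (rbinom(1, 1, p_stop) == 1L && k < config$max_sessions) {
        withdrew <- TRUE
        break
      }
    }
  }
  w <- config$window_s
  sw <- cbind(t0 = w * seq_len(n), t1 = w * (seq_len(n) + 1))
  structure(list(day = as.integer(day), n_sessions = n, vrs = vrs[seq_len(n)],
                 baseline_window = c(0, w), session_windows = sw,
                 withdrew_early = withdrew),
            class = "painfuse_timeline")
}

#' Pain-class code of a window
#'
#' 0 for the baseline window and for sessions rated 0, 1 for ratings 1-5,
#' 2 for ratings 6-10.  This is the code the generator's effect sizes
#' multiply, and the numeric "true score" used by the fusion layer.
#'
#' @param vrs integer rating vector, or `NA` for the baseline window.
#' @return integer codes in `{0, 1, 2}`.
#' @export
pain_code <- function(vrs) {
  ifelse(is.na(vrs) | vrs == 0, 0L, ifelse(vrs <= 5, 1L, 2L))
}

window_table <- function(timeline) {
  data.frame(
    kind = c("baseline", rep("session", timeline$n_sessions)),
    session = c(NA_integer_, seq_len(timeline$n_sessions)),
    vrs = c(NA_integer_, timeline$vrs),
    code = pain_code(c(NA_integer_, timeline$vrs)),
    t0 = c(timeline$baseline_window[1], timeline$session_windows[, "t0"]),
    t1 = c(timeline$baseline_window[2], timeline$session_windows[, "t1"]),
    stringsAsFactors = FALSE
  )
}

# Gaussian noise confined to [lo, hi) Hz by spectral masking, rescaled to
# an exact target SD (0 target -> zeros).  Used to build EEG windows whose
# per-band variance is the controlled quantity.
band_limited_noise <- function(n, fs, lo, hi, sd_target) {
  if (sd_target <= 0) return(numeric(n))
  f <- (seq_len(n) - 1) * fs / n
  fol <- pmin(f, fs - f)                      # two-sided frequency axis
  mask <- fol >= lo & fol < hi
  x <- rnorm(n)
  xf <- fft(x)
  xf[!mask] <- 0i
  y <- Re(fft(xf, inverse = TRUE)) / n
  s <- sd(y)
  if (s == 0) return(numeric(n))
  y * (sd_target / s)
}

#' Synthesize one modality's recording for a subject-day
#'
#' Builds the contiguous multi-window recording (baseline window followed by
#' the session windows) for one modality.  Each window's target feature mean
#' is the subject baseline plus `effect_size x noise_sd x pain code` plus a
#' window-level Gaussian intercept; raw samples add fast within-window noise
#' on top.  EEG windows are sums of five band-limited noise components whose
#' per-channel, per-band variance is `exp(target log-power)`; facial action
#' units are 17 probability series with the pain effect concentrated on
#' AU04/AU09/AU10 and none on AU45; BVP is a quasi-periodic pulse wave at
#' the window's target heart rate; blood pressure yields exactly one pre and
#' one post cuff reading with a systolic post-increase.
#'
#' @param profile subject profile.
#' @param timeline day timeline from [generate_timeline()].
#' @param modality one of `r paste(MODALITIES, collapse = ", ")`.
#' @param config a [generator_config()] object.
#' @param seed integer seed.
#' @return a `painfuse_recording` list: `modality`, `sampling_rate`,
#'   `channels`, `time_s`, `samples` (samples x channels matrix; for BP a
#'   2 x 2 pre/post x systolic/diastolic matrix), and `windows` (per-window
#'   metadata with VRS and pain code).
#' @export
synthesize_recording <- function(profile, timeline, modality, config, seed) {
  if (!modality %in% MODALITIES)
    stop_input("input error: unknown modality '%s'", modality)
  mseed <- derive_seed(seed, 32452843L, timeline$day,
                       match(modality, MODALITIES))
  set.seed(mseed)
  wt <- window_table(timeline)
  nw <- nrow(wt)
  w <- config$window_s
  eff <- config$effect_sizes[[modality]]
  nsd <- config$noise_sd[[modality]]
  base <- profile$baseline_means[[modality]]

  if (modality == "BP") {
    pre <- base + rnorm(2, 0, 2)
    d_sys <- eff * nsd + rnorm(1, 0, nsd)
    d_dia <- rnorm(1, 0, config$bp_diastolic_delta_sd)
    samples <- rbind(pre = pre, post = pre + c(d_sys, d_dia))
    colnames(samples) <- c("systolic", "diastolic")
    return(structure(list(modality = "BP", sampling_rate = NA_real_,
                          channels = c("systolic", "diastolic"),
                          time_s = NULL, samples = samples, windows = wt),
                     class = "painfuse_recording"))
  }

  fs <- config$sampling_rates[[modality]]
  npw <- round(w * fs)                    # samples per window
  n <- npw * nw
  time_s <- (seq_len(n) - 1) / fs
  code <- wt$code

  if (modality == "EEG") {
    ch <- config$eeg_channels
    f2 <- {
      f <- (seq_len(npw) - 1) * fs / npw
      pmin(f, fs - f)
    }
    masks <- lapply(seq_len(nrow(EEG_BANDS)), function(bi)
      f2 >= EEG_BANDS$lo[bi] & f2 < EEG_BANDS$hi[bi])
    dirs <- eeg_effect_directions(ch)
    samples <- matrix(0, n, length(ch), dimnames = list(NULL, ch))
    for (ci in seq_along(ch)) {
      # target log-power per window x band, then one FFT pair per window:
      # white noise is masked per band and scaled so each band component has
      # exactly the target variance.
      lp <- outer(rep(0, nw), base[ci, ], "+") +
        outer(code, dirs[ci, ] * eff * nsd) +
        matrix(rnorm(nw * 5, 0, nsd), nw, 5)
      for (wi in seq_len(nw)) {
        X <- fft(rnorm(npw))
        Y <- complex(length.out = npw)
        for (bi in seq_len(5)) {
          m <- masks[[bi]]
          comp_var <- sum(Mod(X[m])^2) / npw^2
          if (comp_var > 0)
            Y[m] <- Y[m] + X[m] * sqrt(exp(lp[wi, bi]) / comp_var)
        }
        idx <- (wi - 1) * npw + seq_len(npw)
        samples[idx, ci] <- Re(fft(Y, inverse = TRUE)) / npw
      }
    }
  } else if (modality == "FE") {
    mu <- matrix(rep(base, each = nw), nw, 17, dimnames = list(NULL, AU_NAMES))
    mu[, config$fe_pain_aus] <- mu[, config$fe_pain_aus] + eff * nsd * code
    mu <- mu + matrix(rnorm(nw * 17, 0, nsd), nw, 17)
    mu <- clamp(mu, 0.02, 0.95)
    samples <- matrix(0, n, 17, dimnames = list(NULL, AU_NAMES))
    for (wi in seq_len(nw)) {
      idx <- (wi - 1) * npw + seq_len(npw)
      samples[idx, ] <- clamp(
        matrix(rep(mu[wi, ], each = npw), npw, 17) +
          matrix(rnorm(npw * 17, 0, 0.1), npw, 17), 0, 1)
    }
  } else if (modality == "BVP") {
    hr <- pmax(base + eff * nsd * code + rnorm(nw, 0, nsd), 40)
    samples <- matrix(0, n, 1, dimnames = list(NULL, "bvp"))
    for (wi in seq_len(nw)) {
      idx <- (wi - 1) * npw + seq_len(npw)
      tt <- (seq_len(npw) - 1) / fs
      phase <- runif(1, 0, 2 * pi)
      pulse <- exp(1.5 * (cos(2 * pi * hr[wi] / 60 * tt + phase) - 1))
      samples[idx, 1] <- pulse + rnorm(npw, 0, 0.02)
    }
  } else if (modality == "RR") {
    rate <- pmax(base + eff * nsd * code + rnorm(nw, 0, nsd), 6)
    samples <- matrix(0, n, 1, dimnames = list(NULL, "rr"))
    for (wi in seq_len(nw)) {
      idx <- (wi - 1) * npw + seq_len(npw)
      tt <- (seq_len(npw) - 1) / fs
      phase <- runif(1, 0, 2 * pi)
      samples[idx, 1] <- sin(2 * pi * rate[wi] / 60 * tt + phase) +
        rnorm(npw, 0, 0.05)
    }
  } else if (modality == "EMG") {
    rms <- pmax(base + eff * nsd * code + rnorm(nw, 0, nsd), 0.2)
    samples <- matrix(rnorm(n, 0, rep(rms, each = npw)), n, 1,
                      dimnames = list(NULL, "emg"))
  } else {                                 # EM, SC, ST: level + slow noise
    lvl <- base + eff * nsd * code + rnorm(nw, 0, nsd)
    floor_lvl <- c(EM = 1, SC = 0.2, ST = 20)[[modality]]
    lvl <- pmax(lvl, floor_lvl)
    sample_sd <- c(EM = 0.05, SC = 0.05, ST = 0.02)[[modality]]
    col <- tolower(modality)
    samples <- matrix(rep(lvl, each = npw) + rnorm(n, 0, sample_sd), n, 1,
                      dimnames = list(NULL, if (modality == "EM") "pupil_mm"
                                            else col))
  }
  structure(list(modality = modality, sampling_rate = fs,
                 channels = colnames(samples), time_s = time_s,
                 samples = samples, windows = wt),
            class = "painfuse_recording")
}

#' Simulate all enabled recordings for one subject-day
#'
#' @param profile subject profile.
#' @param day day index.
#' @param config a [generator_config()] object.
#' @param seed integer seed (per-modality streams are derived from it).
#' @return list with `timeline` and `recordings` (named by modality).
#' @export
simulate_subject_day <- function(profile, day, config, seed) {
  timeline <- generate_timeline(profile, day, config, seed)
  recs <- lapply(config$modalities, function(m)
    synthesize_recording(profile, timeline, m, config, seed))
  names(recs) <- config$modalities
  list(timeline = timeline, recordings = recs)
}

#' Simulate the cohort's subject profiles
#'
#' @param config a [generator_config()] object.
#' @return list of `config$n_subjects` profiles with ids `S01, S02, ...`.
#' @export
cohort_profiles <- function(config) {
  validate_config(config)
  lapply(seq_len(config$n_subjects), function(i)
    generate_subject(derive_seed(config$seed, 7919L, i), config,
                     subject_id = sprintf("S%02d", i)))
}
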