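#' Configuration for the synthetic cold-pressor cohort generator
#'
#' Builds the configuration object consumed by [generate_subject()],
#' [generate_timeline()], [synthesize_recording()], [simulate_cohort_features()]
#' and [generate_dataset()].  Defaults encode the study conditions the
#' analysis assumes: 26 subjects, 3 repeated days, a 20-s relaxed baseline
#' followed by up to ten 20-s cold-pressor sessions rated 0-10 on the verbal
#' rating scale (VRS), nine modalities at their native sampling rates, and
#' pain-state effects on skin conductance, pupil diameter, skin temperature,
#' systolic blood pressure, EEG band power and facial action units, with
#' null effects on heart rate, EMG and respiration rate.
#'
#' @param n_subjects number of subjects (default 26).
#' @param n_days repeated experiment days per subject (default 3).
#' @param max_sessions maximum cold-pressor sessions per day (default 10).
#' @param window_s window length in seconds (default 20).
#' @param sampling_rates named list of sampling rates in Hz for the sampled
#'   modalities.  Defaults: FE 30, EEG 500, EM 50, SC/BVP/EMG/RR/ST 2048.
#'   Blood pressure is not sampled; it yields exactly one pre and one post
#'   cuff reading per day.  See [reduced_sampling_rates()] for a cheaper
#'   profile used in large replicate simulation studies.
#' @param eeg_channels EEG channel names (10-20 system subset).
#' @param effect_sizes named numeric: standardized shift of each modality's
#'   target feature per pain-class code step (0 baseline, 1 low, 2 high),
#'   in units of that modality's window-level noise SD.  Sign is direction:
#'   skin temperature falls under cold immersion, hence negative.
#' @param noise_sd named numeric: window-to-window SD of each modality's
#'   target feature (µS, mm, bpm, °C, breaths/min, µV, mmHg; EEG in
#'   log-power units; FE in AU-probability units).
#' @param subject_sd named numeric: between-subject SD of baseline feature
#'   levels (same units as `noise_sd`).
#' @param modalities character vector of enabled modalities.
#' @param sensitivity_meanlog,sensitivity_sdlog lognormal parameters of the
#'   subject pain-sensitivity multiplier.
#' @param tolerance_range range of the uniform subject tolerance (VRS units);
#'   early withdrawal becomes possible once a rating exceeds tolerance.
#' @param vrs_growth_rate logistic growth rate of the latent pain state per
#'   session, multiplied by subject sensitivity.
#' @param vrs_offset logistic offset; larger means later pain onset.
#' @param vrs_latent_sd SD of session-level noise on the logistic argument.
#' @param day1_rating_shift additive shift (VRS units) applied to latent pain
#'   on day 1 only, before rounding and clipping.
#' @param withdrawal_slope slope of the logistic withdrawal probability in
#'   (rating - tolerance), applied only when rating > tolerance.
#' @param seed integer seed; together with the configuration it fully
#'   determines every generated dataset.
#' @return an object of class `painfuse_config` (a validated list).
#' @examples
#' cfg <- generator_config(n_subjects = 2, n_days = 1)
#' cfg$effect_sizes[["SC"]]
#' @export
generator_config <- function(n_subjects = 26,
                             n_days = 3,
                             max_sessions = 10,
                             window_s = 20,
                             sampling_rates = list(FE = 30, EEG = 500, EM = 50,
                                                   SC = 2048, BVP = 2048,
                                                   EMG = 2048, RR = 2048,
                                                   ST = 2048),
                             eeg_channels = DEFAULT_EEG_CHANNELS,
                             effect_sizes = c(FE = 1.2, EEG = 1.2, EM = 1.0,
                                              SC = 1.0, BVP = 0, EMG = 0,
                                              RR = 0, ST = -1.0, BP = 2.0),
                             noise_sd = c(FE = 0.15, EEG = 0.3, EM = 0.3,
                                          SC = 0.5, BVP = 3, EMG = 0.8,
                                          RR = 1.5, ST = 0.3, BP = 4),
                             subject_sd = c(FE = 0.15, EEG = 0.5, EM = 0.4,
                                            SC = 1.0, BVP = 6, EMG = 1.5,
                                            RR = 2, ST = 0.5, BP = 6),
                             modalities = MODALITIES,
                             sensitivity_meanlog = 0,
                             sensitivity_sdlog = 0.3,
                             tolerance_range = c(6, 10),
                             vrs_growth_rate = 0.9,
                             vrs_offset = 5,
                             vrs_latent_sd = 0.5,
                             day1_rating_shift = 1.0,
                             withdrawal_slope = 2,
                             seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_days = as.integer(n_days),
    max_sessions = as.integer(max_sessions), window_s = window_s,
    sampling_rates = sampling_rates, eeg_channels = eeg_channels,
    effect_sizes = effect_sizes, noise_sd = noise_sd,
    subject_sd = subject_sd, modalities = modalities,
    sensitivity_meanlog = sensitivity_meanlog,
    sensitivity_sdlog = sensitivity_sdlog,
    tolerance_range = tolerance_range,
    vrs_growth_rate = vrs_growth_rate, vrs_offset = vrs_offset,
    vrs_latent_sd = vrs_latent_sd,
    day1_rating_shift = day1_rating_shift,
    withdrawal_slope = withdrawal_slope,
    seed = as.integer(seed),
    # population baseline levels (units per modality; EEG per band, log µV^2)
    baseline_pop = list(
      EM = 4.0, SC = 5.0, BVP = 70, EMG = 5.0, RR = 15, ST = 32,
      BP = c(systolic = 115, diastolic = 75),
      FE = 0.08,
      EEG = c(delta = log(20), theta = log(10), alpha = log(15),
              beta = log(8), gamma = log(4))
    ),
    # AUs carrying the pain effect; blink (AU45) deliberately excluded
    fe_pain_aus = c("AU04", "AU09", "AU10"),
    bp_diastolic_delta_sd = 2
  )
  class(cfg) <- "painfuse_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  num_fields <- c(cfg$effect_sizes, cfg$noise_sd, cfg$subject_sd,
                  cfg$sensitivity_meanlog, cfg$sensitivity_sdlog,
                  cfg$day1_rating_shift, unlist(cfg$sampling_rates))
  if (any(!is.finite(num_fields)))
    stop_input("configuration error: non-finite generator parameter")
  if (cfg$n_subjects < 1 || cfg$n_days < 1 || cfg$max_sessions < 1 ||
      cfg$max_sessions > 10)
    stop_input("configuration error: invalid cohort dimensions")
  if (any(cfg$noise_sd <= 0))
    stop_input("configuration error: noise_sd must be positive")
  if (any(cfg$subject_sd < 0))
    stop_input("configuration error: subject_sd must be nonnegative")
  if (cfg$day1_rating_shift < 0)
    stop_input("configuration error: day1_rating_shift must be >= 0")
  if (!all(cfg$modalities %in% MODALITIES))
    stop_input("configuration error: unknown modality in 'modalities'")
  miss <- setdiff(setdiff(cfg$modalities, "BP"), names(cfg$sampling_rates))
  if (length(miss))
    stop_input("configuration error: no sampling rate for %s",
               paste(miss, collapse = ", "))
  invisible(cfg)
}

#' Reduced sampling-rate profile for replicate simulation studies
#'
#' Window-level summary features (means, slopes, RMS, band powers, peak
#' rates) are insensitive to sampling rate well above the bandwidth of
#' interest, so large Monte-Carlo studies over many replicate cohorts can
#' run at reduced rates without changing the distribution of any feature
#' the analysis consumes.  EEG stays at 250 Hz to keep the gamma band
#' (30-50 Hz) below Nyquist.
#'
#' @return named list of sampling rates (Hz) accepted by
#'   [generator_config()]'s `sampling_rates` argument.
#' @export
reduced_sampling_rates <- function() {
  list(FE = 30, EEG = 250, EM = 50, SC = 256, BVP = 256, EMG = 256,
       RR = 256, ST = 256)
}
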