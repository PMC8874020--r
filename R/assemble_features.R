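# Reduction of subject-day recordings to labeled per-window feature vectors.

#' Feature-column prefix of a modality
#'
#' Feature columns are namespaced `fe.AU01 ... eeg.Pz.gamma ... bp.sys_delta`
#' so per-modality models can select their group by prefix.
#'
#' @param modality modality code.
#' @return prefix string such as `"eeg."`.
#' @export
feature_namespace <- function(modality) {
  if (!modality %in% MODALITIES)
    stop_input("input error: unknown modality '%s'", modality)
  paste0(tolower(modality), ".")
}

#' Names of a modality's feature columns in a feature table
#'
#' @param features feature data frame.
#' @param modality modality code.
#' @return character vector of matching column names (possibly empty).
#' @export
feature_columns <- function(features, modality) {
  ns <- feature_namespace(modality)
  grep(paste0("^", sub("\\.$", "\\\\.", ns)), names(features), value = TRUE)
}

window_slice <- function(rec, wi) {
  npw <- round((rec$windows$t1[wi] - rec$windows$t0[wi]) * rec$sampling_rate)
  rec$samples[(wi - 1) * npw + seq_len(npw), , drop = FALSE]
}

#' Reduce one subject-day's recordings to session feature vectors
#'
#' One row per window (baseline first, then each session): facial AU means,
#' EEG channel-by-band powers, filtered pupil mean and SD, skin-conductance
#' mean and slope, BVP-derived heart rate, EMG RMS, respiration rate, skin
#' temperature mean and slope, and the day's post-minus-pre cuff deltas
#' broadcast to every window of the day.
#'
#' @param recordings named list of `painfuse_recording` objects for one
#'   subject-day (as produced by [simulate_subject_day()]).
#' @param subject_id subject identifier for the output rows.
#' @param day day index for the output rows.
#' @return data frame: `subject`, `day`, `window` (1-based, window 1 is the
#'   baseline), `kind`, `session` (0 for baseline), `vrs`, `label`, then
#'   namespaced feature columns.
#' @export
session_features_day <- function(recordings, subject_id, day) {
  ref <- recordings[[which(!vapply(recordings, function(r)
    identical(r$modality, "BP"), logical(1)))[1]]]
  if (is.null(ref)) stop_input("schema error: no sampled modality present")
  wt <- ref$windows
  nw <- nrow(wt)
  rows <- vector("list", nw)
  bp_delta <- NULL
  if (!is.null(recordings$BP)) {
    d <- recordings$BP$samples["post", ] - recordings$BP$samples["pre", ]
    bp_delta <- c(bp.sys_delta = unname(d["systolic"]),
                  bp.dia_delta = unname(d["diastolic"]))
  }
  for (wi in seq_len(nw)) {
    feats <- numeric(0)
    for (m in names(recordings)) {
      rec <- recordings[[m]]
      if (m == "BP") next
      sl <- window_slice(rec, wi)
      fs <- rec$sampling_rate
      feats <- c(feats, switch(
        m,
        FE = setNames(au_session_features(sl),
                      paste0("fe.", colnames(sl))),
        EEG = {
          p <- eeg_session_powers(sl, fs)
          setNames(as.vector(t(p)),
                   paste0("eeg.", rep(rownames(p), each = ncol(p)), ".",
                          rep(colnames(p), nrow(p))))
        },
        EM = {
          clean <- pupil_velocity_filter(sl[, 1], fs)
          c(em.mean = mean(clean), em.sd = sd(clean))
        },
        SC = setNames(mean_slope(sl[, 1], fs), c("sc.mean", "sc.slope")),
        BVP = c(bvp.hr = heart_rate_from_bvp(sl[, 1], fs)),
        EMG = c(emg.rms = emg_rms(sl[, 1])),
        RR = c(rr.rate = respiration_rate(sl[, 1], fs)),
        ST = setNames(mean_slope(sl[, 1], fs), c("st.mean", "st.slope")),
        stop_input("input error: unknown modality '%s'", m)
      ))
    }
    if (!is.null(bp_delta)) feats <- c(feats, bp_delta)
    rows[[wi]] <- feats
  }
  fmat <- do.call(rbind, rows)
  labels <- vapply(seq_len(nw), function(wi)
    as.character(label_from_vrs(wt$kind[wi], wt$vrs[wi])), character(1))
  out <- data.frame(
    subject = subject_id, day = as.integer(day), window = seq_len(nw),
    kind = wt$kind,
    session = ifelse(wt$kind == "baseline", 0L, wt$session),
    vrs = wt$vrs,
    label = factor(labels, levels = PAIN_LEVELS),
    stringsAsFactors = FALSE
  )
  cbind(out, as.data.frame(fmat))
}

#' Simulate a cohort and return its session feature table
#'
#' Streams through subjects and days: each subject-day's recordings are
#' generated, reduced to features, and discarded, so full-rate cohorts never
#' need to be held in memory.
#'
#' @param config a [generator_config()] object.
#' @param progress print a dot per subject (default FALSE).
#' @return feature data frame, one row per window across the whole cohort.
#' @examples
#' cfg <- generator_config(n_subjects = 2, n_days = 1,
#'                         sampling_rates = reduced_sampling_rates(),
#'                         eeg_channels = c("Fz", "Cz", "Pz"))
#' head(simulate_cohort_features(cfg))
#' @export
simulate_cohort_features <- function(config, progress = FALSE) {
  profiles <- cohort_profiles(config)
  parts <- vector("list", config$n_subjects * config$n_days)
  k <- 0L
  for (i in seq_along(profiles)) {
    for (d in seq_len(config$n_days)) {
      sd_seed <- derive_seed(config$seed, 17389L, i, d)
      sim <- simulate_subject_day(profiles[[i]], d, config, sd_seed)
      k <- k + 1L
      parts[[k]] <- session_features_day(sim$recordings,
                                         profiles[[i]]$subject_id, d)
    }
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  do.call(rbind, parts)
}
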