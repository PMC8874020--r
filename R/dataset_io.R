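# On-disk dataset layout:
#   <root>/manifest.json
#   <root>/subject_<id>/day_<d>/{eeg.csv, em.csv, fe.csv, physio.csv,
#                                bp.csv, ratings.csv}
# physio.csv holds the 2048-Hz channels (sc, bvp, emg, st, rr) on a shared
# time base; each CSV carries a time_s column.  All files are plain text so
# regeneration under the same seed is byte-identical.

PHYSIO_MODS <- c("SC", "BVP", "EMG", "ST", "RR")

#' Generate a synthetic dataset on disk
#'
#' Writes per-subject, per-day CSV recordings for every enabled modality,
#' a ratings file, and a JSON manifest recording the configuration, seed
#' and schema version.  The same configuration and seed always reproduce a
#' byte-identical tree.
#'
#' @param config a [generator_config()] object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.  Side effect: the dataset tree.
#' @export
generate_dataset <- function(config, dir) {
  validate_config(config)
  phys <- intersect(PHYSIO_MODS, config$modalities)
  rates <- unlist(config$sampling_rates[phys])
  if (length(unique(rates)) > 1)
    stop_input("configuration error: physio modalities must share one sampling rate for disk output")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop_input("I/O error: cannot create '%s'", dir)
  profiles <- cohort_profiles(config)
  subject_days <- list()
  for (i in seq_along(profiles)) {
    sid <- profiles[[i]]$subject_id
    for (d in seq_len(config$n_days)) {
      sd_seed <- derive_seed(config$seed, 17389L, i, d)
      sim <- simulate_subject_day(profiles[[i]], d, config, sd_seed)
      ddir <- file.path(dir, paste0("subject_", sid), paste0("day_", d))
      dir.create(ddir, recursive = TRUE, showWarnings = FALSE)
      recs <- sim$recordings
      files <- character(0)
      if (length(phys)) {
        px <- data.frame(time_s = recs[[phys[1]]]$time_s)
        for (m in phys) px[[tolower(m)]] <- recs[[m]]$samples[, 1]
        write.csv(px, file.path(ddir, "physio.csv"), row.names = FALSE)
        files <- c(files, "physio.csv")
      }
      if ("EEG" %in% names(recs)) {
        ex <- data.frame(time_s = recs$EEG$time_s)
        ex <- cbind(ex, as.data.frame(recs$EEG$samples))
        write.csv(ex, file.path(ddir, "eeg.csv"), row.names = FALSE)
        files <- c(files, "eeg.csv")
      }
      if ("EM" %in% names(recs)) {
        write.csv(data.frame(time_s = recs$EM$time_s,
                             pupil_mm = recs$EM$samples[, 1]),
                  file.path(ddir, "em.csv"), row.names = FALSE)
        files <- c(files, "em.csv")
      }
      if ("FE" %in% names(recs)) {
        fx <- cbind(data.frame(time_s = recs$FE$time_s),
                    as.data.frame(recs$FE$samples))
        write.csv(fx, file.path(ddir, "fe.csv"), row.names = FALSE)
        files <- c(files, "fe.csv")
      }
      if ("BP" %in% names(recs)) {
        bx <- data.frame(reading = rownames(recs$BP$samples),
                         systolic = recs$BP$samples[, "systolic"],
                         diastolic = recs$BP$samples[, "diastolic"])
        write.csv(bx, file.path(ddir, "bp.csv"), row.names = FALSE)
        files <- c(files, "bp.csv")
      }
      tl <- sim$timeline
      write.csv(data.frame(session = seq_len(tl$n_sessions), vrs = tl$vrs),
                file.path(ddir, "ratings.csv"), row.names = FALSE)
      files <- c(files, "ratings.csv")
      subject_days[[length(subject_days) + 1L]] <- list(
        subject = sid, day = d, n_sessions = tl$n_sessions,
        withdrew_early = tl$withdrew_early, files = files)
    }
  }
  manifest <- list(
    schema_version = 1L, generator = "painfuse", seed = config$seed,
    config = list(n_subjects = config$n_subjects, n_days = config$n_days,
                  max_sessions = config$max_sessions,
                  window_s = config$window_s,
                  sampling_rates = config$sampling_rates,
                  eeg_channels = config$eeg_channels,
                  modalities = config$modalities,
                  effect_sizes = as.list(config$effect_sizes),
                  noise_sd = as.list(config$noise_sd),
                  subject_sd = as.list(config$subject_sd)),
    subject_days = subject_days)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

read_manifest <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop_input("schema error: no manifest.json in '%s'", dir)
  jsonlite::read_json(mf, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

read_subject_day <- function(dir, sid, day, man) {
  ddir <- file.path(dir, paste0("subject_", sid), paste0("day_", day))
  cfg <- man$config
  ratings <- read.csv(file.path(ddir, "ratings.csv"))
  w <- cfg$window_s
  n <- nrow(ratings)
  wt <- data.frame(
    kind = c("baseline", rep("session", n)),
    session = c(NA_integer_, ratings$session),
    vrs = c(NA_integer_, ratings$vrs),
    code = pain_code(c(NA_integer_, ratings$vrs)),
    t0 = w * (0:n), t1 = w * (1:(n + 1)), stringsAsFactors = FALSE)
  mk <- function(modality, samples, fs) {
    structure(list(modality = modality, sampling_rate = fs,
                   channels = colnames(samples),
                   time_s = (seq_len(nrow(samples)) - 1) / fs,
                   samples = samples, windows = wt),
              class = "painfuse_recording")
  }
  recs <- list()
  mods <- unlist(cfg$modalities)
  phys <- intersect(PHYSIO_MODS, mods)
  if (length(phys)) {
    fp <- file.path(ddir, "physio.csv")
    if (!file.exists(fp)) stop_input("schema error: missing %s", fp)
    px <- read.csv(fp)
    for (m in phys)
      recs[[m]] <- mk(m, as.matrix(px[, tolower(m), drop = FALSE]),
                      cfg$sampling_rates[[m]])
  }
  for (m in intersect(c("EEG", "EM", "FE"), mods)) {
    fp <- file.path(ddir, paste0(tolower(m), ".csv"))
    if (!file.exists(fp)) stop_input("schema error: missing %s", fp)
    x <- read.csv(fp, check.names = FALSE)
    recs[[m]] <- mk(m, as.matrix(x[, setdiff(names(x), "time_s"),
                                   drop = FALSE]),
                    cfg$sampling_rates[[m]])
  }
  if ("BP" %in% mods) {
    fp <- file.path(ddir, "bp.csv")
    if (!file.exists(fp)) stop_input("schema error: missing %s", fp)
    bx <- read.csv(fp)
    samples <- as.matrix(bx[, c("systolic", "diastolic")])
    rownames(samples) <- bx$reading
    recs[["BP"]] <- structure(
      list(modality = "BP", sampling_rate = NA_real_,
           channels = c("systolic", "diastolic"), time_s = NULL,
           samples = samples, windows = wt),
      class = "painfuse_recording")
  }
  recs
}

#' Assemble the labeled session feature table of a dataset
#'
#' For an on-disk dataset directory, reads every subject-day listed in the
#' manifest and reduces it with [session_features_day()].  Rows are one per
#' window; disabled modalities simply have no feature group (recorded in the
#' `disabled_modalities` attribute).
#'
#' @param dataset path to a dataset directory written by [generate_dataset()].
#' @return feature data frame as in [simulate_cohort_features()].
#' @export
assemble_session_features <- function(dataset) {
  if (!is.character(dataset) || !dir.exists(dataset))
    stop_input("input error: 'dataset' must be a dataset directory")
  man <- read_manifest(dataset)
  parts <- lapply(man$subject_days, function(sd) {
    recs <- read_subject_day(dataset, sd$subject, sd$day, man)
    session_features_day(recs, sd$subject, sd$day)
  })
  out <- do.call(rbind, parts)
  attr(out, "disabled_modalities") <-
    setdiff(MODALITIES, unlist(man$config$modalities))
  out
}
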