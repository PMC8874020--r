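test_that("subject profiles are deterministic and respect their invariants", {
  cfg <- fast_cfg()
  p1 <- generate_subject(1, cfg)
  p2 <- generate_subject(1, cfg)
  expect_identical(p1, p2)
  expect_gt(p1$sensitivity, 0)
  expect_gte(p1$tolerance, cfg$tolerance_range[1])
  expect_lte(p1$tolerance, cfg$tolerance_range[2])
  expect_true(all(unlist(p1$baseline_means[c("EM", "SC", "BVP", "EMG",
                                             "RR", "ST", "BP")]) > 0))
  expect_false(identical(p1$baseline_means,
                         generate_subject(2, cfg)$baseline_means))
})

test_that("zero random-effect SDs give every subject identical baselines", {
  cfg <- fast_cfg(subject_sd = c(FE = 0, EEG = 0, EM = 0, SC = 0, BVP = 0,
                                 EMG = 0, RR = 0, ST = 0, BP = 0))
  p1 <- generate_subject(1, cfg)
  p2 <- generate_subject(99, cfg)
  expect_equal(p1$baseline_means, p2$baseline_means)
})

test_that("subject sensitivity follows the configured lognormal law", {
  cfg <- fast_cfg()
  logs <- vapply(seq_len(1000), function(i)
    log(generate_subject(i, cfg)$sensitivity), numeric(1))
  se <- cfg$sensitivity_sdlog / sqrt(1000)
  expect_lt(abs(mean(logs) - cfg$sensitivity_meanlog), 3 * se)
  expect_lt(abs(sd(logs) - cfg$sensitivity_sdlog), 0.05)
})

test_that("timelines: zero stimulus, full tolerance, and day-1 shift", {
  cfg <- fast_cfg(day1_rating_shift = 0)
  p <- generate_subject(1, cfg)
  p$sensitivity <- 1e-9
  tl <- generate_timeline(p, 1, cfg, 5)
  expect_equal(tl$n_sessions, 10)
  expect_true(all(tl$vrs == 0))

  cfg2 <- fast_cfg(n_days = 3, tolerance_range = c(10, 10))
  p2 <- generate_subject(3, cfg2)
  tl2 <- generate_timeline(p2, 2, cfg2, 7)
  expect_equal(tl2$n_sessions, 10)
  expect_false(tl2$withdrew_early)

  # configured day effect: day-1 ratings exceed day-2 ratings on average
  cfg3 <- fast_cfg(n_days = 3)
  m <- vapply(seq_len(500), function(i) {
    pp <- generate_subject(i, cfg3)
    c(mean(generate_timeline(pp, 1, cfg3, i)$vrs),
      mean(generate_timeline(pp, 2, cfg3, i)$vrs))
  }, numeric(2))
  tt <- t.test(m[1, ], m[2, ], alternative = "greater", paired = TRUE)
  expect_lt(tt$p.value, 0.01)
  expect_error(generate_timeline(p, 4, cfg, 1), "day")
})

test_that("recordings have the right shape, rates, ranges and windows", {
  cfg <- fast_cfg(n_days = 3)
  p <- generate_subject(2, cfg)
  tl <- generate_timeline(p, 2, cfg, 4)
  w <- cfg$window_s
  expect_equal(unname(tl$baseline_window), c(0, w))
  expect_equal(unname(tl$session_windows[, "t1"] - tl$session_windows[, "t0"]),
               rep(w, tl$n_sessions))
  expect_equal(unname(tl$session_windows[1, "t0"]), w)

  for (m in c("FE", "EEG", "EM", "SC")) {
    rec <- synthesize_recording(p, tl, m, cfg, 4)
    dur <- w * (tl$n_sessions + 1)
    expect_lte(abs(nrow(rec$samples) - dur * rec$sampling_rate), 1)
  }
  fe <- synthesize_recording(p, tl, "FE", cfg, 4)
  expect_identical(colnames(fe$samples),
                   c("AU01", "AU02", "AU04", "AU05", "AU06", "AU07", "AU09",
                     "AU10", "AU12", "AU14", "AU15", "AU17", "AU20", "AU23",
                     "AU25", "AU26", "AU45"))
  expect_true(all(fe$samples >= 0 & fe$samples <= 1))
  bp <- synthesize_recording(p, tl, "BP", cfg, 4)
  expect_equal(dim(bp$samples), c(2, 2))
  expect_identical(rownames(bp$samples), c("pre", "post"))
  expect_error(synthesize_recording(p, tl, "ECG", cfg, 4), "unknown modality")

  rec1 <- synthesize_recording(p, tl, "SC", cfg, 4)
  rec2 <- synthesize_recording(p, tl, "SC", cfg, 4)
  expect_identical(rec1, rec2)
})

test_that("configured SC effect size is recovered from generated windows", {
  cfg <- fast_cfg(effect_sizes = c(FE = 0, EEG = 0, EM = 0, SC = 1.0,
                                   BVP = 0, EMG = 0, RR = 0, ST = 0, BP = 0))
  p <- generate_subject(1, cfg)
  tl <- manual_timeline(rep(c(3, 8), 5))     # codes 1 and 2 alternating
  lp <- hp <- numeric(0)
  for (r in 1:40) {
    rec <- synthesize_recording(p, tl, "SC", cfg, 100 + r)
    npw <- round(cfg$window_s * rec$sampling_rate)
    wm <- vapply(seq_len(11), function(wi)
      mean(rec$samples[(wi - 1) * npw + seq_len(npw), 1]), numeric(1))
    lp <- c(lp, wm[rec$windows$code == 1])
    hp <- c(hp, wm[rec$windows$code == 2])
  }
  pooled_sd <- sqrt((var(lp) + var(hp)) / 2)
  smd <- (mean(hp) - mean(lp)) / pooled_sd
  expect_lt(abs(smd - 1.0), 0.2)
})

test_that("zero-effect windows are exchangeable across pain states", {
  cfg <- fast_cfg(effect_sizes = zero_effects())
  p <- generate_subject(1, cfg)
  tl <- manual_timeline(rep(8, 10))          # baseline + 10 high-pain windows
  rejections <- 0
  for (r in 1:60) {
    b <- hp <- numeric(0)
    for (d in 1:4) {
      rec <- synthesize_recording(p, tl, "SC", cfg, 1000 + 10 * r + d)
      npw <- round(cfg$window_s * rec$sampling_rate)
      wm <- vapply(seq_len(11), function(wi)
        mean(rec$samples[(wi - 1) * npw + seq_len(npw), 1]), numeric(1))
      b <- c(b, wm[1]); hp <- c(hp, wm[-1])
    }
    rejections <- rejections +
      (suppressWarnings(ks.test(b, hp))$p.value < 0.05)
  }
  expect_lte(rejections / 60, 0.15)          # near-nominal under the null
})

test_that("datasets on disk are structurally complete and byte-reproducible", {
  cfg <- generator_config(n_subjects = 2, n_days = 1, max_sessions = 4,
                          sampling_rates = list(FE = 30, EEG = 250, EM = 50,
                                                SC = 64, BVP = 64, EMG = 64,
                                                RR = 64, ST = 64),
                          eeg_channels = c("Cz", "Pz"), seed = 5)
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  unlink(c(d1, d2), recursive = TRUE)
  generate_dataset(cfg, d1)
  man <- jsonlite::read_json(file.path(d1, "manifest.json"),
                             simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  expect_equal(length(man$subject_days), 2)
  f1 <- list.files(file.path(d1, "subject_S01", "day_1"))
  expect_setequal(f1, c("physio.csv", "eeg.csv", "em.csv", "fe.csv",
                        "bp.csv", "ratings.csv"))
  generate_dataset(cfg, d2)
  files <- list.files(d1, recursive = TRUE)
  expect_identical(files, list.files(d2, recursive = TRUE))
  h1 <- tools::md5sum(file.path(d1, files))
  h2 <- tools::md5sum(file.path(d2, files))
  expect_identical(unname(h1), unname(h2))

  # features assembled from disk match the in-memory pipeline
  fd <- assemble_session_features(d1)
  fm <- simulate_cohort_features(cfg)
  expect_equal(fd[, sort(names(fd))], fm[, sort(names(fm))],
               tolerance = 1e-6, ignore_attr = TRUE)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("default configuration encodes the study conditions", {
  cfg <- generator_config()
  expect_equal(cfg$n_subjects, 26)
  expect_equal(cfg$n_days, 3)
  expect_equal(cfg$max_sessions, 10)
  expect_equal(cfg$sampling_rates[c("FE", "EEG", "EM", "SC")],
               list(FE = 30, EEG = 500, EM = 50, SC = 2048))
  expect_equal(unname(cfg$effect_sizes[c("BVP", "EMG", "RR")]), c(0, 0, 0))
  expect_lt(cfg$effect_sizes[["ST"]], 0)
  expect_error(generator_config(noise_sd = c(FE = -1)), "configuration")
})
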