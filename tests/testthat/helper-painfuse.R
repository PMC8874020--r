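# Shared fixtures: reduced-rate generator configs, separable Gaussian
# feature clouds, and the brute-force simplex grid oracle for the GA.

fast_cfg <- function(n_subjects = 6, n_days = 1, seed = 1L, ...) {
  generator_config(n_subjects = n_subjects, n_days = n_days,
                   sampling_rates = reduced_sampling_rates(),
                   eeg_channels = c("Fz", "Cz", "C3", "Pz"),
                   seed = seed, ...)
}

zero_effects <- function() {
  c(FE = 0, EEG = 0, EM = 0, SC = 0, BVP = 0, EMG = 0, RR = 0, ST = 0, BP = 0)
}

# three well-separated Gaussian clouds; one row per window, with subject ids
# assigned round-robin so the table works with both CV schemes
cloud_features <- function(n_per_class = 30, sep = 6, sd = 0.5, seed = 1,
                           n_subjects = 6, subject_offset_sd = 0) {
  set.seed(seed)
  lab <- rep(c("B", "LP", "HP"), each = n_per_class)
  n <- length(lab)
  centers <- matrix(c(0, 0, 0, 0,
                      sep, sep, 0, 0,
                      sep, sep, sep, sep), 3, 4, byrow = TRUE)
  x <- centers[match(lab, c("B", "LP", "HP")), ] + matrix(rnorm(n * 4, 0, sd), n, 4)
  subject <- sprintf("S%02d", rep_len(seq_len(n_subjects), n))
  if (subject_offset_sd > 0) {
    off <- matrix(rnorm(n_subjects * 4, 0, subject_offset_sd), n_subjects, 4)
    x <- x + off[match(subject, sprintf("S%02d", seq_len(n_subjects))), ]
  }
  colnames(x) <- c("x.f1", "x.f2", "x.f3", "x.f4")
  cbind(data.frame(subject = subject, day = 1L, window = seq_len(n),
                   kind = "session", session = seq_len(n),
                   vrs = NA_integer_,
                   label = factor(lab, levels = c("B", "LP", "HP")),
                   stringsAsFactors = FALSE),
        as.data.frame(x))
}

# exhaustive 0.01-step search over the 2-simplex (w1, 1 - w1); returns the
# lexicographically best (violations, mae)
grid_best_fitness <- function(s1, s2, y, threshold = 0.5, step = 0.01) {
  best <- c(violations = Inf, mae = Inf)
  for (w1 in seq(0, 1, by = step)) {
    err <- abs(w1 * s1 + (1 - w1) * s2 - y)
    f <- c(violations = sum(err > threshold), mae = mean(err))
    if (f[1] < best[1] || (f[1] == best[1] && f[2] < best[2])) best <- f
  }
  best
}

# hand-built timeline for controlled synthesis (bypasses the VRS model)
manual_timeline <- function(vrs, day = 2L, window_s = 20) {
  n <- length(vrs)
  structure(list(day = as.integer(day), n_sessions = n, vrs = as.integer(vrs),
                 baseline_window = c(0, window_s),
                 session_windows = cbind(t0 = window_s * seq_len(n),
                                         t1 = window_s * (seq_len(n) + 1)),
                 withdrew_early = FALSE),
            class = "painfuse_timeline")
}
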