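# Evaluation machinery: stratified k-fold and leave-one-subject-out
# cross-validation of the cascade, per-class F1, and one-way /
# repeated-measures ANOVA of features across the three pain states.

#' 3 x 3 confusion matrix in fixed class order
#'
#' @param truth true labels (factor or character in `{B, LP, HP}`).
#' @param pred predicted labels.
#' @return integer matrix, rows = truth, columns = predictions.
#' @export
confusion_matrix <- function(truth, pred) {
  truth <- factor(as.character(truth), levels = PAIN_LEVELS)
  pred <- factor(as.character(pred), levels = PAIN_LEVELS)
  as.matrix(table(truth = truth, pred = pred))
}

#' Per-class F1 from a confusion matrix
#'
#' `F1_c = 2 TP / (2 TP + FP + FN)`, defined as 0 when the denominator is 0.
#'
#' @param confusion square count matrix, rows = truth, columns = predictions.
#' @return named numeric vector of per-class F1 scores.
#' @export
f1_per_class <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (any(confusion < 0) || any(confusion != round(confusion)))
    stop_input("input error: confusion matrix must hold nonnegative counts")
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  den <- 2 * tp + fp + fn
  f1 <- ifelse(den == 0, 0, 2 * tp / den)
  names(f1) <- rownames(confusion)
  f1
}

stratified_folds <- function(labels, k, seed) {
  set.seed(derive_seed(seed, 9973L))
  ord <- unlist(lapply(split(seq_along(labels), labels), function(idx)
    idx[sample.int(length(idx))]))
  fold <- integer(length(labels))
  fold[ord] <- rep_len(seq_len(k), length(ord))
  fold
}

#' Stratified k-fold cross-validation of the cascade
#'
#' Windows are partitioned into `k` class-stratified folds; each fold is
#' predicted by a cascade trained on the others.  Per-class F1 is averaged
#' over folds; the pooled confusion matrix is also returned.  If a training
#' split lacks a class the partition is resampled once, then it is an error.
#'
#' @param features labeled feature table.
#' @param labels labels (default `features$label`).
#' @param k number of folds (default 5).
#' @param seed partition seed.
#' @param cascade_cfg a [cascade_config()].
#' @return an `painfuse_eval` list: `scheme`, `per_class_f1`, `macro_f1`,
#'   `confusion`, `n_folds_or_subjects`, `fold_f1` (fold x class matrix).
#' @export
kfold_cv <- function(features, labels = features$label, k = 5, seed = 1L,
                     cascade_cfg = cascade_config()) {
  labels <- factor(as.character(labels), levels = PAIN_LEVELS)
  n <- length(labels)
  if (n < k) stop_input("input error: fewer rows than folds")
  fold <- stratified_folds(labels, k, seed)
  for (attempt in 1:2) {
    ok <- all(vapply(seq_len(k), function(f)
      all(table(labels[fold != f]) > 0), logical(1)))
    if (ok) break
    if (attempt == 2)
      stop_input("training error: a class is absent from a training split")
    fold <- stratified_folds(labels, k, seed + 1L)
  }
  x <- feature_matrix(features)
  cm <- matrix(0L, 3, 3, dimnames = list(PAIN_LEVELS, PAIN_LEVELS))
  fold_f1 <- matrix(NA_real_, k, 3, dimnames = list(NULL, PAIN_LEVELS))
  for (f in seq_len(k)) {
    tr <- fold != f
    model <- train_cascade(x[tr, , drop = FALSE], labels[tr], cascade_cfg)
    pred <- predict_label(model, x[!tr, , drop = FALSE])
    cmf <- confusion_matrix(labels[!tr], pred)
    fold_f1[f, ] <- f1_per_class(cmf)
    cm <- cm + cmf
  }
  per_class <- colMeans(fold_f1)
  structure(list(scheme = "kfold5", per_class_f1 = per_class,
                 macro_f1 = mean(per_class), confusion = cm,
                 n_folds_or_subjects = k, fold_f1 = fold_f1),
            class = "painfuse_eval")
}

#' Leave-one-subject-out cross-validation of the cascade
#'
#' One fold per subject: all of that subject's windows are held out and
#' predicted by a cascade trained on the remaining subjects.  Per-class F1
#' is averaged over folds, skipping classes absent from a fold's test
#' subject.
#'
#' @param features labeled feature table.
#' @param labels labels (default `features$label`).
#' @param subject_ids subject of each row (default `features$subject`).
#' @param cascade_cfg a [cascade_config()].
#' @return an `painfuse_eval` list as in [kfold_cv()], with `scheme = "loso"`
#'   and one fold row per subject.
#' @export
loso_cv <- function(features, labels = features$label,
                    subject_ids = features$subject,
                    cascade_cfg = cascade_config()) {
  labels <- factor(as.character(labels), levels = PAIN_LEVELS)
  subjects <- unique(subject_ids)
  if (length(subjects) < 3)
    stop_input("input error: leave-one-subject-out needs >= 3 subjects")
  x <- feature_matrix(features)
  cm <- matrix(0L, 3, 3, dimnames = list(PAIN_LEVELS, PAIN_LEVELS))
  fold_f1 <- matrix(NA_real_, length(subjects), 3,
                    dimnames = list(subjects, PAIN_LEVELS))
  for (si in seq_along(subjects)) {
    te <- subject_ids == subjects[si]
    model <- train_cascade(x[!te, , drop = FALSE], labels[!te], cascade_cfg)
    pred <- predict_label(model, x[te, , drop = FALSE])
    cmf <- confusion_matrix(labels[te], pred)
    f1 <- f1_per_class(cmf)
    f1[rowSums(cmf) == 0] <- NA_real_      # class absent from this subject
    fold_f1[si, ] <- f1
    cm <- cm + cmf
  }
  per_class <- colMeans(fold_f1, na.rm = TRUE)
  structure(list(scheme = "loso", per_class_f1 = per_class,
                 macro_f1 = mean(per_class), confusion = cm,
                 n_folds_or_subjects = length(subjects), fold_f1 = fold_f1),
            class = "painfuse_eval")
}

#' One-way or repeated-measures ANOVA across the three pain states
#'
#' The one-way variant is the classic between-group F test on all
#' observations.  The repeated variant blocks on subject: it fits
#' `value ~ state + subject` on the window-level observations, so the state
#' F statistic is tested against the within-subject residual with
#' `dof_subject = n_subjects - 1`.  Blocking at the window level keeps the
#' test exactly F-calibrated under independent window noise even when
#' subjects contribute unequal numbers of windows per state (a subject-mean
#' aggregation is not, because cell means then have unequal variances).
#'
#' @param values numeric observations.
#' @param states pain state of each observation (factor in `{B, LP, HP}`).
#' @param variant `"oneway"` or `"repeated"`.
#' @param subject_ids required for the repeated variant.
#' @return list of class `painfuse_anova`: `F`, `p`, `dof_between`,
#'   `dof_within` (oneway) or `dof_subject` and `dof_error` (repeated),
#'   `variant`, `n_subjects` (repeated only).
#' @export
anova_three_states <- function(values, states,
                               variant = c("oneway", "repeated"),
                               subject_ids = NULL) {
  variant <- match.arg(variant)
  states <- factor(as.character(states), levels = PAIN_LEVELS)
  keep <- is.finite(values) & !is.na(states)
  values <- values[keep]; states <- states[keep]
  if (any(table(states) < 2))
    stop_input("input error: every pain state needs >= 2 observations")
  if (variant == "oneway") {
    fit <- aov(values ~ states)
    tab <- summary(fit)[[1]]
    return(structure(list(F = tab[1, "F value"], p = tab[1, "Pr(>F)"],
                          dof_between = tab[1, "Df"],
                          dof_within = tab[2, "Df"], variant = "oneway"),
                     class = "painfuse_anova"))
  }
  if (is.null(subject_ids))
    stop_input("input error: repeated variant needs subject_ids")
  subject_ids <- factor(subject_ids[keep])
  n <- nlevels(subject_ids)
  if (n < 2) stop_input("input error: repeated variant needs >= 2 subjects")
  dat <- data.frame(v = values, state = states, subject = subject_ids)
  # subject first: aov's sequential SS then test state adjusted for block
  fit <- aov(v ~ subject + state, data = dat)
  tab <- summary(fit)[[1]]          # rows: subject, state, Residuals
  structure(list(F = tab[2, "F value"], p = tab[2, "Pr(>F)"],
                 dof_between = tab[2, "Df"],
                 dof_subject = n - 1L,
                 dof_error = tab[3, "Df"],
                 variant = "repeated", n_subjects = n),
            class = "painfuse_anova")
}

# BP deltas are one post-minus-pre reading per subject-day, constant across
# that day's windows; the matching test is whether the mean delta differs
# from zero across subjects (paired pre/post design, F = t^2, dof = n - 1).
bp_delta_test <- function(features, col) {
  agg <- aggregate(features[[col]],
                   list(subject = features$subject, day = features$day),
                   function(v) v[1])
  per_subj <- aggregate(agg$x, list(subject = agg$subject), mean)$x
  n <- length(per_subj)
  if (n < 3 || sd(per_subj) == 0) return(list(F = NA_real_, p = NA_real_, n = n))
  tt <- t.test(per_subj)
  list(F = unname(tt$statistic)^2, p = tt$p.value, n = n)
}

#' ANOVA significance screen over all features
#'
#' Runs the three-state ANOVA (repeated-measures by default, days pooled)
#' for every feature column.  EEG band powers are log-transformed first
#' (spectral power is lognormal; the ANOVA's additive model applies on the
#' log scale).  Blood-pressure deltas, being one pre/post difference per
#' day rather than per-session measurements, are instead tested for a
#' nonzero mean across subjects (paired cuff design).
#'
#' @param features labeled feature table.
#' @param variant `"repeated"` (default) or `"oneway"`.
#' @param bonferroni add a Bonferroni-adjusted p column (default TRUE).
#' @return data frame with one row per feature: `feature`, `modality`, `F`,
#'   `dof1`, `dof2`, `p`, `p_bonferroni`, `test`.
#' @export
significance_screen <- function(features, variant = "repeated",
                                bonferroni = TRUE) {
  cols <- setdiff(names(features), META_COLS)
  rows <- lapply(cols, function(col) {
    modality <- toupper(sub("\\..*$", "", col))
    if (modality == "BP") {
      r <- bp_delta_test(features, col)
      data.frame(feature = col, modality = modality, F = r$F,
                 dof1 = 1L, dof2 = r$n - 1L, p = r$p,
                 test = "paired_prepost", stringsAsFactors = FALSE)
    } else {
      v <- features[[col]]
      if (modality == "EEG") v <- log(pmax(v, .Machine$double.eps))
      r <- anova_three_states(v, features$label, variant,
                              features$subject)
      data.frame(feature = col, modality = modality, F = r$F,
                 dof1 = r$dof_between,
                 dof2 = if (variant == "repeated") r$dof_error else r$dof_within,
                 p = r$p, test = paste0("anova_", variant),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (bonferroni) out$p_bonferroni <- pmin(out$p * nrow(out), 1)
  out
}
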