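# Two-stage cascade classification of 20-s windows into B / LP / HP:
# stage 1 separates pain from no-pain, stage 2 (consulted only when stage 1
# votes pain) separates low from high pain.  Each stage is an SVM whose
# decision values are mapped to probabilities by a Platt-style sigmoid.

META_COLS <- c("subject", "day", "window", "kind", "session", "vrs", "label")

#' Extract the numeric feature matrix from a feature table
#'
#' Drops the metadata columns (`subject`, `day`, `window`, `kind`,
#' `session`, `vrs`, `label`) and returns the rest as a numeric matrix.
#'
#' @param features feature data frame.
#' @return numeric matrix.
#' @export
feature_matrix <- function(features) {
  cols <- setdiff(names(features), META_COLS)
  as.matrix(features[, cols, drop = FALSE])
}

#' Cascade training configuration
#'
#' @param kernel SVM kernel, `"radial"` (default) or `"linear"`.
#' @param cost regularization constant C (default 1).
#' @param gamma RBF bandwidth; `NULL` (default) uses the median heuristic
#'   `1 / (2 median ||x_i - x_j||^2)` on the standardized training rows.
#' @param seed integer seed (kept for interface symmetry; training is
#'   deterministic).
#' @return list of class `painfuse_cascade_config`.
#' @export
cascade_config <- function(kernel = c("radial", "linear"), cost = 1,
                           gamma = NULL, seed = 1L) {
  structure(list(kernel = match.arg(kernel), cost = cost, gamma = gamma,
                 seed = as.integer(seed)),
            class = "painfuse_cascade_config")
}

median_heuristic_gamma <- function(x) {
  n <- nrow(x)
  idx <- if (n > 200) round(seq(1, n, length.out = 200)) else seq_len(n)
  d2 <- dist(x[idx, , drop = FALSE])^2
  m <- median(d2)
  if (!is.finite(m) || m <= 0) m <- ncol(x)
  1 / (2 * m)
}

fit_stage <- function(x, y, cfg) {
  # y: two-level factor; returns svm + sigmoid coefficients mapping the
  # decision value to P(second level).
  wts <- 1 / table(y)
  wts <- wts / sum(wts) * length(wts)
  gamma <- if (is.null(cfg$gamma)) median_heuristic_gamma(x) else cfg$gamma
  fit <- e1071::svm(x, y, kernel = cfg$kernel, cost = cfg$cost,
                    gamma = gamma, scale = FALSE,
                    class.weights = stats::setNames(as.numeric(wts),
                                                    names(wts)))
  dv <- attr(predict(fit, x, decision.values = TRUE), "decision.values")[, 1]
  ybin <- as.integer(y == levels(y)[2])
  platt <- suppressWarnings(glm(ybin ~ dv, family = binomial()))
  list(svm = fit, platt = coef(platt))
}

stage_prob <- function(stage, x) {
  dv <- attr(predict(stage$svm, x, decision.values = TRUE),
             "decision.values")[, 1]
  as.numeric(plogis(stage$platt[1] + stage$platt[2] * dv))
}

#' Train the two-stage pain cascade
#'
#' Standardizes features (training mean/SD), fits stage 1 (B vs pain) on all
#' rows and stage 2 (LP vs HP) on the pain rows only, with inverse-frequency
#' class weights (baseline windows are the rare class).
#'
#' @param features feature data frame or numeric matrix (metadata columns
#'   are ignored).
#' @param labels factor or character vector in `{B, LP, HP}`.
#' @param config a [cascade_config()].
#' @param namespace optional note of which modality group the model consumes.
#' @return a `painfuse_cascade` model.
#' @export
train_cascade <- function(features, labels, config = cascade_config(),
                          namespace = "all") {
  x <- if (is.data.frame(features)) feature_matrix(features) else
    as.matrix(features)
  labels <- factor(as.character(labels), levels = PAIN_LEVELS)
  if (anyNA(labels)) stop_input("training error: labels outside {B, LP, HP}")
  if (nrow(x) != length(labels))
    stop_input("training error: features/labels length mismatch")
  tab <- table(labels)
  if (any(tab == 0))
    stop_input("training error: class %s absent from training data",
               paste(names(tab)[tab == 0], collapse = ", "))
  if (any(tab < 5))
    stop_input("training error: fewer than 5 rows in class %s",
               paste(names(tab)[tab < 5], collapse = ", "))
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  xs <- scale(x, mu, sdv)
  y1 <- factor(ifelse(labels == "B", "nopain", "pain"),
               levels = c("nopain", "pain"))
  stage1 <- fit_stage(xs, y1, config)
  pain <- labels != "B"
  y2 <- factor(as.character(labels[pain]), levels = c("LP", "HP"))
  stage2 <- fit_stage(xs[pain, , drop = FALSE], y2, config)
  structure(list(stage1 = stage1, stage2 = stage2,
                 standardizer = list(mean = mu, sd = sdv),
                 feature_names = colnames(x), namespace = namespace,
                 config = config),
            class = "painfuse_cascade")
}

cascade_newdata <- function(model, x) {
  if (is.data.frame(x)) x <- feature_matrix(x)
  x <- as.matrix(x)
  miss <- setdiff(model$feature_names, colnames(x))
  if (length(miss))
    stop_input("input error: missing feature(s): %s",
               paste(miss[seq_len(min(5, length(miss)))], collapse = ", "))
  x <- x[, model$feature_names, drop = FALSE]
  scale(x, model$standardizer$mean, model$standardizer$sd)
}

#' Calibrated stage probabilities of a cascade
#'
#' @param model a `painfuse_cascade`.
#' @param x feature rows covering the model's feature names.
#' @return data frame with `p_pain` (stage 1) and `p_hp` (stage 2,
#'   conditional on pain).
#' @export
cascade_probs <- function(model, x) {
  xs <- cascade_newdata(model, x)
  data.frame(p_pain = stage_prob(model$stage1, xs),
             p_hp = stage_prob(model$stage2, xs))
}

#' Predict pain-class labels with the cascade
#'
#' Stage 1 routes: below 0.5 pain probability the window is `B` and stage 2
#' is never consulted; otherwise stage 2 decides LP vs HP.  Ties at exactly
#' 0.5 go to the higher-pain branch.
#'
#' @param model a `painfuse_cascade`.
#' @param x feature rows.
#' @return factor of labels with levels `B`, `LP`, `HP`.
#' @export
predict_label <- function(model, x) {
  pr <- cascade_probs(model, x)
  lab <- ifelse(pr$p_pain < 0.5, "B", ifelse(pr$p_hp < 0.5, "LP", "HP"))
  factor(lab, levels = PAIN_LEVELS)
}

#' Expected-class-code score from calibrated stage probabilities
#'
#' `score = p_pain * (1 + p_hp)`: the expected class code when B/LP/HP are
#' coded 0/1/2 and the two stages are treated as a chain.  Bounded in
#' `[0, 2]` and monotone in both probabilities.
#'
#' @param p_pain stage-1 calibrated probability of pain.
#' @param p_hp stage-2 calibrated probability of high pain given pain.
#' @return numeric score in `[0, 2]`.
#' @export
cascade_score <- function(p_pain, p_hp) p_pain * (1 + p_hp)

#' Predict continuous sensor scores with the cascade
#'
#' @param model a `painfuse_cascade`.
#' @param x feature rows.
#' @return numeric vector of scores in `[0, 2]` (see [cascade_score()]).
#' @export
predict_score <- function(model, x) {
  pr <- cascade_probs(model, x)
  cascade_score(pr$p_pain, pr$p_hp)
}

#' Train one cascade per modality
#'
#' Restricts the feature table to each enabled modality's namespaced columns
#' and trains a cascade on that group alone, producing the per-sensor models
#' whose scores feed decision-level fusion.
#'
#' @param features feature data frame (with metadata columns).
#' @param labels labels for the rows.
#' @param config a [cascade_config()].
#' @param modalities modalities to train (default: all with columns present).
#' @return named list of `painfuse_cascade` models.
#' @export
train_per_modality <- function(features, labels, config = cascade_config(),
                               modalities = NULL) {
  if (is.null(modalities))
    modalities <- MODALITIES[vapply(MODALITIES, function(m)
      length(feature_columns(features, m)) > 0, logical(1))]
  if (length(modalities) == 0)
    stop_input("configuration error: no enabled modality with features")
  models <- list()
  for (m in modalities) {
    cols <- feature_columns(features, m)
    if (length(cols) == 0)
      stop_input("configuration error: modality %s has no feature columns", m)
    models[[m]] <- train_cascade(features[, cols, drop = FALSE], labels,
                                 config, namespace = m)
  }
  models
}

#' Per-modality score matrix
#'
#' @param models named list from [train_per_modality()].
#' @param features feature rows to score.
#' @return rows x modalities matrix of scores in `[0, 2]`.
#' @export
score_matrix <- function(models, features) {
  s <- vapply(models, function(m)
    predict_score(m, features[, m$feature_names, drop = FALSE]),
    numeric(nrow(features)))
  colnames(s) <- names(models)
  s
}
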