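# Decision-level fusion: fused score = sum_i w_i s_i over the nine sensor
# scores, with nonnegative weights on the unit simplex learned by a
# real-coded genetic algorithm (tournament selection, blend crossover,
# Gaussian mutation, elitism, clip-and-renormalize simplex repair).

#' Fuse per-sensor scores with a weight vector
#'
#' @param s numeric sensor scores.
#' @param w numeric weights, same length as `s` (nine modalities in the
#'   full model; restricted sets carry zeros on excluded sensors).
#' @return the weighted sum `sum(w * s)`.
#' @export
fuse <- function(s, w) {
  if (length(s) != length(w))
    stop_input("input error: scores and weights must have equal length")
  if (!all(is.finite(s)) || !all(is.finite(w)))
    stop_input("input error: non-finite score or weight")
  sum(w * s)
}

#' GA configuration for fusion-weight learning
#'
#' Defaults follow the fusion optimizer's operating point: crossover rate
#' 0.8, mutation rate 0.02, population 50, at most 50 generations.
#'
#' @param population_size individuals per generation (default 50).
#' @param max_generations generation cap (default 50).
#' @param crossover_rate probability a selected pair is blended (default 0.8).
#' @param mutation_rate per-gene Gaussian mutation probability (default 0.02).
#' @param mutation_sd SD of the mutation perturbation (default 0.1).
#' @param tournament_size tournament selection size (default 3).
#' @param elitism number of best individuals copied unchanged (default 1).
#' @param threshold class-units tolerance defining a fitness violation
#'   (default 0.5, half the spacing between class codes).
#' @param seed integer seed; the optimization is deterministic given it.
#' @return list of class `painfuse_ga_config`.
#' @export
ga_config <- function(population_size = 50, max_generations = 50,
                      crossover_rate = 0.8, mutation_rate = 0.02,
                      mutation_sd = 0.1, tournament_size = 3, elitism = 1,
                      threshold = 0.5, seed = 1L) {
  cfg <- list(population_size = as.integer(population_size),
              max_generations = as.integer(max_generations),
              crossover_rate = crossover_rate, mutation_rate = mutation_rate,
              mutation_sd = mutation_sd,
              tournament_size = as.integer(tournament_size),
              elitism = as.integer(elitism), threshold = threshold,
              seed = as.integer(seed))
  if (cfg$population_size < 1 || cfg$max_generations < 1 ||
      cfg$tournament_size < 1 || cfg$elitism < 0)
    stop_input("configuration error: GA sizes must be >= 1")
  if (any(c(cfg$crossover_rate, cfg$mutation_rate) < 0) ||
      any(c(cfg$crossover_rate, cfg$mutation_rate) > 1))
    stop_input("configuration error: GA rates must be in [0, 1]")
  class(cfg) <- "painfuse_ga_config"
  cfg
}

project_simplex <- function(w) {
  w <- pmax(w, 0)
  s <- sum(w)
  if (s == 0) rep(1 / length(w), length(w)) else w / s
}

#' Fitness of a fusion weight vector
#'
#' Counts threshold violations (windows whose absolute fused-vs-true-score
#' error exceeds `threshold`) and the mean absolute error.  Candidate
#' orderings compare violations first, MAE as tiebreak.
#'
#' @param w weight vector (one entry per column of `S`).
#' @param S windows x sensors score matrix.
#' @param y true scores (class codes 0/1/2).
#' @param threshold violation tolerance in class units (default 0.5).
#' @return named numeric `c(violations, mae)`.
#' @export
fitness <- function(w, S, y, threshold = 0.5) {
  if (length(y) == 0) stop_input("input error: empty fusion dataset")
  err <- abs(as.numeric(S %*% w) - y)
  c(violations = sum(err > threshold), mae = mean(err))
}

#' Learn fusion weights with a real-coded genetic algorithm
#'
#' Chromosomes are weight vectors on the unit simplex over the active
#' sensors.  Each generation applies tournament selection, arithmetic blend
#' crossover with probability `crossover_rate`, per-gene Gaussian mutation
#' with probability `mutation_rate`, simplex repair after every operator,
#' and elitism.  Runs to `max_generations`, stopping early only when the
#' best individual fits exactly (zero violations and zero MAE) so that the
#' MAE tiebreak keeps refining weights after all windows are within the
#' violation threshold.
#'
#' @param S windows x sensors score matrix (named columns).
#' @param y true scores, class codes 0/1/2.
#' @param cfg a [ga_config()].
#' @return list: `weights` (named, nonnegative, summing to 1), `fitness`
#'   (violations and MAE of the best individual), and `history` (best
#'   fitness per generation; non-increasing by elitism).
#' @export
ga_optimize <- function(S, y, cfg = ga_config()) {
  S <- as.matrix(S)
  if (nrow(S) == 0 || length(y) != nrow(S))
    stop_input("input error: empty fusion dataset or length mismatch")
  set.seed(cfg$seed)
  k <- ncol(S)
  np <- cfg$population_size
  pop <- t(apply(matrix(runif(np * k), np, k), 1, project_simplex))
  if (k == 1) pop <- matrix(1, np, 1)
  eval_pop <- function(P) {
    A <- abs(S %*% t(P) - y)              # n x np
    list(viol = colSums(A > cfg$threshold), mae = colMeans(A))
  }
  fit <- eval_pop(pop)
  rank_of <- function(f) order(f$viol, f$mae)
  history <- data.frame(generation = integer(0), violations = integer(0),
                        mae = numeric(0))
  for (g in seq_len(cfg$max_generations)) {
    rk <- rank_of(fit)
    best <- rk[1]
    history <- rbind(history, data.frame(generation = g,
                                         violations = fit$viol[best],
                                         mae = fit$mae[best]))
    if (fit$viol[best] == 0 && fit$mae[best] < 1e-12) break
    if (g == cfg$max_generations) break
    pos <- integer(np)                     # rank position of each individual
    pos[rk] <- seq_len(np)
    tournament <- function() {
      cand <- sample.int(np, cfg$tournament_size, replace = TRUE)
      cand[which.min(pos[cand])]
    }
    nextpop <- matrix(0, np, k)
    ne <- min(cfg$elitism, np)
    if (ne > 0) nextpop[seq_len(ne), ] <- pop[rk[seq_len(ne)], , drop = FALSE]
    i <- ne
    while (i < np) {
      p1 <- pop[tournament(), ]
      p2 <- pop[tournament(), ]
      if (runif(1) < cfg$crossover_rate) {
        u <- runif(k)
        c1 <- u * p1 + (1 - u) * p2
        c2 <- (1 - u) * p1 + u * p2
      } else {
        c1 <- p1; c2 <- p2
      }
      for (child in list(c1, c2)) {
        if (i >= np) break
        mut <- runif(k) < cfg$mutation_rate
        child[mut] <- child[mut] + rnorm(sum(mut), 0, cfg$mutation_sd)
        i <- i + 1
        nextpop[i, ] <- project_simplex(child)
      }
    }
    pop <- nextpop
    fit <- eval_pop(pop)
  }
  rk <- rank_of(fit)
  w <- project_simplex(pop[rk[1], ])
  names(w) <- colnames(S)
  list(weights = w,
       fitness = c(violations = unname(fit$viol[rk[1]]),
                   mae = unname(fit$mae[rk[1]])),
       history = history)
}

#' Pain class from a fused score
#'
#' Nearest class code in `{0, 1, 2}`, with exact midpoints (0.5, 1.5)
#' rounded to the higher-pain class and out-of-range scores clipped.
#'
#' @param fs numeric fused scores.
#' @return factor with levels `B`, `LP`, `HP`.
#' @export
classify_from_fused <- function(fs) {
  if (any(!is.finite(fs))) stop_input("input error: non-finite fused score")
  code <- ifelse(fs < 0.5, 0L, ifelse(fs < 1.5, 1L, 2L))
  factor(PAIN_LEVELS[code + 1L], levels = PAIN_LEVELS)
}

#' The three standard modality sets of the fusion ablation
#'
#' Set 1 uses all nine signals, set 2 only EEG and facial expression,
#' set 3 everything except EEG and facial expression.
#'
#' @return named list of modality character vectors.
#' @export
modality_sets <- function() {
  list(all = MODALITIES,
       eeg_fe = c("EEG", "FE"),
       no_eeg_fe = setdiff(MODALITIES, c("EEG", "FE")))
}

#' Fusion ablation over modality sets
#'
#' Splits windows into a stratified train/test partition, trains one cascade
#' per modality on the training part, then for each modality set zeroes the
#' excluded sensors, re-runs the GA on the restricted training score
#' columns, and evaluates the fused classification on the held-out part.
#'
#' @param features labeled feature table (e.g. [simulate_cohort_features()]).
#' @param sets named list of modality vectors (default [modality_sets()]).
#' @param cascade_cfg a [cascade_config()].
#' @param ga_cfg a [ga_config()]; its seed also fixes the split.
#' @param train_frac fraction of windows used for training (default 0.7).
#' @return named list per set: `weights` (length 9, zeros on excluded
#'   sensors), `ga_fitness`, `confusion` (3 x 3), `per_class_f1`,
#'   `macro_f1`; plus attribute `split` recording the partition sizes.
#' @export
run_modality_sets <- function(features, sets = modality_sets(),
                              cascade_cfg = cascade_config(),
                              ga_cfg = ga_config(), train_frac = 0.7) {
  y_all <- factor(as.character(features$label), levels = PAIN_LEVELS)
  set.seed(derive_seed(ga_cfg$seed, 2738933L))
  tr <- unlist(lapply(split(seq_len(nrow(features)), y_all), function(idx)
    sample(idx, max(1, round(train_frac * length(idx))))))
  te <- setdiff(seq_len(nrow(features)), tr)
  models <- train_per_modality(features[tr, , drop = FALSE], y_all[tr],
                               cascade_cfg)
  S_tr <- score_matrix(models, features[tr, , drop = FALSE])
  S_te <- score_matrix(models, features[te, , drop = FALSE])
  code_tr <- as.integer(y_all[tr]) - 1L
  out <- list()
  for (sn in names(sets)) {
    active <- sets[[sn]]
    missing <- setdiff(active, names(models))
    if (length(missing))
      stop_input("configuration error: set '%s' references disabled modality %s",
                 sn, paste(missing, collapse = ", "))
    ga <- ga_optimize(S_tr[, active, drop = FALSE], code_tr, ga_cfg)
    w_full <- setNames(numeric(length(models)), names(models))
    w_full[active] <- ga$weights
    fused <- as.numeric(S_te[, active, drop = FALSE] %*% ga$weights)
    pred <- classify_from_fused(fused)
    cm <- confusion_matrix(y_all[te], pred)
    f1 <- f1_per_class(cm)
    out[[sn]] <- list(weights = w_full, ga_fitness = ga$fitness,
                      confusion = cm, per_class_f1 = f1,
                      macro_f1 = mean(f1))
  }
  attr(out, "split") <- c(train = length(tr), test = length(te))
  out
}
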