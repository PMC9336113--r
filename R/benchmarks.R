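# High-level evaluation wrappers tying the classifiers to the CV harness.

#' Feature matrix of one trial for the neural classifier
#'
#' @param trial a trial from [generate_dataset()] (or any list with a
#'   cleaned `$sequence`).
#' @return feature matrix from [encode_features()].
#' @export
trial_features <- function(trial) {
  encode_features(normalize_sequence(trial$sequence, mirror = TRUE))
}

#' Rule-based leave-one-subject-out evaluation
#'
#' The rule-based classifier has no training step, so each fold simply scores
#' the held-out subject's trials with the given (or scenario-default)
#' thresholds.
#'
#' @param trials dataset from [generate_dataset()].
#' @param thresholds a [threshold_set()] or NULL for per-scenario defaults.
#' @param smooth_window odd smoothing window in frames.
#' @return a `cv_result`.
#' @export
rb_loso <- function(trials, thresholds = NULL, smooth_window = 5L) {
  loso_cv(trials,
          fit = function(train) thresholds,
          predict_fn = function(th, trial)
            rb_assess(trial$sequence, th, smooth_window = smooth_window))
}

nn_fit_trials <- function(train, hp, seed) {
  X <- do.call(rbind, lapply(train, trial_features))
  Y <- do.call(rbind, lapply(train, `[[`, "labels"))
  train_two_stage(X, Y, hp, seed = seed)
}

#' Neural two-stage leave-one-subject-out evaluation
#'
#' Fits the two-stage model on all but one subject and scores the held-out
#' subject, per fold.
#'
#' @param trials dataset from [generate_dataset()].
#' @param hp a [two_stage_hyperparams()]; NULL picks the defaults of the
#'   dataset's exercise.
#' @param seed training seed (same for every fold).
#' @return a `cv_result`.
#' @export
nn_loso <- function(trials, hp = NULL, seed = 1L) {
  if (is.null(hp)) hp <- two_stage_hyperparams(trials[[1]]$exercise)
  loso_cv(trials,
          fit = function(train) nn_fit_trials(train, hp, seed),
          predict_fn = function(model, trial)
            predict(model, trial_features(trial)))
}

#' Neural two-stage leave-one-exercise-out evaluation
#'
#' Two folds (train E1 / test E2 and the reverse); both datasets must share
#' the frontal positioning scenario.
#'
#' @param trials_a,trials_b datasets for the two exercises.
#' @inheritParams nn_loso
#' @return a `cv_result`.
#' @export
nn_loeo <- function(trials_a, trials_b, hp = NULL, seed = 1L) {
  if (is.null(hp)) hp <- two_stage_hyperparams(trials_a[[1]]$exercise)
  loeo_cv(trials_a, trials_b,
          fit = function(train) nn_fit_trials(train, hp, seed),
          predict_fn = function(model, trial)
            predict(model, trial_features(trial)))
}

#' Grid search over two-stage architectures
#'
#' Optional exploration routine over the architecture/learning-rate grid
#' (1-3 layers; 16-512 units; initial rates 1e-4 to 0.1), scored by LOSO
#' mean micro-F1. Not run by default anywhere — the per-exercise defaults of
#' [two_stage_hyperparams()] stand.
#'
#' @param trials dataset from [generate_dataset()].
#' @param c1_units,c2_units,lrs candidate values (kept small by default;
#'   the full printed grid is much larger).
#' @param seed training seed.
#' @return data.frame of configurations and their mean F1, best first.
#' @export
two_stage_grid <- function(trials, c1_units = c(16L, 64L),
                           c2_units = c(16L, 64L),
                           lrs = c(0.001, 0.01), seed = 1L) {
  grid <- expand.grid(c1 = c1_units, c2 = c2_units, lr = lrs)
  grid$f1 <- vapply(seq_len(nrow(grid)), function(i) {
    hp <- two_stage_hyperparams(c1_hidden = grid$c1[i], c2_hidden = grid$c2[i],
                                c1_lr = grid$lr[i], c2_lr = grid$lr[i])
    cv <- nn_loso(trials, hp, seed = seed)
    cv$summary$mean[cv$summary$metric == "f1"]
  }, numeric(1))
  grid[order(-grid$f1), ]
}
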