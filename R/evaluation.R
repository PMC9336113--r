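#' Micro-averaged multilabel metrics
#'
#' Pools true/false positive and false negative counts over every (frame,
#' label) slot of the 5-slot one-hot space — the Normal slot participates, so
#' all-Normal predictions are scored too — then computes precision
#' TP/(TP+FP), recall TP/(TP+FN), their harmonic mean F1, and the Hamming
#' loss (FP+FN)/(N*L), the fraction of mispredicted label slots. Zero
#' denominators yield 0 with a warning.
#'
#' @param y_true,y_pred `n x 5` one-hot label matrices of equal shape, rows
#'   respecting Normal exclusivity.
#' @return an `mlc_metrics` list: `precision`, `recall`, `f1`, `hamming`,
#'   all in \[0, 1\].
#' @export
mlc_metrics <- function(y_true, y_pred) {
  check_label_matrix(y_true)
  check_label_matrix(y_pred)
  if (!all(dim(y_true) == dim(y_pred)))
    stop("y_true and y_pred must have identical shapes")
  tp <- sum(y_true == 1L & y_pred == 1L)
  fp <- sum(y_true == 0L & y_pred == 1L)
  fn <- sum(y_true == 1L & y_pred == 0L)
  precision <- if (tp + fp == 0) {
    warning("no predicted positives; precision set to 0"); 0
  } else tp / (tp + fp)
  recall <- if (tp + fn == 0) {
    warning("no true positives; recall set to 0"); 0
  } else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  hamming <- (fp + fn) / (nrow(y_true) * ncol(y_true))
  structure(list(precision = precision, recall = recall, f1 = f1,
                 hamming = hamming),
            class = "mlc_metrics")
}

#' @export
print.mlc_metrics <- function(x, ...) {
  cat(sprintf("<mlc_metrics> P %.4f  R %.4f  F1 %.4f  Hamming %.4f\n",
              x$precision, x$recall, x$f1, x$hamming))
  invisible(x)
}

#' Multilabel dataset statistics
#'
#' `p_min` is the fraction of samples carrying exactly one active label (in
#' the 5-slot space a Normal frame is single-labelled), so `1 - p_min` is the
#' multi-labelled fraction. `IRLbl` is the per-label imbalance ratio: the
#' occurrence count of the most frequent label divided by the label's own
#' count, so the modal label has ratio 1 and rare labels ratios much greater
#' than 1. Labels that never occur get `NA`.
#'
#' @param labels `n x 5` one-hot label matrix or a list of label sets.
#' @return a `dataset_stats` list: `p_min` and named `irlbl` vector.
#' @export
dataset_stats <- function(labels) {
  if (is.list(labels)) labels <- as_label_matrix(labels)
  check_label_matrix(labels)
  if (nrow(labels) == 0L) stop("empty label set")
  p_min <- mean(rowSums(labels) == 1L)
  counts <- colSums(labels)
  irlbl <- ifelse(counts > 0, max(counts) / counts, NA_real_)
  names(irlbl) <- colnames(labels)
  structure(list(p_min = p_min, irlbl = irlbl), class = "dataset_stats")
}

#' @export
print.dataset_stats <- function(x, ...) {
  cat(sprintf("<dataset_stats> P_min %.4f (multi-labelled %.2f%%)\n",
              x$p_min, 100 * (1 - x$p_min)))
  print(round(x$irlbl, 2))
  invisible(x)
}

fold_metrics_frame <- function(folds) {
  do.call(rbind, lapply(names(folds), function(k) {
    m <- folds[[k]]
    data.frame(fold = k, precision = m$precision, recall = m$recall,
               f1 = m$f1, hamming = m$hamming, stringsAsFactors = FALSE)
  }))
}

cv_result <- function(folds, scheme) {
  df <- fold_metrics_frame(folds)
  summ <- data.frame(
    metric = c("precision", "recall", "f1", "hamming"),
    mean = vapply(c("precision", "recall", "f1", "hamming"),
                  function(m) mean(df[[m]]), numeric(1)),
    sd = vapply(c("precision", "recall", "f1", "hamming"),
                function(m) stats::sd(df[[m]]), numeric(1)))
  structure(list(folds = df, summary = summ, scheme = scheme),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", x$scheme, " over ", nrow(x$folds), " folds\n", sep = "")
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-9s %.4f +/- %.4f\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$sd[i]))
  invisible(x)
}

#' Leave-one-subject-out cross-validation
#'
#' One fold per subject: the held-out subject's trials never contribute to
#' training, the model is fit on everyone else and scored on the held-out
#' frames. Fold metrics are averaged unweighted; the summary reports mean and
#' standard deviation over folds.
#'
#' @param trials list of trials; each trial must carry `$subject`, and
#'   whatever `fit`/`predict_fn` need (the synthetic generator's trials do).
#' @param fit function(train_trials) returning a fitted model (or static
#'   parameters, e.g. a threshold set).
#' @param predict_fn function(model, trial) returning an `n x 5` one-hot
#'   prediction matrix for that trial's frames.
#' @param truth_fn function(trial) returning the trial's `n x 5` ground-truth
#'   matrix; defaults to `trial$labels`.
#' @return a `cv_result`.
#' @export
loso_cv <- function(trials, fit, predict_fn,
                    truth_fn = function(trial) trial$labels) {
  subjects <- vapply(trials, function(tr) as.character(tr$subject), character(1))
  ids <- sort(unique(subjects))
  if (length(ids) < 2L) stop("LOSO needs at least 2 subjects")
  folds <- list()
  for (s in ids) {
    train <- trials[subjects != s]
    test <- trials[subjects == s]
    model <- fit(train)
    pred <- do.call(rbind, lapply(test, function(tr) predict_fn(model, tr)))
    truth <- do.call(rbind, lapply(test, truth_fn))
    folds[[s]] <- mlc_metrics(truth, pred)
  }
  cv_result(folds, "leave-one-subject-out")
}

#' Leave-one-exercise-out cross-validation
#'
#' Two folds: train on exercise 1 / test on exercise 2, then the reverse.
#' Only meaningful when both exercises share the positioning scenario (E1 and
#' E2, both frontal S1), so a scenario mismatch is an error.
#'
#' @param trials_a,trials_b trial lists for the two exercises.
#' @inheritParams loso_cv
#' @return a `cv_result` with 2 folds.
#' @export
loeo_cv <- function(trials_a, trials_b, fit, predict_fn,
                    truth_fn = function(trial) trial$labels) {
  sc_a <- unique(vapply(trials_a, function(tr) tr$scenario, character(1)))
  sc_b <- unique(vapply(trials_b, function(tr) tr$scenario, character(1)))
  if (length(sc_a) != 1L || !identical(sc_a, sc_b))
    stop("LOEO requires both exercises to share one positioning scenario ",
         "(got ", paste(sc_a, collapse = "/"), " vs ",
         paste(sc_b, collapse = "/"), ")")
  ex_a <- unique(vapply(trials_a, function(tr) tr$exercise, character(1)))
  ex_b <- unique(vapply(trials_b, function(tr) tr$exercise, character(1)))
  run_fold <- function(train, test) {
    model <- fit(train)
    pred <- do.call(rbind, lapply(test, function(tr) predict_fn(model, tr)))
    truth <- do.call(rbind, lapply(test, truth_fn))
    mlc_metrics(truth, pred)
  }
  folds <- list()
  folds[[paste0("test_", ex_b)]] <- run_fold(trials_a, trials_b)
  folds[[paste0("test_", ex_a)]] <- run_fold(trials_b, trials_a)
  cv_result(folds, "leave-one-exercise-out")
}
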