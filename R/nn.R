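# Default keypoints fed to the neural classifiers. Columns are side-resolved
# (affected vs unaffected) so a mirrored left-affected subject and a
# right-affected subject with the same pose yield identical feature rows.
nn_feature_joints <- function(affected_side) {
  aff <- side_joints(affected_side)
  opp <- side_joints(other_side(affected_side))
  c(nose = 0L, neck = 1L, midhip = 8L,
    shoulder_aff = aff$shoulder, shoulder_unaff = opp$shoulder,
    elbow_aff = aff$elbow, wrist_aff = aff$wrist,
    hip_aff = aff$hip, hip_unaff = opp$hip,
    eye_aff = aff$eye, eye_unaff = opp$eye,
    ear_aff = aff$ear, ear_unaff = opp$ear)
}

#' Encode a mirrored normalized sequence as a feature matrix
#'
#' One row per frame; columns are the (x, y) body-frame coordinates of a
#' fixed, documented keypoint subset (spine, both shoulders and hips,
#' affected elbow/wrist, eyes and ears), side-resolved so the affected limb
#' always occupies the same columns. Confidences are never included. The
#' sequence must have gone through the mirror step — the whole point of
#' mirroring is that the healthy side is a common reference across subjects.
#'
#' @param nseq a mirrored `normalized_sequence`.
#' @return numeric matrix `n_frames x 26` with named columns.
#' @export
encode_features <- function(nseq) {
  stopifnot(inherits(nseq, "normalized_sequence"))
  if (!isTRUE(nseq$mirrored))
    stop("encode_features requires a mirrored sequence ",
         "(normalize_sequence(..., mirror = TRUE))")
  joints <- nn_feature_joints(nseq$affected_side)
  rows <- t(vapply(nseq$frames, function(m) {
    xy <- m[jrow(joints), c("x", "y"), drop = FALSE]
    as.numeric(t(xy))
  }, numeric(2L * length(joints))))
  colnames(rows) <- as.vector(rbind(paste0("x_", names(joints)),
                                    paste0("y_", names(joints))))
  rows
}

#' Hyperparameters of the two-stage neural classifier
#'
#' Architecture and optimisation settings for the binary compensation gate
#' (C1, ReLU activations) and the one-vs-rest multilabel identifier (C2, tanh
#' activations). Both are trained with Adam on mini-batches of 5 samples for
#' at most 550 epochs. Per-exercise defaults come from the grid exploration
#' over 1-3 layers, 16-512 units and initial learning rates 1e-4 to 0.1:
#' E1 uses C1 1x16 (lr 0.001) and C2 1x64 (lr 0.001); E2 uses C1 2x16
#' (lr 0.001) and C2 1x16 (lr 0.01); E3 uses C1 1x96 (lr 0.01) and C2 1x16
#' (lr 0.001).
#'
#' @param exercise "E1", "E2" or "E3" to pick that exercise's defaults.
#' @param c1_hidden,c2_hidden integer vectors of hidden-layer sizes.
#' @param c1_lr,c2_lr initial Adam learning rates.
#' @param batch_size mini-batch size.
#' @param max_iter maximum training epochs.
#' @return a `two_stage_hyperparams` object.
#' @export
two_stage_hyperparams <- function(exercise = NULL, c1_hidden = 16L,
                                  c2_hidden = 64L, c1_lr = 0.001,
                                  c2_lr = 0.001, batch_size = 5L,
                                  max_iter = 550L) {
  if (!is.null(exercise)) {
    exercise <- match.arg(exercise, EXERCISES)
    d <- switch(exercise,
                E1 = list(c1 = 16L, c1lr = 0.001, c2 = 64L, c2lr = 0.001),
                E2 = list(c1 = c(16L, 16L), c1lr = 0.001, c2 = 16L, c2lr = 0.01),
                E3 = list(c1 = 96L, c1lr = 0.01, c2 = 16L, c2lr = 0.001))
    c1_hidden <- d$c1; c1_lr <- d$c1lr; c2_hidden <- d$c2; c2_lr <- d$c2lr
  }
  stopifnot(length(c1_hidden) >= 1L, length(c2_hidden) >= 1L,
            all(c1_hidden >= 1L), all(c2_hidden >= 1L),
            c1_lr > 0, c2_lr > 0, batch_size >= 1L, max_iter >= 1L)
  structure(list(c1_hidden = as.integer(c1_hidden),
                 c2_hidden = as.integer(c2_hidden),
                 c1_lr = c1_lr, c2_lr = c2_lr,
                 c1_activation = "relu", c2_activation = "tanh",
                 batch_size = as.integer(batch_size),
                 max_iter = as.integer(max_iter)),
            class = "two_stage_hyperparams")
}

#' Train the two-stage neural compensation classifier
#'
#' Stage C1 is a binary gate trained on all frames with target "any
#' compensation label active". Stage C2 is a one-vs-rest multilabel
#' classifier — one binary network per compensation label (TF, TR, SE, O) —
#' trained *only* on frames that carry at least one compensation label, so
#' the dominant Normal class never dilutes it. Training is deterministic
#' given `seed`.
#'
#' @param features numeric feature matrix from [encode_features()].
#' @param labels `n x 5` one-hot label matrix (see [as_label_matrix()]).
#' @param hp a [two_stage_hyperparams()].
#' @param seed integer seed controlling initialisation and batch shuffling.
#' @return a `two_stage_model`.
#' @export
train_two_stage <- function(features, labels, hp = two_stage_hyperparams(),
                            seed = 1L) {
  features <- as.matrix(features)
  check_label_matrix(labels, n = nrow(features))
  any_comp <- as.numeric(rowSums(labels[, 1:4, drop = FALSE]) > 0)
  if (length(unique(any_comp)) < 2L)
    stop("degenerate label distribution: C1 needs both compensation and ",
         "Normal frames (got ",
         if (all(any_comp == 0)) "all Normal" else "all compensation", ")")
  set.seed(seed)
  c1 <- mlp_fit(features, any_comp, hidden = hp$c1_hidden,
                activation = hp$c1_activation, lr = hp$c1_lr,
                batch_size = hp$batch_size, max_iter = hp$max_iter)
  comp_idx <- which(any_comp == 1)
  Xc <- features[comp_idx, , drop = FALSE]
  c2 <- vector("list", 4L)
  names(c2) <- LABEL_NAMES[1:4]
  for (k in 1:4) {
    yk <- labels[comp_idx, k]
    if (length(unique(yk)) < 2L) {
      # label absent (or universal) among compensation frames: constant rule
      c2[[k]] <- list(constant = unique(yk))
    } else {
      c2[[k]] <- mlp_fit(Xc, yk, hidden = hp$c2_hidden,
                         activation = hp$c2_activation, lr = hp$c2_lr,
                         batch_size = hp$batch_size, max_iter = hp$max_iter)
    }
  }
  structure(list(c1 = c1, c2 = c2, hp = hp,
                 feature_names = colnames(features),
                 label_names = LABEL_NAMES),
            class = "two_stage_model")
}

#' @export
print.two_stage_model <- function(x, ...) {
  cat("<two_stage_model>\n",
      "  C1 gate: ", paste(x$hp$c1_hidden, collapse = "x"), " units (",
      x$hp$c1_activation, "), lr ", x$hp$c1_lr, ", ",
      x$c1$n_epochs, " epochs\n",
      "  C2 one-vs-rest over ", paste(names(x$c2), collapse = "/"), ": ",
      paste(x$hp$c2_hidden, collapse = "x"), " units (",
      x$hp$c2_activation, "), lr ", x$hp$c2_lr, "\n",
      "  features: ", length(x$feature_names), "\n", sep = "")
  invisible(x)
}

c2_scores <- function(model, X) {
  vapply(model$c2, function(m) {
    if (!is.null(m$constant)) rep(as.numeric(m$constant), nrow(X))
    else mlp_prob(m, X)
  }, numeric(nrow(X)))
}

#' Predict frame labels with a two-stage model
#'
#' Frames gated negative by C1 are Normal and never reach C2. Gated-positive
#' frames receive every label whose C2 score is at least `cutoff`; when no
#' score clears the cutoff, the single highest-scoring label is assigned, so
#' a gated-positive frame is never left label-less.
#'
#' @param object a `two_stage_model`.
#' @param features feature matrix with the training column layout.
#' @param cutoff per-label decision threshold (default 0.5).
#' @param ... unused.
#' @return `n x 5` one-hot label matrix.
#' @export
predict.two_stage_model <- function(object, features, cutoff = 0.5, ...) {
  features <- as.matrix(features)
  if (!is.null(object$feature_names) &&
      !identical(colnames(features), object$feature_names))
    stop("feature columns do not match the training layout")
  n <- nrow(features)
  out <- matrix(0L, n, N_LABELS, dimnames = list(NULL, LABEL_NAMES))
  gate <- mlp_prob(object$c1, features) >= 0.5
  out[!gate, 5L] <- 1L
  if (any(gate)) {
    sc <- c2_scores(object, features[gate, , drop = FALSE])
    if (is.null(dim(sc))) sc <- matrix(sc, nrow = 1L)
    pick <- sc >= cutoff
    none <- rowSums(pick) == 0L
    if (any(none))
      pick[cbind(which(none), max.col(sc[none, , drop = FALSE]))] <- TRUE
    out[gate, 1:4] <- pick * 1L
  }
  out
}
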