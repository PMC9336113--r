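#' Rule thresholds for the rule-based classifier
#'
#' One threshold per compensation rule, in the unit of the variable the rule
#' watches: degrees for angular variables, baseline-spine body units for
#' displacements, and relative area for head-area changes. `eps_eq` and
#' `eps_gg` make the frontal-scenario two-shoulder rule concrete: with both
#' shoulder angles above `th_SE`, a difference within `eps_eq` reads as pure
#' trunk rotation, a difference of at least `eps_gg` as rotation plus
#' shoulder elevation, and the gap in between as rotation-dominant (label TR
#' only), so the decision is continuous in the difference.
#'
#' @param th_TF trunk-forward threshold: relative head-area change in S1,
#'   spine angle (degrees) in S2/S3.
#' @param th_TR trunk-rotation threshold: shoulder x displacement (S2) or
#'   absolute chest-length change (S3), body units.
#' @param th_SE shoulder-elevation threshold: shoulder angle (degrees) in S1,
#'   shoulder y displacement (body units) in S2/S3.
#' @param th_O trunk-tilt angle threshold (degrees), S1.
#' @param th_TI absolute relative head-size change threshold, S2/S3.
#' @param eps_eq tolerance (degrees) under which the two shoulder angles are
#'   considered equal.
#' @param eps_gg margin (degrees) beyond which the affected shoulder is
#'   considered to clearly dominate; must exceed `eps_eq`.
#' @return a `threshold_set`.
#' @export
threshold_set <- function(th_TF, th_TR, th_SE, th_O, th_TI,
                          eps_eq = 5, eps_gg = 15) {
  th <- list(th_TF = th_TF, th_TR = th_TR, th_SE = th_SE, th_O = th_O,
             th_TI = th_TI, eps_eq = eps_eq, eps_gg = eps_gg)
  if (any(unlist(th) < 0)) stop("all thresholds must be >= 0")
  if (eps_gg <= eps_eq) stop("eps_gg must exceed eps_eq")
  structure(th, class = "threshold_set")
}

#' Default thresholds per positioning scenario
#'
#' Defaults calibrated on the synthetic benchmark geometry (see the methods
#' vignette): large enough that smoothed pixel noise at realistic levels
#' never crosses them, small enough that a compensation of twice the
#' threshold is comfortably inside the detected range. All values are exposed
#' so detection sensitivity can be adjusted per patient or exercise.
#'
#' @param scenario "S1", "S2" or "S3".
#' @return a [threshold_set()].
#' @export
default_thresholds <- function(scenario) {
  scenario <- match.arg(scenario, SCENARIOS)
  if (scenario == "S1") {
    threshold_set(th_TF = 0.20, th_TR = 10, th_SE = 10, th_O = 10,
                  th_TI = 0.20, eps_eq = 5, eps_gg = 15)
  } else {
    threshold_set(th_TF = 5, th_TR = 0.10, th_SE = 0.10, th_O = 5,
                  th_TI = 0.20, eps_eq = 5, eps_gg = 15)
  }
}

#' Classify one frontal-view (S1) frame
#'
#' Independent rules, evaluated as a union (several compensations can be
#' active in one frame):
#' * head area: change above `th_TF` adds TF (0); below `-th_TF` adds the
#'   trunk-backward pattern, label O (3);
#' * shoulders: with (1) the affected and (2) the unaffected shoulder angle,
#'   (1) above `th_SE` alone adds SE (2); both above `th_SE` adds TR (1), and
#'   additionally SE when (1) - (2) is at least `eps_gg`;
#' * trunk tilt above `th_O` adds O (3).
#'
#' An empty union is the exclusive Normal label (4).
#'
#' @param vars named list/row with `head_area_change`,
#'   `shoulder_angle_affected`, `shoulder_angle_unaffected`,
#'   `trunk_tilt_angle`.
#' @param th a [threshold_set()].
#' @return integer vector of active labels (subset of 0:3; empty = Normal).
#' @export
classify_frame_s1 <- function(vars, th) {
  need <- c("head_area_change", "shoulder_angle_affected",
            "shoulder_angle_unaffected", "trunk_tilt_angle")
  miss <- setdiff(need, names(vars))
  if (length(miss)) stop("missing S1 variable(s): ", paste(miss, collapse = ", "))
  lab <- integer(0)
  dH <- vars[["head_area_change"]]
  if (dH > th$th_TF) lab <- c(lab, 0L)
  if (dH < -th$th_TF) lab <- c(lab, 3L)
  a1 <- vars[["shoulder_angle_affected"]]
  a2 <- vars[["shoulder_angle_unaffected"]]
  if (a1 > th$th_SE && a2 < th$th_SE) {
    lab <- c(lab, 2L)
  } else if (a1 > th$th_SE && a2 > th$th_SE) {
    if (a1 - a2 >= th$eps_gg) lab <- c(lab, 1L, 2L) else lab <- c(lab, 1L)
  }
  if (vars[["trunk_tilt_angle"]] > th$th_O) lab <- c(lab, 3L)
  sort(unique(lab))
}

#' Classify one side-view (S2/S3) frame
#'
#' * trunk forward/backward: spine angle above `th_TF`, with the sign of the
#'   shoulder-to-neck x displacement deciding forward (TF, 0) vs backward
#'   (O, 3);
#' * trunk rotation: shoulder x displacement above `th_TR` (S2) or absolute
#'   chest-length change above `th_TR` (S3) adds TR (1);
#' * shoulder elevation: shoulder y displacement above `th_SE` adds SE (2);
#' * trunk tilt: absolute head-size change above `th_TI` adds O (3).
#'
#' @param vars named list/row with `spine_angle`, `shoulder_x_disp`,
#'   `shoulder_y_disp`, `chest_len_change`, `head_size_change`.
#' @param th a [threshold_set()].
#' @param scenario "S2" or "S3".
#' @return integer vector of active labels (subset of 0:3; empty = Normal).
#' @export
classify_frame_s2s3 <- function(vars, th, scenario) {
  if (!scenario %in% c("S2", "S3"))
    stop("classify_frame_s2s3 handles scenarios S2 and S3 only")
  need <- c("spine_angle", "shoulder_x_disp", "shoulder_y_disp",
            "chest_len_change", "head_size_change")
  miss <- setdiff(need, names(vars))
  if (length(miss)) stop("missing variable(s): ", paste(miss, collapse = ", "))
  lab <- integer(0)
  if (vars[["spine_angle"]] > th$th_TF) {
    if (vars[["shoulder_x_disp"]] > 0) lab <- c(lab, 0L)
    if (vars[["shoulder_x_disp"]] < 0) lab <- c(lab, 3L)
  }
  tr_var <- if (scenario == "S2") vars[["shoulder_x_disp"]] else vars[["chest_len_change"]]
  if (tr_var > th$th_TR) lab <- c(lab, 1L)
  if (vars[["shoulder_y_disp"]] > th$th_SE) lab <- c(lab, 2L)
  if (vars[["head_size_change"]] > th$th_TI) lab <- c(lab, 3L)
  sort(unique(lab))
}

#' Rule-based multilabel classification of a kinematic series
#'
#' Applies the per-frame rules of the active scenario independently to every
#' frame (no temporal smoothing of labels; the variables themselves are
#' already smoothed). The output is a pure function of the variables and the
#' thresholds.
#'
#' @param series a `kinematic_series` from [compute_kinematics()].
#' @param th a [threshold_set()]; defaults to the scenario's
#'   [default_thresholds()].
#' @return an `n x 5` one-hot label matrix (see [as_label_matrix()]).
#' @export
rb_classify <- function(series, th = NULL) {
  scenario <- attr(series, "scenario")
  if (is.null(scenario)) stop("series lacks a scenario attribute")
  if (is.null(th)) th <- default_thresholds(scenario)
  classify <- if (scenario == "S1") {
    function(row) classify_frame_s1(row, th)
  } else {
    function(row) classify_frame_s2s3(row, th, scenario)
  }
  sets <- lapply(seq_len(nrow(series)), function(i) classify(as.list(series[i, ])))
  as_label_matrix(sets)
}

#' End-to-end rule-based assessment of a cleaned sequence
#'
#' Convenience wrapper: normalize (no mirror), compute the kinematic
#' variables, classify.
#'
#' @param seq a cleaned single-skeleton [pose_sequence()].
#' @param th a [threshold_set()] or NULL for scenario defaults.
#' @param smooth_window odd smoothing window (frames).
#' @return an `n x 5` one-hot label matrix.
#' @export
rb_assess <- function(seq, th = NULL, smooth_window = 5L) {
  nseq <- normalize_sequence(seq, mirror = FALSE)
  rb_classify(compute_kinematics(nseq, smooth_window = smooth_window), th)
}
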