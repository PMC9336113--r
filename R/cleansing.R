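#' Cleansing configuration
#'
#' Keypoint-quality rules applied before any kinematic analysis. A frame is
#' kept only if every *relevant* joint was detected with confidence strictly
#' above `s_min_relevant` and every remaining joint with confidence above
#' zero. The default relevant set is the affected-side shoulder/elbow/wrist,
#' the opposite shoulder, and the spine joints (Nose, Neck, MidHip); it is
#' configurable because different exercises may watch different joints.
#'
#' @param s_min_relevant confidence threshold for relevant joints (default
#'   0.36; the comparison is strict, `s > 0.36`).
#' @param relevant_joints integer vector of 0-based BODY_25 ids, or NULL to
#'   derive the default set from the sequence's affected side.
#' @return a `cleansing_config` object.
#' @export
cleansing_config <- function(s_min_relevant = 0.36, relevant_joints = NULL) {
  if (s_min_relevant < 0 || s_min_relevant > 1)
    stop("s_min_relevant must lie in [0, 1]")
  if (!is.null(relevant_joints) && any(!relevant_joints %in% 0:24))
    stop("relevant_joints must be BODY_25 ids (0-24)")
  structure(list(s_min_relevant = s_min_relevant,
                 relevant_joints = relevant_joints),
            class = "cleansing_config")
}

default_relevant_joints <- function(affected_side) {
  aff <- side_joints(affected_side)
  opp <- side_joints(other_side(affected_side))
  sort(c(0L, 1L, 8L, aff$shoulder, aff$elbow, aff$wrist, opp$shoulder))
}

#' Remove ghost skeletons from a frame
#'
#' Spurious extra skeletons emitted by the pose detector typically lack the
#' spine joints: a skeleton is a ghost when its Nose, Neck *and* MidHip all
#' have zero confidence, and only then. Surviving skeletons are untouched.
#'
#' @param frame a [frame_observation()].
#' @return the frame with ghost skeletons removed.
#' @export
remove_ghost_skeletons <- function(frame) {
  stopifnot(inherits(frame, "frame_observation"))
  keep <- vapply(frame$skeletons, function(sk) {
    any(sk[jrow(c(0L, 1L, 8L)), "s"] > 0)
  }, logical(1))
  frame$skeletons <- frame$skeletons[keep]
  frame
}

#' Select the patient among several skeletons
#'
#' In a multi-person frame (e.g. patient plus caregiver) the patient is the
#' person closest to the image centre, measured by the Euclidean distance of
#' the MidHip keypoint to the centre. Exact ties go to the lower person index.
#'
#' @param frame a [frame_observation()] (run [remove_ghost_skeletons()] first).
#' @return the selected [skeleton()].
#' @export
select_patient <- function(frame) {
  stopifnot(inherits(frame, "frame_observation"))
  if (length(frame$skeletons) == 0L)
    stop("no patient: frame ", frame$t, " has no skeletons")
  centre <- frame$image_size / 2
  d <- vapply(frame$skeletons, function(sk) {
    sqrt(sum((sk[jrow(8L), c("x", "y")] - centre)^2))
  }, numeric(1))
  frame$skeletons[[which.min(d)]]
}

#' Filter frames by keypoint confidence
#'
#' Applies the keep rule of [cleansing_config()] to a sequence whose frames
#' each hold a single patient skeleton, returning the surviving sub-sequence
#' and exact counts. The operation is idempotent.
#'
#' @param seq a single-skeleton [pose_sequence()].
#' @param cfg a [cleansing_config()].
#' @return `list(sequence, report)` where `report` is a `cleansing_report`.
#' @export
filter_frames <- function(seq, cfg = cleansing_config()) {
  stopifnot(inherits(seq, "pose_sequence"))
  rel <- cfg$relevant_joints
  if (is.null(rel)) rel <- default_relevant_joints(seq$affected_side)
  keep <- vapply(seq$frames, function(f) {
    if (length(f$skeletons) != 1L)
      stop("filter_frames expects one skeleton per frame (frame ", f$t, ")")
    s <- f$skeletons[[1]][, "s"]
    all(s[jrow(rel)] > cfg$s_min_relevant) && all(s[-jrow(rel)] > 0)
  }, logical(1))
  out <- seq
  out$frames <- seq$frames[keep]
  rep <- cleansing_report(frames_in = length(seq$frames),
                          frames_kept = sum(keep),
                          skeletons_removed = 0L,
                          frames_dropped_low_confidence = sum(!keep),
                          corrected_keypoints = 0L)
  list(sequence = out, report = rep)
}

cleansing_report <- function(frames_in, frames_kept, skeletons_removed,
                             frames_dropped_low_confidence, corrected_keypoints) {
  r <- list(frames_in = as.integer(frames_in),
            frames_kept = as.integer(frames_kept),
            skeletons_removed = as.integer(skeletons_removed),
            frames_dropped_low_confidence = as.integer(frames_dropped_low_confidence),
            corrected_keypoints = as.integer(corrected_keypoints))
  stopifnot(r$frames_kept <= r$frames_in, all(unlist(r) >= 0L))
  structure(r, class = "cleansing_report")
}

#' @export
print.cleansing_report <- function(x, ...) {
  cat("<cleansing_report> ", x$frames_kept, "/", x$frames_in, " frames kept; ",
      x$skeletons_removed, " skeleton(s) removed; ",
      x$frames_dropped_low_confidence, " frame(s) dropped (low confidence); ",
      x$corrected_keypoints, " keypoint(s) corrected\n", sep = "")
  invisible(x)
}

#' Replace individual keypoint coordinates
#'
#' Programmatic stand-in for manual keypoint correction: each row of
#' `corrections` names a (frame, joint) pair and the new pixel coordinates.
#' Confidences are preserved. Unknown (t, joint) pairs are an error.
#'
#' @param seq a single-skeleton [pose_sequence()].
#' @param corrections data.frame with columns `t`, `joint_id`, `x`, `y`.
#' @return the corrected sequence.
#' @export
correct_keypoints <- function(seq, corrections) {
  stopifnot(inherits(seq, "pose_sequence"))
  if (nrow(corrections) == 0L) return(seq)
  need <- c("t", "joint_id", "x", "y")
  if (!all(need %in% names(corrections)))
    stop("corrections need columns t, joint_id, x, y")
  ts <- vapply(seq$frames, `[[`, integer(1), "t")
  for (i in seq_len(nrow(corrections))) {
    ci <- corrections[i, ]
    k <- match(ci$t, ts)
    if (is.na(k)) stop("no frame with t = ", ci$t)
    if (!ci$joint_id %in% 0:24) stop("unknown joint_id ", ci$joint_id)
    if (length(seq$frames[[k]]$skeletons) != 1L)
      stop("correct_keypoints expects one skeleton per frame (frame ", ci$t, ")")
    seq$frames[[k]]$skeletons[[1]][jrow(ci$joint_id), c("x", "y")] <-
      c(ci$x, ci$y)
  }
  seq
}

#' Full cleansing pipeline
#'
#' Runs, in order: ghost-skeleton removal, patient selection (frames left with
#' no skeleton are dropped and counted with the low-confidence drops),
#' optional keypoint corrections, and the confidence filter. The result holds
#' exactly one patient skeleton per kept frame.
#'
#' @inheritParams filter_frames
#' @param corrections optional data.frame for [correct_keypoints()].
#' @return `list(sequence, report)`.
#' @export
cleanse_sequence <- function(seq, cfg = cleansing_config(), corrections = NULL) {
  stopifnot(inherits(seq, "pose_sequence"))
  frames_in <- length(seq$frames)
  removed <- 0L
  frames <- vector("list", frames_in)
  has_patient <- logical(frames_in)
  for (i in seq_along(seq$frames)) {
    f <- remove_ghost_skeletons(seq$frames[[i]])
    removed <- removed + (length(seq$frames[[i]]$skeletons) - length(f$skeletons))
    if (length(f$skeletons) >= 1L) {
      extra <- length(f$skeletons) - 1L
      f$skeletons <- list(select_patient(f))
      removed <- removed + extra
      has_patient[i] <- TRUE
    }
    frames[[i]] <- f
  }
  seq$frames <- frames[has_patient]
  ncorr <- 0L
  if (!is.null(corrections) && nrow(corrections) > 0L) {
    seq <- correct_keypoints(seq, corrections)
    ncorr <- nrow(corrections)
  }
  flt <- filter_frames(seq, cfg)
  rep <- cleansing_report(
    frames_in = frames_in,
    frames_kept = flt$report$frames_kept,
    skeletons_removed = removed,
    frames_dropped_low_confidence = frames_in - flt$report$frames_kept,
    corrected_keypoints = ncorr)
  list(sequence = flt$sequence, report = rep)
}
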