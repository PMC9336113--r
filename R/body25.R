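#' The OpenPose BODY_25 keypoint layout
#'
#' Joint ids (0-based, as emitted by OpenPose) and names of the 25-keypoint
#' body model. Id 0 is the Nose, 1 the Neck, 2/5 the right/left shoulders and
#' 8 the MidHip; sides are anatomical (the subject's right, not the viewer's).
#'
#' @return A data.frame with columns `id` (integer, 0-24) and `name`.
#' @examples
#' body25_joints()[1:9, ]
#' @export
body25_joints <- function() {
  data.frame(id = 0:24, name = BODY25_NAMES, stringsAsFactors = FALSE)
}

BODY25_NAMES <- c(
  "Nose", "Neck", "RShoulder", "RElbow", "RWrist",
  "LShoulder", "LElbow", "LWrist", "MidHip", "RHip",
  "RKnee", "RAnkle", "LHip", "LKnee", "LAnkle",
  "REye", "LEye", "REar", "LEar", "LBigToe",
  "LSmallToe", "LHeel", "RBigToe", "RSmallToe", "RHeel")

#' Resolve BODY_25 joint names to 0-based ids
#'
#' @param name character vector of joint names (see [body25_joints()]).
#' @return integer vector of 0-based joint ids.
#' @export
body25_id <- function(name) {
  idx <- match(name, BODY25_NAMES)
  if (anyNA(idx)) {
    stop("unknown BODY_25 joint name(s): ",
         paste(name[is.na(idx)], collapse = ", "))
  }
  idx - 1L
}

# 1-based matrix row for a 0-based joint id.
jrow <- function(id) id + 1L

# Side-resolved joint ids (0-based). `side` is the anatomical side.
side_joints <- function(side) {
  side <- match.arg(side, c("left", "right"))
  if (side == "right") {
    list(shoulder = 2L, elbow = 3L, wrist = 4L, hip = 9L, eye = 15L, ear = 17L)
  } else {
    list(shoulder = 5L, elbow = 6L, wrist = 7L, hip = 12L, eye = 16L, ear = 18L)
  }
}

other_side <- function(side) if (side == "left") "right" else "left"

# Joints used for the head-area model by default.
HEAD_JOINT_IDS <- c(0L, 15L, 16L, 17L, 18L)  # Nose, REye, LEye, REar, LEar
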