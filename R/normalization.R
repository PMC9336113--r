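#' Normalize a cleaned sequence into the spine-scaled body frame
#'
#' Three steps, applied to every frame of a single-skeleton sequence:
#'
#' 1. *Transformation* — each keypoint is translated so that the frame's
#'    MidHip becomes the origin of the body frame, and the y axis is flipped
#'    to up-positive (image coordinates are down-positive; with y up,
#'    "shoulder elevation" means increasing y).
#' 2. *Normalization* — all coordinates are divided by the baseline spine
#'    length, the Neck-MidHip distance measured at the first kept frame, so
#'    body-part dimensions cancel; at that frame the Neck sits at distance 1
#'    from the origin.
#' 3. *Mirror* (optional, for classifier features only) — if the affected-side
#'    shoulder lies in the negative-x half-plane, all x coordinates are
#'    negated so the affected limb is always on the positive-x side and the
#'    healthy side serves as the reference. The rule-based path never mirrors,
#'    since each of its variables is already relative to a reference joint.
#'
#' The transformation is translation-only; an optional rotation that aligns
#' the baseline spine with the +y axis can be switched on with `rotate`.
#'
#' @param seq a cleaned single-skeleton [pose_sequence()].
#' @param mirror logical; apply the mirror step (neural-network features).
#' @param rotate logical; also rotate so the baseline spine is vertical
#'   (off by default).
#' @return a `normalized_sequence`: list with `frames` (list of 25 x 3
#'   matrices in body units, confidences preserved), `t`, the sequence
#'   metadata, `spine_len_ref` (pixels), `mirrored` and `facing` (+1 when the
#'   nose points towards +x at baseline, -1 otherwise).
#' @export
normalize_sequence <- function(seq, mirror = FALSE, rotate = FALSE) {
  stopifnot(inherits(seq, "pose_sequence"))
  if (length(seq$frames) == 0L) stop("empty sequence")
  body <- lapply(seq$frames, function(f) {
    if (length(f$skeletons) != 1L)
      stop("normalize_sequence expects one skeleton per frame (frame ", f$t, ")")
    to_body_frame(f$skeletons[[1]])
  })
  base <- body[[1]]
  spine_ref <- sqrt(sum(base[jrow(1L), c("x", "y")]^2))
  if (spine_ref <= 0)
    stop("degenerate pose: zero spine length at the baseline frame")
  if (rotate) {
    # rotate every frame so the *baseline* spine direction maps to +y
    sp <- base[jrow(1L), c("x", "y")]
    th <- atan2(sp[1], sp[2])            # angle of spine from +y
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
    body <- lapply(body, function(m) {
      m[, c("x", "y")] <- m[, c("x", "y")] %*% t(R)
      m
    })
  }
  body <- lapply(body, function(m) {
    m[, c("x", "y")] <- m[, c("x", "y")] / spine_ref
    m
  })
  out <- structure(list(frames = body,
                        t = vapply(seq$frames, `[[`, integer(1), "t"),
                        fps = seq$fps, subject_id = seq$subject_id,
                        exercise_id = seq$exercise_id, scenario = seq$scenario,
                        affected_side = seq$affected_side,
                        spine_len_ref = spine_ref, mirrored = FALSE,
                        facing = local({
                          dx <- body[[1]][jrow(0L), "x"] - body[[1]][jrow(1L), "x"]
                          if (dx < 0) -1 else 1
                        })),
                   class = "normalized_sequence")
  if (mirror) out <- mirror_to_reference(out)
  out
}

#' Translate one skeleton to the body frame
#'
#' Subtracts the MidHip position from every joint and flips the y axis to
#' up-positive. Confidences are untouched. Errors if the MidHip was not
#' detected.
#'
#' @param skel a [skeleton()] in image coordinates.
#' @return a 25 x 3 matrix (x, y, s) with the MidHip at the origin, y up.
#' @export
to_body_frame <- function(skel) {
  stopifnot(inherits(skel, "skeleton") || (is.matrix(skel) && all(dim(skel) == c(25L, 3L))))
  if (skel[jrow(8L), "s"] <= 0)
    stop("MidHip not detected; cannot define the body frame")
  origin <- skel[jrow(8L), c("x", "y")]
  m <- unclass(skel)
  m[, "x"] <- m[, "x"] - origin[1]
  m[, "y"] <- -(m[, "y"] - origin[2])   # image y is down-positive
  m
}

#' Mirror a normalized sequence so the affected side is at positive x
#'
#' Applied only for the neural-network feature path. If the affected-side
#' shoulder's mean x coordinate is negative, every x coordinate in the
#' sequence is negated; otherwise the sequence is returned unchanged. Either
#' way `mirrored` is set, and applying the operation twice is the identity.
#'
#' @param nseq a `normalized_sequence`.
#' @param affected_side override for the sequence's affected side.
#' @return the (possibly reflected) `normalized_sequence` with
#'   `mirrored = TRUE`.
#' @export
mirror_to_reference <- function(nseq, affected_side = nseq$affected_side) {
  stopifnot(inherits(nseq, "normalized_sequence"))
  sh <- side_joints(affected_side)$shoulder
  mean_x <- mean(vapply(nseq$frames, function(m) m[jrow(sh), "x"], numeric(1)))
  if (mean_x < 0) {
    nseq$frames <- lapply(nseq$frames, function(m) {
      m[, "x"] <- -m[, "x"]
      m
    })
    nseq$facing <- -nseq$facing
  }
  nseq$mirrored <- TRUE
  nseq
}

#' Centred moving-average smoothing
#'
#' Moving average with an odd, centred window; at the series edges the window
#' shrinks to the available samples, so constants are preserved everywhere.
#'
#' @param x numeric vector.
#' @param window odd window length in frames (default 5).
#' @return smoothed numeric vector of the same length.
#' @examples
#' smooth_series(c(0, 0, 5, 0, 0))  # centre value 1
#' @export
smooth_series <- function(x, window = 5L) {
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop("window must be a positive integer")
  if (window %% 2L == 0L) stop("window must be odd")
  n <- length(x)
  if (n == 0L || window == 1L) return(x)
  h <- (window - 1L) %/% 2L
  # direct windowed mean: constant series come back bit-identical
  vapply(seq_len(n), function(i) mean(x[max(1L, i - h):min(n, i + h)]),
         numeric(1))
}
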