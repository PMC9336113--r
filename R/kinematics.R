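#' Geometric primitives on 2D joints
#'
#' `angle_between(j1, j2, j3)` is the angle, in degrees, between the vectors
#' from `j2` to `j1` and from `j2` to `j3` (vertex at `j2`): the arc cosine of
#' the normalized dot product, clamped to \[-1, 1\], so the result lies in
#' \[0, 180\]. A zero-length vector is a degenerate-geometry error.
#' `joint_displacement` returns the per-axis differences `j1 - j2` and
#' `joint_distance` the Euclidean distance.
#'
#' @param j1,j2,j3 numeric length-2 points (x, y).
#' @return `angle_between`: degrees in \[0, 180\]; `joint_displacement`:
#'   named vector `c(dx, dy)`; `joint_distance`: a length.
#' @examples
#' angle_between(c(0, 1), c(0, 0), c(1, 0))  # 90
#' joint_distance(c(3, 4), c(0, 0))          # 5
#' @export
angle_between <- function(j1, j2, j3) {
  u <- as.numeric(j1[1:2]) - as.numeric(j2[1:2])
  v <- as.numeric(j3[1:2]) - as.numeric(j2[1:2])
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("degenerate geometry: zero-length vector in angle_between()")
  c_ <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, c_))) * 180 / pi
}

#' @rdname angle_between
#' @export
joint_displacement <- function(j1, j2) {
  c(dx = as.numeric(j1[1]) - as.numeric(j2[1]),
    dy = as.numeric(j1[2]) - as.numeric(j2[2]))
}

#' @rdname angle_between
#' @export
joint_distance <- function(j1, j2) {
  sqrt(sum((as.numeric(j1[1:2]) - as.numeric(j2[1:2]))^2))
}

#' Head-area model
#'
#' The head "size" observed in the image shrinks or grows as the patient
#' leans away from or towards the camera, so its relative change tracks
#' forward/backward trunk motion in the frontal view and trunk tilt in the
#' side views. The pose model gives no head outline, so the area is defined
#' here as the convex-hull area (shoelace formula) over the detected head
#' keypoints — by default Nose, both eyes and both ears. When fewer than 3
#' usable points remain, the squared inter-eye distance is used as a fallback
#' area proxy (it scales like an area); with the fallback disabled, a
#' degenerate configuration yields area 0 with a warning.
#'
#' @param joints 0-based BODY_25 ids to use for the hull.
#' @param fallback logical; allow the squared inter-eye distance fallback.
#' @return a `head_model` object.
#' @export
head_model <- function(joints = HEAD_JOINT_IDS, fallback = TRUE) {
  if (any(!joints %in% 0:24)) stop("head model joints must be BODY_25 ids")
  structure(list(joints = as.integer(joints), fallback = isTRUE(fallback),
                 area = "convex-hull"),
            class = "head_model")
}

#' Head area of one skeleton
#'
#' @param skel 25 x 3 keypoint matrix (any frame: image or body coordinates;
#'   the area unit is the square of the coordinate unit).
#' @param model a [head_model()].
#' @return scalar area.
#' @export
head_area <- function(skel, model = head_model()) {
  pts <- skel[jrow(model$joints), c("x", "y"), drop = FALSE]
  pts <- pts[skel[jrow(model$joints), "s"] > 0, , drop = FALSE]
  if (nrow(pts) < 2L) stop("head area needs at least 2 detected head points")
  a <- 0
  if (nrow(pts) >= 3L) {
    hull <- grDevices::chull(pts)
    hp <- pts[hull, , drop = FALSE]
    xs <- hp[, 1]; ys <- hp[, 2]
    a <- abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
  }
  if (a == 0) {
    if (model$fallback) {
      eyes <- jrow(c(15L, 16L))
      if (all(skel[eyes, "s"] > 0))
        return(joint_distance(skel[eyes[1], ], skel[eyes[2], ])^2)
    }
    warning("degenerate head geometry: collinear points, area 0")
  }
  a
}

# Angle between baseline and current position of a moving joint, seen from a
# fixed vertex; 0 when the joint has not moved (the formula's own baseline).
angle_from_baseline <- function(vertex, p_base, p_now) {
  if (joint_distance(p_base, p_now) < 1e-12) return(0)
  angle_between(p_base, vertex, p_now)
}

#' Per-frame kinematic variables of a normalized sequence
#'
#' Computes the scenario's kinematic variable set against the `t = 1`
#' baseline (the first kept frame), then smooths every series with a centred
#' moving average.
#'
#' Frontal scenario (S1):
#' * `head_area_change` — relative head-area change (H_t - H_1) / H_1; grows
#'   when the patient leans towards the camera (trunk forward), shrinks when
#'   leaning back.
#' * `shoulder_angle_affected`, `shoulder_angle_unaffected` — angular
#'   displacement of each shoulder about the baseline neck: simultaneous rise
#'   of both signals trunk rotation, an isolated rise of the affected one
#'   shoulder elevation.
#' * `trunk_tilt_angle` — angle between the baseline and current spine
#'   (MidHip-to-Neck) directions, i.e. the lateral lean of the torso.
#'
#' Side scenarios (S2 perpendicular, S3 oblique; x displacements are oriented
#' by the facing direction so that positive means "forward"):
#' * `spine_angle` — spine angular displacement (same construction as the
#'   trunk tilt above, here the sagittal lean).
#' * `neck_x_disp` — neck displacement along x from its own baseline.
#' * `shoulder_x_disp`, `shoulder_y_disp` — affected shoulder displacement
#'   relative to the neck.
#' * `chest_len_change` — absolute change of the projected shoulder-to-
#'   shoulder (chest) length, which shortens/stretches under trunk rotation.
#' * `head_size_change` — absolute relative head-area change, tracking trunk
#'   tilt towards/away from the camera.
#'
#' @param nseq an un-mirrored `normalized_sequence` (see
#'   [normalize_sequence()]).
#' @param model a [head_model()].
#' @param smooth_window odd moving-average window in frames (5 as used for
#'   kinematic-variable validation; 1 disables smoothing).
#' @return a data.frame of class `kinematic_series`: column `t` plus one
#'   column per variable; the scenario and facing sign are kept as
#'   attributes.
#' @export
compute_kinematics <- function(nseq, model = head_model(), smooth_window = 5L) {
  stopifnot(inherits(nseq, "normalized_sequence"))
  if (isTRUE(nseq$mirrored))
    stop("kinematic variables are defined on un-mirrored sequences")
  frames <- nseq$frames
  n <- length(frames)
  if (n == 0L) stop("empty sequence")
  # Baseline quantities come from the filtered keypoint signal evaluated at
  # t = 1: with a centred window the filter shrinks to the first
  # (window+1)/2 frames there, so the baseline is their mean. This keeps the
  # t = 1 reference but does not hang it on a single noisy detection.
  nb <- max(1L, min(n, (as.integer(smooth_window) + 1L) %/% 2L))
  base <- frames[[1]]
  if (nb > 1L) {
    base[, c("x", "y")] <-
      Reduce(`+`, lapply(frames[seq_len(nb)],
                         function(m) m[, c("x", "y")])) / nb
  }
  aff <- side_joints(nseq$affected_side)$shoulder
  una <- side_joints(other_side(nseq$affected_side))$shoulder
  neck1 <- base[jrow(1L), c("x", "y")]
  origin <- c(0, 0)                     # MidHip: body-frame origin each frame
  out <- data.frame(t = nseq$t)
  H <- vapply(frames, head_area, numeric(1), model = model)
  dH <- (H - H[1]) / H[1]
  if (nseq$scenario == "S1") {
    out$head_area_change <- dH
    out$shoulder_angle_affected <- vapply(frames, function(f)
      angle_from_baseline(neck1, base[jrow(aff), c("x", "y")],
                          f[jrow(aff), c("x", "y")]), numeric(1))
    out$shoulder_angle_unaffected <- vapply(frames, function(f)
      angle_from_baseline(neck1, base[jrow(una), c("x", "y")],
                          f[jrow(una), c("x", "y")]), numeric(1))
    out$trunk_tilt_angle <- vapply(frames, function(f)
      angle_from_baseline(origin, neck1, f[jrow(1L), c("x", "y")]), numeric(1))
  } else {
    facing <- nseq$facing
    out$spine_angle <- vapply(frames, function(f)
      angle_from_baseline(origin, neck1, f[jrow(1L), c("x", "y")]), numeric(1))
    out$neck_x_disp <- facing * vapply(frames, function(f)
      f[jrow(1L), "x"] - neck1[1], numeric(1))
    out$shoulder_x_disp <- facing * vapply(frames, function(f)
      f[jrow(aff), "x"] - f[jrow(1L), "x"], numeric(1))
    out$shoulder_y_disp <- vapply(frames, function(f)
      f[jrow(aff), "y"] - f[jrow(1L), "y"], numeric(1))
    chest1 <- joint_distance(base[jrow(2L), ], base[jrow(5L), ])
    out$chest_len_change <- vapply(frames, function(f)
      abs(joint_distance(f[jrow(2L), ], f[jrow(5L), ]) - chest1), numeric(1))
    out$head_size_change <- abs(dH)
  }
  for (v in setdiff(names(out), "t"))
    out[[v]] <- smooth_series(out[[v]], smooth_window)
  structure(out, scenario = nseq$scenario, facing = nseq$facing,
            affected_side = nseq$affected_side,
            class = c("kinematic_series", "data.frame"))
}
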