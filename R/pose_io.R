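#' Construct a single-person skeleton
#'
#' A skeleton is a 25 x 3 numeric matrix with columns `x`, `y`, `s` (detection
#' confidence in \[0, 1\]) and one row per BODY_25 joint, in id order. Image
#' coordinates are kept exactly as read: pixels, origin top-left, y downward.
#' The triple (0, 0, 0) encodes an undetected joint.
#'
#' @param xys numeric 25 x 3 matrix or a flat length-75 vector in OpenPose
#'   order (x1, y1, s1, x2, ...).
#' @return a `skeleton` object.
#' @export
skeleton <- function(xys) {
  if (is.numeric(xys) && is.null(dim(xys))) {
    if (length(xys) != 75L) stop("flat keypoint vector must have length 75")
    xys <- matrix(xys, ncol = 3L, byrow = TRUE)
  }
  if (!is.matrix(xys) || nrow(xys) != 25L || ncol(xys) != 3L)
    stop("a skeleton is a 25 x 3 matrix (x, y, s)")
  m <- matrix(as.numeric(xys), 25L, 3L,
              dimnames = list(BODY25_NAMES, c("x", "y", "s")))
  if (any(!is.finite(m))) stop("skeleton coordinates must be finite")
  if (any(m[, "s"] < 0 | m[, "s"] > 1))
    stop("confidence scores must lie in [0, 1]")
  structure(m, class = c("skeleton", "matrix", "array"))
}

#' Construct a single-frame observation
#'
#' @param t frame number (1-based, integer-valued).
#' @param skeletons list of [skeleton()] objects (possibly empty).
#' @param image_size integer vector `c(width, height)` in pixels.
#' @return a `frame_observation` object.
#' @export
frame_observation <- function(t, skeletons = list(), image_size = c(640L, 480L)) {
  t <- as.integer(t)
  if (is.na(t) || t < 1L) stop("frame number t must be >= 1")
  if (!is.list(skeletons)) stop("`skeletons` must be a list")
  skeletons <- lapply(skeletons, function(s)
    if (inherits(s, "skeleton")) s else skeleton(s))
  if (length(image_size) != 2L || any(image_size <= 0))
    stop("image_size must be c(width, height), both positive")
  structure(list(t = t, skeletons = skeletons,
                 image_size = as.numeric(image_size)),
            class = "frame_observation")
}

SCENARIOS <- c("S1", "S2", "S3")
EXERCISES <- c("E1", "E2", "E3")

# Camera scenario compatible with each exercise: frontal for E1/E2, side
# (perpendicular or oblique) for the cane exercise E3.
exercise_scenarios <- function(exercise) {
  switch(exercise, E1 = "S1", E2 = "S1", E3 = c("S2", "S3"),
         stop("unknown exercise: ", exercise))
}

#' Construct a raw keypoint sequence
#'
#' Time-ordered frame observations plus the trial metadata every downstream
#' step needs: frame rate, subject and exercise ids, the camera positioning
#' scenario (S1 frontal, S2 affected side perpendicular to the camera, S3
#' oblique) and which body side is affected. Frame numbers must be strictly
#' increasing and the scenario must be compatible with the exercise (E1 and E2
#' are performed facing the camera, S1; E3 from the side, S2 or S3).
#'
#' @param frames list of [frame_observation()] objects.
#' @param fps frames per second.
#' @param subject_id,exercise_id subject identifier and exercise ("E1".."E3").
#' @param scenario positioning scenario, one of "S1", "S2", "S3".
#' @param affected_side "left" or "right".
#' @return a `pose_sequence` object.
#' @export
pose_sequence <- function(frames, fps, subject_id, exercise_id, scenario,
                          affected_side) {
  if (!is.list(frames) || !all(vapply(frames, inherits, TRUE, "frame_observation")))
    stop("`frames` must be a list of frame_observation objects")
  ts <- vapply(frames, `[[`, integer(1), "t")
  if (length(ts) && any(diff(ts) <= 0L))
    stop("frame numbers must be strictly increasing")
  if (!is.numeric(fps) || fps <= 0) stop("fps must be positive")
  if (!scenario %in% SCENARIOS)
    stop("unknown scenario: ", scenario, " (expected S1, S2 or S3)")
  if (!exercise_id %in% EXERCISES)
    stop("unknown exercise: ", exercise_id)
  if (!scenario %in% exercise_scenarios(exercise_id))
    stop("scenario ", scenario, " is not valid for exercise ", exercise_id)
  affected_side <- match.arg(affected_side, c("left", "right"))
  structure(list(frames = frames, fps = as.numeric(fps),
                 subject_id = as.character(subject_id),
                 exercise_id = exercise_id, scenario = scenario,
                 affected_side = affected_side),
            class = "pose_sequence")
}

#' @export
print.pose_sequence <- function(x, ...) {
  nsk <- vapply(x$frames, function(f) length(f$skeletons), integer(1))
  cat("<pose_sequence> ", length(x$frames), " frames @ ", x$fps, " fps\n",
      "  subject ", x$subject_id, ", exercise ", x$exercise_id,
      ", scenario ", x$scenario, ", affected side: ", x$affected_side, "\n",
      "  skeletons per frame: ",
      if (length(nsk)) paste0(min(nsk), "-", max(nsk)) else "none", "\n",
      sep = "")
  invisible(x)
}

#' Parse one OpenPose BODY_25 JSON frame
#'
#' Accepts the per-frame JSON document OpenPose writes: an object with a
#' `people` array whose elements carry a flat 75-number `pose_keypoints_2d`
#' list (x, y, confidence for each of the 25 joints). Person order is
#' preserved; an empty or missing `people` array yields a frame with zero
#' skeletons. No person or joint is ever silently dropped.
#'
#' @param doc a JSON string, a path to a JSON file, or an already-parsed list.
#' @param t frame number to assign (1-based).
#' @param image_size image dimensions `c(width, height)` in pixels.
#' @return a [frame_observation()].
#' @export
parse_openpose_frame <- function(doc, t, image_size = c(640L, 480L)) {
  if (is.character(doc)) {
    doc <- jsonlite::fromJSON(doc, simplifyVector = FALSE)
  }
  if (!is.list(doc)) stop("malformed OpenPose document: not a JSON object")
  people <- doc$people
  if (is.null(people)) people <- list()
  skels <- vector("list", length(people))
  for (i in seq_along(people)) {
    kp <- unlist(people[[i]]$pose_keypoints_2d, use.names = FALSE)
    if (is.null(kp) || !is.numeric(kp) || length(kp) != 75L)
      stop("malformed pose_keypoints_2d for person ", i,
           ": expected 75 numbers, got ", length(kp))
    skels[[i]] <- skeleton(kp)
  }
  frame_observation(t, skels, image_size)
}

#' Read a directory of per-frame OpenPose JSON files
#'
#' Files are ordered by the trailing integer in their file name (the OpenPose
#' `_keypoints.json` convention); a gap in the numbering is kept as a gap in
#' the frame numbers and reported with a warning.
#'
#' @param dir directory containing one JSON document per frame.
#' @inheritParams pose_sequence
#' @param image_size image dimensions in pixels.
#' @return a [pose_sequence()].
#' @export
read_openpose_dir <- function(dir, fps, subject_id, exercise_id, scenario,
                              affected_side, image_size = c(640L, 480L)) {
  files <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  if (length(files) == 0L) stop("no JSON files found in ", dir)
  num <- suppressWarnings(as.integer(sub(".*?(\\d+)[^\\d]*\\.json$", "\\1",
                                         basename(files))))
  if (anyNA(num)) {
    # no parseable frame numbers: fall back to lexicographic order, 1..n
    ord <- order(basename(files))
    num <- seq_along(files)
  } else {
    ord <- order(num)
    num <- num[ord] - min(num[ord]) + 1L  # renumber to start at t = 1
  }
  files <- files[ord]
  if (any(diff(num) > 1L))
    warning("gap in frame numbering after frame(s) ",
            paste(num[which(diff(num) > 1L)], collapse = ", "))
  frames <- mapply(function(f, t) parse_openpose_frame(f, t, image_size),
                   files, num, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  pose_sequence(frames, fps, subject_id, exercise_id, scenario, affected_side)
}

#' Save / load the internal sequence format
#'
#' The internal format is a diff-able CSV with one row per (frame, person,
#' joint) and columns `t`, `person`, `joint_id`, `x`, `y`, `s`, plus a JSON
#' sidecar (`<path>.meta.json`) holding the sequence metadata (fps, subject,
#' exercise, scenario, affected side, image size and the full frame-number
#' list, so frames with zero skeletons survive the round trip). `save_sequence`
#' followed by `load_sequence` is the identity on all fields.
#'
#' @param seq a [pose_sequence()].
#' @param path CSV file path.
#' @return `save_sequence` returns `path` invisibly; `load_sequence` returns a
#'   [pose_sequence()].
#' @export
save_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "pose_sequence"))
  rows <- lapply(seq$frames, function(f) {
    if (length(f$skeletons) == 0L) return(NULL)
    do.call(rbind, lapply(seq_along(f$skeletons), function(p) {
      sk <- f$skeletons[[p]]
      data.frame(t = f$t, person = p, joint_id = 0:24,
                 x = sk[, "x"], y = sk[, "y"], s = sk[, "s"])
    }))
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(t = integer(0), person = integer(0), joint_id = integer(0),
                     x = numeric(0), y = numeric(0), s = numeric(0))
  utils::write.csv(df, path, row.names = FALSE)
  img <- if (length(seq$frames)) seq$frames[[1]]$image_size else c(640, 480)
  meta <- list(format = "compens2d-sequence", version = 1L,
               fps = seq$fps, subject_id = seq$subject_id,
               exercise_id = seq$exercise_id, scenario = seq$scenario,
               affected_side = seq$affected_side,
               image_size = img,
               frame_numbers = vapply(seq$frames, `[[`, integer(1), "t"))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".meta.json")

#' @rdname save_sequence
#' @export
load_sequence <- function(path) {
  mpath <- sidecar_path(path)
  if (!file.exists(mpath))
    stop("missing metadata sidecar ", mpath,
         " (scenario/affected_side are required)")
  meta <- jsonlite::fromJSON(mpath)
  for (f in c("fps", "scenario", "affected_side", "subject_id", "exercise_id"))
    if (is.null(meta[[f]])) stop("metadata sidecar lacks required field `", f, "`")
  if (!meta$scenario %in% SCENARIOS)
    stop("unknown scenario: ", meta$scenario)
  df <- utils::read.csv(path)
  need <- c("t", "person", "joint_id", "x", "y", "s")
  if (!all(need %in% names(df))) stop("sequence CSV lacks required columns")
  ts <- as.integer(meta$frame_numbers)
  if (length(ts) && any(diff(ts) > 1L))
    warning("gap in frame numbering after frame(s) ",
            paste(ts[which(diff(ts) > 1L)], collapse = ", "))
  image_size <- as.numeric(meta$image_size)
  frames <- lapply(ts, function(t) {
    sub <- df[df$t == t, , drop = FALSE]
    skels <- lapply(sort(unique(sub$person)), function(p) {
      rows <- sub[sub$person == p, , drop = FALSE]
      rows <- rows[order(rows$joint_id), , drop = FALSE]
      if (nrow(rows) != 25L)
        stop("frame ", t, " person ", p, ": expected 25 joints, got ", nrow(rows))
      skeleton(cbind(rows$x, rows$y, rows$s))
    })
    frame_observation(t, skels, image_size)
  })
  pose_sequence(frames, meta$fps, meta$subject_id, meta$exercise_id,
                meta$scenario, meta$affected_side)
}
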