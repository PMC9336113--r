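#' Synthetic subject template
#'
#' Parameters of the 2D articulated stick model used to emulate a seated
#' patient filmed by a fixed camera. The model is deliberately not a 3D
#' renderer: every classifier in the package consumes 2D keypoints, so the
#' geometry is posed directly in the image plane, per positioning scenario
#' (S1 frontal; S2 affected side perpendicular to the camera; S3 oblique —
#' side views always face +x). Isotropic Gaussian pixel noise and a
#' confidence model (constant base level with a misdetection probability
#' that draws confidences below the 0.36 cleansing threshold) are applied on
#' top of the deterministic geometry.
#'
#' @param scenario "S1", "S2" or "S3".
#' @param affected_side "left" or "right".
#' @param spine_px baseline Neck-MidHip distance in pixels.
#' @param shoulder_half frontal half shoulder width, fraction of spine.
#' @param image_size image `c(width, height)` in pixels.
#' @param fps camera frame rate.
#' @param noise_sd pixel-noise standard deviation (px, per coordinate).
#' @param conf_base confidence assigned to detected joints.
#' @param conf_dropout per-joint, per-frame probability of a misdetection
#'   (confidence drawn uniformly in \[0.05, 0.30\]).
#' @return a `subject_template`.
#' @export
subject_template <- function(scenario = "S1", affected_side = "right",
                             spine_px = 200, shoulder_half = 0.35,
                             image_size = c(640, 480), fps = 25,
                             noise_sd = 0, conf_base = 0.9,
                             conf_dropout = 0) {
  scenario <- match.arg(scenario, SCENARIOS)
  affected_side <- match.arg(affected_side, c("left", "right"))
  stopifnot(spine_px > 0, noise_sd >= 0, conf_dropout >= 0, conf_dropout <= 1,
            conf_base > 0.36, conf_base <= 1)
  structure(list(scenario = scenario, affected_side = affected_side,
                 spine_px = spine_px, shoulder_half = shoulder_half,
                 image_size = as.numeric(image_size), fps = fps,
                 noise_sd = noise_sd, conf_base = conf_base,
                 conf_dropout = conf_dropout,
                 chest_base = if (scenario == "S2") 0.04 else 0.45),
            class = "subject_template")
}

EPISODE_KINDS <- c(tf = 0L, tb = 3L, tr = 1L, se = 2L, tilt = 3L)

#' Scripted compensation episodes for one trial
#'
#' An episode injects one compensation pattern over a frame interval with a
#' linear on/off ramp. Kinds map to labels as: `tf` trunk forward (0), `tb`
#' trunk backward (3), `tr` trunk rotation (1), `se` shoulder elevation (2),
#' `tilt` trunk tilt (3). The magnitude is expressed as a multiple of the
#' matched rule threshold, so `magnitude = 2` drives the watched kinematic
#' variable to twice its detection threshold at the episode plateau — the
#' contract that makes the generator usable as a classification oracle.
#' Episodes must start at frame 4 or later so the frames forming the rest
#' baseline (the filtered keypoint signal at `t = 1` spans frames 1-3) are
#' undisturbed.
#'
#' @param n_frames trial length in frames.
#' @param episodes list of lists with fields `kind`, `start`, `end`,
#'   `magnitude` and optional `ramp` (frames, default 5).
#' @return a `compensation_script`.
#' @export
compensation_script <- function(n_frames, episodes = list()) {
  n_frames <- as.integer(n_frames)
  stopifnot(n_frames >= 2L)
  episodes <- lapply(episodes, function(e) {
    if (is.null(e$ramp)) e$ramp <- 5L
    if (!e$kind %in% names(EPISODE_KINDS)) stop("unknown episode kind: ", e$kind)
    if (e$start < 4L || e$end > n_frames || e$start > e$end)
      stop("episode [", e$start, ", ", e$end, "] outside frames 4..", n_frames)
    if (e$magnitude <= 0) stop("episode magnitude must be > 0")
    e$label <- EPISODE_KINDS[[e$kind]]
    e
  })
  structure(list(n_frames = n_frames, episodes = episodes),
            class = "compensation_script")
}

# Ramped activation profile of one episode, on 1..n (0 outside the episode,
# linear ramps of `ramp` frames inside it, 1 on the plateau).
episode_profile <- function(e, n) {
  i <- seq_len(n)
  inside <- i >= e$start & i <= e$end
  p <- numeric(n)
  p[inside] <- pmin(1, (i[inside] - e$start + 1) / e$ramp,
                    (e$end - i[inside] + 1) / e$ramp)
  p
}

# Sum of magnitude-weighted (or plain) profiles over episodes of a kind.
kind_effect <- function(script, kind, n, weighted = TRUE) {
  eff <- numeric(n)
  for (e in script$episodes) {
    if (e$kind == kind)
      eff <- eff + (if (weighted) e$magnitude else 1) * episode_profile(e, n)
  }
  eff
}

# Baseline shoulder-below-neck offset in body units (y up): used by the side
# scenarios' shoulder-elevation channel.
SH_DY_BASE <- -0.08

# Analytic, noise-free values of every rule variable the script injects, in
# the exact form (signed/absolute) the kinematics module computes before
# smoothing. These are both the blueprint for the geometry and, once
# smoothed, the ground-truth input.
synth_channels <- function(template, script, th) {
  n <- script$n_frames
  e_tf <- kind_effect(script, "tf", n)
  e_tb <- kind_effect(script, "tb", n)
  e_tr <- kind_effect(script, "tr", n)
  e_se <- kind_effect(script, "se", n)
  e_ti <- kind_effect(script, "tilt", n)
  if (template$scenario == "S1") {
    list(dH = th$th_TF * (e_tf - e_tb),
         ang_aff = th$th_SE * (e_tr + e_se),
         ang_un = th$th_SE * e_tr,
         tilt = th$th_O * e_ti)
  } else {
    p_tf <- kind_effect(script, "tf", n, weighted = FALSE)
    p_tb <- kind_effect(script, "tb", n, weighted = FALSE)
    # protraction/retraction cue; saturates when episodes overlap
    marker <- 0.5 * th$th_TR * pmin(1, pmax(-1, p_tf - p_tb))
    tr_off <- th$th_TR * e_tr
    raise <- numeric(n)
    for (e in script$episodes) {
      if (e$kind == "se")
        raise <- raise + episode_profile(e, n) * (e$magnitude * th$th_SE - SH_DY_BASE)
    }
    cb <- template$chest_base
    aff_x <- marker + if (template$scenario == "S2") tr_off else numeric(n)
    un_x <- if (template$scenario == "S3") -tr_off else numeric(n)
    list(spine_signed = th$th_TF * (e_tf - e_tb),
         aff_x = aff_x, un_x = un_x, raise = raise,
         dH = th$th_TI * e_ti,
         chest = sqrt((cb + aff_x - un_x)^2 + raise^2) - cb,
         shy = SH_DY_BASE + raise)
  }
}

# Smoothed channels -> the kinematic_series data.frame the rule classifier
# reads, column for column.
channels_to_series <- function(template, ch, w = 5L) {
  n <- length(ch[[1]])
  sm <- function(x) smooth_series(x, w)
  if (template$scenario == "S1") {
    df <- data.frame(t = seq_len(n),
                     head_area_change = sm(ch$dH),
                     shoulder_angle_affected = sm(ch$ang_aff),
                     shoulder_angle_unaffected = sm(ch$ang_un),
                     trunk_tilt_angle = sm(ch$tilt))
  } else {
    df <- data.frame(t = seq_len(n),
                     spine_angle = sm(abs(ch$spine_signed)),
                     neck_x_disp = sm(sin(ch$spine_signed * pi / 180)),
                     shoulder_x_disp = sm(ch$aff_x),
                     shoulder_y_disp = sm(ch$shy),
                     chest_len_change = sm(abs(ch$chest)),
                     head_size_change = sm(abs(ch$dH)))
  }
  structure(df, scenario = template$scenario, facing = 1,
            affected_side = template$affected_side,
            class = c("kinematic_series", "data.frame"))
}

rot2 <- function(p, centre, theta_deg) {
  th <- theta_deg * pi / 180
  d <- p - centre
  centre + c(cos(th) * d[1] - sin(th) * d[2],
             sin(th) * d[1] + cos(th) * d[2])
}

# Rotation direction (sign of theta for rot2 in image coords, y down) that
# raises a point sitting at `rel` from its centre.
raise_sign <- function(rel_x) if (rel_x < 0) 1 else -1

base_skeleton_px <- function(template) {
  w <- template$image_size[1]; h <- template$image_size[2]
  s <- template$spine_px
  cx <- w / 2; hy <- h * 0.68; ny <- hy - s
  m <- matrix(0, 25L, 2L, dimnames = list(BODY25_NAMES, c("x", "y")))
  sw <- template$shoulder_half
  if (template$scenario == "S1") {
    m["MidHip", ] <- c(cx, hy)
    m["Neck", ] <- c(cx, ny)
    m["RShoulder", ] <- c(cx - sw * s, ny + 0.08 * s)
    m["LShoulder", ] <- c(cx + sw * s, ny + 0.08 * s)
    m["RElbow", ] <- c(cx - (sw + 0.07) * s, ny + 0.40 * s)
    m["LElbow", ] <- c(cx + (sw + 0.07) * s, ny + 0.40 * s)
    m["RWrist", ] <- c(cx - (sw + 0.10) * s, ny + 0.68 * s)
    m["LWrist", ] <- c(cx + (sw + 0.10) * s, ny + 0.68 * s)
    m["Nose", ] <- c(cx, ny - 0.18 * s)
    m["REye", ] <- c(cx - 0.07 * s, ny - 0.30 * s)
    m["LEye", ] <- c(cx + 0.07 * s, ny - 0.30 * s)
    m["REar", ] <- c(cx - 0.16 * s, ny - 0.26 * s)
    m["LEar", ] <- c(cx + 0.16 * s, ny - 0.26 * s)
    m["RHip", ] <- c(cx - 0.13 * s, hy)
    m["LHip", ] <- c(cx + 0.13 * s, hy)
    m["RKnee", ] <- c(cx - 0.16 * s, hy + 0.30 * s)
    m["LKnee", ] <- c(cx + 0.16 * s, hy + 0.30 * s)
    m["RAnkle", ] <- c(cx - 0.16 * s, hy + 0.55 * s)
    m["LAnkle", ] <- c(cx + 0.16 * s, hy + 0.55 * s)
    m["RBigToe", ] <- c(cx - 0.16 * s, hy + 0.62 * s)
    m["RSmallToe", ] <- c(cx - 0.20 * s, hy + 0.61 * s)
    m["RHeel", ] <- c(cx - 0.15 * s, hy + 0.57 * s)
    m["LBigToe", ] <- c(cx + 0.16 * s, hy + 0.62 * s)
    m["LSmallToe", ] <- c(cx + 0.20 * s, hy + 0.61 * s)
    m["LHeel", ] <- c(cx + 0.15 * s, hy + 0.57 * s)
  } else {
    aff <- side_joints(template$affected_side)
    opp <- side_joints(other_side(template$affected_side))
    cb <- template$chest_base
    nm <- function(id) jrow(id)
    m["MidHip", ] <- c(cx, hy)
    m["Neck", ] <- c(cx, ny)
    m[nm(aff$shoulder), ] <- c(cx, ny + 0.08 * s)
    m[nm(opp$shoulder), ] <- c(cx - cb * s, ny + 0.08 * s)
    m[nm(aff$elbow), ] <- c(cx + 0.12 * s, ny + 0.38 * s)
    m[nm(opp$elbow), ] <- c(cx - 0.10 * s, ny + 0.36 * s)
    m[nm(aff$wrist), ] <- c(cx + 0.16 * s, ny + 0.65 * s)
    m[nm(opp$wrist), ] <- c(cx - 0.12 * s, ny + 0.62 * s)
    m["Nose", ] <- c(cx + 0.20 * s, ny - 0.18 * s)
    m[nm(aff$eye), ] <- c(cx + 0.13 * s, ny - 0.32 * s)
    m[nm(opp$eye), ] <- c(cx + 0.05 * s, ny - 0.33 * s)
    m[nm(aff$ear), ] <- c(cx + 0.02 * s, ny - 0.25 * s)
    m[nm(opp$ear), ] <- c(cx - 0.04 * s, ny - 0.23 * s)
    m[nm(aff$hip), ] <- c(cx + 0.05 * s, hy)
    m[nm(opp$hip), ] <- c(cx - 0.05 * s, hy)
    kf <- c(0.40, 0.37)  # knees forward of the hips (seated)
    m[c("RKnee", "LKnee")[1], ] <- c(cx + kf[1] * s, hy + 0.12 * s)
    m[c("RKnee", "LKnee")[2], ] <- c(cx + kf[2] * s, hy + 0.14 * s)
    m["RAnkle", ] <- c(cx + 0.42 * s, hy + 0.45 * s)
    m["LAnkle", ] <- c(cx + 0.40 * s, hy + 0.47 * s)
    m["RBigToe", ] <- c(cx + 0.50 * s, hy + 0.50 * s)
    m["RSmallToe", ] <- c(cx + 0.49 * s, hy + 0.52 * s)
    m["RHeel", ] <- c(cx + 0.38 * s, hy + 0.49 * s)
    m["LBigToe", ] <- c(cx + 0.48 * s, hy + 0.52 * s)
    m["LSmallToe", ] <- c(cx + 0.47 * s, hy + 0.54 * s)
    m["LHeel", ] <- c(cx + 0.36 * s, hy + 0.51 * s)
  }
  m
}

#' Generate one synthetic trial with ground-truth labels
#'
#' Poses the stick model frame by frame: a reach-and-return arm movement of
#' the affected wrist spans the trial, and each scripted episode deforms the
#' geometry so that the kinematic variable its rule watches takes exactly
#' `magnitude x threshold` at the plateau (head-area scaling for trunk
#' forward/backward, opposed shoulder rotations about the neck for frontal
#' trunk rotation, shoulder x shift / chest-length change for side-view
#' rotation, a shoulder raise for elevation, and a spine rotation or head
#' scaling for tilt). Gaussian pixel noise and the confidence model are
#' applied last.
#'
#' Ground truth is rule-consistent: the generator records the analytic
#' noise-free value of every rule variable, smooths it with the same 5-frame
#' window the kinematics module uses, and thresholds it with the matched
#' thresholds. On noise-free data the full pipeline therefore reproduces the
#' ground truth exactly, which is what makes the generator an oracle; the
#' scripted episode intervals are returned alongside.
#'
#' @param template a [subject_template()].
#' @param script a [compensation_script()].
#' @param seed integer seed, or NULL to use the current RNG stream.
#' @param thresholds matched [threshold_set()]; defaults to the scenario's
#'   [default_thresholds()].
#' @param subject_id,trial_id identifiers stored in the sequence.
#' @param exercise exercise id to record; NULL picks the scenario's default
#'   (E1 for S1, E3 for side views).
#' @return list with `sequence` (a [pose_sequence()]), `labels` (`n x 5`
#'   ground-truth matrix), `channels` (raw analytic variable series),
#'   `episodes`, and `thresholds`.
#' @export
generate_sequence <- function(template, script, seed = NULL, thresholds = NULL,
                              subject_id = "SYN", trial_id = 1L,
                              exercise = NULL) {
  stopifnot(inherits(template, "subject_template"),
            inherits(script, "compensation_script"))
  if (!is.null(seed)) set.seed(seed)
  th <- if (is.null(thresholds)) default_thresholds(template$scenario) else thresholds
  n <- script$n_frames
  ch <- synth_channels(template, script, th)
  truth_series <- channels_to_series(template, ch)
  labels <- rb_classify(truth_series, th)
  base <- base_skeleton_px(template)
  s <- template$spine_px
  aff <- side_joints(template$affected_side)
  una <- side_joints(other_side(template$affected_side))
  head_rows <- jrow(HEAD_JOINT_IDS)
  # reach-and-return arm motion towards a mouth-level target
  wrist_rest <- base[jrow(aff$wrist), ]
  wrist_tgt <- base["Nose", ] + c(0, 0.10 * s)
  elbow_rest <- base[jrow(aff$elbow), ]
  elbow_tgt <- (base[jrow(aff$shoulder), ] + wrist_tgt) / 2
  reach <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / max(n - 1, 1)))
  if (is.null(exercise))
    exercise <- if (template$scenario == "S1") "E1" else "E3"
  frames <- vector("list", n)
  for (i in seq_len(n)) {
    m <- base
    m[jrow(aff$wrist), ] <- wrist_rest + reach[i] * (wrist_tgt - wrist_rest)
    m[jrow(aff$elbow), ] <- elbow_rest + reach[i] * (elbow_tgt - elbow_rest)
    if (template$scenario == "S1") {
      a1 <- ch$ang_aff[i]; a2 <- ch$ang_un[i]
      if (a1 != 0) {
        r <- jrow(aff$shoulder)
        m[r, ] <- rot2(base[r, ], base["Neck", ],
                       raise_sign(base[r, 1] - base["Neck", 1]) * a1)
      }
      if (a2 != 0) {
        r <- jrow(una$shoulder)
        m[r, ] <- rot2(base[r, ], base["Neck", ],
                       -raise_sign(base[r, 1] - base["Neck", 1]) * a2)
      }
      if (ch$tilt[i] != 0)
        m["Neck", ] <- rot2(base["Neck", ], base["MidHip", ], ch$tilt[i])
      if (ch$dH[i] != 0) {
        ctr <- colMeans(m[head_rows, ])
        f <- sqrt(1 + ch$dH[i])
        m[head_rows, ] <- sweep(sweep(m[head_rows, ], 2, ctr) * f, 2, ctr, "+")
      }
    } else {
      neck0 <- base["Neck", ]
      neck1 <- if (ch$spine_signed[i] != 0)
        rot2(neck0, base["MidHip", ], ch$spine_signed[i]) else neck0
      disp <- neck1 - neck0
      upper <- c("Neck", "Nose", BODY25_NAMES[jrow(c(aff$shoulder, una$shoulder,
                                                     aff$eye, una$eye,
                                                     aff$ear, una$ear,
                                                     aff$elbow, una$elbow,
                                                     aff$wrist, una$wrist))])
      m[upper, ] <- sweep(m[upper, ], 2, disp, "+")
      m[jrow(aff$shoulder), 1] <- m[jrow(aff$shoulder), 1] + s * ch$aff_x[i]
      m[jrow(una$shoulder), 1] <- m[jrow(una$shoulder), 1] + s * ch$un_x[i]
      m[jrow(aff$shoulder), 2] <- m[jrow(aff$shoulder), 2] - s * ch$raise[i]
      if (ch$dH[i] != 0) {
        ctr <- colMeans(m[head_rows, ])
        f <- sqrt(1 + ch$dH[i])
        m[head_rows, ] <- sweep(sweep(m[head_rows, ], 2, ctr) * f, 2, ctr, "+")
      }
    }
    if (template$noise_sd > 0)
      m <- m + matrix(stats::rnorm(50L, 0, template$noise_sd), 25L, 2L)
    conf <- rep(template$conf_base, 25L)
    if (template$conf_dropout > 0) {
      drop <- stats::runif(25L) < template$conf_dropout
      conf[drop] <- stats::runif(sum(drop), 0.05, 0.30)
    }
    frames[[i]] <- frame_observation(i, list(skeleton(cbind(m, conf))),
                                     template$image_size)
  }
  seq <- pose_sequence(frames, template$fps, subject_id, exercise,
                       template$scenario, template$affected_side)
  list(sequence = seq, labels = labels, channels = ch,
       episodes = script$episodes, thresholds = th, trial_id = trial_id)
}

default_kind_weights <- c(tf = 0.15, tb = 0.10, tr = 0.20, se = 0.35, tilt = 0.20)

#' Generate a labelled multi-subject dataset
#'
#' Subject templates are drawn from realistic ranges (spine 170-230 px,
#' shoulder half-width 0.30-0.40 spine, random affected side; for E3 each
#' subject is filmed in S2 or S3), and each subject performs `trials`
#' movement trials of `n_frames` frames, with 0-2 compensation episodes per
#' trial whose kinds follow `kind_weights`. Set a near-zero weight on one
#' kind (see `rare_label_weights()`) to reproduce the strongly imbalanced
#' regime where one label's imbalance ratio is much greater than 1.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param exercise "E1", "E2" or "E3".
#' @param trials trials per subject.
#' @param n_frames frames per trial.
#' @param seed integer seed (the whole dataset is deterministic given it).
#' @param noise_sd pixel-noise standard deviation.
#' @param magnitude episode magnitude, in multiples of the matched threshold.
#' @param kind_weights named sampling weights over episode kinds.
#' @param conf_dropout per-joint misdetection probability.
#' @return list of trials; each trial is a [generate_sequence()] result plus
#'   `subject`, `exercise` and `scenario` fields.
#' @export
generate_dataset <- function(n_subjects = 6L, exercise = "E1", trials = 10L,
                             n_frames = 75L, seed = 1L, noise_sd = 0,
                             magnitude = 2, kind_weights = default_kind_weights,
                             conf_dropout = 0) {
  stopifnot(n_subjects >= 2L)
  exercise <- match.arg(exercise, EXERCISES)
  set.seed(seed)
  kinds <- names(kind_weights)
  out <- list()
  for (si in seq_len(n_subjects)) {
    scenario <- if (exercise == "E3") sample(c("S2", "S3"), 1L) else "S1"
    tpl <- subject_template(
      scenario = scenario,
      affected_side = sample(c("left", "right"), 1L),
      spine_px = stats::runif(1, 170, 230),
      shoulder_half = stats::runif(1, 0.30, 0.40),
      noise_sd = noise_sd, conf_dropout = conf_dropout)
    sid <- sprintf("P%02d", si)
    for (ti in seq_len(trials)) {
      n_ep <- sample(0:2, 1L, prob = c(0.2, 0.5, 0.3))
      eps <- list()
      if (n_ep > 0L) {
        for (k in seq_len(n_ep)) {
          dur <- sample(20:28, 1L)
          start <- sample(8:(n_frames - dur - 2L), 1L)
          eps[[k]] <- list(kind = sample(kinds, 1L, prob = kind_weights),
                           start = start, end = start + dur,
                           magnitude = magnitude)
        }
      }
      trial <- generate_sequence(tpl, compensation_script(n_frames, eps),
                                 subject_id = sid, trial_id = ti,
                                 exercise = exercise)
      trial$subject <- sid
      trial$exercise <- exercise
      trial$scenario <- scenario
      out[[length(out) + 1L]] <- trial
    }
  }
  out
}

#' Kind weights that make trunk rotation a rare label
#'
#' @return named weight vector for [generate_dataset()].
#' @export
rare_label_weights <- function() {
  c(tf = 0.20, tb = 0.12, tr = 0.01, se = 0.45, tilt = 0.22)
}

#' Contaminate a sequence with detection artifacts
#'
#' Emulates the three failure modes of markerless pose extraction that the
#' cleansing module removes: ghost skeletons without spine joints, a second
#' (off-centre) person, and relevant-joint confidence dropouts below the
#' 0.36 threshold. The patient's own keypoints are never altered, so
#' cleansing a contaminated sequence recovers the clean sequence's kept
#' frames exactly.
#'
#' @param seq a single-skeleton [pose_sequence()].
#' @param ghost_rate per-frame probability of adding a ghost skeleton.
#' @param extra_person logical; add a persistent second person far from the
#'   image centre.
#' @param dropout per-frame probability of forcing one relevant joint's
#'   confidence into (0, 0.36).
#' @param seed integer seed or NULL.
#' @return `list(sequence, log)` where `log` is a data.frame of injected
#'   artifacts (`frame`, `type`, `joint_id`).
#' @export
inject_artifacts <- function(seq, ghost_rate = 0, extra_person = FALSE,
                             dropout = 0, seed = NULL) {
  stopifnot(inherits(seq, "pose_sequence"),
            ghost_rate >= 0, ghost_rate <= 1, dropout >= 0, dropout <= 1)
  if (!is.null(seed)) set.seed(seed)
  rel <- default_relevant_joints(seq$affected_side)
  log <- list()
  for (i in seq_along(seq$frames)) {
    f <- seq$frames[[i]]
    if (length(f$skeletons) != 1L)
      stop("inject_artifacts expects one skeleton per frame")
    pat <- f$skeletons[[1]]
    w <- f$image_size[1]; h <- f$image_size[2]
    if (dropout > 0 && stats::runif(1) < dropout) {
      j <- sample(rel, 1L)
      pat[jrow(j), "s"] <- stats::runif(1, 0.05, 0.30)
      f$skeletons[[1]] <- pat
      log[[length(log) + 1L]] <- data.frame(frame = f$t, type = "dropout",
                                            joint_id = j)
    }
    if (extra_person) {
      other <- unclass(pat)
      other[, "x"] <- pmin(other[, "x"] + 0.35 * w, w - 1)
      f$skeletons <- c(f$skeletons, list(skeleton(other)))
      log[[length(log) + 1L]] <- data.frame(frame = f$t, type = "extra",
                                            joint_id = NA_integer_)
    }
    if (ghost_rate > 0 && stats::runif(1) < ghost_rate) {
      g <- matrix(0, 25L, 3L)
      limb <- sample(2:24, 6L)
      g[limb, 1] <- stats::runif(6L, 0, w)
      g[limb, 2] <- stats::runif(6L, 0, h)
      g[limb, 3] <- stats::runif(6L, 0.3, 0.7)
      g[jrow(c(0L, 1L, 8L)), ] <- 0  # no spine joints: the ghost signature
      f$skeletons <- c(f$skeletons, list(skeleton(g)))
      log[[length(log) + 1L]] <- data.frame(frame = f$t, type = "ghost",
                                            joint_id = NA_integer_)
    }
    seq$frames[[i]] <- f
  }
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(frame = integer(0), type = character(0), joint_id = integer(0))
  list(sequence = seq, log = log)
}
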