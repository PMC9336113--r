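# Shared fixture builders: everything is generated in code at test time.

# A detected skeleton with all joints at distinct positions and confidence s.
make_skel <- function(s = 0.9, origin = c(300, 200), step = 10) {
  xy <- cbind(origin[1] + step * (0:24), origin[2] + step * ((0:24) %% 7))
  skeleton(cbind(xy, rep(s, 25)))
}

# Place a skeleton's MidHip at a given pixel position.
skel_with_midhip <- function(midhip, s = 0.9) {
  sk <- make_skel(s)
  shift <- midhip - sk[9, c("x", "y")]
  sk[, "x"] <- sk[, "x"] + shift[1]
  sk[, "y"] <- sk[, "y"] + shift[2]
  skeleton(unclass(sk))
}

# Minimal OpenPose frame document (list form) for n people.
openpose_doc <- function(kp_list) {
  list(version = 1.3,
       people = lapply(kp_list, function(kp) list(pose_keypoints_2d = kp)))
}

# Static single-skeleton sequence of n frames.
static_sequence <- function(n = 10, s = 0.9, fps = 25, scenario = "S1",
                            exercise = "E1", side = "right") {
  sk <- make_skel(s)
  frames <- lapply(seq_len(n), function(t) frame_observation(t, list(sk)))
  pose_sequence(frames, fps, "SUBJ", exercise, scenario, side)
}

# Quick noiseless benchmark trial. With `episodes` unset, a single
# shoulder-elevation episode is scripted when the trial is long enough.
quick_trial <- function(scenario = "S1", side = "right", n = 60,
                        episodes = NULL, noise_sd = 0, seed = 1) {
  if (is.null(episodes)) {
    episodes <- if (n >= 45)
      list(list(kind = "se", start = 20, end = 40, magnitude = 2)) else list()
  }
  tpl <- subject_template(scenario, side, noise_sd = noise_sd)
  generate_sequence(tpl, compensation_script(n, episodes), seed = seed)
}

# Independent one-hot label sampler respecting Normal exclusivity.
random_labels <- function(n, p_comp = 0.4) {
  sets <- lapply(seq_len(n), function(i) {
    if (stats::runif(1) < p_comp)
      sort(sample(0:3, sample(1:3, 1))) else integer(0)
  })
  as_label_matrix(sets)
}
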