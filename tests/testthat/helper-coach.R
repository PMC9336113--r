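# Scripted coach-FSM case exercising all 11 transition rules, with its
# hand-authored golden event log (authored directly from the transition
# table, not from running the implementation).

obs_fsm <- function(positioned = TRUE, moving = FALSE, target = FALSE,
                    comp = NA_character_, new_trial = FALSE) {
  structure(list(positioned = positioned, moving = moving,
                 target_reached = target, comp = comp, new_trial = new_trial),
            class = "coach_observation")
}

run_fsm_script <- function(stream, cfg, dt = 1) {
  coach <- new_coach()
  log <- NULL
  for (k in seq_along(stream)) {
    st <- coach_step(coach, stream[[k]], dt, cfg)
    coach <- st$coach
    if (nrow(st$events))
      log <- rbind(log, cbind(step = k, st$events))
  }
  list(log = log, state = coach$state)
}

golden_fsm_case <- function() {
  cfg <- coach_config(th_pos = 1, th_tg = 2, onset_frames = 2, stop_frames = 3)
  stream <- list(
    obs_fsm(positioned = FALSE),                 # 1: o, timer below th_pos
    obs_fsm(positioned = FALSE),                 # 2: rule 1 re-prompt
    obs_fsm(),                                   # 3: rule 3, o -> i
    obs_fsm(moving = TRUE),                      # 4: onset streak 1
    obs_fsm(moving = TRUE),                      # 5: rule 4, i -> e
    obs_fsm(moving = TRUE),                      # 6: rule 6, e -> n
    obs_fsm(moving = TRUE, comp = "tr"),         # 7: rule 9, n -> tr
    obs_fsm(moving = TRUE, comp = "se"),         # 8: rule 10, tr -> se
    obs_fsm(moving = TRUE),                      # 9: silent se -> n + rule 7
    obs_fsm(moving = TRUE, comp = "td"),         # 10: rule 11, n -> td
    obs_fsm(positioned = FALSE),                 # 11: rule 2, td -> o
    obs_fsm(),                                   # 12: rule 3, o -> i
    obs_fsm(moving = TRUE),                      # 13
    obs_fsm(moving = TRUE),                      # 14: rule 4, i -> e
    obs_fsm(),                                   # 15: rule 6, e -> n
    obs_fsm(),                                   # 16: still streak 2
    obs_fsm(),                                   # 17: rule 5, n -> e
    obs_fsm(),                                   # 18: rule 6, e -> n
    obs_fsm(moving = TRUE, target = TRUE),       # 19: rule 8, n -> tg
    obs_fsm(),                                   # 20: tg holds, silent
    obs_fsm(new_trial = TRUE))                   # 21: rule 4, tg -> e
  golden <- data.frame(
    step = c(2, 2, 3, 3, 5, 6, 7, 7, 8, 8, 9, 10, 10, 11, 11, 12, 12, 14,
             15, 17, 18, 19, 19, 21),
    rule = c(1, 1, 3, 3, 4, 6, 9, 9, 10, 10, 7, 11, 11, 2, 2, 3, 3, 4,
             6, 5, 6, 8, 8, 4),
    kind = c("speech", "marker", "marker", "speech", "marker", "speech",
             "speech", "marker", "speech", "marker", "speech", "speech",
             "marker", "speech", "marker", "marker", "speech", "marker",
             "speech", "speech", "speech", "speech", "marker", "marker"),
    tag = c("reposition", "position_rect", "position_rect", "directions",
            "target", "start_evaluation", "correct_trunk_rotation", "trunk",
            "correct_shoulder_elevation", "shoulder", "encourage",
            "correct_trunk_displacement", "trunk", "reposition",
            "position_rect", "position_rect", "directions", "target",
            "start_evaluation", "propose_repetition", "start_evaluation",
            "praise", "target", "target"),
    color = c(NA, "red", "green", NA, "green", NA, NA, "red", NA, "red",
              NA, NA, "red", NA, "red", "green", NA, "green", NA, NA, NA,
              NA, "blue", "green"),
    stringsAsFactors = FALSE)
  list(cfg = cfg, stream = stream, golden = golden)
}
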