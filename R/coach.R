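COACH_STATES <- c("o", "i", "e", "n", "tr", "se", "td", "tg")

#' Virtual-coach configuration
#'
#' Timing, geometry and detection parameters of the reflex-agent coach:
#' `th_pos` seconds between repeated repositioning prompts while the patient
#' is out of position; `th_tg` seconds of evaluation without reaching the
#' target before an encouragement; the valid-placement rectangle in image
#' pixels; the hand target (body units, body frame) and its radius; and the
#' movement onset/stop detector (affected-wrist speed above `onset_speed`
#' body units/s for `onset_frames` consecutive frames starts a trial, below
#' it for `stop_frames` frames reads as "patient stopped moving").
#'
#' @param th_pos,th_tg timing thresholds in seconds (both > 0).
#' @param position_rect `c(xmin, ymin, xmax, ymax)` in pixels.
#' @param target_point `c(x, y)` in body units.
#' @param target_radius target tolerance in body units (> 0).
#' @param onset_speed wrist-speed threshold in body units per second.
#' @param onset_frames,stop_frames consecutive-frame counts for movement
#'   onset and stop.
#' @param priority order in which simultaneous compensation classes win a
#'   coach state (first = highest); trunk rotation first by default.
#' @return a `coach_config`.
#' @export
coach_config <- function(th_pos = 5, th_tg = 10,
                         position_rect = c(40, 10, 600, 470),
                         target_point = c(0, 1.2), target_radius = 0.15,
                         onset_speed = 0.2, onset_frames = 3L,
                         stop_frames = 15L,
                         priority = c("tr", "se", "td")) {
  stopifnot(th_pos > 0, th_tg > 0, target_radius > 0,
            length(position_rect) == 4L, onset_speed > 0,
            onset_frames >= 1L, stop_frames >= 1L,
            setequal(priority, c("tr", "se", "td")))
  structure(list(th_pos = th_pos, th_tg = th_tg,
                 position_rect = as.numeric(position_rect),
                 target_point = as.numeric(target_point),
                 target_radius = target_radius, onset_speed = onset_speed,
                 onset_frames = as.integer(onset_frames),
                 stop_frames = as.integer(stop_frames),
                 priority = priority),
            class = "coach_config")
}

#' Subtitle text for each speech tag
#'
#' Feedback is emitted as text events; this table maps the speech tags the
#' state machine produces to display subtitles.
#'
#' @return named character vector.
#' @export
speech_text <- function() {
  c(reposition = "Please move back into the highlighted area.",
    directions = "Well positioned! Follow the exercise instructions.",
    start_evaluation = "Let's begin: reach the target position.",
    propose_repetition = "You stopped - let's repeat the movement.",
    encourage = "Keep going, try to reach the target!",
    praise = "Well done, you reached the target!",
    correct_trunk_rotation = "Try not to rotate your torso.",
    correct_shoulder_elevation = "Relax your shoulder, keep it down.",
    correct_trunk_displacement = "Keep your trunk upright, don't lean.")
}

#' Derive one coach observation from a frame
#'
#' Reduces a frame to the booleans the state machine consumes: `positioned`
#' (every watched joint inside the placement rectangle, in pixels), `moving`
#' (affected-wrist speed above the onset threshold), `target_reached`
#' (affected wrist within the target radius, in body units) and the dominant
#' compensation class — labels TF/O (0/3) map to trunk displacement `td`,
#' TR (1) to `tr`, SE (2) to `se`, and simultaneous labels are resolved by
#' the configured priority order (trunk rotation > shoulder elevation >
#' trunk displacement by default).
#'
#' @param skel_px patient [skeleton()] in image pixels.
#' @param skel_body the same skeleton in the normalized body frame (25 x 3).
#' @param labels integer label set for the frame (subset of 0:3, empty =
#'   Normal).
#' @param cfg a [coach_config()].
#' @param wrist_speed affected-wrist speed in body units/s.
#' @param affected_side "left" or "right".
#' @param new_trial logical; explicit new-trial signal (releases the target
#'   state).
#' @return a `coach_observation` list.
#' @export
coach_observe <- function(skel_px, skel_body, labels, cfg, wrist_speed = 0,
                          affected_side = "right", new_trial = FALSE) {
  watch <- c(0L, 1L, 2L, 5L, 8L)   # spine + both shoulders
  r <- cfg$position_rect
  xy <- skel_px[jrow(watch), c("x", "y"), drop = FALSE]
  positioned <- all(xy[, 1] >= r[1] & xy[, 1] <= r[3] &
                      xy[, 2] >= r[2] & xy[, 2] <= r[4])
  wrist <- skel_body[jrow(side_joints(affected_side)$wrist), c("x", "y")]
  target_reached <-
    sqrt(sum((wrist - cfg$target_point)^2)) <= cfg$target_radius
  comp <- NA_character_
  if (length(labels) > 0L) {
    present <- c(tr = 1L %in% labels, se = 2L %in% labels,
                 td = any(c(0L, 3L) %in% labels))
    for (cl in cfg$priority) if (present[[cl]]) { comp <- cl; break }
  }
  structure(list(positioned = positioned,
                 moving = wrist_speed > cfg$onset_speed,
                 target_reached = target_reached, comp = comp,
                 new_trial = isTRUE(new_trial)),
            class = "coach_observation")
}

#' Create a fresh coach in the out-of-position state
#'
#' @return a `coach_state` object (state `"o"`, timers and streaks zeroed).
#' @export
new_coach <- function() {
  structure(list(state = "o", t_prompt = 0, t_trial = 0,
                 move_streak = 0L, still_streak = 0L),
            class = "coach_state")
}

emit <- function(events, rule, kind, tag, color = NA_character_) {
  rbind(events, data.frame(rule = rule, kind = kind, tag = tag,
                           color = color, stringsAsFactors = FALSE))
}

no_events <- function() {
  data.frame(rule = integer(0), kind = character(0), tag = character(0),
             color = character(0), stringsAsFactors = FALSE)
}

rule_events <- function(rule) {
  ev <- no_events()
  switch(as.character(rule),
    "1" = emit(emit(ev, 1L, "speech", "reposition"),
               1L, "marker", "position_rect", "red"),
    "2" = emit(emit(ev, 2L, "speech", "reposition"),
               2L, "marker", "position_rect", "red"),
    "3" = emit(emit(ev, 3L, "marker", "position_rect", "green"),
               3L, "speech", "directions"),
    "4" = emit(ev, 4L, "marker", "target", "green"),
    "5" = emit(ev, 5L, "speech", "propose_repetition"),
    "6" = emit(ev, 6L, "speech", "start_evaluation"),
    "7" = emit(ev, 7L, "speech", "encourage"),
    "8" = emit(emit(ev, 8L, "speech", "praise"),
               8L, "marker", "target", "blue"),
    "9" = emit(emit(ev, 9L, "speech", "correct_trunk_rotation"),
               9L, "marker", "trunk", "red"),
    "10" = emit(emit(ev, 10L, "speech", "correct_shoulder_elevation"),
                10L, "marker", "shoulder", "red"),
    "11" = emit(emit(ev, 11L, "speech", "correct_trunk_displacement"),
                11L, "marker", "trunk", "red"))
}

#' Advance the coach state machine by one observation
#'
#' Implements the eleven transition/action rules of the reflex agent:
#' (1) staying out of position re-prompts every `th_pos` seconds; (2) moving
#' out of position from any evaluating state returns to `o` with a red
#' rectangle; (3) becoming well-positioned turns the rectangle green and
#' gives directions; (4) movement onset starts the exercise and shows the
#' green target marker (also how an explicit new-trial signal leaves the
#' target state); (5) stopping mid-evaluation proposes a repetition;
#' (6) from the exercise state the coach starts evaluating and asks for the
#' target; (7) spending more than `th_tg` seconds evaluating without
#' reaching the target triggers an encouragement; (8) reaching the target
#' praises and turns the target marker blue; (9-11) a detected trunk
#' rotation / shoulder elevation / trunk displacement moves to the matching
#' state with a correction and a red compensation marker. Moves back to the
#' normal-movement state are silent, and the target state holds until a new
#' trial is signalled.
#'
#' @param coach a `coach_state` from [new_coach()].
#' @param obs a [coach_observe()] result.
#' @param dt elapsed time since the previous observation, seconds.
#' @param cfg a [coach_config()].
#' @return `list(coach, events)`; `events` is a data.frame with columns
#'   `rule`, `kind`, `tag`, `color`.
#' @export
coach_step <- function(coach, obs, dt, cfg) {
  stopifnot(inherits(coach, "coach_state"), coach$state %in% COACH_STATES)
  ev <- no_events()
  st <- coach$state
  coach$move_streak <- if (obs$moving) coach$move_streak + 1L else 0L
  coach$still_streak <- if (!obs$moving) coach$still_streak + 1L else 0L
  eval_states <- c("n", "tr", "se", "td")
  if (obs$new_trial && st == "tg") {
    coach$state <- "e"
    ev <- rbind(ev, rule_events(4))
  } else if (!obs$positioned) {
    if (st == "o") {
      coach$t_prompt <- coach$t_prompt + dt
      if (coach$t_prompt > cfg$th_pos) {
        ev <- rbind(ev, rule_events(1))
        coach$t_prompt <- 0
      }
    } else if (st %in% eval_states) {        # S \ {o, e, tg}
      coach$state <- "o"
      coach$t_prompt <- 0
      ev <- rbind(ev, rule_events(2))
    }                                        # from e or tg: hold
  } else {
    if (st == "o") {
      coach$state <- "i"
      ev <- rbind(ev, rule_events(3))
    } else if (st == "i") {
      if (coach$move_streak >= cfg$onset_frames) {
        coach$state <- "e"
        ev <- rbind(ev, rule_events(4))
      }
    } else if (st == "e") {
      coach$state <- "n"
      coach$t_trial <- 0
      ev <- rbind(ev, rule_events(6))
    } else if (st %in% eval_states) {
      coach$t_trial <- coach$t_trial + dt
      if (obs$target_reached) {
        coach$state <- "tg"
        ev <- rbind(ev, rule_events(8))
      } else if (coach$still_streak >= cfg$stop_frames) {
        coach$state <- "e"
        coach$still_streak <- 0L
        ev <- rbind(ev, rule_events(5))
      } else {
        target <- if (is.na(obs$comp)) "n" else obs$comp
        target <- if (target == "td") "td" else target
        if (target != st && target != "n") {
          coach$state <- target
          ev <- rbind(ev, rule_events(switch(target, tr = 9, se = 10, td = 11)))
        } else if (target == "n" && st != "n") {
          coach$state <- "n"                 # silent return to normal
        }
        if (coach$t_trial > cfg$th_tg) {
          ev <- rbind(ev, rule_events(7))
          coach$t_trial <- 0
        }
      }
    }                                        # tg: absorbing until new trial
  }
  list(coach = coach, events = ev)
}

#' Replay a labelled sequence through the virtual coach
#'
#' Offline replay of the interactive loop: wall-clock time is frame index
#' divided by the frame rate, the affected-wrist speed is differenced from
#' the normalized trajectory, and the per-frame labels drive the
#' compensation states. The result is a deterministic event log.
#'
#' @param seq a cleaned single-skeleton [pose_sequence()].
#' @param labels `n x 5` one-hot label matrix aligned with the frames.
#' @param cfg a [coach_config()].
#' @param new_trial_frames frames at which an explicit new-trial signal is
#'   raised (releases the target state, see [coach_step()]).
#' @return list with `log` (data.frame: `frame`, `time`, `state_prev`,
#'   `state`, `rule`, `kind`, `tag`, `color`) and `states` (per-frame state
#'   character vector).
#' @export
coach_run <- function(seq, labels, cfg = coach_config(),
                      new_trial_frames = integer(0)) {
  stopifnot(inherits(seq, "pose_sequence"))
  n <- length(seq$frames)
  check_label_matrix(labels, n = n)
  nseq <- normalize_sequence(seq, mirror = FALSE)
  sets <- label_sets(labels)
  wrist_row <- jrow(side_joints(seq$affected_side)$wrist)
  dt <- 1 / seq$fps
  coach <- new_coach()
  states <- character(n)
  log <- NULL
  for (i in seq_len(n)) {
    speed <- if (i == 1L) 0 else {
      d <- nseq$frames[[i]][wrist_row, c("x", "y")] -
        nseq$frames[[i - 1L]][wrist_row, c("x", "y")]
      sqrt(sum(d^2)) * seq$fps
    }
    obs <- coach_observe(seq$frames[[i]]$skeletons[[1]], nseq$frames[[i]],
                         sets[[i]], cfg, wrist_speed = speed,
                         affected_side = seq$affected_side,
                         new_trial = i %in% new_trial_frames)
    prev <- coach$state
    stepped <- coach_step(coach, obs, dt, cfg)
    coach <- stepped$coach
    states[i] <- coach$state
    if (nrow(stepped$events)) {
      log <- rbind(log, cbind(data.frame(frame = seq$frames[[i]]$t,
                                         time = (i - 1L) * dt,
                                         state_prev = prev,
                                         state = coach$state,
                                         stringsAsFactors = FALSE),
                              stepped$events))
    }
  }
  if (is.null(log))
    log <- data.frame(frame = integer(0), time = numeric(0),
                      state_prev = character(0), state = character(0),
                      rule = integer(0), kind = character(0),
                      tag = character(0), color = character(0))
  list(log = log, states = states)
}
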