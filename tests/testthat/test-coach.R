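`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("observations derive placement, target and dominant class", {
  cfg <- coach_config(position_rect = c(0, 0, 640, 480),
                      target_point = c(0, 1.2), target_radius = 0.15)
  tr <- quick_trial(n = 10)
  skp <- tr$sequence$frames[[1]]$skeletons[[1]]
  skb <- normalize_sequence(tr$sequence)$frames[[1]]
  o1 <- coach_observe(skp, skb, integer(0), cfg)
  expect_true(o1$positioned)
  expect_true(is.na(o1$comp))
  # wrist placed exactly at the target point
  skb2 <- skb
  skb2[5, c("x", "y")] <- cfg$target_point  # RWrist, affected right
  expect_true(coach_observe(skp, skb2, integer(0), cfg)$target_reached)
  # shrink the rectangle so a shoulder falls outside
  tight <- coach_config(position_rect = c(300, 0, 340, 480))
  expect_false(coach_observe(skp, skb, integer(0), tight)$positioned)
  # dominant class over every label subset, against the priority oracle
  prio <- c("tr", "se", "td")
  for (mask in 0:7) {
    labs <- c(if (bitwAnd(mask, 1)) 1L, if (bitwAnd(mask, 2)) 2L,
              if (bitwAnd(mask, 4)) 3L)
    got <- coach_observe(skp, skb, labs %||% integer(0), cfg)$comp
    present <- c(tr = 1L %in% labs, se = 2L %in% labs,
                 td = any(c(0L, 3L) %in% labs))
    want <- NA_character_
    for (p in prio) if (present[[p]]) { want <- p; break }
    expect_identical(got, want, info = paste("mask", mask))
  }
  # label 0 alone also reads as trunk displacement
  expect_identical(coach_observe(skp, skb, 0L, cfg)$comp, "td")
})

test_that("a scripted stream reproduces the hand-authored golden event log", {
  case <- golden_fsm_case()
  res <- run_fsm_script(case$stream, case$cfg)
  got <- res$log
  rownames(got) <- rownames(case$golden) <- NULL
  got$step <- as.numeric(got$step); got$rule <- as.numeric(got$rule)
  expect_equal(got, case$golden)
  expect_identical(res$state, "e")
  expect_setequal(unique(case$golden$rule), 1:11)  # every rule exercised
})

test_that("a never-positioned patient only receives repositioning prompts", {
  cfg <- coach_config(th_pos = 2)
  res <- run_fsm_script(replicate(9, obs_fsm(positioned = FALSE),
                                  simplify = FALSE), cfg, dt = 1)
  expect_true(all(res$log$rule == 1))
  # th_pos = 2 s at 1 fps: prompts on steps 3, 6, 9
  expect_equal(unique(res$log$step), c(3, 6, 9))
  expect_identical(res$state, "o")
})

test_that("the target state is absorbing and the machine never leaves its space", {
  cfg <- coach_config(th_pos = 1, th_tg = 2, onset_frames = 1, stop_frames = 4)
  # drive to tg, then feed compensation labels: no compensation events
  to_tg <- list(obs_fsm(), obs_fsm(moving = TRUE), obs_fsm(),
                obs_fsm(target = TRUE))
  coach <- new_coach()
  for (o in to_tg) coach <- coach_step(coach, o, 1, cfg)$coach
  expect_identical(coach$state, "tg")
  for (o in list(obs_fsm(comp = "tr"), obs_fsm(comp = "se"),
                 obs_fsm(positioned = FALSE))) {
    st <- coach_step(coach, o, 1, cfg)
    expect_identical(st$coach$state, "tg")
    expect_equal(nrow(st$events), 0)
    coach <- st$coach
  }
  # fuzz: random observation streams stay inside the 8-state space and only
  # ever emit the 11 defined rules
  set.seed(14)
  coach <- new_coach()
  for (k in 1:400) {
    o <- obs_fsm(positioned = runif(1) < 0.8, moving = runif(1) < 0.5,
                 target = runif(1) < 0.05,
                 comp = sample(c(NA, "tr", "se", "td"), 1),
                 new_trial = runif(1) < 0.05)
    st <- coach_step(coach, o, 0.2, cfg)
    coach <- st$coach
    expect_true(coach$state %in% c("o", "i", "e", "n", "tr", "se", "td", "tg"))
    if (nrow(st$events)) expect_true(all(st$events$rule %in% 1:11))
  }
})

test_that("replaying a labelled trial praises once when the target is reached", {
  tr <- quick_trial(n = 60, episodes = list())
  cfg <- coach_config(position_rect = c(0, 0, 640, 480),
                      target_point = c(0, 1.25), target_radius = 0.3,
                      onset_speed = 0.05, th_tg = 100)
  res <- coach_run(tr$sequence, tr$labels, cfg)
  expect_equal(sum(res$log$tag == "praise"), 1)
  # once in tg, it stays there
  k <- which(res$states == "tg")[1]
  expect_true(all(res$states[k:60] == "tg"))
  expect_error(coach_run(tr$sequence, tr$labels[-1, ], cfg), "rows")
})
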