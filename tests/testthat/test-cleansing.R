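test_that("ghost removal drops exactly the skeletons missing all spine joints", {
  zero_at <- function(ids) {
    sk <- unclass(make_skel())
    sk[ids + 1L, "s"] <- 0
    skeleton(sk)
  }
  # brute force over the 2^3 zero-patterns of the spine joints
  spine <- c(0L, 1L, 8L)
  for (mask in 0:7) {
    ids <- spine[bitwAnd(mask, c(1L, 2L, 4L)) > 0]
    f <- frame_observation(1, list(zero_at(ids)))
    kept <- length(remove_ghost_skeletons(f)$skeletons)
    expect_identical(kept, if (length(ids) == 3L) 0L else 1L,
                     info = paste("zero at", paste(ids, collapse = ",")))
  }
  # survivors are untouched
  good <- make_skel(0.8)
  ghost <- zero_at(spine)
  out <- remove_ghost_skeletons(frame_observation(2, list(good, ghost)))
  expect_length(out$skeletons, 1)
  expect_equal(unclass(out$skeletons[[1]]), unclass(good))
})

test_that("patient selection takes the skeleton closest to the image centre", {
  img <- c(640, 480)
  near <- skel_with_midhip(c(330, 240))   # 10 px from centre
  far <- skel_with_midhip(c(370, 240))    # 50 px
  f <- frame_observation(1, list(near, far), img)
  expect_equal(unclass(select_patient(f)), unclass(near))
  f2 <- frame_observation(1, list(far, near), img)
  expect_equal(unclass(select_patient(f2)), unclass(near))
  # single skeleton; exact tie -> lower index; empty -> error
  expect_equal(unclass(select_patient(frame_observation(1, list(far), img))),
               unclass(far))
  tie_a <- skel_with_midhip(c(310, 240))
  tie_b <- skel_with_midhip(c(330, 240))
  picked <- select_patient(frame_observation(1, list(tie_a, tie_b), img))
  expect_equal(unclass(picked), unclass(tie_a))
  expect_error(select_patient(frame_observation(1, list(), img)), "no patient")
})

test_that("confidence filtering matches an independent per-frame predicate", {
  set.seed(42)
  n <- 20
  cfg <- cleansing_config(0.36)
  rel <- compens2d:::default_relevant_joints("right")
  frames <- vector("list", n)
  for (i in seq_len(n)) {
    sk <- unclass(make_skel(0.9))
    if (i %in% c(4, 9, 17))                 # three violating frames
      sk[sample(rel, 1) + 1L, "s"] <- 0.2
    if (i == 12) sk[20, "s"] <- 0.36 + 1e-9 # just above: kept (strict >)
    frames[[i]] <- frame_observation(i, list(skeleton(sk)))
  }
  seq <- pose_sequence(frames, 25, "P", "E1", "S1", "right")
  res <- filter_frames(seq, cfg)
  # independent predicate
  keep <- vapply(frames, function(f) {
    s <- f$skeletons[[1]][, "s"]
    all(s[rel + 1L] > 0.36) && all(s[-(rel + 1L)] > 0)
  }, logical(1))
  expect_identical(res$report$frames_kept, sum(keep))
  expect_identical(res$report$frames_kept, 17L)
  expect_identical(res$report$frames_in - res$report$frames_kept,
                   res$report$frames_dropped_low_confidence)
  # idempotence
  res2 <- filter_frames(res$sequence, cfg)
  expect_identical(res2$report$frames_dropped_low_confidence, 0L)
  expect_length(res2$sequence$frames, length(res$sequence$frames))
})

test_that("keypoint corrections replace exactly the listed coordinates", {
  seq <- static_sequence(8)
  expect_identical(correct_keypoints(seq, data.frame(t = integer(0),
                                                     joint_id = integer(0),
                                                     x = numeric(0),
                                                     y = numeric(0))), seq)
  fixed <- correct_keypoints(seq, data.frame(t = 5, joint_id = 2,
                                             x = 111, y = 222))
  for (i in seq_along(seq$frames)) {
    a <- unclass(seq$frames[[i]]$skeletons[[1]])
    b <- unclass(fixed$frames[[i]]$skeletons[[1]])
    if (i == 5) {
      expect_equal(unname(b[3, c("x", "y")]), c(111, 222))
      expect_equal(b[3, "s"], a[3, "s"])    # confidence preserved
      expect_equal(b[-3, ], a[-3, ])
    } else {
      expect_equal(b, a)
    }
  }
  expect_error(correct_keypoints(seq, data.frame(t = 999, joint_id = 2,
                                                 x = 0, y = 0)), "999")
})

test_that("the full pipeline counts ghosts, extras and dropped frames exactly", {
  tr <- quick_trial(n = 30)
  cont <- inject_artifacts(tr$sequence, ghost_rate = 0.5, extra_person = TRUE,
                           dropout = 0.2, seed = 3)
  res <- cleanse_sequence(cont$sequence)
  log <- cont$log
  expect_identical(res$report$skeletons_removed,
                   sum(log$type %in% c("ghost", "extra")))
  expect_identical(res$report$frames_dropped_low_confidence,
                   length(unique(log$frame[log$type == "dropout"])))
  expect_identical(res$report$frames_in, 30L)
})
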