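s1_vars <- function(dH = 0, a1 = 0, a2 = 0, tilt = 0) {
  list(head_area_change = dH, shoulder_angle_affected = a1,
       shoulder_angle_unaffected = a2, trunk_tilt_angle = tilt)
}

s23_vars <- function(spine = 0, shx = 0, shy = 0, chest = 0, dH = 0) {
  list(spine_angle = spine, shoulder_x_disp = shx, shoulder_y_disp = shy,
       chest_len_change = chest, head_size_change = dH)
}

test_that("frontal rules fire per category and default to Normal", {
  th <- default_thresholds("S1")
  eps <- 1e-6
  expect_identical(classify_frame_s1(s1_vars(dH = th$th_TF + eps), th), 0L)
  expect_identical(classify_frame_s1(s1_vars(dH = -th$th_TF - eps), th), 3L)
  expect_identical(classify_frame_s1(s1_vars(), th), integer(0))  # Normal
  expect_identical(classify_frame_s1(s1_vars(tilt = th$th_O + eps), th), 3L)
  # two-shoulder rule: elevation alone, rotation, rotation + elevation
  expect_identical(classify_frame_s1(s1_vars(a1 = th$th_SE + 10), th), 2L)
  expect_identical(
    classify_frame_s1(s1_vars(a1 = th$th_SE + 10,
                              a2 = th$th_SE + 10 - th$eps_eq / 2), th), 1L)
  expect_identical(
    classify_frame_s1(s1_vars(a1 = th$th_SE + 10 + th$eps_gg,
                              a2 = th$th_SE + 10), th), c(1L, 2L))
  # the gap between eps_eq and eps_gg stays rotation-dominant
  expect_identical(
    classify_frame_s1(s1_vars(a1 = th$th_SE + 10 + (th$eps_eq + th$eps_gg) / 2,
                              a2 = th$th_SE + 10), th), 1L)
  # unions: head and tilt can fire together
  expect_identical(classify_frame_s1(s1_vars(dH = 1, tilt = 90), th),
                   c(0L, 3L))
  expect_error(classify_frame_s1(list(head_area_change = 1), th), "missing")
})

test_that("side-view rules fire per category with scenario-specific rotation", {
  th <- default_thresholds("S2")
  eps <- 1e-6
  # forward/backward disambiguated by the shoulder-neck x sign
  expect_identical(classify_frame_s2s3(
    s23_vars(spine = th$th_TF + 1, shx = 0.01), th, "S2"), 0L)
  expect_identical(classify_frame_s2s3(
    s23_vars(spine = th$th_TF + 1, shx = -0.01), th, "S2"), 3L)
  expect_identical(classify_frame_s2s3(
    s23_vars(shx = th$th_TR + eps), th, "S2"), 1L)
  expect_identical(classify_frame_s2s3(
    s23_vars(chest = th$th_TR + eps), th, "S3"), 1L)
  expect_identical(classify_frame_s2s3(
    s23_vars(chest = th$th_TR + eps), th, "S2"), integer(0))
  expect_identical(classify_frame_s2s3(
    s23_vars(shy = th$th_SE + eps), th, "S2"), 2L)
  expect_identical(classify_frame_s2s3(
    s23_vars(dH = th$th_TI + eps), th, "S3"), 3L)
  expect_identical(classify_frame_s2s3(s23_vars(), th, "S3"), integer(0))
  expect_error(classify_frame_s2s3(s23_vars(), th, "S1"), "S2 and S3")
})

test_that("sequence classification matches generator ground truth without noise", {
  tr <- quick_trial(n = 70, episodes = list(
    list(kind = "se", start = 30, end = 60, magnitude = 2)))
  pred <- rb_assess(tr$sequence)
  expect_identical(unname(pred), unname(tr$labels))
  # infinite thresholds: everything Normal
  inf_th <- threshold_set(Inf, Inf, Inf, Inf, Inf)
  pred_inf <- rb_assess(tr$sequence, inf_th)
  expect_true(all(pred_inf[, 5] == 1L))
  # near-zero thresholds: every frame with any active variable gets a label
  tiny <- threshold_set(1e-9, 1e-9, 1e-9, 1e-9, 1e-9, eps_eq = 0,
                        eps_gg = 1e-12)
  kin <- compute_kinematics(normalize_sequence(tr$sequence))
  pred0 <- rb_classify(kin, tiny)
  active <- apply(abs(as.matrix(kin[, -1])), 1, max) > 1e-9
  expect_identical(unname(pred0[, 5] == 0L), unname(active))
})

test_that("raising thresholds only removes detections (monotone rules)", {
  # Every simple rule (one variable against one threshold) is monotone:
  # raising its threshold can only remove its label. The frontal two-shoulder
  # rule is the documented exception - raising th_SE can reclassify a
  # rotation as an elevation - so for th_SE the monotone guarantees are
  # weaker: a Normal frame stays Normal, and label 1 is never added.
  set.seed(31)
  th1 <- default_thresholds("S1")
  th2 <- default_thresholds("S2")
  for (k in 1:200) {
    v1 <- s1_vars(dH = runif(1, -0.6, 0.6), a1 = runif(1, 0, 40),
                  a2 = runif(1, 0, 40), tilt = runif(1, 0, 30))
    b1 <- classify_frame_s1(v1, th1)
    for (f in c("th_TF", "th_O")) {
      up <- th1; up[[f]] <- up[[f]] + runif(1, 0.1, 10)
      expect_length(setdiff(classify_frame_s1(v1, up), b1), 0)
    }
    up <- th1; up$th_SE <- up$th_SE + runif(1, 0.1, 30)
    r <- classify_frame_s1(v1, up)
    if (length(b1) == 0) expect_length(r, 0)
    expect_false(1L %in% setdiff(r, b1))
    # side views: all rules simple, full monotonicity
    v2 <- s23_vars(spine = runif(1, 0, 15), shx = runif(1, -0.3, 0.3),
                   shy = runif(1, -0.2, 0.3), chest = runif(1, 0, 0.3),
                   dH = runif(1, 0, 0.5))
    for (scn in c("S2", "S3")) {
      b2 <- classify_frame_s2s3(v2, th2, scn)
      for (f in c("th_TF", "th_TR", "th_SE", "th_TI")) {
        up <- th2; up[[f]] <- up[[f]] + runif(1, 0.05, 5)
        expect_length(setdiff(classify_frame_s2s3(v2, up, scn), b2), 0)
      }
    }
  }
})

test_that("classification output respects Normal exclusivity and is pure", {
  tr <- quick_trial(n = 40, noise_sd = 2, seed = 8, episodes = list(
    list(kind = "tr", start = 10, end = 30, magnitude = 2)))
  p1 <- rb_assess(tr$sequence)
  p2 <- rb_assess(tr$sequence)
  expect_identical(p1, p2)
  expect_silent(compens2d:::check_label_matrix(p1))
})
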