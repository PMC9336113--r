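test_that("angle, displacement and distance primitives are exact", {
  expect_equal(angle_between(c(0, 1), c(0, 0), c(1, 0)), 90)
  expect_equal(angle_between(c(2, 0), c(0, 0), c(5, 0)), 0)
  # independent oracle: signed angles via atan2
  atan2_angle <- function(j1, j2, j3) {
    a <- atan2(j1[2] - j2[2], j1[1] - j2[1])
    b <- atan2(j3[2] - j2[2], j3[1] - j2[1])
    d <- abs(a - b) %% (2 * pi)
    min(d, 2 * pi - d) * 180 / pi
  }
  expect_equal(angle_between(c(1, 0), c(0, 0), c(1, 1)),
               atan2_angle(c(1, 0), c(0, 0), c(1, 1)))
  set.seed(7)
  for (k in 1:50) {
    p <- matrix(rnorm(6), 3)
    expect_equal(angle_between(p[1, ], p[2, ], p[3, ]),
                 atan2_angle(p[1, ], p[2, ], p[3, ]))
  }
  expect_error(angle_between(c(0, 0), c(0, 0), c(1, 1)), "degenerate")
  expect_equal(joint_distance(c(3, 4), c(0, 0)), 5)
  expect_equal(unname(joint_displacement(c(1, 2), c(1, 2))), c(0, 0))
  for (k in 1:20) {
    a <- rnorm(2); b <- rnorm(2)
    d <- joint_displacement(a, b)
    expect_equal(joint_distance(a, b)^2, sum(d^2))
  }
})

test_that("head area is a convex-hull area with quadratic scaling", {
  sk <- unclass(make_skel())
  sk[, c("x", "y")] <- 0
  hm <- head_model(joints = c(0L, 15L, 16L))
  sk[c(1, 16, 17), c("x", "y")] <- rbind(c(0, 0), c(1, 0), c(0, 1))
  expect_equal(head_area(skeleton(sk), hm), 0.5)
  sk2 <- sk; sk2[c(1, 16, 17), c("x", "y")] <- sk[c(1, 16, 17), c("x", "y")] * 2
  expect_equal(head_area(skeleton(sk2), hm), 2)
  # collinear points, fallback disabled: zero area with a warning
  sk3 <- sk; sk3[c(1, 16, 17), c("x", "y")] <- cbind(1:3, 1:3)
  expect_warning(a <- head_area(skeleton(sk3), head_model(c(0L, 15L, 16L),
                                                          fallback = FALSE)),
                 "degenerate")
  expect_equal(a, 0)
})

test_that("a static skeleton yields constant series, zero where baselined", {
  for (scn in c("S1", "S2")) {
    tr <- quick_trial(scenario = scn, n = 15, episodes = list())
    kin <- compute_kinematics(normalize_sequence(tr$sequence))
    for (v in setdiff(names(kin), "t")) {
      # every series is constant over time ...
      expect_equal(kin[[v]], rep(kin[[v]][1], 15), info = paste(scn, v),
                   tolerance = 1e-12)
      # ... and every baseline-referenced one is exactly zero
      # (shoulder_y_disp is a per-frame shoulder-to-neck offset and rests at
      # the anatomical baseline instead)
      if (v != "shoulder_y_disp")
        expect_equal(kin[[v]], rep(0, 15), info = paste(scn, v),
                     tolerance = 1e-12)
    }
  }
})

test_that("trunk rotation raises both shoulder-angle series together", {
  tr <- quick_trial(scenario = "S1", n = 50,
                    episodes = list(list(kind = "tr", start = 15, end = 40,
                                         magnitude = 2)))
  kin <- compute_kinematics(normalize_sequence(tr$sequence))
  plateau <- 25:32
  expect_true(all(kin$shoulder_angle_affected[plateau] > 15))
  expect_true(all(kin$shoulder_angle_unaffected[plateau] > 15))
  expect_equal(kin$shoulder_angle_affected[plateau],
               kin$shoulder_angle_unaffected[plateau], tolerance = 1e-8)
})

test_that("a side-view forward lean shows in spine angle and neck displacement", {
  tr <- quick_trial(scenario = "S2", n = 50,
                    episodes = list(list(kind = "tf", start = 15, end = 40,
                                         magnitude = 2)))
  kin <- compute_kinematics(normalize_sequence(tr$sequence))
  plateau <- 25:32
  # injected lean: 2 x th_TF = 10 degrees; neck moves towards the facing side
  expect_equal(kin$spine_angle[plateau], rep(10, length(plateau)),
               tolerance = 1e-8)
  expect_equal(kin$neck_x_disp[plateau], rep(sin(10 * pi / 180),
                                             length(plateau)),
               tolerance = 1e-8)
  expect_true(all(kin$shoulder_x_disp[plateau] > 0))
})

test_that("kinematics are invariant to translation and uniform scaling", {
  tr <- quick_trial(n = 40, episodes = list(list(kind = "se", start = 10,
                                                 end = 30, magnitude = 2)),
                    noise_sd = 2, seed = 5)
  kin <- compute_kinematics(normalize_sequence(tr$sequence))
  set.seed(9)
  for (k in 1:3) {
    shift <- runif(2, -40, 40)
    scale <- runif(1, 0.5, 2)
    moved <- tr$sequence
    moved$frames <- lapply(moved$frames, function(f) {
      xy <- f$skeletons[[1]][, c("x", "y")]
      f$skeletons[[1]][, c("x", "y")] <- sweep(xy * scale, 2, shift, "+")
      f
    })
    kin2 <- compute_kinematics(normalize_sequence(moved))
    for (v in setdiff(names(kin), "t"))
      expect_equal(kin2[[v]], kin[[v]], tolerance = 1e-9, info = v)
  }
})

test_that("head-size change is symmetric for equal forward/backward leans", {
  fwd <- quick_trial(n = 40, episodes = list(list(kind = "tf", start = 10,
                                                  end = 30, magnitude = 1.5)))
  bwd <- quick_trial(n = 40, episodes = list(list(kind = "tb", start = 10,
                                                  end = 30, magnitude = 1.5)))
  kf <- compute_kinematics(normalize_sequence(fwd$sequence))
  kb <- compute_kinematics(normalize_sequence(bwd$sequence))
  expect_equal(abs(kf$head_area_change), abs(kb$head_area_change),
               tolerance = 1e-9)
})
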