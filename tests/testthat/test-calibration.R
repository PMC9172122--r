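test_that("calibration round-trips exactly on rigid data", {
  cal <- template_cal()
  tf <- template_foot()
  set.seed(31)
  # a "dynamic" trial: the static pose rigidly moved each frame
  for (i in 1:3) {
    R <- random_rotation()
    t <- rnorm(3, sd = 500)
    moved <- rigid_move(tf, R, t)
    moved$frame <- 1L
    trial <- afm_trial(moved, rate = 100)
    fr <- reconstruct_frames(trial, cal)
    for (s in afm_segments()$segment) {
      direct <- anatomical_frame(moved, s)
      expect_lt(max(abs(fr$segments[[s]]$R[, , 1] - direct$R)), 1e-9)
      expect_lt(max(abs(fr$segments[[s]]$origin[1, ] - direct$origin)), 1e-9)
    }
  }
})

test_that("least-squares tracking agrees with the marker triad on rigid data", {
  cal <- template_cal()
  syn <- synthesize_gait(n_strides = 1)
  a <- afm_joint_angles(syn$trial, cal, tracking = "triad", planar = FALSE)
  b <- afm_joint_angles(syn$trial, cal, tracking = "least_squares", planar = FALSE)
  expect_angles_equal(a, b, 1e-8)
})

test_that("calcaneal length and virtual points match hand arithmetic", {
  cal <- template_cal()
  m <- as.matrix(tibble::column_to_rownames(template_foot(), "marker"))
  expect_equal(
    cal$calcaneal_length,
    sqrt(sum((m["CALP", ] - (m["ST", ] + m["PT", ]) / 2)^2))
  )
  # CAp reconstructed to lab equals the floor projection it was built from
  hind <- anatomical_frame(template_foot(), "hindfoot")
  cap_lab <- hind$origin + as.numeric(hind$R %*% cal$cap_in_hindfoot)
  cap_expect <- (m["CALP", ] + (m["ST", ] + m["PT", ]) / 2) / 2
  cap_expect[2] <- 0
  expect_equal(cap_lab, unname(cap_expect), tolerance = 1e-9)
})

test_that("calibration is invariant under rigid motion of the static trial", {
  cal0 <- template_cal()
  # floor-preserving motion (yaw about the vertical + horizontal shift):
  # everything is invariant, including the floor-projected arch points
  yaw <- 35 * pi / 180
  Ry <- matrix(c(cos(yaw), 0, -sin(yaw), 0, 1, 0, sin(yaw), 0, cos(yaw)), 3, 3)
  cal_yaw <- afm_calibrate(
    rigid_move_trial(synthesize_static(), Ry, c(120, 0, -300)),
    side = "right"
  )
  expect_equal(cal_yaw$calcaneal_length, cal0$calcaneal_length, tolerance = 1e-9)
  expect_equal(cal_yaw$static_angles$angle, cal0$static_angles$angle, tolerance = 1e-8)
  expect_equal(cal_yaw$cap_in_hindfoot, cal0$cap_in_hindfoot, tolerance = 1e-8)
  # arbitrary rotation: joint angles and calcaneal length are still
  # invariant (the arch angles are referenced to the floor plane and are
  # only meaningful for a foot standing on it)
  set.seed(32)
  cal_rot <- afm_calibrate(
    rigid_move_trial(synthesize_static(), random_rotation(), c(100, 40, -250)),
    side = "right"
  )
  expect_equal(cal_rot$calcaneal_length, cal0$calcaneal_length, tolerance = 1e-9)
  joint_rows <- !cal0$static_angles$joint %in% c("MLA")
  expect_equal(
    cal_rot$static_angles$angle[joint_rows],
    cal0$static_angles$angle[joint_rows],
    tolerance = 1e-8
  )
})

test_that("static angles equal direct frame decompositions of the template", {
  cal <- template_cal()
  tf <- template_foot()
  for (j in seq_len(nrow(afm_joints()))) {
    row <- afm_joints()[j, ]
    a <- cardan_zxy(
      anatomical_frame(tf, row$proximal), anatomical_frame(tf, row$distal)
    )
    got <- cal$static_angles[cal$static_angles$joint == row$joint, ]
    keep <- if (row$joint == "HX_FFM") c(1, 3) else 1:3
    expect_equal(got$angle, unname(a)[keep], tolerance = 1e-9)
  }
  expect_equal(
    cal$static_angles$angle[cal$static_angles$joint == "TTA"],
    tta_angle(tf)
  )
})

test_that("the CAp fallback scales a reference ratio by calcaneal length", {
  cal <- afm_calibrate(synthesize_static(), full_foot_contact = FALSE)
  expect_null(cal$cap_in_hindfoot)
  expect_true(is.na(cal$static_angles$angle[cal$static_angles$joint == "MLA"]))
  z <- cap_fallback(cal, reference_ratio = c(0, 0, 0))
  expect_equal(z$cap_in_hindfoot, c(0, 0, 0))
  r <- c(0.1, -0.5, 0.02)
  f <- cap_fallback(cal, reference_ratio = r)
  expect_equal(f$cap_in_hindfoot, r * cal$calcaneal_length)
  expect_equal(f$cap_source, "fallback")
  # self-consistency: the template's own ratio reproduces its measured CAp
  full <- template_cal()
  back <- cap_fallback(cal, reference_ratio = full$cap_in_hindfoot / full$calcaneal_length)
  expect_equal(back$cap_in_hindfoot, full$cap_in_hindfoot, tolerance = 1e-9)
  expect_equal(
    back$static_angles$angle[back$static_angles$joint == "MLA"],
    full$static_angles$angle[full$static_angles$joint == "MLA"],
    tolerance = 1e-9
  )
})

test_that("a dropped tracking marker invalidates only its frame", {
  cal <- template_cal()
  syn <- synthesize_gait(n_strides = 1)
  tr <- tibble::as_tibble(syn$trial)
  k <- 30L
  tr$x[tr$frame == k & tr$marker == "ST"] <- NA
  trial <- afm_trial(tr, rate = syn$rate)
  fr <- reconstruct_frames(trial, cal)
  expect_false(fr$segments$hindfoot$valid[k])
  expect_true(all(fr$segments$hindfoot$valid[-k]))
  expect_true(all(fr$segments$forefoot$valid)) # other segments unaffected
  curves <- afm_joint_angles(trial, cal, joints = "HF_SK", planar = FALSE)
  expect_true(all(is.na(curves$angle[curves$frame == k])))
  expect_true(all(is.finite(curves$angle[curves$frame != k])))
})
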