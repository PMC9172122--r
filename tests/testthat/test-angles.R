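test_that("noise-free prescribed gait curves are recovered through the full pipeline", {
  syn <- synthesize_gait(n_strides = 2)
  cal <- template_cal()
  curves <- afm_joint_angles(syn$trial, cal)
  expect_angles_equal(curves, syn$truth$angles, 1e-6)
})

test_that("a zero-amplitude profile keeps every angle at its static value", {
  prof <- gait_profile()
  prof$amplitude <- 0
  syn <- synthesize_gait(profile = prof, n_strides = 1)
  cal <- template_cal()
  curves <- afm_joint_angles(syn$trial, cal)
  by_joint <- dplyr::summarise(
    dplyr::group_by(curves, .data$joint, .data$plane),
    spread = max(.data$angle) - min(.data$angle), .groups = "drop"
  )
  expect_lt(max(by_joint$spread), 1e-9)
  joined <- dplyr::inner_join(
    dplyr::distinct(curves, .data$joint, .data$plane, .keep_all = TRUE),
    cal$static_angles,
    by = c("joint", "plane"), suffix = c("", "_static")
  )
  expect_lt(max(abs(joined$angle - joined$angle_static)), 1e-9)
})

test_that("angles are invariant under global rigid motion of the trial", {
  syn <- synthesize_gait(n_strides = 1)
  cal <- template_cal()
  base <- afm_joint_angles(syn$trial, cal)
  set.seed(41)
  moved <- rigid_move_trial(syn$trial, random_rotation(), c(-300, 120, 800))
  expect_angles_equal(afm_joint_angles(moved, cal), base, 1e-9)
})

test_that("a mirrored left-side trial yields the right-side curves", {
  syn_r <- synthesize_gait(n_strides = 1, side = "right")
  syn_l <- synthesize_gait(n_strides = 1, side = "left")
  cal_r <- template_cal()
  cal_l <- afm_calibrate(synthesize_static(side = "left"), side = "left")
  expect_angles_equal(
    afm_joint_angles(syn_l$trial, cal_l),
    afm_joint_angles(syn_r$trial, cal_r),
    1e-9
  )
})

test_that("0.5 mm marker noise leaves RMS angle errors small", {
  syn <- synthesize_gait(n_strides = 2, noise_sd = 0.5, seed = 77)
  cal <- template_cal()
  curves <- afm_joint_angles(syn$trial, cal)
  cmp <- dplyr::inner_join(curves, syn$truth$angles,
    by = c("time", "joint", "plane"), suffix = c("", "_truth")
  )
  rms <- dplyr::summarise(
    dplyr::group_by(cmp, .data$joint, .data$plane),
    rms = sqrt(mean((.data$angle - .data$angle_truth)^2)), .groups = "drop"
  )
  expect_lt(max(rms$rms), 3)
})

test_that("the MLA formula matches planar trigonometry and arch height monotonicity", {
  # CAp at origin, NAV at (60, 40, 0), HM1p at (120, 0, 0):
  # angle between (60, 40, 0) and (-60, 40, 0) = 2 atan(60/40)
  id <- afmkin:::new_afm_frame(c(0, 0, 0), diag(3))
  got <- mla_angle(id, id, c(60, 40, 0), c(0, 0, 0), c(120, 0, 0))
  expect_equal(got, 2 * atan(60 / 40) * 180 / pi, tolerance = 1e-10)
  # raising the navicular (higher arch) strictly decreases the MLA
  heights <- seq(30, 80, by = 10)
  mlas <- vapply(
    heights,
    function(h) mla_angle(id, id, c(60, h, 0), c(0, 0, 0), c(120, 0, 0)),
    numeric(1)
  )
  expect_true(all(diff(mlas) < 0))
})

test_that("MLA is unchanged when the whole foot moves as one body", {
  cal <- template_cal()
  tf <- template_foot()
  tf$frame <- 1L
  base <- afm_joint_angles(afm_trial(tf, 100), cal)
  set.seed(42)
  moved <- rigid_move(template_foot(), random_rotation(), c(50, -20, 10))
  moved$frame <- 1L
  after <- afm_joint_angles(afm_trial(moved, 100), cal)
  expect_equal(
    after$angle[after$joint == "MLA"], base$angle[base$joint == "MLA"],
    tolerance = 1e-9
  )
})

test_that("the TTA follows its two-vector definition", {
  flat <- tibble::tibble(
    marker = c("BM1", "BM2", "BM5"),
    x = c(0, 10, 20), y = 0, z = c(-10, 0, 10)
  )
  expect_equal(tta_angle(flat), 0, tolerance = 1e-9)
  bent <- tibble::tibble(
    marker = c("BM1", "BM2", "BM5"),
    x = c(0, 1, 2), y = c(0, 1, 0), z = 0
  )
  expect_equal(tta_angle(bent), 90, tolerance = 1e-9)
  set.seed(43)
  m <- tibble::tibble(
    marker = c("BM1", "BM2", "BM5"),
    x = rnorm(3, sd = 30), y = rnorm(3, sd = 10), z = rnorm(3, sd = 20)
  )
  expect_equal(
    tta_angle(rigid_move(m, random_rotation(), rnorm(3))),
    tta_angle(m),
    tolerance = 1e-9
  )
  expect_error(tta_angle(flat[-2, ]), "BM2")
})

test_that("range of motion is max minus min, averaged over strides", {
  const <- tibble::tibble(joint = "j", plane = "sagittal", angle = rep(4.2, 30))
  expect_equal(angle_rom(const)$rom, 0)
  expect_equal(
    angle_rom(tibble::tibble(joint = "j", plane = "p", angle = c(-5, 10, 3)))$rom,
    15
  )
  two <- tibble::tibble(
    joint = "j", plane = "p",
    stride = rep(1:2, each = 3), angle = c(0, 4, 2, 0, 8, 2)
  )
  expect_equal(angle_rom(two)$rom, (4 + 8) / 2)
  expect_error(
    angle_rom(tibble::tibble(joint = "j", plane = "p", angle = NA_real_)),
    "all-gap"
  )
})

test_that("two-configuration comparison reports zero for identical or rigidly moved sets", {
  tf <- template_foot()
  same <- compare_marker_sets(tf, tf)
  expect_true(all(abs(same$error) < 1e-12))
  set.seed(44)
  moved <- rigid_move(tf, random_rotation(), rnorm(3, sd = 100))
  rigid <- compare_marker_sets(tf, moved)
  expect_lt(max(abs(rigid$error)), 1e-9)
})

test_that("a 2 mm medial CALP shift reproduces the small-angle frontal error", {
  tf <- template_foot()
  shifted <- tf
  shifted$z[shifted$marker == "CALP"] <- shifted$z[shifted$marker == "CALP"] - 2
  out <- compare_marker_sets(tf, shifted,
    segments = "hindfoot", joints = character(0), align = FALSE
  )
  frontal <- out$error[out$plane == "frontal"]
  # closed form: 2 mm over the 40 mm CALD-CALP spacing, (180/pi)/40 deg/mm
  expect_equal(abs(frontal), 2 * (180 / pi) / 40, tolerance = 0.15)
  # and it matches twice the fitted per-mm gradient much more tightly
  grad <- marker_sensitivity(tf, "hindfoot", "CALP")
  g <- grad$slope[grad$axis == "medio_lateral" & grad$plane == "frontal"]
  expect_equal(frontal, -2 * g, tolerance = 0.02)
})
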