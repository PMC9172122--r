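test_that("the marker dictionary has 18 physical and 4 virtual markers with correct roles", {
  mk <- afm_markers()
  expect_equal(sum(mk$role != "virtual"), 18)
  expect_equal(sum(mk$role == "virtual"), 4)
  expect_setequal(mk$marker[mk$role == "anatomical"], c("FH", "LM", "MM", "CALP"))
  expect_setequal(mk$marker[mk$role == "tracking"], c("ASHN", "LSHN"))
})

test_that("virtual midpoints are pairwise averages and leave originals untouched", {
  ms <- tibble::tibble(
    marker = c("BM1", "BM2", "BM5", "HM1", "HM2", "HM5"),
    x = c(0, 2, 4, 10, 12, 14), y = c(0, 0, 0, 2, 4, 6), z = c(1, 1, 1, 0, 0, 0)
  )
  out <- add_virtual_midpoints(ms)
  expect_equal(
    unlist(out[out$marker == "mBM12", c("x", "y", "z")], use.names = FALSE),
    c(1, 0, 1)
  )
  expect_equal(out[seq_len(nrow(ms)), ], ms)
  # all parents coincident: all midpoints coincide there too
  same <- tibble::tibble(marker = ms$marker, x = 5, y = -2, z = 3)
  out2 <- add_virtual_midpoints(same)
  expect_true(all(out2$x == 5 & out2$y == -2 & out2$z == 3))
  # template coordinates: hand-computed averages
  tf <- add_virtual_midpoints(template_foot())
  m <- as.matrix(tibble::column_to_rownames(tf, "marker"))
  expect_equal(m["mHM25", ], (m["HM2", ] + m["HM5", ]) / 2)
  expect_error(
    add_virtual_midpoints(ms[ms$marker != "BM2", ]),
    "BM2"
  )
})

test_that("the hindfoot frame matches a direct evaluation of its defining formulas", {
  ms <- tibble::tibble(
    marker = c("CALP", "CALD", "ST", "PT"),
    x = c(0, 0, 58, 58), y = c(60, 20, 30, 22), z = c(0, 0, -25, 30)
  )
  f <- anatomical_frame(ms, "hindfoot")
  expect_equal(f$origin, c(0, 40, 0))
  x_expect <- c(58, -14, 2.5) / sqrt(sum(c(58, -14, 2.5)^2))
  expect_equal(f$R[, 1], x_expect, tolerance = 1e-12)
  # y perpendicular to both x and z, right-handed
  expect_lt(abs(sum(f$R[, 2] * f$R[, 1])), 1e-9)
  expect_lt(abs(sum(f$R[, 2] * f$R[, 3])), 1e-9)
  expect_equal(det(f$R), 1, tolerance = 1e-9)
  # z direction: X x (CALP - CALD) with CALP - CALD = (0, 40, 0), normalized
  z_raw <- c(
    x_expect[2] * 0 - x_expect[3] * 40,
    x_expect[3] * 0 - x_expect[1] * 0,
    x_expect[1] * 40 - x_expect[2] * 0
  )
  expect_equal(f$R[, 3], z_raw / sqrt(sum(z_raw^2)), tolerance = 1e-9)
})

test_that("anatomical and technical frames are equivariant under rigid motion", {
  tf <- template_foot()
  set.seed(21)
  for (i in 1:5) {
    R <- random_rotation()
    t <- rnorm(3, sd = 300)
    moved <- rigid_move(tf, R, t)
    for (s in afm_segments()$segment) {
      f0 <- anatomical_frame(tf, s)
      f1 <- anatomical_frame(moved, s)
      expect_lt(max(abs(f1$R - R %*% f0$R)), 1e-9)
      expect_lt(max(abs(f1$origin - (as.numeric(R %*% f0$origin) + t))), 1e-9)
    }
    for (s in c("shank", "hindfoot", "midfoot", "forefoot")) {
      f0 <- technical_frame(tf, s)
      f1 <- technical_frame(moved, s)
      expect_lt(max(abs(f1$R - R %*% f0$R)), 1e-9)
    }
  }
})

test_that("a mirrored left foot reports identical joint angles in all planes", {
  right <- template_foot("right")
  left <- template_foot("left") # z-negated copy
  for (j in seq_len(nrow(afm_joints()))) {
    row <- afm_joints()[j, ]
    a_r <- cardan_zxy(
      anatomical_frame(right, row$proximal, "right"),
      anatomical_frame(right, row$distal, "right")
    )
    a_l <- cardan_zxy(
      anatomical_frame(left, row$proximal, "left"),
      anatomical_frame(left, row$distal, "left")
    )
    expect_equal(unname(a_l), unname(a_r), tolerance = 1e-9)
  }
})

test_that("template frames follow ISB directions across the child-to-adult size range", {
  for (scale in c(0.7, 1, 1.4)) {
    tf <- template_foot(scale = scale)
    for (s in afm_segments()$segment) {
      R <- anatomical_frame(tf, s)$R
      expect_gt(R[1, 1], 0) # x has a forward component
      expect_gt(R[2, 2], 0) # y has an upward component
      expect_gt(R[3, 3], 0) # z has a rightward component
    }
    # midfoot vertical axis points upward, not just non-zero
    expect_gt(anatomical_frame(tf, "midfoot")$R[2, 2], 0.5)
  }
})

test_that("technical frames use the documented marker triples deterministically", {
  ms <- tibble::tibble(
    marker = c("CALD", "ST", "PT"),
    x = c(0, 1, 0), y = c(0, 0, 1), z = c(0, 0, 0)
  )
  f <- technical_frame(ms, "hindfoot")
  expect_equal(f$origin, c(0, 0, 0))
  expect_equal(f$R, diag(3), tolerance = 1e-12)
  expect_equal(technical_frame(template_foot(), "hindfoot")$origin,
    unlist(template_foot()[template_foot()$marker == "CALD", c("x", "y", "z")],
      use.names = FALSE
    ),
    tolerance = 1e-12
  )
  expect_error(technical_frame(ms[-1, ], "hindfoot"), "CALD")
  expect_error(technical_frame(template_foot(), "hallux"), "no technical")
})

test_that("missing or absent markers raise named errors, never silent zeros", {
  tf <- template_foot()
  expect_error(anatomical_frame(tf[tf$marker != "NAV", ], "midfoot"), "NAV")
  gap <- tf
  gap$x[gap$marker == "ST"] <- NA
  expect_error(anatomical_frame(gap, "hindfoot"), "ST")
})
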