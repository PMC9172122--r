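test_that("the displacement frame is horizontal, orthonormal and equivariant in yaw", {
  aligned <- tibble::tibble(
    marker = c("CALD", "HM2"), x = c(0, 180), y = c(20, 30), z = c(5, 5)
  )
  f0 <- displacement_frame(aligned)
  expect_equal(f0$R, diag(3), tolerance = 1e-9) # heel-toe line along lab x
  tf <- template_foot()
  f <- displacement_frame(tf)
  # template heel-toe line: x is its horizontal projection
  d <- c(180, 0, -10)
  expect_equal(f$R[, 1], d / sqrt(sum(d^2)), tolerance = 1e-12)
  yaw <- 30 * pi / 180
  R <- matrix(c(cos(yaw), 0, -sin(yaw), 0, 1, 0, sin(yaw), 0, cos(yaw)), 3, 3)
  f2 <- displacement_frame(rigid_move(tf, R, c(0, 0, 0)))
  expect_equal(f2$R, R %*% f$R, tolerance = 1e-9)
  set.seed(61)
  arb <- rigid_move(tf, random_rotation(), rnorm(3, sd = 100))
  fa <- displacement_frame(arb)
  expect_lt(abs(fa$R[2, 1]), 1e-9) # x stays horizontal
  expect_equal(fa$R[, 2], c(0, 1, 0)) # y stays the lab vertical
  expect_lt(max(abs(crossprod(fa$R) - diag(3))), 1e-9)
})

test_that("a marker outside the segment definition is not-applicable, not zero", {
  expect_error(
    marker_sensitivity(template_foot(), "hindfoot", "NAV"),
    "does not enter"
  )
})

test_that("two-marker-axis gradients match the small-angle closed form", {
  # pitch-free hindfoot: the ST/PT midpoint level with the CALD/CALP
  # midpoint, so origin shifts cannot leak yaw into the frontal plane
  ms <- tibble::tibble(
    marker = c("CALP", "CALD", "ST", "PT", "HM2"),
    x = c(0, 0, 58, 58, 175), y = c(60, 20, 40, 40, 40), z = c(0, 0, -25, 25, 0)
  )
  closed_form <- (180 / pi) / 40
  for (mk in c("CALP", "CALD")) {
    sens <- marker_sensitivity(ms, "hindfoot", mk)
    g <- sens$gradient[sens$axis == "medio_lateral" & sens$plane == "frontal"]
    expect_equal(g, closed_form, tolerance = 0.02)
    expect_gt(sens$r_squared[sens$axis == "medio_lateral" & sens$plane == "frontal"], 0.999)
  }
  # on the template (pitched hindfoot x axis) the coupling splits the pair
  # symmetrically: their mean still matches the closed form
  tab <- sensitivity_table(template_foot(), segments = "hindfoot")
  pair <- tab$gradient[tab$axis == "medio_lateral" & tab$plane == "frontal" &
    tab$marker %in% c("CALP", "CALD")]
  expect_equal(mean(pair), closed_form, tolerance = 0.02)
})

test_that("midpoint construction halves the effect of a single-marker displacement", {
  tf <- add_virtual_midpoints(template_foot())
  fr <- displacement_frame(tf)
  grad_of <- function(marker, axis, d_seq, scale = 1) {
    errs <- vapply(d_seq, function(d) {
      ms <- tf
      idx <- ms$marker == marker
      ms$x[idx] <- ms$x[idx] + scale * d * fr$R[1, axis]
      ms$y[idx] <- ms$y[idx] + scale * d * fr$R[2, axis]
      ms$z[idx] <- ms$z[idx] + scale * d * fr$R[3, axis]
      # midpoints are already present, so the displaced one is respected
      orientation_error(
        anatomical_frame(tf, "forefoot"),
        anatomical_frame(ms, "forefoot")
      )[["frontal"]]
    }, numeric(1))
    unname(coef(stats::lm(errs ~ d_seq))[2])
  }
  d_seq <- seq(-10, 10)
  # moving HM1 by d is exactly moving mHM12 by d/2 (HM1 enters the forefoot
  # frame only through that midpoint)
  g_bm <- marker_sensitivity(template_foot(), "forefoot", "HM1")
  g_hm1 <- g_bm$slope[g_bm$axis == "superior_inferior" & g_bm$plane == "frontal"]
  expect_equal(g_hm1, grad_of("mHM12", 2, d_seq, scale = 0.5), tolerance = 1e-9)
  # in the linear regime the fitted gradient is half within 1%
  small <- seq(-2, 2, by = 0.2)
  g_small <- marker_sensitivity(template_foot(), "forefoot", "HM1",
    range_mm = 2, step_mm = 0.2
  )
  expect_equal(
    g_small$slope[g_small$axis == "superior_inferior" & g_small$plane == "frontal"],
    grad_of("mHM12", 2, small) / 2,
    tolerance = 0.01
  )
})

test_that("gradients scale inversely with foot size and survive rigid motion", {
  tab1 <- sensitivity_table(template_foot(), segments = "hindfoot")
  tab2 <- sensitivity_table(template_foot(scale = 2), segments = "hindfoot")
  big <- tab1$gradient > 0.05
  expect_equal(tab2$gradient[big], tab1$gradient[big] / 2, tolerance = 0.01)
  # rigid floor-preserving motion (yaw + shift): identical gradients, since
  # the displacement axes are tied to the lab vertical and the heel-toe line
  yaw <- 40 * pi / 180
  Ry <- matrix(c(cos(yaw), 0, -sin(yaw), 0, 1, 0, sin(yaw), 0, cos(yaw)), 3, 3)
  moved <- rigid_move(template_foot(), Ry, c(500, 0, -200))
  tab3 <- sensitivity_table(moved, segments = "hindfoot")
  expect_equal(tab3$gradient, tab1$gradient, tolerance = 1e-6)
})

test_that("the fitted errors are linear over the +/-10 mm range", {
  tab <- sensitivity_table(template_foot())
  relevant <- tab[tab$gradient > 0.05, ]
  expect_gt(nrow(relevant), 10)
  expect_true(all(relevant$r_squared > 0.99))
  expect_true(all(is.finite(tab$gradient)))
  expect_true(all(tab$n_points == 21))
})

test_that("table shape: records per segment, hallux planes, threshold counts", {
  tab <- sensitivity_table(template_foot(), segments = c("hindfoot", "forefoot"))
  expect_equal(sum(tab$segment == "hindfoot"), 4 * 3 * 3)
  expect_equal(sum(tab$segment == "forefoot"), 6 * 3 * 3)
  expect_equal(count_sensitive(tab, 0), nrow(tab))
  hx <- marker_sensitivity(template_foot(), "hallux", "HLX")
  expect_equal(nrow(hx), 3 * 2) # sagittal and transverse only
  expect_false("frontal" %in% hx$plane)
})
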