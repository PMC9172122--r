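# Shared fixtures and oracles. Everything is generated in code; fixed seeds
# keep the property loops reproducible.

# Random rotation (uniform-ish via QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Apply a rigid motion to a marker tibble.
rigid_move <- function(markers, R, t) {
  m <- as.matrix(markers[, c("x", "y", "z")]) %*% t(R)
  markers$x <- m[, 1] + t[1]
  markers$y <- m[, 2] + t[2]
  markers$z <- m[, 3] + t[3]
  markers
}

# Apply a rigid motion to every frame of a trial.
rigid_move_trial <- function(trial, R, t) {
  m <- as.matrix(trial[, c("x", "y", "z")]) %*% t(R)
  out <- tibble::as_tibble(trial)
  out$x <- m[, 1] + t[1]
  out$y <- m[, 2] + t[2]
  out$z <- m[, 3] + t[3]
  afm_trial(out, trial_rate(trial))
}

frame_diff <- function(f1, f2) {
  max(max(abs(f1$R - f2$R)), max(abs(f1$origin - f2$origin)))
}

template_cal <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- afm_calibrate(synthesize_static(), side = "right")
    cache
  }
})

expect_angles_equal <- function(a, b, tol) {
  cmp <- dplyr::inner_join(a, b,
    by = intersect(intersect(names(a), names(b)), c("time", "frame", "joint", "plane")),
    suffix = c("_1", "_2")
  )
  expect_gt(nrow(cmp), 0)
  expect_lt(max(abs(cmp$angle_1 - cmp$angle_2), na.rm = TRUE), tol)
}

withr_local_file <- function(name) {
  file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
}
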