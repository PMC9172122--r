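# 3D primitives shared by every downstream module. All lengths are mm, all
# reported angles degrees; radians only ever appear inside a function body.

vec_norm <- function(v) sqrt(sum(v * v))

vec_unit <- function(v, what = "vector") {
  n <- vec_norm(v)
  if (!is.finite(n) || n < .Machine$double.eps * 100) {
    stop("invalid geometry: zero-length ", what, call. = FALSE)
  }
  v / n
}

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

deg <- function(rad) rad * 180 / pi
rad <- function(deg) deg * pi / 180

rot_x <- function(a) {
  a <- rad(a)
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}
rot_y <- function(a) {
  a <- rad(a)
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}
rot_z <- function(a) {
  a <- rad(a)
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

#' Project a point onto a plane
#'
#' Orthogonal projection of `p` onto the plane with normal `normal` passing
#' through `point_on_plane`. This is the `projection(Marker, Norm Vector,
#' Point)` primitive used by the shank coordinate-system construction.
#'
#' @param p Numeric length-3 point (mm).
#' @param normal Numeric length-3 plane normal (any nonzero length).
#' @param point_on_plane Numeric length-3 point on the plane (mm).
#' @return Numeric length-3 projected point.
#' @examples
#' project_point_on_plane(c(3, 4, 7), c(0, 0, 1), c(0, 0, 0))
#' @export
project_point_on_plane <- function(p, normal, point_on_plane) {
  n <- vec_unit(normal, "plane normal")
  p - sum((p - point_on_plane) * n) * n
}

#' Angle between two 3D vectors
#'
#' Numerically stable angle via `atan2(|u x v|, u . v)`; symmetric and
#' scale-invariant. Used for the planar arch angles (MLA, TTA).
#'
#' @param u,v Numeric length-3 vectors (nonzero).
#' @return Angle in degrees, in `[0, 180]`.
#' @examples
#' angle_between(c(1, 0, 0), c(1, 1, 0))
#' @export
angle_between <- function(u, v) {
  if (vec_norm(u) < .Machine$double.eps * 100 ||
      vec_norm(v) < .Machine$double.eps * 100) {
    stop("invalid geometry: angle_between() needs two nonzero vectors",
      call. = FALSE
    )
  }
  deg(atan2(vec_norm(cross3(u, v)), sum(u * v)))
}

axis_index <- c(x = 1L, y = 2L, z = 3L)

#' Build a right-handed orthonormal frame from two vectors
#'
#' Uniform re-orthonormalization used by every segment coordinate-system
#' construction: the `primary` direction is kept exactly, the `secondary`
#' vector fixes the (primary, secondary) plane, and the third axis completes
#' a right-handed triad. `primary_axis` and `secondary_axis` say which
#' anatomical axes (`"x"` anterior, `"y"` superior, `"z"` right) the two
#' vectors define.
#'
#' @param origin Numeric length-3 frame origin (mm).
#' @param primary Direction of the primary axis (kept exactly, normalized).
#' @param secondary Vector lying in the plane of the primary and secondary
#'   axes, on the positive secondary side.
#' @param primary_axis,secondary_axis One of `"x"`, `"y"`, `"z"`.
#' @param context Optional label naming the segment/markers, used in error
#'   messages for degenerate geometry.
#' @return An `afm_frame`: list with `origin` (length-3) and `R` (3x3 rotation
#'   whose columns are the frame's x, y, z axes in parent coordinates).
#' @export
build_frame <- function(origin, primary, secondary,
                        primary_axis = "x", secondary_axis = "y",
                        context = NULL) {
  stopifnot(primary_axis %in% names(axis_index),
    secondary_axis %in% names(axis_index),
    primary_axis != secondary_axis
  )
  where <- if (is.null(context)) "" else paste0(" (", context, ")")
  np <- vec_norm(primary)
  ns <- vec_norm(secondary)
  if (np < 1e-12 || ns < 1e-12) {
    stop("degenerate frame", where, ": zero-length axis vector", call. = FALSE)
  }
  sin_angle <- vec_norm(cross3(primary / np, secondary / ns))
  if (sin_angle < 1e-6) {
    stop("degenerate frame", where, ": primary and secondary axis vectors ",
      "are (anti)parallel",
      call. = FALSE
    )
  }
  u <- primary / np
  i <- axis_index[[primary_axis]]
  j <- axis_index[[secondary_axis]]
  k <- 6L - i - j
  cyclic <- (j - i) %% 3L == 1L
  if (cyclic) {
    w <- vec_unit(cross3(u, secondary))
    v <- cross3(w, u)
  } else {
    w <- vec_unit(cross3(secondary, u))
    v <- cross3(u, w)
  }
  R <- matrix(0, 3, 3)
  R[, i] <- u
  R[, j] <- v
  R[, k] <- w
  new_afm_frame(origin, R)
}

new_afm_frame <- function(origin, R) {
  structure(list(origin = as.numeric(origin), R = R), class = "afm_frame")
}

#' @export
print.afm_frame <- function(x, ...) {
  cat("<afm_frame>\n origin:", format(round(x$origin, 3)), "\n")
  cat(" axes (columns x, y, z):\n")
  print(round(x$R, 6))
  invisible(x)
}

# Validity check used by tests and defensive code paths.
is_rotation <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) < tol &&
    abs(det(R) - 1) < tol
}

#' Cardan z-x'-y'' decomposition of a relative rotation
#'
#' Decomposes the rotation from a proximal to a distal frame into three
#' sequential rotations: about the proximal medio-lateral (z) axis
#' (sagittal: dorsiflexion positive), the floating anterior-posterior (x)
#' axis (frontal: inversion positive), and the distal superior-inferior (y)
#' axis (transverse: internal rotation / adduction positive). Signs are for a
#' right foot with ISB axes; left feet are handled upstream by mirroring.
#'
#' Near the gimbal singularity (|frontal| within ~1e-6 rad of 90 deg) the
#' sagittal/transverse split is conventional: transverse is set to 0 and the
#' whole z-y rotation is reported as sagittal, with attribute
#' `gimbal = TRUE`.
#'
#' @param prox,dist 3x3 rotation matrices (or `afm_frame` objects) of the
#'   proximal and distal segment expressed in a common parent frame.
#' @return Named numeric vector `c(sagittal, frontal, transverse)` in
#'   degrees, each in (-180, 180].
#' @examples
#' cardan_zxy(diag(3), rot_frame(12, -7, 4))
#' @export
cardan_zxy <- function(prox, dist) {
  Rp <- if (inherits(prox, "afm_frame")) prox$R else prox
  Rd <- if (inherits(dist, "afm_frame")) dist$R else dist
  R <- crossprod(Rp, Rd) # t(Rp) %*% Rd
  s2 <- min(1, max(-1, R[3, 2]))
  gimbal <- (1 - abs(s2)) < 1e-12 # |frontal| within ~1e-6 rad of 90 deg
  if (gimbal) {
    # z and y axes collinear: only the sum/difference of sagittal and
    # transverse is observable. Convention: transverse = 0.
    a <- atan2(R[2, 1], R[1, 1])
    out <- c(sagittal = deg(a), frontal = deg(asin(s2)), transverse = 0)
  } else {
    out <- c(
      sagittal = deg(atan2(-R[1, 2], R[2, 2])),
      frontal = deg(asin(s2)),
      transverse = deg(atan2(-R[3, 1], R[3, 3]))
    )
  }
  if (gimbal) attr(out, "gimbal") <- TRUE
  out
}

#' Compose a rotation from Cardan z-x'-y'' angles
#'
#' Inverse of [cardan_zxy()]: builds the relative rotation
#' `Rz(sagittal) Rx(frontal) Ry(transverse)`.
#'
#' @param sagittal,frontal,transverse Angles in degrees.
#' @return 3x3 rotation matrix.
#' @export
rot_frame <- function(sagittal, frontal, transverse) {
  rot_z(sagittal) %*% rot_x(frontal) %*% rot_y(transverse)
}

#' Three-plane orientation error between two poses of one segment
#'
#' Cardan z-x'-y'' decomposition of the rotation from a reference pose to a
#' test pose of the same segment. This is the quantity reported by the
#' marker-misplacement sensitivity analysis and by two-configuration
#' (soft-tissue-artifact style) comparisons.
#'
#' @param ref,test 3x3 rotation matrices or `afm_frame`s.
#' @return Named numeric vector `c(sagittal, frontal, transverse)` (degrees).
#' @export
orientation_error <- function(ref, test) {
  cardan_zxy(ref, test)
}
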