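# Joint angles for the seven model joints, the MLA/TTA planar arch angles,
# range of motion, and two-configuration comparisons (the soft-tissue-
# artifact style evaluation).

plane_names <- c("sagittal", "frontal", "transverse")

#' Medial longitudinal arch angle at one instant
#'
#' Angle at the navicular between the floor-projected calcaneus point (CAp)
#' and the floor-projected first metatarsal head (HM1p), both mapped to lab
#' coordinates from their calibrated segment-fixed positions through the
#' current hindfoot and forefoot frames. Larger angle = flatter arch.
#' [afm_joint_angles()] evaluates this per frame as the `MLA` curve.
#'
#' @param hind_frame,fore_frame Current hindfoot / forefoot `afm_frame`s.
#' @param nav Navicular marker position (lab, mm).
#' @param cap_local CAp in hindfoot anatomical coordinates
#'   (`cal$cap_in_hindfoot`).
#' @param hm1p_local HM1p in forefoot anatomical coordinates
#'   (`cal$hm1p_in_forefoot`).
#' @return Angle in degrees.
#' @export
mla_angle <- function(hind_frame, fore_frame, nav, cap_local, hm1p_local) {
  cap_lab <- hind_frame$origin + as.numeric(hind_frame$R %*% cap_local)
  hm1p_lab <- fore_frame$origin + as.numeric(fore_frame$R %*% hm1p_local)
  angle_between(nav - cap_lab, nav - hm1p_lab)
}

#' Transverse tarsal arch angle
#'
#' Angle between the vector from BM1 to BM2 and the vector from BM2 to BM5
#' at one instant. Collinear metatarsal bases give 0 (flat transverse arch).
#'
#' @param markers Marker set with BM1, BM2, BM5.
#' @return Angle in degrees.
#' @export
tta_angle <- function(markers) {
  m <- marker_matrix(markers)
  require_markers(m, c("BM1", "BM2", "BM5"), "the transverse tarsal arch angle")
  angle_between(m["BM2", ] - m["BM1", ], m["BM5", ] - m["BM2", ])
}

#' Joint and arch angle curves from a dynamic trial
#'
#' Runs the whole kinematic pipeline: reconstructs anatomical frames via the
#' calibration, decomposes each joint's proximal-to-distal rotation with the
#' Cardan z-x'-y'' sequence (sagittal = dorsi/plantarflexion, frontal =
#' in/eversion, transverse = internal/external rotation at the ankle and
#' add/abduction distally), and evaluates the MLA and TTA planar angles.
#' The hallux-medial forefoot frontal plane is not expressible with a single
#' hallux marker and is omitted. Frames with missing tracking markers yield
#' `NA` angles (gaps), never interpolated values.
#'
#' @param trial An [afm_trial()].
#' @param cal An `afm_calibration`.
#' @param joints Joints to compute (subset of `afm_joints()$joint`).
#' @param planar Include the MLA and TTA planar angles (`plane = "planar"`).
#' @param tracking Passed to [reconstruct_frames()].
#' @param rate Sampling-rate override.
#' @return Tibble with columns `frame`, `time`, `joint`, `plane`, `angle`.
#' @examples
#' syn <- synthesize_gait(n_strides = 1)
#' cal <- afm_calibrate(synthesize_static())
#' curves <- afm_joint_angles(syn$trial, cal)
#' @export
afm_joint_angles <- function(trial, cal, joints = afm_joints()$joint,
                             planar = TRUE,
                             tracking = c("triad", "least_squares"),
                             rate = NULL) {
  tracking <- match.arg(tracking)
  bad <- setdiff(joints, joint_table$joint)
  if (length(bad)) {
    stop("unknown joint(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  jt <- joint_table[joint_table$joint %in% joints, ]
  segs <- unique(c(jt$proximal, jt$distal, if (planar) c("hindfoot", "forefoot")))
  fr <- reconstruct_frames(trial, cal, segments = segs, tracking = tracking, rate = rate)
  n <- length(fr$frames)

  per_joint <- purrr::pmap_dfr(jt, function(joint, proximal, distal) {
    p <- fr$segments[[proximal]]
    d <- fr$segments[[distal]]
    ang <- matrix(NA_real_, n, 3, dimnames = list(NULL, plane_names))
    ok <- p$valid & d$valid
    for (i in which(ok)) {
      ang[i, ] <- cardan_zxy(p$R[, , i], d$R[, , i])
    }
    out <- tibble::tibble(
      frame = rep(fr$frames, 3),
      time = rep(fr$time, 3),
      joint = joint,
      plane = rep(plane_names, each = n),
      angle = c(ang)
    )
    if (joint == "HX_FFM") out <- out[out$plane != "frontal", ]
    out
  })

  if (planar) {
    arr <- trial_array(trial)
    if (cal$side == "left") arr$xyz[, , 3] <- -arr$xyz[, , 3]
    hind <- fr$segments$hindfoot
    fore <- fr$segments$forefoot
    mla <- rep(NA_real_, n)
    tta <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      m <- markers_at(arr, i)
      if (all(c("BM1", "BM2", "BM5") %in% rownames(m)) &&
        !anyNA(m[c("BM1", "BM2", "BM5"), ])) {
        tta[i] <- angle_between(m["BM2", ] - m["BM1", ], m["BM5", ] - m["BM2", ])
      }
      if (!is.null(cal$cap_in_hindfoot) && hind$valid[i] && fore$valid[i] &&
        "NAV" %in% rownames(m) && !anyNA(m["NAV", ])) {
        mla[i] <- mla_angle(
          new_afm_frame(hind$origin[i, ], hind$R[, , i]),
          new_afm_frame(fore$origin[i, ], fore$R[, , i]),
          m["NAV", ], cal$cap_in_hindfoot, cal$hm1p_in_forefoot
        )
      }
    }
    per_joint <- dplyr::bind_rows(
      per_joint,
      tibble::tibble(
        frame = rep(fr$frames, 2), time = rep(fr$time, 2),
        joint = rep(c("MLA", "TTA"), each = n),
        plane = "planar", angle = c(mla, tta)
      )
    )
  }
  per_joint
}

#' Foot-shank angles with a plug-in foot frame
#'
#' The model defines no foot segment of its own; the foot-shank (`F_SK`)
#' angle uses whatever foot frame the surrounding lower-extremity marker
#' model provides. Supply the per-frame foot rotation matrices (in the same
#' lab frame as the trial; for a left foot the same mirrored-to-right
#' convention used internally, i.e. built from z-negated markers).
#'
#' @param frames An `afm_frames` object from [reconstruct_frames()]
#'   (must include the shank).
#' @param foot_rotation 3 x 3 x n array of foot anatomical rotations.
#' @return Tibble `frame`, `time`, `joint = "F_SK"`, `plane`, `angle`.
#' @export
foot_shank_angles <- function(frames, foot_rotation) {
  stopifnot(inherits(frames, "afm_frames"))
  sk <- frames$segments$shank
  if (is.null(sk)) stop("frames must include the shank segment", call. = FALSE)
  n <- length(frames$frames)
  stopifnot(length(dim(foot_rotation)) == 3, dim(foot_rotation)[3] == n)
  ang <- matrix(NA_real_, n, 3, dimnames = list(NULL, plane_names))
  for (i in which(sk$valid)) {
    if (!anyNA(foot_rotation[, , i])) {
      ang[i, ] <- cardan_zxy(sk$R[, , i], foot_rotation[, , i])
    }
  }
  tibble::tibble(
    frame = rep(frames$frames, 3), time = rep(frames$time, 3),
    joint = "F_SK", plane = rep(plane_names, each = n), angle = c(ang)
  )
}

#' Range of motion of angle curves
#'
#' Max minus min per curve; when a `stride` column is present the ROM is
#' computed per stride and averaged over strides.
#'
#' @param curves Tibble with `joint`, `plane`, `angle` and optionally
#'   `stride`.
#' @return Tibble `joint`, `plane`, `rom`, `n_strides`.
#' @export
angle_rom <- function(curves) {
  stopifnot(all(c("joint", "plane", "angle") %in% names(curves)))
  has_stride <- "stride" %in% names(curves)
  g <- dplyr::group_by(
    curves,
    .data$joint, .data$plane,
    .stride = if (has_stride) .data$stride else 1L
  )
  per <- dplyr::summarise(
    g,
    rom = {
      a <- .data$angle[is.finite(.data$angle)]
      if (!length(a)) {
        stop("range of motion of an all-gap curve is undefined", call. = FALSE)
      }
      max(a) - min(a)
    },
    .groups = "drop"
  )
  dplyr::summarise(
    dplyr::group_by(per, .data$joint, .data$plane),
    n_strides = dplyr::n(),
    rom = mean(.data$rom),
    .groups = "drop"
  )
}

#' Compare angles between two marker configurations
#'
#' Builds anatomical frames from two marker sets of the same foot (e.g.
#' marker positions with and without soft-tissue-artifact displacement, the
#' first set being the reference) and returns the three-plane segment
#' orientation errors and the joint-angle differences.
#'
#' @param reference,test Marker sets (tibbles `marker`, `x`, `y`, `z`).
#' @param side `"right"` or `"left"`.
#' @param segments Segments for orientation errors.
#' @param joints Joints for angle differences.
#' @param align Remove the best-fit (least-squares) rigid motion between the
#'   shared markers of the two sets before comparing, so that a global
#'   repositioning of the foot does not masquerade as segment orientation
#'   error. Joint-angle differences are unaffected by alignment.
#' @return Tibble `type` (`"segment"`/`"joint"`), `name`, `plane`,
#'   `reference`, `test`, `error` (test minus reference, degrees; for
#'   segments the Cardan orientation error of the test pose with respect to
#'   the reference pose).
#' @export
compare_marker_sets <- function(reference, test, side = "right",
                                segments = c("shank", "hindfoot", "forefoot"),
                                joints = c("HF_SK", "FF_HF"),
                                align = TRUE) {
  side <- check_side(side)
  if (align) {
    mr <- marker_matrix(reference)
    mt <- marker_matrix(test)
    shared <- intersect(rownames(mr), rownames(mt))
    fit <- kabsch(mt[shared, , drop = FALSE], mr[shared, , drop = FALSE])
    mt <- sweep(mt %*% t(fit$R), 2, -fit$t)
    test <- marker_tibble(mt)
  }
  need <- unique(c(
    segments,
    joint_table$proximal[joint_table$joint %in% joints],
    joint_table$distal[joint_table$joint %in% joints]
  ))
  ref_f <- lapply(
    stats::setNames(need, need),
    function(s) anatomical_frame(reference, s, side)
  )
  test_f <- lapply(
    stats::setNames(need, need),
    function(s) anatomical_frame(test, s, side)
  )
  seg_rows <- purrr::map_dfr(segments, function(s) {
    e <- orientation_error(ref_f[[s]], test_f[[s]])
    tibble::tibble(
      type = "segment", name = s, plane = plane_names,
      reference = NA_real_, test = NA_real_, error = as.numeric(e)
    )
  })
  joint_rows <- purrr::map_dfr(joints, function(j) {
    row <- joint_table[joint_table$joint == j, ]
    a_ref <- cardan_zxy(ref_f[[row$proximal]], ref_f[[row$distal]])
    a_test <- cardan_zxy(test_f[[row$proximal]], test_f[[row$distal]])
    out <- tibble::tibble(
      type = "joint", name = j, plane = plane_names,
      reference = as.numeric(a_ref), test = as.numeric(a_test),
      error = as.numeric(a_test - a_ref)
    )
    if (j == "HX_FFM") out <- out[out$plane != "frontal", ]
    out
  })
  dplyr::bind_rows(seg_rows, joint_rows)
}
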