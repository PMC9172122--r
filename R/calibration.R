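# Static-trial calibration: express each tracked segment's anatomical frame
# in its technical frame, fix the arch virtual points (CAp, HM1p) to their
# segments, measure calcaneal length and the static angles; then reconstruct
# anatomical frames frame-by-frame during gait.

#' Calibrate the model from a static trial
#'
#' Averages marker positions over the static trial, builds all anatomical
#' and technical frames, and stores for each tracked segment (shank,
#' hindfoot, forefoot) the rigid transform from its technical to its
#' anatomical frame. The virtual arch points are fixed to their segments:
#' `CAp` (midpoint of CALP and the ST/PT midpoint, dropped to the floor) in
#' hindfoot coordinates and `HM1p` (HM1 dropped to the floor) in forefoot
#' coordinates. Also records calcaneal length (CALP to ST/PT midpoint) and
#' the static joint, MLA and TTA angles.
#'
#' `CAp` is only meaningful if the subject stood with complete foot contact;
#' set `full_foot_contact = FALSE` otherwise and apply [cap_fallback()] to
#' use a reference position normalized to calcaneal length.
#'
#' @param static_trial An [afm_trial()] (or a single-instant marker tibble)
#'   containing all 18 physical markers.
#' @param side `"right"` or `"left"`.
#' @param full_foot_contact Logical flag (not auto-detected): was the foot
#'   flat on the floor during the static trial?
#' @param floor_y Height of the floor plane in lab coordinates (mm);
#'   "projected on the ground" sets the vertical coordinate to this value.
#' @param rate Sampling rate override when `static_trial` lacks one.
#' @return An object of class `afm_calibration`.
#' @examples
#' cal <- afm_calibrate(synthesize_static(), side = "right")
#' tidy(cal)
#' @export
afm_calibrate <- function(static_trial, side = "right",
                          full_foot_contact = TRUE, floor_y = 0,
                          rate = NULL) {
  side <- check_side(side)
  if (inherits(static_trial, "afm_trial") || "frame" %in% names(static_trial)) {
    n_frames <- dplyr::n_distinct(static_trial$frame)
    if (n_frames < 1) stop("static trial has no frames", call. = FALSE)
    markers <- average_markers(static_trial)
  } else {
    n_frames <- 1L
    markers <- static_trial
  }
  m <- orient_markers(marker_matrix(markers), side)
  require_markers(m, physical_marker_names(), "static calibration")
  m <- add_virtual_midpoints(m)

  anat <- lapply(stats::setNames(segment_names, segment_names), function(s) {
    anatomical_frame_right(s, m)
  })
  segments <- lapply(
    stats::setNames(calibrated_segments, calibrated_segments),
    function(s) {
      trio <- technical_marker_sets[[s]]
      tech <- build_frame(
        m[trio[1], ], m[trio[2], ] - m[trio[1], ], m[trio[3], ] - m[trio[1], ],
        "x", "y",
        context = paste0(s, " technical")
      )
      a <- anat[[s]]
      list(
        rotation = crossprod(tech$R, a$R), # anatomical axes in technical frame
        translation = as.numeric(crossprod(tech$R, a$origin - tech$origin)),
        tracking_markers = trio,
        tracking_static = m[trio, , drop = FALSE]
      )
    }
  )

  drop_to_floor <- function(p) c(p[1], floor_y, p[3])
  st_pt_mid <- (m["ST", ] + m["PT", ]) / 2
  calcaneal_length <- vec_norm(m["CALP", ] - st_pt_mid)
  hm1p_lab <- drop_to_floor(m["HM1", ])
  hm1p_in_forefoot <- as.numeric(
    crossprod(anat$forefoot$R, hm1p_lab - anat$forefoot$origin)
  )
  if (full_foot_contact) {
    cap_lab <- drop_to_floor((m["CALP", ] + st_pt_mid) / 2)
    cap_in_hindfoot <- as.numeric(
      crossprod(anat$hindfoot$R, cap_lab - anat$hindfoot$origin)
    )
    cap_source <- "static"
  } else {
    cap_lab <- NULL
    cap_in_hindfoot <- NULL
    cap_source <- "none"
  }

  cal <- structure(
    list(
      side = side,
      floor_y = floor_y,
      full_foot_contact = full_foot_contact,
      segments = segments,
      cap_in_hindfoot = cap_in_hindfoot,
      hm1p_in_forefoot = hm1p_in_forefoot,
      cap_source = cap_source,
      calcaneal_length = calcaneal_length,
      markers_static = m,
      static_frames = anat,
      n_frames_static = n_frames
    ),
    class = "afm_calibration"
  )
  cal$static_angles <- static_angle_table(cal)
  cal
}

# Joint + planar angles of the averaged static pose.
static_angle_table <- function(cal) {
  anat <- cal$static_frames
  rows <- purrr::pmap_dfr(joint_table, function(joint, proximal, distal) {
    a <- cardan_zxy(anat[[proximal]]$R, anat[[distal]]$R)
    out <- tibble::tibble(
      joint = joint,
      plane = c("sagittal", "frontal", "transverse"),
      angle = as.numeric(a)
    )
    if (joint == "HX_FFM") out <- out[out$plane != "frontal", ]
    out
  })
  m <- cal$markers_static
  planar <- tibble::tibble(
    joint = c("MLA", "TTA"),
    plane = "planar",
    angle = c(
      if (is.null(cal$cap_in_hindfoot)) {
        NA_real_
      } else {
        mla_angle(
          anat$hindfoot, anat$forefoot, m["NAV", ],
          cal$cap_in_hindfoot, cal$hm1p_in_forefoot
        )
      },
      angle_between(m["BM2", ] - m["BM1", ], m["BM5", ] - m["BM2", ])
    )
  )
  dplyr::bind_rows(rows, planar)
}

#' Fall back to a reference CAp position
#'
#' When the static trial was recorded without complete foot contact, the
#' floor-projected calcaneus point cannot be measured. This replaces it with
#' a reference position in hindfoot anatomical coordinates, expressed per
#' unit calcaneal length and scaled by the subject's own calcaneal length.
#'
#' @param cal An `afm_calibration`.
#' @param reference_ratio Length-3 numeric: CAp position in the hindfoot
#'   anatomical frame per unit calcaneal length. The package default
#'   ([afm_cap_reference()]) is derived from the synthetic template foot and
#'   is not a population-based value.
#' @return The calibration with `cap_in_hindfoot` set and
#'   `cap_source = "fallback"`.
#' @export
cap_fallback <- function(cal, reference_ratio = afm_cap_reference()) {
  stopifnot(inherits(cal, "afm_calibration"), length(reference_ratio) == 3)
  if (!is.finite(cal$calcaneal_length) || cal$calcaneal_length <= 0) {
    stop("nonpositive calcaneal length; cannot scale the reference CAp",
      call. = FALSE
    )
  }
  cal$cap_in_hindfoot <- as.numeric(reference_ratio) * cal$calcaneal_length
  cal$cap_source <- "fallback"
  cal$static_angles <- static_angle_table(cal)
  cal
}

#' Reference CAp ratio from the synthetic template foot
#'
#' CAp position in hindfoot anatomical coordinates per unit calcaneal
#' length, measured on the packaged template foot standing flat. A stand-in
#' for a laboratory reference dataset: synthetic, not population-derived.
#'
#' @return Numeric length 3.
#' @export
afm_cap_reference <- function() {
  cal <- afm_calibrate(template_foot(), side = "right")
  cal$cap_in_hindfoot / cal$calcaneal_length
}

#' @export
print.afm_calibration <- function(x, ...) {
  cat(
    "<afm_calibration>", x$side, "foot;",
    sprintf("calcaneal length %.1f mm;", x$calcaneal_length),
    "CAp source:", x$cap_source, "\n"
  )
  cat(" static angles:\n")
  print(tidyr::pivot_wider(x$static_angles,
    names_from = "plane", values_from = "angle"
  ), n = 9)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname afm_calibrate
#' @param x An `afm_calibration`.
#' @param ... Unused.
#' @export
tidy.afm_calibration <- function(x, ...) x$static_angles

#' @rdname afm_calibrate
#' @export
glance.afm_calibration <- function(x, ...) {
  tibble::tibble(
    side = x$side,
    calcaneal_length = x$calcaneal_length,
    cap_source = x$cap_source,
    full_foot_contact = x$full_foot_contact,
    n_frames_static = x$n_frames_static
  )
}

# ---- dynamic reconstruction ----------------------------------------------

# Kabsch least-squares rotation mapping point cloud P0 onto P (rows = points).
kabsch <- function(P0, P) {
  c0 <- colMeans(P0)
  c1 <- colMeans(P)
  H <- crossprod(sweep(P0, 2, c0), sweep(P, 2, c1))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = c1 - as.numeric(R %*% c0))
}

#' Reconstruct per-frame anatomical segment frames
#'
#' Rebuilds every segment's anatomical frame for each frame of a dynamic
#' trial: shank, hindfoot and forefoot through their technical tracking
#' frames and the calibrated anatomical-in-technical transforms; midfoot,
#' medial/lateral forefoot and hallux directly from their (all retained)
#' anatomical markers. The virtual arch points CAp and HM1p are mapped to
#' lab coordinates from their calibrated segment-fixed positions.
#'
#' Frames with a missing tracking marker are flagged invalid (`NA` pose),
#' never interpolated.
#'
#' @param trial An [afm_trial()] with the tracking markers.
#' @param cal An `afm_calibration` from [afm_calibrate()].
#' @param segments Segments to reconstruct (default all seven).
#' @param tracking `"triad"` (the deterministic three-marker construction,
#'   exactly invertible on rigid data) or `"least_squares"` (Kabsch fit over
#'   the segment's tracking markers).
#' @param rate Sampling-rate override.
#' @return A list of class `afm_frames`: per segment a list with rotation
#'   array `R` (3 x 3 x n), `origin` (n x 3) and `valid` (logical n), plus
#'   `time`, `cap`, `hm1p`.
#' @export
reconstruct_frames <- function(trial, cal, segments = afm_segments()$segment,
                               tracking = c("triad", "least_squares"),
                               rate = NULL) {
  stopifnot(inherits(cal, "afm_calibration"))
  tracking <- match.arg(tracking)
  segments <- vapply(segments, check_segment, character(1))
  arr <- trial_array(trial)
  if (cal$side == "left") arr$xyz[, , 3] <- -arr$xyz[, , 3]
  n <- length(arr$frames)

  out <- lapply(stats::setNames(segments, segments), function(s) {
    list(
      R = array(NA_real_, c(3, 3, n)),
      origin = matrix(NA_real_, n, 3),
      valid = rep(FALSE, n)
    )
  })
  cap <- matrix(NA_real_, n, 3)
  hm1p <- matrix(NA_real_, n, 3)

  direct_needed <- intersect(segments, direct_segments)
  for (i in seq_len(n)) {
    m <- markers_at(arr, i)
    for (s in intersect(segments, calibrated_segments)) {
      segcal <- cal$segments[[s]]
      trio <- segcal$tracking_markers
      if (!all(trio %in% rownames(m)) || anyNA(m[trio, ])) next
      if (tracking == "triad") {
        tech <- build_frame(
          m[trio[1], ], m[trio[2], ] - m[trio[1], ], m[trio[3], ] - m[trio[1], ],
          "x", "y",
          context = paste0(s, " technical")
        )
        R <- tech$R %*% segcal$rotation
        o <- tech$origin + as.numeric(tech$R %*% segcal$translation)
      } else {
        fit <- kabsch(segcal$tracking_static, m[trio, , drop = FALSE])
        a0 <- cal$static_frames[[s]]
        R <- fit$R %*% a0$R
        o <- as.numeric(fit$R %*% a0$origin) + fit$t
      }
      out[[s]]$R[, , i] <- R
      out[[s]]$origin[i, ] <- o
      out[[s]]$valid[i] <- TRUE
    }
    if (length(direct_needed)) {
      need <- unique(unlist(anatomical_marker_sets[direct_needed]))
      have <- all(need %in% rownames(m)) && !anyNA(m[need, ])
      if (have) {
        mi <- add_virtual_midpoints(m)
        for (s in direct_needed) {
          f <- anatomical_frame_right(s, mi)
          out[[s]]$R[, , i] <- f$R
          out[[s]]$origin[i, ] <- f$origin
          out[[s]]$valid[i] <- TRUE
        }
      }
    }
    if ("hindfoot" %in% segments && out$hindfoot$valid[i] &&
      !is.null(cal$cap_in_hindfoot)) {
      cap[i, ] <- out$hindfoot$origin[i, ] +
        as.numeric(out$hindfoot$R[, , i] %*% cal$cap_in_hindfoot)
    }
    if ("forefoot" %in% segments && out$forefoot$valid[i]) {
      hm1p[i, ] <- out$forefoot$origin[i, ] +
        as.numeric(out$forefoot$R[, , i] %*% cal$hm1p_in_forefoot)
    }
  }

  structure(
    list(
      segments = out, time = arr$time, frames = arr$frames,
      cap = cap, hm1p = hm1p,
      nav = if ("NAV" %in% arr$markers) matrix(arr$xyz[, "NAV", ], n, 3) else NULL,
      side = cal$side
    ),
    class = "afm_frames"
  )
}
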