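# Synthetic fixtures: an anthropometric template foot, a rigid-segment gait
# generator with ground-truth angles and events, and perturbation injection
# (misplacement, soft-tissue-artifact style offsets, noise).

template_coords <- rbind(
  CALP = c(-5, 60, 0), CALD = c(-5, 20, 0), ST = c(58, 30, -25), PT = c(58, 22, 30),
  NAV = c(75, 45, -20), BM1 = c(95, 30, -25), BM2 = c(105, 32, -8), BM5 = c(85, 22, 30),
  HM1 = c(165, 28, -35), HM2 = c(175, 30, -10), HM5 = c(150, 20, 32), HLX = c(205, 22, -28),
  MM = c(15, 75, -35), LM = c(15, 70, 38), TT = c(60, 380, 0), FH = c(30, 360, 45),
  ASHN = c(45, 230, 0), LSHN = c(25, 225, 30)
)

# Marker-to-rigid-body assignment used by the generator (each physical
# marker rides exactly one segment body).
body_markers <- list(
  shank = c("TT", "FH", "ASHN", "LSHN", "LM", "MM"),
  hindfoot = c("CALP", "CALD", "ST", "PT"),
  midfoot = "NAV",
  forefoot = c("BM1", "BM2", "BM5", "HM1", "HM2", "HM5"),
  hallux = "HLX"
)

#' Template foot marker set
#'
#' Fixed, anthropometrically plausible neutral-standing marker positions for
#' a right foot of roughly EU shoe size 41 (mm, y-up, x anterior, floor at
#' y = 0; CALD-CALP spacing 40 mm at scale 1). Left feet are mirrored in z;
#' `scale` scales uniformly (about 0.7-1.4 covers child to large adult).
#'
#' @param side `"right"` or `"left"`.
#' @param scale Uniform scale factor (> 0).
#' @return Marker tibble (`marker`, `x`, `y`, `z`).
#' @examples
#' template_foot()
#' @export
template_foot <- function(side = "right", scale = 1) {
  side <- check_side(side)
  if (!is.numeric(scale) || length(scale) != 1 || !is.finite(scale) || scale <= 0) {
    stop("scale must be a positive number", call. = FALSE)
  }
  m <- template_coords * scale
  if (side == "left") m <- mirror_markers(m)
  marker_tibble(m)
}

#' Default joint-angle profile for the gait generator
#'
#' Smooth periodic prescribed curves, one per joint and plane:
#' `angle(t) = offset + amplitude * sin(2 pi t / stride_time + phase)`.
#' `offset = NA` means "the template's static angle", so motion oscillates
#' about the neutral pose. Amplitudes are within physiological bounds
#' (<= 40 deg); the Lisfranc (FF_MF) amplitudes default to 0 so that every
#' prescribed curve is exactly recoverable from the generated markers (the
#' midfoot coordinate system shares BM2/BM5 with the forefoot, so nonzero
#' prescribed Lisfranc motion deforms that marker triple — a property of the
#' marker model, not of the generator). The hallux frontal plane is not
#' expressible and is pinned to 0.
#'
#' @return Tibble `joint`, `plane`, `amplitude` (deg), `phase` (deg),
#'   `offset` (deg or `NA`).
#' @export
gait_profile <- function() {
  tibble::tribble(
    ~joint, ~plane, ~amplitude, ~phase, ~offset,
    "HF_SK", "sagittal", 12, -90, NA,
    "HF_SK", "frontal", 4, 30, NA,
    "HF_SK", "transverse", 3, 60, NA,
    "MF_HF", "sagittal", 4, 0, NA,
    "MF_HF", "frontal", 3, 45, NA,
    "MF_HF", "transverse", 3, 90, NA,
    "FF_MF", "sagittal", 0, 0, NA,
    "FF_MF", "frontal", 0, 0, NA,
    "FF_MF", "transverse", 0, 0, NA,
    "HX_FFM", "sagittal", 18, 180, NA,
    "HX_FFM", "transverse", 3, 0, NA
  )
}

# Evaluate and restore RNG state around seeded noise injection.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  )
  set.seed(seed)
  expr
}

profile_fun <- function(profile, statics, stride_time) {
  stopifnot(all(c("joint", "plane", "amplitude", "phase") %in% names(profile)))
  if (any(!is.finite(profile$amplitude)) || any(profile$amplitude < 0) ||
    any(profile$amplitude > 40)) {
    stop("invalid gait profile: amplitudes must be finite, >= 0 and <= 40 deg",
      call. = FALSE
    )
  }
  if (!"offset" %in% names(profile)) profile$offset <- NA_real_
  function(joint, plane, t) {
    row <- profile[profile$joint == joint & profile$plane == plane, ]
    off <- statics[[paste(joint, plane)]] %||% 0
    if (nrow(row) == 0) {
      return(rep(off, length(t)))
    }
    o <- if (is.na(row$offset[1])) off else row$offset[1]
    o + row$amplitude[1] * sin(2 * pi * t / stride_time + rad(row$phase[1]))
  }
}

#' Synthesize a walking trial with known ground truth
#'
#' Generates marker trajectories by moving the template foot as a kinematic
#' chain of rigid segments: the hindfoot follows a foot-flat-in-stance
#' trajectory (stationary during stance, smooth forward/upward swing), the
#' shank pose realizes the prescribed hindfoot-shank angles, the midfoot
#' follows the prescribed midfoot-hindfoot angles, the forefoot the
#' prescribed Lisfranc angles and the hallux the prescribed MTP1 angles.
#' Markers are rigidly attached to their segment; optional perturbations
#' (constant misplacement offsets, pose-dependent soft-tissue-artifact
#' offsets, isotropic noise) are applied afterwards.
#'
#' Returned ground truth: the prescribed/derived angle curves of all seven
#' joints plus MLA and TTA, and the exact initial-contact/toe-off times.
#' With the default profile (zero Lisfranc amplitude) every pipeline angle
#' reproduces its ground-truth curve exactly on noise-free data.
#'
#' @param profile Prescribed curves, see [gait_profile()].
#' @param side,scale Passed to [template_foot()].
#' @param rate Sampling rate in Hz (>= 50).
#' @param n_strides Number of complete gait cycles.
#' @param stride_time Stride duration in s.
#' @param stance_fraction Fraction of the stride spent in stance.
#' @param stride_length Forward progression per stride in mm.
#' @param foot_lift Peak foot-center lift during swing in mm.
#' @param noise_sd Isotropic marker noise SD in mm.
#' @param misplacement Named list `marker -> c(dx, dy, dz)` (mm): constant
#'   offsets applied to the template before generation (a misplaced but
#'   consistently tracked marker).
#' @param sta Named list `marker -> c(cx, cy, cz)` (mm per degree): soft-
#'   tissue-artifact style offsets proportional to the hindfoot-shank
#'   sagittal deviation from static, applied after generation.
#' @param seed Seed for the noise; RNG state is restored afterwards.
#' @return A list of class `afm_synthetic`: `trial` (an [afm_trial()]),
#'   `truth` (list with `angles`, `events`, `exact`), and the generation
#'   parameters.
#' @export
synthesize_gait <- function(profile = gait_profile(), side = "right",
                            scale = 1, rate = 100, n_strides = 3,
                            stride_time = 1.1, stance_fraction = 0.6,
                            stride_length = 1200, foot_lift = 45,
                            noise_sd = 0, misplacement = NULL, sta = NULL,
                            seed = NULL) {
  side <- check_side(side)
  if (rate < 50) stop("rate must be >= 50 Hz", call. = FALSE)
  stopifnot(n_strides >= 1, stride_time > 0, stance_fraction > 0, stance_fraction < 1)

  m0 <- marker_matrix(template_foot("right", scale))
  # misplaced markers ride their body at a consistently wrong location; the
  # ground truth below stays that of the ideal model
  mp <- m0
  if (!is.null(misplacement)) {
    bad <- setdiff(names(misplacement), rownames(m0))
    if (length(bad)) stop("misplacement of unknown marker(s): ", paste(bad, collapse = ", "), call. = FALSE)
    for (mk in names(misplacement)) mp[mk, ] <- mp[mk, ] + misplacement[[mk]]
  }
  mm0 <- add_virtual_midpoints(m0)
  F0 <- lapply(
    stats::setNames(segment_names, segment_names),
    function(s) anatomical_frame_right(s, mm0)
  )
  statics <- list()
  for (j in seq_len(nrow(joint_table))) {
    a <- cardan_zxy(F0[[joint_table$proximal[j]]]$R, F0[[joint_table$distal[j]]]$R)
    for (p in 1:3) statics[[paste(joint_table$joint[j], plane_names[p])]] <- a[[p]]
  }
  pf <- profile_fun(profile, statics, stride_time)

  T_s <- stride_time
  sf <- stance_fraction
  total_time <- (n_strides + 1 + 0.3) * T_s
  n <- floor(total_time * rate) + 1L
  t <- (seq_len(n) - 1) / rate

  # foot-center progression: stationary in stance, smooth swing
  k <- pmin(floor(t / T_s), n_strides)
  u <- pmin(t / T_s - k, 1)
  su <- pmax((u - sf) / (1 - sf), 0)
  dx <- (k + (su - sin(2 * pi * su) / (2 * pi))) * stride_length
  dy <- foot_lift * sin(pi * su)^2

  # prescribed per-frame relative rotations
  ang <- function(joint) {
    vapply(
      plane_names,
      function(p) if (joint == "HX_FFM" && p == "frontal") rep(0, n) else pf(joint, p, t),
      numeric(n)
    )
  }
  a_hfsk <- ang("HF_SK")
  a_mfhf <- ang("MF_HF")
  a_ffmf <- ang("FF_MF")
  a_hxffm <- ang("HX_FFM")

  # static arch references for ground truth
  floor_y <- 0
  st_pt_mid <- (m0["ST", ] + m0["PT", ]) / 2
  cap0 <- (m0["CALP", ] + st_pt_mid) / 2
  cap0[2] <- floor_y
  hm1p0 <- m0["HM1", ]
  hm1p0[2] <- floor_y

  xyz <- array(NA_real_, c(n, nrow(m0), 3), dimnames = list(NULL, rownames(m0), c("x", "y", "z")))
  truth_rows <- vector("list", n)
  R_HF0 <- F0$hindfoot$R
  for (i in seq_len(n)) {
    d <- c(dx[i], dy[i], 0)
    R_relHS <- rot_frame(a_hfsk[i, 1], a_hfsk[i, 2], a_hfsk[i, 3])
    R_relMH <- rot_frame(a_mfhf[i, 1], a_mfhf[i, 2], a_mfhf[i, 3])
    R_relFM <- rot_frame(a_ffmf[i, 1], a_ffmf[i, 2], a_ffmf[i, 3])
    R_relHX <- rot_frame(a_hxffm[i, 1], a_hxffm[i, 2], a_hxffm[i, 3])

    R_HF <- R_HF0
    R_SK <- R_HF %*% t(R_relHS)
    R_MF <- R_HF %*% R_relMH
    R_FF <- R_MF %*% R_relFM
    R_FFM <- R_FF %*% crossprod(F0$forefoot$R, F0$medial_forefoot$R)
    R_FFL <- R_FF %*% crossprod(F0$forefoot$R, F0$lateral_forefoot$R)
    R_HX <- R_FFM %*% R_relHX

    # rigid body transforms (pivot chain: ankle, Chopart, Lisfranc, MTP1)
    move <- function(R_now, R_stat, pivot0, pivot_now, pts) {
      sweep((pts - rep(pivot0, each = nrow(pts))) %*% t(R_now %*% t(R_stat)), 2, -pivot_now)
    }
    hf_pts <- mp[body_markers$hindfoot, , drop = FALSE]
    xyz[i, body_markers$hindfoot, ] <- sweep(hf_pts, 2, -d) # rotation constant
    ankle0 <- (m0["LM", ] + m0["MM", ]) / 2
    ankle_now <- ankle0 + d
    xyz[i, body_markers$shank, ] <- move(
      R_SK, F0$shank$R, ankle0, ankle_now,
      mp[body_markers$shank, , drop = FALSE]
    )
    chop0 <- F0$midfoot$origin
    chop_now <- chop0 + d
    Q_MF <- R_MF %*% t(F0$midfoot$R)
    A_MF <- function(p) chop_now + as.numeric(Q_MF %*% (p - chop0))
    xyz[i, "NAV", ] <- A_MF(mp["NAV", ])
    lis0 <- F0$forefoot$origin
    lis_now <- A_MF(lis0)
    Q_FF <- R_FF %*% t(F0$forefoot$R)
    A_FF <- function(p) lis_now + as.numeric(Q_FF %*% (p - lis0))
    xyz[i, body_markers$forefoot, ] <- t(apply(
      mp[body_markers$forefoot, , drop = FALSE], 1, A_FF
    ))
    hm1_now <- A_FF(mp["HM1", ])
    xyz[i, "HLX", ] <- hm1_now +
      as.numeric((R_HX %*% t(F0$hallux$R)) %*% (mp["HLX", ] - mp["HM1", ]))

    # derived ground-truth angles
    ffhf <- cardan_zxy(R_HF, R_FF)
    ffm <- cardan_zxy(R_MF, R_FFM)
    ffl <- cardan_zxy(R_MF, R_FFL)
    nav_now <- A_MF(m0["NAV", ])
    cap_now <- cap0 + d
    hm1p_now <- A_FF(hm1p0)
    truth_rows[[i]] <- c(
      ffhf, ffm, ffl,
      MLA = angle_between(nav_now - cap_now, nav_now - hm1p_now)
    )
  }

  derived <- do.call(rbind, truth_rows)
  bm <- m0[c("BM1", "BM2", "BM5"), ]
  tta0 <- angle_between(bm[2, ] - bm[1, ], bm[3, ] - bm[2, ])
  truth_angles <- dplyr::bind_rows(
    curve_rows("HF_SK", t, a_hfsk),
    curve_rows("MF_HF", t, a_mfhf),
    curve_rows("FF_MF", t, a_ffmf),
    curve_rows("HX_FFM", t, a_hxffm, drop_frontal = TRUE),
    curve_rows("FF_HF", t, derived[, 1:3]),
    curve_rows("FFM_MF", t, derived[, 4:6]),
    curve_rows("FFL_MF", t, derived[, 7:9]),
    tibble::tibble(
      time = rep(t, 2), joint = rep(c("MLA", "TTA"), each = n),
      plane = "planar", angle = c(derived[, 10], rep(tta0, n))
    )
  )

  # perturbations
  if (!is.null(sta)) {
    bad <- setdiff(names(sta), rownames(m0))
    if (length(bad)) stop("STA offsets for unknown marker(s): ", paste(bad, collapse = ", "), call. = FALSE)
    drive <- a_hfsk[, 1] - statics[["HF_SK sagittal"]]
    for (mk in names(sta)) {
      xyz[, mk, ] <- xyz[, mk, ] + outer(drive, sta[[mk]])
    }
  }
  if (noise_sd > 0) {
    xyz <- xyz + with_seed(seed, array(stats::rnorm(length(xyz), 0, noise_sd), dim(xyz)))
  }
  if (side == "left") xyz[, , 3] <- -xyz[, , 3]

  trial <- trial_from_array(xyz, rate,
    metadata = list(side = side, source = "synthesize_gait", seed = seed)
  )
  events <- tibble::tibble(
    event = c(rep("TO", n_strides + 1), rep("IC", n_strides + 1)),
    time = c((0:n_strides + sf) * T_s, (1:(n_strides + 1)) * T_s)
  )
  events$frame <- round(events$time * rate) + 1L
  events <- events[order(events$time), ]

  structure(
    list(
      trial = trial,
      truth = list(
        angles = truth_angles, events = events,
        exact = max(abs(sweep(a_ffmf, 2, a_ffmf[1, ]))) < 1e-12
      ),
      side = side, scale = scale, rate = rate, n_strides = n_strides,
      stride_time = stride_time, stance_fraction = stance_fraction,
      noise_sd = noise_sd, seed = seed
    ),
    class = "afm_synthetic"
  )
}

curve_rows <- function(joint, t, mat, drop_frontal = FALSE) {
  planes <- plane_names
  out <- tibble::tibble(
    time = rep(t, 3), joint = joint,
    plane = rep(planes, each = length(t)), angle = c(mat[, 1], mat[, 2], mat[, 3])
  )
  if (drop_frontal) out <- out[out$plane != "frontal", ]
  out
}

#' Synthesize a neutral-standing static trial
#'
#' Template-foot markers held still for `duration` seconds, with optional
#' seeded isotropic noise.
#'
#' @inheritParams synthesize_gait
#' @param duration Trial length in s.
#' @return An [afm_trial()].
#' @export
synthesize_static <- function(side = "right", scale = 1, rate = 100,
                              duration = 0.1, noise_sd = 0, seed = NULL) {
  side <- check_side(side)
  m <- marker_matrix(template_foot(side, scale))
  n <- max(1L, floor(duration * rate))
  xyz <- array(NA_real_, c(n, nrow(m), 3),
    dimnames = list(NULL, rownames(m), c("x", "y", "z"))
  )
  for (l in 1:3) xyz[, , l] <- matrix(m[, l], n, nrow(m), byrow = TRUE)
  if (noise_sd > 0) {
    xyz <- xyz + with_seed(seed, array(stats::rnorm(length(xyz), 0, noise_sd), dim(xyz)))
  }
  trial_from_array(xyz, rate, metadata = list(side = side, source = "synthesize_static"))
}

#' @export
print.afm_synthetic <- function(x, ...) {
  cat(sprintf(
    "<afm_synthetic> %s foot, %d strides at %g Hz, noise %g mm%s\n",
    x$side, x$n_strides, x$rate, x$noise_sd,
    if (x$truth$exact) "" else " (approximate midfoot truth: nonzero Lisfranc amplitude)"
  ))
  print(x$trial)
  invisible(x)
}
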