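# Segment coordinate-system constructions: the anatomical frames (one per
# segment, from palpated landmarks) and the technical tracking frames (three
# retained markers per tracked segment).

segment_names <- c(
  "shank", "hindfoot", "midfoot", "forefoot",
  "medial_forefoot", "lateral_forefoot", "hallux"
)

# Physical markers entering each segment's anatomical frame (midpoints
# expanded to their parents). Used for marker requirements and to decide
# which (segment, marker) sensitivity records are applicable.
anatomical_marker_sets <- list(
  shank = c("LM", "MM", "FH", "TT"),
  hindfoot = c("CALD", "CALP", "ST", "PT"),
  midfoot = c("NAV", "BM2", "BM5"),
  forefoot = c("BM1", "BM2", "BM5", "HM1", "HM2", "HM5"),
  medial_forefoot = c("BM1", "BM2", "HM1", "HM2"),
  lateral_forefoot = c("BM2", "BM5", "HM2", "HM5"),
  hallux = c("HM1", "HLX", "BM1", "BM2", "HM2")
)

technical_marker_sets <- list(
  shank = c("TT", "ASHN", "LSHN"),
  hindfoot = c("CALD", "ST", "PT"),
  midfoot = c("NAV", "BM2", "BM5"),
  forefoot = c("BM1", "HM2", "BM5")
)

needs_midpoints <- c("forefoot", "medial_forefoot", "lateral_forefoot", "hallux")

# Segments whose defining markers all survive into dynamic trials; their
# anatomical frames are recomputed directly each frame instead of being
# reconstructed through a technical frame.
direct_segments <- c("midfoot", "medial_forefoot", "lateral_forefoot", "hallux")
calibrated_segments <- c("shank", "hindfoot", "forefoot")

#' AFM segments
#'
#' @return Tibble with one row per segment: `segment`, whether it is part of
#'   the optional medial/lateral forefoot split, and the markers defining its
#'   anatomical and technical coordinate systems.
#' @export
afm_segments <- function() {
  tibble::tibble(
    segment = segment_names,
    optional = segment_names %in% c("medial_forefoot", "lateral_forefoot"),
    anatomical_markers = unname(anatomical_marker_sets[segment_names]),
    technical_markers = lapply(segment_names, function(s) {
      technical_marker_sets[[s]] %||% character(0)
    })
  )
}

joint_table <- tibble::tribble(
  ~joint, ~proximal, ~distal,
  "HF_SK", "shank", "hindfoot",
  "MF_HF", "hindfoot", "midfoot",
  "FF_HF", "hindfoot", "forefoot",
  "FF_MF", "midfoot", "forefoot",
  "FFL_MF", "midfoot", "lateral_forefoot",
  "FFM_MF", "midfoot", "medial_forefoot",
  "HX_FFM", "medial_forefoot", "hallux"
)

#' AFM joints
#'
#' The seven model joints with their proximal/distal segment mapping:
#' hindfoot-shank (ankle complex), midfoot-hindfoot (Chopart),
#' forefoot-hindfoot, forefoot-midfoot (Lisfranc), lateral/medial
#' forefoot-midfoot, and hallux-medial forefoot (MTP1). The foot-shank
#' (`F_SK`) angle is available through [foot_shank_angles()] by plugging in
#' an externally defined foot frame.
#'
#' @return Tibble with columns `joint`, `proximal`, `distal`.
#' @export
afm_joints <- function() joint_table

check_segment <- function(segment) {
  if (!segment %in% segment_names) {
    stop("unknown segment '", segment, "'; see afm_segments()", call. = FALSE)
  }
  segment
}

# Core per-segment constructions, right-foot formulas, on a marker matrix
# that is already right-oriented and contains the virtual midpoints.
anatomical_frame_right <- function(segment, m) {
  g <- function(n) m[n, ]
  mid <- function(a, b) (m[a, ] + m[b, ]) / 2
  switch(segment,
    shank = {
      O <- mid("LM", "MM")
      n <- cross3(g("LM") - O, g("FH") - O) # quasi-frontal plane O, LM, FH
      tt_proj <- project_point_on_plane(g("TT"), n, O)
      # Y to the projected tibial tuberosity; X = Y x (LM - O); Z completes
      build_frame(O, tt_proj - O, g("LM") - O, "y", "z", context = "shank (LM, MM, FH, TT)")
    },
    hindfoot = {
      O <- mid("CALD", "CALP")
      build_frame(O, mid("ST", "PT") - O, g("CALP") - g("CALD"), "x", "y",
        context = "hindfoot (CALD, CALP, ST, PT)"
      )
    },
    midfoot = {
      O <- mid("NAV", "BM5")
      Y <- cross3(g("BM5") - g("NAV"), g("BM2") - g("NAV"))
      build_frame(O, g("BM2") - O, Y, "x", "y", context = "midfoot (NAV, BM2, BM5)")
    },
    forefoot = {
      O <- mid("mBM12", "mBM25")
      Y <- cross3(g("mHM25") - O, g("mHM12") - O)
      build_frame(O, mid("mHM12", "mHM25") - O, Y, "x", "y",
        context = "forefoot (metatarsal midpoints)"
      )
    },
    medial_forefoot = {
      O <- g("mBM12")
      X <- g("mHM12") - O
      build_frame(O, X, cross3(g("BM2") - g("BM1"), X), "x", "y",
        context = "medial forefoot (BM1, BM2, HM1, HM2)"
      )
    },
    lateral_forefoot = {
      O <- g("mBM25")
      X <- g("mHM25") - O
      build_frame(O, X, cross3(g("BM5") - g("BM2"), X), "x", "y",
        context = "lateral forefoot (BM2, BM5, HM2, HM5)"
      )
    },
    hallux = {
      O <- g("HM1")
      X <- g("HLX") - O
      z_mff <- anatomical_frame_right("medial_forefoot", m)$R[, 3]
      # Y = Z_medial_forefoot x X; Z completes the right-handed triad
      build_frame(O, X, cross3(z_mff, X), "x", "y",
        context = "hallux (HM1, HLX + medial forefoot z)"
      )
    }
  )
}

#' Anatomical segment coordinate system
#'
#' Builds a segment's anatomical frame from a labeled marker set using the
#' AFM landmark constructions (ISB axes: x anterior, y superior, z to the
#' right). For the left side the marker set is internally reflected across
#' the lab sagittal plane and the right-foot formulas applied, which is
#' equivalent to the published flipped subtraction orders and keeps
#' dorsiflexion/inversion/adduction positive on both sides.
#'
#' @param markers Marker set (tibble `marker`, `x`, `y`, `z`, mm, y-up).
#' @param segment One of `afm_segments()$segment`.
#' @param side `"right"` or `"left"`.
#' @return An `afm_frame` (origin + 3x3 rotation).
#' @examples
#' anatomical_frame(template_foot(), "hindfoot")
#' @export
anatomical_frame <- function(markers, segment, side = "right") {
  check_segment(segment)
  m <- orient_markers(marker_matrix(markers), side)
  need <- anatomical_marker_sets[[segment]]
  require_markers(m, need, paste0(segment, " anatomical frame"))
  if (segment %in% needs_midpoints) m <- add_virtual_midpoints(m)
  anatomical_frame_right(segment, m)
}

#' Technical (tracking) coordinate system
#'
#' Deterministic orthonormal frame from a segment's three tracking markers:
#' origin at the first marker, primary axis toward the second, the third
#' fixing the plane. The same construction is used for static and dynamic
#' trials, so anatomical frames stored relative to it at calibration are
#' reconstructed exactly for rigid marker clouds.
#'
#' @inheritParams anatomical_frame
#' @param segment One of `"shank"`, `"hindfoot"`, `"midfoot"`, `"forefoot"`.
#' @return An `afm_frame`.
#' @export
technical_frame <- function(markers, segment, side = "right") {
  trio <- technical_marker_sets[[segment]]
  if (is.null(trio)) {
    stop("segment '", segment, "' has no technical coordinate system; ",
      "its anatomical frame is recomputed directly each frame",
      call. = FALSE
    )
  }
  m <- orient_markers(marker_matrix(markers), side)
  require_markers(m, trio, paste0(segment, " technical frame"))
  build_frame(
    m[trio[1], ], m[trio[2], ] - m[trio[1], ], m[trio[3], ] - m[trio[1], ],
    "x", "y",
    context = paste0(segment, " technical (", paste(trio, collapse = ", "), ")")
  )
}
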