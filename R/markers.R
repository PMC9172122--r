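# The AFM marker set: 18 physical markers plus 4 virtual metatarsal
# midpoints. Roles: "anatomical" markers are only needed in the static trial,
# "tracking" markers only during gait, "both" serve both purposes.

afm_marker_table <- tibble::tribble(
  ~marker, ~segment,    ~role,         ~description,
  "TT",    "shank",     "both",        "Tibial tuberosity, most anterior prominence",
  "FH",    "shank",     "anatomical",  "Fibular head, most proximal apex",
  "ASHN",  "shank",     "tracking",    "Anterior shin, halfway the shank on the tibia",
  "LSHN",  "shank",     "tracking",    "Lateral shin, on the FH-LM line at ASHN height",
  "LM",    "shank",     "anatomical",  "Lateral malleolus, distal apex",
  "MM",    "shank",     "anatomical",  "Medial malleolus, distal apex",
  "CALP",  "hindfoot",  "anatomical",  "Calcaneus posterior aspect, proximal (Achilles attachment)",
  "CALD",  "hindfoot",  "both",        "Calcaneus posterior aspect, distal",
  "ST",    "hindfoot",  "both",        "Sustentaculum tali, most medial apex",
  "PT",    "hindfoot",  "both",        "Peroneal tubercle, most lateral apex",
  "NAV",   "midfoot",   "both",        "Navicular tuberosity, most medial apex",
  "BM1",   "forefoot",  "both",        "Base metatarsal 1, dorso-medial",
  "BM2",   "forefoot",  "both",        "Base metatarsal 2",
  "BM5",   "forefoot",  "both",        "Base metatarsal 5, dorso-medial",
  "HM1",   "forefoot",  "both",        "Head metatarsal 1, dorso-medial",
  "HM2",   "forefoot",  "both",        "Head metatarsal 2",
  "HM5",   "forefoot",  "both",        "Head metatarsal 5, dorso-medial",
  "HLX",   "hallux",    "both",        "Proximal phalanx hallux, most distal, dorso-medial",
  "mBM12", "forefoot",  "virtual",     "Midpoint between BM1 and BM2",
  "mBM25", "forefoot",  "virtual",     "Midpoint between BM2 and BM5",
  "mHM12", "forefoot",  "virtual",     "Midpoint between HM1 and HM2",
  "mHM25", "forefoot",  "virtual",     "Midpoint between HM2 and HM5"
)

virtual_midpoint_parents <- list(
  mBM12 = c("BM1", "BM2"),
  mBM25 = c("BM2", "BM5"),
  mHM12 = c("HM1", "HM2"),
  mHM25 = c("HM2", "HM5")
)

#' The AFM marker dictionary
#'
#' One row per marker: name, owning segment, role (`"anatomical"` = static
#' trial only, `"tracking"` = gait only, `"both"`, `"virtual"` = computed
#' midpoint) and a placement description.
#'
#' @return A tibble with columns `marker`, `segment`, `role`, `description`.
#' @examples
#' afm_markers()
#' @export
afm_markers <- function() afm_marker_table

physical_marker_names <- function() {
  afm_marker_table$marker[afm_marker_table$role != "virtual"]
}

tracking_marker_names <- function() {
  afm_marker_table$marker[afm_marker_table$role %in% c("tracking", "both")]
}

#' Marker label aliases
#'
#' Mapping from common laboratory labels to canonical AFM marker names:
#' the canonical names themselves plus `R_`/`L_`-prefixed and lower-case
#' variants. Used by the trial readers; unmapped labels are kept but ignored
#' by the model.
#'
#' @return A tibble with columns `alias`, `marker`.
#' @export
afm_marker_aliases <- function() {
  nm <- physical_marker_names()
  tibble::tibble(
    alias = c(nm, paste0("R_", nm), paste0("L_", nm), tolower(nm)),
    marker = rep(nm, 4)
  )
}

# ---- marker set representation -------------------------------------------
# User-facing: tibble with columns marker, x, y, z (mm, lab frame, y-up).
# Internal: named n x 3 matrix, rows = markers.

marker_matrix <- function(markers) {
  if (is.matrix(markers)) {
    return(markers)
  }
  stopifnot(is.data.frame(markers))
  need <- c("marker", "x", "y", "z")
  if (!all(need %in% names(markers))) {
    stop("a marker set needs columns marker, x, y, z", call. = FALSE)
  }
  if (anyDuplicated(markers$marker)) {
    stop("duplicate marker labels: ",
      paste(unique(markers$marker[duplicated(markers$marker)]), collapse = ", "),
      call. = FALSE
    )
  }
  m <- as.matrix(markers[, c("x", "y", "z")])
  rownames(m) <- markers$marker
  m
}

marker_tibble <- function(m) {
  tibble::tibble(
    marker = rownames(m),
    x = unname(m[, 1]), y = unname(m[, 2]), z = unname(m[, 3])
  )
}

require_markers <- function(m, names, context = "this computation") {
  missing <- setdiff(names, rownames(m))
  missing <- union(missing, names[rowSums(!is.finite(m[intersect(names, rownames(m)), , drop = FALSE])) > 0])
  if (length(missing)) {
    stop("missing marker(s) for ", context, ": ",
      paste(sort(missing), collapse = ", "),
      call. = FALSE
    )
  }
  invisible(TRUE)
}

#' Add virtual metatarsal midpoints to a marker set
#'
#' Adds the four virtual markers `mBM12`, `mBM25`, `mHM12`, `mHM25` (pairwise
#' midpoints of the metatarsal base/head markers). Virtual markers already
#' present are left untouched, so a caller may supply displaced midpoints
#' deliberately.
#'
#' @param markers Marker set: tibble with columns `marker`, `x`, `y`, `z`.
#' @return The marker set with the four midpoints appended.
#' @examples
#' add_virtual_midpoints(template_foot())
#' @export
add_virtual_midpoints <- function(markers) {
  was_df <- is.data.frame(markers)
  m <- marker_matrix(markers)
  add <- setdiff(names(virtual_midpoint_parents), rownames(m))
  if (length(add)) {
    parents <- unique(unlist(virtual_midpoint_parents[add]))
    require_markers(m, parents, "virtual midpoint construction")
    extra <- t(vapply(
      add,
      function(v) {
        p <- virtual_midpoint_parents[[v]]
        (m[p[1], ] + m[p[2], ]) / 2
      },
      numeric(3)
    ))
    m <- rbind(m, extra)
  }
  if (was_df) marker_tibble(m) else m
}

# Reflect a marker set across the lab sagittal plane (z -> -z). Left feet
# are processed by mirroring into right-foot geometry, which is equivalent to
# the flipped cross-product subtraction orders of the left-foot formulas and
# keeps clinical angle signs on both sides.
mirror_markers <- function(m) {
  was_df <- is.data.frame(m)
  mm <- marker_matrix(m)
  mm[, 3] <- -mm[, 3]
  if (was_df) marker_tibble(mm) else mm
}

check_side <- function(side) {
  side <- match.arg(side, c("right", "left"))
  side
}

orient_markers <- function(m, side) {
  if (check_side(side) == "left") mirror_markers(m) else m
}
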