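# Virtual marker-misplacement sensitivity: displace each anatomical marker
# +/-10 mm in 1 mm steps along the axes of a foot-specific frame, decompose
# the segment orientation error against the undisplaced pose, and fit the
# least-squares gradient in deg/mm.

displacement_axes <- c("anterior_posterior", "superior_inferior", "medio_lateral")

#' Foot-specific displacement frame
#'
#' The frame whose axes define the marker displacement directions:
#' x = horizontal (floor-plane) projection of the CALD-to-HM2 direction
#' (anterior-posterior), y = lab vertical (superior-inferior),
#' z = x cross y (medio-lateral), origin at CALD.
#'
#' @param markers Marker set with CALD and HM2.
#' @param side `"right"` or `"left"`.
#' @return An `afm_frame`.
#' @export
displacement_frame <- function(markers, side = "right") {
  m <- orient_markers(marker_matrix(markers), side)
  require_markers(m, c("CALD", "HM2"), "the displacement frame")
  d <- m["HM2", ] - m["CALD", ]
  d[2] <- 0
  if (vec_norm(d) < 1e-9) {
    stop("degenerate displacement frame: foot axis is vertical", call. = FALSE)
  }
  x <- vec_unit(d)
  y <- c(0, 1, 0)
  new_afm_frame(m["CALD", ], matrix(c(x, y, cross3(x, y)), 3, 3))
}

ols_slope <- function(x, y) {
  xc <- x - mean(x)
  b <- sum(xc * y) / sum(xc * xc)
  fitted <- mean(y) + b * xc
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot < 1e-24) 1 else 1 - ss_res / ss_tot
  c(slope = b, r_squared = r2)
}

#' Sensitivity of one segment's orientation to one marker's placement
#'
#' Displaces `marker` from -`range_mm` to +`range_mm` in `step_mm` steps
#' along each displacement-frame axis, rebuilds the segment's anatomical
#' frame, decomposes its orientation error with respect to the undisplaced
#' reference, and fits an ordinary least-squares line per anatomical plane.
#' The fit uses the signed planar errors; `gradient` is the absolute slope
#' and `slope` keeps the sign.
#'
#' A marker not entering the segment's anatomical frame is an explicit
#' error, not a zero gradient.
#'
#' @param markers Static marker set.
#' @param segment Segment whose orientation is evaluated.
#' @param marker Marker to displace.
#' @param side `"right"` or `"left"`.
#' @param range_mm,step_mm Displacement range and step (default -10..+10 mm
#'   in 1 mm steps, 21 points including 0).
#' @param frame Displacement frame override (an `afm_frame`).
#' @return Tibble of class `afm_sensitivity`: one row per (axis, plane) with
#'   `segment`, `marker`, `axis`, `plane`, `gradient` (deg/mm, absolute),
#'   `slope` (signed), `r_squared`, `n_points`.
#' @export
marker_sensitivity <- function(markers, segment, marker, side = "right",
                               range_mm = 10, step_mm = 1, frame = NULL) {
  check_segment(segment)
  side <- check_side(side)
  used <- anatomical_marker_sets[[segment]]
  if (!marker %in% used) {
    stop("marker ", marker, " does not enter the ", segment,
      " anatomical frame (uses ", paste(used, collapse = ", "), ")",
      call. = FALSE
    )
  }
  m <- orient_markers(marker_matrix(markers), side)
  require_markers(m, used, paste0(segment, " sensitivity"))
  fr <- frame %||% displacement_frame(marker_tibble(m), "right")
  prep <- function(mm) {
    if (segment %in% needs_midpoints) add_virtual_midpoints(mm) else mm
  }
  ref <- anatomical_frame_right(segment, prep(m))
  d_seq <- seq(-range_mm, range_mm, by = step_mm)
  planes_used <- if (segment == "hallux") c("sagittal", "transverse") else plane_names

  purrr::map_dfr(1:3, function(ax) {
    errs <- t(vapply(d_seq, function(d) {
      md <- m
      md[marker, ] <- md[marker, ] + d * fr$R[, ax]
      as.numeric(cardan_zxy(ref$R, anatomical_frame_right(segment, prep(md))$R))
    }, numeric(3)))
    colnames(errs) <- plane_names
    purrr::map_dfr(planes_used, function(pl) {
      fit <- ols_slope(d_seq, errs[, pl])
      tibble::tibble(
        segment = segment, marker = marker,
        axis = displacement_axes[ax], plane = pl,
        gradient = abs(fit[["slope"]]), slope = fit[["slope"]],
        r_squared = fit[["r_squared"]], n_points = length(d_seq)
      )
    })
  }) |> as_sensitivity(side = side, range_mm = range_mm, step_mm = step_mm)
}

as_sensitivity <- function(df, side, range_mm, step_mm) {
  structure(df,
    side = side, range_mm = range_mm, step_mm = step_mm,
    class = c("afm_sensitivity", class(df))
  )
}

#' Full marker-placement sensitivity table
#'
#' [marker_sensitivity()] for every anatomical marker of the requested
#' segments: one record per (marker, displacement axis, anatomical plane) —
#' e.g. 36 records for the hindfoot (4 markers x 3 axes x 3 planes) and 54
#' for the forefoot.
#'
#' @inheritParams marker_sensitivity
#' @param segments Segments to tabulate (default: the hindfoot and forefoot,
#'   the two segments tracked through calibrated technical frames whose
#'   markers are all palpated landmarks).
#' @return An `afm_sensitivity` tibble (see [marker_sensitivity()]).
#' @examples
#' tab <- sensitivity_table(template_foot())
#' count_sensitive(tab, 1.0)
#' @export
sensitivity_table <- function(markers, segments = c("hindfoot", "forefoot"),
                              side = "right", range_mm = 10, step_mm = 1) {
  fr <- displacement_frame(markers, side)
  purrr::map_dfr(segments, function(s) {
    purrr::map_dfr(
      anatomical_marker_sets[[check_segment(s)]],
      function(mk) {
        marker_sensitivity(markers, s, mk,
          side = side,
          range_mm = range_mm, step_mm = step_mm, frame = fr
        )
      }
    )
  }) |> as_sensitivity(side = side, range_mm = range_mm, step_mm = step_mm)
}

#' Count sensitivity records at or above a threshold
#'
#' @param table An `afm_sensitivity` tibble.
#' @param threshold Gradient threshold in deg/mm.
#' @return Number of records with `|gradient| >= threshold`.
#' @export
count_sensitive <- function(table, threshold) {
  sum(abs(table$gradient) >= threshold)
}

#' @export
print.afm_sensitivity <- function(x, ...) {
  cat(sprintf(
    "<afm_sensitivity> %d records (%s side, +/-%g mm in %g mm steps); %d with gradient >= 0.5 deg/mm\n",
    nrow(x), attr(x, "side") %||% "?", attr(x, "range_mm") %||% NA,
    attr(x, "step_mm") %||% NA, count_sensitive(x, 0.5)
  ))
  print(tibble::as_tibble(x))
  invisible(x)
}
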