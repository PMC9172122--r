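# File I/O: TRC and wide-CSV marker trials, JSON calibration documents,
# CSV/JSON result writers. Positions are stored in mm; vertical-axis
# conventions are converted to the package's y-up lab frame on read.

# Rotate a z-up point cloud (x forward, y left, z up) into the y-up lab
# frame (x forward, y up, z right).
convert_up_axis <- function(df, vertical = c("y", "z")) {
  vertical <- match.arg(vertical)
  if (vertical == "z") {
    df <- dplyr::mutate(df, y0 = .data$y, y = .data$z, z = -.data$y0)
    df$y0 <- NULL
  }
  df
}

map_marker_labels <- function(labels) {
  al <- afm_marker_aliases()
  idx <- match(labels, al$alias)
  miss <- is.na(idx)
  idx[miss] <- match(tolower(labels[miss]), al$alias)
  out <- labels
  out[!is.na(idx)] <- al$marker[idx[!is.na(idx)]]
  out
}

#' Read a marker trial
#'
#' Dispatches on file extension to [read_trc()] or [read_trial_csv()].
#' Labels are mapped to canonical marker names through
#' [afm_marker_aliases()]; unmapped labels are preserved but ignored by the
#' model. Units are converted to mm and the vertical axis to y.
#'
#' @param path File path (`.trc` or `.csv`).
#' @param format `"trc"`, `"csv"` or `NULL` (from extension).
#' @param ... Passed on to the format reader.
#' @return An [afm_trial()].
#' @export
read_trial <- function(path, format = NULL, ...) {
  format <- format %||% tolower(tools::file_ext(path))
  switch(format,
    trc = read_trc(path, ...),
    csv = read_trial_csv(path, ...),
    stop("unknown trial format '", format, "' (supported: trc, csv)", call. = FALSE)
  )
}

#' Read a TRC marker file
#'
#' Standard TRC layout: two header lines of metadata, a label row (Frame#,
#' Time, one label per marker spanning three coordinate columns), a
#' coordinate-name row, then data.
#'
#' @param path File path.
#' @param vertical Vertical axis of the file's lab frame (`"y"` or `"z"`).
#' @return An [afm_trial()].
#' @export
read_trc <- function(path, vertical = "y") {
  lines <- readLines(path)
  if (length(lines) < 5) stop("not a TRC file: ", path, call. = FALSE)
  meta_keys <- strsplit(lines[2], "\t")[[1]]
  meta_vals <- strsplit(lines[3], "\t")[[1]]
  meta <- stats::setNames(as.list(meta_vals), meta_keys)
  rate <- as.numeric(meta[["DataRate"]] %||% meta[["CameraRate"]])
  if (!length(rate) || is.na(rate)) {
    stop("TRC file lacks a DataRate: ", path, call. = FALSE)
  }
  units <- meta[["Units"]] %||% "mm"
  to_mm <- switch(units, mm = 1, m = 1000, cm = 10,
    stop("unsupported TRC units '", units, "'", call. = FALSE)
  )
  labels <- strsplit(lines[4], "\t")[[1]]
  labels <- labels[!(labels %in% c("Frame#", "Time", ""))]
  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  mat <- do.call(rbind, lapply(strsplit(data_lines, "\t"), function(x) {
    suppressWarnings(as.numeric(x))
  }))
  n_mark <- length(labels)
  if (ncol(mat) < 2 + 3 * n_mark) {
    stop("malformed TRC data block: ", path, call. = FALSE)
  }
  df <- purrr::map_dfr(seq_len(n_mark), function(j) {
    tibble::tibble(
      frame = as.integer(mat[, 1]),
      time = mat[, 2],
      marker = map_marker_labels(labels[j]),
      x = mat[, 2 + 3 * j - 2] * to_mm,
      y = mat[, 2 + 3 * j - 1] * to_mm,
      z = mat[, 2 + 3 * j] * to_mm
    )
  })
  df <- convert_up_axis(df, vertical)
  afm_trial(df, rate, metadata = list(path = path, units = units))
}

#' Write a trial to TRC
#'
#' @param trial An [afm_trial()].
#' @param path Output path.
#' @param rate Sampling-rate override.
#' @return `path`, invisibly.
#' @export
write_trc <- function(trial, path, rate = NULL) {
  rate <- trial_rate(trial, rate)
  arr <- trial_array(trial)
  n <- length(arr$frames)
  k <- length(arr$markers)
  header <- c(
    paste0("PathFileType\t4\t(X/Y/Z)\t", basename(path)),
    paste(c(
      "DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
      "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames"
    ), collapse = "\t"),
    paste(c(rate, rate, n, k, "mm", rate, 1, n), collapse = "\t"),
    paste(c("Frame#", "Time", as.vector(rbind(arr$markers, "", ""))), collapse = "\t"),
    paste(c("", "", paste0(rep(c("X", "Y", "Z"), k), rep(seq_len(k), each = 3))), collapse = "\t")
  )
  body <- vapply(seq_len(n), function(i) {
    coords <- t(arr$xyz[i, , , drop = TRUE])
    paste(c(arr$frames[i], format(arr$time[i], digits = 10), format(c(coords), digits = 10)),
      collapse = "\t"
    )
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a wide-CSV marker trial
#'
#' Columns: `frame`, optional `time`, then `<label>_x`, `<label>_y`,
#' `<label>_z` per marker.
#'
#' @param path File path.
#' @param rate Sampling rate in Hz (required if the file has no time
#'   column).
#' @param vertical Vertical axis convention of the file (`"y"` or `"z"`).
#' @param units `"mm"`, `"cm"` or `"m"`.
#' @return An [afm_trial()].
#' @export
read_trial_csv <- function(path, rate = NULL, vertical = "y", units = "mm") {
  wide <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  to_mm <- switch(units, mm = 1, cm = 10, m = 1000,
    stop("unsupported units '", units, "'", call. = FALSE)
  )
  coord_cols <- grep("_(x|y|z)$", names(wide), value = TRUE)
  if (!length(coord_cols)) {
    stop("no '<marker>_x/_y/_z' columns found in ", path, call. = FALSE)
  }
  long <- tidyr::pivot_longer(
    wide[, c(intersect(c("frame", "time"), names(wide)), coord_cols)],
    dplyr::all_of(coord_cols),
    names_to = c("marker", "axis"), names_pattern = "(.*)_([xyz])$",
    values_to = "value"
  )
  df <- tidyr::pivot_wider(long, names_from = "axis", values_from = "value")
  df$marker <- map_marker_labels(df$marker)
  df[c("x", "y", "z")] <- df[c("x", "y", "z")] * to_mm
  df <- convert_up_axis(df, vertical)
  if (!"time" %in% names(df) && is.null(rate)) {
    stop("CSV has no time column: pass `rate`", call. = FALSE)
  }
  rate <- rate %||% {
    tt <- sort(unique(df$time))
    1 / stats::median(diff(tt))
  }
  afm_trial(df, rate, metadata = list(path = path))
}

#' Write a trial to wide CSV
#'
#' @inheritParams write_trc
#' @export
write_trial_csv <- function(trial, path) {
  wide <- tidyr::pivot_wider(
    tibble::as_tibble(trial),
    id_cols = c("frame", "time"),
    names_from = "marker", values_from = c("x", "y", "z"),
    names_glue = "{marker}_{.value}"
  )
  # order columns marker-major
  markers <- unique(trial$marker)
  cols <- c("frame", "time", paste0(rep(markers, each = 3), "_", c("x", "y", "z")))
  readr::write_csv(wide[, cols], path, progress = FALSE)
  invisible(path)
}

afmkin_version <- function() {
  as.character(utils::packageVersion("afmkin"))
}

#' Serialize a calibration to JSON
#'
#' Versioned JSON document holding the side, per-segment anatomical-in-
#' technical transforms, virtual arch points, calcaneal length and static
#' angles. [read_calibration_json()] restores it losslessly.
#'
#' @param cal An `afm_calibration`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(cal, path) {
  stopifnot(inherits(cal, "afm_calibration"))
  doc <- list(
    format = "afmkin-calibration",
    version = afmkin_version(),
    conventions = list(axes = "x anterior, y up, z right (right-foot internal)", units = "mm, deg"),
    side = cal$side,
    floor_y = cal$floor_y,
    full_foot_contact = cal$full_foot_contact,
    cap_source = cal$cap_source,
    calcaneal_length = cal$calcaneal_length,
    cap_in_hindfoot = cal$cap_in_hindfoot,
    hm1p_in_forefoot = cal$hm1p_in_forefoot,
    n_frames_static = cal$n_frames_static,
    segments = lapply(cal$segments, function(s) {
      list(
        rotation = as.vector(s$rotation), # column-major 9 numbers
        translation = s$translation,
        tracking_markers = s$tracking_markers,
        tracking_static = as.vector(s$tracking_static)
      )
    }),
    markers_static = list(
      marker = rownames(cal$markers_static),
      xyz = as.vector(cal$markers_static)
    ),
    static_angles = cal$static_angles
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Restore a calibration from JSON
#'
#' @param path File written by [write_calibration_json()].
#' @return An `afm_calibration`.
#' @export
read_calibration_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "afmkin-calibration")) {
    stop("not an afmkin calibration document: ", path, call. = FALSE)
  }
  m <- matrix(doc$markers_static$xyz,
    ncol = 3,
    dimnames = list(doc$markers_static$marker, NULL)
  )
  segments <- lapply(doc$segments, function(s) {
    trio <- s$tracking_markers
    list(
      rotation = matrix(s$rotation, 3, 3),
      translation = s$translation,
      tracking_markers = trio,
      tracking_static = matrix(s$tracking_static, ncol = 3, dimnames = list(trio, NULL))
    )
  })
  cal <- structure(
    list(
      side = doc$side,
      floor_y = doc$floor_y,
      full_foot_contact = doc$full_foot_contact,
      segments = segments,
      cap_in_hindfoot = doc$cap_in_hindfoot,
      hm1p_in_forefoot = doc$hm1p_in_forefoot,
      cap_source = doc$cap_source,
      calcaneal_length = doc$calcaneal_length,
      markers_static = m,
      static_frames = lapply(
        stats::setNames(segment_names, segment_names),
        function(s) anatomical_frame_right(s, add_virtual_midpoints(m))
      ),
      n_frames_static = doc$n_frames_static
    ),
    class = "afm_calibration"
  )
  cal$static_angles <- static_angle_table(cal)
  cal
}

#' Write analysis results to disk
#'
#' Angle-curve tibbles and sensitivity tables are written as long-format
#' CSV; calibrations and repeatability analyses as JSON with metadata.
#'
#' @param x Result object.
#' @param path Output path.
#' @param ... Unused.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, ...) UseMethod("write_results")

#' @export
write_results.data.frame <- function(x, path, ...) {
  readr::write_csv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' @export
write_results.afm_calibration <- function(x, path, ...) {
  write_calibration_json(x, path)
}

#' @export
write_results.afm_repeatability <- function(x, path, ...) {
  doc <- list(
    format = "afmkin-repeatability",
    version = afmkin_version(),
    pairs = x$pairs,
    sem_aggregation = x$sem_aggregation,
    sigma = x$sigma,
    sem = x$sem,
    summary = x$summary
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
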