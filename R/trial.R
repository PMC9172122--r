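# A trial is a long tibble of labeled marker trajectories: columns frame,
# time (s), marker, x, y, z (mm, lab frame, y vertical). The sampling rate
# and free-form metadata travel as attributes; subsetting with dplyr verbs
# returns plain tibbles, so accessors re-derive what they can.

#' Construct a marker trial
#'
#' @param data Data frame with columns `frame`, `time`, `marker`, `x`, `y`,
#'   `z` (or without `time`, derived from `frame` and `rate`). Positions in
#'   mm, lab frame, y vertical. Gaps are explicit `NA` coordinates.
#' @param rate Sampling rate in Hz (> 0).
#' @param metadata Optional named list (subject, session, tester, side, ...).
#' @return A tibble of class `afm_trial` with attributes `rate`, `metadata`.
#' @export
afm_trial <- function(data, rate, metadata = list()) {
  stopifnot(is.data.frame(data), is.numeric(rate), rate > 0)
  data <- tibble::as_tibble(data)
  if (!"frame" %in% names(data)) {
    stop("trial data needs a 'frame' column", call. = FALSE)
  }
  if (!"time" %in% names(data)) {
    data$time <- (data$frame - min(data$frame)) / rate
  }
  need <- c("frame", "time", "marker", "x", "y", "z")
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    stop("trial data is missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  per_frame <- table(data$frame)
  if (length(unique(per_frame)) > 1) {
    stop("trial is not rectangular: every frame must list the same markers ",
      "(use NA coordinates for gaps)",
      call. = FALSE
    )
  }
  structure(
    data[, need],
    rate = rate,
    metadata = metadata,
    class = c("afm_trial", class(data))
  )
}

#' @export
print.afm_trial <- function(x, ...) {
  cat(sprintf(
    "<afm_trial> %d frames, %d markers, %g Hz, %.2f s\n",
    dplyr::n_distinct(x$frame), dplyr::n_distinct(x$marker),
    trial_rate(x), dplyr::n_distinct(x$frame) / trial_rate(x)
  ))
  print(tibble::as_tibble(x))
  invisible(x)
}

#' Sampling rate of a trial
#' @param trial An `afm_trial` (or tibble carrying a `rate` attribute).
#' @param rate Optional override.
#' @return Rate in Hz.
#' @export
trial_rate <- function(trial, rate = NULL) {
  r <- rate %||% attr(trial, "rate")
  if (is.null(r)) {
    stop("sampling rate unknown: pass `rate` or use afm_trial()", call. = FALSE)
  }
  r
}

# Dense array view: list(frames, time, markers, xyz[frame, marker, 3]).
trial_array <- function(trial) {
  frames <- sort(unique(trial$frame))
  markers <- unique(trial$marker)
  n <- length(frames)
  k <- length(markers)
  ord <- order(match(trial$frame, frames), match(trial$marker, markers))
  tr <- trial[ord, ]
  xyz <- array(NA_real_, c(n, k, 3), dimnames = list(NULL, markers, c("x", "y", "z")))
  xyz[, , 1] <- matrix(tr$x, n, k, byrow = TRUE)
  xyz[, , 2] <- matrix(tr$y, n, k, byrow = TRUE)
  xyz[, , 3] <- matrix(tr$z, n, k, byrow = TRUE)
  time <- matrix(tr$time, n, k, byrow = TRUE)[, 1]
  list(frames = frames, time = time, markers = markers, xyz = xyz)
}

# Marker matrix at one array index.
markers_at <- function(arr, i) {
  m <- arr$xyz[i, , ]
  if (is.null(dim(m))) m <- matrix(m, ncol = 3, dimnames = list(arr$markers, NULL))
  m
}

# Mean marker positions over frames (gap frames excluded per marker).
average_markers <- function(trial) {
  df <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(trial), .data$marker),
    x = mean(.data$x, na.rm = TRUE),
    y = mean(.data$y, na.rm = TRUE),
    z = mean(.data$z, na.rm = TRUE),
    .groups = "drop"
  )
  df
}

# Build a trial tibble from an array of positions [frame, marker, 3].
trial_from_array <- function(xyz, rate, time = NULL, metadata = list()) {
  n <- dim(xyz)[1]
  markers <- dimnames(xyz)[[2]]
  time <- time %||% ((seq_len(n) - 1) / rate)
  df <- tibble::tibble(
    frame = rep(seq_len(n), each = length(markers)),
    time = rep(time, each = length(markers)),
    marker = rep(markers, n),
    x = as.vector(t(xyz[, , 1])),
    y = as.vector(t(xyz[, , 2])),
    z = as.vector(t(xyz[, , 3]))
  )
  afm_trial(df, rate, metadata)
}
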