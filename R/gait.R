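# Gait events from foot velocity, stride segmentation, 0-100% gait-cycle
# normalization and stride averaging.

# Zero-phase Butterworth low-pass (order-2 filter run forward and backward,
# i.e. 4th-order zero-lag response).
lowpass <- function(x, rate, cutoff) {
  if (cutoff <= 0 || cutoff >= rate / 2) {
    return(x)
  }
  bf <- signal::butter(2, cutoff / (rate / 2), type = "low")
  # odd reflection padding to suppress forward-backward edge transients
  n <- length(x)
  pad <- min(n - 1, ceiling(3 * rate / cutoff))
  head_pad <- 2 * x[1] - x[(pad + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- as.numeric(signal::filtfilt(bf, c(head_pad, x, tail_pad)))
  y[(pad + 1):(pad + n)]
}

#' Detect gait events from foot velocity
#'
#' Foot center = midpoint of the heel and toe proxy markers (CALD, HM2 by
#' default). Its vertical position is low-pass filtered (zero-lag
#' Butterworth) and differentiated by central differences. Each swing phase
#' shows an ascent lobe (vertical velocity above `threshold`) followed by a
#' descent lobe (below `-threshold`); lobes whose peak speed stays below
#' `min_peak` are ignored, so a standing trial yields zero events. Toe-off
#' is placed at the first sample of an ascent lobe and initial contact just
#' after the last sample of the following descent lobe.
#'
#' @param trial An [afm_trial()].
#' @param markers Heel and toe proxy markers averaged into the foot center.
#' @param cutoff Low-pass cutoff in Hz.
#' @param threshold Vertical-speed threshold (mm/s) bounding the lobes.
#' @param min_peak Minimum peak vertical speed (mm/s) for a lobe to count as
#'   part of a swing.
#' @param min_gap Minimum spacing between consecutive events of the same
#'   type, in seconds.
#' @param rate Sampling-rate override.
#' @return A tibble of class `afm_events` with columns `event` (`"IC"` /
#'   `"TO"`), `frame`, `time`; attribute `direction` is the sign of the net
#'   walking direction along the lab x axis.
#' @export
detect_gait_events <- function(trial, markers = c("CALD", "HM2"),
                               cutoff = 7, threshold = 20, min_peak = 100,
                               min_gap = 0.25, rate = NULL) {
  rate <- trial_rate(trial, rate)
  arr <- trial_array(trial)
  miss <- setdiff(markers, arr$markers)
  if (length(miss)) {
    stop("missing marker(s) for event detection: ",
      paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  n <- length(arr$frames)
  if (n < 3) stop("trial too short for event detection", call. = FALSE)
  fc_y <- rowMeans(arr$xyz[, markers, 2, drop = FALSE], dims = 1)
  fc_x <- rowMeans(arr$xyz[, markers, 1, drop = FALSE], dims = 1)
  if (anyNA(fc_y)) {
    stop("event detection needs gap-free heel/toe trajectories", call. = FALSE)
  }
  y <- lowpass(fc_y, rate, cutoff)
  v <- c(NA, (y[-(1:2)] - y[seq_len(n - 2)]) * rate / 2, NA)
  v[1] <- v[2]
  v[n] <- v[n - 1]

  runs_of <- function(keep) {
    r <- rle(keep)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    idx <- which(r$values)
    Map(c, starts[idx], ends[idx])
  }
  lobe_tbl <- function(runs, sgn) {
    purrr::map_dfr(runs, function(se) {
      seg <- v[se[1]:se[2]]
      tibble::tibble(start = se[1], end = se[2], peak = max(sgn * seg))
    })
  }
  asc <- lobe_tbl(runs_of(v > threshold), 1)
  des <- lobe_tbl(runs_of(v < -threshold), -1)
  if (nrow(asc)) asc <- asc[asc$peak >= min_peak, ]
  if (nrow(des)) des <- des[des$peak >= min_peak, ]

  ev <- dplyr::bind_rows(
    if (nrow(asc)) tibble::tibble(event = "TO", idx = asc$start),
    if (nrow(des)) tibble::tibble(event = "IC", idx = pmin(des$end + 1L, n))
  )
  if (nrow(ev)) {
    ev <- ev[order(ev$idx), ]
    # drop same-type repeats closer than min_gap
    keep <- rep(TRUE, nrow(ev))
    last <- c(TO = -Inf, IC = -Inf)
    for (i in seq_len(nrow(ev))) {
      t_i <- arr$time[ev$idx[i]]
      if (t_i - last[[ev$event[i]]] < min_gap) {
        keep[i] <- FALSE
      } else {
        last[[ev$event[i]]] <- t_i
      }
    }
    ev <- ev[keep, ]
  }
  out <- tibble::tibble(
    event = if (nrow(ev)) ev$event else character(0),
    frame = if (nrow(ev)) arr$frames[ev$idx] else integer(0),
    time = if (nrow(ev)) arr$time[ev$idx] else numeric(0)
  )
  structure(out,
    direction = sign(fc_x[n] - fc_x[1]),
    rate = rate,
    class = c("afm_events", class(out))
  )
}

#' Normalize angle curves to the gait cycle
#'
#' Cuts each initial-contact-to-initial-contact interval out of the angle
#' curves and linearly resamples it to 101 points (0-100% of the gait
#' cycle, endpoints inclusive).
#'
#' @param curves Tibble from [afm_joint_angles()] (`time`, `joint`, `plane`,
#'   `angle`).
#' @param events An `afm_events` tibble (or any tibble with `event` and
#'   `time`); needs at least two initial contacts.
#' @param n_points Samples per normalized stride (101 = each percent).
#' @return Tibble `joint`, `plane`, `stride`, `cycle` (0-100), `angle`.
#' @export
normalize_gait_cycle <- function(curves, events, n_points = 101) {
  ic <- sort(events$time[events$event == "IC"])
  if (length(ic) < 2) stop("no complete stride (need two initial contacts)", call. = FALSE)
  pct <- seq(0, 100, length.out = n_points)
  strides <- tibble::tibble(
    stride = seq_len(length(ic) - 1),
    t0 = ic[-length(ic)], t1 = ic[-1]
  )
  dplyr::group_modify(
    dplyr::group_by(curves, .data$joint, .data$plane),
    function(df, key) {
      purrr::pmap_dfr(strides, function(stride, t0, t1) {
        tt <- t0 + (t1 - t0) * pct / 100
        tibble::tibble(
          stride = stride, cycle = pct,
          angle = stats::approx(df$time, df$angle, xout = tt, rule = 2)$y
        )
      })
    }
  ) |> dplyr::ungroup()
}

#' Average normalized strides pointwise
#'
#' @param normalized Output of [normalize_gait_cycle()].
#' @return Tibble `joint`, `plane`, `cycle`, `angle` (mean over strides),
#'   `sd`, `n`.
#' @export
stride_average <- function(normalized) {
  dplyr::summarise(
    dplyr::group_by(normalized, .data$joint, .data$plane, .data$cycle),
    sd = stats::sd(.data$angle, na.rm = TRUE),
    n = sum(is.finite(.data$angle)),
    angle = mean(.data$angle, na.rm = TRUE),
    .groups = "drop"
  )[, c("joint", "plane", "cycle", "angle", "sd", "n")]
}
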