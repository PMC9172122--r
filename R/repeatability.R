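# Session-to-session variability (sigma), standard error of measurement
# (SEM) and distribution-aware group summaries for curves, static angles and
# range of motion.

#' Two-measurement variability
#'
#' Standard deviation between two measurements (n = 2, denominator n - 1,
#' i.e. |a - b| / sqrt(2)) per point, averaged over the points for curves.
#' Scalar quantities (static angle, ROM) pass length-1 vectors.
#'
#' @param a,b Numeric vectors of equal length (e.g. 101-point normalized
#'   curves).
#' @return Variability sigma in the units of the input.
#' @examples
#' pair_sigma(rep(2, 101), rep(0, 101)) # 2 / sqrt(2)
#' @export
pair_sigma <- function(a, b) {
  if (length(a) != length(b)) {
    stop("pair_sigma() needs two equally long measurements", call. = FALSE)
  }
  mean(abs(a - b) / sqrt(2))
}

#' Standard error of measurement from paired differences
#'
#' SEM = sqrt(error variance), the error variance being the mean over
#' subjects of the within-pair variance d^2/2. For curves (matrix input,
#' rows = subjects, columns = gait-cycle points) the default mirrors the
#' sigma computation: SEM per point, then averaged over the cycle.
#' `aggregation = "subject_first"` instead pools each subject's squared
#' differences over the cycle before the square root.
#'
#' @param differences Numeric vector (one difference per subject) or matrix
#'   (subjects x points).
#' @param aggregation `"pointwise"` or `"subject_first"`.
#' @return SEM in the units of the input.
#' @export
sem_pairs <- function(differences, aggregation = c("pointwise", "subject_first")) {
  aggregation <- match.arg(aggregation)
  d <- if (is.matrix(differences)) differences else matrix(differences, ncol = 1)
  if (nrow(d) < 2) {
    stop("SEM needs paired measurements from at least 2 subjects", call. = FALSE)
  }
  if (aggregation == "pointwise") {
    mean(sqrt(colMeans(d^2 / 2)))
  } else {
    sqrt(mean(rowMeans(d^2 / 2)))
  }
}

#' Group summary of per-subject variabilities
#'
#' Tests the sigmas for normality (Shapiro-Wilk at `alpha`) and reports
#' median \[IQR\] when non-normal, mean +/- SD when normal; both summaries
#' are always retained.
#'
#' @param sigmas Numeric vector, one variability per subject (>= 3).
#' @param alpha Shapiro-Wilk significance level.
#' @return One-row tibble: `n`, `shapiro_p`, `normal`, `mean`, `sd`,
#'   `median`, `iqr`, `display`.
#' @export
summarize_sigmas <- function(sigmas, alpha = 0.05) {
  sigmas <- sigmas[is.finite(sigmas)]
  if (length(sigmas) < 3) {
    stop("group summary needs at least 3 subjects", call. = FALSE)
  }
  p <- if (stats::sd(sigmas) < 1e-12) 1 else stats::shapiro.test(sigmas)$p.value
  normal <- p >= alpha
  tibble::tibble(
    n = length(sigmas), shapiro_p = p, normal = normal,
    mean = mean(sigmas), sd = stats::sd(sigmas),
    median = stats::median(sigmas),
    iqr = stats::IQR(sigmas),
    display = if (normal) {
      sprintf("%.1f ± %.1f°", mean(sigmas), stats::sd(sigmas))
    } else {
      sprintf("%.1f [%.1f°]", stats::median(sigmas), stats::IQR(sigmas))
    }
  )
}

#' Inter- and intra-tester repeatability analysis
#'
#' Takes tidy per-session results (normalized curves, static angles, ROM)
#' for every subject and computes, for each comparison pair of sessions
#' (by default intra-tester A1 vs A2 and inter-tester A1 vs B1):
#' per-subject variability sigma ([pair_sigma()]), the group SEM
#' ([sem_pairs()]), and the distribution-aware group summary
#' ([summarize_sigmas()]).
#'
#' @param data Tibble with columns `subject`, `session`, `joint`, `plane`,
#'   `quantity` (`"curve"`, `"static"` or `"rom"`), `cycle` (percent of gait
#'   cycle for curves, `NA` otherwise) and `value` (degrees).
#' @param pairs Named list of length-2 session vectors to compare.
#' @param sem_aggregation Passed to [sem_pairs()].
#' @param alpha Shapiro-Wilk level for the group summaries.
#' @return An object of class `afm_repeatability` with tibbles `sigma`
#'   (per subject), `sem` and `summary` (per angle), plus [tidy()] and
#'   [glance()] methods.
#' @export
repeatability <- function(data,
                          pairs = list(intra = c("A1", "A2"), inter = c("A1", "B1")),
                          sem_aggregation = c("pointwise", "subject_first"),
                          alpha = 0.05) {
  sem_aggregation <- match.arg(sem_aggregation)
  need <- c("subject", "session", "joint", "plane", "quantity", "value")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("repeatability data is missing column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  if (!"cycle" %in% names(data)) data$cycle <- NA_real_

  per_pair <- purrr::imap_dfr(pairs, function(ss, label) {
    a <- data[data$session == ss[1], ]
    b <- data[data$session == ss[2], ]
    joined <- dplyr::inner_join(
      a, b,
      by = c("subject", "joint", "plane", "quantity", "cycle"),
      suffix = c("_1", "_2")
    )
    joined$comparison <- label
    joined
  })
  per_pair$d <- per_pair$value_1 - per_pair$value_2

  sigma <- dplyr::summarise(
    dplyr::group_by(
      per_pair, .data$comparison, .data$subject,
      .data$joint, .data$plane, .data$quantity
    ),
    sigma = pair_sigma(.data$value_1, .data$value_2),
    .groups = "drop"
  )

  sem <- dplyr::summarise(
    dplyr::group_by(
      per_pair, .data$comparison, .data$joint, .data$plane, .data$quantity
    ),
    sem = {
      w <- tidyr::pivot_wider(
        tibble::tibble(
          subject = subject,
          cycle = dplyr::coalesce(cycle, 0), d = d
        ),
        names_from = "cycle", values_from = "d"
      )
      sem_pairs(as.matrix(w[, -1]), sem_aggregation)
    },
    .groups = "drop"
  )

  summary <- dplyr::reframe(
    dplyr::group_by(sigma, .data$comparison, .data$joint, .data$plane, .data$quantity),
    summarize_sigmas(.data$sigma, alpha)
  )

  structure(
    list(
      sigma = sigma, sem = sem, summary = summary,
      pairs = pairs, sem_aggregation = sem_aggregation
    ),
    class = "afm_repeatability"
  )
}

#' @export
print.afm_repeatability <- function(x, ...) {
  cat(
    "<afm_repeatability>",
    paste(names(x$pairs), collapse = "/"), "comparisons;",
    dplyr::n_distinct(x$sigma$subject), "subjects;",
    dplyr::n_distinct(x$sigma$joint), "angles\n"
  )
  print(glance(x))
  invisible(x)
}

#' @rdname repeatability
#' @param x An `afm_repeatability`.
#' @param ... Unused.
#' @export
tidy.afm_repeatability <- function(x, ...) {
  dplyr::left_join(
    x$summary, x$sem,
    by = c("comparison", "joint", "plane", "quantity")
  )
}

#' @rdname repeatability
#' @export
glance.afm_repeatability <- function(x, ...) {
  # headline numbers: median [IQR] of all per-subject sigmas, and the mean
  # +/- SD of the per-angle SEMs
  sig <- dplyr::summarise(
    dplyr::group_by(x$sigma, .data$comparison, .data$quantity),
    sigma_median = stats::median(.data$sigma),
    sigma_iqr = stats::IQR(.data$sigma),
    .groups = "drop"
  )
  sem <- dplyr::summarise(
    dplyr::group_by(x$sem, .data$comparison, .data$quantity),
    n_angles = dplyr::n(),
    sem_mean = mean(.data$sem),
    sem_sd = stats::sd(.data$sem),
    .groups = "drop"
  )
  dplyr::left_join(sig, sem, by = c("comparison", "quantity"))
}
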