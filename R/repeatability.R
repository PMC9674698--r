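# Bland-Altman test-retest repeatability metrics.
#
# Inputs are per-image severity scores and class decisions with a patient
# grouping; all same-visit images of one patient form one test-retest group.
# Two metrics summarise repeatability: the classification disagreement rate
# (fraction of patients whose images receive non-identical predicted
# classes) and the normalized non-parametric 95% limits of agreement of the
# Bland-Altman score differences.

check_scores_tbl <- function(scores, need_decision = FALSE) {
  if (!is.data.frame(scores)) abort("scores must be a data frame.")
  need <- c("patient_id", "score", if (need_decision) "decision")
  miss <- setdiff(need, names(scores))
  if (length(miss)) abort(paste("scores is missing columns:",
                                paste(miss, collapse = ", ")))
  invisible(scores)
}

#' Bland-Altman points from test-retest groups
#'
#' One point per patient: the x-coordinate is the mean of all the patient's
#' severity scores; the y-coordinate is the signed difference
#' `first - second` (in table order) when the patient has exactly two images,
#' and the non-negative `max - min` when there are more than two. Patients
#' with fewer than two scores are skipped with a warning and counted in the
#' `n_skipped` attribute.
#'
#' @param scores A data frame with columns `patient_id` and `score`, one row
#'   per image, rows in acquisition (manifest) order.
#' @return A tibble with columns `patient_id`, `mean_score`, `difference`,
#'   `n_views`; attribute `n_skipped` counts dropped single-image patients.
#' @export
bland_altman_points <- function(scores) {
  check_scores_tbl(scores)
  pts <- scores |>
    group_by(.data$patient_id) |>
    summarise(mean_score = mean(.data$score),
              difference = if (n() == 2L) .data$score[1] - .data$score[2]
                           else max(.data$score) - min(.data$score),
              n_views = n(), .groups = "drop")
  skipped <- pts$n_views < 2L
  if (any(skipped)) {
    warn(sprintf("%d patient(s) with < 2 images skipped from Bland-Altman points.",
                 sum(skipped)))
  }
  structure(pts[!skipped, ], n_skipped = sum(skipped))
}

#' Normalized non-parametric 95% limits of agreement
#'
#' Tests the Bland-Altman differences for normality (Shapiro-Wilk, alpha =
#' 0.05). If normality is not rejected the limits are `mean +/- 1.96 sd`; if
#' it is rejected (or the test is unavailable, e.g. fewer than 3 points or
#' zero variance) the empirical 2.5th and 97.5th percentiles are used, with
#' linear interpolation between order statistics. The reported scalar is the
#' half-width of the interval, `(upper - lower) / 2`, divided by the width of
#' the score range, so 0 means perfect agreement and values are comparable
#' across head types.
#'
#' @param points A [bland_altman_points()] tibble (or any data frame with a
#'   `difference` column), or a bare numeric vector of differences.
#' @param score_range Length-2 numeric `(lo, hi)` of the head's score scale.
#' @return Normalized LoA half-width (scalar >= 0) with attributes `method`
#'   (`"normal"` or `"percentile"`), `lower`, `upper` (unnormalized bounds)
#'   and `low_confidence` (`TRUE` when based on fewer than 20 points).
#' @export
loa95 <- function(points, score_range) {
  d <- if (is.data.frame(points)) points$difference else as.numeric(points)
  if (length(d) == 0L) abort("no Bland-Altman differences supplied.")
  if (length(score_range) != 2L || score_range[2] <= score_range[1]) {
    abort("score_range must be (lo, hi) with lo < hi.")
  }
  normal <- FALSE
  if (length(d) >= 3L && sd(d) > 0) {
    dsw <- if (length(d) > 5000L) d[seq_len(5000L)] else d
    normal <- shapiro.test(dsw)$p.value >= 0.05
  }
  if (sd(d) == 0) {
    lower <- upper <- d[1]
    method <- "percentile"
  } else if (normal) {
    lower <- mean(d) - 1.96 * sd(d)
    upper <- mean(d) + 1.96 * sd(d)
    method <- "normal"
  } else {
    qs <- quantile(d, c(0.025, 0.975), type = 7, names = FALSE)
    lower <- qs[1]; upper <- qs[2]
    method <- "percentile"
  }
  val <- ((upper - lower) / 2) / (score_range[2] - score_range[1])
  structure(val, method = method, lower = lower, upper = upper,
            low_confidence = length(d) < 20L)
}

#' Classification disagreement rate
#'
#' The fraction of patients whose same-visit images receive non-identical
#' class decisions.
#'
#' @param scores A data frame with columns `patient_id` and `decision`, one
#'   row per image.
#' @return Fraction in `[0, 1]`.
#' @export
disagreement_rate <- function(scores) {
  if (!is.data.frame(scores) ||
      !all(c("patient_id", "decision") %in% names(scores))) {
    abort("scores needs `patient_id` and `decision` columns.")
  }
  if (nrow(scores) == 0L) abort("no scores supplied.")
  per <- scores |>
    group_by(.data$patient_id) |>
    summarise(disagree = length(unique(.data$decision)) > 1L, .groups = "drop")
  mean(per$disagree)
}

#' Full repeatability report
#'
#' Combines [bland_altman_points()], [loa95()] and [disagreement_rate()] for
#' one model's scored test-retest set.
#'
#' @param scores Data frame with columns `patient_id`, `score`, `decision`
#'   (one row per image, in acquisition order).
#' @param score_range Length-2 `(lo, hi)` score scale of the head.
#' @return A `repeatability_report`: list with `disagreement_rate`, `loa95`
#'   (plus `loa_method`, `loa_lower`, `loa_upper`, `low_confidence`),
#'   `points`, `n_patients`, `n_skipped`, `mixed_group_sizes` (TRUE when the
#'   set mixes signed 2-view differences with max-min multi-view
#'   differences) and `score_range`.
#' @export
repeatability_report <- function(scores, score_range) {
  check_scores_tbl(scores, need_decision = TRUE)
  pts <- bland_altman_points(scores)
  loa <- loa95(pts, score_range)
  structure(list(
    disagreement_rate = disagreement_rate(scores),
    loa95 = as.numeric(loa),
    loa_method = attr(loa, "method"),
    loa_lower = attr(loa, "lower"),
    loa_upper = attr(loa, "upper"),
    low_confidence = attr(loa, "low_confidence"),
    points = pts,
    n_patients = nrow(pts),
    n_skipped = attr(pts, "n_skipped"),
    mixed_group_sizes = length(unique(pts$n_views)) > 1L,
    score_range = score_range),
    class = "repeatability_report")
}

#' @exportS3Method base::print
print.repeatability_report <- function(x, ...) {
  cat(sprintf("<repeatability_report> %d patients\n", x$n_patients))
  cat(sprintf("  disagreement rate: %.3f\n", x$disagreement_rate))
  cat(sprintf("  95%% LoA (normalized half-width, %s path): %.3f%s\n",
              x$loa_method, x$loa95,
              if (x$low_confidence) "  [low confidence: < 20 patients]" else ""))
  invisible(x)
}
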