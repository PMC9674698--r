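# broom-style tidiers for the result objects.

#' @describeIn repeatability_report Bland-Altman points as a tibble.
#' @param x A `repeatability_report`.
#' @param ... Unused.
#' @export
tidy.repeatability_report <- function(x, ...) {
  as_tibble(x$points)
}

#' @describeIn repeatability_report One-row metric summary.
#' @export
glance.repeatability_report <- function(x, ...) {
  tibble(disagreement = x$disagreement_rate, loa95 = x$loa95,
         loa_method = x$loa_method, loa_lower = x$loa_lower,
         loa_upper = x$loa_upper, n_patients = x$n_patients,
         n_skipped = x$n_skipped, low_confidence = x$low_confidence)
}

#' @describeIn calibration_curve Per-bin reliability statistics.
#' @param x A `calibration_report`.
#' @param ... Unused.
#' @export
tidy.calibration_report <- function(x, ...) {
  x$bins
}

#' @describeIn calibration_curve One-row Brier summary.
#' @export
glance.calibration_report <- function(x, ...) {
  tibble(brier = x$brier, n_pairs = x$n_pairs)
}

#' @describeIn evaluate_model One-row summary of all evaluation metrics.
#' @param x A `model_evaluation`.
#' @param ... Unused.
#' @export
glance.model_evaluation <- function(x, ...) {
  tibble(head = x$head$kind, k = x$head$k, mc = x$mc,
         disagreement = x$repeatability$disagreement_rate,
         loa95 = x$repeatability$loa95,
         accuracy = x$accuracy, kappa = x$kappa,
         brier = if (!is.null(x$calibration)) x$calibration$brier else NA_real_,
         n_patients = x$repeatability$n_patients)
}

#' @describeIn evaluate_model Per-image predictions as a plain tibble.
#' @export
tidy.model_evaluation <- function(x, ...) {
  as_tibble(x$predictions)
}

#' @describeIn bootstrap_compare Two-row per-model bootstrap summary.
#' @param x A `comparison_result`.
#' @param ... Unused.
#' @export
tidy.comparison_result <- function(x, ...) {
  tibble(model = c("a", "b"),
         estimate = c(x$mean_a, x$mean_b),
         conf.low = c(x$ci_a[1], x$ci_b[1]),
         conf.high = c(x$ci_a[2], x$ci_b[2]))
}

#' @describeIn bootstrap_compare One-row test summary.
#' @export
glance.comparison_result <- function(x, ...) {
  tibble(metric = x$metric, p.value = x$p_value, significant = x$significant,
         normality_p = x$normality_p, method = x$method,
         n_replicates = x$n_replicates, n_dropped = x$n_dropped)
}

#' @describeIn sweep_iterations Sweep grid plus the dropout-disabled baseline
#'   as an `n = 0` row.
#' @param x An `mc_sweep`.
#' @param ... Unused.
#' @export
tidy.mc_sweep <- function(x, ...) {
  bind_rows(
    tibble(n = 0L, loa95 = attr(x, "baseline_loa95"),
           disagreement = attr(x, "baseline_disagreement"), baseline = TRUE),
    mutate(as_tibble(x), baseline = FALSE))
}

#' @describeIn train_model Per-epoch training history.
#' @param x A trained `mc_model`.
#' @param ... Unused.
#' @export
tidy.mc_model <- function(x, ...) {
  if (is.null(x$history)) abort("model has no training history yet.")
  x$history
}

#' @describeIn run_benchmark Per-seed, per-model metric rows.
#' @param x A `benchmark_result`.
#' @param ... Unused.
#' @export
tidy.benchmark_result <- function(x, ...) {
  x$metrics
}

#' @describeIn run_benchmark Median metrics per model over seeds.
#' @export
glance.benchmark_result <- function(x, ...) {
  x$metrics |>
    group_by(.data$model) |>
    summarise(across(c("disagreement", "loa95", "accuracy", "kappa", "brier"),
                     median), n_seeds = n(), .groups = "drop")
}
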