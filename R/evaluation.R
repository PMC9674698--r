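# Classification, agreement and calibration metrics, and the bootstrap
# model-comparison machinery.

#' Classification accuracy
#'
#' @param truth,estimate Integer class vectors (zero-based) of equal length.
#' @return Fraction of exact matches.
#' @export
accuracy <- function(truth, estimate) {
  stopifnot(length(truth) == length(estimate), length(truth) > 0L)
  mean(truth == estimate)
}

#' Quadratic weighted Cohen's kappa
#'
#' Chance-corrected agreement between two ordinal ratings with quadratic
#' distance weights `w_ij = (i - j)^2 / (k - 1)^2`:
#' `kappa = 1 - sum(w * O) / sum(w * E)`, where `O` is the observed confusion
#' matrix and `E` the outer product of its marginals scaled to `n`. Symmetric
#' in its arguments and invariant to reversing the class order.
#'
#' @param truth,estimate Integer class vectors in `0..k-1`.
#' @param k Number of classes.
#' @return Kappa in `[-1, 1]`, or `NA` (with a warning) when the chance
#'   agreement term is degenerate (e.g. both raters constant).
#' @export
quadratic_weighted_kappa <- function(truth, estimate, k) {
  stopifnot(length(truth) == length(estimate), length(truth) > 0L)
  k <- as.integer(k)
  if (any(c(truth, estimate) < 0L) || any(c(truth, estimate) > k - 1L)) {
    abort("classes must lie in 0..k-1.")
  }
  n <- length(truth)
  O <- table(factor(truth, levels = 0:(k - 1L)),
             factor(estimate, levels = 0:(k - 1L)))
  E <- outer(rowSums(O), colSums(O)) / n
  w <- outer(0:(k - 1L), 0:(k - 1L), function(i, j) (i - j)^2) / (k - 1L)^2
  denom <- sum(w * E)
  if (denom <= .Machine$double.eps) {
    warn("quadratic weighted kappa undefined: degenerate marginals.")
    return(NA_real_)
  }
  1 - sum(w * O) / denom
}

#' Brier score
#'
#' Mean squared distance between predicted probabilities and the one-hot
#' truth. For a binary head this is `mean((p_pos - y)^2)` (range `[0, 1]`);
#' for probability-vector heads the sum-over-classes convention is used,
#' `mean over samples of sum_c (p_c - 1[y = c])^2` (range `[0, 2]`).
#' 0 indicates perfect calibration and sharpness.
#'
#' @param probs Matrix of probability vectors (one row per sample), or a
#'   vector of positive-class probabilities for the binary case.
#' @param truth Zero-based true classes (`0/1` for binary).
#' @return Nonnegative scalar.
#' @export
brier <- function(probs, truth) {
  if (is.null(dim(probs)) || ncol(as_row_matrix(probs)) == 1L) {
    p <- as.numeric(probs)
    stopifnot(length(p) == length(truth))
    return(mean((p - truth)^2))
  }
  m <- as_row_matrix(probs)
  stopifnot(nrow(m) == length(truth))
  onehot <- matrix(0, nrow(m), ncol(m))
  onehot[cbind(seq_len(nrow(m)), truth + 1L)] <- 1
  mean(rowSums((m - onehot)^2))
}

#' Reliability (calibration) curve
#'
#' Pools one-vs-rest (sample, class) pairs — for a binary head just
#' `(p_pos, y)` — and partitions the predicted probabilities into `n_bins`
#' equal-width bins on `[0, 1]`. Each bin reports the mean predicted
#' probability, the observed frequency of the class being true, the count,
#' and the 2.5/97.5 percentile span of the predictions in the bin. Empty
#' bins are emitted with count 0 and `NA` frequency.
#'
#' @inheritParams brier
#' @param n_bins Number of equal-width probability bins (default 10).
#' @return A `calibration_report`: list with `brier` and `bins` (tibble with
#'   `bin`, `lower`, `upper`, `mean_pred`, `observed_freq`, `count`,
#'   `pred_lo`, `pred_hi`).
#' @export
calibration_curve <- function(probs, truth, n_bins = 10L) {
  stopifnot(n_bins >= 1L)
  if (is.null(dim(probs)) || ncol(as_row_matrix(probs)) == 1L) {
    p <- as.numeric(probs)
    y <- as.integer(truth)
  } else {
    m <- as_row_matrix(probs)
    p <- as.vector(m)
    y <- as.vector(vapply(seq_len(ncol(m)),
                          function(cl) as.integer(truth == cl - 1L),
                          integer(nrow(m))))
  }
  stopifnot(length(p) == length(y), all(p >= -1e-9 & p <= 1 + 1e-9))
  edges <- seq(0, 1, length.out = n_bins + 1L)
  idx <- pmin(pmax(findInterval(p, edges, rightmost.closed = TRUE), 1L), n_bins)
  bins <- lapply(seq_len(n_bins), function(bn) {
    sel <- idx == bn
    cnt <- sum(sel)
    tibble(bin = bn, lower = edges[bn], upper = edges[bn + 1L],
           mean_pred = if (cnt) mean(p[sel]) else NA_real_,
           observed_freq = if (cnt) mean(y[sel]) else NA_real_,
           count = cnt,
           pred_lo = if (cnt) quantile(p[sel], 0.025, names = FALSE) else NA_real_,
           pred_hi = if (cnt) quantile(p[sel], 0.975, names = FALSE) else NA_real_)
  })
  structure(list(brier = brier(probs, truth), bins = bind_rows(bins),
                 n_pairs = length(p)),
            class = "calibration_report")
}

#' @exportS3Method base::print
print.calibration_report <- function(x, ...) {
  cat(sprintf("<calibration_report> Brier %.4f over %d (sample, class) pairs\n",
              x$brier, x$n_pairs))
  print(x$bins, n = nrow(x$bins))
  invisible(x)
}

#' Grouped bootstrap comparison of two models
#'
#' Resamples patients (not images) with replacement `B` times, using the
#' *same* resampled patient indices for both models, computes `metric` on
#' each replicate, and reports per-model bootstrap means with 95% percentile
#' confidence intervals and a two-sided paired t-test on the replicate
#' distributions (significance at 0.05). The replicate differences are also
#' Shapiro-Wilk tested and the normality p-value reported. A permutation
#' test on the replicate differences is available via `method`.
#'
#' @param preds_a,preds_b Data frames over the same patient population, each
#'   with a `patient_id` column plus whatever columns `metric` needs.
#' @param metric Function taking one resampled data frame and returning a
#'   scalar; replicates where it returns `NA` (for either model) are dropped
#'   and counted.
#' @param B Number of bootstrap replicates (default 500).
#' @param seed Resampling seed.
#' @param method `"t"` (default, two-sided paired t-test) or `"permutation"`
#'   (sign-flip permutation test on replicate differences).
#' @param metric_name Label stored in the result.
#' @return A `comparison_result`: list with per-model means/CIs, `p_value`,
#'   `significant`, `normality_p`, `n_dropped` and the replicate tibble.
#' @export
bootstrap_compare <- function(preds_a, preds_b, metric, B = 500L, seed = 1L,
                              method = c("t", "permutation"),
                              metric_name = "metric") {
  method <- match.arg(method)
  stopifnot(is.function(metric), B >= 2L)
  pats <- sort(unique(c(preds_a$patient_id, preds_b$patient_id)))
  if (!setequal(unique(preds_a$patient_id), unique(preds_b$patient_id))) {
    warn("prediction sets cover different patient populations; using the union.")
  }
  split_a <- split(preds_a, preds_a$patient_id)
  split_b <- split(preds_b, preds_b$patient_id)
  resample_metric <- function(spl, ids) {
    take <- spl[ids]
    take <- take[!vapply(take, is.null, logical(1))]
    df <- bind_rows(take, .id = NULL)
    # re-key resampled duplicates so a patient drawn twice counts twice
    reps <- vapply(take, nrow, integer(1))
    df$patient_id <- rep(paste0("r", seq_along(take)), times = reps)
    metric(df)
  }
  withr::with_seed(derive_seed(seed, "boot"), {
    rep_a <- rep_b <- numeric(B)
    for (i in seq_len(B)) {
      ids <- sample(pats, length(pats), replace = TRUE)
      rep_a[i] <- resample_metric(split_a, ids)
      rep_b[i] <- resample_metric(split_b, ids)
    }
  })
  ok <- is.finite(rep_a) & is.finite(rep_b)
  n_dropped <- sum(!ok)
  ra <- rep_a[ok]; rb <- rep_b[ok]
  diffs <- ra - rb
  if (sd(diffs) == 0) {
    p <- 1
  } else if (method == "t") {
    p <- t.test(diffs)$p.value
  } else {
    withr::with_seed(derive_seed(seed, "perm"), {
      obs <- mean(diffs)
      flips <- replicate(2000, mean(diffs * sample(c(-1, 1), length(diffs),
                                                   replace = TRUE)))
      p <- mean(abs(flips) >= abs(obs))
    })
  }
  normality_p <- if (length(diffs) >= 3L && sd(diffs) > 0) {
    shapiro.test(if (length(diffs) > 5000L) diffs[seq_len(5000L)] else diffs)$p.value
  } else NA_real_
  ci <- function(x) quantile(x, c(0.025, 0.975), names = FALSE)
  structure(list(
    metric = metric_name,
    mean_a = mean(ra), ci_a = ci(ra),
    mean_b = mean(rb), ci_b = ci(rb),
    p_value = p, significant = p < 0.05,
    normality_p = normality_p, method = method,
    n_replicates = length(ra), n_dropped = n_dropped,
    replicates = tibble(replicate = seq_along(ra), a = ra, b = rb)),
    class = "comparison_result")
}

#' @exportS3Method base::print
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s (%s test, %d replicates)\n",
              x$metric, x$method, x$n_replicates))
  cat(sprintf("  A: %.4f [%.4f, %.4f]\n", x$mean_a, x$ci_a[1], x$ci_a[2]))
  cat(sprintf("  B: %.4f [%.4f, %.4f]\n", x$mean_b, x$ci_b[1], x$ci_b[2]))
  cat(sprintf("  p = %.4g%s\n", x$p_value,
              if (x$significant) "  (significant at 0.05)" else ""))
  invisible(x)
}
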