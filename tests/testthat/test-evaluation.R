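test_that("accuracy is the exact-match fraction", {
  expect_equal(accuracy(c(0, 1, 2), c(0, 1, 2)), 1)
  expect_equal(accuracy(c(0, 1, 2, 2), c(0, 1, 2, 1)), 0.75)
  withr::with_seed(5, {
    truth <- sample(0:4, 1e5, TRUE)
    est <- sample(0:4, 1e5, TRUE)
    expect_equal(accuracy(truth, est), 0.2, tolerance = 0.005 / 0.2)
  })
})

# independent O(n^2) pair-counting oracle for quadratic weighted kappa
qwk_oracle <- function(truth, pred, k) {
  w <- function(i, j) (i - j)^2 / (k - 1)^2
  n <- length(truth)
  num <- sum(w(truth, pred))
  den <- sum(outer(truth, pred, w)) / n
  1 - num / den
}

test_that("quadratic weighted kappa matches the pair-counting oracle", {
  withr::with_seed(21, {
    for (i in 1:120) {
      k <- sample(3:5, 1)
      n <- sample(c(50, 200), 1)
      truth <- sample(0:(k - 1), n, TRUE)
      pred <- pmin(pmax(truth + sample(-1:1, n, TRUE,
                                       prob = c(0.2, 0.6, 0.2)), 0), k - 1)
      expect_equal(quadratic_weighted_kappa(truth, pred, k),
                   qwk_oracle(truth, pred, k), tolerance = 1e-10)
    }
  })
})

test_that("kappa is 1 on perfect agreement, symmetric, reversal-invariant", {
  withr::with_seed(8, {
    truth <- sample(0:3, 100, TRUE)
    pred <- sample(0:3, 100, TRUE)
  })
  expect_equal(quadratic_weighted_kappa(truth, truth, 4), 1)
  expect_lt(quadratic_weighted_kappa(truth, pmin(truth + 1, 3), 4), 1)
  expect_equal(quadratic_weighted_kappa(truth, pred, 4),
               quadratic_weighted_kappa(pred, truth, 4))
  expect_equal(quadratic_weighted_kappa(truth, pred, 4),
               quadratic_weighted_kappa(3 - truth, 3 - pred, 4))
  expect_warning(res <- quadratic_weighted_kappa(rep(1, 10), rep(1, 10), 3),
                 "degenerate")
  expect_true(is.na(res))
})

test_that("Brier score matches closed forms", {
  onehot <- diag(3)[c(1, 2, 3), ]
  expect_equal(brier(onehot, 0:2), 0)
  expect_equal(brier(rep(0.5, 10), rep(c(0, 1), 5)), 0.25)
  # k = 3 uniform predictions, any labels: sum over classes of (1/3 - d)^2
  u <- matrix(1 / 3, 6, 3)
  expect_equal(brier(u, rep(0:2, 2)), (2 / 3)^2 + 2 * (1 / 3)^2)
  expect_equal(brier(u, rep(0:2, 2)), 2 / 3)
})

test_that("reliability curve bins behave on constructed inputs", {
  # all predictions 1.0 and all correct -> a single top bin at frequency 1
  cal <- calibration_curve(rep(1, 50), rep(1L, 50))
  filled <- cal$bins[cal$bins$count > 0, ]
  expect_equal(nrow(filled), 1L)
  expect_equal(filled$bin, 10L)
  expect_equal(filled$observed_freq, 1)
  expect_equal(cal$brier, 0)
  # overconfident one-hot predictions wrong half the time: top bin freq 0.5
  k <- 2
  probs <- cbind(rep(c(1, 0), 20), rep(c(0, 1), 20))
  truth <- rep(c(0L, 1L), 20)
  truth[seq(1, 40, by = 2)] <- 1L - truth[seq(1, 40, by = 2)]
  cal2 <- calibration_curve(probs, truth)
  top <- cal2$bins[cal2$bins$bin == 10, ]
  expect_equal(top$observed_freq, 0.5)
  # empty bins are emitted with count 0 and NA frequency
  expect_true(any(cal2$bins$count == 0 & is.na(cal2$bins$observed_freq)))
  # bin counts sum to the number of pooled (sample, class) pairs
  expect_equal(sum(cal2$bins$count), length(truth) * k)
})

test_that("a perfectly calibrated simulation tracks the identity line", {
  withr::with_seed(31, {
    p <- runif(1e5)
    y <- as.integer(runif(1e5) < p)
  })
  cal <- calibration_curve(p, y)
  filled <- cal$bins[cal$bins$count > 0, ]
  # each filled bin's observed frequency within a 4-sigma binomial band
  for (i in seq_len(nrow(filled))) {
    se <- sqrt(filled$mean_pred[i] * (1 - filled$mean_pred[i]) /
                 filled$count[i])
    expect_lt(abs(filled$observed_freq[i] - filled$mean_pred[i]),
              4 * se + 1e-6)
  }
})

test_that("binary Brier decomposes into calibration plus refinement", {
  withr::with_seed(13, {
    p <- rbeta(20000, 2, 2)
    # miscalibrated outcomes: true probability is p^1.3
    y <- as.integer(runif(20000) < p^1.3)
  })
  cal <- calibration_curve(p, y, n_bins = 10)
  bins <- cal$bins[cal$bins$count > 0, ]
  wsum <- sum(bins$count)
  calib_term <- sum(bins$count * (bins$mean_pred - bins$observed_freq)^2) / wsum
  refine_term <- sum(bins$count * bins$observed_freq *
                       (1 - bins$observed_freq)) / wsum
  expect_equal(cal$brier, calib_term + refine_term, tolerance = 0.01)
})

test_that("grouped bootstrap comparison: identical inputs give p near 1", {
  withr::with_seed(17, {
    tbl <- tibble::tibble(patient_id = rep(sprintf("P%02d", 1:25), each = 2),
                          label = sample(0:2, 50, TRUE),
                          decision = sample(0:2, 50, TRUE))
  })
  metric <- function(df) accuracy(df$label, df$decision)
  cmp <- bootstrap_compare(tbl, tbl, metric, B = 100, seed = 2)
  expect_equal(cmp$p_value, 1)
  expect_false(cmp$significant)
  expect_equal(cmp$mean_a, cmp$mean_b)
  # a metric constant across replicates yields a zero-width CI
  cmp2 <- bootstrap_compare(tbl, tbl, function(df) 0.5, B = 50, seed = 2)
  expect_equal(cmp2$ci_a, c(0.5, 0.5))
})

test_that("bootstrap comparison detects a clearly shifted metric", {
  withr::with_seed(19, {
    n_sig <- 0L
    contains <- 0L
    for (r in 1:10) {
      pats <- sprintf("P%02d", 1:30)
      lab <- sample(0:1, 60, TRUE)
      good <- tibble::tibble(patient_id = rep(pats, each = 2), label = lab,
                             decision = ifelse(runif(60) < 0.9, lab, 1L - lab))
      bad <- tibble::tibble(patient_id = rep(pats, each = 2), label = lab,
                            decision = ifelse(runif(60) < 0.5, lab, 1L - lab))
      metric <- function(df) accuracy(df$label, df$decision)
      cmp <- bootstrap_compare(good, bad, metric, B = 200, seed = r)
      n_sig <- n_sig + cmp$significant
      pt <- metric(good)
      contains <- contains + (cmp$ci_a[1] <= pt && pt <= cmp$ci_a[2])
    }
    expect_gte(n_sig, 9L)
    expect_gte(contains, 9L)
  })
})
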