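test_that("Bland-Altman points use signed pair differences and max-min beyond", {
  tbl <- scores_table(list(A = c(0.8, 0.2), B = c(0.3, 0.3, 0.3),
                           C = c(0.1, 0.5, 0.2)))
  pts <- bland_altman_points(tbl)
  pts <- pts[order(pts$patient_id), ]
  expect_equal(pts$mean_score, c(0.5, 0.3, 0.8 / 3), tolerance = 1e-12)
  expect_equal(pts$difference, c(0.6, 0, 0.4))
  # signed difference keeps orientation for two-view patients
  tbl2 <- scores_table(list(A = c(0.2, 0.8)))
  expect_equal(bland_altman_points(tbl2)$difference, -0.6)
})

test_that("patients with fewer than two images are skipped with a warning", {
  tbl <- scores_table(list(A = c(0.5, 0.7), B = 0.4))
  expect_warning(pts <- bland_altman_points(tbl), "skipped")
  expect_equal(nrow(pts), 1L)
  expect_equal(attr(pts, "n_skipped"), 1L)
})

test_that("loa95 handles degenerate, uniform and rescaled differences", {
  expect_equal(as.numeric(loa95(rep(0, 30), c(0, 1))), 0)
  # near-uniform differences on [-1, 1], range width 2: percentile half-width
  # approaches 0.95 / 2 of the range
  d <- seq(-1, 1, length.out = 2001)
  l <- loa95(d, c(0, 2))
  expect_equal(attr(l, "method"), "percentile")
  expect_equal(as.numeric(l), 0.475, tolerance = 0.002)
  # scale equivariance on the percentile path
  withr::with_seed(1, dd <- rexp(200)^2)
  l1 <- loa95(dd, c(0, 1))
  l2 <- loa95(2 * dd, c(0, 1))
  expect_equal(attr(l1, "method"), "percentile")
  expect_equal(as.numeric(l2), 2 * as.numeric(l1), tolerance = 1e-12)
  # normal-looking differences take the parametric path
  withr::with_seed(3, dn <- rnorm(200))
  ln <- loa95(dn, c(0, 1))
  expect_equal(attr(ln, "method"), "normal")
  expect_equal(as.numeric(ln), 1.96 * sd(dn), tolerance = 1e-12)
  expect_true(attr(loa95(c(0.1, -0.2, 0.3), c(0, 1)), "low_confidence"))
})

# independent sort-based type-7 quantile oracle
quantile_oracle <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[pmin(lo + 1, length(x))] - x[lo])
}

test_that("percentile-path loa95 matches the sort-based quantile oracle", {
  withr::with_seed(7, {
    checked <- 0L
    for (i in 1:150) {
      n <- sample(20:50, 1)
      d <- rlnorm(n)^2 * sample(c(-1, 1), n, TRUE) # heavy-tailed, non-normal
      l <- loa95(d, c(0, 1))
      if (attr(l, "method") != "percentile") next
      oracle <- (quantile_oracle(d, 0.975) - quantile_oracle(d, 0.025)) / 2
      expect_equal(as.numeric(l), oracle, tolerance = 1e-12)
      checked <- checked + 1L
    }
    expect_gte(checked, 100L)
  })
})

test_that("empirical 2.5/97.5 percentiles stay inside the extreme order statistics", {
  withr::with_seed(11, {
    d <- sort(c(-rexp(20), rexp(20))) # n = 40, symmetric
    q <- c(quantile_oracle(d, 0.025), quantile_oracle(d, 0.975))
    expect_gte(q[1], d[1]); expect_lte(q[1], d[2])
    expect_lte(q[2], d[40]); expect_gte(q[2], d[39])
    expect_equal(q, quantile(d, c(0.025, 0.975), names = FALSE),
                 tolerance = 1e-12)
  })
})

test_that("disagreement rate counts patients with non-identical decisions", {
  tbl <- scores_table(list(A = c(1, 1, 1), B = c(1, 1), C = c(1, 1)),
                      list(A = c(0, 0, 1), B = c(2, 2), C = c(1, 1)))
  expect_equal(disagreement_rate(tbl), 1 / 3)
  tbl$decision <- 1L
  expect_equal(disagreement_rate(tbl), 0)
})

test_that("repeatability metrics are invariant to patient relabeling and order", {
  withr::with_seed(3, {
    tbl <- tibble::tibble(
      patient_id = rep(sprintf("P%02d", 1:30), each = 2),
      score = runif(60), decision = sample(0:2, 60, TRUE))
  })
  rep1 <- repeatability_report(tbl, c(0, 2))
  # relabel and reorder patients (keeping within-patient row order)
  perm <- sample(30)
  tbl2 <- tbl
  tbl2$patient_id <- rep(sprintf("Q%02d", perm), each = 2)
  tbl2 <- tbl2[order(rep(perm, each = 2), rep(1:2, 30)), ]
  rep2 <- repeatability_report(tbl2, c(0, 2))
  expect_equal(rep1$disagreement_rate, rep2$disagreement_rate)
  expect_equal(rep1$loa95, rep2$loa95)
})
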