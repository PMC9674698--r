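make_mc_set <- function(draws, head) {
  structure(list(draws = draws, head = head, seed = 1L,
                 n_samples = dim(draws)[1]),
            class = "mc_prediction_set")
}

test_that("aggregation is the element-wise mean of the draws", {
  d <- array(0, c(2, 1, 2)); d[1, 1, ] <- c(1, 0); d[2, 1, ] <- c(0, 1)
  expect_equal(aggregate_mc(make_mc_set(d, head_kind("ordinal", 3))), matrix(c(0.5, 0.5), 1))
  d3 <- array(0, c(2, 1, 3))
  d3[1, 1, ] <- c(0.6, 0.3, 0.1); d3[2, 1, ] <- c(0.2, 0.5, 0.3)
  expect_equal(aggregate_mc(make_mc_set(d3, head_kind("multiclass", 3))), matrix(c(0.4, 0.4, 0.2), 1))
  # a single draw is returned unchanged
  expect_equal(aggregate_mc(make_mc_set(d3, head_kind("multiclass", 3)), n = 1),
               matrix(d3[1, , ], 1))
  expect_error(aggregate_mc(make_mc_set(d3, head_kind("multiclass", 3)), n = 5), "1..n_samples")
})

test_that("models without dropout layers refuse MC inference", {
  m <- build_model(model_spec(head_kind("multiclass", 3), input_size = 8,
                              channels = c(2, 2, 2), dropout = FALSE))
  expect_error(mc_forward(m, matrix(runif(64), 1), mc_config(3)),
               "no dropout layers")
})

test_that("rate-0 dropout makes every MC draw equal the deterministic pass", {
  m <- build_model(model_spec(head_kind("multiclass", 3), input_size = 8,
                              channels = c(2, 2, 2), dropout = TRUE,
                              dropout_rate = 0), seed = 3)
  X <- matrix(runif(3 * 64), 3)
  pr <- mc_forward(m, X, mc_config(5, seed = 1))
  det <- deterministic_forward(m, X)
  for (t in 1:5) {
    expect_equal(matrix(pr$draws[t, , ], 3), det, tolerance = 1e-12)
  }
})

test_that("draws are seeded, id-keyed and prefix-stable in N", {
  st <- small_trained()
  te <- mcrepeat:::dataset_split(st$dataset, "test")
  X <- te$images[1:6, ]
  ids <- te$manifest$image_id[1:6]
  p1 <- mc_forward(st$model, X, mc_config(8, seed = 42), ids)
  p2 <- mc_forward(st$model, X, mc_config(8, seed = 42), ids)
  expect_identical(p1$draws, p2$draws)
  # first n draws of a longer run equal the draws of a shorter run
  p3 <- mc_forward(st$model, X, mc_config(3, seed = 42), ids)
  expect_equal(p3$draws, p1$draws[1:3, , , drop = FALSE], tolerance = 1e-12)
  # per-image streams: a subset of images keeps its draws exactly
  p4 <- mc_forward(st$model, X[c(2, 5), ], mc_config(8, seed = 42), ids[c(2, 5)])
  expect_equal(p4$draws, p1$draws[, c(2, 5), , drop = FALSE], tolerance = 1e-10)
  # different seed changes the draws
  p5 <- mc_forward(st$model, X, mc_config(8, seed = 43), ids)
  expect_false(identical(p5$draws, p1$draws))
})

test_that("score of the aggregate equals the mean per-draw score exactly", {
  st <- small_trained()
  te <- mcrepeat:::dataset_split(st$dataset, "test")
  pr <- mc_forward(st$model, te$images[1:10, ], mc_config(12, seed = 7),
                   te$manifest$image_id[1:10])
  agg <- aggregate_mc(pr)
  # aggregated multiclass outputs stay on the simplex
  expect_equal(rowSums(agg), rep(1, 10), tolerance = 1e-9)
  expect_true(all(agg >= 0))
  per_draw <- sapply(1:12, function(t) score_from_probs(matrix(pr$draws[t, , ], 10)))
  expect_equal(score_from_probs(agg), rowMeans(per_draw), tolerance = 1e-12)
})

test_that("aggregate score variance shrinks roughly as 1/n", {
  st <- small_trained()
  te <- mcrepeat:::dataset_split(st$dataset, "test")
  X <- te$images[1, , drop = FALSE]
  score_var <- function(n, reps = 60) {
    s <- sapply(seq_len(reps), function(r) {
      pr <- mc_forward(st$model, X, mc_config(n, seed = 1000 + r), "img")
      score_from_probs(aggregate_mc(pr))
    })
    var(s)
  }
  v1 <- score_var(1); v5 <- score_var(5); v25 <- score_var(25)
  expect_gt(v1, v5)
  expect_gt(v5, v25)
  expect_gt(v1 / v25, 8)  # ideal ratio 25, generous sampling tolerance
})

test_that("iteration sweep reuses common draws and reports the baseline", {
  st <- small_trained()
  sw <- sweep_iterations(st$model, st$dataset, n_grid = c(1, 4, 8),
                         cfg = mc_config(8, seed = 5))
  expect_equal(sw$n, c(1L, 4L, 8L))
  expect_true(all(is.finite(sw$loa95)))
  expect_true(is.finite(attr(sw, "baseline_loa95")))
  # n = N_max equals aggregating the full draw set directly
  te <- mcrepeat:::dataset_split(st$dataset, "test")
  pr <- mc_forward(st$model, te$images, mc_config(8, seed = 5),
                   te$manifest$image_id)
  agg <- aggregate_mc(pr)
  sc <- score_outputs(agg, st$model$spec$head)
  tbl <- tibble::tibble(patient_id = te$manifest$patient_id,
                        score = sc$score, decision = sc$decision)
  rep8 <- repeatability_report(tbl, c(0, 2))
  expect_equal(sw$loa95[sw$n == 8], rep8$loa95, tolerance = 1e-12)
  expect_error(sweep_iterations(st$model, st$dataset, n_grid = c(1, 50),
                                cfg = mc_config(8)), "exceeds")
})

test_that("a rate-0 dropout model sweeps flat at the baseline", {
  ds <- tiny_dataset()
  m0 <- build_model(model_spec(head_kind("multiclass", 3), dropout = TRUE,
                               dropout_rate = 0), seed = 8)
  sw <- sweep_iterations(m0, ds, n_grid = c(1, 3), cfg = mc_config(3, seed = 1))
  expect_equal(sw$loa95, rep(attr(sw, "baseline_loa95"), 2), tolerance = 1e-12)
  expect_equal(sw$disagreement,
               rep(attr(sw, "baseline_disagreement"), 2), tolerance = 1e-12)
})
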