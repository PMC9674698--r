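# Test-time Monte Carlo dropout inference.
#
# At test time the dropout layers are kept active while everything else runs
# in evaluation mode; N stochastic forward passes are drawn per image and the
# final prediction is their element-wise average in probability space
# (post-softmax/sigmoid). Averaging logits instead would not commute with the
# severity-score mapping and is deliberately not offered. Each image owns an
# RNG substream derived from (seed, image id), so draws do not depend on
# batch composition or evaluation order, and the first n draws of a larger
# run are exactly the draws of a smaller run (common random numbers for the
# iteration sweep).

#' Monte Carlo inference configuration
#'
#' @param n_samples Number of stochastic forward passes N (default 50).
#' @param seed Base seed for the per-image draw streams.
#' @param aggregate Aggregation rule; only `"mean"` is supported.
#' @return An `mc_config` list.
#' @export
mc_config <- function(n_samples = 50L, seed = 1L, aggregate = "mean") {
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 1L) abort("n_samples must be >= 1.")
  aggregate <- match.arg(aggregate, "mean")
  structure(list(n_samples = n_samples, seed = as.integer(seed),
                 aggregate = aggregate),
            class = "mc_config")
}

# Per-image channel dropout masks for all draws: for image stream `img_seed`
# the Bernoulli sequence is ordered draw-major, then layer, then channel, so
# draw prefixes are reproducible across different N.
image_masks <- function(img_seed, channels, n_draws, rate) {
  n_per_draw <- sum(channels)
  withr::with_seed(img_seed, {
    bits <- rbinom(n_per_draw * n_draws, 1L, 1 - rate)
  })
  array(bits, dim = c(n_per_draw, n_draws)) # column t = draw t
}

#' Monte Carlo dropout forward passes
#'
#' Runs `cfg$n_samples` stochastic forward passes of `model` over a batch of
#' images with the channel-dropout layers active and all other behaviour
#' deterministic, and returns the per-draw activated head outputs.
#'
#' @param model A trained `mc_model` containing dropout layers.
#' @param images Matrix of flattened images, one per row.
#' @param cfg An [mc_config()].
#' @param image_ids Optional character/integer ids (default row indices) used
#'   to derive each image's RNG substream.
#' @return An `mc_prediction_set`: list with `draws` (array
#'   `n_samples x n_images x output_width` of activated outputs), `head`,
#'   `seed` and `n_samples`.
#' @export
mc_forward <- function(model, images, cfg = mc_config(), image_ids = NULL) {
  stopifnot(inherits(model, "mc_model"), inherits(cfg, "mc_config"))
  if (!has_dropout(model)) {
    abort(paste("model has no dropout layers: MC sampling would silently",
                "equal a single deterministic pass. Build the model with",
                "dropout = TRUE (rate 0 is allowed)."))
  }
  images <- as_row_matrix(images)
  B <- nrow(images)
  image_ids <- image_ids %||% seq_len(B)
  stopifnot(length(image_ids) == B)
  ch <- model$geom$channels
  N <- cfg$n_samples
  rate <- model$geom$rate
  # per-image mask streams, ordered so draw prefixes are stable in N
  per_img <- lapply(seq_len(B), function(b) {
    image_masks(derive_seed(cfg$seed, "mc", image_ids[b]), ch, N, rate)
  })
  width <- head_width(model$spec$head)
  draws <- array(NA_real_, dim = c(N, B, width))
  splits <- c(0L, cumsum(ch))
  for (t in seq_len(N)) {
    masks <- lapply(seq_along(ch), function(l) {
      m <- vapply(per_img, function(a) a[(splits[l] + 1L):splits[l + 1L], t],
                  numeric(ch[l]))
      matrix(t(m), nrow = B, ncol = ch[l])
    })
    fw <- nn_forward(model$params, images, model$geom, masks = masks)
    draws[t, , ] <- head_output(fw$logits, model$spec$head)
  }
  structure(list(draws = draws, head = model$spec$head,
                 seed = cfg$seed, n_samples = N),
            class = "mc_prediction_set")
}

#' @exportS3Method base::print
print.mc_prediction_set <- function(x, ...) {
  cat(sprintf("<mc_prediction_set> %d draws x %d images, %s head (k = %d)\n",
              x$n_samples, dim(x$draws)[2], x$head$kind, x$head$k))
  invisible(x)
}

#' Aggregate Monte Carlo draws into the final prediction
#'
#' Element-wise mean over the draws, in probability space: the average of
#' valid probability vectors is itself a valid probability vector, and by
#' linearity of the severity-score mapping the score of the aggregate equals
#' the mean per-draw score.
#'
#' @param preds An `mc_prediction_set`, optionally truncated with `n`.
#' @param n Use only the first `n` draws (common-random-number prefix);
#'   default all.
#' @return Matrix of aggregated head outputs, one row per image.
#' @export
aggregate_mc <- function(preds, n = NULL) {
  stopifnot(inherits(preds, "mc_prediction_set"))
  N <- dim(preds$draws)[1]
  n <- n %||% N
  if (n < 1L || n > N) abort("n must lie in 1..n_samples.")
  out <- apply(preds$draws[seq_len(n), , , drop = FALSE], c(2L, 3L), mean)
  matrix(out, nrow = dim(preds$draws)[2], ncol = dim(preds$draws)[3])
}

#' Deterministic (dropout-disabled) forward pass
#'
#' The non-MC baseline: a single forward pass with every dropout layer
#' disabled and all other inference behaviour identical.
#'
#' @param model An `mc_model`.
#' @param images Matrix of flattened images, one per row.
#' @return Matrix of activated head outputs, one row per image.
#' @export
deterministic_forward <- function(model, images) {
  stopifnot(inherits(model, "mc_model"))
  images <- as_row_matrix(images)
  fw <- nn_forward(model$params, images, model$geom)
  head_output(fw$logits, model$spec$head)
}

#' Repeatability versus number of MC iterations
#'
#' Draws `max(n_grid)` MC samples once per test image and, for each `n` in
#' `n_grid`, aggregates the *first* `n` draws (common random numbers, so the
#' curve is free of resampling noise between grid points), scores and
#' classifies the aggregate, and computes the repeatability metrics over the
#' split's test-retest groups. The dropout-disabled single-pass baseline is
#' reported alongside.
#'
#' @param model A trained `mc_model` with dropout layers.
#' @param dataset A `synth_dataset`.
#' @param n_grid Integer grid of MC iteration counts.
#' @param cfg An [mc_config()]; `cfg$n_samples` must be at least `max(n_grid)`.
#' @param split Dataset split to evaluate (default `"test"`).
#' @param preds Optional precomputed [mc_forward()] draw set for the split
#'   (with at least `max(n_grid)` draws); drawn here when `NULL`.
#' @return An `mc_sweep`: tibble with columns `n`, `loa95`, `disagreement`,
#'   plus attributes `baseline_loa95`, `baseline_disagreement` (dropout
#'   disabled) and `n_patients`.
#' @export
sweep_iterations <- function(model, dataset, n_grid = c(1, 2, 5, 10, 20, 30, 40, 50),
                             cfg = mc_config(), split = "test", preds = NULL) {
  n_grid <- sort(unique(as.integer(n_grid)))
  if (max(n_grid) > cfg$n_samples) {
    abort("n_grid exceeds the configured number of MC samples.")
  }
  ds <- dataset_split(dataset, split)
  head <- model$spec$head
  rng <- score_range(head)
  if (is.null(preds)) {
    preds <- mc_forward(model, ds$images, cfg, image_ids = ds$manifest$image_id)
  }
  if (dim(preds$draws)[1] < max(n_grid) ||
      dim(preds$draws)[2] != nrow(ds$manifest)) {
    abort("supplied draw set does not match the split or the grid maximum.")
  }
  rows <- lapply(n_grid, function(n) {
    out <- aggregate_mc(preds, n)
    sc <- score_outputs(out, head)
    tbl <- tibble(patient_id = ds$manifest$patient_id,
                  image_id = ds$manifest$image_id,
                  score = sc$score, decision = sc$decision)
    rep <- repeatability_report(tbl, score_range = rng)
    tibble(n = n, loa95 = rep$loa95, disagreement = rep$disagreement_rate)
  })
  res <- bind_rows(rows)
  base_out <- deterministic_forward(model, ds$images)
  bsc <- score_outputs(base_out, head)
  btbl <- tibble(patient_id = ds$manifest$patient_id,
                 image_id = ds$manifest$image_id,
                 score = bsc$score, decision = bsc$decision)
  brep <- repeatability_report(btbl, score_range = rng)
  structure(res, class = c("mc_sweep", class(res)),
            baseline_loa95 = brep$loa95,
            baseline_disagreement = brep$disagreement_rate,
            n_patients = brep$n_patients)
}
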