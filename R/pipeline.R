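# Evaluation pipeline and reporting: score a model over a dataset split,
# assemble repeatability/classification/calibration reports, pair MC with
# non-MC variants, and write the CSV/JSON artifacts the CLI exposes.

#' Score a model over a dataset split
#'
#' Runs either MC-dropout inference (aggregated over `mc_cfg$n_samples`
#' draws) or the deterministic dropout-disabled pass, maps raw outputs to
#' severity scores and class decisions, and returns one row per image.
#'
#' @param model A trained `mc_model`.
#' @param dataset A `synth_dataset`.
#' @param split Dataset split (`"test"`, `"val"`, `"train"`).
#' @param mc Use Monte Carlo dropout inference?
#' @param mc_cfg An [mc_config()] (used when `mc = TRUE`).
#' @param mc_preds Optional precomputed [mc_forward()] draw set over the same
#'   split (avoids redrawing when the draws are shared with an iteration
#'   sweep).
#' @return A `prediction_set` tibble (`patient_id`, `image_id`, `label`,
#'   `score`, `decision`) with the raw aggregated outputs in attribute
#'   `outputs` and the head in attribute `head`.
#' @export
predict_dataset <- function(model, dataset, split = "test", mc = FALSE,
                            mc_cfg = mc_config(), mc_preds = NULL) {
  ds <- dataset_split(dataset, split)
  if (nrow(ds$manifest) == 0L) abort(sprintf("split '%s' is empty.", split))
  out <- if (mc) {
    if (is.null(mc_preds)) {
      mc_preds <- mc_forward(model, ds$images, mc_cfg,
                             image_ids = ds$manifest$image_id)
    }
    aggregate_mc(mc_preds)
  } else {
    deterministic_forward(model, ds$images)
  }
  sc <- score_outputs(out, model$spec$head)
  truth <- model_truth(ds$manifest$label, model$spec$head, dataset$config$k)
  tbl <- tibble(patient_id = ds$manifest$patient_id,
                image_id = ds$manifest$image_id,
                label = truth,
                score = sc$score, decision = sc$decision)
  structure(tbl, outputs = out, head = model$spec$head, mc = mc,
            class = c("prediction_set", class(tbl)))
}

# ground-truth class on the head's own label scale (binary heads on k-class
# data are scored against the mid-scale binarised label)
model_truth <- function(labels, head, data_k) {
  if (head$kind == "binary") as.integer(labels > (data_k - 1) / 2)
  else as.integer(labels)
}

#' Evaluate a model: repeatability + classification + calibration
#'
#' @inheritParams predict_dataset
#' @return A `model_evaluation`: list with `predictions`, `repeatability`
#'   (a [repeatability_report()]), `accuracy`, `kappa`, `calibration` (a
#'   [calibration_curve()] report, `NULL` for regression heads, which have no
#'   probabilities), `head` and `mc`.
#' @export
evaluate_model <- function(model, dataset, split = "test", mc = FALSE,
                           mc_cfg = mc_config(), mc_preds = NULL) {
  preds <- predict_dataset(model, dataset, split, mc, mc_cfg, mc_preds)
  head <- model$spec$head
  rng <- score_range(head)
  rep <- repeatability_report(preds, score_range = rng)
  k_eff <- if (head$kind == "binary") 2L else head$k
  kap <- quadratic_weighted_kappa(preds$label, preds$decision, k_eff)
  calib <- if (head$kind != "regression") {
    calibration_curve(attr(preds, "outputs"), preds$label)
  }
  structure(list(predictions = preds, repeatability = rep,
                 accuracy = accuracy(preds$label, preds$decision),
                 kappa = kap, calibration = calib,
                 head = head, mc = mc),
            class = "model_evaluation")
}

#' @exportS3Method base::print
print.model_evaluation <- function(x, ...) {
  cat(sprintf("<model_evaluation> %s head (k = %d), %s inference\n",
              x$head$kind, x$head$k, if (x$mc) "MC dropout" else "deterministic"))
  cat(sprintf("  disagreement %.3f | 95%% LoA %.3f | kappa %.3f | accuracy %.3f%s\n",
              x$repeatability$disagreement_rate, x$repeatability$loa95,
              x$kappa, x$accuracy,
              if (!is.null(x$calibration))
                sprintf(" | Brier %.3f", x$calibration$brier) else ""))
  invisible(x)
}

#' Train and evaluate an MC / non-MC model pair
#'
#' Builds, trains and evaluates the dropout (MC-inference) and no-dropout
#' (deterministic) variants of one head on one synthetic dataset — the
#' minimal unit of the benchmark. The two variants differ only by the
#' dropout configuration switch.
#'
#' @param dataset A `synth_dataset`.
#' @param head A [head_kind()].
#' @param train_cfg A [train_config()].
#' @param mc_samples Number of MC draws at test time.
#' @param seed Seed controlling weight init, training and MC draws.
#' @return List with `mc` and `plain` (`model_evaluation`s), the trained
#'   `mc_model` / `plain_model`, and a two-row `metrics` tibble.
#' @export
evaluate_pair <- function(dataset, head = head_kind("multiclass", dataset$config$k),
                          train_cfg = train_config(), mc_samples = 50L,
                          seed = train_cfg$seed) {
  sz <- dataset$config$image_size
  spec_mc <- model_spec(head, input_size = sz, dropout = TRUE,
                        dropout_rate = train_cfg$dropout_rate)
  spec_plain <- model_spec(head, input_size = sz, dropout = FALSE)
  cfg <- train_cfg; cfg$seed <- as.integer(seed)
  m_mc <- train_model(build_model(spec_mc, seed = derive_seed(seed, "init", 1)),
                      dataset, cfg)
  m_plain <- train_model(build_model(spec_plain, seed = derive_seed(seed, "init", 2)),
                         dataset, cfg)
  te <- dataset_split(dataset, "test")
  mc_cfg <- mc_config(mc_samples, seed = derive_seed(seed, "mc"))
  mc_preds <- mc_forward(m_mc, te$images, mc_cfg,
                         image_ids = te$manifest$image_id)
  ev_mc <- evaluate_model(m_mc, dataset, mc = TRUE, mc_cfg = mc_cfg,
                          mc_preds = mc_preds)
  ev_plain <- evaluate_model(m_plain, dataset, mc = FALSE)
  metrics <- bind_rows(glance(ev_mc), glance(ev_plain))
  metrics$model <- c("mc", "plain")
  list(mc = ev_mc, plain = ev_plain, mc_model = m_mc, plain_model = m_plain,
       mc_preds = mc_preds,
       metrics = metrics[, c("model", setdiff(names(metrics), "model"))])
}

#' Run the reference synthetic benchmark
#'
#' The packaged desk-scale analogue of the full study: for each seed,
#' generate the reference synthetic test-retest dataset (`k = 3`, 300
#' patients, 2 views/patient, boundary label noise 0.25), train the
#' multiclass dropout and no-dropout models, evaluate repeatability,
#' agreement and calibration on the test split, and (optionally) sweep the
#' number of MC iterations with common random draws.
#'
#' @param seeds Integer vector of benchmark seeds (one dataset + model pair
#'   per seed).
#' @param head A [head_kind()]; default 3-class multiclass.
#' @param gen_cfg Base [synth_config()]; its seed is replaced per run.
#' @param train_cfg Base [train_config()]; its seed is replaced per run.
#' @param mc_samples MC draws for evaluation and the sweep maximum.
#' @param n_grid MC-iteration grid for the sweep; `NULL` skips the sweep.
#' @return A `benchmark_result`: list with `metrics` (tibble, one row per
#'   seed x model), `sweeps` (list of `mc_sweep` per seed, possibly empty)
#'   and `seeds`.
#' @export
run_benchmark <- function(seeds = 0:4, head = head_kind("multiclass", 3),
                          gen_cfg = synth_config(),
                          train_cfg = train_config(),
                          mc_samples = 50L,
                          n_grid = c(1, 2, 5, 10, 20, 30, 40, 50)) {
  rows <- list()
  sweeps <- list()
  for (sd in seeds) {
    cfg <- gen_cfg; cfg$seed <- as.integer(sd)
    ds <- generate_dataset(cfg)
    pair <- evaluate_pair(ds, head = head, train_cfg = train_cfg,
                          mc_samples = mc_samples, seed = sd)
    m <- pair$metrics
    m$seed <- sd
    rows[[length(rows) + 1L]] <- m
    if (!is.null(n_grid)) {
      sweeps[[as.character(sd)]] <-
        sweep_iterations(pair$mc_model, ds, n_grid,
                         cfg = mc_config(mc_samples, seed = derive_seed(sd, "mc")),
                         preds = pair$mc_preds)
    }
  }
  structure(list(metrics = bind_rows(rows), sweeps = sweeps, seeds = seeds),
            class = "benchmark_result")
}

#' @exportS3Method base::print
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> %d seed(s)\n", length(x$seeds)))
  med <- x$metrics |>
    group_by(.data$model) |>
    summarise(across(c("disagreement", "loa95", "accuracy", "kappa", "brier"),
                     median), .groups = "drop")
  print(med)
  invisible(x)
}

#' Median smallest MC iteration count reaching the full-draw plateau
#'
#' For each seed's sweep, finds the smallest `n` in the grid whose LoA is no
#' more than `(1 + tol)` times the LoA at the largest grid point, then
#' returns the median over seeds. The comparison is one-sided: the question
#' a plateau answers is when additional draws stop *gaining* repeatability,
#' and an LoA already at or below the full-draw value has no further gain
#' left to realize.
#'
#' @param sweeps List of `mc_sweep` results (e.g. `run_benchmark()$sweeps`).
#' @param tol Relative tolerance (default 0.05).
#' @return Median smallest plateau `n` (numeric).
#' @export
plateau_iteration <- function(sweeps, tol = 0.05) {
  ns <- vapply(sweeps, function(sw) {
    ref <- sw$loa95[which.max(sw$n)]
    ok <- sw$loa95 <= (1 + tol) * ref
    min(sw$n[ok])
  }, numeric(1))
  median(ns)
}

# ---- file-based reporting used by the CLI ----

#' Write evaluation artifacts for one model
#'
#' Emits `scores.csv` (per-image scores/decisions), `metrics.csv` (one-row
#' summary), `bland_altman.csv` (mean/difference points) and, for
#' probability heads, `calibration.csv` (per-bin reliability statistics).
#'
#' @param ev A [evaluate_model()] result.
#' @param dir Output directory.
#' @param name Model name used in the files.
#' @return `dir`, invisibly.
#' @export
write_evaluation <- function(ev, dir, name = "model") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(as_tibble(ev$predictions),
                   file.path(dir, paste0(name, "_scores.csv")))
  g <- glance(ev); g$model <- name
  readr::write_csv(g, file.path(dir, paste0(name, "_metrics.csv")))
  readr::write_csv(ev$repeatability$points,
                   file.path(dir, paste0(name, "_bland_altman.csv")))
  if (!is.null(ev$calibration)) {
    readr::write_csv(ev$calibration$bins,
                     file.path(dir, paste0(name, "_calibration.csv")))
  }
  invisible(dir)
}

#' Compare an MC / non-MC model pair by grouped bootstrap
#'
#' Runs [bootstrap_compare()] on disagreement rate, normalized 95% LoA,
#' accuracy and quadratic weighted kappa computed from two per-image score
#' tables, and marks the significant winner per metric (lower is better for
#' the repeatability metrics, higher for the classification metrics).
#'
#' @param scores_mc,scores_plain Data frames with `patient_id`, `label`,
#'   `score`, `decision`.
#' @param score_range Length-2 score scale `(lo, hi)`.
#' @param k Number of classes for kappa.
#' @param B,seed Bootstrap settings.
#' @return Tibble with one row per metric: bootstrap means, CIs, p-value,
#'   significance and `winner` (`"mc"`, `"plain"` or `NA`).
#' @export
compare_pair <- function(scores_mc, scores_plain, score_range, k,
                         B = 500L, seed = 1L) {
  metrics <- list(
    disagreement = list(f = function(df) disagreement_rate(df), lower = TRUE),
    loa95 = list(f = function(df) {
      pts <- suppressWarnings(bland_altman_points(df))
      if (nrow(pts) == 0L) return(NA_real_)
      as.numeric(loa95(pts, score_range))
    }, lower = TRUE),
    accuracy = list(f = function(df) accuracy(df$label, df$decision),
                    lower = FALSE),
    kappa = list(f = function(df)
      suppressWarnings(quadratic_weighted_kappa(df$label, df$decision, k)),
      lower = FALSE))
  rows <- lapply(names(metrics), function(nm) {
    cmp <- bootstrap_compare(scores_mc, scores_plain, metrics[[nm]]$f,
                             B = B, seed = derive_seed(seed, nm),
                             metric_name = nm)
    better_mc <- if (metrics[[nm]]$lower) cmp$mean_a < cmp$mean_b
                 else cmp$mean_a > cmp$mean_b
    tibble(metric = nm,
           mc_mean = cmp$mean_a, mc_lo = cmp$ci_a[1], mc_hi = cmp$ci_a[2],
           plain_mean = cmp$mean_b, plain_lo = cmp$ci_b[1],
           plain_hi = cmp$ci_b[2],
           p_value = cmp$p_value, significant = cmp$significant,
           winner = ifelse(cmp$significant, ifelse(better_mc, "mc", "plain"),
                           NA_character_))
  })
  bind_rows(rows)
}

#' Append a structured JSON-lines log record
#'
#' @param path Log file path (created if needed).
#' @param stage Stage name.
#' @param ... Named fields to record (seeds, paths, counts...).
#' @return The record, invisibly.
#' @export
log_stage <- function(path, stage, ...) {
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                stage = stage), list(...))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
      file = path, append = TRUE, sep = "")
  invisible(rec)
}
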