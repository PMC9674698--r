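# Shared fixtures. Everything is generated in code; the heavier shared
# objects (a small trained model pair, the acceptance benchmark) are built
# once per test run and memoised in this environment.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# tiny dataset: fast to generate, big enough to train a usable model
tiny_config <- function(seed = 1L, n_patients = 40L, ...) {
  args <- utils::modifyList(
    list(n_patients = n_patients, k = 3, images_per_patient = 2,
         image_size = 32, boundary_noise_sd = 0.25, seed = seed),
    list(...))
  do.call(synth_config, args)
}

tiny_dataset <- function() {
  memo("tiny_dataset", generate_dataset(tiny_config()))
}

# a small trained multiclass dropout model on a mid-sized dataset (shared by
# the mc-inference and pipeline tests)
small_trained <- function() {
  memo("small_trained", {
    ds <- generate_dataset(tiny_config(seed = 3L, n_patients = 80L))
    spec <- model_spec(head_kind("multiclass", 3), dropout = TRUE,
                       dropout_rate = 0.2)
    model <- train_model(build_model(spec, seed = 5L), ds,
                         train_config(seed = 5L, epochs = 10))
    list(model = model, dataset = ds)
  })
}

# random probability simplex rows
random_simplex <- function(n, k) {
  m <- matrix(rexp(n * k), n, k)
  m / rowSums(m)
}

# per-image scores table from explicit per-patient score lists
scores_table <- function(score_list, decision_list = NULL) {
  ids <- names(score_list) %||% paste0("P", seq_along(score_list))
  tibble::tibble(
    patient_id = rep(ids, lengths(score_list)),
    score = unlist(score_list, use.names = FALSE),
    decision = if (is.null(decision_list)) 0L
               else unlist(decision_list, use.names = FALSE))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
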