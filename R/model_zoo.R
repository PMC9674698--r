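# Small trainable convolutional severity classifiers.
#
# The desk-scale backbone is a 3-block CNN (3x3 conv, ReLU, 2x2 average
# pool, spatial/channel dropout after each block) followed by global average
# pooling and one of four heads: binary (1 sigmoid unit, BCE), multiclass
# (k softmax units, cross-entropy), ordinal (CORAL: shared weight vector with
# k - 1 rank biases, cumulative BCE) and regression (1 linear unit, MSE on
# the zero-based class index). "No-dropout" variants contain no dropout
# layers at all, so the MC/non-MC pairs of one head differ only by that
# single configuration switch.

#' Model specification
#'
#' @param head A [head_kind()].
#' @param input_size Square input side in pixels (must be divisible by 8).
#' @param channels Feature channels of the three conv blocks.
#' @param dropout If `TRUE`, a spatial (channel) dropout layer follows each
#'   conv block; if `FALSE` the model contains no dropout layers and cannot
#'   be used for MC inference.
#' @param dropout_rate Per-channel zeroing probability in `[0, 1)`; whole
#'   feature channels are dropped independently per image and forward pass.
#'   A rate of 0 keeps the layers but makes them deterministic.
#' @return A `model_spec` list.
#' @export
model_spec <- function(head, input_size = 32L, channels = c(8L, 16L, 32L),
                       dropout = TRUE, dropout_rate = 0.2) {
  stopifnot(inherits(head, "head_kind"))
  input_size <- as.integer(input_size)
  if (input_size %% 8L != 0L) abort("input_size must be divisible by 8.")
  if (length(channels) != 3L) abort("the small backbone has 3 conv blocks.")
  if (dropout_rate < 0 || dropout_rate >= 1) abort("dropout_rate must be in [0, 1).")
  structure(list(head = head, input_size = input_size,
                 channels = as.integer(channels),
                 dropout = isTRUE(dropout), dropout_rate = dropout_rate),
            class = "model_spec")
}

#' Build a model from a specification
#'
#' @param spec A [model_spec()].
#' @param seed Seed for the weight initialisation.
#' @return An `mc_model` with He-initialised parameters, exposing a
#'   deterministic (dropout-disabled) and, when the spec has dropout layers,
#'   a stochastic (dropout-active) forward mode.
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  params <- nn_init(spec$input_size, spec$channels, spec$head, seed)
  geom <- list(input_size = spec$input_size, channels = spec$channels,
               head = spec$head,
               rate = if (spec$dropout) spec$dropout_rate else 0)
  structure(list(spec = spec, params = params, geom = geom, history = NULL),
            class = "mc_model")
}

#' @exportS3Method base::print
print.mc_model <- function(x, ...) {
  cat(sprintf("<mc_model> %s head, k = %d, %s (rate %.2f), input %dx%d\n",
              x$spec$head$kind, x$spec$head$k,
              if (x$spec$dropout) "channel dropout" else "no dropout layers",
              x$spec$dropout_rate, x$spec$input_size, x$spec$input_size))
  if (!is.null(x$history)) {
    cat(sprintf("  trained %d epochs, best val loss %.4f\n",
                nrow(x$history), min(x$history$val_loss)))
  }
  invisible(x)
}

has_dropout <- function(model) model$spec$dropout

# activation from logits to the head's output space
head_output <- function(logits, head) {
  logits <- as_row_matrix(logits)
  switch(head$kind,
    binary = 1 / (1 + exp(-logits)),
    ordinal = 1 / (1 + exp(-logits)),
    regression = logits,
    multiclass = {
      z <- logits - apply(logits, 1L, max)
      ez <- exp(z)
      ez / rowSums(ez)
    })
}

# numerically stable elementwise binary cross-entropy with logits
bce_with_logits <- function(z, y) {
  pmax(z, 0) - z * y + log1p(exp(-abs(z)))
}

#' CORAL ordinal loss
#'
#' Sum over the `k - 1` cumulative binary tasks of the binary cross-entropy
#' between `sigmoid(logit_j)` and the cumulative encoding bit `e_j` (see
#' [encode_ordinal_label()]); averaged over rows when given matrices. All
#' task importance weights are 1. The loss is nonnegative and approaches 0
#' only as the logits saturate toward their targets.
#'
#' @param logits Length `k - 1` logit vector, or a matrix of rows.
#' @param target Cumulative 0/1 encoding of the same shape.
#' @return Mean per-sample loss (a nonnegative scalar).
#' @export
coral_loss <- function(logits, target) {
  z <- as_row_matrix(logits)
  e <- as_row_matrix(target)
  if (!all(dim(z) == dim(e))) abort("logits and target shapes must match.")
  mean(rowSums(bce_with_logits(z, e)))
}

# loss value + gradient wrt logits for a batch; targets is the per-head
# target representation produced by head_targets()
loss_and_grad <- function(logits, targets, head) {
  B <- nrow(as_row_matrix(logits))
  switch(head$kind,
    binary = {
      z <- as.numeric(logits); y <- targets
      list(loss = mean(bce_with_logits(z, y)),
           dlogits = matrix((1 / (1 + exp(-z)) - y) / B, ncol = 1))
    },
    multiclass = {
      p <- head_output(logits, head)
      onehot <- matrix(0, B, head$k)
      onehot[cbind(seq_len(B), targets + 1L)] <- 1
      eps <- 1e-12
      list(loss = -mean(log(p[cbind(seq_len(B), targets + 1L)] + eps)),
           dlogits = (p - onehot) / B)
    },
    ordinal = {
      z <- as_row_matrix(logits)
      list(loss = coral_loss(z, targets),
           dlogits = (1 / (1 + exp(-z)) - targets) / B)
    },
    regression = {
      z <- as.numeric(logits); y <- targets
      list(loss = mean((z - y)^2),
           dlogits = matrix(2 * (z - y) / B, ncol = 1))
    })
}

# Map integer dataset labels 0..data_k-1 to the head's training targets.
# A binary head on a k-class dataset uses a mid-scale cut: positive iff
# label > (data_k - 1) / 2 (for k = 2 this is the label itself).
head_targets <- function(labels, head, data_k = head$k) {
  switch(head$kind,
    multiclass = as.integer(labels),
    regression = as.numeric(labels),
    ordinal = encode_ordinal_label(as.integer(labels), head$k),
    binary = as.integer(labels > (data_k - 1) / 2))
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param epochs Number of training epochs.
#' @param dropout_rate Channel dropout rate used when the pipeline builds
#'   dropout models from this config.
#' @param seed Training seed (shuffling, augmentation, dropout masks).
#' @param scheduler_factor,scheduler_patience Reduce-on-plateau learning-rate
#'   schedule: multiply the rate by `scheduler_factor` when the validation
#'   loss has not improved for `scheduler_patience` epochs.
#' @param augment_rotation,augment_flip_prob Training augmentation: rotation
#'   uniform in `[-augment_rotation, augment_rotation]` degrees and
#'   horizontal flip probability. Applied only during training.
#' @param augment Disable all augmentation with `FALSE`.
#' @param snapshot Which epoch's parameters the trained model keeps:
#'   `"loss"` (default) returns the best validation-loss epoch;
#'   `"accuracy"` returns the best validation-accuracy epoch (falls back to
#'   loss for regression heads). Accuracy snapshots are only advisable with
#'   validation sets large enough that accuracy is not a coarse step
#'   function.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 32L, epochs = 25L,
                         dropout_rate = 0.1, seed = 1L,
                         scheduler_factor = 0.1, scheduler_patience = 10L,
                         augment_rotation = 15, augment_flip_prob = 0.5,
                         augment = TRUE, snapshot = c("loss", "accuracy")) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1,
            scheduler_factor > 0, scheduler_factor < 1, scheduler_patience >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), dropout_rate = dropout_rate,
                 seed = as.integer(seed), scheduler_factor = scheduler_factor,
                 scheduler_patience = as.integer(scheduler_patience),
                 augment_rotation = augment_rotation,
                 augment_flip_prob = augment_flip_prob,
                 augment = isTRUE(augment),
                 snapshot = match.arg(snapshot)),
            class = "train_config")
}

augment_batch <- function(X, dim, rotation, flip_prob) {
  H <- dim[1]; W <- dim[2]
  for (i in seq_len(nrow(X))) {
    ang <- runif(1, -rotation, rotation)
    fl <- runif(1) < flip_prob
    if (abs(ang) > 1e-9 || fl) {
      img <- affine_transform(matrix(X[i, ], H, W), angle_deg = ang, flip = fl)
      X[i, ] <- as.vector(img)
    }
  }
  X
}

#' Train a model on a synthetic dataset
#'
#' Optimises the head-appropriate loss (BCE / cross-entropy / CORAL / MSE)
#' with Adam, a reduce-on-plateau learning-rate schedule, and training-only
#' augmentation (rotation, horizontal flips). Dropout layers (if present) are
#' active during training; validation is evaluated with dropout disabled.
#' The returned model carries the parameters of the best validation epoch and
#' a per-epoch history. Fully seeded: identical config and dataset give
#' identical trained weights.
#'
#' @param model An [build_model()] output.
#' @param dataset A `synth_dataset` with train and val splits.
#' @param cfg A [train_config()].
#' @return The trained `mc_model`, with a `history` tibble
#'   (`epoch`, `train_loss`, `val_loss`, `lr`).
#' @export
train_model <- function(model, dataset, cfg = train_config()) {
  stopifnot(inherits(model, "mc_model"), inherits(dataset, "synth_dataset"),
            inherits(cfg, "train_config"))
  head <- model$spec$head
  tr <- dataset_split(dataset, "train")
  va <- dataset_split(dataset, "val")
  if (nrow(va$manifest) == 0L) abort("validation split is empty.")
  if (nrow(tr$manifest) == 0L) abort("training split is empty.")
  # patient-level split discipline
  stopifnot(length(intersect(tr$manifest$patient_id, va$manifest$patient_id)) == 0L)
  Xtr <- tr$images
  ytr_lab <- tr$manifest$label
  Xva <- va$images
  yva <- head_targets(va$manifest$label, head, dataset$config$k)
  ytr_all <- head_targets(ytr_lab, head, dataset$config$k)
  params <- model$params
  geom <- model$geom
  state <- adam_init(params)
  lr <- cfg$learning_rate
  use_acc <- cfg$snapshot %||% "loss"
  use_acc <- use_acc == "accuracy" && head$kind != "regression"
  best <- list(loss = Inf, acc = -Inf, params = params)
  best_loss <- Inf # scheduler tracks validation loss regardless of snapshot
  since_improve <- 0L
  hist <- vector("list", cfg$epochs)
  n <- nrow(Xtr)
  for (ep in seq_len(cfg$epochs)) {
    ep_losses <- c()
    withr::with_seed(derive_seed(cfg$seed, "epoch", ep), {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      for (bi in batches) {
        Xb <- Xtr[bi, , drop = FALSE]
        if (cfg$augment) {
          Xb <- augment_batch(Xb, dataset$image_dim,
                              cfg$augment_rotation, cfg$augment_flip_prob)
        }
        masks <- if (has_dropout(model)) {
          make_dropout_masks(geom$channels, length(bi), geom$rate)
        }
        yb <- if (is.matrix(ytr_all)) ytr_all[bi, , drop = FALSE] else ytr_all[bi]
        fw <- nn_forward(params, Xb, geom, masks = masks, keep_cache = TRUE)
        lg <- loss_and_grad(fw$logits, yb, head)
        grads <- nn_backward(params, geom, fw$cache, lg$dlogits)
        st <- adam_step(params, grads, state, lr)
        params <- st$params; state <- st$state
        ep_losses <- c(ep_losses, lg$loss)
      }
    })
    vw <- nn_forward(params, Xva, geom)
    vl <- loss_and_grad(vw$logits, yva, head)$loss
    va_acc <- if (head$kind != "regression") {
      dec <- decide_class(head_output(vw$logits, head), head)
      truth <- model_truth(va$manifest$label, head, dataset$config$k)
      mean(dec == truth)
    } else NA_real_
    hist[[ep]] <- tibble(epoch = ep, train_loss = mean(ep_losses),
                         val_loss = vl, val_accuracy = va_acc, lr = lr)
    # accuracy snapshots keep the latest epoch achieving the best accuracy
    improved <- if (use_acc) va_acc >= best$acc - 1e-12 else vl < best$loss - 1e-8
    if (improved) best <- list(loss = vl, acc = va_acc, params = params)
    if (vl < best_loss - 1e-8) {
      best_loss <- vl
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
      if (since_improve >= cfg$scheduler_patience) {
        lr <- lr * cfg$scheduler_factor
        since_improve <- 0L
      }
    }
  }
  model$params <- best$params
  model$history <- bind_rows(hist)
  model
}
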