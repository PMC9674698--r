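# Low-level convolutional network engine.
#
# Feature maps live in a single "pixel-major" dense layout throughout the
# stack: a (H*W*B) x C matrix whose rows index (pixel p fastest, image b
# next) and whose columns are channels. A 3x3 same-padded convolution is
# computed as nine shifted dense matrix products (one per kernel offset)
# against cached row-gather index maps, so all heavy lifting is C-level
# subsetting plus BLAS GEMM on small matrices. This keeps the 3-block net at
# 32x32 fast enough to train on one CPU without a deep-learning framework.

.geom_cache <- new.env(parent = emptyenv())

# kernel offsets, dr fastest; offset o and its spatial inverse 10 - o
.conv_offsets <- expand.grid(dr = -1:1, dc = -1:1)

# Row-gather maps for the nine 3x3 offsets on an H x W grid with B images:
# entry r = p + HW*(b-1) of map o points at the padded-source row holding
# pixel (r+dr, c+dc) of the same image, or at the all-zero pad row HW*B + 1.
shift_maps <- function(H, W, B) {
  key <- paste("shift", H, W, B, sep = "_")
  if (!is.null(.geom_cache[[key]])) return(.geom_cache[[key]])
  HW <- H * W
  r <- rep(seq_len(H), times = W)
  cc <- rep(seq_len(W), each = H)
  pad_row <- HW * B + 1L
  maps <- lapply(seq_len(9L), function(o) {
    rs <- r + .conv_offsets$dr[o]
    cs <- cc + .conv_offsets$dc[o]
    ok <- rs >= 1L & rs <= H & cs >= 1L & cs <= W
    q <- ifelse(ok, rs + (cs - 1L) * H, NA_integer_)
    m <- outer(q, HW * (seq_len(B) - 1L), `+`)
    m[is.na(m)] <- pad_row
    as.integer(m)
  })
  .geom_cache[[key]] <- maps
  maps
}

# 2x2 average pooling source-row maps: four (HWo*B)-long gathers.
pool_maps <- function(H, W, B) {
  key <- paste("pool", H, W, B, sep = "_")
  if (!is.null(.geom_cache[[key]])) return(.geom_cache[[key]])
  Ho <- H %/% 2L; Wo <- W %/% 2L
  HW <- H * W
  ro <- rep(seq_len(Ho), times = Wo)
  co <- rep(seq_len(Wo), each = Ho)
  maps <- list()
  i <- 1L
  for (dc in 0:1) for (dr in 0:1) {
    q <- (2L * ro - 1L + dr) + (2L * co - 2L + dc) * H
    maps[[i]] <- as.integer(outer(q, HW * (seq_len(B) - 1L), `+`))
    i <- i + 1L
  }
  .geom_cache[[key]] <- maps
  maps
}

# rows of the (9*Cin x Cout) weight matrix belonging to kernel offset o
offset_rows <- function(o, Cin) o + 9L * (seq_len(Cin) - 1L)

# He-initialised parameters for the conv stack + head.
nn_init <- function(input_size, channels, head, seed) {
  withr::with_seed(seed, {
    Cin <- 1L
    conv <- vector("list", length(channels))
    for (l in seq_along(channels)) {
      Cout <- channels[l]
      fan_in <- 9L * Cin
      conv[[l]] <- list(
        W = matrix(rnorm(fan_in * Cout, sd = sqrt(2 / fan_in)), fan_in, Cout),
        b = numeric(Cout))
      Cin <- Cout
    }
    nfeat <- channels[length(channels)]
    out_w <- head_width(head)
    if (head$kind == "ordinal") {
      # CORAL head: one shared weight vector, k - 1 rank-specific biases
      hw <- list(W = matrix(rnorm(nfeat, sd = sqrt(1 / nfeat)), nfeat, 1L),
                 b = numeric(out_w))
    } else {
      hw <- list(W = matrix(rnorm(nfeat * out_w, sd = sqrt(1 / nfeat)), nfeat, out_w),
                 b = numeric(out_w))
    }
    list(conv = conv, head = hw)
  })
}

# Channel dropout masks: one B x Cout 0/1 matrix per conv block, drawn from
# the current RNG state. Whole channels are kept/zeroed per image.
make_dropout_masks <- function(channels, B, rate) {
  lapply(channels, function(C) {
    matrix(rbinom(B * C, 1L, 1 - rate), B, C)
  })
}

# append one all-zero pad row (target of out-of-frame gathers)
pad_rows <- function(M) rbind(M, 0)

conv_block_forward <- function(X_m, Wmat, bvec, H, W, B, Cin, Cout) {
  HW <- H * W
  sm <- shift_maps(H, W, B)
  Xp <- pad_rows(X_m)
  Z <- matrix(rep(bvec, each = HW * B), HW * B, Cout)
  for (o in seq_len(9L)) {
    Z <- Z + Xp[sm[[o]], , drop = FALSE] %*%
      Wmat[offset_rows(o, Cin), , drop = FALSE]
  }
  Z
}

# Forward pass. `masks` NULL means dropout layers act as identity (the
# dropout-disabled evaluation mode). With masks, inverted dropout scaling
# 1/(1 - rate) keeps activations unbiased, so rate 0 is exactly identity.
nn_forward <- function(params, X, geom, masks = NULL, keep_cache = FALSE) {
  rate <- geom$rate %||% 0
  B <- nrow(X)
  H <- geom$input_size; W <- geom$input_size
  # B x HW image rows -> pixel-major (HW*B) x 1
  Fcur <- matrix(t(X), ncol = 1L)
  Cin <- 1L
  cache <- if (keep_cache) list(blocks = vector("list", length(params$conv)))
  for (l in seq_along(params$conv)) {
    Cout <- geom$channels[l]
    Z <- conv_block_forward(Fcur, params$conv[[l]]$W, params$conv[[l]]$b,
                            H, W, B, Cin, Cout)
    relu_mask <- Z > 0
    A <- Z * relu_mask
    pm <- pool_maps(H, W, B)
    Fp <- 0.25 * (A[pm[[1]], , drop = FALSE] + A[pm[[2]], , drop = FALSE] +
                  A[pm[[3]], , drop = FALSE] + A[pm[[4]], , drop = FALSE])
    if (!is.null(masks)) {
      HWo <- (H %/% 2L) * (W %/% 2L)
      Fp <- Fp * masks[[l]][rep(seq_len(B), each = HWo), , drop = FALSE] /
        (1 - rate)
    }
    if (keep_cache) {
      cache$blocks[[l]] <- list(X_m = Fcur, relu_mask = relu_mask,
                                H = H, W = W, Cin = Cin, Cout = Cout,
                                mask = if (!is.null(masks)) masks[[l]])
    }
    Fcur <- Fp
    H <- H %/% 2L; W <- W %/% 2L
    Cin <- Cout
  }
  # global average pooling over the final H x W map of each channel
  HW <- H * W
  feat <- matrix(.colMeans(Fcur, HW, B * Cin), B, Cin)
  hp <- params$head
  if (geom$head$kind == "ordinal") {
    logits <- matrix(feat %*% hp$W, B, length(hp$b)) +
      rep(hp$b, each = B)
  } else {
    logits <- feat %*% hp$W + rep(hp$b, each = B)
  }
  if (keep_cache) {
    cache$feat <- feat
    cache$final_HW <- HW
    cache$B <- B
  }
  list(logits = logits, cache = cache)
}

# Backward pass from dL/dlogits; returns gradients with the params structure.
# The image-gradient of the first block is never needed and is skipped.
nn_backward <- function(params, geom, cache, dlogits) {
  B <- cache$B
  feat <- cache$feat
  hp <- params$head
  if (geom$head$kind == "ordinal") {
    drow <- rowSums(dlogits)
    gW <- t(feat) %*% drow
    gb <- colSums(dlogits)
    dfeat <- drow %o% drop(hp$W)
  } else {
    gW <- t(feat) %*% dlogits
    gb <- colSums(dlogits)
    dfeat <- dlogits %*% t(hp$W)
  }
  grads <- list(conv = vector("list", length(params$conv)),
                head = list(W = gW, b = gb))
  HW <- cache$final_HW
  rate <- geom$rate %||% 0
  dF <- dfeat[rep(seq_len(B), each = HW), , drop = FALSE] / HW
  for (l in rev(seq_along(params$conv))) {
    bl <- cache$blocks[[l]]
    HWo <- (bl$H %/% 2L) * (bl$W %/% 2L)
    if (!is.null(bl$mask)) {
      dF <- dF * bl$mask[rep(seq_len(B), each = HWo), , drop = FALSE] /
        (1 - rate)
    }
    # average-pool backward: each source pixel receives dF/4
    pm <- pool_maps(bl$H, bl$W, B)
    dA <- matrix(0, bl$H * bl$W * B, bl$Cout)
    for (i in 1:4) dA[pm[[i]], ] <- 0.25 * dF
    dZ <- dA * bl$relu_mask
    sm <- shift_maps(bl$H, bl$W, B)
    Xp <- pad_rows(bl$X_m)
    W <- params$conv[[l]]$W
    gWl <- matrix(0, nrow(W), ncol(W))
    need_dX <- l > 1L
    dXl <- if (need_dX) matrix(0, bl$H * bl$W * B, bl$Cin)
    for (o in seq_len(9L)) {
      rows <- offset_rows(o, bl$Cin)
      Xs <- Xp[sm[[o]], , drop = FALSE]
      gWl[rows, ] <- crossprod(Xs, dZ)
      if (need_dX) {
        # out pixel r read source sm_o[r]; so source q receives the
        # contribution of out pixel sm_{-o}[q] (pad rows contribute zero)
        Gp <- pad_rows(dZ %*% t(W[rows, , drop = FALSE]))
        dXl <- dXl + Gp[sm[[10L - o]], , drop = FALSE]
      }
    }
    grads$conv[[l]] <- list(W = gWl, b = colSums(dZ))
    if (need_dX) dF <- dXl
  }
  grads
}

# ---- Adam optimiser on the nested parameter list ----

adam_init <- function(params) {
  zero_like <- function(p) rapply(p, function(x) x * 0, how = "replace")
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  for (l in seq_along(params$conv)) {
    for (nm in c("W", "b")) {
      r <- upd(params$conv[[l]][[nm]], as.matrix(grads$conv[[l]][[nm]]),
               state$m$conv[[l]][[nm]], state$v$conv[[l]][[nm]])
      params$conv[[l]][[nm]] <- r$p
      state$m$conv[[l]][[nm]] <- r$m
      state$v$conv[[l]][[nm]] <- r$v
    }
  }
  for (nm in c("W", "b")) {
    r <- upd(params$head[[nm]], as.matrix(grads$head[[nm]]),
             state$m$head[[nm]], state$v$head[[nm]])
    params$head[[nm]] <- r$p
    state$m$head[[nm]] <- r$m
    state$v$head[[nm]] <- r$v
  }
  list(params = params, state = state)
}
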