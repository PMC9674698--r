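# Synthetic ordinal-severity test-retest image generator.
#
# Each synthetic patient has one continuous latent disease severity s in
# [0, k - 1]. A patient's anatomy is rendered once as a grayscale image whose
# lesion burden (blob count, blob contrast, diffuse haze) increases with s;
# the >= 2 views of that patient are re-acquisitions of the same anatomy
# under benign jitter (flip / small rotation / translation / lighting /
# sensor noise). Labels are the nearest-integer bin of s plus Gaussian
# boundary noise, emulating inter-rater disagreement concentrated at class
# boundaries.

#' Acquisition jitter specification
#'
#' Describes the benign acquisition differences between same-visit views.
#' All bounds are intentionally within the training augmentation family
#' (rotation at most +/- 15 degrees, horizontal flips), so a robust model
#' should be repeatable under them.
#'
#' @param flip_prob Probability of a horizontal flip per view.
#' @param rotation_deg Rotation drawn uniformly from `[-rotation_deg, rotation_deg]`
#'   (degrees, must be <= 15).
#' @param translate_px Integer translation drawn uniformly from
#'   `[-translate_px, translate_px]` in each axis.
#' @param brightness Additive lighting offset drawn uniformly from
#'   `[-brightness, brightness]` (intensity units on a 0-1 scale).
#' @param noise_sd Per-pixel Gaussian sensor noise standard deviation.
#' @return A `jitter_spec` list.
#' @export
jitter_spec <- function(flip_prob = 0.5, rotation_deg = 10, translate_px = 2,
                        brightness = 0.05, noise_sd = 0.02) {
  if (rotation_deg < 0 || rotation_deg > 15) {
    abort("rotation_deg must lie in [0, 15] (the training augmentation bound).")
  }
  if (flip_prob < 0 || flip_prob > 1) abort("flip_prob must be in [0, 1].")
  if (translate_px < 0 || brightness < 0 || noise_sd < 0) {
    abort("translate_px, brightness and noise_sd must be >= 0.")
  }
  structure(list(flip_prob = flip_prob, rotation_deg = rotation_deg,
                 translate_px = translate_px, brightness = brightness,
                 noise_sd = noise_sd),
            class = "jitter_spec")
}

#' Synthetic dataset configuration
#'
#' @param n_patients Number of synthetic patients.
#' @param k Number of ordinal severity classes.
#' @param class_probs Length-`k` class prior (sums to 1).
#' @param images_per_patient Number of same-visit views per patient (>= 2).
#' @param image_size Square image side in pixels.
#' @param boundary_noise_sd Standard deviation of the Gaussian label noise
#'   added to the latent severity before binning (severity units); 0 gives
#'   exact binning.
#' @param jitter A [jitter_spec()].
#' @param domain_shift If `TRUE`, retest views (view index >= 2) additionally
#'   receive an out-of-training-family transform (25 degree rotation and a
#'   +0.15 lighting offset), emulating evaluation on an unseen view.
#' @param flip_retest_mode If `TRUE`, each patient's views are the rendered
#'   image and its exact horizontal mirror, with no other jitter (the
#'   flip-retest emulation used when only one image per visit exists).
#' @param split_fractions Named train/val/test patient fractions.
#' @param seed Base seed; the full dataset is a pure function of the config.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_patients = 300L, k = 3L,
                         class_probs = rep(1 / k, k),
                         images_per_patient = 2L, image_size = 32L,
                         boundary_noise_sd = 0.25,
                         jitter = jitter_spec(),
                         domain_shift = FALSE, flip_retest_mode = FALSE,
                         split_fractions = c(train = 0.6, val = 0.1, test = 0.3),
                         seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) abort("k must be >= 2.")
  if (length(class_probs) != k || any(class_probs < 0) ||
      abs(sum(class_probs) - 1) > 1e-8) {
    abort("class_probs must be a length-k simplex vector.")
  }
  if (images_per_patient < 2L) abort("images_per_patient must be >= 2.")
  if (boundary_noise_sd < 0) abort("boundary_noise_sd must be >= 0.")
  if (!inherits(jitter, "jitter_spec")) abort("jitter must be a jitter_spec().")
  if (!setequal(names(split_fractions), c("train", "val", "test")) ||
      abs(sum(split_fractions) - 1) > 1e-8) {
    abort("split_fractions must be named train/val/test and sum to 1.")
  }
  structure(list(n_patients = as.integer(n_patients), k = k,
                 class_probs = as.numeric(class_probs),
                 images_per_patient = as.integer(images_per_patient),
                 image_size = as.integer(image_size),
                 boundary_noise_sd = boundary_noise_sd, jitter = jitter,
                 domain_shift = isTRUE(domain_shift),
                 flip_retest_mode = isTRUE(flip_retest_mode),
                 split_fractions = split_fractions[c("train", "val", "test")],
                 seed = as.integer(seed)),
            class = "synth_config")
}

# cached separable Gaussian blur kernel matrix (rows normalised)
blur_matrix <- function(n, sigma = 2) {
  key <- paste("blur", n, sigma, sep = "_")
  if (!is.null(.geom_cache[[key]])) return(.geom_cache[[key]])
  K <- outer(seq_len(n), seq_len(n), function(i, j) exp(-(i - j)^2 / (2 * sigma^2)))
  K <- K / rowSums(K)
  .geom_cache[[key]] <- K
  K
}

#' Render a synthetic severity image
#'
#' Renders one patient's anatomy at latent severity `s` as a grayscale image
#' in `[0, 1]`. Severity enters through three strictly increasing channels:
#' the lesion blob count `round(3 s)`, the blob contrast `0.30 + 0.12 s`, and
#' a faint diffuse central haze of amplitude `0.10 s`. At `s = 0` the image
#' is lesion-free background texture. Deterministic given `seed`.
#'
#' @param s Latent severity, `s >= 0` (in class-index units, `[0, k - 1]`).
#' @param image_size Square image side in pixels.
#' @param seed Integer seed for the patient's anatomy.
#' @return An `image_size` x `image_size` numeric matrix in `[0, 1]`.
#' @export
render_severity <- function(s, image_size = 32L, seed = 1L) {
  if (s < 0) abort("latent severity must be >= 0.")
  n <- as.integer(image_size)
  withr::with_seed(seed, {
    K <- blur_matrix(n, sigma = 2)
    tex <- K %*% matrix(rnorm(n * n), n, n) %*% t(K)
    tex <- tex / max(sd(tex), 1e-12) * 0.04
    img <- 0.12 + tex
    ctr <- (n + 1) / 2
    gx <- matrix(rep(seq_len(n), n), n, n)        # row coordinate
    gy <- t(gx)                                   # column coordinate
    if (s > 0) {
      img <- img + 0.10 * s *
        exp(-((gx - ctr)^2 + (gy - ctr)^2) / (2 * (n / 3)^2))
      n_blobs <- as.integer(floor(3 * s + 0.5))
      for (b in seq_len(n_blobs)) {
        cx <- runif(1, 0.18 * n, 0.82 * n)
        cy <- runif(1, 0.18 * n, 0.82 * n)
        sb <- runif(1, 1.3, 2.8)
        amp <- 0.30 + 0.12 * s + runif(1, -0.04, 0.04)
        img <- img + amp * exp(-((gx - cx)^2 + (gy - cy)^2) / (2 * sb^2))
      }
    }
    pmin(pmax(img, 0), 1)
  })
}

#' Affine view transform with bilinear resampling
#'
#' Applies (in this order) a horizontal flip, a rotation about the image
#' centre, an integer translation and an additive brightness offset, sampling
#' bilinearly and filling out-of-frame pixels with the image median. This is
#' the primitive behind both acquisition jitter and training augmentation.
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param angle_deg Rotation angle in degrees (counter-clockwise).
#' @param dx,dy Translation in pixels (columns, rows).
#' @param flip Logical, horizontal flip.
#' @param brightness Additive intensity offset.
#' @param fill Out-of-frame fill value; defaults to `median(img)`.
#' @return Transformed matrix, clipped to `[0, 1]`.
#' @export
affine_transform <- function(img, angle_deg = 0, dx = 0, dy = 0, flip = FALSE,
                             brightness = 0, fill = NULL) {
  H <- nrow(img); W <- ncol(img)
  if (is.null(fill)) fill <- median(img)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  r <- rep(seq_len(H), times = W)
  cc <- rep(seq_len(W), each = H)
  x <- cc - cx - dx
  y <- r - cy - dy
  th <- angle_deg * pi / 180
  xs <- cos(th) * x + sin(th) * y
  ys <- -sin(th) * x + cos(th) * y
  if (flip) xs <- -xs
  sc <- xs + cx
  sr <- ys + cy
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  val <- numeric(H * W)
  pick <- function(ri, ci) {
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    out <- rep(fill, length(ri))
    out[ok] <- img[cbind(ri[ok], ci[ok])]
    out
  }
  val <- (1 - fr) * (1 - fc) * pick(r0, c0) +
         (1 - fr) * fc       * pick(r0, c0 + 1) +
         fr       * (1 - fc) * pick(r0 + 1, c0) +
         fr       * fc       * pick(r0 + 1, c0 + 1)
  out <- matrix(val, H, W)
  pmin(pmax(out + brightness, 0), 1)
}

hflip <- function(img) img[, rev(seq_len(ncol(img))), drop = FALSE]

#' Bin a latent severity into a noisy ordinal label
#'
#' The label is the nearest-integer bin of `s + eps` with
#' `eps ~ Normal(0, boundary_noise_sd)`, clipped to `0..k-1`. With
#' `boundary_noise_sd = 0` this is exact binning; otherwise the probability
#' of a flipped label decays with the distance of `s` from the nearest class
#' boundary (half-integers), concentrating label noise at the boundaries.
#'
#' @param s Latent severity value(s).
#' @param k Number of classes.
#' @param boundary_noise_sd Label noise standard deviation (severity units).
#' @param seed Integer seed.
#' @return Integer label(s) in `0..k-1`.
#' @export
assign_label <- function(s, k, boundary_noise_sd = 0, seed = 1L) {
  withr::with_seed(seed, {
    eps <- rnorm(length(s), 0, boundary_noise_sd)
    pmin(pmax(as.integer(floor(s + eps + 0.5)), 0L), k - 1L)
  })
}

# Largest-remainder stratified patient split, per label class.
stratified_split <- function(labels, fractions, seed) {
  n <- length(labels)
  split <- character(n)
  withr::with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- sample(which(labels == cl))
      m <- length(idx)
      exact <- fractions * m
      base <- floor(exact)
      rem <- m - sum(base)
      if (rem > 0) {
        order_frac <- order(exact - base, decreasing = TRUE)
        base[order_frac[seq_len(rem)]] <- base[order_frac[seq_len(rem)]] + 1
      }
      split[idx] <- rep(names(fractions), times = base)
    }
  })
  split
}

#' Generate a synthetic test-retest dataset
#'
#' Draws one latent severity per patient to match `class_probs` (a class is
#' drawn from the prior, then `s` uniformly within that class's unit bin),
#' assigns a boundary-noisy label, renders the patient's anatomy once, and
#' acquires `images_per_patient` jittered views. Patients are split into
#' train/val/test strata preserving the label distribution to within one
#' patient per class. The whole dataset is a deterministic function of the
#' config (including its seed).
#'
#' @param cfg A [synth_config()].
#' @return A `synth_dataset`: list with `images` (one flattened image per
#'   row, pixels column-major), `image_dim`, `manifest` (tibble with
#'   `patient_id`, `image_id`, `view_index`, `split`, `label`, `latent_s`)
#'   and `config`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- cfg$n_patients; k <- cfg$k; m <- cfg$images_per_patient
  sz <- cfg$image_size; jt <- cfg$jitter
  withr::with_seed(derive_seed(cfg$seed, "classes"), {
    cls <- sample.int(k, n, replace = TRUE, prob = cfg$class_probs) - 1L
    s <- pmin(pmax(runif(n, cls - 0.5, cls + 0.5), 0), k - 1)
  })
  labels <- assign_label(s, k, cfg$boundary_noise_sd,
                         seed = derive_seed(cfg$seed, "labels"))
  images <- matrix(0, n * m, sz * sz)
  pid <- sprintf("P%04d", seq_len(n))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    base <- render_severity(s[i], sz, seed = derive_seed(cfg$seed, "render", i))
    views <- vector("list", m)
    if (cfg$flip_retest_mode) {
      for (v in seq_len(m)) views[[v]] <- if (v %% 2L == 1L) base else hflip(base)
    } else {
      for (v in seq_len(m)) {
        views[[v]] <- withr::with_seed(derive_seed(cfg$seed, "view", i, v), {
          ang <- runif(1, -jt$rotation_deg, jt$rotation_deg)
          dx <- sample(seq(-jt$translate_px, jt$translate_px), 1)
          dy <- sample(seq(-jt$translate_px, jt$translate_px), 1)
          fl <- runif(1) < jt$flip_prob
          br <- runif(1, -jt$brightness, jt$brightness)
          if (cfg$domain_shift && v >= 2L) {
            # unseen-view emulation: parameters outside the training family
            ang <- ang + 25
            br <- br + 0.15
          }
          vimg <- affine_transform(base, ang, dx, dy, fl, br)
          if (jt$noise_sd > 0) {
            vimg <- pmin(pmax(vimg + matrix(rnorm(sz * sz, 0, jt$noise_sd),
                                            sz, sz), 0), 1)
          }
          vimg
        })
      }
    }
    for (v in seq_len(m)) images[(i - 1L) * m + v, ] <- as.vector(views[[v]])
    rows[[i]] <- tibble(patient_id = pid[i],
                        image_id = sprintf("%s_V%d", pid[i], seq_len(m)),
                        view_index = seq_len(m),
                        label = labels[i], latent_s = s[i])
  }
  manifest <- bind_rows(rows)
  split <- stratified_split(labels, cfg$split_fractions,
                            seed = derive_seed(cfg$seed, "split"))
  manifest$split <- rep(split, each = m)
  manifest <- manifest[, c("patient_id", "image_id", "view_index",
                           "split", "label", "latent_s")]
  structure(list(images = images, image_dim = c(sz, sz),
                 manifest = manifest, config = cfg),
            class = "synth_dataset")
}

#' @exportS3Method base::print
print.synth_dataset <- function(x, ...) {
  cat(sprintf("<synth_dataset> %d patients x %d views, k = %d, %dx%d px\n",
              x$config$n_patients, x$config$images_per_patient, x$config$k,
              x$image_dim[1], x$image_dim[2]))
  print(table(split = x$manifest$split[x$manifest$view_index == 1],
              label = x$manifest$label[x$manifest$view_index == 1]))
  invisible(x)
}

# subset helper: images + manifest of one split
dataset_split <- function(ds, split) {
  idx <- which(ds$manifest$split == split)
  list(images = ds$images[idx, , drop = FALSE],
       manifest = ds$manifest[idx, , drop = FALSE])
}

#' Write a synthetic dataset to disk (PNG images + CSV manifest + YAML config)
#'
#' @param ds A `synth_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synth_dataset"))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(ds$images))) {
    img <- matrix(ds$images[i, ], ds$image_dim[1], ds$image_dim[2])
    png::writePNG(img, file.path(dir, "images",
                                 paste0(ds$manifest$image_id[i], ".png")))
  }
  readr::write_csv(ds$manifest, file.path(dir, "manifest.csv"))
  cfg <- ds$config
  cfg_list <- unclass(cfg)
  cfg_list$jitter <- unclass(cfg_list$jitter)
  cfg_list$split_fractions <- as.list(cfg_list$split_fractions)
  yaml::write_yaml(cfg_list, file.path(dir, "config.yaml"),
                   precision = 15)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing `images/`, `manifest.csv`, `config.yaml`.
#' @return A `synth_dataset`.
#' @export
read_dataset <- function(dir) {
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"),
                              show_col_types = FALSE)
  cfg_list <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg <- synth_config(
    n_patients = cfg_list$n_patients, k = cfg_list$k,
    class_probs = unlist(cfg_list$class_probs),
    images_per_patient = cfg_list$images_per_patient,
    image_size = cfg_list$image_size,
    boundary_noise_sd = cfg_list$boundary_noise_sd,
    jitter = do.call(jitter_spec, cfg_list$jitter),
    domain_shift = cfg_list$domain_shift,
    flip_retest_mode = cfg_list$flip_retest_mode,
    split_fractions = unlist(cfg_list$split_fractions),
    seed = cfg_list$seed)
  sz <- cfg$image_size
  images <- matrix(0, nrow(manifest), sz * sz)
  for (i in seq_len(nrow(manifest))) {
    img <- png::readPNG(file.path(dir, "images",
                                  paste0(manifest$image_id[i], ".png")))
    if (length(dim(img)) == 3L) img <- img[, , 1]
    images[i, ] <- as.vector(img)
  }
  structure(list(images = images, image_dim = c(sz, sz),
                 manifest = as_tibble(manifest), config = cfg),
            class = "synth_dataset")
}
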