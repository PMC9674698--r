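test_that("rendering is deterministic and lesion-free at zero severity", {
  img1 <- render_severity(1.3, 32, seed = 5)
  img2 <- render_severity(1.3, 32, seed = 5)
  expect_identical(img1, img2)
  expect_false(identical(img1, render_severity(1.3, 32, seed = 6)))
  # s = 0: pure background texture, no central haze or blobs
  img0 <- render_severity(0, 32, seed = 5)
  expect_lt(max(img0), 0.5)
  expect_lt(sd(img0), 0.06)
})

test_that("mean lesion signal is monotone in the latent severity", {
  means <- sapply(c(0, 1, 2), function(s) {
    mean(sapply(1:200, function(i) mean(render_severity(s, 32, seed = i))))
  })
  expect_true(all(diff(means) > 0))
  # blob contrast: high-intensity pixel mass grows with s
  burden <- sapply(c(0, 1, 2), function(s) {
    mean(sapply(1:200, function(i) mean(render_severity(s, 32, seed = i) > 0.3)))
  })
  expect_true(all(diff(burden) > 0))
})

test_that("label assignment bins the latent severity with boundary noise", {
  expect_equal(assign_label(1.4, 3, 0, seed = 1), 1L)
  expect_equal(assign_label(c(0.2, 0.6, 1.6), 3, 0, seed = 1), c(0L, 1L, 2L))
  # exactly on a boundary: each side with probability ~ 1/2
  labs <- assign_label(rep(0.5, 10000), 3, 0.25, seed = 9)
  expect_lt(abs(mean(labs == 1L) - 0.5), 0.02)
  # flip probability decays with distance like the Gaussian tail
  flip_at <- function(d) {
    labs <- assign_label(rep(1 - 0.5 - d, 8000), 3, 0.25, seed = 33)
    mean(labs != 0L)
  }
  for (d in c(0.1, 0.25, 0.4)) {
    expect_lt(abs(flip_at(d) - pnorm(-d / 0.25)), 0.02)
  }
})

test_that("affine jitter primitive is exact on pure flips and translations", {
  withr::with_seed(2, img <- matrix(runif(64), 8, 8))
  expect_equal(affine_transform(img, flip = TRUE),
               img[, 8:1], tolerance = 1e-12)
  tr <- affine_transform(img, dx = 1, dy = 0)
  expect_equal(tr[, 2:8], img[, 1:7], tolerance = 1e-12)
  # rotation bound enforcement lives in the jitter spec
  expect_error(jitter_spec(rotation_deg = 20), "15")
})

test_that("generated datasets are seeded, stratified and class-balanced", {
  cfg <- tiny_config(seed = 7, n_patients = 99, boundary_noise_sd = 0)
  ds <- generate_dataset(cfg)
  ds2 <- generate_dataset(cfg)
  expect_identical(ds$images, ds2$images)
  expect_identical(ds$manifest, ds2$manifest)
  pat <- ds$manifest[ds$manifest$view_index == 1, ]
  # exact binning + uniform class prior: counts inside a 3.5-sigma band
  for (cl in 0:2) {
    expect_lt(abs(sum(pat$label == cl) - 33), 3.5 * sqrt(99 * (1 / 3) * (2 / 3)))
  }
  # stratified split: class proportions preserved to within one patient
  tab <- table(pat$split, pat$label)
  for (cl in 1:3) {
    expect_lte(max(abs(tab[, cl] - sum(tab[, cl]) *
                         cfg$split_fractions[rownames(tab)])), 1)
  }
  # no patient appears in two splits
  expect_equal(anyDuplicated(unique(ds$manifest[, c("patient_id", "split")])$patient_id), 0)
})

test_that("zero jitter yields pixel-identical views; flip-retest mirrors", {
  cfg0 <- tiny_config(seed = 4, n_patients = 10,
                      jitter = jitter_spec(flip_prob = 0, rotation_deg = 0,
                                           translate_px = 0, brightness = 0,
                                           noise_sd = 0))
  ds0 <- generate_dataset(cfg0)
  expect_equal(ds0$images[seq(1, 20, 2), ], ds0$images[seq(2, 20, 2), ])
  cfgf <- tiny_config(seed = 4, n_patients = 6, flip_retest_mode = TRUE)
  dsf <- generate_dataset(cfgf)
  for (i in seq(1, 12, 2)) {
    v1 <- matrix(dsf$images[i, ], 32, 32)
    v2 <- matrix(dsf$images[i + 1, ], 32, 32)
    expect_identical(v2, v1[, 32:1])
  }
})

test_that("domain-shift mode perturbs only the retest views, beyond jitter", {
  base <- tiny_config(seed = 12, n_patients = 8)
  shifted <- tiny_config(seed = 12, n_patients = 8, domain_shift = TRUE)
  ds_a <- generate_dataset(base)
  ds_b <- generate_dataset(shifted)
  first_views <- seq(1, 16, 2)
  expect_identical(ds_a$images[first_views, ], ds_b$images[first_views, ])
  retest <- first_views + 1
  expect_false(any(rowSums(abs(ds_a$images[retest, ] -
                                 ds_b$images[retest, ])) < 1))
  # the shift is brighter on average (out-of-family lighting offset)
  expect_gt(mean(ds_b$images[retest, ]) - mean(ds_a$images[retest, ]), 0.05)
})

test_that("datasets round-trip through PNG + CSV + YAML", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(tiny_config(seed = 2, n_patients = 6))
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(back$manifest, ds$manifest)
  expect_equal(back$config$k, ds$config$k)
  expect_equal(back$config$jitter$rotation_deg, ds$config$jitter$rotation_deg)
  # 8-bit PNG quantization
  expect_lt(max(abs(back$images - ds$images)), 1 / 254)
})
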