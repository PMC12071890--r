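test_that("untrained network predicts the identity transform at any size", {
  mod <- build_network(network_spec(levels = 2, base_channels = 8), seed = 1)
  for (sh in list(c(16, 16, 16), c(32, 32, 16))) {
    v <- rand_volume(3, shape = sh, spacing = c(4, 4, 4), mean = -200, sd = 300)
    pr <- predict_sct(v, mod)
    expect_equal(dim(pr$dvf$field), c(sh, 3))
    expect_true(all(pr$dvf$field == 0))
    expect_equal(pr$sct$data, v$data, tolerance = 1e-12)
  }
  # spatial dims not divisible by 2^levels: error names the axis
  bad <- rand_volume(4, shape = c(18, 16, 16))
  expect_error(predict_sct(bad, mod), "axis x")
})

test_that("parameter count grows with the initial channel count", {
  n8 <- length(build_network(network_spec(levels = 2, base_channels = 8))$theta)
  n16 <- length(build_network(network_spec(levels = 2, base_channels = 16))$theta)
  n32 <- length(build_network(network_spec(levels = 2, base_channels = 32))$theta)
  expect_lt(n8, n16); expect_lt(n16, n32)
})

test_that("warping: zero field identity, integer-shift oracle, binary masks", {
  v <- rand_volume(5, shape = c(12, 10, 8), spacing = c(2, 2, 2))
  zero <- dvf_field(array(0, dim = c(12, 10, 8, 3)), c(2, 2, 2))
  expect_identical(warp_volume(v, zero, "nearest")$data, v$data)
  expect_lt(max(abs(warp_volume(v, zero)$data - v$data)), 1e-6)
  # constant integer-voxel shifts against a brute-force index-shift oracle
  for (shift_vox in list(c(2, 0, 0), c(0, -1, 0), c(1, 2, -1))) {
    u <- array(0, dim = c(12, 10, 8, 3))
    for (d in 1:3) u[, , , d] <- shift_vox[d] * 2  # mm = voxels * spacing
    w <- warp_volume(v, dvf_field(u, c(2, 2, 2)), "nearest")$data
    ix <- seq_len(12 - abs(shift_vox[1])); iy <- seq_len(10 - abs(shift_vox[2]))
    iz <- seq_len(8 - abs(shift_vox[3]))
    if (shift_vox[1] < 0) ix <- ix + abs(shift_vox[1])
    if (shift_vox[2] < 0) iy <- iy + abs(shift_vox[2])
    if (shift_vox[3] < 0) iz <- iz + abs(shift_vox[3])
    expect_identical(w[ix, iy, iz],
                     v$data[ix + shift_vox[1], iy + shift_vox[2], iz + shift_vox[3]],
                     info = paste(shift_vox, collapse = ","))
  }
  # nearest-neighbor warping keeps masks binary
  m <- array(as.double(v$data > 0), dim = c(12, 10, 8))
  u <- array(1.3, dim = c(12, 10, 8, 3))
  wm <- warp_volume(image_volume(m, c(2, 2, 2)), dvf_field(u, c(2, 2, 2)),
                    "nearest")$data
  expect_true(all(wm %in% c(0, 1)))
  expect_error(warp_volume(v, dvf_field(array(0, dim = c(6, 6, 6, 3)), c(2, 2, 2))),
               "grid")
})

test_that("SSIM: identity, anticorrelation, noise monotonicity", {
  spec <- phantom_spec(grid_shape = c(24, 24, 12), spacing_mm = c(10, 10, 12),
                       noise_sd = 0)
  ph <- make_thorax_phantom(spec)
  expect_equal(ssim_volume(ph$volume, ph$volume), 1, tolerance = 1e-12)
  # binary-contrast phantom against its inversion on the [0,1] scale
  b <- image_volume(array(as.double(ph$masks$body), dim = c(24, 24, 12)))
  inv <- image_volume(1 - b$data)
  expect_lt(ssim_volume(b, inv, normalize = FALSE), 0)
  set.seed(6)
  ss <- sapply(c(0, 0.05, 0.1), function(s) {
    noisy <- image_volume(hu_norm_for_test(ph$volume$data) +
                            array(rnorm(prod(dim(b$data)), 0, s),
                                  dim = dim(b$data)))
    ssim_volume(image_volume(hu_norm_for_test(ph$volume$data)), noisy,
                normalize = FALSE)
  })
  expect_true(all(diff(ss) < 0))
  expect_error(ssim_volume(b, inv, window = 30), "window larger")
})

test_that("loss: zero at perfect identity, additive parts, quadratic regularizer", {
  spec <- phantom_spec(grid_shape = c(16, 16, 8), spacing_mm = c(8, 8, 10),
                       noise_sd = 0)
  ph <- make_thorax_phantom(spec)
  zero <- dvf_field(array(0, dim = c(16, 16, 8, 3)), c(8, 8, 10))
  expect_equal(dvf_loss(ph$volume, ph$volume, zero), 0, tolerance = 1e-12)
  # dvf = 0: R = 0, loss = 1 - ssim(dct, pct)
  other <- make_thorax_phantom(phantom_spec(grid_shape = c(16, 16, 8),
                                            spacing_mm = c(8, 8, 10),
                                            noise_sd = 5, random_seed = 2))
  expect_equal(dvf_loss(ph$volume, other$volume, zero, lambda = 0.5),
               1 - ssim_volume(ph$volume, other$volume), tolerance = 1e-12)
  # doubling a nonzero linear field quadruples R
  u <- array(0, dim = c(16, 16, 8, 3))
  u[, , , 1] <- array(rep(seq(0, 3, length.out = 16), 16 * 8), dim = c(16, 16, 8))
  r1 <- sctselect:::cpp_reg_value(u)
  r2 <- sctselect:::cpp_reg_value(2 * u)
  expect_equal(r2, 4 * r1, tolerance = 1e-12)
  expect_error(dvf_loss(ph$volume, ph$volume, zero, lambda = -1), "non-negative")
})

test_that("training descends, is seed-deterministic, and identity pairs stay put", {
  fx <- recovery_fixture(seed = 31, shape = c(16, 16, 8), spacing = c(16, 16, 20),
                         amp = 4, width = 50)
  pair <- list(list(dct = fx$dct, pct = fx$pct))
  ts <- train_spec(learning_rate = 5e-3, epochs = 40, batch_size = 1)
  losses <- sapply(1:3, function(s) {
    fit <- train_dvfnet(pair, build_network(network_spec(2, 8), seed = s), ts)
    c(first = fit$history[1], last = tail(fit$history, 1))
  })
  expect_true(all(losses["last", ] < losses["first", ]))
  # determinism: identical data + seed, identical loss history
  f1 <- train_dvfnet(pair, build_network(network_spec(2, 8), seed = 1), ts)
  f2 <- train_dvfnet(pair, build_network(network_spec(2, 8), seed = 1), ts)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$theta, f2$theta)
  # identity pairs: no spurious deformation (mean |dvf| < 0.5 mm)
  idp <- list(list(dct = fx$dct, pct = fx$dct))
  fid <- train_dvfnet(idp, build_network(network_spec(2, 8), seed = 1), ts)
  pr <- predict_sct(fx$dct, fid)
  expect_lt(mean(dvf_magnitude(pr$dvf)), 0.5)
})

test_that("trained on curved-to-flat pairs, the synthetic CT beats the diagnostic CT on a held-out case", {
  small_def <- list(n_blobs = 2, amplitude_mm = c(1, 2.5), width_mm = c(25, 45))
  for (seed in 1:3) {
    tr <- lapply(seed * 10 + 1:2, function(s)
      prep_case(make_case(s, deformation = small_def)))
    ho <- prep_case(make_case(seed * 10 + 9, deformation = small_def))
    mod <- build_network(network_spec(levels = 2, base_channels = 8), seed = seed)
    fit <- train_dvfnet(tr, mod, train_spec(learning_rate = 5e-3, epochs = 120,
                                            batch_size = 2))
    pr <- predict_sct(ho$dct, fit)
    expect_lt(mae(pr$sct, ho$pct), mae(ho$dct, ho$pct),
              label = sprintf("held-out MAE, seed %d", seed))
  }
})

test_that("a CTV mask warped by a predicted smooth field stays connected", {
  fx <- recovery_fixture(seed = 41)
  mod <- train_dvfnet(list(list(dct = fx$dct, pct = fx$pct)),
                      build_network(network_spec(2, 8), seed = 1),
                      train_spec(learning_rate = 5e-3, epochs = 60,
                                 batch_size = 1))
  pr <- predict_sct(fx$dct, mod)
  ctv_w <- warp_mask(fx$masks$ctv, pr$dvf, fx$dct$spacing)
  lab <- sctselect:::cpp_label3d(ctv_w)
  expect_equal(max(lab), 1)
  expect_true(all(ctv_w %in% c(TRUE, FALSE)))
})

test_that("model checkpoints round-trip through the text format", {
  mod <- build_network(network_spec(levels = 2, base_channels = 8), seed = 2)
  dir <- tempfile("ckpt")
  save_model(mod, dir)
  back <- load_model(dir)
  expect_equal(back$theta, mod$theta, tolerance = 1e-15)
  expect_equal(back$spec$levels, mod$spec$levels)
  v <- rand_volume(1, shape = c(16, 16, 8))
  expect_identical(predict_sct(v, back)$dvf$field, predict_sct(v, mod)$dvf$field)
})
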