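# shared fixtures and independent oracles

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

hu_norm_for_test <- function(x) {
  array(pmin(pmax((x + 1000) / 2000, 0), 1), dim = dim(x))
}

rand_volume <- function(seed, shape = c(12, 10, 8), spacing = c(2, 2, 3),
                        mean = 0, sd = 100) {
  set.seed(seed)
  image_volume(array(rnorm(prod(shape), mean, sd), dim = shape), spacing)
}

# brute-force cumulative DVH oracle from the sorted voxel dose multiset
oracle_dvh_cum <- function(doses, edges) {
  vapply(edges, function(e) sum(doses >= e) / length(doses), numeric(1))
}

# independent two-pass concordance correlation implementation
oracle_ccc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sx2 <- sum((x - mx)^2) / n; sy2 <- sum((y - my)^2) / n
  sxy <- sum((x - mx) * (y - my)) / n
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

# brute-force voxel-wise gEUD
oracle_geud <- function(doses, n) mean(doses^(1 / n))^n

# numeric Jacobian determinant of x -> x + u(x) at interior voxels
jacobian_dets <- function(dvf) {
  u <- dvf$field; sp <- dvf$spacing
  sh <- dim(u)[1:3]
  ix <- 2:(sh[1] - 1); iy <- 2:(sh[2] - 1); iz <- 2:(sh[3] - 1)
  J <- array(0, dim = c(length(ix), length(iy), length(iz), 3, 3))
  for (d in 1:3) {
    J[, , , d, 1] <- (u[ix + 1, iy, iz, d] - u[ix - 1, iy, iz, d]) / (2 * sp[1])
    J[, , , d, 2] <- (u[ix, iy + 1, iz, d] - u[ix, iy - 1, iz, d]) / (2 * sp[2])
    J[, , , d, 3] <- (u[ix, iy, iz + 1, d] - u[ix, iy, iz - 1, d]) / (2 * sp[3])
  }
  for (d in 1:3) J[, , , d, d] <- J[, , , d, d] + 1
  a <- J[, , , 1, 1]; b <- J[, , , 1, 2]; cc_ <- J[, , , 1, 3]
  d_ <- J[, , , 2, 1]; e <- J[, , , 2, 2]; f <- J[, , , 2, 3]
  g <- J[, , , 3, 1]; h <- J[, , , 3, 2]; i <- J[, , , 3, 3]
  a * (e * i - f * h) - b * (d_ * i - f * g) + cc_ * (d_ * h - e * g)
}

# phantom pair linked by a known single-blob field centred in the body
# (the network parameter-recovery fixture)
recovery_fixture <- function(seed = 11, shape = c(32, 32, 16),
                             spacing = c(8, 8, 10), amp = 5, width = 40) {
  spec0 <- phantom_spec(grid_shape = shape, spacing_mm = spacing,
                        couch_kind = "none", noise_sd = 3, random_seed = seed)
  ph <- make_thorax_phantom(spec0)
  co <- lapply(1:3, function(a) (seq_len(shape[a]) - (shape[a] + 1) / 2) * spacing[a])
  X <- array(rep(co[[1]], shape[2] * shape[3]), dim = shape)
  Y <- array(rep(rep(co[[2]], each = shape[1]), shape[3]), dim = shape)
  Z <- array(rep(co[[3]], each = shape[1] * shape[2]), dim = shape)
  g <- exp(-((X - 10)^2 + (Y + 10)^2 + Z^2) / (2 * width^2))
  u <- array(0, dim = c(shape, 3))
  u[, , , 1] <- 3.5 * g; u[, , , 2] <- -2.5 * g; u[, , , 3] <- 2 * g
  u <- u * (amp / max(sqrt(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2)))
  dvf_true <- dvf_field(u, spacing)
  list(dct = ph$volume, pct = warp_volume(ph$volume, dvf_true),
       dvf_true = dvf_true, body = ph$masks$body, masks = ph$masks)
}

mean_epe <- function(dvf, dvf_true, body) {
  df <- dvf$field - dvf_true$field
  mean(sqrt(df[, , , 1]^2 + df[, , , 2]^2 + df[, , , 3]^2)[body])
}

# small 2 mm-isotropic thorax (a (6, -4, 2) mm shift is an exact
# integer-voxel shift on this grid, giving an interpolation-free oracle)
mini_phantom_2mm <- function(seed = 4, noise_sd = 5) {
  phantom_spec(grid_shape = c(64, 64, 32), spacing_mm = c(2, 2, 2),
               body_radii_mm = c(55, 42), lung_radii_mm = c(19, 26),
               lung_offset_mm = 27, lung_z_half_mm = 24,
               heart_radius_mm = 15, heart_center_mm = c(-6, -6, -8),
               esophagus_radius_mm = 3.5, esophagus_center_mm = c(0, 9),
               spine_radius_mm = 7, spine_center_mm = c(0, 27),
               ctv_radius_mm = 7, ctv_center_mm = c(20, -2, 12),
               noise_sd = noise_sd, random_seed = seed)
}

# translated copy plus its mask, for rigid-recovery fixtures
shifted_pair <- function(fixed, body_mask, shift_mm) {
  moving <- translate_volume(fixed, -shift_mm)
  mmask <- translate_volume(
    image_volume(array(as.double(body_mask), dim = dim(body_mask)),
                 fixed$spacing), -shift_mm, method = "nearest", pad = 0)
  list(moving = moving, mask = mmask$data > 0.5)
}

# preprocessed (couch-removed, histogram-matched) training pair from the
# full diagnostic/planning case generator
prep_case <- function(cs) {
  d <- suppressWarnings(remove_couch(cs$dct))
  p <- remove_couch(cs$pct)
  lut <- build_hu_lut(d$volume, p$volume, d$body_mask, p$body_mask)
  list(dct = apply_lut(d$volume, lut), pct = p$volume,
       body_dct = d$body_mask, body_pct = p$body_mask)
}
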