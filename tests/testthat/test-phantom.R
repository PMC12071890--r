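test_that("phantom construction: HU assignment, mask algebra, determinism", {
  spec <- phantom_spec(noise_sd = 0)
  ph <- make_thorax_phantom(spec)
  m <- ph$masks
  # outside the body everything is air
  expect_true(all(ph$volume$data[!m$body] == -1000))
  # exact tissue HU before noise; within 5 HU of it after sigma = 5 noise
  expect_equal(mean(ph$volume$data[m$lung_total]), -700, tolerance = 8 / 700)
  lungish <- m$lung_total & !m$ctv
  expect_true(all(ph$volume$data[lungish] == -700))
  spec5 <- phantom_spec(noise_sd = 5, random_seed = 3)
  ph5 <- make_thorax_phantom(spec5)
  expect_lt(abs(mean(ph5$volume$data[ph5$masks$lung_total & !ph5$masks$ctv]) + 700), 5)
  # determinism: same spec + seed, identical volumes
  ph5b <- make_thorax_phantom(spec5)
  expect_identical(ph5$volume$data, ph5b$volume$data)
  # mask algebra
  expect_identical(m$lung_total, m$lung_left | m$lung_right)
  for (nm in c("lung_total", "heart", "esophagus", "spine", "ctv"))
    expect_true(all(!m[[nm]] | m$body), info = nm)
  # geometry validation names the offending organ
  expect_error(phantom_spec(heart_radius_mm = 90), "heart")
})

test_that("couch insertion: flat slab, curved sag, disjointness", {
  spec <- phantom_spec(noise_sd = 0)
  ph <- make_thorax_phantom(spec)
  fl <- add_couch(ph$volume, ph$masks$body, "flat")
  expect_false(any(fl$couch_mask & ph$masks$body))
  # flat: body voxels unchanged, slab of constant thickness
  expect_identical(fl$volume$data[ph$masks$body], ph$volume$data[ph$masks$body])
  per_x <- apply(fl$couch_mask, 1, sum)
  expect_equal(length(unique(per_x[per_x > 0])), 1)
  # curved: posterior surface displaced toward the couch, anterior unchanged
  cu <- add_couch(ph$volume, ph$masks$body, "curved")
  ymax_before <- max(which(apply(ph$masks$body, 2, any)))
  ymax_after <- max(which(apply(cu$body_mask, 2, any)))
  expect_gt(ymax_after, ymax_before)
  ymin_before <- min(which(apply(ph$masks$body, 2, any)))
  ymin_after <- min(which(apply(cu$body_mask, 2, any)))
  expect_equal(ymin_after, ymin_before)
})

test_that("smooth displacement fields: amplitude bound, smoothness, invertibility", {
  grid <- list(dim = c(24, 24, 12), spacing = c(6, 6, 8))
  # zero blobs: identically zero
  z <- make_smooth_dvf(deformation_spec(n_blobs = 0), grid)
  expect_true(all(z$field == 0))
  # one blob of amplitude 3: peak magnitude in [2.7, 3]
  one <- make_smooth_dvf(deformation_spec(n_blobs = 1, amplitude_mm = c(3, 3),
                                          width_mm = c(30, 30),
                                          random_seed = 5), grid)
  peak <- max(dvf_magnitude(one))
  expect_gte(peak, 2.7); expect_lte(peak, 3.0 + 1e-9)
  # folding guard and positive Jacobian for amplitude < width
  expect_error(deformation_spec(amplitude_mm = c(5, 30), width_mm = c(10, 20)),
               "folding")
  multi <- make_smooth_dvf(deformation_spec(n_blobs = 3, amplitude_mm = c(2, 5),
                                            width_mm = c(20, 40),
                                            random_seed = 6), grid)
  expect_true(all(is.finite(multi$field)))
  expect_true(all(jacobian_dets(multi) > 0))
  # determinism
  multi2 <- make_smooth_dvf(deformation_spec(n_blobs = 3, amplitude_mm = c(2, 5),
                                             width_mm = c(20, 40),
                                             random_seed = 6), grid)
  expect_identical(multi$field, multi2$field)
})

test_that("dose fields honor the prescription, falloff ordering and controls", {
  spec <- phantom_spec(noise_sd = 0)
  ph <- make_thorax_phantom(spec)
  sp <- spec$spacing_mm
  pair <- dose_spec_pair("proton", 60)
  dph <- make_dose(ph$masks, pair$photon, sp)
  dpr <- make_dose(ph$masks, pair$proton, sp)
  for (d in list(dph, dpr)) {
    expect_true(all(d$data >= 0))
    expect_true(all(abs(d$data[ph$masks$ctv] - 60) / 60 <= 0.05))
  }
  # heart lies distal to the target: proton spares it
  expect_lt(mean(dpr$data[ph$masks$heart]), mean(dph$data[ph$masks$heart]))
  # the photon-favoring pair reverses the OAR ordering
  rev <- dose_spec_pair("photon", 60)
  dph2 <- make_dose(ph$masks, rev$photon, sp)
  dpr2 <- make_dose(ph$masks, rev$proton, sp)
  for (organ in c("heart", "lung_total", "esophagus"))
    expect_gt(mean(dpr2$data[ph$masks[[organ]]]),
              mean(dph2$data[ph$masks[[organ]]]))
  # zero prescription: identically zero dose
  z <- make_dose(ph$masks, dose_spec("photon", prescription_gy = 0), sp)
  expect_true(all(z$data == 0))
  expect_error(make_dose(list(ctv = array(FALSE, dim = dim(ph$volume$data))),
                         pair$photon, sp), "empty")
})

test_that("contrast and truncation failure modes behave as constructed", {
  spec <- phantom_spec(grid_shape = c(20, 20, 10), spacing_mm = c(10, 10, 10),
                       noise_sd = 0)
  ph <- make_thorax_phantom(spec)
  vm <- array(FALSE, dim = c(20, 20, 10))
  vm[9:10, 9:10, 3:7] <- vm[9:10, 9:10, 3:7]  # keep FALSE, then set 100 voxels
  idx <- which(ph$masks$heart)[1:100]
  vm[idx] <- TRUE
  with_c <- add_contrast(ph$volume, vm, delta = 200)
  # closed-form MAE: delta * |mask| / N over the whole grid
  expect_equal(mae(with_c, ph$volume), 200 * 100 / prod(dim(vm)))
  expect_identical(truncate_fov(ph$volume, 0)$data, ph$volume$data)
  tr <- truncate_fov(ph$volume, 0.3)
  expect_lt(dim(tr$data)[1], 20)
  expect_error(truncate_fov(ph$volume, 0.5), "0, 0.3")
})
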