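test_that("couch removal recovers the body and is idempotent", {
  spec <- phantom_spec(noise_sd = 0)
  ph <- make_thorax_phantom(spec)
  cb <- add_couch(ph$volume, ph$masks$body, "flat")
  rc <- remove_couch(cb$volume)
  expect_gte(dice(rc$body_mask, ph$masks$body), 0.99)
  expect_false(rc$qa$truncation)
  # no couch voxels survive; inside the body the volume is untouched
  expect_false(any(rc$volume$data[cb$couch_mask] > -1000))
  expect_equal(mae(rc$volume, ph$volume, mask = ph$masks$body), 0)
  # idempotence
  rc2 <- remove_couch(rc$volume)
  expect_identical(rc2$body_mask, rc$body_mask)
  expect_identical(rc2$volume$data, rc$volume$data)
  # clean input passes through: outside body all air
  rc3 <- remove_couch(ph$volume)
  expect_equal(rc3$volume$data[ph$masks$body], ph$volume$data[ph$masks$body])
  expect_true(all(rc3$volume$data[!rc3$body_mask] == -1000))
  expect_error(remove_couch(image_volume(array(-1000, dim = c(8, 8, 8)))),
               "threshold")
})

test_that("lateral truncation raises the QA flag", {
  spec <- phantom_spec(noise_sd = 0, couch_kind = "curved")
  ph <- make_thorax_phantom(spec)
  tr <- truncate_fov(ph$volume, 0.2)
  expect_warning(rc <- remove_couch(tr), "truncation QA")
  expect_true(rc$qa$truncation)
})

test_that("histogram-matching LUT recovers shifts and matches deciles", {
  spec <- phantom_spec(noise_sd = 5, random_seed = 9)
  ph <- make_thorax_phantom(spec)
  body <- ph$masks$body
  # source = reference: identity within one bin width
  lut_id <- build_hu_lut(ph$volume, ph$volume, body, body)
  occ <- lut_id$occupied
  expect_lt(max(abs(lut_id$values[occ] - lut_id$centers[occ])), lut_id$bin_width)
  # reference = source + 50: LUT(h) = h + 50 within one bin width
  ref <- image_volume(ph$volume$data + 50, ph$volume$spacing)
  lut <- build_hu_lut(ph$volume, ref, body, body)
  occ <- lut$occupied
  expect_lt(max(abs(lut$values[occ] - (lut$centers[occ] + 50))), lut$bin_width)
  expect_true(all(diff(lut$values) >= 0))
  # application shrinks the mismatch and matches the deciles
  mapped <- apply_lut(ph$volume, lut)
  expect_lt(mae(mapped, ref), mae(ph$volume, ref))
  qs <- seq(0.1, 0.9, by = 0.1)
  expect_lt(max(abs(quantile(mapped$data[body], qs) -
                      quantile(ref$data[body], qs))), lut$bin_width)
  # identity LUT leaves a volume unchanged; constant stays constant
  same <- apply_lut(ph$volume, lut_id)
  expect_lt(mae(same, ph$volume), lut_id$bin_width)
  cst <- image_volume(array(40, dim = c(6, 6, 6)))
  expect_equal(length(unique(as.vector(apply_lut(cst, lut)$data))), 1)
  expect_error(build_hu_lut(ph$volume, ph$volume, body, body, n_bins = 16),
               "at least 64")
})

test_that("rigid alignment recovers constructed translations to search resolution", {
  ph <- make_thorax_phantom(mini_phantom_2mm())
  fixed <- remove_couch(ph$volume)
  # moving = fixed: zero translation
  al0 <- rigid_align(fixed$volume, fixed$volume, fixed$body_mask, fixed$body_mask)
  expect_true(all(abs(al0$translation_mm) <= 0.5))
  # constructed (6, -4, 2) mm shift: recovered within 0.5 mm per axis
  shift <- c(6, -4, 2)
  sh <- shifted_pair(fixed$volume, fixed$body_mask, shift)
  al <- rigid_align(sh$moving, fixed$volume, sh$mask, fixed$body_mask)
  expect_true(all(abs(al$translation_mm - shift) <= 0.5))
  expect_gte(al$ncc_after, al$ncc_before)
})

test_that("resampling preserves extent, constants and round trips", {
  spec <- phantom_spec(noise_sd = 0)
  ph <- make_thorax_phantom(spec)
  # identity at the source shape
  expect_identical(resample_volume(ph$volume, dim(ph$volume$data))$data,
                   ph$volume$data)
  # constant volume stays constant at any shape
  cst <- image_volume(array(7, dim = c(16, 16, 8)), c(2, 2, 4))
  rs <- resample_volume(cst, c(10, 6, 4))
  expect_true(all(abs(rs$data - 7) < 1e-12))
  # in-plane downscale by 2: spacing doubles (extent preserved)
  half <- resample_volume(ph$volume, c(32, 32, 16))
  expect_equal(half$spacing, ph$volume$spacing * 2)
  # round trip changes the mean by < 1 HU
  back <- resample_volume(half, c(64, 64, 32))
  expect_lt(abs(mean(back$data) - mean(ph$volume$data)), 1)
  expect_error(resample_volume(ph$volume, c(0, 10, 10)), "positive")
})

test_that("augmentation ops: flip involution, rotation conservation, binary masks", {
  spec <- phantom_spec(noise_sd = 0)
  ph <- make_thorax_phantom(spec)
  flipped2 <- augment(augment(ph$volume, "hflip"), "hflip")
  expect_identical(flipped2$data, ph$volume$data)
  # rotating the (centrally placed) body conserves its voxel count within 1%
  body_vol <- image_volume(array(as.double(ph$masks$body),
                                 dim = dim(ph$volume$data)), ph$volume$spacing)
  rot <- augment(body_vol, "rot45cw", method = "nearest", pad = 0)
  expect_lt(abs(sum(rot$data) - sum(ph$masks$body)) / sum(ph$masks$body), 0.01)
  expect_true(all(rot$data %in% c(0, 1)))
})
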