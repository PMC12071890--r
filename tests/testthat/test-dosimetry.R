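test_that("DVH of uniform and two-voxel doses is forced by the definitions", {
  m <- array(TRUE, dim = c(3, 3, 1))
  d <- image_volume(array(10, dim = c(3, 3, 1)), c(2, 2, 2))
  curve <- compute_dvh(d, m)
  expect_equal(dvh_metric(curve, "vxgy", x = 5), 100)
  expect_equal(dvh_metric(curve, "vxgy", x = 20), 0)
  expect_equal(dvh_metric(curve, "vxgy", x = 10), 100)  # closed threshold (>=)
  expect_equal(dvh_metric(curve, "mean"), 10, tolerance = 0.05)
  expect_equal(dvh_metric(curve, "max"), 10, tolerance = 0.05)
  expect_equal(dvh_metric(curve, "vxgy", x = 0), 100)
  two <- image_volume(array(c(10, 30, 0, 0), dim = c(2, 2, 1)), c(1, 1, 1))
  msk <- array(c(TRUE, TRUE, FALSE, FALSE), dim = c(2, 2, 1))
  c2 <- compute_dvh(two, msk)
  expect_equal(dvh_metric(c2, "vxgy", x = 20), 50)
  expect_equal(dvh_metric(c2, "mean"), 20, tolerance = 0.05)
  expect_error(compute_dvh(d, array(FALSE, dim = c(3, 3, 1))), "empty")
})

test_that("DVH curves match the sort-based voxel oracle at every bin", {
  set.seed(10)
  for (i in 1:8) {
    sh <- c(6, 5, 4)
    dose <- image_volume(array(runif(prod(sh), 0, 40), dim = sh), c(2, 2, 2))
    mask <- array(runif(prod(sh)) < 0.6, dim = sh)
    if (!any(mask)) next
    curve <- compute_dvh(dose, mask)
    expect_equal(curve$cum, oracle_dvh_cum(dose$data[mask], curve$edges))
    expect_true(all(diff(curve$cum) <= 0))
    expect_equal(curve$cum[1], 1)
    expect_equal(curve$cum[length(curve$cum)], 0)
    # mean from the curve vs direct voxel mean within half a bin
    expect_lt(abs(dvh_metric(curve, "mean") - mean(dose$data[mask])), 0.05)
  }
})

test_that("scaling all doses up weakly increases VxGy and the mean", {
  set.seed(11)
  sh <- c(6, 6, 4)
  dose <- image_volume(array(rexp(prod(sh), 1 / 10), dim = sh), c(2, 2, 2))
  mask <- array(TRUE, dim = sh)
  c1 <- compute_dvh(dose, mask)
  c2 <- compute_dvh(image_volume(1.5 * dose$data, dose$spacing), mask)
  for (x in c(2, 5, 10, 20))
    expect_gte(dvh_metric(c2, "vxgy", x = x), dvh_metric(c1, "vxgy", x = x))
  expect_gt(dvh_metric(c2, "mean"), dvh_metric(c1, "mean"))
})

test_that("proton-photon DVH deltas and sign concordance follow the definitions", {
  p <- c(esophagus.mean = 10, lung_total.v20gy = 30, heart.mean = 5)
  identical_panels <- delta_dvh_panel(sct = list(proton = p, photon = p),
                                      pct = list(proton = p, photon = p))
  expect_true(all(identical_panels$delta_sct == 0))
  expect_true(all(identical_panels$concordant))
  # proton lower on both CTs: negative deltas, concordant
  ph <- p + 4
  both <- delta_dvh_panel(sct = list(proton = p, photon = ph),
                          pct = list(proton = p + 1, photon = ph))
  expect_true(all(both$delta_sct < 0) && all(both$delta_pct < 0))
  expect_true(all(both$concordant))
  expect_equal(both$delta_diff, both$delta_sct - both$delta_pct)
  # mixed signs are discordant
  mix <- delta_dvh_panel(sct = list(proton = p - 2, photon = p),
                         pct = list(proton = p + 1, photon = p))
  expect_false(any(mix$concordant))
  expect_error(delta_dvh_panel(sct = list(proton = p, photon = p[-1]),
                               pct = list(proton = p, photon = p)),
               "missing")
})

test_that("agreement summary arithmetic matches the concordant/total definition", {
  set.seed(12)
  n <- 47
  deltas <- data.frame(metric = rep(c("esophagus.mean", "lung_total.v10gy"),
                                    length.out = n),
                       delta_sct = rnorm(n), delta_pct = rnorm(n))
  deltas$concordant <- c(rep(TRUE, 43), rep(FALSE, 4))
  deltas$delta_diff <- deltas$delta_sct - deltas$delta_pct
  s <- agreement_summary(deltas)
  expect_equal(s$rate_pct, 100 * 43 / 47, tolerance = 1e-12)
  expect_equal(round(s$rate_pct, 2), 91.49)
  expect_equal(s$ccc, ccc(deltas$delta_sct, deltas$delta_pct))
  all_conc <- deltas; all_conc$concordant <- TRUE
  expect_equal(agreement_summary(all_conc)$rate_pct, 100)
  same <- data.frame(metric = "heart.mean", delta_sct = c(1, -2, 3),
                     delta_pct = c(1, -2, 3), delta_diff = 0, concordant = TRUE)
  expect_equal(agreement_summary(same)$ccc, 1)
})
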