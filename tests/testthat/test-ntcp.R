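test_that("gEUD is the power mean of the dose distribution", {
  # hand example: v = (0.5, 0.5), d = (0, 60), n = 0.5
  expect_equal(geud(list(v = c(0.5, 0.5), d = c(0, 60)), n = 0.5),
               sqrt(0.5 * 60^2), tolerance = 1e-12)
  expect_equal(round(geud(list(v = c(0.5, 0.5), d = c(0, 60)), 0.5), 2), 42.43)
  # n = 1 reduces to the mean dose
  set.seed(20)
  dose <- image_volume(array(runif(120, 0, 50), dim = c(6, 5, 4)), c(2, 2, 2))
  mask <- array(TRUE, dim = c(6, 5, 4))
  curve <- compute_dvh(dose, mask)
  expect_equal(geud(curve, 1), dvh_metric(curve, "mean"), tolerance = 1e-12)
  # uniform dose: Deff = D for any n
  u <- compute_dvh(image_volume(array(20, dim = c(4, 4, 2)), c(1, 1, 1)),
                   array(TRUE, dim = c(4, 4, 2)))
  for (n in c(0.05, 0.3, 1)) expect_equal(geud(u, n), 20, tolerance = 0.05)
  # power-mean bounds and monotonicity in n (smaller n -> closer to max)
  expect_lte(geud(curve, 0.5), max(dose$data) + 0.05)
  expect_gte(geud(curve, 0.5), min(dose$data) - 0.05)
  expect_gt(geud(curve, 0.2), geud(curve, 0.9))
  # two-level distribution: n -> 0 approaches the max dose
  two <- list(v = c(0.5, 0.5), d = c(10, 50))
  expect_equal(geud(two, 0.01), 50, tolerance = 0.01 * 50)
  expect_error(geud(curve, 0), "\\(0, 1\\]")
})

test_that("binned gEUD agrees with voxel-wise brute force within 0.5%", {
  set.seed(21)
  for (i in 1:6) {
    sh <- c(7, 6, 4)
    dose <- image_volume(array(runif(prod(sh), 0, 60), dim = sh), c(2, 2, 2))
    mask <- array(runif(prod(sh)) < 0.7, dim = sh)
    curve <- compute_dvh(dose, mask)
    for (n in c(0.1, 0.35, 0.87, 1)) {
      bf <- oracle_geud(dose$data[mask], n)
      expect_lt(abs(geud(curve, n) - bf) / bf, 0.005)
    }
  }
})

test_that("LKB NTCP is the probit of the normalized effective dose", {
  p <- lkb_params("test_endpoint", td50_gy = 50, m = 0.1, n = 1)
  uniform_dvh <- function(d) compute_dvh(
    image_volume(array(d, dim = c(4, 4, 2)), c(1, 1, 1)),
    array(TRUE, dim = c(4, 4, 2)), bin_width = 1e-3)
  # Deff = TD50 -> 0.5
  expect_equal(lkb_ntcp(uniform_dvh(50), p)$ntcp, 0.5, tolerance = 1e-3)
  # Deff = TD50 (1 + m) -> Phi(1)
  expect_equal(lkb_ntcp(uniform_dvh(55), p)$ntcp, pnorm(1), tolerance = 1e-3)
  expect_equal(round(pnorm(1), 4), 0.8413)
  # zero dose: t = -10, vanishing probability
  expect_lt(lkb_ntcp(uniform_dvh(0), p)$ntcp, 1e-15)
  # strictly increasing in Deff; larger m flattens the curve
  n1 <- lkb_ntcp(uniform_dvh(40), p)$ntcp
  n2 <- lkb_ntcp(uniform_dvh(45), p)$ntcp
  expect_gt(n2, n1)
  p2 <- lkb_params("test_endpoint", 50, m = 0.3, n = 1)
  expect_lt(abs(lkb_ntcp(uniform_dvh(40), p2)$ntcp - 0.5),
            abs(n1 - 0.5))
  expect_error(lkb_params("x", -1, 0.1, 0.5), "TD50")
  expect_error(lkb_params("x", 50, 0.1, 1.5), "n must be")
})

test_that("NTCP differences are antisymmetric and guarded against mismatches", {
  a <- ntcp_result("heart_pericarditis", "proton", "sct", 0.02)
  b <- ntcp_result("heart_pericarditis", "photon", "sct", 0.05)
  expect_equal(delta_ntcp(a, b), -0.03)
  expect_equal(delta_ntcp(a, b), -delta_ntcp(b, a))
  expect_equal(delta_ntcp(a, a), 0)
  c2 <- ntcp_result("lung_pneumonitis", "photon", "sct", 0.05)
  expect_error(delta_ntcp(a, c2), "different endpoints")
  d2 <- ntcp_result("heart_pericarditis", "photon", "pct", 0.05)
  expect_error(delta_ntcp(a, d2), "different CT")
})

test_that("relevance filter keeps endpoint-cases with any value above 0.05%", {
  grid <- expand.grid(modality = c("photon", "proton"), ct = c("sct", "pct"),
                      stringsAsFactors = FALSE)
  mk <- function(case, endpoint, ntcps) cbind(case = case, endpoint = endpoint,
                                              grid, ntcp = ntcps)
  # all four at 0.04% -> excluded; one at 0.06% -> included
  vals <- rbind(mk(1, "heart_pericarditis", rep(4e-4, 4)),
                mk(2, "heart_pericarditis", c(6e-4, 1e-4, 1e-4, 1e-4)))
  f <- relevance_filter(vals, threshold_pct = 0.05)
  expect_equal(f$included[f$case == 1], FALSE)
  expect_equal(f$included[f$case == 2], TRUE)
  # cohort-shaped fixture: 15 cases x 3 endpoints = 45 candidates, 19 pass
  set.seed(22)
  eps <- c("heart_pericarditis", "lung_pneumonitis", "esophagus_perforation")
  rows <- list()
  k <- 0
  for (cs in 1:15) for (ep in eps) {
    k <- k + 1
    high <- k <= 19  # first 19 endpoint-cases engineered above threshold
    base <- if (high) runif(1, 0.01, 0.4) else runif(1, 0, 0.0003)
    rows[[k]] <- mk(cs, ep, pmin(1, base * runif(4, 0.5, 1.5)))
  }
  cohort <- do.call(rbind, rows)
  fc <- relevance_filter(cohort, 0.05)
  expect_equal(sum(fc$included), 19)
  expect_equal(sum(!fc$included), 26)
})

test_that("modality verdict reports sign concordance, accuracy and CCC", {
  grid <- expand.grid(modality = c("photon", "proton"), ct = c("sct", "pct"),
                      stringsAsFactors = FALSE)
  mk <- function(case, ep, photon_sct, proton_sct, photon_pct, proton_pct) {
    data.frame(case = case, endpoint = ep,
               modality = grid$modality, ct = grid$ct,
               ntcp = c(photon_sct, proton_sct, photon_pct, proton_pct))
  }
  # all sign-matched: accuracy 100
  v <- rbind(mk(1, "a", 0.03, 0.02, 0.04, 0.02),   # deltas -0.01, -0.02
             mk(2, "a", 0.01, 0.04, 0.02, 0.06),   # +3, +4
             mk(3, "a", 0.06, 0.01, 0.02, 0.01))   # -5, -1
  r <- modality_verdict(v, threshold_pct = 0.05)
  expect_equal(r$summary$trend_accuracy_pct, 100)
  expect_true(all(r$pairs$concordant))
  expect_equal(r$pairs$preferred_sct[r$pairs$case == 2], "photon")
  expect_equal(r$pairs$preferred_pct[r$pairs$case == 1], "proton")
  # a discordant pair: accuracy 0
  v2 <- mk(1, "a", 0.03, 0.02, 0.02, 0.04)  # -0.01 vs +0.02
  r2 <- modality_verdict(v2, threshold_pct = 0.05)
  expect_equal(r2$summary$trend_accuracy_pct, 0)
  # everything filtered out: explicit empty status
  v3 <- mk(1, "a", 1e-5, 2e-5, 1e-5, 3e-5)
  r3 <- modality_verdict(v3, threshold_pct = 0.05)
  expect_equal(r3$status, "no relevant endpoints")
  # the Eq.(2)-style identity holds bit-exactly
  expect_equal(r$pairs$delta_diff, r$pairs$delta_sct - r$pairs$delta_pct)
})

test_that("default LKB parameter file loads with valid invariants", {
  pars <- default_lkb_params()
  expect_setequal(names(pars),
                  c("heart_pericarditis", "lung_pneumonitis",
                    "esophagus_perforation"))
  for (p in pars) {
    expect_gt(p$td50_gy, 0)
    expect_gt(p$m, 0)
    expect_true(p$n > 0 && p$n <= 1)
  }
})
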