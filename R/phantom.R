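#' Thorax phantom specification
#'
#' Parameters for the synthetic thorax generator that stands in for paired
#' diagnostic/planning CT data: an elliptical body with fat and muscle
#' layers, two lungs, heart, esophagus, spine, a spherical clinical target
#' volume (CTV) in the upper lung, and an optional treatment/diagnostic
#' couch. All geometry is in mm; HU values follow standard CT ranges and
#' are configurable.
#'
#' @param grid_shape integer length-3, voxels per axis (x lateral,
#'   y anterior-to-posterior, z inferior-to-superior).
#' @param spacing_mm voxel spacing in mm.
#' @param body_radii_mm lateral/anteroposterior radii of the body ellipse.
#' @param lung_radii_mm lateral/AP radii of each lung cross-section.
#' @param lung_offset_mm lateral offset of each lung centre from midline.
#' @param lung_z_half_mm half-length of the lungs along z.
#' @param heart_radius_mm,heart_center_mm heart sphere geometry.
#' @param esophagus_radius_mm,esophagus_center_mm esophageal tube geometry
#'   (runs the full z extent).
#' @param spine_radius_mm,spine_center_mm spinal column geometry.
#' @param ctv_radius_mm,ctv_center_mm spherical CTV in the upper lung.
#' @param hu named HU assignment map (air, lung, soft, muscle, fat, bone,
#'   tumor, contrast, couch); all within \[-1024, 3071\].
#' @param couch_kind "curved" (diagnostic-style bed), "flat" (treatment
#'   couch) or "none".
#' @param contrast_enabled add an intravenous-contrast blob inside the heart.
#' @param truncation_fraction fraction (0-0.3) of the lateral field of view
#'   replaced by air, emulating a truncated acquisition.
#' @param noise_sd additive Gaussian HU noise standard deviation (0 = none).
#' @param hu_shift_body global HU shift applied inside the body, emulating a
#'   scanning-protocol calibration difference.
#' @param random_seed seed; the generator is a pure function of (spec, seed).
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 32),
                         spacing_mm = c(4, 4, 5),
                         body_radii_mm = c(110, 80),
                         lung_radii_mm = c(38, 52),
                         lung_offset_mm = 55,
                         lung_z_half_mm = 62,
                         heart_radius_mm = 32,
                         heart_center_mm = c(-12, -12, -15),
                         esophagus_radius_mm = 6,
                         esophagus_center_mm = c(0, 18),
                         spine_radius_mm = 13,
                         spine_center_mm = c(0, 52),
                         ctv_radius_mm = 15,
                         ctv_center_mm = c(40, -5, 25),
                         hu = c(air = -1000, lung = -700, soft = 20,
                                muscle = 40, fat = -90, bone = 400,
                                tumor = 50, contrast = 240, couch = 200),
                         couch_kind = c("none", "curved", "flat"),
                         contrast_enabled = FALSE,
                         truncation_fraction = 0,
                         noise_sd = 0,
                         hu_shift_body = 0,
                         random_seed = 1L) {
  couch_kind <- match.arg(couch_kind)
  spec <- list(grid_shape = as.integer(grid_shape), spacing_mm = as.numeric(spacing_mm),
               body_radii_mm = body_radii_mm, lung_radii_mm = lung_radii_mm,
               lung_offset_mm = lung_offset_mm, lung_z_half_mm = lung_z_half_mm,
               heart_radius_mm = heart_radius_mm, heart_center_mm = heart_center_mm,
               esophagus_radius_mm = esophagus_radius_mm,
               esophagus_center_mm = esophagus_center_mm,
               spine_radius_mm = spine_radius_mm, spine_center_mm = spine_center_mm,
               ctv_radius_mm = ctv_radius_mm, ctv_center_mm = ctv_center_mm,
               hu = hu, couch_kind = couch_kind,
               contrast_enabled = isTRUE(contrast_enabled),
               truncation_fraction = truncation_fraction,
               noise_sd = noise_sd, hu_shift_body = hu_shift_body,
               random_seed = as.integer(random_seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(s) {
  if (length(s$grid_shape) != 3L || any(s$grid_shape < 8))
    stop("grid_shape must be 3 positive integers (>= 8)")
  if (any(s$spacing_mm <= 0)) stop("spacing_mm must be positive")
  if (any(s$hu < -1024) || any(s$hu > 3071))
    stop("HU assignments must lie within [-1024, 3071]")
  if (s$truncation_fraction < 0 || s$truncation_fraction > 0.3)
    stop("truncation_fraction must be in [0, 0.3]")
  rb <- s$body_radii_mm
  # an organ fits if its in-plane boundary stays inside the body ellipse
  fits <- function(name, cx, cy, rx, ry) {
    th <- seq(0, 2 * pi, length.out = 256)
    bx <- cx + rx * cos(th); by <- cy + ry * sin(th)
    if (any((bx / rb[1])^2 + (by / rb[2])^2 > 1))
      stop(sprintf("organ '%s' exceeds the body outline", name))
  }
  fits("lung", s$lung_offset_mm, -5, s$lung_radii_mm[1], s$lung_radii_mm[2])
  fits("heart", s$heart_center_mm[1], s$heart_center_mm[2],
       s$heart_radius_mm, s$heart_radius_mm)
  fits("esophagus", s$esophagus_center_mm[1], s$esophagus_center_mm[2],
       s$esophagus_radius_mm, s$esophagus_radius_mm)
  fits("spine", s$spine_center_mm[1], s$spine_center_mm[2],
       s$spine_radius_mm, s$spine_radius_mm)
  fits("ctv", s$ctv_center_mm[1], s$ctv_center_mm[2],
       s$ctv_radius_mm, s$ctv_radius_mm)
  invisible(s)
}

# voxel-centre coordinate grids in mm, centred on the volume midpoint
grid_coords <- function(shape, spacing) {
  lapply(1:3, function(a) (seq_len(shape[a]) - (shape[a] + 1) / 2) * spacing[a])
}

#' Generate a thorax phantom
#'
#' Builds the HU volume and ground-truth structure masks from a
#' [phantom_spec()]. Masks satisfy: every organ is inside the body, total
#' lung is the union of left and right lung, and the couch (if any) is
#' disjoint from the body.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` ([image_volume()]) and `masks`, a named list
#'   of logical arrays (`body`, `lung_left`, `lung_right`, `lung_total`,
#'   `heart`, `esophagus`, `spine`, `ctv`, and `couch` when present).
#' @export
make_thorax_phantom <- function(spec) {
  validate_phantom_spec(spec)
  sh <- spec$grid_shape; sp <- spec$spacing_mm
  co <- grid_coords(sh, sp)
  X <- array(rep(co[[1]], times = sh[2] * sh[3]), dim = sh)
  Y <- array(rep(rep(co[[2]], each = sh[1]), times = sh[3]), dim = sh)
  Z <- array(rep(co[[3]], each = sh[1] * sh[2]), dim = sh)
  hu <- spec$hu
  rb <- spec$body_radii_mm
  e <- (X / rb[1])^2 + (Y / rb[2])^2
  body <- e <= 1
  vol <- array(hu[["air"]], dim = sh)
  vol[body & e > 0.80] <- hu[["fat"]]
  vol[body & e <= 0.80 & e > 0.62] <- hu[["muscle"]]
  vol[body & e <= 0.62] <- hu[["soft"]]

  lungfun <- function(sgn) {
    ((X - sgn * spec$lung_offset_mm) / spec$lung_radii_mm[1])^2 +
      ((Y + 5) / spec$lung_radii_mm[2])^2 <= 1 &
      abs(Z) <= spec$lung_z_half_mm
  }
  lung_l <- lungfun(+1) & body
  lung_r <- lungfun(-1) & body
  hc <- spec$heart_center_mm
  heart <- ((X - hc[1])^2 + (Y - hc[2])^2 + (Z - hc[3])^2) <= spec$heart_radius_mm^2
  heart <- heart & body
  eso <- ((X - spec$esophagus_center_mm[1])^2 +
            (Y - spec$esophagus_center_mm[2])^2) <= spec$esophagus_radius_mm^2
  eso <- eso & body
  spine <- ((X - spec$spine_center_mm[1])^2 +
              (Y - spec$spine_center_mm[2])^2) <= spec$spine_radius_mm^2
  spine <- spine & body
  cc <- spec$ctv_center_mm
  ctv <- ((X - cc[1])^2 + (Y - cc[2])^2 + (Z - cc[3])^2) <= spec$ctv_radius_mm^2
  ctv <- ctv & body
  lung_l <- lung_l & !heart & !spine & !eso
  lung_r <- lung_r & !heart & !spine & !eso

  vol[lung_l | lung_r] <- hu[["lung"]]
  vol[heart] <- hu[["muscle"]] + 5
  vol[eso] <- hu[["soft"]] + 15
  vol[spine] <- hu[["bone"]]
  vol[ctv] <- hu[["tumor"]]

  masks <- list(body = body, lung_left = lung_l, lung_right = lung_r,
                lung_total = lung_l | lung_r, heart = heart,
                esophagus = eso, spine = spine, ctv = ctv)

  if (spec$hu_shift_body != 0) vol[body] <- vol[body] + spec$hu_shift_body
  if (spec$contrast_enabled) {
    vessel <- ((X - hc[1])^2 + (Y - hc[2])^2 + (Z - hc[3])^2) <= 8^2
    volv <- image_volume(vol, sp)
    volv <- add_contrast(volv, vessel, delta = hu[["contrast"]] - hu[["muscle"]])
    vol <- volv$data
    masks$vessel <- vessel
  }
  if (spec$noise_sd > 0) {
    vol <- vol + with_seed(spec$random_seed,
                           array(rnorm(prod(sh), 0, spec$noise_sd), dim = sh))
  }
  out <- image_volume(vol, sp)
  if (spec$couch_kind != "none") {
    cb <- add_couch(out, body, kind = spec$couch_kind, couch_hu = hu[["couch"]])
    out <- cb$volume
    masks$couch <- cb$couch_mask
    if (spec$couch_kind == "curved") masks$body <- cb$body_mask
  }
  if (spec$truncation_fraction > 0)
    out <- truncate_fov(out, spec$truncation_fraction)
  list(volume = out, masks = masks)
}

#' Insert a couch below the body
#'
#' A flat treatment couch is a constant-thickness slab behind the posterior
#' body surface; a curved diagnostic bed is a concave arc, and the posterior
#' body contour is additionally sagged into it by a smooth displacement
#' (emulating the positional difference between diagnostic and treatment
#' scans).
#'
#' @param volume an [image_volume()] in HU.
#' @param body_mask logical array on the same grid.
#' @param kind "flat" or "curved".
#' @param couch_hu couch HU value.
#' @param thickness_mm couch slab thickness.
#' @param gap_mm air gap between body surface and couch top.
#' @param sag_mm peak posterior displacement of the body for the curved bed.
#' @param curve_depth_mm depth of the curved bed arc.
#' @return list with `volume`, `couch_mask` and (possibly sagged) `body_mask`.
#' @export
add_couch <- function(volume, body_mask, kind = c("flat", "curved"),
                      couch_hu = 200, thickness_mm = 15, gap_mm = 15,
                      sag_mm = 8, curve_depth_mm = 12) {
  kind <- match.arg(kind)
  vol_check(volume)
  sh <- dim(volume$data); sp <- volume$spacing
  if (!identical(dim(body_mask), sh)) stop("body mask does not match volume grid")
  co <- grid_coords(sh, sp)
  vol <- volume$data
  bm <- body_mask
  if (kind == "curved" && sag_mm > 0) {
    # smooth posterior sag: backward-warp so the posterior surface moves
    # toward the bed, most at the lateral centre
    gx <- exp(-(co[[1]] / 60)^2)
    ymax_mm <- max(co[[2]][apply(body_mask, 2, any)])
    y0 <- 0.7 * ymax_mm   # only the posterior shell moves; organs stay put
    hy <- pmin(1, pmax(0, (co[[2]] - y0) / (ymax_mm - y0)))^2
    u <- array(0, dim = c(sh, 3))
    u[, , , 2] <- array(rep(outer(gx, hy), sh[3]), dim = sh) * (-sag_mm)
    fld <- dvf_field(u, sp)
    vol <- cpp_warp(vol, fld$field, sp, 0L)
    bm <- cpp_warp(array(as.double(body_mask), sh), fld$field, sp, 1L) > 0.5
  }
  ymax_idx <- max(which(apply(bm, 2, any)))
  gap_vox <- ceiling(gap_mm / sp[2]) + 1L  # air rows >= gap_mm between body and couch
  y_top <- ymax_idx + gap_vox
  if (y_top + ceiling(thickness_mm / sp[2]) > sh[2])
    stop("couch does not fit inside the grid behind the body")
  xs <- co[[1]]
  width <- 0.85 * max(abs(xs))
  couch <- array(FALSE, dim = sh)
  th_vox <- ceiling(thickness_mm / sp[2])
  for (i in seq_len(sh[1])) {
    if (abs(xs[i]) > width) next
    off <- if (kind == "curved")
      round(curve_depth_mm / sp[2] * (1 - (xs[i] / width)^2)) else 0L
    ys <- (y_top + off):min(sh[2], y_top + off + th_vox - 1L)
    couch[i, ys, ] <- TRUE
  }
  if (any(couch & bm)) stop("couch would overlap the body interior")
  vol[couch] <- couch_hu
  list(volume = image_volume(vol, sp, volume$origin),
       couch_mask = couch, body_mask = bm)
}

#' Add contrast enhancement inside a vessel mask
#'
#' Raises HU by `delta` inside `vessel_mask` — a failure-mode fixture
#' emulating intravenous contrast present on diagnostic but not planning
#' scans.
#'
#' @param volume an [image_volume()].
#' @param vessel_mask logical array on the volume grid.
#' @param delta HU increase (default +200).
#' @return the modified [image_volume()].
#' @export
add_contrast <- function(volume, vessel_mask, delta = 200) {
  vol_check(volume)
  if (!identical(dim(vessel_mask), dim(volume$data)))
    stop("vessel mask does not match volume grid")
  v <- volume$data
  v[vessel_mask] <- v[vessel_mask] + delta
  image_volume(v, volume$spacing, volume$origin)
}

#' Truncate the lateral field of view
#'
#' Crops the outer lateral fraction of the reconstructed field of view,
#' split evenly between both sides, so that anatomy wider than the
#' remaining FOV is cut off at the image boundary — the appearance of a
#' truncated acquisition, and a failure-mode fixture for the truncation QA
#' check.
#'
#' @param volume an [image_volume()].
#' @param fraction total fraction of the lateral FOV removed, in \[0, 0.3\].
#' @return the truncated [image_volume()] (lateral axis shortened).
#' @export
truncate_fov <- function(volume, fraction) {
  vol_check(volume)
  if (fraction < 0 || fraction > 0.3) stop("fraction must be in [0, 0.3]")
  if (fraction == 0) return(volume)
  v <- volume$data
  nx <- dim(v)[1]
  ncut <- round(nx * fraction / 2)
  if (ncut == 0) return(volume)
  keep <- (ncut + 1):(nx - ncut)
  origin <- volume$origin
  origin[1] <- origin[1] + ncut * volume$spacing[1]
  image_volume(v[keep, , , drop = FALSE], volume$spacing, origin)
}

#' Smooth deformation specification
#'
#' A ground-truth displacement field is a sum of Gaussian-windowed
#' displacement blobs. Keeping the maximum amplitude below the minimum blob
#' width keeps the field smooth and invertible (positive Jacobian
#' determinant).
#'
#' @param n_blobs number of Gaussian displacement blobs.
#' @param amplitude_mm length-2 range of blob displacement magnitudes (mm).
#' @param width_mm length-2 range of blob Gaussian widths (mm).
#' @param random_seed seed.
#' @return a `deformation_spec` list.
#' @export
deformation_spec <- function(n_blobs = 3, amplitude_mm = c(2, 5),
                             width_mm = c(20, 40), random_seed = 1L) {
  if (max(amplitude_mm) >= min(width_mm))
    stop("maximum amplitude must stay below the minimum blob width (folding risk)")
  structure(list(n_blobs = as.integer(n_blobs),
                 amplitude_mm = amplitude_mm, width_mm = width_mm,
                 random_seed = as.integer(random_seed)),
            class = "deformation_spec")
}

#' Generate a smooth ground-truth displacement field
#'
#' @param spec a [deformation_spec()].
#' @param grid an [image_volume()], or a list with `dim` and `spacing`.
#' @return a [dvf_field()] with max displacement magnitude bounded by the
#'   spec's maximum amplitude.
#' @export
make_smooth_dvf <- function(spec, grid) {
  if (inherits(grid, "image_volume")) grid <- list(dim = dim(grid$data), spacing = grid$spacing)
  sh <- as.integer(grid$dim); sp <- as.numeric(grid$spacing)
  if (any(sh <= 0)) stop("grid dimensions must be positive")
  u <- array(0, dim = c(sh, 3))
  if (spec$n_blobs > 0) {
    co <- grid_coords(sh, sp)
    X <- array(rep(co[[1]], times = sh[2] * sh[3]), dim = sh)
    Y <- array(rep(rep(co[[2]], each = sh[1]), times = sh[3]), dim = sh)
    Z <- array(rep(co[[3]], each = sh[1] * sh[2]), dim = sh)
    blobs <- with_seed(spec$random_seed, {
      lapply(seq_len(spec$n_blobs), function(j) {
        ctr <- sapply(1:3, function(a) runif(1, 0.7 * min(co[[a]]), 0.7 * max(co[[a]])))
        dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
        amp <- runif(1, spec$amplitude_mm[1], spec$amplitude_mm[2])
        sig <- runif(1, spec$width_mm[1], spec$width_mm[2])
        list(ctr = ctr, a = dir * amp, sig = sig)
      })
    })
    for (b in blobs) {
      g <- exp(-((X - b$ctr[1])^2 + (Y - b$ctr[2])^2 + (Z - b$ctr[3])^2) /
                 (2 * b$sig^2))
      for (d in 1:3) u[, , , d] <- u[, , , d] + b$a[d] * g
    }
    mag <- sqrt(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2)
    mmax <- max(mag)
    bound <- max(spec$amplitude_mm)
    if (mmax > bound) u <- u * (bound / mmax)
  }
  dvf_field(u, sp)
}

#' Dose field specification
#'
#' Geometric photon- or proton-like dose model: the target receives the
#' prescription; outside it the dose falls off with Gaussian widths along
#' the beam axis (proximal/distal) and laterally, plus an entrance-dose
#' plateau on the proximal side. The proton kind has a sharp distal falloff
#' and zero dose beyond a distal margin. This is a controllable stand-in
#' for optimized treatment plans, not beam physics.
#'
#' @param modality "photon" or "proton".
#' @param prescription_gy prescription dose (Gy).
#' @param target name of the target mask (default "ctv").
#' @param falloff_mm Gaussian widths c(proximal, lateral, distal) in mm.
#' @param entrance_frac entrance-dose fraction on the proximal side (0-1).
#' @param beam_axis axis the beam travels along: "x", "y" or "z".
#' @param beam_from "high" (enters from the high-coordinate side) or "low".
#' @param distal_margin_mm dose is zero beyond this distance past the distal
#'   target edge (proton default 15 mm; Inf for photons).
#' @return a `dose_spec` list.
#' @export
dose_spec <- function(modality = c("photon", "proton"),
                      prescription_gy = 60, target = "ctv",
                      falloff_mm = NULL, entrance_frac = NULL,
                      beam_axis = "z", beam_from = "high",
                      distal_margin_mm = NULL) {
  modality <- match.arg(modality)
  if (is.null(falloff_mm))
    falloff_mm <- if (modality == "photon") c(80, 30, 60) else c(30, 10, 6)
  if (is.null(distal_margin_mm))
    distal_margin_mm <- if (modality == "photon") Inf else 18
  if (is.null(entrance_frac)) entrance_frac <- if (modality == "photon") 0.45 else 0.35
  if (prescription_gy < 0) stop("prescription must be non-negative")
  if (entrance_frac < 0 || entrance_frac > 1) stop("entrance_frac must be in [0, 1]")
  structure(list(modality = modality, prescription_gy = prescription_gy,
                 target = target, falloff_mm = falloff_mm,
                 entrance_frac = entrance_frac, beam_axis = beam_axis,
                 beam_from = beam_from, distal_margin_mm = distal_margin_mm),
            class = "dose_spec")
}

#' Photon/proton dose-spec pair with a controlled preference
#'
#' Returns a pair of [dose_spec()]s engineered so that organ-at-risk doses
#' (hence NTCP differences, proton minus photon) have a known sign:
#' `"proton"`-favoring pairs use the sharp proton falloff; `"photon"`-favoring
#' pairs widen the proton lateral/entrance dose so the photon plan spares
#' the organs at risk instead.
#'
#' @param favor "proton" or "photon".
#' @param prescription_gy prescription dose (Gy).
#' @param ... passed to both [dose_spec()]s.
#' @return list with elements `photon` and `proton`.
#' @export
dose_spec_pair <- function(favor = c("proton", "photon"),
                           prescription_gy = 60, ...) {
  favor <- match.arg(favor)
  if (favor == "proton") {
    list(photon = dose_spec("photon", prescription_gy, ...),
         proton = dose_spec("proton", prescription_gy, ...))
  } else {
    list(photon = dose_spec("photon", prescription_gy,
                            falloff_mm = c(25, 10, 12), entrance_frac = 0.1, ...),
         proton = dose_spec("proton", prescription_gy,
                            falloff_mm = c(90, 45, 50), entrance_frac = 0.9,
                            distal_margin_mm = 300, ...))
  }
}

#' Generate a dose field from structure masks
#'
#' @param masks named list of logical arrays (must contain the target).
#' @param spec a [dose_spec()].
#' @param spacing voxel spacing in mm.
#' @return an [image_volume()] holding dose in Gy.
#' @export
make_dose <- function(masks, spec, spacing) {
  target <- masks[[spec$target]]
  if (is.null(target) || !any(target)) stop("empty or missing target mask")
  sh <- dim(target); sp <- as.numeric(spacing)
  rx <- spec$prescription_gy
  if (rx == 0) return(image_volume(array(0, dim = sh), sp))
  ax <- match(spec$beam_axis, c("x", "y", "z"))
  co <- grid_coords(sh, sp)
  a_mm <- co[[ax]]
  idx <- which(target, arr.ind = TRUE)
  t_rng <- range(a_mm[idx[, ax]])
  # lateral distance to the target's shadow along the beam axis
  other <- setdiff(1:3, ax)
  shadow <- apply(target, other, any)
  sh2 <- dim(shadow)
  shadow3 <- array(shadow, dim = c(sh2, 1L))
  lat2 <- cpp_edt(shadow3, c(sp[other], 1))[, , 1]
  sig <- spec$falloff_mm
  # longitudinal factor per axis position
  if (spec$beam_from == "high") {
    dp <- pmax(0, a_mm - t_rng[2])   # proximal: beyond high edge
    dd <- pmax(0, t_rng[1] - a_mm)   # distal: beyond low edge
  } else {
    dp <- pmax(0, t_rng[1] - a_mm)
    dd <- pmax(0, a_mm - t_rng[2])
  }
  flong <- ifelse(dp > 0,
                  spec$entrance_frac + (1 - spec$entrance_frac) * exp(-0.5 * (dp / sig[1])^2),
                  exp(-0.5 * (dd / sig[3])^2))
  flong[dd > spec$distal_margin_mm] <- 0
  flat2 <- exp(-0.5 * (lat2 / sig[2])^2)
  dose_p <- outer(flat2, flong)          # dims (other1, other2, ax)
  perm <- match(1:3, c(other, ax))
  dose <- aperm(dose_p, perm) * rx
  dose[target] <- rx
  image_volume(dose, sp)
}
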