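#' Remove the couch and extract the body
#'
#' Thresholding plus morphological closing: the body mask is the largest 3D
#' connected component of voxels above `air_threshold` after closing with a
#' ball of `closing_radius_mm` and hole filling; everything outside is set
#' to air (-1000 HU). Raises a truncation QA flag (attribute, not an error)
#' when the body mask touches two or more of the four lateral volume faces,
#' the signature of a laterally cut-off acquisition.
#'
#' @param volume an [image_volume()] in HU.
#' @param air_threshold HU threshold separating tissue from air/couch gap.
#' @param closing_radius_mm morphological closing radius (mm).
#' @param qa_min_faces number of touched lateral faces that raises the
#'   truncation flag (default 2: symmetric lateral truncation clips both
#'   lateral faces).
#' @return list with `volume` (couch-free), `body_mask`, and `qa` (list with
#'   logical `truncation`).
#' @export
remove_couch <- function(volume, air_threshold = -250, closing_radius_mm = 5,
                         qa_min_faces = 2) {
  vol_check(volume)
  v <- volume$data
  sh <- dim(v); sp <- volume$spacing
  fg <- v > air_threshold
  if (!any(fg)) stop("no voxels above the air threshold; not a CT of a body?")
  closed <- morph_close(fg, sp, closing_radius_mm)
  lab <- cpp_label3d(closed)
  if (max(lab) == 0) stop("no connected component above threshold")
  sizes <- tabulate(lab[lab > 0])
  body <- array(lab == which.max(sizes), dim = sh)
  body <- fill_holes3d(body)
  # keep only thresholded tissue within the closed component, then the couch
  # (a separate component) is gone and internal air (lungs) is retained
  out <- v
  out[!body] <- -1000
  faces <- c(any(body[1, , ]), any(body[sh[1], , ]),
             any(body[, 1, ]), any(body[, sh[2], ]))
  qa <- list(truncation = sum(faces) >= qa_min_faces)
  if (qa$truncation)
    warning("truncation QA flag: body mask touches ", sum(faces),
            " lateral volume face(s)")
  list(volume = image_volume(out, sp, volume$origin), body_mask = body, qa = qa)
}

# binary closing with an approximately spherical structuring element,
# realized with two Euclidean distance transforms
morph_close <- function(mask, spacing, radius_mm) {
  if (radius_mm <= 0) return(mask)
  dil <- cpp_edt(mask, spacing) <= radius_mm
  er <- array(cpp_edt(!dil, spacing) > radius_mm, dim = dim(mask))
  mask | er  # closing is extensive: never erode the original foreground
}

# fill internal cavities: background components not connected to the border
fill_holes3d <- function(mask) {
  sh <- dim(mask)
  lab <- cpp_label3d(!mask)
  border_labels <- unique(c(lab[1, , ], lab[sh[1], , ], lab[, 1, ], lab[, sh[2], ],
                            lab[, , 1], lab[, , sh[3]]))
  border_labels <- border_labels[border_labels > 0]
  filled <- mask | (lab > 0 & !(lab %in% border_labels))
  array(filled, dim = sh)
}

#' Histogram-matching HU look-up table
#'
#' Classical histogram matching restricted to body voxels: each source
#' quantile maps to the reference HU at the same quantile. The resulting
#' LUT is monotone non-decreasing and covers \[-1024, 3071\].
#'
#' @param source,reference [image_volume()]s (couch-removed).
#' @param source_mask,reference_mask logical body masks.
#' @param n_bins number of LUT bins (>= 64).
#' @return a `hu_lut` list with `centers`, `values`, `bin_width` and
#'   `occupied` (which bins contain source mass).
#' @export
build_hu_lut <- function(source, reference, source_mask, reference_mask,
                         n_bins = 256) {
  vol_check(source); vol_check(reference)
  if (n_bins < 64) stop("n_bins must be at least 64")
  sv <- source$data[source_mask]
  rv <- reference$data[reference_mask]
  if (length(sv) == 0 || length(rv) == 0) stop("empty body mask")
  # bins span the occupied source range (bin width adapts to the data);
  # outside it quantile matching is undefined and the map falls back to
  # identity, so the LUT domain still covers all of [-1024, 3071] and air
  # stays air
  lo <- min(sv); hi <- max(sv)
  if (hi <= lo) stop("source body histogram is degenerate (constant)")
  bw <- (hi - lo) / n_bins
  centers <- lo + bw * (seq_len(n_bins) - 0.5)
  # each bin maps at its mid-mass quantile (mean of the ECDF at the two bin
  # edges): an occupied bin then maps onto the reference value of its own
  # central rank, and the inverse-ECDF quantile (type 1) returns actual
  # reference HU values, never interpolating across empty histogram gaps
  F_ <- ecdf(sv)
  Fs <- (F_(centers - bw / 2) + F_(centers + bw / 2)) / 2
  values <- as.numeric(quantile(rv, probs = Fs, type = 1, names = FALSE))
  # bins that actually contain source mass; in empty interior gaps the
  # mapping is a monotone bridge with no voxels to apply it to
  occupied <- tabulate(findInterval(sv, lo + bw * (0:n_bins),
                                    rightmost.closed = TRUE,
                                    all.inside = TRUE), nbins = n_bins) > 0
  centers <- c(-1024, lo - bw, centers, hi + bw, 3071)
  values <- c(-1024, lo - bw, values, hi + bw, 3071)
  occupied <- c(FALSE, FALSE, occupied, FALSE, FALSE)
  values <- cummax(values)  # enforce monotonicity against quantile ties
  structure(list(centers = centers, values = values, bin_width = bw,
                 occupied = occupied),
            class = "hu_lut")
}

#' Apply a HU look-up table
#'
#' Per-voxel lookup with linear interpolation between bin centers; HU
#' outside the LUT domain are clamped to the end values.
#'
#' @param volume an [image_volume()].
#' @param lut a `hu_lut` from [build_hu_lut()].
#' @return the mapped [image_volume()].
#' @export
apply_lut <- function(volume, lut) {
  vol_check(volume)
  if (!inherits(lut, "hu_lut")) stop("`lut` must be a hu_lut")
  if (is.unsorted(lut$values)) stop("LUT must be monotone")
  v <- approx(lut$centers, lut$values, xout = as.vector(volume$data),
              rule = 2)$y
  image_volume(array(v, dim = dim(volume$data)), volume$spacing, volume$origin)
}

#' Rigid (translation-only) alignment by NCC search
#'
#' Initializes at the body-mask centroid difference, then refines with an
#' exhaustive ±10 mm search (2 mm steps) and a ±2 mm local search (0.5 mm
#' steps), maximizing normalized cross-correlation over the fixed body
#' mask. Rotation is assumed negligible for supine thorax scans.
#'
#' @param moving,fixed couch-removed [image_volume()]s on the same grid.
#' @param moving_mask,fixed_mask body masks.
#' @param coarse_range_mm,coarse_step_mm,fine_step_mm search parameters.
#' @return list with `volume` (aligned moving), `translation_mm`, and the
#'   NCC before/after.
#' @export
rigid_align <- function(moving, fixed, moving_mask, fixed_mask,
                        coarse_range_mm = 10, coarse_step_mm = 2,
                        fine_step_mm = 0.5) {
  vol_check(moving); vol_check(fixed)
  stop_unless_same_grid(moving, fixed)
  sp <- fixed$spacing
  sh <- dim(fixed$data)
  centroid <- function(m) {
    idx <- which(m, arr.ind = TRUE)
    colMeans(idx) * sp
  }
  t0 <- centroid(fixed_mask) - centroid(moving_mask)
  # score only voxels whose samples stay in-grid over the whole search range,
  # so border padding cannot bias the optimum (the body often spans the full
  # z extent); translation during scoring clamps at the border for the same
  # reason
  strip <- ceiling((coarse_range_mm + 2) / sp) + 1L
  interior <- array(FALSE, dim = sh)
  interior[(strip[1] + 1):(sh[1] - strip[1]),
           (strip[2] + 1):(sh[2] - strip[2]),
           (strip[3] + 1):(sh[3] - strip[3])] <- TRUE
  region <- which(fixed_mask & interior)
  if (length(region) == 0) region <- which(fixed_mask)
  fx <- fixed$data[region]
  fx <- fx - mean(fx)
  fxn <- sqrt(sum(fx^2))
  ncc_at <- function(t_mm) {
    shifted <- translate_volume(moving, t_mm, border = "clamp")
    mv <- shifted$data[region]
    mv <- mv - mean(mv)
    den <- sqrt(sum(mv^2)) * fxn
    if (den == 0) return(-1)
    sum(mv * fx) / den
  }
  search <- function(center, range, step) {
    offs <- seq(-range, range, by = step)
    best <- c(ncc = -2, t = c(0, 0, 0))
    best_t <- center; best_v <- -2
    for (dx in offs) for (dy in offs) for (dz in offs) {
      t_try <- center + c(dx, dy, dz)
      v <- ncc_at(t_try)
      if (v > best_v) { best_v <- v; best_t <- t_try }
    }
    list(t = best_t, ncc = best_v, at_boundary = any(abs(best_t - center) >= range - 1e-9))
  }
  coarse <- search(t0, coarse_range_mm, coarse_step_mm)
  fine <- search(coarse$t, 2, fine_step_mm)
  if (coarse$at_boundary)
    warning("NCC search ended on the coarse search boundary; possible gross misalignment")
  ncc0 <- ncc_at(c(0, 0, 0))
  out <- translate_volume(moving, fine$t)
  list(volume = out, translation_mm = fine$t, ncc_before = ncc0,
       ncc_after = fine$ncc)
}

#' Translate a volume by a world-space offset
#'
#' @param volume an [image_volume()].
#' @param t_mm translation in mm; output voxel x takes the value of the
#'   input at x - t.
#' @param method "trilinear" or "nearest".
#' @param pad fill value outside the grid.
#' @param border "pad" fills out-of-grid samples with `pad`; "clamp" repeats
#'   the border value.
#' @return the translated [image_volume()].
#' @export
translate_volume <- function(volume, t_mm, method = "trilinear", pad = -1000,
                             border = c("pad", "clamp")) {
  border <- match.arg(border)
  vol_check(volume)
  sh <- dim(volume$data)
  M <- diag(3)
  tv <- -as.numeric(t_mm) / volume$spacing
  out <- cpp_affine_sample(volume$data, as.integer(sh), M, tv,
                           if (method == "nearest") 1L else 0L, pad,
                           if (border == "clamp") 1L else 0L)
  image_volume(out, volume$spacing, volume$origin)
}

#' Resample a volume to a target grid shape
#'
#' Trilinear interpolation onto a grid spanning the same physical extent;
#' spacing is rescaled so the extent is preserved.
#'
#' @param volume an [image_volume()].
#' @param target_shape integer length-3 (default 128 x 128 x 64).
#' @param method "trilinear" (volumes) or "nearest" (masks).
#' @return the resampled [image_volume()].
#' @export
resample_volume <- function(volume, target_shape = c(128, 128, 64),
                            method = "trilinear") {
  vol_check(volume)
  target_shape <- as.integer(target_shape)
  if (any(target_shape <= 0)) stop("target shape must be positive")
  sh <- dim(volume$data)
  if (identical(sh, target_shape)) return(volume)
  scale <- sh / target_shape
  M <- diag(scale)
  t <- (scale - 1) / 2
  out <- cpp_affine_sample(volume$data, target_shape, M, t,
                           if (method == "nearest") 1L else 0L, -1000, 1L)
  image_volume(out, volume$spacing * scale, volume$origin)
}

#' Resample a mask (nearest neighbor)
#' @param mask logical array.
#' @param spacing its voxel spacing (mm).
#' @param target_shape target grid shape.
#' @return logical array on the target grid.
#' @export
resample_mask <- function(mask, spacing, target_shape) {
  v <- resample_volume(image_volume(array(as.double(mask), dim = dim(mask)), spacing),
                       target_shape, method = "nearest")
  array(v$data > 0.5, dim = dim(v$data))
}

#' Training augmentation: in-plane rotation or horizontal flip
#'
#' `rot45cw` rotates axial slices clockwise by 45 degrees (viewer
#' convention) with air padding; `hflip` mirrors left-right. Apply the same
#' operation jointly to a (dCT, pCT) pair and its masks (`nearest` for
#' masks keeps them binary).
#'
#' @param volume an [image_volume()].
#' @param op "rot45cw" or "hflip".
#' @param method "trilinear" or "nearest".
#' @param pad fill value for voxels rotated in from outside.
#' @param angle_deg rotation angle (clockwise, default 45).
#' @return the augmented [image_volume()].
#' @export
augment <- function(volume, op = c("rot45cw", "hflip"), method = "trilinear",
                    pad = -1000, angle_deg = 45) {
  op <- match.arg(op)
  vol_check(volume)
  sh <- dim(volume$data)
  if (op == "hflip") {
    out <- volume$data[rev(seq_len(sh[1])), , , drop = FALSE]
    return(image_volume(array(out, dim = sh), volume$spacing, volume$origin))
  }
  th <- -angle_deg * pi / 180  # clockwise in the axial viewer
  cx <- (sh[1] - 1) / 2; cy <- (sh[2] - 1) / 2
  M <- diag(3)
  M[1, 1] <- cos(th); M[1, 2] <- -sin(th)
  M[2, 1] <- sin(th); M[2, 2] <- cos(th)
  t <- c(cx - M[1, 1] * cx - M[1, 2] * cy,
         cy - M[2, 1] * cx - M[2, 2] * cy, 0)
  out <- cpp_affine_sample(volume$data, as.integer(sh), M, t,
                           if (method == "nearest") 1L else 0L, pad, 0L)
  image_volume(out, volume$spacing, volume$origin)
}
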