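#' Cumulative dose-volume histogram of a structure
#'
#' Bins the voxel dose multiset inside the mask on a uniform grid and
#' records the fraction of the structure volume receiving at least each bin
#' edge dose. The curve starts at 1 at 0 Gy, is non-increasing, and reaches
#' 0 above the maximum dose.
#'
#' @param dose an [image_volume()] in Gy.
#' @param mask logical array on the dose grid.
#' @param bin_width dose bin width in Gy (default 0.1).
#' @param structure optional structure name carried in the result.
#' @return a `dvh_curve`: `edges` (Gy), `cum` (fraction >= edge),
#'   `bin_width`, `structure`, `total_cc`, plus the voxel `mean` and `max`.
#' @export
compute_dvh <- function(dose, mask, bin_width = 0.1, structure = "structure") {
  vol_check(dose)
  if (!identical(dim(mask), dim(dose$data)))
    stop("dose and mask grids do not match")
  d <- dose$data[mask]
  if (length(d) == 0) stop("empty structure mask")
  if (any(d < 0)) stop("negative dose")
  dmax <- max(d)
  edges <- seq(0, (floor(dmax / bin_width) + 1) * bin_width, by = bin_width)
  cum <- vapply(edges, function(e) mean(d >= e), numeric(1))
  vox_cc <- prod(dose$spacing) / 1000
  structure(list(edges = edges, cum = cum, bin_width = bin_width,
                 structure = structure, total_cc = length(d) * vox_cc,
                 mean = mean(d), max = dmax),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve> %s: %.1f cc, mean %.2f Gy, max %.2f Gy, %d bins\n",
              x$structure, x$total_cc, x$mean, x$max, length(x$edges)))
  invisible(x)
}

# differential DVH: fractional volume per bin and bin-centre dose
dvh_differential <- function(curve) {
  nb <- length(curve$edges) - 1
  v <- curve$cum[seq_len(nb)] - curve$cum[seq_len(nb) + 1]
  d <- (curve$edges[seq_len(nb)] + curve$edges[seq_len(nb) + 1]) / 2
  keep <- v > 0
  list(v = v[keep], d = d[keep])
}

#' DVH metrics: mean, max, VxGy
#'
#' `mean` is computed from the differential form of the curve; `max` is the
#' centre of the highest occupied bin; `VxGy` is the cumulative volume
#' fraction at dose x (volume receiving >= x Gy), in percent, with linear
#' interpolation between bin edges.
#'
#' @param curve a `dvh_curve`.
#' @param kind "mean", "max" or "vxgy".
#' @param x threshold dose in Gy for `vxgy` (>= 0).
#' @return the metric value (Gy for mean/max, % for VxGy).
#' @export
dvh_metric <- function(curve, kind = c("mean", "max", "vxgy"), x = NULL) {
  kind <- match.arg(kind)
  if (kind == "mean") {
    df <- dvh_differential(curve)
    return(sum(df$v * df$d))
  }
  if (kind == "max") {
    df <- dvh_differential(curve)
    return(max(df$d))
  }
  if (is.null(x) || x < 0) stop("VxGy needs a threshold x >= 0")
  if (x >= max(curve$edges)) return(0)
  100 * approx(curve$edges, curve$cum, xout = x, rule = 2)$y
}

#' Organ-at-risk DVH metric panel
#'
#' The thoracic panel: esophagus (mean, V35Gy, V60Gy), total lung (mean,
#' V10Gy, V20Gy), heart (mean, max, V30Gy).
#'
#' @param dose an [image_volume()] in Gy.
#' @param masks named list with `esophagus`, `lung_total` and `heart`.
#' @param bin_width DVH bin width (Gy).
#' @return named numeric vector of the nine metrics
#'   (`<structure>.<metric>`).
#' @export
oar_panel <- function(dose, masks, bin_width = 0.1) {
  need <- c("esophagus", "lung_total", "heart")
  if (!all(need %in% names(masks)))
    stop("masks must include esophagus, lung_total and heart")
  curves <- lapply(need, function(s) compute_dvh(dose, masks[[s]], bin_width, s))
  names(curves) <- need
  c(esophagus.mean  = dvh_metric(curves$esophagus, "mean"),
    esophagus.v35gy = dvh_metric(curves$esophagus, "vxgy", 35),
    esophagus.v60gy = dvh_metric(curves$esophagus, "vxgy", 60),
    lung_total.mean = dvh_metric(curves$lung_total, "mean"),
    lung_total.v10gy = dvh_metric(curves$lung_total, "vxgy", 10),
    lung_total.v20gy = dvh_metric(curves$lung_total, "vxgy", 20),
    heart.mean = dvh_metric(curves$heart, "mean"),
    heart.max  = dvh_metric(curves$heart, "max"),
    heart.v30gy = dvh_metric(curves$heart, "vxgy", 30))
}

#' Proton-photon DVH differences on synthetic and planning CT
#'
#' For each metric: the proton-minus-photon difference on the synthetic CT,
#' the same difference on the planning CT, their difference, and a
#' sign-concordance flag (zero is concordant with either sign).
#'
#' @param sct list with `proton` and `photon` metric panels computed on the
#'   synthetic CT (from [oar_panel()]).
#' @param pct same, computed on the planning CT.
#' @return data.frame with one row per metric: `metric`, `delta_sct`,
#'   `delta_pct`, `delta_diff`, `concordant`.
#' @export
delta_dvh_panel <- function(sct, pct) {
  m <- names(sct$proton)
  for (panel in list(sct$photon, pct$proton, pct$photon)) {
    miss <- setdiff(m, names(panel))
    if (length(miss))
      stop("metric sets do not match; missing: ", paste(miss, collapse = ", "))
  }
  d_sct <- sct$proton[m] - sct$photon[m]
  d_pct <- pct$proton[m] - pct$photon[m]
  data.frame(metric = m,
             delta_sct = as.numeric(d_sct),
             delta_pct = as.numeric(d_pct),
             delta_diff = as.numeric(d_sct - d_pct),
             concordant = sign(d_sct) == sign(d_pct) | d_sct == 0 | d_pct == 0,
             row.names = NULL)
}

#' Agreement summary over DVH differences
#'
#' @param deltas a data.frame from [delta_dvh_panel()] (rows from several
#'   cases may be concatenated).
#' @return list with the agreement `rate_pct`
#'   (concordant / total x 100), raw `n_concordant` / `n_total`, `ccc` of
#'   the paired differences, and `mean_abs_diff` of `delta_diff` per
#'   structure.
#' @export
agreement_summary <- function(deltas) {
  if (nrow(deltas) == 0) stop("no DVH differences to summarize")
  rate <- 100 * sum(deltas$concordant) / nrow(deltas)
  cc <- if (nrow(deltas) >= 2 &&
            !(var(deltas$delta_sct) == 0 && var(deltas$delta_pct) == 0))
    ccc(deltas$delta_sct, deltas$delta_pct) else NA_real_
  structure_of <- sub("\\..*$", "", deltas$metric)
  mad <- tapply(abs(deltas$delta_diff), structure_of, mean)
  list(rate_pct = rate, n_concordant = sum(deltas$concordant),
       n_total = nrow(deltas), ccc = cc,
       mean_abs_diff = as.list(mad))
}
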