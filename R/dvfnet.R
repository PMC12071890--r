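#' Network specification for the DVF-predicting encoder-decoder
#'
#' A fully convolutional 3D encoder-decoder with skip connections maps a
#' single-channel CT volume to a 3-channel displacement vector field (mm)
#' of the same spatial size. Each block is 3D convolution (3^3 kernel) +
#' per-volume batch normalization + leaky-ReLU; channel count doubles at
#' each encoding level; the output head is zero-initialized so the initial
#' prediction is the identity transform.
#'
#' @param levels number of resolution levels (2x pooling per level).
#' @param base_channels channels at the first level (doubles per level).
#' @param convs_per_block convolution blocks per level.
#' @param in_channels,out_channels fixed at 1 and 3.
#' @param normalization,activation descriptive; per-volume batch
#'   normalization and leaky-ReLU (slope 0.1) are implemented.
#' @param kernel 3D kernel size (fixed at 3).
#' @return a `network_spec` list.
#' @export
network_spec <- function(levels = 3, base_channels = 32, convs_per_block = 1,
                         in_channels = 1, out_channels = 3,
                         normalization = "batch", activation = "leaky_relu",
                         kernel = 3) {
  if (in_channels != 1 || out_channels != 3)
    stop("the network maps 1 input channel to a 3-component field")
  if (kernel != 3) stop("kernel size is fixed at 3")
  if (levels < 1 || base_channels < 1 || convs_per_block < 1)
    stop("levels, base_channels and convs_per_block must be positive")
  structure(list(levels = as.integer(levels),
                 base_channels = as.integer(base_channels),
                 convs_per_block = as.integer(convs_per_block),
                 in_channels = 1L, out_channels = 3L,
                 normalization = normalization, activation = activation,
                 kernel = 3L),
            class = "network_spec")
}

#' Training specification
#'
#' @param learning_rate Adam learning rate (default 1e-5).
#' @param batch_size volumes per optimizer step (default 2).
#' @param epochs training epochs (default 1500).
#' @param lambda weight of the displacement-gradient (diffusion)
#'   regularizer (default 0.01).
#' @param ssim_window SSIM window edge length in voxels (default 7).
#' @param hu_window HU range mapped to \[0, 1\] for the SSIM loss.
#' @param seed random seed for parameter initialization.
#' @return a `train_spec` list.
#' @export
train_spec <- function(learning_rate = 1e-5, batch_size = 2, epochs = 1500,
                       lambda = 0.01, ssim_window = 7,
                       hu_window = c(-1000, 1000), seed = 1L) {
  if (learning_rate <= 0) stop("learning rate must be positive")
  if (epochs < 1) stop("epochs must be >= 1")
  if (lambda < 0) stop("regularization weight must be non-negative")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lambda = lambda,
                 ssim_window = as.integer(ssim_window),
                 hu_window = as.numeric(hu_window), seed = as.integer(seed)),
            class = "train_spec")
}

#' Build (initialize) the network
#'
#' He-normal weights, unit-gain normalization parameters, and a
#' zero-initialized output head: an untrained model predicts the zero field,
#' so warping with it returns the input unchanged.
#'
#' @param spec a [network_spec()].
#' @param seed initialization seed.
#' @return a `dvf_model` with elements `spec` and `theta`.
#' @export
build_network <- function(spec = network_spec(), seed = 1L) {
  theta <- cpp_nn_init(spec$levels, spec$base_channels, spec$convs_per_block,
                       as.integer(seed))
  structure(list(spec = spec, theta = theta, history = numeric(0)),
            class = "dvf_model")
}

#' @export
print.dvf_model <- function(x, ...) {
  cat(sprintf("<dvf_model> %d levels, %d base channels, %d parameters%s\n",
              x$spec$levels, x$spec$base_channels, length(x$theta),
              if (length(x$history)) sprintf(", trained %d epochs", length(x$history)) else " (untrained)"))
  invisible(x)
}

check_shape_divisible <- function(shape, levels) {
  div <- 2^levels
  for (a in 1:3) {
    if (shape[a] %% div != 0)
      stop(sprintf("axis %s (size %d) is not divisible by 2^levels = %d",
                   c("x", "y", "z")[a], shape[a], div))
  }
  invisible(TRUE)
}

hu_normalize <- function(x, hu_window = c(-1000, 1000)) {
  pmin(pmax((x - hu_window[1]) / diff(hu_window), 0), 1)
}

#' Warp a volume with a displacement field
#'
#' Backward warping: the output at voxel x samples the input at
#' x + u(x) (u in mm, converted to voxels via the spacing); out-of-grid
#' samples take the border value. Use `nearest` for masks so they stay
#' binary.
#'
#' @param volume an [image_volume()].
#' @param dvf a [dvf_field()] on the same grid.
#' @param interpolation "trilinear" or "nearest".
#' @return the warped [image_volume()].
#' @export
warp_volume <- function(volume, dvf, interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  vol_check(volume)
  if (!inherits(dvf, "dvf_field")) stop("`dvf` must be a dvf_field")
  if (!identical(dim(volume$data), dim(dvf$field)[1:3]))
    stop("displacement field grid does not match the volume")
  out <- cpp_warp(volume$data, dvf$field, volume$spacing,
                  if (interpolation == "nearest") 1L else 0L)
  image_volume(out, volume$spacing, volume$origin)
}

#' Warp a mask with a displacement field (stays binary)
#' @param mask logical array.
#' @param dvf a [dvf_field()].
#' @param spacing voxel spacing in mm.
#' @return warped logical array.
#' @export
warp_mask <- function(mask, dvf, spacing) {
  v <- cpp_warp(array(as.double(mask), dim = dim(mask)), dvf$field, spacing, 1L)
  array(v > 0.5, dim = dim(mask))
}

#' Structural similarity between two volumes
#'
#' Mean over sliding 3D windows of the standard SSIM expression
#' (luminance x contrast x structure, stabilizing constants C1 = 0.01^2 and
#' C2 = 0.03^2 on the normalized scale). Intensities are first mapped from
#' `hu_window` to \[0, 1\].
#'
#' @param a,b [image_volume()]s on the same grid.
#' @param window window edge length in voxels.
#' @param hu_window HU range mapped to \[0, 1\].
#' @param normalize set FALSE if inputs are already on \[0, 1\].
#' @return SSIM in \[-1, 1\].
#' @export
ssim_volume <- function(a, b, window = 7, hu_window = c(-1000, 1000),
                        normalize = TRUE) {
  vol_check(a); vol_check(b)
  stop_unless_same_grid(a, b)
  an <- if (normalize) hu_normalize(a$data, hu_window) else a$data
  bn <- if (normalize) hu_normalize(b$data, hu_window) else b$data
  cpp_ssim(an, bn, as.integer(window), 0.01^2, 0.03^2)
}

#' Registration training loss
#'
#' `(1 - SSIM(warp(dct, dvf), pct)) + lambda * R(dvf)` where R is the mean
#' squared forward-difference spatial gradient of each displacement
#' component (diffusion regularizer).
#'
#' @param dct,pct [image_volume()]s on one grid.
#' @param dvf a [dvf_field()].
#' @param lambda regularization weight (>= 0).
#' @param window,hu_window see [ssim_volume()].
#' @return the scalar loss.
#' @export
dvf_loss <- function(dct, pct, dvf, lambda = 0.01, window = 7,
                     hu_window = c(-1000, 1000)) {
  if (lambda < 0) stop("lambda must be non-negative")
  warped <- warp_volume(dct, dvf)
  (1 - ssim_volume(warped, pct, window, hu_window)) +
    lambda * cpp_reg_value(dvf$field)
}

#' Train the DVF network
#'
#' Minimizes the mean registration loss over (dCT, pCT) pairs with Adam.
#' Training is deterministic given the data, the model initialization and
#' the training spec (fixed batch order, per-volume normalization
#' statistics).
#'
#' @param pairs list of `list(dct = , pct = )` [image_volume()] pairs, all
#'   on one grid with shape divisible by `2^levels`.
#' @param model a `dvf_model` from [build_network()].
#' @param tspec a [train_spec()].
#' @return the trained `dvf_model`, with per-epoch `history` of the mean
#'   loss.
#' @export
train_dvfnet <- function(pairs, model, tspec = train_spec()) {
  if (length(pairs) < 1) stop("need at least one training pair")
  sh <- dim(pairs[[1]]$dct$data)
  sp <- pairs[[1]]$dct$spacing
  check_shape_divisible(sh, model$spec$levels)
  for (p in pairs) {
    stop_unless_same_grid(p$dct, p$pct, "dct/pct pair")
    if (!identical(dim(p$dct$data), sh)) stop("all pairs must share one shape")
  }
  fit <- cpp_nn_train(model$spec$levels, model$spec$base_channels,
                      model$spec$convs_per_block, model$theta,
                      lapply(pairs, function(p) p$dct$data),
                      lapply(pairs, function(p) p$pct$data),
                      sp, tspec$learning_rate, tspec$epochs, tspec$lambda,
                      tspec$ssim_window, tspec$batch_size,
                      tspec$hu_window[1], tspec$hu_window[2],
                      0.01^2, 0.03^2)
  model$theta <- fit$theta
  model$history <- c(model$history, fit$history)
  model$train_spec <- tspec
  model
}

#' Predict a synthetic CT (and its DVF) from a diagnostic CT
#'
#' Runs the network on the (preprocessed: couch-removed, HU-normalized,
#' resampled) dCT, then warps the dCT with the predicted field. The DVF is
#' returned as well so contours can be mapped onto the synthetic CT. If
#' `predict_shape` is given, the field is predicted at that (coarser) grid
#' and upsampled trilinearly to the native grid before warping — mm units
#' make the field resolution-independent.
#'
#' @param dct an [image_volume()] in HU.
#' @param model a `dvf_model`.
#' @param hu_window HU range mapped to \[0, 1\] for the network input.
#' @param predict_shape optional grid shape for network inference.
#' @return list with `sct` ([image_volume()]) and `dvf` ([dvf_field()]).
#' @export
predict_sct <- function(dct, model, hu_window = c(-1000, 1000),
                        predict_shape = NULL) {
  vol_check(dct)
  sh <- dim(dct$data)
  if (is.null(predict_shape)) {
    check_shape_divisible(sh, model$spec$levels)
    xn <- array(hu_normalize(dct$data, hu_window), dim = sh)
    fld <- cpp_nn_forward(model$spec$levels, model$spec$base_channels,
                          model$spec$convs_per_block, model$theta, xn)
    dvf <- dvf_field(fld, dct$spacing, dct$origin)
  } else {
    small <- resample_volume(dct, predict_shape)
    pred <- predict_sct(small, model, hu_window)
    dvf <- upsample_dvf(pred$dvf, sh, dct$spacing)
  }
  sct <- warp_volume(dct, dvf)
  list(sct = sct, dvf = dvf)
}

# trilinear upsampling of a displacement field to a finer grid spanning the
# same extent; displacement values are mm, so only the grid changes
upsample_dvf <- function(dvf, target_shape, target_spacing) {
  shs <- dim(dvf$field)[1:3]
  comps <- lapply(1:3, function(d) {
    v <- image_volume(array(dvf$field[, , , d], dim = shs), dvf$spacing)
    resample_volume(v, target_shape)$data
  })
  fld <- array(0, dim = c(target_shape, 3))
  for (d in 1:3) fld[, , , d] <- comps[[d]]
  dvf_field(fld, target_spacing, dvf$origin)
}

#' Save / load a model checkpoint
#'
#' A checkpoint directory holds a JSON manifest (network and training spec)
#' plus the flat parameter vector as plain text.
#'
#' @param model a `dvf_model`.
#' @param dir checkpoint directory.
#' @return `load_model()` returns the `dvf_model`.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(spec = unclass(model$spec),
                   train_spec = if (!is.null(model$train_spec)) unclass(model$train_spec),
                   n_params = length(model$theta),
                   history = model$history)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(sprintf("%.17g", model$theta), file.path(dir, "theta.txt"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  spec <- do.call(network_spec, manifest$spec[c("levels", "base_channels",
                                                "convs_per_block")])
  theta <- as.numeric(readLines(file.path(dir, "theta.txt")))
  if (length(theta) != manifest$n_params) stop("corrupt checkpoint")
  structure(list(spec = spec, theta = theta,
                 history = as.numeric(manifest$history)),
            class = "dvf_model")
}
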