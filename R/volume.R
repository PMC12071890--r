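#' 3D image volume
#'
#' Container for a 3D scalar grid (CT in Hounsfield units, or dose in Gy)
#' with voxel spacing and world origin. World coordinate of voxel index
#' `(i, j, k)` (1-based) is `origin + (index - 1) * spacing`.
#'
#' @param data 3D numeric array.
#' @param spacing voxel spacing in mm, length 3, all positive.
#' @param origin world coordinate of the first voxel centre, length 3 (mm).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive values (mm)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("`origin` must have length 3")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing %s mm, range [%.1f, %.1f]\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

vol_check <- function(x, name = "volume") {
  if (!inherits(x, "image_volume")) stop(sprintf("`%s` must be an image_volume", name))
  x
}

same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-6))
}

stop_unless_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a, b)) stop(sprintf("%s are not on the same grid", what))
  invisible(TRUE)
}

#' Displacement vector field
#'
#' Per-voxel 3-vector displacement in mm on the same grid as its volume,
#' stored as a 4D array (`nx x ny x nz x 3`). A backward warp samples the
#' input at `x + u(x)`.
#'
#' @param field 4D numeric array, last dimension 3 (x, y, z components, mm).
#' @param spacing,origin grid metadata, as in [image_volume()].
#' @return An object of class `dvf_field`.
#' @export
dvf_field <- function(field, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(field) || length(dim(field)) != 4L || dim(field)[4] != 3L)
    stop("`field` must be a 4D array with 3 components in the last dimension")
  if (any(!is.finite(field))) stop("displacement field must be finite everywhere")
  structure(list(field = field, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "dvf_field")
}

#' @export
print.dvf_field <- function(x, ...) {
  d <- dim(x$field)
  mag <- sqrt(x$field[, , , 1]^2 + x$field[, , , 2]^2 + x$field[, , , 3]^2)
  cat(sprintf("<dvf_field> %d x %d x %d, max |u| = %.2f mm\n",
              d[1], d[2], d[3], max(mag)))
  invisible(x)
}

#' Displacement magnitude (mm) of a field
#' @param dvf a [dvf_field()].
#' @return 3D array of Euclidean displacement magnitudes.
#' @export
dvf_magnitude <- function(dvf) {
  sqrt(dvf$field[, , , 1]^2 + dvf$field[, , , 2]^2 + dvf$field[, , , 3]^2)
}

#' Read / write volumes as NIfTI
#'
#' Volumes, masks and dose grids are exchanged as NIfTI files; spacing is
#' stored in the pixdim header. Displacement fields are stored as 4D NIfTI
#' with the vector component in the last axis.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume()` returns an [image_volume()].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  pd <- RNifti::pixdim(img)
  image_volume(arr, spacing = pd[1:3], origin = c(0, 0, 0))
}

#' @rdname read_volume
#' @param vol an [image_volume()] (or logical mask array wrapped in one).
#' @export
write_volume <- function(vol, path) {
  vol_check(vol)
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume
#' @param dvf a [dvf_field()].
#' @export
write_dvf <- function(dvf, path) {
  img <- RNifti::asNifti(dvf$field)
  RNifti::pixdim(img) <- c(dvf$spacing, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume
#' @export
read_dvf <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  pd <- RNifti::pixdim(img)
  dvf_field(arr, spacing = pd[1:3])
}

# run code under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
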