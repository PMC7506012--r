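#' 3-D CT volume container
#'
#' A minimal container for a 3-D CT image: a numeric array of Hounsfield
#' units plus the voxel spacing (mm per axis) and the world coordinate of
#' the first voxel. All geometry in the package is expressed in world
#' millimetres; voxel indices are 1-based as usual in R.
#'
#' @param data 3-D numeric array of attenuation values (HU).
#' @param spacing numeric length-3, mm per voxel along each axis (> 0).
#' @param origin numeric length-3, world position (mm) of voxel (1,1,1).
#' @return An object of class `ct_volume`.
#' @examples
#' vol <- ct_volume(array(0, c(8, 8, 4)), spacing = c(1, 1, 3))
#' dim(vol$data)
#' @export
ct_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = " x ")))
  rng <- range(x$data, na.rm = TRUE)
  cat(sprintf("  HU range [%.1f, %.1f], origin (%s) mm\n",
              rng[1], rng[2], paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

is_ct_volume <- function(x) inherits(x, "ct_volume")

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

stopifnot_same_grid <- function(a, b) {
  if (!same_grid(a, b))
    stop("volumes are not on the same grid (dimensions, spacing and origin must match)")
}

## World-coordinate axes of the voxel centres, one vector per axis.
grid_axes <- function(vol) {
  d <- dim(vol$data)
  lapply(1:3, function(a) vol$origin[a] + (seq_len(d[a]) - 1) * vol$spacing[a])
}

## n x 3 matrix of world coordinates for every voxel (column-major order,
## matching as.vector() on the data array).
grid_coords <- function(vol) {
  d <- dim(vol$data)
  ax <- grid_axes(vol)
  cbind(rep(ax[[1]], times = d[2] * d[3]),
        rep(rep(ax[[2]], each = d[1]), times = d[3]),
        rep(ax[[3]], each = d[1] * d[2]))
}

## Convert world mm coordinates (n x 3) to continuous 1-based voxel indices.
world_to_index <- function(vol, xyz) {
  sweep(sweep(xyz, 2, vol$origin, "-"), 2, vol$spacing, "/") + 1
}

#' Read a CT volume from a NIfTI file
#'
#' Axis-aligned volumes only: the rotational part of the NIfTI transform is
#' ignored (a message is emitted if it is not diagonal), spacing is taken
#' from `pixdim` and the origin from the stored transform translation.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [ct_volume].
#' @export
read_ct_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3-D NIfTI image")
  arr <- array(as.numeric(img), dim(img))
  sp <- RNifti::pixdim(img)[1:3]
  xf <- try(RNifti::xform(img), silent = TRUE)
  org <- c(0, 0, 0)
  if (!inherits(xf, "try-error") && is.matrix(xf)) {
    rot <- xf[1:3, 1:3]
    if (max(abs(rot - diag(diag(rot)))) > 1e-4)
      message("non-axis-aligned NIfTI transform: rotation ignored")
    org <- xf[1:3, 4]
  }
  ct_volume(arr, spacing = sp, origin = org)
}

#' Write a CT volume to a NIfTI file
#'
#' @param vol a [ct_volume].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI storage type, `"float"` (default) or `"int16"`.
#' @return `path`, invisibly.
#' @export
write_ct_nifti <- function(vol, path, datatype = c("float", "int16")) {
  datatype <- match.arg(datatype)
  stopifnot(is_ct_volume(vol))
  data <- vol$data
  if (datatype == "int16") {
    data <- round(data)
    storage.mode(data) <- "integer"
  }
  xf <- diag(4)
  diag(xf)[1:3] <- vol$spacing
  xf[1:3, 4] <- vol$origin
  img <- RNifti::asNifti(data)
  img <- RNifti::`sform<-`(img, structure(xf, code = 2L))
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
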