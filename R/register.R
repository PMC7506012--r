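# Rigid + coarse deformable registration of the delayed-phase volume onto
# the pre-contrast volume, and the DeltaHU subtraction image.

#' Spatial transform (rigid + optional deformation field)
#'
#' Maps fixed-image world coordinates to moving-image world coordinates:
#' `y = R((x + u(x)) - c) + c + t`, with `R` built from the three rotation
#' angles (degrees, applied as Rz Ry Rx), `t` the translation (mm), `c` the
#' rotation centre and `u` an optional smooth displacement field (mm) on
#' the fixed grid.
#'
#' @param translation,rotation numeric length-3 (mm, degrees).
#' @param center rotation centre (mm).
#' @param field optional deformation field: list with `data` (4-D array,
#'   last dimension 3, displacement mm), `spacing`, `origin` on the fixed
#'   grid.
#' @return Object of class `spatial_transform`.
#' @export
spatial_transform <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0),
                              center = c(0, 0, 0), field = NULL) {
  stopifnot(length(translation) == 3, length(rotation) == 3,
            length(center) == 3)
  if (!is.null(field))
    stopifnot(is.array(field$data), length(dim(field$data)) == 4,
              dim(field$data)[4] == 3)
  structure(list(translation = as.numeric(translation),
                 rotation = as.numeric(rotation),
                 center = as.numeric(center), field = field),
            class = "spatial_transform")
}

#' @export
print.spatial_transform <- function(x, ...) {
  cat(sprintf("<spatial_transform> t = (%s) mm, rot = (%s) deg, field: %s\n",
              paste(sprintf("%.2f", x$translation), collapse = ", "),
              paste(sprintf("%.2f", x$rotation), collapse = ", "),
              if (is.null(x$field)) "none" else "deformable"))
  invisible(x)
}

rotation_matrix <- function(rotation_deg) {
  r <- rotation_deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

## Evaluate the mapping for fixed-grid world coordinates xyz (n x 3).
transform_map <- function(t, xyz) {
  x <- xyz
  if (!is.null(t$field)) {
    f <- t$field
    dd <- dim(f$data)[1:3]
    idx <- sweep(sweep(xyz, 2, f$origin, "-"), 2, f$spacing, "/") + 1
    for (a in 1:3) {
      comp <- interp_trilinear(array(f$data[, , , a], dd), idx, outside = 0)
      x[, a] <- x[, a] + comp
    }
  }
  R <- rotation_matrix(t$rotation)
  xc <- sweep(x, 2, t$center, "-")
  y <- xc %*% t(R)
  sweep(y, 2, t$center + t$translation, "+")
}

## Inverse of the rigid part (no field): x = R^-1(y - c - t) + c.
invert_rigid <- function(t) {
  R <- rotation_matrix(t$rotation)
  # pure-rotation inverse has angles solving R' = R^T; return a transform
  # realised directly through the inverse matrix mapping
  structure(list(translation = t$translation, rotation = t$rotation,
                 center = t$center, field = NULL, inverse = TRUE),
            class = c("inverse_rigid", "spatial_transform"))
}

transform_map_inverse_rigid <- function(t, xyz) {
  R <- rotation_matrix(t$rotation)
  y <- sweep(xyz, 2, t$center + t$translation, "-")
  x <- y %*% R  # y %*% t(R^-1) = y %*% R
  sweep(x, 2, t$center, "+")
}

#' Resample a volume through a spatial transform
#'
#' Pull-back resampling of `volume` onto the `fixed` grid: each output
#' voxel takes the (linear or cubic-smoothed) interpolated value of
#' `volume` at the mapped position. Voxels mapping outside the field of
#' view are set to `NA` (a sentinel, never silently zero-filled).
#'
#' @param volume the moving [ct_volume].
#' @param transform a [spatial_transform].
#' @param fixed optional [ct_volume] defining the output grid (defaults to
#'   the moving volume's own grid).
#' @param interpolation `"linear"` (default) or `"nearest"`.
#' @return A [ct_volume] on the fixed grid with attribute `provenance`.
#' @export
apply_transform <- function(volume, transform, fixed = volume,
                            interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stopifnot(is_ct_volume(volume), inherits(transform, "spatial_transform"))
  xyz <- grid_coords(fixed)
  y <- if (inherits(transform, "inverse_rigid"))
    transform_map_inverse_rigid(transform, xyz)
  else transform_map(transform, xyz)
  idx <- world_to_index(volume, y)
  if (interpolation == "nearest") idx <- round(idx)
  vals <- interp_trilinear(volume$data, idx, outside = NA_real_)
  out <- ct_volume(array(vals, dim(fixed$data)), fixed$spacing, fixed$origin)
  attr(out, "provenance") <- list(transform = transform,
                                  interpolation = interpolation)
  out
}

#' Register a moving volume onto a fixed volume
#'
#' Multi-resolution (3-level) intensity registration minimising the mean
#' squared difference. The rigid stage optimises 3 translations + 3
#' rotations by Nelder-Mead; `mode = "deformable"` then refines with a
#' coarse demons-style free-form stage whose field is smoothed at roughly
#' 16 mm, run at half resolution. Because pre-contrast and delayed-phase
#' images differ by regional enhancement, the moving intensities are
#' normalised onto the fixed image first (`"quantile"` histogram matching
#' by default; `"meanshift"` subtracts the mean difference; `"none"`).
#'
#' @param moving,fixed [ct_volume]s with overlapping physical extents.
#' @param mode `"rigid"` or `"deformable"`.
#' @param normalize intensity normalisation applied to the moving image
#'   before the metric: `"quantile"`, `"meanshift"` or `"none"`.
#' @param mask optional logical array on the fixed grid restricting the
#'   metric (the vendor behaviour is unspecified; unmasked by default).
#' @param max_iter iteration cap per resolution level.
#' @param tol relative metric-change convergence tolerance.
#' @return A [spatial_transform]; attributes `metric` (final MSD) and
#'   `converged` report the optimisation outcome.
#' @export
register <- function(moving, fixed, mode = c("rigid", "deformable"),
                     normalize = c("quantile", "meanshift", "none"),
                     mask = NULL, max_iter = 200, tol = 1e-6) {
  mode <- match.arg(mode)
  normalize <- match.arg(normalize)
  stopifnot(is_ct_volume(moving), is_ct_volume(fixed))
  check_overlap(moving, fixed)
  center <- fixed$origin + (dim(fixed$data) - 1) * fixed$spacing / 2
  par <- rep(0, 6)
  levels <- list(list(f = 4L, stride = 1L), list(f = 2L, stride = 1L),
                 list(f = 1L, stride = 2L))
  metric_val <- NA_real_
  converged <- TRUE
  for (lv in levels) {
    fx <- pyramid_level(fixed, lv$f)
    mv <- pyramid_level(moving, lv$f)
    # pre-smoothing plus sub-voxel jitter of the sample points keep the
    # metric free of interpolation scalloping (period-1-voxel ripples that
    # otherwise trap the optimiser at grid-aligned offsets)
    fx$data <- smooth_gaussian(fx$data, 1)
    mv$data <- smooth_gaussian(mv$data, 1)
    mv$data <- normalize_intensity(mv$data, fx$data, normalize)
    mask_l <- if (is.null(mask)) NULL else
      downsample_block(mask + 0, lv$f) > 0.5
    sub <- metric_points(fx, lv$stride, mask_l)
    fvals <- sub$fvals
    fn <- function(p) {
      t <- spatial_transform(p[1:3], p[4:6], center)
      y <- transform_map(t, sub$xyz)
      w <- interp_trilinear(mv$data, world_to_index(mv, y), outside = NA_real_)
      ok <- !is.na(w)
      if (sum(ok) < 32) return(1e12)
      mean((w[ok] - fvals[ok])^2)
    }
    # Nelder-Mead for robustness at the coarsest level, then BFGS
    # (finite-difference gradients) for sub-voxel refinement
    if (lv$f == levels[[1]]$f) {
      opt <- stats::optim(par, fn, method = "Nelder-Mead",
                          control = list(maxit = max_iter * 4, reltol = tol,
                                         parscale = c(1, 1, 1, 0.5, 0.5, 0.5)))
      par <- opt$par
    }
    opt <- stats::optim(par, fn, method = "BFGS",
                        control = list(maxit = max_iter, reltol = tol,
                                       parscale = c(1, 1, 1, 0.5, 0.5, 0.5)))
    if (opt$value <= fn(par)) par <- opt$par
    metric_val <- opt$value
    if (opt$convergence != 0) converged <- FALSE
  }
  out <- spatial_transform(par[1:3], par[4:6], center)
  if (mode == "deformable")
    out <- demons_refine(moving, fixed, out, normalize, mask = mask)
  attr(out, "metric") <- metric_val
  attr(out, "converged") <- converged
  if (!converged)
    warning(sprintf("rigid stage hit the iteration cap (final MSD %.3f)",
                    metric_val))
  out
}

check_overlap <- function(moving, fixed) {
  lo_m <- moving$origin
  hi_m <- moving$origin + (dim(moving$data) - 1) * moving$spacing
  lo_f <- fixed$origin
  hi_f <- fixed$origin + (dim(fixed$data) - 1) * fixed$spacing
  if (any(hi_m < lo_f) || any(hi_f < lo_m))
    stop("moving and fixed volumes do not overlap in physical space")
}

pyramid_level <- function(vol, factor) {
  if (factor == 1) return(vol)
  ct_volume(downsample_block(vol$data, factor),
            spacing = vol$spacing * factor,
            origin = vol$origin + (factor - 1) * vol$spacing / 2)
}

## Metric sample points: a strided grid with a fixed pseudo-random
## sub-voxel jitter (so each point carries a different interpolation
## phase), with the fixed-image values interpolated once at those points.
metric_points <- function(vol, stride, mask = NULL) {
  d <- dim(vol$data)
  ii <- seq(1, d[1], by = stride)
  jj <- seq(1, d[2], by = stride)
  kk <- seq(1, d[3], by = stride)
  idx <- cbind(rep(ii, times = length(jj) * length(kk)),
               rep(rep(jj, each = length(ii)), times = length(kk)),
               rep(kk, each = length(ii) * length(jj)))
  if (!is.null(mask)) {
    lin <- idx[, 1] + (idx[, 2] - 1) * d[1] + (idx[, 3] - 1) * d[1] * d[2]
    idx <- idx[mask[lin], , drop = FALSE]
  }
  jit <- with_seed(600313, matrix(stats::runif(length(idx), -0.45, 0.45),
                                  ncol = 3))
  idx <- idx + jit
  fvals <- interp_trilinear(vol$data, idx, outside = NA_real_)
  keep <- !is.na(fvals)
  idx <- idx[keep, , drop = FALSE]
  xyz <- sweep(sweep(idx, 2, 1, "-") %*% diag(vol$spacing), 2, vol$origin, "+")
  list(xyz = xyz, fvals = fvals[keep])
}

normalize_intensity <- function(moving_data, fixed_data, normalize) {
  switch(normalize,
         none = moving_data,
         meanshift = moving_data - mean(moving_data, na.rm = TRUE) +
           mean(fixed_data, na.rm = TRUE),
         quantile = array(match_quantiles(as.vector(moving_data),
                                          as.vector(fixed_data)),
                          dim(moving_data)))
}

## Fluid-style demons refinement at half resolution: the per-iteration
## update follows the fixed-image gradient and is smoothed with a Gaussian
## (sigma_fluid voxels, ~6 mm regularisation scale) before being added to
## the accumulated field. Smoothing the update rather than the field keeps
## the recovered deformation from being attenuated toward zero.
demons_refine <- function(moving, fixed, rigid, normalize,
                          mask = NULL, iterations = 100, sigma_fluid = 3,
                          sigma_diffusion = 0, step_cap = 1.5) {
  f2 <- pyramid_level(fixed, 2L)
  d <- dim(f2$data)
  # moving resampled through the rigid transform onto the half-res grid
  m2 <- apply_transform(moving, rigid, fixed = f2)
  m2dat <- m2$data
  m2dat[is.na(m2dat)] <- stats::median(m2dat, na.rm = TRUE)
  m2dat <- normalize_intensity(m2dat, f2$data, normalize)
  fs <- smooth_gaussian(f2$data, 1)
  ms <- smooth_gaussian(m2dat, 1)
  gx <- central_diff(fs, 1)
  gy <- central_diff(fs, 2)
  gz <- central_diff(fs, 3)
  g2 <- gx^2 + gy^2 + gz^2
  base_idx <- cbind(rep(seq_len(d[1]), times = d[2] * d[3]),
                    rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
                    rep(seq_len(d[3]), each = d[1] * d[2]))
  ux <- array(0, d); uy <- array(0, d); uz <- array(0, d)
  for (it in seq_len(iterations)) {
    idx <- base_idx + cbind(as.vector(ux), as.vector(uy), as.vector(uz))
    w <- interp_trilinear(ms, idx, outside = NA_real_)
    diffv <- array(w, d) - fs
    diffv[is.na(diffv)] <- 0
    denom <- g2 + diffv^2
    denom[denom < 1e-8] <- 1e-8
    fac <- diffv / denom
    sx <- pmax(pmin(fac * gx, step_cap), -step_cap)
    sy <- pmax(pmin(fac * gy, step_cap), -step_cap)
    sz <- pmax(pmin(fac * gz, step_cap), -step_cap)
    ux <- ux - smooth_gaussian(sx, sigma_fluid)
    uy <- uy - smooth_gaussian(sy, sigma_fluid)
    uz <- uz - smooth_gaussian(sz, sigma_fluid)
    if (sigma_diffusion > 0) {
      ux <- smooth_gaussian(ux, sigma_diffusion)
      uy <- smooth_gaussian(uy, sigma_diffusion)
      uz <- smooth_gaussian(uz, sigma_diffusion)
    }
  }
  # upsample to the fixed full-resolution grid, in mm
  field <- array(0, c(dim(fixed$data), 3))
  full_idx <- world_to_index(f2, grid_coords(fixed))
  comp <- list(ux, uy, uz)
  for (a in 1:3) {
    vals <- interp_trilinear(comp[[a]], full_idx, outside = 0)
    field[, , , a] <- vals * f2$spacing[a]
  }
  spatial_transform(rigid$translation, rigid$rotation, rigid$center,
                    field = list(data = field, spacing = fixed$spacing,
                                 origin = fixed$origin))
}

central_diff <- function(arr, axis) {
  off <- c(0, 0, 0)
  off[axis] <- 1
  (shift_array(arr, -off, 0) - shift_array(arr, off, 0)) / 2
}

#' Serialize a spatial transform
#'
#' Rigid parameters go to JSON; a deformation field, if present, is stored
#' as a 4-D NIfTI next to it (path recorded in the JSON).
#'
#' @param transform a [spatial_transform].
#' @param path output JSON path.
#' @param field_path optional NIfTI path for the deformation field;
#'   defaults to `path` with a `_field.nii.gz` suffix.
#' @return `path`, invisibly.
#' @export
write_transform_json <- function(transform, path, field_path = NULL) {
  stopifnot(inherits(transform, "spatial_transform"))
  obj <- list(translation = transform$translation,
              rotation = transform$rotation,
              center = transform$center)
  if (!is.null(transform$field)) {
    if (is.null(field_path))
      field_path <- sub("\\.json$", "", path)
    if (!grepl("\\.nii(\\.gz)?$", field_path))
      field_path <- paste0(field_path, "_field.nii.gz")
    img <- RNifti::asNifti(transform$field$data)
    RNifti::writeNifti(img, field_path)
    obj$field_file <- basename(field_path)
    obj$field_spacing <- transform$field$spacing
    obj$field_origin <- transform$field$origin
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform_json
#' @return `read_transform_json`: the reconstructed [spatial_transform].
#' @export
read_transform_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  field <- NULL
  if (!is.null(obj$field_file)) {
    img <- RNifti::readNifti(file.path(dirname(path), obj$field_file))
    img <- array(as.numeric(img), dim(img))
    field <- list(data = img,
                  spacing = as.numeric(obj$field_spacing),
                  origin = as.numeric(obj$field_origin))
  }
  spatial_transform(as.numeric(obj$translation), as.numeric(obj$rotation),
                    as.numeric(obj$center), field = field)
}

#' Subtraction volume (delayed minus pre-contrast)
#'
#' Voxelwise difference of the registered delayed-phase volume and the
#' pre-contrast volume on the shared grid. `NA` sentinels (out-of-field
#' after resampling) propagate into the difference.
#'
#' @param delayed_registered,pre [ct_volume]s on the same grid.
#' @return A [ct_volume] with class `subtraction_volume`; attribute
#'   `provenance` records the transform/interpolation if the delayed
#'   volume carried one.
#' @export
subtract <- function(delayed_registered, pre) {
  stopifnot(is_ct_volume(delayed_registered), is_ct_volume(pre))
  stopifnot_same_grid(delayed_registered, pre)
  out <- ct_volume(delayed_registered$data - pre$data, pre$spacing, pre$origin)
  class(out) <- c("subtraction_volume", class(out))
  attr(out, "provenance") <- attr(delayed_registered, "provenance")
  out
}
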