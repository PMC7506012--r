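# Left-ventricular geometry: endo/epi masks, long axis, AHA 16-segment
# parcellation and the cavity blood-pool ROI.

#' Left-ventricular geometry
#'
#' Bundles the endocardial and epicardial masks, the long-axis frame and
#' (after [parcellate_aha16()]) the AHA 16-segment label map. The myocardial
#' mask is always `epi & !endo`. The long axis points from the mitral base
#' plane towards the apex; `ref_angle` (degrees) anchors sector 1 (basal
#' anterior, by convention the anterior right-ventricular insertion).
#'
#' @param endo_mask,epi_mask logical 3-D arrays (cavity, resp. cavity+wall).
#' @param long_axis unit vector, base to apex.
#' @param base_mm,apex_mm world positions (mm) of the base-plane centre and
#'   the epicardial apex on the long axis.
#' @param ref_angle reference angle in degrees for sector numbering.
#' @param spacing,origin grid geometry as in [ct_volume()].
#' @param labels optional integer array of AHA labels (0 = background/cap).
#' @return An object of class `lv_geometry`.
#' @export
lv_geometry <- function(endo_mask, epi_mask, long_axis, base_mm, apex_mm,
                        ref_angle = 0, spacing = c(1, 1, 1),
                        origin = c(0, 0, 0), labels = NULL) {
  stopifnot(is.logical(endo_mask), is.logical(epi_mask),
            identical(dim(endo_mask), dim(epi_mask)))
  if (any(endo_mask & !epi_mask))
    stop("endocardial mask must lie inside the epicardial mask")
  long_axis <- long_axis / sqrt(sum(long_axis^2))
  structure(list(
    endo_mask = endo_mask, epi_mask = epi_mask,
    myo_mask = epi_mask & !endo_mask,
    long_axis = long_axis, base_mm = base_mm, apex_mm = apex_mm,
    ref_angle = ref_angle, spacing = as.numeric(spacing),
    origin = as.numeric(origin), labels = labels
  ), class = "lv_geometry")
}

#' @export
print.lv_geometry <- function(x, ...) {
  cat(sprintf("<lv_geometry> myocardium %d voxels, cavity %d voxels\n",
              sum(x$myo_mask), sum(x$endo_mask)))
  cat(sprintf("  axis length %.1f mm, ref angle %.1f deg, labels: %s\n",
              sqrt(sum((x$apex_mm - x$base_mm)^2)), x$ref_angle,
              if (is.null(x$labels)) "none" else "AHA-16"))
  invisible(x)
}

#' Segment the left ventricle
#'
#' With `contours` supplied the masks are taken (or rasterised) from them,
#' mirroring manual endo/epicardial border tracing. Without contours a
#' 3-class intensity clustering (k-means) with connected-component cleanup
#' produces an automatic segmentation adequate for phantom images: the
#' brightest class seeds the blood cavity and the middle class the wall.
#' The long axis is the principal axis of the cavity; the apex is the end
#' where the epicardium extends beyond the cavity (closed apex).
#'
#' @param volume a [ct_volume] containing the LV.
#' @param contours optional manual contours: either a list with logical
#'   arrays `endo` and `epi`, or a list of per-slice polygons as produced
#'   by [read_contours_json()].
#' @param ref_angle reference angle (degrees) anchoring AHA sector 1.
#' @return An [lv_geometry] (without labels; see [parcellate_aha16()]).
#' @export
segment_lv <- function(volume, contours = NULL, ref_angle = 0) {
  stopifnot(is_ct_volume(volume))
  if (!is.null(contours)) {
    masks <- contours_to_masks(contours, volume)
    endo <- masks$endo; epi <- masks$epi
  } else {
    masks <- auto_segment_lv(volume)
    endo <- masks$endo; epi <- masks$epi
  }
  if (!any(endo))
    stop("segmentation failure: empty LV cavity")
  ax <- estimate_lv_axis(endo, epi, volume$spacing, volume$origin)
  lv_geometry(endo, epi, ax$long_axis, ax$base_mm, ax$apex_mm,
              ref_angle = ref_angle, spacing = volume$spacing,
              origin = volume$origin)
}

auto_segment_lv <- function(volume) {
  vals <- as.vector(volume$data)
  uv <- unique(vals[is.finite(vals)])
  if (length(uv) < 3)
    stop("segmentation failure: volume has no intensity structure")
  samp <- vals[is.finite(vals)]
  if (length(samp) > 50000) samp <- samp[seq(1, length(samp), length.out = 50000)]
  km <- stats::kmeans(samp, centers = 3, nstart = 3)
  cen <- sort(km$centers[, 1])
  t_lo <- (cen[1] + cen[2]) / 2
  t_hi <- (cen[2] + cen[3]) / 2
  blood <- array(vals > t_hi, dim(volume$data))
  if (!any(blood)) stop("segmentation failure: empty LV cavity")
  bl <- label_components(blood)
  cavity <- bl == which.max(tabulate(bl[bl > 0]))
  heart <- array(vals > t_lo, dim(volume$data))
  hl <- label_components(heart)
  cav_ids <- unique(hl[cavity])
  cav_ids <- cav_ids[cav_ids > 0]
  epi <- array(hl %in% cav_ids, dim(volume$data))
  list(endo = cavity, epi = epi)
}

estimate_lv_axis <- function(endo, epi, spacing, origin) {
  idx <- which(endo)
  d <- dim(endo)
  co <- cbind((((idx - 1) %% d[1])) * spacing[1] + origin[1],
              (((idx - 1) %/% d[1]) %% d[2]) * spacing[2] + origin[2],
              ((idx - 1) %/% (d[1] * d[2])) * spacing[3] + origin[3])
  ctr <- colMeans(co)
  pc <- stats::prcomp(co, center = TRUE)
  u <- pc$rotation[, 1]
  te <- as.vector((co - matrix(ctr, nrow(co), 3, byrow = TRUE)) %*% u)
  idx_p <- which(epi)
  cp <- cbind((((idx_p - 1) %% d[1])) * spacing[1] + origin[1],
              (((idx_p - 1) %/% d[1]) %% d[2]) * spacing[2] + origin[2],
              ((idx_p - 1) %/% (d[1] * d[2])) * spacing[3] + origin[3])
  tp <- as.vector((cp - matrix(ctr, nrow(cp), 3, byrow = TRUE)) %*% u)
  # apex = side where the epicardium overhangs the cavity (closed apex)
  if ((max(tp) - max(te)) < (min(te) - min(tp))) u <- -u
  tproj_p <- as.vector((cp - matrix(ctr, nrow(cp), 3, byrow = TRUE)) %*% u)
  half_vox <- mean(spacing) / 2
  base_mm <- ctr + u * (min(tproj_p) - half_vox)
  apex_mm <- ctr + u * (max(tproj_p) + half_vox)
  list(long_axis = u, base_mm = base_mm, apex_mm = apex_mm)
}

#' Assign the AHA 16-segment parcellation
#'
#' The base-to-apex axis is split into basal, mid and apical thirds of equal
#' length after excluding the most apical `cap_fraction` of the axis (the
#' apex cap, absent from the 16-segment model). Basal and mid rings are cut
#' into six 60-degree sectors (labels 1-6 and 7-12), the apical ring into
#' four 90-degree sectors (13-16), counted from `ref_angle`.
#'
#' @param geom an [lv_geometry].
#' @param cap_fraction fraction of the axis excluded at the apex (default 0.1).
#' @return `geom` with the `labels` array filled (0 outside wall/cap).
#' @export
parcellate_aha16 <- function(geom, cap_fraction = 0.1) {
  stopifnot(inherits(geom, "lv_geometry"))
  if (is.null(geom$ref_angle) || !is.finite(geom$ref_angle))
    stop("reference angle is undefined")
  d <- dim(geom$myo_mask)
  idx <- which(geom$myo_mask)
  co <- cbind((((idx - 1) %% d[1])) * geom$spacing[1] + geom$origin[1],
              (((idx - 1) %/% d[1]) %% d[2]) * geom$spacing[2] + geom$origin[2],
              ((idx - 1) %/% (d[1] * d[2])) * geom$spacing[3] + geom$origin[3])
  u <- geom$long_axis
  L <- sum((geom$apex_mm - geom$base_mm) * u)
  v <- co - matrix(geom$base_mm, nrow(co), 3, byrow = TRUE)
  s <- as.vector(v %*% u) / L
  frame <- axis_frame(u)
  ang <- atan2(as.vector(v %*% frame$ey), as.vector(v %*% frame$ex))
  ang <- (ang - geom$ref_angle * pi / 180) %% (2 * pi)
  span <- 1 - cap_fraction
  lab <- integer(length(s))
  ring <- findInterval(s, c(0, span / 3, 2 * span / 3, span)) # 1,2,3 = rings
  basal <- ring == 1
  mid <- ring == 2
  apical <- ring == 3
  lab[basal] <- 1L + pmin(floor(ang[basal] * 3 / pi), 5)
  lab[mid] <- 7L + pmin(floor(ang[mid] * 3 / pi), 5)
  lab[apical] <- 13L + pmin(floor(ang[apical] * 2 / pi), 3)
  labels <- array(0L, d)
  labels[idx] <- lab
  geom$labels <- labels
  geom
}

## Orthonormal in-plane frame for a long axis; ex is the zero-angle
## direction, ey completes a right-handed (u, ex, ey) set so the sector
## angle increases counterclockwise when viewed from the apex.
axis_frame <- function(u) {
  r0 <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  ex <- r0 - u * sum(r0 * u)
  ex <- ex / sqrt(sum(ex^2))
  ey <- c(u[2] * ex[3] - u[3] * ex[2],
          u[3] * ex[1] - u[1] * ex[3],
          u[1] * ex[2] - u[2] * ex[1])
  list(ex = ex, ey = ey)
}

#' Blood-pool region of interest
#'
#' Erodes the LV cavity by `margin_mm` so the ROI keeps clear of
#' partial-volume voxels at the endocardial border, mirroring the cavity
#' ROI placed on the subtraction image to measure the blood enhancement.
#'
#' @param geom an [lv_geometry].
#' @param margin_mm erosion margin in mm (0 returns the full cavity).
#' @return Logical mask of the ROI.
#' @export
blood_pool_roi <- function(geom, margin_mm = 3) {
  stopifnot(inherits(geom, "lv_geometry"), margin_mm >= 0)
  roi <- erode_ball(geom$endo_mask, margin_mm, geom$spacing)
  if (!any(roi))
    stop(sprintf(
      "erosion by %.1f mm empties the cavity; use a smaller margin", margin_mm))
  roi
}

#' Read per-slice contour polygons from JSON
#'
#' The JSON layout is a list with elements `endo` and `epi`; each is an
#' array of objects `{"slice": k, "x": [...], "y": [...]}` giving a closed
#' polygon in world mm on axial slice `k`.
#'
#' @param path JSON file path.
#' @return A contour list usable as `contours` in [segment_lv()].
#' @export
read_contours_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  lapply(obj, function(set) {
    lapply(set, function(cc) {
      list(slice = as.integer(cc$slice),
           xy = cbind(as.numeric(cc$x), as.numeric(cc$y)))
    })
  })
}

contours_to_masks <- function(contours, volume) {
  if (is.list(contours) && is.logical(contours$endo) && is.logical(contours$epi)) {
    stopifnot(identical(dim(contours$endo), dim(volume$data)),
              identical(dim(contours$epi), dim(volume$data)))
    return(list(endo = contours$endo, epi = contours$epi))
  }
  if (!all(c("endo", "epi") %in% names(contours)))
    stop("contours must provide `endo` and `epi`")
  list(endo = rasterize_contour_set(contours$endo, volume),
       epi = rasterize_contour_set(contours$epi, volume))
}

rasterize_contour_set <- function(set, volume) {
  d <- dim(volume$data)
  mask <- array(FALSE, d)
  ax <- grid_axes(volume)
  for (cc in set) {
    k <- cc$slice
    if (k < 1 || k > d[3]) next
    px <- rep(ax[[1]], times = d[2])
    py <- rep(ax[[2]], each = d[1])
    inside <- point_in_polygon(px, py, cc$xy)
    sl <- mask[, , k]
    sl[inside] <- TRUE
    mask[, , k] <- sl
  }
  mask
}

## Even-odd ray-casting test, vectorised over points.
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
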