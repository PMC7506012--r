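# Per-segment and per-patient extracellular volume: segment enhancement,
# blood enhancement, the ECV relation, delayed-enhancement pattern
# classification with exclusion of ischemic segments, and the polar map.

#' Per-segment myocardial enhancement
#'
#' Mean DeltaHU of the subtraction volume over each AHA segment's voxels.
#' `NA` sentinels (out-of-field after resampling) are excluded; a segment
#' with no usable voxels yields `NA` rather than an error.
#'
#' @param sub subtraction [ct_volume] (see [subtract()]).
#' @param geom an [lv_geometry] with labels filled.
#' @return Numeric vector of 16 DeltaHUm values (HU).
#' @export
delta_hu_myocardium <- function(sub, geom) {
  stopifnot(is_ct_volume(sub), inherits(geom, "lv_geometry"))
  if (is.null(geom$labels)) stop("geometry labels are not filled")
  stopifnot(identical(dim(sub$data), dim(geom$labels)))
  vapply(1:16, function(s) {
    v <- sub$data[geom$labels == s]
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
}

#' Blood-pool enhancement
#'
#' Mean DeltaHU of the subtraction volume over the cavity ROI.
#'
#' @param sub subtraction [ct_volume].
#' @param roi logical blood-pool mask (see [blood_pool_roi()]).
#' @return DeltaHUb in HU.
#' @export
delta_hu_blood <- function(sub, roi) {
  stopifnot(is_ct_volume(sub), is.logical(roi))
  v <- sub$data[roi]
  v <- v[!is.na(v)]
  if (length(v) == 0) stop("validation error: empty blood-pool ROI")
  mean(v)
}

#' Extracellular volume fraction
#'
#' `ECV = (DeltaHUm / DeltaHUb) * (1 - Hct)`. Values outside \[0, 1\] are
#' returned as computed with a quality warning (never clipped).
#'
#' @param delta_hu_m myocardial enhancement (HU); may be a vector.
#' @param delta_hu_b blood enhancement (HU), non-zero.
#' @param hct hematocrit fraction in (0, 1).
#' @return ECV fraction(s).
#' @examples
#' ecv(30, 60, 0.334)
#' @export
ecv <- function(delta_hu_m, delta_hu_b, hct) {
  if (length(delta_hu_b) != 1 || !is.finite(delta_hu_b) || delta_hu_b == 0)
    stop("division error: DeltaHUb must be a single non-zero value")
  if (length(hct) != 1 || !is.finite(hct) || hct <= 0 || hct >= 1)
    stop("validation error: hematocrit must lie in (0, 1)")
  out <- (delta_hu_m / delta_hu_b) * (1 - hct)
  bad <- !is.na(out) & (out < 0 | out > 1)
  if (any(bad))
    warning(sprintf("%d ECV value(s) outside [0, 1]; check enhancement quality",
                    sum(bad)))
  out
}

#' Classify delayed-enhancement patterns per segment
#'
#' Voxels above `threshold` are grouped into connected lesions (minimum
#' volume `min_lesion_ml` to ignore noise specks). A lesion reaching the
#' subendocardial band (transmural depth < 0.25, the operational surrogate
#' for a subendocardial/transmural pattern in a coronary distribution)
#' marks every segment it occupies as `ischemic`; a lesion confined to the
#' midwall/subepicardium is `nonischemic`; segments without lesions are
#' `none`. Ischemic dominates if a segment carries both.
#'
#' @param sub subtraction [ct_volume].
#' @param geom labelled [lv_geometry].
#' @param threshold HU threshold for enhancement; default is the myocardial
#'   mean + 3 SD of the subtraction values.
#' @param min_lesion_ml minimum lesion volume in mL.
#' @return Factor of length 16 with levels none/ischemic/nonischemic.
#' @export
classify_delayed_enhancement <- function(sub, geom, threshold = NULL,
                                         min_lesion_ml = 0.1) {
  stopifnot(is_ct_volume(sub), inherits(geom, "lv_geometry"))
  if (is.null(geom$labels)) stop("geometry labels are not filled")
  myo <- geom$myo_mask
  vals <- sub$data
  if (is.null(threshold)) {
    mv <- vals[myo]
    mv <- mv[!is.na(mv)]
    threshold <- mean(mv) + 3 * stats::sd(mv)
  }
  lesion_vox <- myo & !is.na(vals) & vals > threshold
  cls <- factor(rep("none", 16), levels = c("none", "ischemic", "nonischemic"))
  if (!any(lesion_vox)) return(cls)
  comp <- label_components(lesion_vox)
  vox_ml <- prod(geom$spacing) / 1000
  depth <- wall_depth_map(geom)
  rank <- c(none = 1, nonischemic = 2, ischemic = 3)
  for (id in seq_len(max(comp))) {
    m <- comp == id
    if (sum(m) * vox_ml < min_lesion_ml) next
    kind <- if (min(depth[m], na.rm = TRUE) < 0.25) "ischemic" else "nonischemic"
    for (s in unique(geom$labels[m])) {
      if (s == 0) next
      if (rank[kind] > rank[as.character(cls[s])]) cls[s] <- kind
    }
  }
  cls
}

## Transmural depth coordinate from the masks: breadth-first (city-block)
## distances to the cavity and to the outside of the epicardium,
## depth = d_endo / (d_endo + d_epi) in (0, 1).
wall_depth_map <- function(geom) {
  myo <- geom$myo_mask
  d_endo <- bfs_distance(geom$endo_mask, myo)
  d_epi <- bfs_distance(!geom$epi_mask, myo)
  depth <- array(NA_real_, dim(myo))
  ok <- myo & !is.na(d_endo) & !is.na(d_epi)
  depth[ok] <- d_endo[ok] / (d_endo[ok] + d_epi[ok])
  depth
}

#' Build the per-segment ECV table
#'
#' Combines segment enhancement, blood enhancement, the ECV relation and
#' pattern classification into the analysis table; segments classified
#' ischemic are flagged excluded (their ECV is reported as `NA`).
#'
#' @param sub subtraction [ct_volume].
#' @param geom labelled [lv_geometry].
#' @param hct hematocrit fraction.
#' @param roi_margin_mm blood-pool ROI erosion margin (mm).
#' @param threshold,min_lesion_ml passed to [classify_delayed_enhancement()].
#' @return data.frame of class `segment_ecv_table` with columns `segment`,
#'   `delta_hu_m`, `ecv`, `class`, `excluded`; attributes `delta_hu_b`,
#'   `hematocrit` and `patient_ecv`.
#' @export
ecv_segment_table <- function(sub, geom, hct, roi_margin_mm = 3,
                              threshold = NULL, min_lesion_ml = 0.1) {
  dhum <- delta_hu_myocardium(sub, geom)
  dhub <- delta_hu_blood(sub, blood_pool_roi(geom, roi_margin_mm))
  cls <- classify_delayed_enhancement(sub, geom, threshold = threshold,
                                      min_lesion_ml = min_lesion_ml)
  ev <- ecv(dhum, dhub, hct)
  excluded <- cls == "ischemic"
  ev[excluded] <- NA_real_
  tab <- data.frame(segment = 1:16, delta_hu_m = dhum, ecv = ev,
                    class = cls, excluded = excluded)
  class(tab) <- c("segment_ecv_table", "data.frame")
  attr(tab, "delta_hu_b") <- dhub
  attr(tab, "hematocrit") <- hct
  attr(tab, "patient_ecv") <- patient_ecv(tab)
  tab
}

#' Per-patient ECV
#'
#' Unweighted mean of segment ECV over segments not flagged excluded
#' (ischemic segments are excluded from further analysis).
#'
#' @param table a `segment_ecv_table` (or data.frame with `ecv` and
#'   `excluded` columns).
#' @return Patient ECV fraction.
#' @export
patient_ecv <- function(table) {
  keep <- !table$excluded & !is.na(table$ecv)
  if (!any(keep)) stop("patient not evaluable: all 16 segments excluded")
  mean(table$ecv[keep])
}

#' Full pre/delayed to ECV pipeline
#'
#' The three-step chain: register the delayed phase onto the pre-contrast
#' volume and subtract; delineate the LV (from supplied contours/geometry
#' or automatically) and parcellate; measure enhancements and produce the
#' per-segment ECV table.
#'
#' @param pre,delayed [ct_volume]s.
#' @param hct hematocrit fraction.
#' @param geometry optional ready-made [lv_geometry] (labels filled or
#'   not); if `NULL` the LV is segmented automatically from `pre`.
#' @param contours optional manual contours for [segment_lv()].
#' @param mode registration mode: `"deformable"`, `"rigid"`, or `"none"`
#'   for already-aligned phases.
#' @param ref_angle reference angle for the parcellation (degrees).
#' @param ... passed to [ecv_segment_table()].
#' @return A `segment_ecv_table`.
#' @export
ecv_pipeline <- function(pre, delayed, hct, geometry = NULL, contours = NULL,
                         mode = c("deformable", "rigid", "none"),
                         ref_angle = 0, ...) {
  mode <- match.arg(mode)
  if (mode == "none") {
    aligned <- delayed
  } else {
    tr <- register(delayed, pre, mode = mode)
    aligned <- apply_transform(delayed, tr, fixed = pre)
  }
  sub <- subtract(aligned, pre)
  if (is.null(geometry))
    geometry <- segment_lv(pre, contours = contours, ref_angle = ref_angle)
  if (is.null(geometry$labels))
    geometry <- parcellate_aha16(geometry)
  ecv_segment_table(sub, geometry, hct, ...)
}

#' AHA bullseye polar map of segment ECV
#'
#' Renders the standard 16-segment bullseye (three rings of 6/6/4 sectors,
#' apex cap absent) with ECV shown as fractions; excluded segments are
#' hatched and carry no numeral.
#'
#' @param table a `segment_ecv_table`.
#' @param file optional PNG path; if `NULL`, draws on the active device.
#' @param palette colour ramp function for the fill; default blue-red.
#' @param zlim value range mapped onto the palette.
#' @return Invisibly, a data.frame with one row per segment: ring, angular
#'   extent (degrees), value and exclusion flag.
#' @export
ecv_polar_map <- function(table, file = NULL,
                          palette = grDevices::colorRampPalette(
                            c("#2166AC", "#F7F7F7", "#B2182B")),
                          zlim = NULL) {
  stopifnot(nrow(table) == 16)
  rings <- c(rep(1, 6), rep(2, 6), rep(3, 4))
  n_sec <- c(6, 6, 4)[rings]
  start <- c((0:5) * 60, (0:5) * 60, (0:3) * 90)
  layout <- data.frame(segment = 1:16, ring = rings,
                       start_deg = start, end_deg = start + 360 / n_sec,
                       value = table$ecv, excluded = table$excluded)
  if (!is.null(file)) {
    grDevices::png(file, width = 640, height = 640)
    on.exit(grDevices::dev.off())
  }
  vals <- layout$value
  if (is.null(zlim))
    zlim <- range(vals[!is.na(vals)], 0.2, 0.4, na.rm = TRUE)
  cols <- palette(64)
  r_out <- c(1, 0.72, 0.44)
  r_in <- c(0.72, 0.44, 0.16)
  op <- graphics::par(mar = c(1, 1, 3, 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1), asp = 1,
                 axes = FALSE, xlab = "", ylab = "",
                 main = "Segmental ECV (fraction)")
  for (i in 1:16) {
    th <- seq(layout$start_deg[i], layout$end_deg[i], length.out = 32) *
      pi / 180 + pi / 2   # sector 1 starts at 12 o'clock
    ri <- r_in[layout$ring[i]]; ro <- r_out[layout$ring[i]]
    px <- c(ro * cos(th), rev(ri * cos(th)))
    py <- c(ro * sin(th), rev(ri * sin(th)))
    if (layout$excluded[i] || is.na(vals[i])) {
      graphics::polygon(px, py, col = "grey85", density = 15, angle = 45)
    } else {
      f <- (vals[i] - zlim[1]) / diff(zlim)
      col <- cols[pmax(1, pmin(64, 1 + floor(f * 63)))]
      graphics::polygon(px, py, col = col)
      mid <- (layout$start_deg[i] + layout$end_deg[i]) / 2 * pi / 180 + pi / 2
      rm <- (ri + ro) / 2
      graphics::text(rm * cos(mid), rm * sin(mid),
                     sprintf("%.2f", vals[i]), cex = 0.8)
    }
  }
  invisible(layout)
}
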