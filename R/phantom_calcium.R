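# Synthetic unenhanced CT with calcified plaques of known area and peak
# attenuation, for validating the Agatston score.

#' Generate a calcium-scoring phantom
#'
#' Places disc-shaped calcified plaques of requested in-plane area and peak
#' HU on individual axial slices over a soft-tissue background that stays
#' below the 130 HU scoring threshold everywhere outside the plaques.
#'
#' @param spec a [phantom_spec]; supplies grid shape, spacing, background
#'   HU, noise SD (truncated so background never reaches 130 HU) and seed.
#' @param plaques data.frame with columns `x`, `y` (mm, in-plane centre),
#'   `slice` (axial slice index), `area_mm2` and `peak_hu` (>= 130 for a
#'   scoreable plaque).
#' @return List with `volume` (a [ct_volume]) and `truth` listing the
#'   realised lesions (slice, voxel-quantised area, peak HU). Overlapping
#'   plaques are merged into one lesion with a warning.
#' @export
generate_calcium_volume <- function(spec, plaques) {
  stopifnot(inherits(spec, "phantom_spec"))
  plaques <- as.data.frame(plaques)
  d <- spec$grid_shape
  sp <- spec$spacing
  pix_area <- sp[1] * sp[2]
  bg <- min(spec$hu_background, 50)
  vol <- array(bg, d)
  plaque_id <- array(0L, d)
  if (nrow(plaques) > 0) {
    stopifnot(all(c("x", "y", "slice", "area_mm2", "peak_hu") %in%
                    names(plaques)))
    if (any(plaques$peak_hu < 130))
      warning("plaque peak below 130 HU will not be scoreable")
    ax_x <- (seq_len(d[1]) - 1) * sp[1]
    ax_y <- (seq_len(d[2]) - 1) * sp[2]
    gx <- rep(ax_x, times = d[2])
    gy <- rep(ax_y, each = d[1])
    for (r in seq_len(nrow(plaques))) {
      p <- plaques[r, ]
      n_pix <- max(1L, round(p$area_mm2 / pix_area))
      dd <- (gx - p$x)^2 + (gy - p$y)^2
      sel <- order(dd)[seq_len(n_pix)]
      k <- as.integer(p$slice)
      sl <- vol[, , k]
      ov <- plaque_id[, , k]
      if (any(ov[sel] > 0))
        warning("overlapping plaques merged into one lesion")
      sl[sel] <- pmax(sl[sel], p$peak_hu)
      ov[sel] <- r
      vol[, , k] <- sl
      plaque_id[, , k] <- ov
    }
  }
  vol <- with_seed(spec$seed, {
    if (spec$noise_sd > 0) {
      noise <- array(stats::rnorm(prod(d), 0, spec$noise_sd), d)
      # keep background strictly below the scoring threshold
      out <- vol + noise
      bgmask <- plaque_id == 0L
      out[bgmask] <- pmin(out[bgmask], 129)
      out
    } else vol
  })
  # realised lesions: merged connected groups of plaque voxels
  realised <- list()
  if (any(plaque_id > 0)) {
    comp <- label_components(plaque_id > 0, connectivity = 4)
    for (id in seq_len(max(comp))) {
      m <- comp == id
      k <- unique(((which(m) - 1) %/% (d[1] * d[2])) + 1)
      realised[[id]] <- list(slice = k, area_mm2 = sum(m) * pix_area,
                             peak_hu = max(vol[m]))
    }
  }
  truth <- structure(list(spec = spec, plaques = plaques,
                          lesions = realised),
                     class = "phantom_truth")
  list(volume = ct_volume(vol, sp, c(0, 0, 0)), truth = truth)
}
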