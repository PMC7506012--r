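# Coronary calcium (Agatston) scoring, CAD-RADS banding, chamber volumes
# and mass, BSA indexing and the dose conversion.

#' Agatston coronary calcium score
#'
#' Per axial slice, 4-connected components of voxels at or above 130 HU
#' with in-plane area >= 1 mm^2 form lesions. Each lesion scores
#' `area (mm^2) x density weight x (slice thickness / 3 mm)`, the weight
#' being 1/2/3/4 for a peak HU in \[130,200)/\[200,300)/\[300,400)/>=400.
#' The total score is the sum over lesions (classic 3-mm-slice convention,
#' generalised by the thickness factor).
#'
#' @param volume an unenhanced [ct_volume] with known spacing.
#' @param threshold scoring threshold in HU (130 by convention).
#' @param min_area_mm2 minimum lesion area.
#' @return List with `total` (the Agatston score) and `lesions`, a
#'   data.frame with slice, area, peak HU, weight and lesion score.
#' @export
agatston <- function(volume, threshold = 130, min_area_mm2 = 1) {
  stopifnot(is_ct_volume(volume))
  sp <- volume$spacing
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("validation error: voxel spacing must be known and positive")
  pix_area <- sp[1] * sp[2]
  thick_factor <- sp[3] / 3
  mask <- !is.na(volume$data) & volume$data >= threshold
  lesions <- data.frame(slice = integer(), area_mm2 = numeric(),
                        peak_hu = numeric(), weight = integer(),
                        score = numeric())
  if (any(mask)) {
    comp <- label_components(mask, connectivity = 4)
    for (id in seq_len(max(comp))) {
      m <- comp == id
      area <- sum(m) * pix_area
      if (area < min_area_mm2) next
      k <- unique(((which(m) - 1) %/% (dim(m)[1] * dim(m)[2])) + 1)
      peak <- max(volume$data[m])
      w <- agatston_weight(peak)
      lesions <- rbind(lesions, data.frame(
        slice = k, area_mm2 = area, peak_hu = peak, weight = w,
        score = area * w * thick_factor))
    }
  }
  list(total = sum(lesions$score), lesions = lesions)
}

agatston_weight <- function(peak_hu) {
  if (peak_hu >= 400) 4L
  else if (peak_hu >= 300) 3L
  else if (peak_hu >= 200) 2L
  else 1L
}

#' CAD-RADS category from per-vessel stenosis
#'
#' Maximum-severity banding: 0 no atherosclerotic change; 1 for 1-24%
#' stenosis; 2 for 25-49%; 3 for 50-69%; 4A for 70-99% in 1-2 vessels;
#' 4B for 70-99% in 3 vessels or >= 50% left-main stenosis; 5 for any
#' total (100%) occlusion. Category 5 takes precedence over 4B, and the
#' left-main rule is checked before the vessel counts. Obstructive CAD is
#' a category of 3 or higher (>= 50% stenosis in >= 1 vessel).
#'
#' @param vessels named or unnamed numeric vector of per-vessel maximum
#'   stenosis percentages (typically LAD, LCX, RCA).
#' @param left_main left-main stenosis percentage.
#' @return List with `category` (character: "0","1","2","3","4A","4B","5")
#'   and `obstructive` (logical).
#' @examples
#' cad_rads(c(LAD = 80, LCX = 20, RCA = 10))
#' @export
cad_rads <- function(vessels, left_main = 0) {
  st <- c(vessels, left_main)
  if (any(!is.finite(st)) || any(st < 0) || any(st > 100))
    stop("validation error: stenosis values must lie in [0, 100]")
  n70 <- sum(vessels >= 70 & vessels < 100)
  total_occlusion <- any(st == 100)
  category <-
    if (total_occlusion) "5"
    else if (left_main >= 50 || n70 == 3) "4B"
    else if (n70 >= 1) "4A"
    else {
      m <- max(st)
      if (m >= 50) "3" else if (m >= 25) "2" else if (m >= 1) "1" else "0"
    }
  list(category = category,
       obstructive = category %in% c("3", "4A", "4B", "5"))
}

#' Biplane area-length left atrial volume
#'
#' `V = (8 / (3 pi)) * A1 * A2 / L` with areas in cm^2 and length in cm,
#' returning mL.
#'
#' @param a1_cm2,a2_cm2 chamber areas in two orthogonal views (cm^2).
#' @param l_cm long-axis length (cm).
#' @return Volume in mL.
#' @export
la_volume_biplane <- function(a1_cm2, a2_cm2, l_cm) {
  if (any(l_cm == 0)) stop("division error: length must be non-zero")
  if (any(a1_cm2 < 0) || any(a2_cm2 < 0) || any(l_cm < 0))
    stop("validation error: inputs must be non-negative")
  (8 / (3 * pi)) * a1_cm2 * a2_cm2 / l_cm
}

#' Modified Simpson (method-of-discs) biplane volume
#'
#' `V = (pi / 4) * sum(a_i * b_i) * (L / n)` from paired orthogonal disc
#' diameters (cm) in the 4- and 2-chamber views.
#'
#' @param diameters_4ch,diameters_2ch equal-length vectors of disc
#'   diameters (cm).
#' @param length_cm chamber long-axis length (cm).
#' @return Volume in mL.
#' @export
simpson_biplane_volume <- function(diameters_4ch, diameters_2ch, length_cm) {
  if (length(diameters_4ch) != length(diameters_2ch))
    stop("validation error: disc counts differ between views")
  if (length_cm <= 0) stop("validation error: length must be positive")
  n <- length(diameters_4ch)
  (pi / 4) * sum(diameters_4ch * diameters_2ch) * (length_cm / n)
}

#' LV mass from myocardial volume
#'
#' Myocardial density 1.05 g/mL.
#'
#' @param myocardial_volume_ml myocardial volume (mL).
#' @param density_g_ml tissue density, default 1.05.
#' @return Mass in grams.
#' @export
lv_mass <- function(myocardial_volume_ml, density_g_ml = 1.05) {
  if (any(myocardial_volume_ml < 0))
    stop("validation error: volume must be non-negative")
  myocardial_volume_ml * density_g_ml
}

#' Body surface area (Du Bois) and BSA indexing
#'
#' `BSA = 0.007184 * height^0.725 * weight^0.425` (height cm, weight kg).
#'
#' @param height_cm,weight_kg positive body measures.
#' @return BSA in m^2.
#' @export
bsa_dubois <- function(height_cm, weight_kg) {
  if (any(height_cm <= 0) || any(weight_kg <= 0))
    stop("validation error: height and weight must be positive")
  0.007184 * height_cm^0.725 * weight_kg^0.425
}

#' @rdname bsa_dubois
#' @param value raw measurement (e.g. mass g, volume mL).
#' @param bsa body surface area (m^2).
#' @return `bsa_index`: the BSA-indexed value (per m^2).
#' @export
bsa_index <- function(value, bsa) {
  if (any(bsa <= 0)) stop("validation error: BSA must be positive")
  value / bsa
}

#' Effective dose from dose-length product
#'
#' `dose (mSv) = DLP (mGy cm) x k`, with the chest conversion coefficient
#' `k = 0.014 mSv / (mGy cm)` by default.
#'
#' @param dlp_mgy_cm dose-length product (mGy cm), non-negative.
#' @param k_msv_per_mgy_cm body-region conversion coefficient.
#' @return Effective dose in mSv.
#' @examples
#' effective_dose(806.7)
#' @export
effective_dose <- function(dlp_mgy_cm, k_msv_per_mgy_cm = 0.014) {
  if (any(dlp_mgy_cm < 0))
    stop("validation error: DLP must be non-negative")
  dlp_mgy_cm * k_msv_per_mgy_cm
}
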