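# Synthetic dynamic-perfusion data: a gamma-variate arterial input and
# per-segment tissue time-attenuation curves encoding known MBF.

#' Generate synthetic perfusion time-attenuation curves
#'
#' The arterial input is a gamma-variate bolus. Tissue uptake follows the
#' single-compartment maximum-slope model: the tissue curve is the running
#' integral of the arterial curve scaled by flow, so before noise its
#' maximum upslope is exactly `true_mbf * peak_arterial / 6000` HU/s
#' (MBF in mL/100mL/min).
#'
#' @param spec a [phantom_spec]; only `noise_sd` (scaled down to curve
#'   noise) and `seed` are used here.
#' @param true_mbf 16 per-segment MBF values, mL/100mL/min (> 0).
#' @param dt sampling interval in seconds (> 0).
#' @param duration acquisition length in seconds.
#' @param arterial_peak peak arterial enhancement (HU).
#' @param noise_sd SD of Gaussian noise added to the tissue curves (HU);
#'   defaults to 0 (analytically exact curves).
#' @return List with `time` (s), `arterial` (HU), `tissue` (matrix,
#'   samples x 16, HU) and `truth` (`phantom_truth` carrying `true_mbf`).
#' @export
generate_perfusion_series <- function(spec, true_mbf = rep(100, 16), dt = 1,
                                      duration = 30, arterial_peak = 200,
                                      noise_sd = 0) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (dt <= 0) stop("validation error: dt must be positive")
  if (length(true_mbf) != 16 || any(true_mbf <= 0))
    stop("validation error: true_mbf must be 16 positive values")
  tt <- seq(0, duration, by = dt)
  # gamma-variate bolus, peak normalised to arterial_peak at t = tp
  t0 <- 4; alpha <- 3; tp <- 8
  tau <- pmax(tt - t0, 0) / tp
  arterial <- arterial_peak * tau^alpha * exp(alpha * (1 - tau))
  # tissue = flow * cumulative arterial exposure (Fick, no venous outflow
  # over the first pass); flow in (mL/mL)/s = MBF / 100 / 60
  cumart <- cumsum(arterial) * dt
  tissue <- outer(cumart, true_mbf / 6000)
  tissue <- with_seed(spec$seed, {
    if (noise_sd > 0)
      tissue + matrix(stats::rnorm(length(tissue), 0, noise_sd),
                      nrow(tissue))
    else tissue
  })
  truth <- structure(list(spec = spec, true_mbf = true_mbf, dt = dt,
                          arterial_peak = max(arterial)),
                     class = "phantom_truth")
  list(time = tt, arterial = arterial, tissue = tissue, truth = truth)
}
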