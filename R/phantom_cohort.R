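# Simulated two-group cohorts (hemodialysis vs control) with the
# demographic and imaging summary statistics the analysis assumes.

#' Cohort simulation parameters
#'
#' Defaults reproduce the published two-group structure of a hemodialysis
#' (HD) vs propensity-matched control comparison: per-group means/SDs for
#' ECV (%), hematocrit (%), left atrial volume index (mL/m^2), LV mass
#' index (g/m^2), age and BMI, binary covariate prevalences, and the
#' within-group ECV-LAVI correlation.
#'
#' @param n_per_group subjects per group (>= 2).
#' @param continuous data.frame with columns `variable`, `mean_hd`,
#'   `sd_hd`, `mean_control`, `sd_control`. Must contain rows `ecv` and
#'   `lavi` (drawn jointly).
#' @param binary data.frame with columns `variable`, `p_hd`, `p_control`.
#' @param ecv_lavi_correlation within-group Pearson correlation between
#'   ECV and LAVI, |rho| < 1.
#' @param seed integer seed.
#' @return Object of class `cohort_params`.
#' @export
cohort_params <- function(
    n_per_group = 20,
    continuous = data.frame(
      variable = c("ecv", "hematocrit", "lavi", "lvmi", "age", "bmi"),
      mean_hd = c(33.8, 33.4, 51.9, 90.9, 67.4, 23.4),
      sd_hd = c(4.7, 5.0, 22.4, 28.9, 9.6, 3.8),
      mean_control = c(26.6, 41.0, 30.2, 64.5, 66.3, 23.7),
      sd_control = c(2.9, 3.9, 10.4, 11.0, 9.1, 2.3)),
    binary = data.frame(
      variable = c("male", "hypertension", "diabetes", "dyslipidemia",
                   "smoking", "prior_pci", "prior_mi"),
      p_hd = c(0.80, 0.90, 0.55, 0.45, 0.25, 0.35, 0.15),
      p_control = c(0.85, 0.80, 0.50, 0.55, 0.25, 0.40, 0.20)),
    ecv_lavi_correlation = 0.54,
    seed = 1L) {
  if (n_per_group < 2)
    stop("validation error: n_per_group must be at least 2")
  continuous <- as.data.frame(continuous)
  binary <- as.data.frame(binary)
  if (any(continuous$sd_hd <= 0) || any(continuous$sd_control <= 0))
    stop("validation error: all SDs must be positive")
  if (any(binary$p_hd < 0 | binary$p_hd > 1 |
          binary$p_control < 0 | binary$p_control > 1))
    stop("validation error: prevalences must lie in [0, 1]")
  if (abs(ecv_lavi_correlation) >= 1)
    stop("validation error: |ecv_lavi_correlation| must be < 1")
  if (!all(c("ecv", "lavi") %in% continuous$variable))
    stop("continuous parameters must include `ecv` and `lavi`")
  structure(list(n_per_group = as.integer(n_per_group),
                 continuous = continuous, binary = binary,
                 ecv_lavi_correlation = ecv_lavi_correlation,
                 seed = seed),
            class = "cohort_params")
}

#' Simulate a two-group cohort table
#'
#' Continuous variables are drawn from normal distributions at the stated
#' group means/SDs; ECV and LAVI are drawn jointly with the requested
#' within-group correlation; binary covariates are Bernoulli at the stated
#' prevalences.
#'
#' @param params a [cohort_params].
#' @return data.frame, one row per subject, with a `group` factor
#'   (`"HD"`/`"Control"`) followed by the covariate columns.
#' @examples
#' head(generate_cohort(cohort_params(n_per_group = 5)))
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  n <- params$n_per_group
  rho <- params$ecv_lavi_correlation
  with_seed(params$seed, {
    draw_group <- function(which) {
      mcol <- paste0("mean_", which); scol <- paste0("sd_", which)
      cc <- params$continuous
      out <- list()
      i_ecv <- match("ecv", cc$variable)
      i_lav <- match("lavi", cc$variable)
      mu <- c(cc[[mcol]][i_ecv], cc[[mcol]][i_lav])
      sd2 <- c(cc[[scol]][i_ecv], cc[[scol]][i_lav])
      Sigma <- diag(sd2^2)
      Sigma[1, 2] <- Sigma[2, 1] <- rho * sd2[1] * sd2[2]
      el <- MASS::mvrnorm(n, mu, Sigma)
      out$ecv <- el[, 1]
      out$lavi <- el[, 2]
      for (r in seq_len(nrow(cc))) {
        v <- cc$variable[r]
        if (v %in% c("ecv", "lavi")) next
        out[[v]] <- stats::rnorm(n, cc[[mcol]][r], cc[[scol]][r])
      }
      pcol <- paste0("p_", which)
      for (r in seq_len(nrow(params$binary)))
        out[[params$binary$variable[r]]] <-
          stats::rbinom(n, 1, params$binary[[pcol]][r])
      as.data.frame(out)
    }
    hd <- draw_group("hd")
    ctrl <- draw_group("control")
    cbind(group = factor(rep(c("HD", "Control"), each = n),
                         levels = c("HD", "Control")),
          rbind(hd, ctrl))
  })
}
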