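# Measure-level cohort generator: draws per-subject tissue extents and
# dyssynchrony indices with the between-subject statistical structure of an
# acute anterior-infarct cohort, without rendering images. The image-level
# route (one rendered phantom per subject) uses phantom_config() directly.

#' Distributional settings for the synthetic cohort
#'
#' Defaults are calibrated to an acute anterior-infarct population: edema
#' extent 57.5 +/- 14 %circumference; necrosis occupying on average 53% of
#' the edema arc (giving necrosis extent approximately 30.6 +/- 12.6 %circ);
#' necrosis mass approximately 29.6 +/- 9.9 %LV; acute CURE 0.91 +/- 0.05
#' linked linearly to edema extent so that the edema--CURE coefficient of
#' determination is about 0.63; follow-up CURE higher by an amount that
#' grows with acute necrosis extent (dyssynchrony regresses most in
#' ventricles with the largest necrosis), around 0.94 +/- 0.03; LVEDV
#' 156.8 +/- 50.5 ml, EF 40.5 +/- 8.2 %, LV mass 133 +/- 36 g.
#'
#' @param ... Named overrides of any default.
#' @return A named list of parameters.
#' @export
cohort_params <- function(...) {
  p <- list(
    edema_mean = 57.5, edema_sd = 14,
    necrosis_frac_mean = 0.532, necrosis_frac_sd = 0.15,
    mass_slope = 0.7, mass_intercept = 8.2, mass_sd = 4,
    cure_acute_mean = 0.91,
    cure_slope = -0.002835,      # CURE units per %circ edema
    cure_noise_sd = 0.0304,
    dcure_slope = 0.001,         # CURE recovery per %circ necrosis
    dcure_intercept = -0.0006,
    dcure_noise_sd = 0.02,
    lvedv_mean = 156.8, lvedv_sd = 50.5,
    ef_mean = 40.5, ef_sd = 8.2,
    lv_mass_mean = 133, lv_mass_sd = 36)
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown)) stop("unknown cohort parameter(s): ",
                            paste(unknown, collapse = ", "))
  p[names(over)] <- over
  p
}

#' Configured edema--CURE coefficient of determination
#'
#' The r-squared implied by the generator's linear link,
#' `slope^2 * var(edema) / (slope^2 * var(edema) + noise^2)`, before
#' range clipping.
#'
#' @param params A [cohort_params()] list.
#' @return Scalar r-squared in \[0, 1\].
#' @export
cohort_r2 <- function(params = cohort_params()) {
  expl <- params$cure_slope^2 * params$edema_sd^2
  expl / (expl + params$cure_noise_sd^2)
}

#' Generate a measure-level synthetic cohort
#'
#' Draws one record per subject: edema extent, nested necrosis extent
#' (necrosis is a fraction of the edema arc, so salvage = edema - necrosis
#' is non-negative by construction), necrosis mass, acute and follow-up
#' CURE via configurable linear links with Gaussian noise, and global LV
#' measures. All values are clipped to their valid ranges; reproducible
#' given the seed.
#'
#' @param n Number of subjects (>= 2).
#' @param params A [cohort_params()] list.
#' @param seed Integer seed.
#' @return A `cohort_table` data frame with columns `subject`,
#'   `edema_extent`, `necrosis_extent`, `necrosis_mass`, `salvage`,
#'   `CURE_acute`, `CURE_followup`, `LVEDV`, `LVESV`, `LV_mass`, `EF`.
#' @export
#' @examples
#' head(generate_cohort_measures(22, seed = 7))
generate_cohort_measures <- function(n, params = cohort_params(), seed = 1L) {
  if (n < 2) stop("n must be at least 2")
  sds <- params[grep("_sd$", names(params))]
  if (any(unlist(sds) < 0)) stop("variance settings must be non-negative")
  if (params$edema_sd == 0 || params$lvedv_sd == 0) {
    stop("variance settings must be positive")
  }
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  with_seed(seed, {
    edema <- clip(stats::rnorm(n, params$edema_mean, params$edema_sd), 0, 100)
    frac <- clip(stats::rnorm(n, params$necrosis_frac_mean,
                              params$necrosis_frac_sd), 0, 1)
    necrosis <- edema * frac
    necro_mass <- clip(params$mass_intercept + params$mass_slope * necrosis +
                         stats::rnorm(n, 0, params$mass_sd), 0, 100)
    b0 <- params$cure_acute_mean - params$cure_slope * params$edema_mean
    cure_a <- clip(b0 + params$cure_slope * edema +
                     stats::rnorm(n, 0, params$cure_noise_sd), 0, 1)
    dcure <- params$dcure_intercept + params$dcure_slope * necrosis +
      stats::rnorm(n, 0, params$dcure_noise_sd)
    cure_f <- clip(cure_a + dcure, 0, 1)
    lvedv <- clip(stats::rnorm(n, params$lvedv_mean, params$lvedv_sd), 20, Inf)
    ef <- clip(stats::rnorm(n, params$ef_mean, params$ef_sd), 5, 80)
    lv_mass <- clip(stats::rnorm(n, params$lv_mass_mean, params$lv_mass_sd),
                    20, Inf)
    tab <- data.frame(subject = seq_len(n),
                      edema_extent = edema,
                      necrosis_extent = necrosis,
                      necrosis_mass = necro_mass,
                      salvage = edema - necrosis,
                      CURE_acute = cure_a,
                      CURE_followup = cure_f,
                      LVEDV = lvedv,
                      LVESV = lvedv * (1 - ef / 100),
                      LV_mass = lv_mass,
                      EF = ef)
    if (stats::sd(tab$CURE_acute) == 0) {
      warning("CURE_acute is constant across subjects; ",
              "correlations with it are undefined")
    }
    class(tab) <- c("cohort_table", "data.frame")
    tab
  })
}
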