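# Latent subject model: age-linked anatomy (cortical thickness), tissue
# oxygenation and hemoglobin, their mapping to per-wavelength optical
# properties, and the simulated covariate battery.

# Population SD of age for a uniform 18-78 cohort; correlations are targeted
# against this population scale so they converge at large n.
.age_sd <- function(config) diff(config$age_range) / sqrt(12)
.age_z <- function(age, config) (age - mean(config$age_range)) / .age_sd(config)

#' Sample one latent subject
#'
#' Draws cortical thickness as a linear-in-age trend plus noise (target
#' r(age, thickness) from the config), tissue oxygen saturation declining
#' weakly with age, log-normal total hemoglobin, and per-wavelength optical
#' properties: absorption follows the hemoglobin forward model exactly
#' ([derive_mua()]); reduced scattering carries the calibrated anatomy factor
#' (routed through thickness: thinner cortex means a thicker, clearer CSF
#' layer and hence lower scattering and lower EAC) plus independent
#' per-wavelength dispersion. Also draws the simulated covariate battery
#' (cortical volume, WMSA, CRF, heart rate, HRV, PReFx, neuropsychological
#' test scores).
#'
#' @param age Age in years, within the config's `age_range`.
#' @param config An `eac_config`.
#' @param seed Integer seed.
#' @param sex 1 = male, 2 = female (recorded, no effect on optics).
#' @param calib Optional precomputed [calibrate_cohort_optics()] result.
#' @return An object of class `eac_subject` (a named list of latents,
#'   optical properties per wavelength, and true EAC values).
#' @export
sample_subject <- function(age, config, seed, sex = 1L,
                           calib = calibrate_cohort_optics(config)) {
  stopifnot(inherits(config, "eac_config"))
  if (age < config$age_range[1] || age > config$age_range[2]) {
    stop("age must lie in [", config$age_range[1], ", ", config$age_range[2], "]")
  }
  nu <- config$covariate_noise
  za <- .age_z(age, config)
  withr::with_seed(seed, {
    rnoise <- function() nu * stats::rnorm(1)
    mix <- function(r, z, e) r * z + sqrt(1 - r^2) * e

    thick_z <- mix(config$r_age_thickness, za, rnoise())
    thickness <- config$thickness_mean_mm + config$thickness_sd_mm * thick_z
    so2 <- min(1, max(0, config$so2_mean + config$so2_sd *
                        mix(config$r_age_so2, za, rnoise())))
    s_thb <- sqrt(log1p(config$thb_cv^2))
    e_thb <- rnoise()
    total_hb <- config$thb_mean_um * exp(s_thb * e_thb - (nu * s_thb)^2 / 2)

    rho <- config$anatomy_rho
    anatomy <- rho * thick_z + sqrt(1 - rho^2) * rnoise()
    musp <- calib$musp_base * exp(calib$beta_anat * anatomy +
                                    calib$sigma_musp_noise * c(rnoise(), rnoise()))
    mua <- derive_mua(so2, total_hb, calib$wavelength_nm)
    eac <- mu_eff_from_coefficients(mua, musp, "exact")

    # covariate battery: loadings solved so that population correlations with
    # age (and thickness where stated) match the emulated cross-sectional
    # structure; noise scaled by covariate_noise
    volume <- 1 + 0.10 * (-0.5246 * za + 0.4390 * thick_z + 0.4824 * rnoise())
    wmsa <- 8 + 0.8 * mix(0.552, za, rnoise())
    crf <- max(2, 10 + 2.5 * mix(-0.741, za, rnoise()))
    hr_bpm <- max(40, 68 + 8 * mix(-0.144, za, rnoise()))
    hrv_ms <- max(5, 50 + 20 * mix(-0.635, za, rnoise()))
    prefx <- 0.20 + 0.05 * mix(-0.409, za, rnoise())

    perf_z <- -0.2529 * za + 0.3356 * thick_z + 0.8444 * rnoise()
    verbal_z <- mix(0.43, za, rnoise())
    tload <- function(lz) 0.8 * lz + 0.6 * rnoise()
    tests <- list(
      raven = 50 + 10 * tload(perf_z),
      digit_span_forward = 7 + 1.5 * tload(perf_z),
      digit_span_backward = 5.5 + 1.5 * tload(perf_z),
      ospan = 40 + 12 * tload(perf_z),
      trail_a_s = max(8, 30 - 7 * tload(perf_z)),
      trail_b_s = max(15, 70 - 16 * tload(perf_z)),
      shipley_vocabulary = 30 + 4 * tload(verbal_z),
      verbal_fluency = 40 + 10 * tload(verbal_z)
    )
    tests$trail_b_minus_a_s <- tests$trail_b_s - tests$trail_a_s

    structure(list(
      age = age, sex = sex, seed = seed,
      thickness_mm = thickness, cortical_volume = volume, wmsa_log_voxels = wmsa,
      so2 = so2, total_hb_um = total_hb,
      crf_mets = crf, hr_bpm = hr_bpm, hrv_ms = hrv_ms, prefx = prefx,
      performance_z = perf_z, verbal_z = verbal_z, tests = tests,
      wavelength_nm = calib$wavelength_nm,
      mua = mua, musp = musp, eac = eac
    ), class = "eac_subject")
  })
}

#' @export
print.eac_subject <- function(x, ...) {
  cat(sprintf("eac_subject: age %.1f, thickness %.2f mm, SO2 %.2f, tHb %.1f uM\n",
              x$age, x$thickness_mm, x$so2, x$total_hb_um))
  cat(sprintf("  EAC: %.4f (690 nm), %.4f (830 nm) mm^-1\n", x$eac[1], x$eac[2]))
  invisible(x)
}
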