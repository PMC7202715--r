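# Simulation configuration and the analytic calibration that ties the latent
# subject model (age, thickness, oxygenation, hemoglobin) to the cohort-level
# EAC targets (means/SDs per wavelength and the inter-wavelength correlation).

#' Build a simulation configuration for a synthetic cohort
#'
#' The defaults define the emulated study conditions: 48 subjects uniform in
#' age 18-78 (balanced sex per decade), four montage placements per subject
#' with ~384 channels per wavelength each at 15-80 mm, 39.0625 Hz sampling,
#' Poisson shot noise around the diffusion forward model, sub-10 Hz
#' physiological modulation, and cohort calibration targets for the EAC
#' distribution and the age/thickness/oxygenation correlation structure.
#'
#' @param n_subjects Number of subjects.
#' @param master_seed Master seed; all randomness derives from it.
#' @param fs_hz Sampling rate (must exceed 20 Hz so a >10 Hz band exists).
#' @param block_s Block duration, seconds.
#' @param photon_budget Expected counts per sample at a gain-1 reference
#'   channel of 20 mm (Inf for the deterministic noise-free limit).
#' @param cardiac_amp,resp_amp,drift_amp Fractional modulation amplitudes of
#'   the cardiac, respiratory and slow-drift components.
#' @param cardiac_hz,resp_hz,drift_hz Their center frequencies (cardiac is
#'   per-subject, around this default).
#' @param n_montages Montage placements per subject (shared geometry across
#'   subjects, fresh optode gains per subject and placement).
#' @param n_source_pairs,n_detectors,head_radius_mm,theta_max_deg,gain_sigma
#'   Montage geometry and gain-heterogeneity parameters.
#' @param eac_mean_690,eac_sd_690,eac_mean_830,eac_sd_830,eac_r Cohort EAC
#'   calibration targets (mm^-1 and Pearson r between wavelengths).
#' @param r_age_thickness,r_age_so2 Latent correlation targets.
#' @param so2_mean,so2_sd,thb_mean_um,thb_cv,thickness_mean_mm,thickness_sd_mm
#'   Latent physiological distribution parameters.
#' @param anatomy_rho Fraction (as a correlation) of the anatomy factor carried
#'   by cortical thickness; the remainder is thickness-independent anatomy.
#' @param field_occipital,field_lateral Amplitudes of the fixed cohort-level
#'   azimuthal EAC field (occipital-frontal and lobe terms); 0 disables it.
#' @param covariate_noise Multiplier on every latent noise draw (0 makes the
#'   generator a deterministic function of age).
#' @param age_range Admissible age range, years.
#' @return A list of class `eac_config`.
#' @export
simulation_config <- function(n_subjects = 48,
                              master_seed = 1,
                              fs_hz = 39.0625,
                              block_s = 30,
                              photon_budget = 1e5,
                              cardiac_amp = 0.02, cardiac_hz = 1.1,
                              resp_amp = 0.01, resp_hz = 0.25,
                              drift_amp = 0.005, drift_hz = 0.03,
                              n_montages = 4,
                              n_source_pairs = 48, n_detectors = 32,
                              head_radius_mm = 90, theta_max_deg = 100,
                              gain_sigma = 0.5,
                              eac_mean_690 = 0.192, eac_sd_690 = 0.040,
                              eac_mean_830 = 0.170, eac_sd_830 = 0.036,
                              eac_r = 0.85,
                              r_age_thickness = -0.65,
                              r_age_so2 = -0.313,
                              so2_mean = 0.65, so2_sd = 0.06,
                              thb_mean_um = 70, thb_cv = 0.15,
                              thickness_mean_mm = 2.55, thickness_sd_mm = 0.16,
                              anatomy_rho = 0.9,
                              field_occipital = 0.08, field_lateral = 0.04,
                              covariate_noise = 1,
                              age_range = c(18, 78)) {
  if (fs_hz <= 20) stop("fs_hz must exceed 20 Hz (a >10 Hz band must exist below Nyquist)")
  if (photon_budget <= 0) stop("photon_budget must be > 0")
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  if (anatomy_rho < 0 || anatomy_rho > 1) stop("anatomy_rho must lie in [0, 1]")
  cfg <- as.list(environment())
  class(cfg) <- "eac_config"
  cfg
}

#' Calibrate the latent optical model against the cohort targets
#'
#' Decomposes the target per-wavelength log-EAC variance into (i) an anatomy
#' factor loading equally on both wavelengths through reduced scattering,
#' (ii) a shared total-hemoglobin factor through absorption, (iii) the SO2
#' spectral factor implied by the exact hemoglobin forward model, and (iv)
#' per-wavelength independent scattering noise. The decomposition is solved
#' analytically (delta method around the median subject); baseline reduced
#' scattering per wavelength is solved exactly so the cohort median EAC
#' matches the target log-normal median. Raises an error when the requested
#' targets are infeasible (non-positive variance shares or scattering).
#'
#' @param config An `eac_config`.
#' @return List with per-wavelength baselines and loadings: `musp_base`,
#'   `beta_anat` (log-mu_s' per anatomy SD), `sigma_musp_noise`, sensitivity
#'   terms, and the extinction table used (provenance).
#' @export
calibrate_cohort_optics <- function(config) {
  stopifnot(inherits(config, "eac_config"))
  wl <- c(690, 830)
  eps <- extinction_coefficients(wl)
  mean_t <- c(config$eac_mean_690, config$eac_mean_830)
  sd_t <- c(config$eac_sd_690, config$eac_sd_830)
  sigma_log <- sqrt(log1p((sd_t / mean_t)^2))      # log-normal SD of EAC
  eac_med <- mean_t * exp(-sigma_log^2 / 2)        # log-normal median

  mua_med <- derive_mua(config$so2_mean, config$thb_mean_um, wl)
  musp_base <- eac_med^2 / (3 * mua_med) - mua_med
  if (any(musp_base <= mua_med)) {
    stop("calibration infeasible: implied baseline mu_s' not in the mu_a << mu_s' regime")
  }

  # log-EAC sensitivities at the median subject
  d_mua <- 0.5 * (1 + mua_med / (mua_med + musp_base))
  d_musp <- 0.5 * musp_base / (mua_med + musp_base)

  eps_eff <- eps$hbo * config$so2_mean + eps$hbr * (1 - config$so2_mean)
  c_so2 <- d_mua * (eps$hbo - eps$hbr) / eps_eff * config$so2_sd
  h_thb <- d_mua * sqrt(log1p(config$thb_cv^2))

  cov_target <- config$eac_r * sigma_log[1] * sigma_log[2]
  a2 <- cov_target - h_thb[1] * h_thb[2] - c_so2[1] * c_so2[2]
  if (a2 <= 0) stop("calibration infeasible: anatomy variance share non-positive")
  w2 <- sigma_log^2 - a2 - h_thb^2 - c_so2^2
  if (any(w2 < 0)) {
    stop("calibration infeasible: requested EAC SDs are smaller than the ",
         "variance implied by the physiological factors")
  }

  list(
    wavelength_nm = wl,
    musp_base = musp_base,
    mua_median = mua_med,
    sigma_log_eac = sigma_log,
    anatomy_loading = sqrt(a2),               # log-EAC per anatomy SD
    beta_anat = sqrt(a2) / d_musp,            # log-mu_s' per anatomy SD
    sigma_musp_noise = sqrt(w2) / d_musp,     # independent log-mu_s' noise SD
    so2_loading = c_so2, thb_loading = h_thb,
    d_log_mua = d_mua, d_log_musp = d_musp,
    extinction = eps
  )
}
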