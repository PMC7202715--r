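# Tissue optics primitives: hemoglobin absorption, the effective attenuation
# coefficient, and the continuous-wave semi-infinite diffusion forward model.

# Base-10 molar extinction coefficients (cm^-1 / M) for oxy- and
# deoxy-hemoglobin at the two laser-diode wavelengths, from the standard
# compiled in-vitro spectra (OMLC compilation).
.extinction_cm_M <- data.frame(
  wavelength_nm = c(690, 830),
  hbo = c(276.0, 974.0),
  hbr = c(2051.96, 693.04)
)

#' Hemoglobin extinction coefficients at the supported wavelengths
#'
#' Returns base-10 extinction coefficients for oxy- (HbO) and
#' deoxy-hemoglobin (HbR), converted to mm^-1 per micromolar so that
#' `mu_a = log(10) * (eps_hbo * SO2 + eps_hbr * (1 - SO2)) * tHb_uM`.
#'
#' @param wavelength_nm Wavelength in nm; only 690 and 830 are supported.
#' @return A data frame with columns `wavelength_nm`, `hbo`, `hbr`
#'   (mm^-1 uM^-1, base 10).
#' @export
extinction_coefficients <- function(wavelength_nm = c(690, 830)) {
  i <- match(wavelength_nm, .extinction_cm_M$wavelength_nm)
  if (anyNA(i)) {
    stop("unsupported wavelength: ", paste(wavelength_nm[is.na(i)], collapse = ", "),
         " (only 690 and 830 nm are supported)")
  }
  # cm^-1/M -> mm^-1/uM: divide by 10 (cm -> mm) and by 1e6 (M -> uM)
  data.frame(
    wavelength_nm = wavelength_nm,
    hbo = .extinction_cm_M$hbo[i] * 1e-7,
    hbr = .extinction_cm_M$hbr[i] * 1e-7
  )
}

#' Absorption coefficient from oxygenation and total hemoglobin
#'
#' Forward hemoglobin model for the absorption coefficient:
#' `mu_a = ln(10) * (eps_HbO(lambda) * SO2 + eps_HbR(lambda) * (1 - SO2)) * tHb`
#' plus an optional fixed background (water/lipid) offset.
#'
#' @param so2 Tissue oxygen saturation, fraction in \[0, 1\].
#' @param total_hb Total hemoglobin concentration, micromolar.
#' @param wavelength_nm 690 or 830.
#' @param background Fixed background absorption offset, mm^-1 (default 0).
#' @return Absorption coefficient, mm^-1.
#' @export
derive_mua <- function(so2, total_hb, wavelength_nm, background = 0) {
  if (any(so2 < 0 | so2 > 1)) stop("so2 must lie in [0, 1]")
  if (any(total_hb < 0)) stop("total_hb must be >= 0")
  eps <- extinction_coefficients(wavelength_nm)
  log(10) * (eps$hbo * so2 + eps$hbr * (1 - so2)) * total_hb + background
}

#' Effective attenuation coefficient from absorption and reduced scattering
#'
#' `mu_eff = sqrt(3 * mu_a * (mu_a + mu_s'))`, or the approximate form
#' `sqrt(3 * mu_a * mu_s')` valid when absorption is much weaker than
#' reduced scattering (the usual regime for head tissue in the NIR band).
#'
#' @param mua Absorption coefficient, mm^-1 (>= 0).
#' @param musp Reduced scattering coefficient, mm^-1 (> 0).
#' @param mode `"exact"` or `"approximate"`.
#' @return Effective attenuation coefficient, mm^-1.
#' @export
mu_eff_from_coefficients <- function(mua, musp, mode = c("exact", "approximate")) {
  mode <- match.arg(mode)
  if (any(mua < 0)) stop("mua must be >= 0")
  if (any(musp <= 0)) stop("musp must be > 0")
  if (mode == "exact") sqrt(3 * mua * (mua + musp)) else sqrt(3 * mua * musp)
}

#' Continuous-wave reflectance forward model
#'
#' Expected detected counts for a semi-infinite homogeneous medium with zero
#' boundary conditions: `I(r) = amplitude * exp(-mu_eff * r) / r^2`, so that
#' `ln(I * r^2)` is exactly linear in source-detector distance with slope
#' `-mu_eff`.
#'
#' @param mu_eff Effective attenuation coefficient, mm^-1 (>= 0).
#' @param r_mm Source-detector distance, mm (> 0).
#' @param amplitude Source amplitude in expected counts at unit geometry.
#' @return Expected counts.
#' @export
forward_intensity <- function(mu_eff, r_mm, amplitude = 1) {
  if (any(r_mm <= 0)) stop("r_mm must be > 0")
  if (any(mu_eff < 0)) stop("mu_eff must be >= 0")
  if (any(amplitude <= 0)) stop("amplitude must be > 0")
  amplitude * exp(-mu_eff * r_mm) / r_mm^2
}
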