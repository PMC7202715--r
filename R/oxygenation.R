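# Spectral analysis of the dual-wavelength EAC pair: tissue oxygenation index
# by two-wavelength inversion under a power-law scattering assumption, and
# the principal-component decomposition of the cohort's EAC wavelength space.

#' Tissue oxygenation index from the dual-wavelength EAC pair
#'
#' Assumes a scattering power law `mu_s'(lambda) = musp830 * (lambda/830)^-b`,
#' inverts the EAC definition exactly per wavelength for the absorption
#' coefficient (positive root of `3 mu_a (mu_a + mu_s') = EAC^2`; or the
#' `EAC^2 / (3 mu_s')` approximation), unmixes the two absorption values into
#' oxy- and deoxy-hemoglobin concentrations through the extinction system,
#' and returns `TOI = C_HbO / (C_HbO + C_HbR)`. Negative concentrations are
#' clamped to zero and flagged non-physical before forming the ratio. With
#' fixed `b` and reference scattering, the approximate inversion makes the
#' TOI a function of the EAC ratio only.
#'
#' @param eac_690,eac_830 EAC values, mm^-1 (> 0); vectorized.
#' @param musp830 Reference reduced scattering at 830 nm, mm^-1 (default 0.72).
#' @param b Scattering power-law exponent (default 1).
#' @param approximate Use the `mu_a ~ EAC^2/(3 mu_s')` inversion (default
#'   FALSE: exact positive root).
#' @return Data frame: `toi`, `c_hbo_um`, `c_hbr_um`, `mua_690`, `mua_830`,
#'   `musp_690`, `musp_830`, `nonphysical` flag.
#' @export
toi_from_eac <- function(eac_690, eac_830, musp830 = 0.72, b = 1,
                         approximate = FALSE) {
  if (any(c(eac_690, eac_830) <= 0)) stop("EAC values must be > 0")
  wl <- c(690, 830)
  musp <- musp830 * (wl / 830)^(-b)
  invert <- function(eac, ms) {
    if (approximate) eac^2 / (3 * ms) else
      (-3 * ms + sqrt(9 * ms^2 + 12 * eac^2)) / 6
  }
  mua <- cbind(invert(eac_690, musp[1]), invert(eac_830, musp[2]))

  eps <- extinction_coefficients(wl)
  A <- log(10) * cbind(eps$hbo, eps$hbr)        # 2x2: rows wavelengths
  if (abs(det(A)) < 1e-16) stop("configuration error: singular extinction system")
  conc <- t(solve(A, t(mua)))                   # columns: C_HbO, C_HbR (uM)
  nonphysical <- conc[, 1] < 0 | conc[, 2] < 0
  conc[conc < 0] <- 0
  tot <- conc[, 1] + conc[, 2]
  if (any(tot == 0)) stop("undefined TOI: zero total hemoglobin")
  data.frame(
    toi = conc[, 1] / tot,
    c_hbo_um = conc[, 1], c_hbr_um = conc[, 2],
    mua_690 = mua[, 1], mua_830 = mua[, 2],
    musp_690 = musp[1], musp_830 = musp[2],
    b = b, nonphysical = nonphysical
  )
}

#' Principal-component decomposition of the EAC wavelength space
#'
#' Eigendecomposition of the 2x2 covariance matrix of the per-subject
#' (EAC690, EAC830) pairs (covariance, not correlation: both variables share
#' units). The first component (both loadings positive: the common anatomy
#' axis) and the second (690 loading positive, 830 negative: the spectral
#' difference / oxygenation axis) follow fixed sign conventions.
#'
#' @param eac_690,eac_830 Per-subject EAC values (>= 3 subjects), or a
#'   two-column matrix as first argument.
#' @return Object of class `eac_pca`: `eigenvalues`, `variance_fraction`,
#'   `loadings` (2x2, columns EAC1/EAC2), `scores` (n x 2), `center`.
#' @export
wavelength_pca <- function(eac_690, eac_830 = NULL) {
  x <- if (is.null(eac_830)) as.matrix(eac_690) else cbind(eac_690, eac_830)
  colnames(x) <- c("eac690", "eac830")
  if (nrow(x) < 3) stop("need >= 3 subjects")
  cv <- stats::cov(x)
  if (all(abs(cv) < 1e-300)) stop("degenerate decomposition: zero covariance")
  eg <- eigen(cv, symmetric = TRUE)
  val <- eg$values
  vec <- eg$vectors
  if (val[1] <= 0) stop("degenerate decomposition: non-positive leading eigenvalue")
  # sign conventions: PC1 both loadings positive; PC2 positive at 690 nm
  if (sum(vec[, 1]) < 0) vec[, 1] <- -vec[, 1]
  if (vec[1, 2] < 0) vec[, 2] <- -vec[, 2]
  center <- colMeans(x)
  scores <- sweep(x, 2, center) %*% vec
  colnames(scores) <- colnames(vec) <- c("EAC1", "EAC2")
  rownames(vec) <- colnames(x)
  structure(list(
    eigenvalues = val,
    variance_fraction = val / sum(val),
    loadings = vec, scores = scores, center = center, cov = cv
  ), class = "eac_pca")
}

#' @export
print.eac_pca <- function(x, ...) {
  cat(sprintf("eac_pca: PC1 %.2f%%, PC2 %.2f%% of variance\n",
              100 * x$variance_fraction[1], 100 * x$variance_fraction[2]))
  print(round(x$loadings, 3))
  invisible(x)
}

#' Per-pixel component maps from cohort loadings
#'
#' Applies the cohort-level PC loadings to every pixel's (EAC690, EAC830)
#' pair, after centering by the cohort pixel mean: local EAC1/EAC2 score
#' maps per subject.
#'
#' @param maps_690,maps_830 Lists of per-subject `eac_gridmap` (shared
#'   raster, same subject order).
#' @param pca An `eac_pca` fitted on the same cohort's global values.
#' @return List of per-subject lists with `EAC1` and `EAC2` grid maps.
#' @export
pixelwise_components <- function(maps_690, maps_830, pca) {
  stopifnot(inherits(pca, "eac_pca"), length(maps_690) == length(maps_830))
  a690 <- .stack_maps(maps_690)
  a830 <- .stack_maps(maps_830)
  if (!identical(dim(a690), dim(a830))) stop("grid mismatch")
  m690 <- apply(a690, c(1, 2), mean)
  m830 <- apply(a830, c(1, 2), mean)
  c690 <- sweep(a690, c(1, 2), m690)
  c830 <- sweep(a830, c(1, 2), m830)
  L <- pca$loadings
  lapply(seq_len(dim(a690)[3]), function(i) {
    s1 <- maps_690[[i]]; s2 <- maps_690[[i]]
    s1$value <- c690[, , i] * L["eac690", "EAC1"] + c830[, , i] * L["eac830", "EAC1"]
    s2$value <- c690[, , i] * L["eac690", "EAC2"] + c830[, , i] * L["eac830", "EAC2"]
    list(EAC1 = s1, EAC2 = s2)
  })
}
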