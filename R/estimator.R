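# Multi-distance EAC estimation: the slope of y = ln(SNR^2 r^2) against
# source-detector distance over accepted channels, globally, per distance
# stratum, and per channel neighborhood.

#' Filter SNR samples by source-detector distance
#'
#' Retains samples with `d_min <= r <= d_max` (inclusive both ends) and no
#' invalid flags. The default window 20-50 mm is where log light decay is
#' linear in distance: shorter channels violate the diffusive-slope
#' assumption, longer ones lose SNR linearity.
#'
#' @param samples SNR table (see [compute_snr()]).
#' @param d_min,d_max Window bounds in mm.
#' @return The retained subset.
#' @export
select_channels <- function(samples, d_min = 20, d_max = 50) {
  if (d_min >= d_max) stop("d_min must be < d_max")
  keep <- samples$distance_mm >= d_min & samples$distance_mm <= d_max & !samples$bad
  out <- samples[keep, , drop = FALSE]
  if (nrow(out) == 0) stop("empty selection: no acceptable channels in [",
                           d_min, ", ", d_max, "] mm")
  out
}

#' Neighborhood of a channel
#'
#' Samples of the same wavelength whose channel midpoint lies within
#' `radius_mm` (Euclidean chord distance, inclusive) of the target channel's
#' midpoint; always includes the target itself.
#'
#' @param samples SNR table.
#' @param target One-row SNR table entry (or a list with `mid_x`, `mid_y`,
#'   `mid_z`, `wavelength_nm`).
#' @param radius_mm Neighborhood radius (>= 0).
#' @return Subset of `samples`.
#' @export
channel_neighborhood <- function(samples, target, radius_mm) {
  if (radius_mm < 0) stop("radius_mm must be >= 0")
  d2 <- (samples$mid_x - target$mid_x)^2 + (samples$mid_y - target$mid_y)^2 +
    (samples$mid_z - target$mid_z)^2
  samples[samples$wavelength_nm == target$wavelength_nm &
            d2 <= radius_mm^2 + 1e-9, , drop = FALSE]
}

#' Fit the EAC from a set of SNR samples
#'
#' Ordinary least squares of `y = ln(SNR^2 r^2)` on distance `r`; the EAC is
#' minus the slope and the intercept `k` absorbs source power, detector
#' efficiency and coupling (distance-independent gains).
#'
#' @param samples SNR table subset.
#' @param min_channels Minimum number of samples (default 5).
#' @param min_span_mm Minimum distance spread (default 10 mm).
#' @return List of class `eac_fit`: `mu_eff`, `k`, `n_channels`, `resid_sd`,
#'   `d_range`, `wavelength_nm`, `residuals`.
#' @export
fit_eac <- function(samples, min_channels = 5, min_span_mm = 10) {
  r <- samples$distance_mm
  y <- samples$y
  ok <- is.finite(r) & is.finite(y)
  r <- r[ok]; y <- y[ok]
  if (length(r) < min_channels || diff(range(r)) < min_span_mm) {
    stop("underdetermined fit: need >= ", min_channels, " channels spanning >= ",
         min_span_mm, " mm")
  }
  rc <- r - mean(r)
  slope <- sum(rc * y) / sum(rc^2)
  k <- mean(y) - slope * mean(r)
  resid <- y - (k + slope * r)
  structure(list(
    mu_eff = -slope, k = k, n_channels = length(r),
    resid_sd = stats::sd(resid), d_range = range(r),
    wavelength_nm = samples$wavelength_nm[ok][1],
    residuals = resid
  ), class = "eac_fit")
}

#' @export
print.eac_fit <- function(x, ...) {
  cat(sprintf("eac_fit (%s nm): mu_eff = %.4f mm^-1, k = %.3f, n = %d, resid SD = %.3f\n",
              x$wavelength_nm, x$mu_eff, x$k, x$n_channels, x$resid_sd))
  invisible(x)
}

#' Whole-head (global) EAC per wavelength
#'
#' One fit per wavelength over all acceptable channels in the distance
#' window (a neighborhood radius much larger than the head).
#'
#' @param samples SNR table.
#' @param d_min,d_max Distance window (default 20-50 mm).
#' @param ... Passed to [fit_eac()].
#' @return Data frame: one row per wavelength with `mu_eff`, `k`,
#'   `n_channels`, `resid_sd`.
#' @export
global_eac <- function(samples, d_min = 20, d_max = 50, ...) {
  acc <- select_channels(samples, d_min, d_max)
  do.call(rbind, lapply(sort(unique(acc$wavelength_nm)), function(wl) {
    f <- fit_eac(acc[acc$wavelength_nm == wl, , drop = FALSE], ...)
    data.frame(wavelength_nm = wl, mu_eff = f$mu_eff, k = f$k,
               n_channels = f$n_channels, resid_sd = f$resid_sd)
  }))
}

#' Per-channel EAC map via neighborhood fits
#'
#' For every accepted channel, fits the multi-distance slope over the
#' channels of the same wavelength within `radius_mm` of its midpoint.
#' Underdetermined neighborhoods yield a missing value with a reason code
#' rather than an error.
#'
#' @param samples SNR table.
#' @param radius_mm Neighborhood radius (default 30 mm).
#' @param d_min,d_max Distance window (default 20-50 mm).
#' @param min_channels,min_span_mm Fit floor (see [fit_eac()]).
#' @return Data frame per accepted channel: midpoint, wavelength, `mu_eff`
#'   (NA when underdetermined), `n_used`, `resid_sd`, `reason`.
#' @export
eac_channel_map <- function(samples, radius_mm = 30, d_min = 20, d_max = 50,
                            min_channels = 5, min_span_mm = 10) {
  acc <- select_channels(samples, d_min, d_max)
  out <- acc[, c("channel_id", "montage", "wavelength_nm", "distance_mm",
                 "mid_x", "mid_y", "mid_z")]
  out$mu_eff <- NA_real_
  out$n_used <- 0L
  out$resid_sd <- NA_real_
  out$reason <- NA_character_
  for (wl in unique(acc$wavelength_nm)) {
    idx <- which(acc$wavelength_nm == wl)
    sub <- acc[idx, , drop = FALSE]
    mid <- as.matrix(sub[, c("mid_x", "mid_y", "mid_z")])
    for (j in seq_along(idx)) {
      d2 <- (mid[, 1] - mid[j, 1])^2 + (mid[, 2] - mid[j, 2])^2 +
        (mid[, 3] - mid[j, 3])^2
      nb <- sub[d2 <= radius_mm^2 + 1e-9, , drop = FALSE]
      f <- tryCatch(fit_eac(nb, min_channels, min_span_mm), error = function(e) NULL)
      if (is.null(f)) {
        out$reason[idx[j]] <- "underdetermined"
        out$n_used[idx[j]] <- nrow(nb)
      } else {
        out$mu_eff[idx[j]] <- f$mu_eff
        out$n_used[idx[j]] <- f$n_channels
        out$resid_sd[idx[j]] <- f$resid_sd
      }
    }
  }
  out
}

#' Distance-stratified EAC
#'
#' Independent fits over channels falling (inclusively) in each distance bin;
#' default bins 15-25, 25-35, 35-45, 45-55 mm. Bins with underdetermined
#' fits return a missing value with a reason.
#'
#' @param samples SNR table.
#' @param bins List of c(min, max) mm pairs.
#' @param min_channels Minimum fit size per bin (default 5).
#' @param min_span_mm Minimum distance spread within a bin; by default half
#'   the bin width (the global 10 mm floor cannot be met inside a 10 mm bin).
#' @return Data frame: wavelength, bin bounds, `mu_eff` (NA when missing),
#'   `n_channels`, `reason`.
#' @export
distance_stratified_eac <- function(samples,
                                    bins = list(c(15, 25), c(25, 35),
                                                c(35, 45), c(45, 55)),
                                    min_channels = 5, min_span_mm = NULL) {
  rows <- list()
  for (wl in sort(unique(samples$wavelength_nm))) {
    for (b in bins) {
      span_floor <- if (is.null(min_span_mm)) (b[2] - b[1]) / 2 else min_span_mm
      sub <- samples[samples$wavelength_nm == wl & !samples$bad &
                       samples$distance_mm >= b[1] & samples$distance_mm <= b[2], ,
                     drop = FALSE]
      f <- tryCatch(fit_eac(sub, min_channels, span_floor),
                    error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        wavelength_nm = wl, d_min = b[1], d_max = b[2],
        mu_eff = if (is.null(f)) NA_real_ else f$mu_eff,
        n_channels = nrow(sub),
        reason = if (is.null(f)) "underdetermined" else NA_character_
      )
    }
  }
  do.call(rbind, rows)
}
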