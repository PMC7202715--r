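# Channel intensity time-series simulation: diffusion forward model baseline
# per channel, multiplicative physiological modulation (< 10 Hz), Poisson shot
# noise, and the fixed cohort-level spatial EAC field.

#' Fixed cohort-level spatial EAC modulation field
#'
#' Smooth multiplicative field over the head surface shared by all subjects
#' and both wavelengths: occipital regions run high, frontal and lateral
#' regions low (the large-vein / anatomy pattern seen in group EAC maps).
#' Pure-azimuth design (zero mean over azimuth at every polar angle), so it
#' is distance-neutral for the multi-distance slope in expectation.
#'
#' @param mid Matrix (n x 3) of channel midpoint coordinates, mm (origin at
#'   head-sphere center, +z vertex, +y anterior).
#' @param config An `eac_config` (uses `field_occipital`, `field_lateral`).
#' @return Multiplicative field values (mean ~1).
#' @export
spatial_field <- function(mid, config) {
  mid <- as.matrix(mid)
  phi <- atan2(mid[, 1], mid[, 2])      # azimuth from the anterior (+y) axis
  1 - config$field_occipital * cos(phi) + config$field_lateral * cos(2 * phi)
}

#' Simulate one recording block for a subject and montage
#'
#' Per channel, the baseline expected count is the continuous-wave reflectance
#' forward model at the channel's distance and the subject's (spatially
#' modulated) EAC, scaled by the source and detector gains and normalized so
#' a gain-1 reference channel at 20 mm receives `photon_budget` counts per
#' sample. Each sample is Poisson around the baseline modulated by cardiac
#' (quasi-periodic, subject heart rate with inter-beat jitter from the
#' subject's HRV), respiratory and slow-drift components, all below 10 Hz.
#' With an infinite photon budget the expectation itself is returned (the
#' deterministic noise-free limit).
#'
#' @param subject An `eac_subject`.
#' @param montage An `eac_montage` (with this subject's gain realization).
#' @param config An `eac_config`.
#' @param seed Integer seed.
#' @param field_fun Optional override: function(mid_matrix, wavelength_nm)
#'   returning the multiplicative EAC field (for inhomogeneity studies).
#' @return An object of class `eac_block`: list with `counts` (samples x
#'   channels matrix), `channels` (montage channel table plus `low_light`
#'   flag), `fs_hz`, `time_s`, and `stages` (processing provenance).
#' @export
simulate_timeseries <- function(subject, montage, config, seed, field_fun = NULL) {
  stopifnot(inherits(subject, "eac_subject"), inherits(montage, "eac_montage"),
            inherits(config, "eac_config"))
  ch <- montage$channels
  n <- round(config$fs_hz * config$block_s)
  t_s <- (seq_len(n) - 1) / config$fs_hz

  mid <- as.matrix(ch[, c("mid_x", "mid_y", "mid_z")])
  wl_idx <- match(ch$wavelength_nm, subject$wavelength_nm)
  S <- if (is.null(field_fun)) spatial_field(mid, config) else
    field_fun(mid, ch$wavelength_nm)
  mu_ch <- subject$eac[wl_idx] * S

  gain <- montage$optodes$gain
  noise_free <- is.infinite(config$photon_budget)
  budget <- if (noise_free) 1e12 else config$photon_budget  # clamped-large limit
  amp <- budget / forward_intensity(subject$eac[wl_idx], 20)
  base <- amp * forward_intensity(mu_ch, ch$distance_mm) *
    gain[ch$source] * gain[ch$detector]

  ch$low_light <- base < 1

  withr::with_seed(seed, {
    m <- .physio_modulation(t_s, subject, config)
    counts <- if (noise_free) {
      # infinite-budget limit: the expectation itself, no shot noise
      outer(m, base)
    } else {
      lambda <- outer(m, base)
      matrix(stats::rpois(length(lambda), lambda), nrow = n)
    }
    structure(list(
      counts = counts, channels = ch, fs_hz = config$fs_hz, time_s = t_s,
      stages = character(), i_avg = NULL,
      subject_age = subject$age
    ), class = "eac_block")
  })
}

# Multiplicative physiological modulation: quasi-periodic cardiac component
# (inter-beat intervals jittered by the subject's HRV), respiratory sinusoid
# and slow drift; all spectral content sits well below 10 Hz.
.physio_modulation <- function(t_s, subject, config) {
  dur <- max(t_s) + 1
  ibi_mean <- 60 / subject$hr_bpm
  n_beats <- ceiling(dur / ibi_mean) + 8
  ibi <- pmax(0.3, stats::rnorm(n_beats, ibi_mean, subject$hrv_ms / 1000))
  beats <- cumsum(c(stats::runif(1, 0, ibi_mean), ibi))
  phase <- stats::approx(beats, seq_along(beats), xout = t_s, rule = 2)$y
  # diastolic trough at each beat boundary (integer phase), peak mid-cycle
  cardiac <- -cos(2 * pi * phase)
  resp <- cos(2 * pi * config$resp_hz * t_s + stats::runif(1, 0, 2 * pi))
  drift <- cos(2 * pi * config$drift_hz * t_s + stats::runif(1, 0, 2 * pi))
  pmax(0.05, 1 + config$cardiac_amp * cardiac + config$resp_amp * resp +
         config$drift_amp * drift)
}
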