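# Independent oracles and small fixtures shared across the suite.

# Closed-form OLS through the normal equations (independent of fit_eac).
ols_oracle <- function(r, y) {
  X <- cbind(1, r)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  list(intercept = beta[1], slope = beta[2])
}

# Brute-force pair enumeration of admissible channels for a montage.
brute_force_channel_count <- function(montage, wl, d_range = c(15, 80)) {
  src <- montage$optodes[montage$optodes$kind == paste0("source_", wl), ]
  det <- montage$optodes[montage$optodes$kind == "detector", ]
  n <- 0L
  for (i in seq_len(nrow(src))) {
    for (j in seq_len(nrow(det))) {
      d <- sqrt(sum((c(src$x_mm[i], src$y_mm[i], src$z_mm[i]) -
                       c(det$x_mm[j], det$y_mm[j], det$z_mm[j]))^2))
      if (d >= d_range[1] && d <= d_range[2]) n <- n + 1L
    }
  }
  n
}

# Noise-free SNR table for a homogeneous (or custom per-channel) EAC:
# y = ln(I r^2) from the closed-form forward model, with optional gains.
noise_free_snr <- function(montage, mu_eff_by_wl = c(`690` = 0.19, `830` = 0.17),
                           mu_eff_channel = NULL, use_gains = FALSE,
                           amplitude = 1e6) {
  ch <- montage$channels
  mu <- if (is.null(mu_eff_channel)) {
    unname(mu_eff_by_wl[as.character(ch$wavelength_nm)])
  } else mu_eff_channel
  g <- if (use_gains) {
    montage$optodes$gain[ch$source] * montage$optodes$gain[ch$detector]
  } else 1
  intensity <- forward_intensity(mu, ch$distance_mm, amplitude) * g
  data.frame(
    channel_id = ch$channel_id, montage = 1L,
    wavelength_nm = ch$wavelength_nm, distance_mm = ch$distance_mm,
    mid_x = ch$mid_x, mid_y = ch$mid_y, mid_z = ch$mid_z,
    snr = sqrt(intensity),
    y = log(intensity * ch$distance_mm^2),
    low_light = FALSE, motion = FALSE, bad = FALSE
  )
}

# Sample correlation matrix constructed exactly: columns of Q are centered
# and orthonormal, so cor(Q %*% chol(R)) reproduces R to machine precision.
exact_correlation_data <- function(R, n = 24, seed = 7) {
  k <- nrow(R)
  withr::with_seed(seed, {
    A <- cbind(1, matrix(stats::rnorm(n * k), n))
    Q <- qr.Q(qr(A))[, 2:(k + 1)]   # orthonormal, orthogonal to the intercept
    Q %*% chol(R)
  })
}

tiny_config <- function(block_s = 8, n_subjects = 6, n_montages = 1,
                        n_source_pairs = 16, n_detectors = 12, ...) {
  simulation_config(n_subjects = n_subjects, n_montages = n_montages,
                    n_source_pairs = n_source_pairs, n_detectors = n_detectors,
                    block_s = block_s, ...)
}
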