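# Multi-distance EAC estimation: exact fits, selection and neighborhood
# contracts, stratified fits, gain behaviour and recovery.

snr_row <- function(r, y, wl = 690, mid = c(0, 0, 90), id = seq_along(r)) {
  data.frame(channel_id = id, montage = 1L, wavelength_nm = wl,
             distance_mm = r, mid_x = mid[1], mid_y = mid[2], mid_z = mid[3],
             snr = exp(y / 2) / r, y = y, low_light = FALSE, motion = FALSE,
             bad = FALSE)
}

test_that("an exact linear relation is fit to machine precision", {
  r <- c(20, 30, 40, 50)
  s <- snr_row(r, 10 - 0.19 * r)
  f <- fit_eac(s, min_channels = 4)
  expect_equal(f$mu_eff, 0.19, tolerance = 1e-12)
  expect_equal(f$k, 10, tolerance = 1e-12)
  expect_equal(f$resid_sd, 0, tolerance = 1e-12)
})

test_that("fits agree with an independent normal-equations oracle", {
  withr::with_seed(21, {
    for (rep in 1:20) {
      n <- sample(5:40, 1)
      r <- runif(n, 15, 60)
      y <- 8 - 0.2 * r + rnorm(n, 0, 0.3)
      f <- fit_eac(snr_row(r, y))
      o <- ols_oracle(r, y)
      expect_equal(f$mu_eff, -o$slope, tolerance = 1e-10)
      expect_equal(f$k, o$intercept, tolerance = 1e-10)
    }
  })
})

test_that("degenerate inputs raise underdetermined-fit errors", {
  expect_error(fit_eac(snr_row(c(30, 30), c(1, 2)), min_channels = 2),
               "underdetermined")
  expect_error(fit_eac(snr_row(c(20, 30, 40), 1:3)), "underdetermined")
  # zero span with many samples
  expect_error(fit_eac(snr_row(rep(25, 10), rnorm(10))), "underdetermined")
})

test_that("distance selection is inclusive at both ends and flag-aware", {
  s <- snr_row(c(15, 20, 35, 50, 55), rep(1, 5))
  kept <- select_channels(s, 20, 50)
  expect_equal(kept$distance_mm, c(20, 35, 50))
  s$bad <- TRUE
  expect_error(select_channels(s, 20, 50), "empty selection")
  # brute-force filter oracle on a random montage
  m <- generate_montage(16, 12, seed = 13)
  nf <- noise_free_snr(m)
  kept2 <- select_channels(nf, 20, 50)
  expect_identical(nrow(kept2),
                   sum(nf$distance_mm >= 20 & nf$distance_mm <= 50))
})

test_that("neighborhoods follow the radius contract and a brute-force oracle", {
  m <- generate_montage(16, 12, seed = 17)
  nf <- noise_free_snr(m)
  acc <- select_channels(nf, 20, 50)
  target <- acc[5, ]
  # radius 0: the target only (and any exactly co-located channel)
  nb0 <- channel_neighborhood(acc, target, 0)
  expect_true(all(nb0$mid_x == target$mid_x & nb0$mid_y == target$mid_y))
  expect_true(target$channel_id %in% nb0$channel_id)
  # radius >> head: all accepted same-wavelength channels
  nb_all <- channel_neighborhood(acc, target, 1e4)
  expect_identical(nrow(nb_all), sum(acc$wavelength_nm == target$wavelength_nm))
  # brute-force distance oracle at 30 mm
  nb30 <- channel_neighborhood(acc, target, 30)
  d <- sqrt((acc$mid_x - target$mid_x)^2 + (acc$mid_y - target$mid_y)^2 +
              (acc$mid_z - target$mid_z)^2)
  expect_identical(sort(nb30$channel_id),
                   sort(acc$channel_id[d <= 30 & acc$wavelength_nm == target$wavelength_nm]))
})

test_that("a common gain rescaling shifts k but never the EAC", {
  m <- generate_montage(16, 12, seed = 19, gain_sigma = 0.5)
  nf <- noise_free_snr(m, use_gains = TRUE)
  acc <- select_channels(nf, 20, 50)
  f0 <- fit_eac(acc[acc$wavelength_nm == 690, ])
  scaled <- acc
  scaled$y <- scaled$y + log(7.3)          # every optode gain times sqrt(7.3)
  f1 <- fit_eac(scaled[scaled$wavelength_nm == 690, ])
  expect_equal(f1$mu_eff, f0$mu_eff, tolerance = 1e-12)
  expect_equal(f1$k - f0$k, log(7.3), tolerance = 1e-10)
})

test_that("noise-free homogeneous channels recover the EAC everywhere", {
  m <- generate_montage(24, 18, seed = 23, gain_sigma = 0)
  nf <- noise_free_snr(m, mu_eff_by_wl = c(`690` = 0.21, `830` = 0.18))
  g <- global_eac(nf)
  expect_equal(g$mu_eff[g$wavelength_nm == 690], 0.21, tolerance = 1e-9)
  expect_equal(g$mu_eff[g$wavelength_nm == 830], 0.18, tolerance = 1e-9)
  cm <- eac_channel_map(nf, radius_mm = 30)
  expect_true(all(abs(cm$mu_eff[cm$wavelength_nm == 690] - 0.21) < 1e-9, na.rm = TRUE))
  # a huge radius reproduces the global fit exactly
  cm_glob <- eac_channel_map(nf, radius_mm = 1e4)
  expect_equal(unique(round(cm_glob$mu_eff[cm_glob$wavelength_nm == 830], 12)),
               round(g$mu_eff[g$wavelength_nm == 830], 12))
})

test_that("a left/right inhomogeneity is mapped with the correct contrast", {
  m <- generate_montage(48, 36, seed = 29, gain_sigma = 0)
  ch <- m$channels
  mu_true <- ifelse(ch$mid_x < 0, 0.17, 0.21)
  nf <- noise_free_snr(m, mu_eff_channel = mu_true)
  cm <- eac_channel_map(nf, radius_mm = 28)
  # compare means away from the midline where neighborhoods do not mix sides
  left <- cm$mid_x < -30 & cm$wavelength_nm == 690
  right <- cm$mid_x > 30 & cm$wavelength_nm == 690
  expect_gt(sum(left), 5); expect_gt(sum(right), 5)
  contrast <- mean(cm$mu_eff[right], na.rm = TRUE) - mean(cm$mu_eff[left], na.rm = TRUE)
  expect_lt(abs(contrast - 0.04) / 0.04, 0.10)
})

test_that("distance-stratified fits recover bin-wise truths and flag empty bins", {
  m <- generate_montage(24, 18, seed = 31, gain_sigma = 0)
  # homogeneous: all bins agree
  nf <- noise_free_snr(m)
  st <- distance_stratified_eac(nf)
  expect_equal(st$d_min, rep(c(15, 25, 35, 45), 2))
  ok <- !is.na(st$mu_eff)
  expect_gte(sum(ok & st$wavelength_nm == 690), 3)   # bins actually fit
  expect_true(all(abs(st$mu_eff[ok & st$wavelength_nm == 690] - 0.19) < 1e-9))
  # depth-proxy inhomogeneity: a per-bin constant EAC assigned by channel
  # distance is recovered bin by bin
  ch <- m$channels
  bin_lo <- c(15, 25, 35, 45)
  bin_mu <- c(0.16, 0.18, 0.20, 0.22)
  assigned <- bin_mu[pmin(4, pmax(1, findInterval(ch$distance_mm, bin_lo)))]
  nf2 <- noise_free_snr(m, mu_eff_channel = assigned)
  st2 <- distance_stratified_eac(nf2)
  fit_ok <- which(!is.na(st2$mu_eff))
  expect_gte(length(fit_ok), 6)
  for (j in fit_ok) {
    truth <- bin_mu[match(st2$d_min[j], bin_lo)]
    expect_lt(abs(st2$mu_eff[j] - truth) / truth, 0.10)
  }
  # a bin with too few channels reports a missing value with a reason
  in_bin <- which(nf$distance_mm >= 45 & nf$distance_mm <= 55)
  sparse <- nf[-in_bin[-(1:2)], ]
  st3 <- distance_stratified_eac(sparse)
  bad_bin <- st3[st3$d_min == 45, ]
  expect_true(all(is.na(bad_bin$mu_eff)))
  expect_true(all(bad_bin$reason == "underdetermined"))
})

test_that("recovered EAC increases strictly with generator absorption", {
  m <- generate_montage(20, 16, seed = 37, gain_sigma = 0)
  cfg <- tiny_config(cardiac_amp = 0, resp_amp = 0, drift_amp = 0,
                     field_occipital = 0, field_lateral = 0, block_s = 15)
  calib <- calibrate_cohort_optics(cfg)
  subj <- sample_subject(40, cfg, seed = 3, calib = calib)
  est <- sapply(c(0.8, 1.0, 1.3), function(scale) {
    s2 <- subj
    s2$mua <- subj$mua * scale
    s2$eac <- sqrt(3 * s2$mua * (s2$mua + s2$musp))
    blk <- simulate_timeseries(s2, m, cfg, seed = 11)
    g <- global_eac(preprocess_block(blk))
    g$mu_eff[g$wavelength_nm == 690]
  })
  expect_true(all(diff(est) > 0))
})
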