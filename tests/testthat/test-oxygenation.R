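# TOI inversion and the wavelength-space principal components.

# forward EAC pair under the inversion's own scattering assumptions
forward_pair <- function(so2, thb, musp830 = 0.72, b = 1) {
  musp <- musp830 * (c(690, 830) / 830)^(-b)
  mua <- derive_mua(so2, thb, c(690, 830))
  mu_eff_from_coefficients(mua, musp, "exact")
}

test_that("TOI round-trips the generating saturation exactly", {
  for (so2 in c(0, 0.25, 0.5, 0.65, 0.75, 1)) {
    e <- forward_pair(so2, 50)
    res <- toi_from_eac(e[1], e[2])
    expect_lt(abs(res$toi - so2), 1e-10)
    expect_lt(abs(res$c_hbo_um + res$c_hbr_um - 50), 1e-8)
    # re-applying the EAC definition to the inferred coefficients reproduces
    # the inputs
    back <- mu_eff_from_coefficients(c(res$mua_690, res$mua_830),
                                     c(res$musp_690, res$musp_830), "exact")
    expect_lt(max(abs(back - e)), 1e-9)
  }
})

test_that("the approximate inversion stays within 2% and depends on the ratio only", {
  e <- forward_pair(0.65, 70)
  exact <- toi_from_eac(e[1], e[2])$toi
  approx <- toi_from_eac(e[1], e[2], approximate = TRUE)$toi
  expect_lt(abs(approx / exact - 1), 0.02)
  # ratio-only property of the approximate path: common scaling cancels
  t1 <- toi_from_eac(e[1] * 1.3, e[2] * 1.3, approximate = TRUE)$toi
  expect_equal(t1, approx, tolerance = 1e-12)
})

test_that("non-physical EAC pairs clamp a concentration and flag it", {
  # extreme spectral slope forces a negative deoxy concentration
  res <- toi_from_eac(0.05, 0.25)
  expect_true(res$nonphysical)
  expect_gte(res$toi, 0); expect_lte(res$toi, 1)
  expect_error(toi_from_eac(-0.1, 0.2), "> 0")
})

test_that("wavelength PCA matches the closed-form 2x2 eigen solution", {
  # perfectly correlated pairs: PC1 explains everything along (1,1)/sqrt(2)
  x <- seq(0.1, 0.3, length.out = 12)
  p <- wavelength_pca(x, x)
  expect_equal(p$variance_fraction[1], 1, tolerance = 1e-12)
  expect_equal(unname(p$loadings[, 1]), c(1, 1) / sqrt(2), tolerance = 1e-12)

  # uncorrelated equal variances: fractions near 1/2
  withr::with_seed(44, { a <- rnorm(4000); b <- rnorm(4000) })
  p2 <- wavelength_pca(a, b)
  expect_lt(abs(p2$variance_fraction[1] - 0.5), 0.05)

  # closed-form oracle on an arbitrary covariance
  withr::with_seed(45, { u <- rnorm(200, 0.19, 0.04); v <- 0.6 * u + rnorm(200, 0, 0.02) })
  p3 <- wavelength_pca(u, v)
  cv <- stats::cov(cbind(u, v))
  tr <- sum(diag(cv)); dt <- cv[1, 1] * cv[2, 2] - cv[1, 2]^2
  lam1 <- (tr + sqrt(tr^2 - 4 * dt)) / 2
  expect_equal(p3$eigenvalues[1], lam1, tolerance = 1e-10)
  expect_equal(p3$variance_fraction[1], lam1 / tr, tolerance = 1e-10)
})

test_that("the printed cohort summaries imply a ~92.6% first component", {
  # covariance assembled from the reported SDs (0.040, 0.036) and r = 0.85
  cv <- matrix(c(0.040^2, 0.85 * 0.040 * 0.036,
                 0.85 * 0.040 * 0.036, 0.036^2), 2)
  tr <- sum(diag(cv)); dt <- det(cv)
  lam1 <- (tr + sqrt(tr^2 - 4 * dt)) / 2
  expect_equal(lam1 / tr, 0.92594, tolerance = 1e-4)
})

test_that("PCA respects sign conventions and reconstructs the data", {
  withr::with_seed(46, {
    e690 <- rnorm(48, 0.192, 0.040)
    e830 <- 0.8 * (e690 - 0.192) + 0.170 + rnorm(48, 0, 0.015)
  })
  p <- wavelength_pca(e690, e830)
  expect_true(all(p$loadings[, "EAC1"] > 0))
  expect_gt(p$loadings["eac690", "EAC2"], 0)
  expect_lt(p$loadings["eac830", "EAC2"], 0)
  expect_lt(max(abs(crossprod(p$loadings) - diag(2))), 1e-12)
  recon <- p$scores %*% t(p$loadings)
  recon <- sweep(recon, 2, p$center, "+")
  expect_equal(unname(recon), unname(cbind(e690, e830)), tolerance = 1e-12)
})

test_that("pixel component maps: centering, consistency and patch contrast", {
  withr::with_seed(47, {
    x <- runif(70, -0.8, 0.8); y <- runif(70, -0.8, 0.8)
    g690 <- rnorm(20, 0.192, 0.04)
  })
  g830 <- 0.17 + 0.9 * (g690 - 0.192) * 0.9
  proj <- data.frame(x = x, y = y)
  pca <- wavelength_pca(g690, g830)

  # maps equal to each subject's global pair at every pixel: pixel scores
  # equal the global scores
  maps690 <- lapply(g690, function(v) interpolate_map(proj, rep(v, 70), grid_n = 24))
  maps830 <- lapply(g830, function(v) interpolate_map(proj, rep(v, 70), grid_n = 24))
  px <- pixelwise_components(maps690, maps830, pca)
  for (i in c(1, 9, 20)) {
    ok <- px[[i]]$EAC1$valid
    expect_equal(unique(round(px[[i]]$EAC1$value[ok], 10)),
                 unname(round(pca$scores[i, "EAC1"], 10)))
    expect_equal(unique(round(px[[i]]$EAC2$value[ok], 10)),
                 unname(round(pca$scores[i, "EAC2"], 10)))
  }

  # a subject-varying oxygenation-contrast patch appears in EAC2 but not EAC1
  L <- pca$loadings
  patch <- x^2 + y^2 < 0.15
  d2 <- seq(-0.02, 0.02, length.out = 20)     # per-subject patch amplitude
  maps690p <- lapply(seq_along(g690), function(i) {
    interpolate_map(proj, g690[i] + ifelse(patch, L["eac690", "EAC2"] * d2[i], 0),
                    grid_n = 24)
  })
  maps830p <- lapply(seq_along(g830), function(i) {
    interpolate_map(proj, g830[i] + ifelse(patch, L["eac830", "EAC2"] * d2[i], 0),
                    grid_n = 24)
  })
  # the patch perturbs subject maps along the EAC2 loading direction only,
  # so EAC2 carries the structure and EAC1 stays flat; compare spatial ranges
  pxp <- pixelwise_components(maps690p, maps830p, pca)
  rng1 <- diff(range(pxp[[1]]$EAC1$value[pxp[[1]]$EAC1$valid]))
  rng2 <- diff(range(pxp[[1]]$EAC2$value[pxp[[1]]$EAC2$valid]))
  expect_gt(rng2, 3 * rng1)
})
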