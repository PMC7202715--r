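# Association battery: composite scores, correlations, partial correlations,
# paired tests and Baron-Kenny mediation.

test_that("composite scores standardize, orient and average by domain", {
  tests <- data.frame(a = c(10, 20, 30))
  out <- composite_scores(tests, domains = c(a = "performance"))
  expect_equal(out$performance, as.numeric(scale(tests$a)), tolerance = 1e-12)

  # a timed test one SD faster than average contributes +1 after orientation
  tests2 <- data.frame(trail_a = c(20, 30, 40))
  out2 <- composite_scores(tests2, domains = c(trail_a = "performance"),
                           orientation = c(trail_a = -1))
  expect_equal(out2$performance[1], 1, tolerance = 1e-12)

  # hand-computed two-test, three-subject table
  tests3 <- data.frame(t1 = c(1, 2, 3), t2 = c(6, 5, 1))
  z1 <- (tests3$t1 - 2) / 1
  z2 <- (tests3$t2 - 4) / sd(tests3$t2)
  out3 <- composite_scores(tests3, domains = c(t1 = "d", t2 = "d"))
  expect_equal(out3$d, (z1 + z2) / 2, tolerance = 1e-12)

  expect_warning(
    out4 <- composite_scores(data.frame(t1 = c(1, 2, 3), t2 = c(5, 5, 5)),
                             domains = c(t1 = "d", t2 = "d")),
    "zero variance")
  expect_equal(out4$d, z1, tolerance = 1e-12)
})

test_that("correlate reports Fisher z with the (N-3)^(-1/2) standard error", {
  # r = 0.85 built exactly
  X <- exact_correlation_data(matrix(c(1, 0.85, 0.85, 1), 2), n = 48)
  a <- correlate(X[, 1], X[, 2])
  expect_equal(a$r, 0.85, tolerance = 1e-10)
  expect_equal(round(a$z, 5), 1.25615)
  expect_equal(a$z, atanh(a$r), tolerance = 1e-12)
  expect_equal(a$se_z, 1 / sqrt(45), tolerance = 1e-12)
  expect_equal(round(a$se_z, 5), 0.14907)
  # p agrees with the base-R reference test
  expect_equal(a$p, stats::cor.test(X[, 1], X[, 2])$p.value, tolerance = 1e-10)

  ident <- correlate(1:10, 1:10)
  expect_equal(ident$r, 1)
  expect_true(ident$degenerate_z && is.infinite(ident$z))
  expect_error(correlate(1:10, rep(2, 10)), "zero variance")
})

test_that("partial correlation matches the closed-form triplet formula", {
  R <- matrix(c(1, 0.6, 0.5,
                0.6, 1, 0.5,
                0.5, 0.5, 1), 3)
  X <- exact_correlation_data(R, n = 30)
  pc <- partial_correlate(X[, 1], X[, 2], X[, 3])
  expect_equal(pc$r, (0.6 - 0.25) / 0.75, tolerance = 1e-10)
  expect_equal(round(pc$r, 5), 0.46667)

  # closed-form identity on random jointly constructed data
  withr::with_seed(61, {
    for (i in 1:10) {
      z <- rnorm(40); x <- 0.5 * z + rnorm(40); y <- -0.3 * z + rnorm(40)
      pc2 <- partial_correlate(x, y, z)
      rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
      expect_equal(pc2$r, (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2)),
                   tolerance = 1e-10)
    }
  })

  # identical variables with an independent covariate: partial r = 1
  withr::with_seed(62, { x <- rnorm(20); z <- rnorm(20) })
  expect_equal(partial_correlate(x, x, z)$r, 1, tolerance = 1e-12)
  expect_error(partial_correlate(x, z, z), "collinear")
})

test_that("paired t matches hand arithmetic and rejects degenerate input", {
  y <- c(10, 11, 12, 13, 14)
  x <- y + c(1, 2, 0, 1, 1)
  res <- paired_t(x, y)
  expect_equal(res$t, 1 / (sd(c(1, 2, 0, 1, 1)) / sqrt(5)), tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_error(paired_t(y, y), "degenerate")
  jit <- y + 1 + c(1e-9, -1e-9, 0, 1e-9, -1e-9)
  strong <- paired_t(jit, y)
  expect_gt(abs(strong$t), 1e6)
  expect_lt(strong$p, 1e-10)
})

test_that("mediation recovers a generative chain and its Sobel invariant", {
  withr::with_seed(71, {
    x <- rnorm(1000)
    m <- -0.7 * x + rnorm(1000, 0, sqrt(1 - 0.49))
    y <- 0.5 * m + rnorm(1000, 0, 0.6)
  })
  res <- mediate(x, m, y)
  expect_equal(res$classification, "full")
  expect_gt(abs(res$sobel["statistic"]), 1.96)
  # Sobel formula recomputed from the reported paths
  a <- res$a_path["est"]; b <- res$b2_mediator["est"]
  expect_equal(unname(res$sobel["statistic"]),
               unname(a * b / sqrt(b^2 * res$a_path["se"]^2 + a^2 * res$b2_mediator["se"]^2)),
               tolerance = 1e-12)

  # broken first stage: not assessable
  withr::with_seed(72, {
    x2 <- rnorm(1000); m2 <- rnorm(1000); y2 <- 0.5 * m2 + rnorm(1000)
  })
  expect_equal(mediate(x2, m2, y2)$classification, "not-assessable")
})

test_that("mediation classification is invariant to affine rescaling", {
  withr::with_seed(73, {
    x <- rnorm(200); m <- 0.6 * x + rnorm(200); y <- 0.7 * m + 0.1 * x + rnorm(200)
  })
  r1 <- mediate(x, m, y)
  r2 <- mediate(100 + 3 * x, -2 * m + 7, 0.01 * y - 5)
  expect_equal(r2$classification, r1$classification)
  expect_equal(abs(unname(r2$sobel["statistic"])),
               abs(unname(r1$sobel["statistic"])), tolerance = 1e-8)
})

test_that("independent variables rarely produce spurious mediation", {
  counts <- withr::with_seed(74, {
    sum(replicate(600, {
      x <- rnorm(48); m <- rnorm(48); y <- rnorm(48)
      mediate(x, m, y)$classification %in% c("full", "partial")
    }))
  })
  expect_lte(counts / 600, 0.07)
})

test_that("the battery nulls out age-driven covariates after partialing", {
  withr::with_seed(75, {
    n <- 2000
    age <- runif(n, 18, 78)
    EAC1 <- -0.02 * age + rnorm(n)
    EAC2 <- rnorm(n)
    cov_age <- 2 * age + rnorm(n, 0, 10)   # pure f(age) + independent noise
  })
  tab <- data.frame(age = age, EAC1 = EAC1, EAC2 = EAC2, cov_age = cov_age,
                    twin_a = cov_age, twin_b = cov_age)
  out <- association_battery(tab, covariates = c("cov_age", "twin_a", "twin_b"))
  expect_lt(abs(out$r_eac1_age_partialed[out$variable == "cov_age"]), 0.1)
  expect_lt(abs(out$r_eac2_age_partialed[out$variable == "cov_age"]), 0.1)
  # duplicated covariates give identical rows
  expect_equal(out[out$variable == "twin_a", -1],
               out[out$variable == "twin_b", -1], ignore_attr = TRUE)
  # tiers flag p < 0.05
  expect_true(all(out$tier_eac1[abs(out$p_eac1) < 0.05] == "p<0.05"))
})
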