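# Disk projection, triangulation interpolation, group maps and reliability.

test_that("the azimuthal-equidistant projection maps pole and mid-cap exactly", {
  thm <- 100 * pi / 180
  p <- project_to_disk(rbind(c(0, 0, 90)), theta_max = thm)
  expect_equal(c(p$x, p$y), c(0, 0))
  # a point at half the maximum polar angle, azimuth 30 degrees
  th <- thm / 2; az <- pi / 6
  # with vertex +z the in-disk azimuth basis is (x, y)
  pt <- 90 * c(sin(th) * cos(az), sin(th) * sin(az), cos(th))
  p2 <- project_to_disk(rbind(pt), theta_max = thm)
  expect_equal(p2$rho, 0.5, tolerance = 1e-12)
  expect_equal(p2$azimuth, az, tolerance = 1e-12)
  expect_error(project_to_disk(rbind(c(0, 0, 90)), vertex_dir = c(0, 0, 0)),
               "non-zero")
})

test_that("projection round-trips sphere angles for unclipped points", {
  thm <- 100 * pi / 180
  withr::with_seed(5, {
    th <- runif(50, 0.01, thm)
    az <- runif(50, -pi, pi)
  })
  pts <- 90 * cbind(sin(th) * cos(az), sin(th) * sin(az), cos(th))
  p <- project_to_disk(pts, theta_max = thm)
  expect_false(any(p$clipped))
  back <- project_from_disk(p$x, p$y, theta_max = thm)
  expect_equal(back$theta, th, tolerance = 1e-12)
  expect_equal(atan2(sin(back$azimuth - az), cos(back$azimuth - az)),
               rep(0, 50), tolerance = 1e-12)
  # beyond theta_max: clipped to the rim
  deep <- project_to_disk(rbind(90 * c(sin(thm + 0.2), 0, cos(thm + 0.2))),
                          theta_max = thm)
  expect_true(deep$clipped)
  expect_equal(deep$rho, 1)
})

test_that("interpolation reproduces constants and planes and interpolates", {
  withr::with_seed(9, {
    x <- runif(60, -0.9, 0.9); y <- runif(60, -0.9, 0.9)
  })
  keep <- x^2 + y^2 < 0.95; x <- x[keep]; y <- y[keep]
  proj <- data.frame(x = x, y = y)
  m_const <- interpolate_map(proj, rep(0.5, length(x)), grid_n = 32)
  expect_lt(max(abs(m_const$value[m_const$valid] - 0.5)), 1e-10)

  plane <- 0.1 + 2 * x - 3 * y
  m_plane <- interpolate_map(proj, plane, grid_n = 32)
  inside <- m_plane$valid & !m_plane$extrapolated
  gx <- matrix(m_plane$x, 32, 32)[inside]
  gy <- matrix(rep(m_plane$y, each = 32), 32, 32)[inside]
  expect_lt(max(abs(m_plane$value[inside] - (0.1 + 2 * gx - 3 * gy))), 1e-10)

  # interpolating property at the sample points (raster lookup tolerance)
  vals <- map_lookup(m_plane, x, y)
  expect_lt(max(abs(vals - plane)), 0.05 * diff(range(plane)))

  # convexity: linear scheme stays within the input range inside the hull
  withr::with_seed(10, v <- runif(length(x)))
  m_r <- interpolate_map(proj, v, grid_n = 32)
  ins <- m_r$valid & !m_r$extrapolated
  expect_gte(min(m_r$value[ins]), min(v) - 1e-12)
  expect_lte(max(m_r$value[ins]), max(v) + 1e-12)

  expect_error(interpolate_map(data.frame(x = c(0, .1, .2), y = c(0, .1, .2)),
                               1:3, grid_n = 16), "collinear|degenerate")
})

test_that("group maps give the hand-computed SE-percent and zero for clones", {
  withr::with_seed(3, {
    x <- runif(40, -0.8, 0.8); y <- runif(40, -0.8, 0.8)
  })
  proj <- data.frame(x = x, y = y)
  m1 <- interpolate_map(proj, rep(0.18, 40), grid_n = 24)
  m2 <- interpolate_map(proj, rep(0.22, 40), grid_n = 24)
  g <- group_maps(list(m1, m2))
  ok <- g$mean$valid
  expect_equal(unique(round(g$mean$value[ok], 12)), 0.20)
  # SD = 0.028284, SE = 0.02, SE/mean = 10%
  expect_equal(unique(round(g$se_percent$value[ok], 6)), 10)

  clones <- replicate(4, interpolate_map(proj, 0.1 + x, grid_n = 24),
                      simplify = FALSE)
  g2 <- group_maps(clones)
  expect_equal(max(abs(g2$se_percent$value[g2$mean$valid & g2$mean$value > 0])), 0)
})

test_that("split-half reliability: clones give r = 1, pure noise near 0, and the
          statistic is affine-invariant", {
  withr::with_seed(6, {
    x <- runif(60, -0.8, 0.8); y <- runif(60, -0.8, 0.8)
  })
  proj <- data.frame(x = x, y = y)
  strata <- data.frame(decade = rep(1:4, each = 4), sex = rep(1:2, 8))

  clone_maps <- replicate(16, interpolate_map(proj, 0.15 + 0.1 * x, grid_n = 24),
                          simplify = FALSE)
  res <- split_half_reliability(clone_maps, strata, seed = 2)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_equal(unname(table(res$half)), c(8L, 8L), ignore_attr = TRUE)

  # i.i.d. noise per pixel per subject: near-zero reliability
  tmpl <- interpolate_map(proj, 0.15 + 0.1 * x, grid_n = 48)
  noise_maps <- withr::with_seed(8, replicate(16, {
    m <- tmpl
    m$value[m$valid] <- rnorm(sum(m$valid))
    m$value[!m$valid] <- NA
    m
  }, simplify = FALSE))
  res_noise <- split_half_reliability(noise_maps, strata, seed = 2)
  expect_lt(abs(res_noise$r), 0.1)

  shifted <- lapply(noise_maps, function(m) { m$value <- 3 + 2 * m$value; m })
  res_shift <- split_half_reliability(shifted, strata, seed = 2)
  expect_equal(res_shift$r, res_noise$r, tolerance = 1e-12)
})

test_that("map correlation: identity, antisymmetry, and noise attenuation", {
  withr::with_seed(13, {
    x <- runif(80, -0.8, 0.8); y <- runif(80, -0.8, 0.8)
    v <- rnorm(80)
  })
  proj <- data.frame(x = x, y = y)
  a <- interpolate_map(proj, v, grid_n = 24)
  expect_equal(map_correlation(a, a), 1)
  b <- a; b$value <- -a$value + 5
  expect_equal(map_correlation(a, b), -1)

  # matched-variance independent noise attenuates r towards 1/sqrt(2)
  rs <- sapply(1:20, function(i) {
    withr::with_seed(100 + i, {
      n1 <- rnorm(80, 0, sd(v)); n2 <- rnorm(80, 0, sd(v))
    })
    m1 <- interpolate_map(proj, v + n1, grid_n = 24)
    m2 <- interpolate_map(proj, v + n2, grid_n = 24)
    map_correlation(m1, m2)
  })
  expect_lt(abs(mean(rs) - 0.5), 0.1)   # r1*r2 with each ~ 1/sqrt(2)

  flat <- a; flat$value[flat$valid] <- 1
  expect_error(map_correlation(a, flat), "zero variance")
})
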