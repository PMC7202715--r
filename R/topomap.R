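# Topographic mapping: azimuthal-equidistant projection of channel midpoints
# onto the unit disk, triangulation-based interpolation to a raster, group
# mean / SE-percent maps, split-half reliability and map similarity.

#' Project 3D channel midpoints onto the unit disk
#'
#' Azimuthal-equidistant projection about the vertex: radial coordinate
#' `rho = theta / theta_max` (polar angle from the vertex direction), azimuth
#' preserved. Points beyond `theta_max` are clipped to the rim (`rho = 1`)
#' and flagged -- the flattening distorts ventral relative to dorsal sites.
#'
#' @param midpoints Matrix or data frame (n x 3) of coordinates, mm.
#' @param head_center Center of the head sphere (default origin).
#' @param vertex_dir Direction of the vertex (default +z), need not be unit.
#' @param theta_max Maximum polar angle mapped to the rim, radians
#'   (default 100 degrees).
#' @return Data frame of class `eac_projection`: `x`, `y` (disk coordinates),
#'   `rho`, `azimuth`, `clipped`; projection parameters as attributes.
#' @export
project_to_disk <- function(midpoints, head_center = c(0, 0, 0),
                            vertex_dir = c(0, 0, 1),
                            theta_max = 100 * pi / 180) {
  if (theta_max <= 0 || theta_max > pi) stop("theta_max must lie in (0, pi]")
  nv <- sqrt(sum(vertex_dir^2))
  if (nv < 1e-12) stop("vertex_dir must have non-zero length")
  v <- vertex_dir / nv
  p <- sweep(as.matrix(midpoints), 2, head_center)
  pn <- sqrt(rowSums(p^2))
  if (any(pn < 1e-9)) stop("midpoint coincides with head_center")

  # orthonormal basis perpendicular to the vertex direction
  ref <- if (abs(v[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * v) * v
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(v[2] * e1[3] - v[3] * e1[2],
          v[3] * e1[1] - v[1] * e1[3],
          v[1] * e1[2] - v[2] * e1[1])

  ct <- pmin(1, pmax(-1, p %*% v / pn))
  theta <- acos(drop(ct))
  az <- atan2(drop(p %*% e2), drop(p %*% e1))
  rho <- theta / theta_max
  clipped <- rho > 1
  rho <- pmin(rho, 1)
  out <- data.frame(x = rho * cos(az), y = rho * sin(az),
                    rho = rho, azimuth = az, clipped = clipped)
  attr(out, "vertex_dir") <- v
  attr(out, "basis") <- rbind(e1, e2)
  attr(out, "theta_max") <- theta_max
  attr(out, "head_center") <- head_center
  class(out) <- c("eac_projection", "data.frame")
  out
}

#' Inverse disk projection (disk to sphere angles)
#'
#' Recovers polar angle and azimuth from disk coordinates of an
#' [project_to_disk()] result (exact for unclipped points).
#'
#' @param x,y Disk coordinates.
#' @param theta_max Maximum polar angle of the projection.
#' @return Data frame with `theta`, `azimuth`.
#' @export
project_from_disk <- function(x, y, theta_max = 100 * pi / 180) {
  rho <- sqrt(x^2 + y^2)
  data.frame(theta = rho * theta_max, azimuth = atan2(y, x))
}

#' Interpolate channel values into a disk raster
#'
#' Piecewise-linear (Delaunay triangulation) interpolation of per-channel
#' values over the projected positions; pixels inside the disk but outside
#' the convex hull of the channels are filled by nearest neighbor and
#' flagged as extrapolated.
#'
#' @param projection An `eac_projection` (or data frame with `x`, `y`).
#' @param values Per-channel scalar values (NA allowed; dropped).
#' @param grid_n Raster resolution per axis (default 64).
#' @return Object of class `eac_gridmap`: `value` (grid_n x grid_n matrix),
#'   `valid` (inside-disk mask), `extrapolated` mask, axes `x`, `y`.
#' @export
interpolate_map <- function(projection, values, grid_n = 64) {
  ok <- is.finite(values) & is.finite(projection$x) & is.finite(projection$y)
  px <- projection$x[ok]; py <- projection$y[ok]; pv <- values[ok]
  if (length(pv) < 3) stop("need >= 3 channels with values")
  # collapse duplicated projected locations to their mean value
  key <- paste(round(px, 9), round(py, 9))
  if (anyDuplicated(key)) {
    agg <- tapply(pv, key, mean)
    first <- !duplicated(key)
    pv <- as.numeric(agg[match(key[first], names(agg))])
    px <- px[first]; py <- py[first]
  }
  if (.collinear(px, py)) stop("degenerate geometry: all channels collinear")

  ax <- seq(-1, 1, length.out = grid_n)
  g <- interp::interp(px, py, pv, xo = ax, yo = ax, method = "linear",
                      duplicate = "mean")
  value <- g$z
  valid <- outer(ax, ax, function(a, b) a^2 + b^2 <= 1)
  extrap <- valid & is.na(value)
  if (any(extrap)) {
    idx <- which(extrap, arr.ind = TRUE)
    gx <- ax[idx[, 1]]; gy <- ax[idx[, 2]]
    nn <- vapply(seq_along(gx), function(i) {
      which.min((px - gx[i])^2 + (py - gy[i])^2)
    }, 0L)
    value[extrap] <- pv[nn]
  }
  value[!valid] <- NA_real_
  structure(list(value = value, valid = valid, extrapolated = extrap,
                 x = ax, y = ax, n_channels = length(pv)),
            class = "eac_gridmap")
}

.collinear <- function(x, y, tol = 1e-9) {
  if (length(x) < 3) return(TRUE)
  xc <- x - mean(x); yc <- y - mean(y)
  m <- cbind(xc, yc)
  s <- svd(m, nu = 0, nv = 0)$d
  s[2] <= tol * max(s[1], 1)
}

#' Evaluate a grid map at arbitrary disk points
#'
#' Bilinear lookup on the raster (nearest valid pixel at the rim).
#'
#' @param map An `eac_gridmap`.
#' @param x,y Disk coordinates.
#' @return Interpolated values.
#' @export
map_lookup <- function(map, x, y) {
  ix <- findInterval(x, map$x, all.inside = TRUE)
  iy <- findInterval(y, map$y, all.inside = TRUE)
  vapply(seq_along(x), function(i) {
    xs <- map$x[c(ix[i], ix[i] + 1)]; ys <- map$y[c(iy[i], iy[i] + 1)]
    z <- map$value[c(ix[i], ix[i] + 1), c(iy[i], iy[i] + 1)]
    if (any(!is.finite(z))) {
      zf <- z[is.finite(z)]
      return(if (length(zf)) mean(zf) else NA_real_)  # rim fallback
    }
    tx <- (x[i] - xs[1]) / diff(xs); ty <- (y[i] - ys[1]) / diff(ys)
    (1 - tx) * (1 - ty) * z[1, 1] + tx * (1 - ty) * z[2, 1] +
      (1 - tx) * ty * z[1, 2] + tx * ty * z[2, 2]
  }, 0)
}

.stack_maps <- function(maps) {
  stopifnot(length(maps) >= 1)
  dims <- vapply(maps, function(m) dim(m$value), c(0L, 0L))
  if (length(unique(dims[1, ])) > 1 || length(unique(dims[2, ])) > 1) {
    stop("grid mismatch: maps must share the same raster")
  }
  array(unlist(lapply(maps, `[[`, "value")),
        dim = c(dim(maps[[1]]$value), length(maps)))
}

#' Group mean and SE-percent maps
#'
#' Per-pixel mean across subjects and the standard error of the mean
#' expressed as a percentage of the mean (`100 * (SD/sqrt(n)) / mean`),
#' undefined where the mean is non-positive.
#'
#' @param maps List of `eac_gridmap` on a shared raster (>= 2).
#' @return List: `mean` and `se_percent` grid maps, `n`.
#' @export
group_maps <- function(maps) {
  if (length(maps) < 2) stop("need >= 2 subjects")
  a <- .stack_maps(maps)
  n <- dim(a)[3]
  mu <- apply(a, c(1, 2), mean)
  sdv <- apply(a, c(1, 2), stats::sd)
  sep <- 100 * (sdv / sqrt(n)) / mu
  sep[!is.finite(sep) | mu <= 0] <- NA_real_
  tmpl <- maps[[1]]
  mean_map <- tmpl; mean_map$value <- mu
  se_map <- tmpl; se_map$value <- sep
  list(mean = mean_map, se_percent = se_map, n = n)
}

#' Split-half reliability of group maps
#'
#' Randomly splits subjects into two halves stratified by the given factors
#' (age decade and sex), computes each half's mean map, and returns the
#' pixel-wise Pearson correlation over jointly valid pixels.
#'
#' @param maps List of `eac_gridmap` (one per subject, shared raster).
#' @param strata Data frame of stratification factors (one row per subject),
#'   e.g. decade and sex; singleton strata are assigned at random with a
#'   warning.
#' @param seed Integer seed for the split.
#' @return List: `r`, `half` (group assignment), the two half-mean maps.
#' @export
split_half_reliability <- function(maps, strata, seed = 1) {
  n <- length(maps)
  stopifnot(nrow(strata) == n)
  key <- interaction(strata, drop = TRUE)
  half <- integer(n)
  withr::with_seed(seed, {
    for (g in levels(key)) {
      i <- which(key == g)
      if (length(i) == 1) {
        warning("stratum of size 1; assigning at random")
        half[i] <- sample(1:2, 1)
      } else {
        i <- sample(i)
        half[i] <- rep(1:2, length.out = length(i))
      }
    }
  })
  m1 <- group_maps(maps[half == 1])$mean
  m2 <- group_maps(maps[half == 2])$mean
  list(r = map_correlation(m1, m2), half = half, mean1 = m1, mean2 = m2)
}

#' Pixel-wise correlation between two maps
#'
#' Pearson correlation over jointly valid, finite pixels of a shared raster.
#'
#' @param a,b `eac_gridmap` objects.
#' @return Correlation coefficient.
#' @export
map_correlation <- function(a, b) {
  if (!identical(dim(a$value), dim(b$value))) stop("grid mismatch")
  ok <- a$valid & b$valid & is.finite(a$value) & is.finite(b$value)
  if (sum(ok) < 3) stop("need >= 3 jointly valid pixels")
  va <- a$value[ok]; vb <- b$value[ok]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop("undefined correlation: zero variance in a map")
  }
  stats::cor(va, vb)
}

#' Per-pixel correlation of component maps with a covariate
#'
#' For each pixel, the Pearson correlation across subjects between the
#' per-subject pixel values and a covariate -- the local-component
#' correlation-map analysis.
#'
#' @param maps List of per-subject `eac_gridmap` on a shared raster.
#' @param covariate Numeric vector, one value per subject.
#' @return An `eac_gridmap` of correlations.
#' @export
pixelwise_correlation_map <- function(maps, covariate) {
  a <- .stack_maps(maps)
  stopifnot(dim(a)[3] == length(covariate))
  r <- apply(a, c(1, 2), function(v) {
    if (any(!is.finite(v)) || stats::sd(v) == 0) NA_real_ else
      stats::cor(v, covariate)
  })
  out <- maps[[1]]
  out$value <- r
  out
}
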