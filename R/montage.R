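# Optode montage generation on a spherical head cap, and the channel table
# (all source-detector pairs within the usable distance range, duplicated
# across the two wavelengths with identical geometry: the 690 and 830 nm
# source fibers are co-located pairs).

#' Generate a high-density optode montage on a spherical cap
#'
#' Optodes are placed quasi-uniformly (jittered Fibonacci lattice) on the
#' superior cap of a sphere of radius `head_radius_mm` (polar angle up to
#' `theta_max_deg` from the vertex). Each source position hosts a co-located
#' pair of source fibers (690 and 830 nm); each optode (fiber) carries an
#' independent log-normal gain emulating heterogeneous source power, detector
#' efficiency and scalp coupling. Channels are all source-detector pairs whose
#' chord distance lies in `[d_range[1], d_range[2]]` mm (inclusive), listed
#' once per wavelength with identical geometry.
#'
#' @param n_source_pairs Number of dual-wavelength source positions.
#' @param n_detectors Number of detector positions.
#' @param head_radius_mm Head sphere radius, mm.
#' @param seed Integer seed for jitter, placement assignment and gains.
#' @param gain_sigma SD of log gains (0 gives all gains exactly 1).
#' @param theta_max_deg Maximum polar angle of the cap, degrees.
#' @param d_range Admissible channel distance range in mm (default 15-80).
#' @param jitter_deg SD of angular jitter applied to lattice points, degrees.
#' @return An object of class `eac_montage`: list with `optodes` (data frame:
#'   `optode_id`, `kind` in source_690/source_830/detector, `x_mm`, `y_mm`,
#'   `z_mm`, `gain`), `channels` (data frame: `channel_id`, `source`,
#'   `detector`, `wavelength_nm`, `distance_mm`, `mid_x`, `mid_y`, `mid_z`),
#'   and the generating parameters.
#' @export
generate_montage <- function(n_source_pairs, n_detectors, head_radius_mm = 90,
                             seed = 1, gain_sigma = 0.5, theta_max_deg = 100,
                             d_range = c(15, 80), jitter_deg = 3) {
  if (head_radius_mm <= 0) stop("head_radius_mm must be > 0")
  if (n_source_pairs < 1 || n_detectors < 1) stop("optode counts must be > 0")
  withr::with_seed(seed, {
    n_pos <- n_source_pairs + n_detectors
    pos <- .cap_lattice(n_pos, head_radius_mm, theta_max_deg * pi / 180,
                        jitter_deg * pi / 180)
    idx <- sample.int(n_pos)                       # which lattice points are sources
    src_pos <- pos[idx[seq_len(n_source_pairs)], , drop = FALSE]
    det_pos <- pos[idx[n_source_pairs + seq_len(n_detectors)], , drop = FALSE]

    optodes <- rbind(
      data.frame(kind = "source_690", src_pos),
      data.frame(kind = "source_830", src_pos),
      data.frame(kind = "detector",  det_pos)
    )
    names(optodes)[2:4] <- c("x_mm", "y_mm", "z_mm")
    optodes$optode_id <- seq_len(nrow(optodes))
    optodes$gain <- if (gain_sigma == 0) rep(1, nrow(optodes)) else
      exp(stats::rnorm(nrow(optodes), 0, gain_sigma))
    optodes <- optodes[, c("optode_id", "kind", "x_mm", "y_mm", "z_mm", "gain")]

    channels <- .build_channels(optodes, d_range)
    for (wl in c(690, 830)) {
      n_mid <- sum(channels$wavelength_nm == wl &
                     channels$distance_mm >= 20 & channels$distance_mm <= 50)
      if (n_mid < 5) {
        stop("montage configuration unusable: only ", n_mid,
             " channels in [20, 50] mm at ", wl, " nm")
      }
    }
    structure(list(
      optodes = optodes, channels = channels,
      head_radius_mm = head_radius_mm, theta_max_deg = theta_max_deg,
      d_range = d_range, gain_sigma = gain_sigma, seed = seed
    ), class = "eac_montage")
  })
}

# Quasi-uniform jittered Fibonacci lattice on the spherical cap theta <= theta_max.
.cap_lattice <- function(n, radius, theta_max, jitter) {
  k <- seq_len(n) - 0.5
  u <- 1 - (k / n) * (1 - cos(theta_max))   # cos(theta), uniform in area
  theta <- acos(u)
  golden <- pi * (3 - sqrt(5))
  phi <- k * golden
  theta <- pmin(pmax(theta + stats::rnorm(n, 0, jitter), 0), theta_max)
  phi <- phi + stats::rnorm(n, 0, jitter)
  cbind(x = radius * sin(theta) * cos(phi),
        y = radius * sin(theta) * sin(phi),
        z = radius * cos(theta))
}

.build_channels <- function(optodes, d_range) {
  det <- optodes[optodes$kind == "detector", ]
  out <- vector("list", 2L)
  for (w in seq_along(c(690, 830))) {
    wl <- c(690, 830)[w]
    src <- optodes[optodes$kind == paste0("source_", wl), ]
    dx <- outer(src$x_mm, det$x_mm, "-")
    dy <- outer(src$y_mm, det$y_mm, "-")
    dz <- outer(src$z_mm, det$z_mm, "-")
    dist <- sqrt(dx^2 + dy^2 + dz^2)
    keep <- which(dist >= d_range[1] & dist <= d_range[2], arr.ind = TRUE)
    keep <- matrix(keep, ncol = 2)
    si <- keep[, 1]; di <- keep[, 2]
    out[[w]] <- data.frame(
      source = src$optode_id[si],
      detector = det$optode_id[di],
      wavelength_nm = rep(wl, length(si)),
      distance_mm = dist[keep],
      mid_x = (src$x_mm[si] + det$x_mm[di]) / 2,
      mid_y = (src$y_mm[si] + det$y_mm[di]) / 2,
      mid_z = (src$z_mm[si] + det$z_mm[di]) / 2
    )
  }
  channels <- do.call(rbind, out)
  channels <- channels[order(channels$wavelength_nm, channels$source, channels$detector), ]
  channels$channel_id <- seq_len(nrow(channels))
  rownames(channels) <- NULL
  channels[, c("channel_id", "source", "detector", "wavelength_nm",
               "distance_mm", "mid_x", "mid_y", "mid_z")]
}

#' Redraw optode gains of a montage
#'
#' Keeps the geometry (and the channel table) fixed and draws a fresh
#' log-normal gain for every optode; used to give each subject its own
#' coupling realization of a shared helmet geometry.
#'
#' @param montage An `eac_montage`.
#' @param seed Integer seed.
#' @param gain_sigma SD of log gains; defaults to the montage's own value.
#' @return The montage with new gains.
#' @export
redraw_gains <- function(montage, seed, gain_sigma = montage$gain_sigma) {
  stopifnot(inherits(montage, "eac_montage"))
  n <- nrow(montage$optodes)
  montage$optodes$gain <- if (gain_sigma == 0) rep(1, n) else
    withr::with_seed(seed, exp(stats::rnorm(n, 0, gain_sigma)))
  montage
}

#' @export
print.eac_montage <- function(x, ...) {
  cat("eac_montage:", sum(x$optodes$kind != "detector") / 2, "source pairs,",
      sum(x$optodes$kind == "detector"), "detectors, R =", x$head_radius_mm, "mm\n")
  tab <- table(x$channels$wavelength_nm)
  cat("channels in [", x$d_range[1], ",", x$d_range[2], "] mm:",
      paste(names(tab), "nm:", tab, collapse = ", "), "\n")
  invisible(x)
}
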