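# Preprocessing of channel intensity blocks: block-mean normalization,
# robust movement correction, zero-phase high-pass filtering above the
# physiological band, and the SNR table consumed by the EAC estimator.
# The pipeline order is fixed: normalize -> movement_correct -> highpass ->
# compute_snr.

.add_stage <- function(block, stage) {
  block$stages <- c(block$stages, stage)
  block
}

.check_block <- function(block) {
  stopifnot(inherits(block, "eac_block"))
  invisible(block)
}

#' Normalize a block by its per-channel mean intensity
#'
#' Divides every channel by its block-mean intensity, so the output mean is 1
#' and subsequent variance is the squared coefficient of variation entering
#' the SNR definition.
#'
#' @param block An `eac_block`.
#' @return The block with normalized samples; the original means are kept in
#'   `i_avg`.
#' @export
normalize_block <- function(block) {
  .check_block(block)
  if (any(!is.finite(block$counts))) stop("invalid channel: non-finite samples")
  i_avg <- colMeans(block$counts)
  if (any(i_avg <= 0)) stop("invalid channel: non-positive mean intensity")
  block$counts <- sweep(block$counts, 2, i_avg, "/")
  block$i_avg <- i_avg
  .add_stage(block, "normalize")
}

#' Robust movement (spike) correction
#'
#' Samples whose robust z-score -- deviation from a per-channel running
#' median, scaled by the MAD (with an epsilon floor for degenerate constant
#' channels) -- exceeds `spike_z` are replaced by linear interpolation of
#' neighboring samples. Channels with more than 10% replaced samples are
#' flagged motion-contaminated; more than 50% raises an error.
#'
#' The robust scale is floored at the expected shot-noise scale of the
#' channel (`1/sqrt(i_avg)` on normalized data) so that ordinary photon
#' counting fluctuations on sparse channels -- where the MAD of integer
#' counts can degenerate to zero -- are never mistaken for movement spikes.
#'
#' @param block A normalized `eac_block`.
#' @param spike_z Robust z threshold (default 5).
#' @param k Running-median window (odd, default 15 samples).
#' @return The corrected block; fraction replaced per channel in
#'   `channels$spike_fraction`, motion flag in `channels$motion`.
#' @export
movement_correct <- function(block, spike_z = 5, k = 15) {
  .check_block(block)
  x <- block$counts
  n <- nrow(x)
  frac <- numeric(ncol(x))
  shot_scale <- if (!is.null(block$i_avg)) 1 / sqrt(pmax(block$i_avg, 1e-12)) else
    rep(0, ncol(x))
  for (j in seq_len(ncol(x))) {
    med <- stats::runmed(x[, j], k, endrule = "keep")
    resid <- x[, j] - med
    scale <- max(stats::mad(resid), shot_scale[j], 1e-12)
    bad <- which(abs(resid) > spike_z * scale)
    frac[j] <- length(bad) / n
    if (frac[j] > 0.5) stop("channel rejected: >50% of samples flagged as spikes")
    if (length(bad)) {
      ok <- setdiff(seq_len(n), bad)
      x[bad, j] <- stats::approx(ok, x[ok, j], xout = bad, rule = 2)$y
    }
  }
  block$counts <- x
  block$channels$spike_fraction <- frac
  block$channels$motion <- frac > 0.10
  .add_stage(block, "movement_correct")
}

#' Zero-phase Butterworth high-pass filter
#'
#' Order-4 Butterworth applied forward and backward (zero phase), default
#' cutoff 10 Hz: removes cardiac/respiratory/vasomotor modulation so the
#' residual variance is shot-noise dominated.
#'
#' @param block An `eac_block`.
#' @param cutoff_hz Cutoff frequency; must be below Nyquist.
#' @param order Filter order (default 4).
#' @return The filtered block.
#' @export
highpass_filter <- function(block, cutoff_hz = 10, order = 4) {
  .check_block(block)
  nyq <- block$fs_hz / 2
  if (cutoff_hz >= nyq) stop("cutoff_hz must be below the Nyquist frequency (", nyq, " Hz)")
  bf <- signal::butter(order, cutoff_hz / nyq, type = "high")
  x <- block$counts
  # remove the DC level before filtering: the filter suppresses it anyway,
  # but zero-phase edge handling would otherwise inject O(mean) transients
  x <- sweep(x, 2, colMeans(x))
  block$counts <- .filtfilt_mat(bf$b, bf$a, x)
  .add_stage(block, "highpass")
}

# Zero-phase forward-backward IIR filtering, column-wise on a matrix: one
# C-level filter pass for all channels at once (direct form: convolution for
# the MA part, recursion for the AR part, zero initial state, zero padding
# at the trailing edge before the backward pass).
.filtfilt_mat <- function(b, a, x) {
  x <- as.matrix(x)
  one_pass <- function(m) {
    head0 <- matrix(0, length(b) - 1, ncol(m))
    v <- stats::filter(rbind(head0, m), b, method = "convolution", sides = 1)
    v <- v[-seq_len(length(b) - 1), , drop = FALSE]
    if (length(a) > 1) v <- stats::filter(v, -a[-1], method = "recursive")
    matrix(as.numeric(v), nrow(m), ncol(m))
  }
  np <- 2 * max(length(a), length(b))
  y <- one_pass(rbind(x, matrix(0, np, ncol(x))))
  y <- one_pass(y[nrow(y):1, , drop = FALSE])
  y[seq(nrow(y), nrow(y) - nrow(x) + 1), , drop = FALSE]
}

#' SNR table of a preprocessed block
#'
#' Per channel, `SNR^2 = 1 / var(i(t) / i_avg)` on the filtered normalized
#' series, and the estimator's response variable `y = ln(SNR^2 * r^2)`.
#'
#' @param block An `eac_block` (normalized, movement-corrected, high-passed;
#'   [preprocess_block()] enforces the order).
#' @param on_degenerate `"error"` (default) raises on a zero-variance channel;
#'   `"flag"` records it as invalid instead.
#' @return Data frame (one row per channel): `channel_id`, `montage`,
#'   `wavelength_nm`, `distance_mm`, midpoint coordinates, `snr`, `y`, and
#'   logical flags `low_light`, `motion`, `bad`.
#' @export
compute_snr <- function(block, on_degenerate = c("error", "flag")) {
  .check_block(block)
  on_degenerate <- match.arg(on_degenerate)
  v <- apply(block$counts, 2, stats::var)
  if (any(!is.finite(v))) stop("invalid channel: non-finite variance")
  degenerate <- v <= 0
  if (any(degenerate) && on_degenerate == "error") {
    stop("undefined SNR: zero-variance channel(s) ",
         paste(block$channels$channel_id[degenerate], collapse = ", "))
  }
  ch <- block$channels
  snr <- ifelse(degenerate, NA_real_, 1 / sqrt(v))
  out <- data.frame(
    channel_id = ch$channel_id,
    montage = if (!is.null(ch$montage)) ch$montage else 1L,
    wavelength_nm = ch$wavelength_nm,
    distance_mm = ch$distance_mm,
    mid_x = ch$mid_x, mid_y = ch$mid_y, mid_z = ch$mid_z,
    snr = snr,
    y = log(snr^2 * ch$distance_mm^2),
    low_light = if (!is.null(ch$low_light)) ch$low_light else FALSE,
    motion = if (!is.null(ch$motion)) ch$motion else FALSE
  )
  out$bad <- out$low_light | out$motion | !is.finite(out$y)
  attr(out, "stages") <- block$stages
  out
}

#' Full preprocessing pipeline for one block
#'
#' Applies, in this fixed order: [normalize_block()], [movement_correct()],
#' [highpass_filter()], [compute_snr()]. Dead channels (non-positive mean
#' intensity, e.g. zero-count low-light channels) are not processed; they
#' appear in the output flagged `bad` with missing SNR, so cohort runs never
#' abort on one unusable channel.
#'
#' @param block A raw `eac_block`.
#' @param spike_z Spike threshold for movement correction.
#' @param cutoff_hz High-pass cutoff.
#' @return The SNR table (see [compute_snr()]).
#' @export
preprocess_block <- function(block, spike_z = 5, cutoff_hz = 10) {
  mu <- colMeans(block$counts)
  # dead channels, and low-light-flagged channels (expected < 1 count/sample):
  # kept in the table, marked, but not run through the filter chain -- their
  # variance is not shot-noise interpretable and the estimator never uses them
  low <- if (!is.null(block$channels$low_light)) block$channels$low_light else
    rep(FALSE, ncol(block$counts))
  dead <- mu <= 0 | !is.finite(mu) | low
  dead_ch <- block$channels[dead, , drop = FALSE]
  if (any(dead)) {
    block$counts <- block$counts[, !dead, drop = FALSE]
    block$channels <- block$channels[!dead, , drop = FALSE]
  }
  block <- normalize_block(block)
  block <- movement_correct(block, spike_z = spike_z)
  block <- highpass_filter(block, cutoff_hz = cutoff_hz)
  out <- compute_snr(block, on_degenerate = "flag")
  if (any(dead)) {
    dd <- data.frame(
      channel_id = dead_ch$channel_id,
      montage = if (!is.null(dead_ch$montage)) dead_ch$montage else 1L,
      wavelength_nm = dead_ch$wavelength_nm,
      distance_mm = dead_ch$distance_mm,
      mid_x = dead_ch$mid_x, mid_y = dead_ch$mid_y, mid_z = dead_ch$mid_z,
      snr = NA_real_, y = NA_real_,
      low_light = TRUE, motion = FALSE, bad = TRUE
    )
    st <- attr(out, "stages")
    out <- rbind(out, dd)
    attr(out, "stages") <- st
  }
  out
}
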