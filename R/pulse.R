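# Heart rate and heart-rate variability from the optical pulse: the
# normalized series averaged across acceptable channels, band-passed to the
# cardiac band, with inter-beat intervals measured between consecutive
# diastolic troughs.

#' Heart rate and HRV from optical channel data
#'
#' Averages the normalized series of all acceptable (non-low-light) channels
#' into one pulsating signal, band-passes it to the cardiac band, and detects
#' diastolic troughs by local-minimum search with a refractory period. Heart
#' rate is the inverse of the mean inter-beat interval; HRV is the SD of the
#' inter-beat intervals in ms.
#'
#' @param blocks An `eac_block` or list of them (>= 30 s of data in total).
#' @param band_hz Cardiac band, Hz (default c(0.5, 2.5)).
#' @param refractory_s Minimum spacing between detected beats (default 0.33 s).
#' @return List: `hr_bpm`, `hrv_ms`, `n_beats`, `ibi_ms`.
#' @export
compute_hr_hrv <- function(blocks, band_hz = c(0.5, 2.5), refractory_s = 0.33) {
  if (inherits(blocks, "eac_block")) blocks <- list(blocks)
  fs <- blocks[[1]]$fs_hz
  total_s <- sum(vapply(blocks, function(b) nrow(b$counts) / b$fs_hz, 0))
  if (total_s < 30) stop("need at least 30 s of data for pulse metrics")

  ibi_all <- numeric(0)
  for (b in blocks) {
    x <- b$counts
    if (!"normalize" %in% b$stages) x <- sweep(x, 2, colMeans(x), "/")
    keep <- if (!is.null(b$channels$low_light)) !b$channels$low_light else
      rep(TRUE, ncol(x))
    if (!any(keep)) keep <- rep(TRUE, ncol(x))
    pulse <- rowMeans(x[, keep, drop = FALSE])
    if (stats::sd(pulse) < 1e-12) next
    bf <- signal::butter(4, band_hz / (fs / 2), type = "pass")
    pb <- signal::filtfilt(bf, pulse - mean(pulse))
    # drop the zero-phase filter's settling edges before beat detection
    trim <- round(1.5 * fs)
    if (length(pb) > 2 * trim + 10) pb <- pb[(trim + 1):(length(pb) - trim)]
    troughs <- .find_troughs(pb, fs, refractory_s)
    if (length(troughs) >= 2) {
      ibi_all <- c(ibi_all, diff(troughs) / fs * 1000)
    }
  }
  if (length(ibi_all) < 1) stop("no pulse detected: fewer than 2 beats")
  list(hr_bpm = 60000 / mean(ibi_all),
       hrv_ms = if (length(ibi_all) > 1) stats::sd(ibi_all) else 0,
       n_beats = length(ibi_all) + 1L,
       ibi_ms = ibi_all)
}

# Local-minimum trough detection with a refractory period: candidate minima
# below the signal median, accepted greedily from the deepest up, refined to
# sub-sample precision by parabolic interpolation through the three samples
# around each trough. Returns fractional sample positions.
.find_troughs <- function(x, fs, refractory_s) {
  n <- length(x)
  if (n < 3) return(numeric(0))
  cand <- which(x[2:(n - 1)] < x[1:(n - 2)] & x[2:(n - 1)] <= x[3:n]) + 1L
  cand <- cand[x[cand] < stats::median(x)]
  if (!length(cand)) return(numeric(0))
  cand <- cand[order(x[cand])]
  min_gap <- refractory_s * fs
  kept <- integer(0)
  for (i in cand) {
    if (!length(kept) || all(abs(kept - i) >= min_gap)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  vapply(kept, function(i) {
    if (i <= 1 || i >= n) return(as.numeric(i))
    denom <- x[i - 1] - 2 * x[i] + x[i + 1]
    if (denom <= 0) return(as.numeric(i))
    i + 0.5 * (x[i - 1] - x[i + 1]) / denom
  }, 0)
}
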