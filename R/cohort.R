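# Cohort assembly: age/sex stratification, shared montage geometry with
# per-subject gain realizations, the ground-truth table, and raw-data export.

#' Generate a synthetic cohort
#'
#' Ages are stratified uniformly over decade bins spanning the configured age
#' range with balanced sex within each decade. Every subject shares the same
#' set of montage geometries (the study helmet placements) but receives fresh
#' optode gains per placement; channel time series are regenerated on demand
#' from stored seeds ([subject_raw()]), so the cohort object stays small. All
#' randomness derives from `config$master_seed`.
#'
#' @param config An `eac_config`.
#' @param out_dir Optional directory: writes the ground-truth/covariate table,
#'   montage tables and config ([write_cohort()]).
#' @return An object of class `eac_cohort`: `truth` (one row per subject with
#'   covariates and true optical properties), `subjects` (list of
#'   `eac_subject`), `montages` (shared geometries), `seeds`, `config`,
#'   `calib`.
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "eac_config"))
  calib <- calibrate_cohort_optics(config)
  n <- config$n_subjects
  nm <- config$n_montages

  decades <- seq(config$age_range[1], config$age_range[2] - 10, by = 10)
  decade_idx <- rep(seq_along(decades), length.out = n)     # round-robin fill
  sex <- integer(n)
  for (d in seq_along(decades)) {
    i <- which(decade_idx == d)
    sex[i] <- rep(c(1L, 2L), length.out = length(i))
  }

  seeds <- withr::with_seed(config$master_seed, {
    list(
      geometry = sample.int(.Machine$integer.max, nm),
      ages = sample.int(.Machine$integer.max, 1),
      latent = sample.int(.Machine$integer.max, n),
      gains = matrix(sample.int(.Machine$integer.max, n * nm), n, nm),
      ts = matrix(sample.int(.Machine$integer.max, n * nm), n, nm)
    )
  })
  ages <- withr::with_seed(seeds$ages, {
    stats::runif(n, decades[decade_idx], decades[decade_idx] + 10)
  })

  montages <- lapply(seeds$geometry, function(s) {
    generate_montage(config$n_source_pairs, config$n_detectors,
                     head_radius_mm = config$head_radius_mm, seed = s,
                     gain_sigma = config$gain_sigma,
                     theta_max_deg = config$theta_max_deg)
  })

  subjects <- lapply(seq_len(n), function(i) {
    sample_subject(ages[i], config, seed = seeds$latent[i], sex = sex[i],
                   calib = calib)
  })

  truth <- do.call(rbind, lapply(seq_len(n), function(i) {
    s <- subjects[[i]]
    data.frame(
      id = i, age = s$age, sex = s$sex, decade = decade_idx[i],
      thickness_mm = s$thickness_mm, cortical_volume = s$cortical_volume,
      wmsa_log_voxels = s$wmsa_log_voxels, so2 = s$so2,
      total_hb_um = s$total_hb_um, crf_mets = s$crf_mets,
      hr_bpm = s$hr_bpm, hrv_ms = s$hrv_ms, prefx = s$prefx,
      performance_z = s$performance_z, verbal_z = s$verbal_z,
      mua690 = s$mua[1], mua830 = s$mua[2],
      musp690 = s$musp[1], musp830 = s$musp[2],
      eac690_true = s$eac[1], eac830_true = s$eac[2]
    )
  }))
  tests <- do.call(rbind, lapply(subjects, function(s) as.data.frame(s$tests)))
  truth <- cbind(truth, tests)

  cohort <- structure(list(
    truth = truth, subjects = subjects, montages = montages,
    seeds = seeds, config = config, calib = calib
  ), class = "eac_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' Raw optical data for one subject
#'
#' Re-simulates the subject's recording blocks (one per montage placement)
#' deterministically from the cohort's stored seeds: shared geometry, this
#' subject's gain realization per placement.
#'
#' @param cohort An `eac_cohort`.
#' @param i Subject index.
#' @param field_fun Optional EAC field override (see [simulate_timeseries()]).
#' @return List of `eac_block`, one per montage placement.
#' @export
subject_raw <- function(cohort, i, field_fun = NULL) {
  stopifnot(inherits(cohort, "eac_cohort"))
  lapply(seq_len(cohort$config$n_montages), function(m) {
    mg <- redraw_gains(cohort$montages[[m]], seed = cohort$seeds$gains[i, m])
    blk <- simulate_timeseries(cohort$subjects[[i]], mg, cohort$config,
                               seed = cohort$seeds$ts[i, m],
                               field_fun = field_fun)
    blk$montage <- m
    blk$channels$montage <- m
    blk
  })
}

#' Write a cohort to plain-text files
#'
#' Emits `cohort.tsv` (ground truth and covariates), `montage_<m>.tsv`
#' (optode table: id, kind, position, gain of the shared geometry) and
#' `config.json` (including the extinction-coefficient provenance). With
#' `timeseries = TRUE` also writes per-subject channel intensities as TSV
#' (`subject_<i>_montage_<m>.tsv`: time_s, channel_id, intensity) -- intended
#' for small configurations.
#'
#' @param cohort An `eac_cohort`.
#' @param dir Output directory (created if missing).
#' @param timeseries Also write raw channel intensities (default FALSE).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, timeseries = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(cohort$truth, file.path(dir, "cohort.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (m in seq_along(cohort$montages)) {
    utils::write.table(cohort$montages[[m]]$optodes,
                       file.path(dir, sprintf("montage_%d.tsv", m)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    cfg <- cohort$config
    class(cfg) <- NULL
    cfg$extinction_coefficients <- cohort$calib$extinction
    jsonlite::write_json(cfg, file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (timeseries) {
    for (i in seq_len(cohort$config$n_subjects)) {
      blocks <- subject_raw(cohort, i)
      for (m in seq_along(blocks)) {
        b <- blocks[[m]]
        long <- data.frame(
          time_s = rep(b$time_s, times = ncol(b$counts)),
          channel_id = rep(b$channels$channel_id, each = nrow(b$counts)),
          intensity = as.vector(b$counts)
        )
        utils::write.table(long, file.path(dir, sprintf("subject_%d_montage_%d.tsv", i, m)),
                           sep = "\t", row.names = FALSE, quote = FALSE)
      }
    }
  }
  invisible(dir)
}

#' Read a channel time-series TSV written by [write_cohort()]
#'
#' @param path TSV with columns time_s, channel_id, intensity.
#' @param channels Channel table to attach (from the montage).
#' @param fs_hz Sampling rate.
#' @return An `eac_block`.
#' @export
read_timeseries_tsv <- function(path, channels, fs_hz) {
  long <- utils::read.delim(path)
  ids <- unique(long$channel_id)
  counts <- matrix(long$intensity, ncol = length(ids))
  ch <- channels[match(ids, channels$channel_id), ]
  structure(list(
    counts = counts, channels = ch, fs_hz = fs_hz,
    time_s = unique(long$time_s), stages = character(), i_avg = NULL
  ), class = "eac_block")
}
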