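# End-to-end cohort pipeline: simulate -> preprocess -> estimate (global,
# stratified, per-channel) -> topographic maps -> TOI / wavelength PCA ->
# association battery and mediation.

#' Preprocess and estimate one subject
#'
#' Simulates the subject's blocks from the cohort seeds, runs the fixed
#' preprocessing chain on each, pools the SNR tables across montage
#' placements, and fits global, per-channel and distance-stratified EACs.
#'
#' @param cohort An `eac_cohort`.
#' @param i Subject index.
#' @param radius_mm Neighborhood radius for the channel map.
#' @param do_map Compute the per-channel map (default TRUE).
#' @param do_pulse Compute HR/HRV from the optical pulse (default TRUE).
#' @return List: `snr`, `global` (per wavelength), `stratified`,
#'   `channel_map`, `pulse`.
#' @export
process_subject <- function(cohort, i, radius_mm = 30, do_map = TRUE,
                            do_pulse = TRUE) {
  blocks <- subject_raw(cohort, i)
  snr <- do.call(rbind, lapply(blocks, preprocess_block))
  out <- list(
    snr = snr,
    global = global_eac(snr),
    stratified = distance_stratified_eac(snr)
  )
  out$channel_map <- if (do_map) eac_channel_map(snr, radius_mm = radius_mm) else NULL
  out$pulse <- if (do_pulse) {
    tryCatch(compute_hr_hrv(blocks), error = function(e) NULL)
  } else NULL
  out
}

#' Run the full cohort pipeline
#'
#' Generates the synthetic cohort, processes every subject
#' ([process_subject()]), builds per-subject disk maps at both wavelengths,
#' computes group mean and SE-percent maps, split-half reliability and
#' cross-wavelength map similarity, inverts the global EAC pairs to the
#' tissue oxygenation index, decomposes the EAC wavelength space (EAC1/EAC2),
#' and runs the association battery and the mediation analyses
#' (age -> thickness -> EAC1; age -> TOI -> EAC2).
#'
#' @param config An `eac_config` (or NULL for defaults).
#' @param radius_mm Neighborhood radius for channel maps (default 30 mm).
#' @param grid_n Map raster resolution (default 64).
#' @param do_maps Build topographic maps (default TRUE).
#' @param split_seed Seed for the split-half reliability split.
#' @param verbose Print progress.
#' @return List of class `eac_pipeline`: `cohort`, `table` (per-subject
#'   estimates merged with the truth/covariates), `maps`, `group`,
#'   `reliability`, `cross_wavelength_r`, `pca`, `toi`, `battery`,
#'   `mediation`, `elapsed_s`.
#' @export
run_cohort_pipeline <- function(config = NULL, radius_mm = 30, grid_n = 64,
                                do_maps = TRUE, split_seed = 1,
                                verbose = FALSE) {
  t0 <- proc.time()["elapsed"]
  if (is.null(config)) config <- simulation_config()
  cohort <- generate_cohort(config)
  n <- config$n_subjects
  t_maps <- 0

  tab <- cohort$truth
  tab$eac690_est <- NA_real_; tab$eac830_est <- NA_real_
  tab$hr_est_bpm <- NA_real_; tab$hrv_est_ms <- NA_real_
  maps <- list(`690` = vector("list", n), `830` = vector("list", n))
  stratified <- vector("list", n)

  for (i in seq_len(n)) {
    ps <- process_subject(cohort, i, radius_mm = radius_mm, do_map = FALSE)
    g <- ps$global
    tab$eac690_est[i] <- g$mu_eff[g$wavelength_nm == 690]
    tab$eac830_est[i] <- g$mu_eff[g$wavelength_nm == 830]
    if (!is.null(ps$pulse)) {
      tab$hr_est_bpm[i] <- ps$pulse$hr_bpm
      tab$hrv_est_ms[i] <- ps$pulse$hrv_ms
    }
    stratified[[i]] <- cbind(id = i, ps$stratified)
    if (do_maps) {
      tm <- proc.time()["elapsed"]
      cm <- eac_channel_map(ps$snr, radius_mm = radius_mm)
      for (wl in c("690", "830")) {
        sub <- cm[cm$wavelength_nm == as.numeric(wl), ]
        proj <- project_to_disk(sub[, c("mid_x", "mid_y", "mid_z")],
                                theta_max = config$theta_max_deg * pi / 180)
        maps[[wl]][[i]] <- interpolate_map(proj, sub$mu_eff, grid_n = grid_n)
      }
      t_maps <- t_maps + (proc.time()["elapsed"] - tm)
    }
    if (verbose) message("subject ", i, "/", n, " done")
  }

  toi <- toi_from_eac(tab$eac690_est, tab$eac830_est)
  tab$toi <- toi$toi
  pca <- wavelength_pca(tab$eac690_est, tab$eac830_est)
  tab$EAC1 <- pca$scores[, "EAC1"]
  tab$EAC2 <- pca$scores[, "EAC2"]

  group <- reliability <- cross_r <- NULL
  if (do_maps) {
    group <- lapply(maps, group_maps)
    strata <- data.frame(decade = tab$decade, sex = tab$sex)
    reliability <- lapply(maps, function(mm) {
      tryCatch(split_half_reliability(mm, strata = strata, seed = split_seed),
               error = function(e) NULL)
    })
    cross_r <- map_correlation(group[["690"]]$mean, group[["830"]]$mean)
  }

  battery_cols <- c(age = "age", crf = "crf_mets", sex = "sex",
                    heart_rate = "hr_bpm", heart_rate_variability = "hrv_ms",
                    prefx = "prefx", cortical_thickness = "thickness_mm",
                    cortical_volume = "cortical_volume", wmsa = "wmsa_log_voxels",
                    performance_score = "performance_z", verbal_score = "verbal_z",
                    toi = "toi")
  battery <- association_battery(tab, covariates = unname(battery_cols))

  safe_med <- function(m, y) tryCatch(mediate(tab$age, m, y), error = function(e) NULL)
  mediation <- list(
    thickness_eac1 = safe_med(tab$thickness_mm, tab$EAC1),
    volume_eac1 = safe_med(tab$cortical_volume, tab$EAC1),
    toi_eac2 = safe_med(tab$toi, tab$EAC2)
  )

  structure(list(
    cohort = cohort, table = tab,
    stratified = do.call(rbind, stratified),
    maps = maps, group = group, reliability = reliability,
    cross_wavelength_r = cross_r,
    pca = pca, toi = toi, battery = battery, mediation = mediation,
    elapsed_s = unname(proc.time()["elapsed"] - t0),
    elapsed_maps_s = unname(t_maps)
  ), class = "eac_pipeline")
}

#' @export
print.eac_pipeline <- function(x, ...) {
  tb <- x$table
  cat(sprintf("eac_pipeline: %d subjects, %.1f s\n", nrow(tb), x$elapsed_s))
  cat(sprintf("  EAC690 %.3f +- %.3f, EAC830 %.3f +- %.3f mm^-1, r = %.2f\n",
              mean(tb$eac690_est), stats::sd(tb$eac690_est),
              mean(tb$eac830_est), stats::sd(tb$eac830_est),
              stats::cor(tb$eac690_est, tb$eac830_est)))
  cat(sprintf("  PC1 variance fraction %.1f%%\n", 100 * x$pca$variance_fraction[1]))
  if (!is.null(x$reliability) && !is.null(x$reliability[["690"]])) {
    cat(sprintf("  split-half r: %.3f (690), %.3f (830); cross-wavelength r %.3f\n",
                x$reliability[["690"]]$r, x$reliability[["830"]]$r,
                x$cross_wavelength_r))
  }
  invisible(x)
}
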