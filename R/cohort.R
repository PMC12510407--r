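#' Scan-epoch windows of the repeated-measures design
#'
#' The four wakefulness scan windows (7:00-9:00, 11:00-13:00, 16:00-18:00,
#' 19:00-21:00) in minutes of day, together with the cohort mean scan times
#' reported for each window (7:44, 12:17, 16:03, 19:31).
#'
#' @return Tibble with columns `epoch`, `start_min`, `end_min`, `mean_min`.
#' @export
epoch_windows <- function() {
  tibble(epoch = 1:4,
         start_min = c(420, 660, 960, 1140),
         end_min = c(540, 780, 1080, 1260),
         mean_min = c(464, 737, 963, 1171))
}

#' Default per-epoch true ChP water-density distributions
#'
#' Normal distributions (mean, SD) of true ChP water density per scan epoch,
#' matching the study's reported per-epoch water-density summaries. The SDs
#' are treated as between-subject spread: each subject draws one true
#' density per epoch.
#'
#' @return Tibble with columns `epoch`, `mean`, `sd`.
#' @export
default_density_distributions <- function() {
  tibble(epoch = 1:4,
         mean = c(0.891, 0.891, 0.896, 0.901),
         sd = c(0.038, 0.050, 0.045, 0.058))
}

#' Generate the full synthetic study cohort
#'
#' Builds the complete in-silico study: per-subject true ChP water densities
#' per epoch, scan schedules with per-scan scanner gains, phantom image
#' volumes with Rician noise and ground-truth masks, per-minute actigraphy
#' traces, and (optionally) a same-session reproducibility sub-study. The
#' default configuration is 15 subjects x 4 epochs (60 circadian scans) plus
#' 5 subjects x 2 back-to-back reproducibility scans.
#'
#' All randomness derives deterministically from the single master `seed`
#' via per-subject / per-scan seed streams, so any scan can be regenerated
#' in isolation.
#'
#' @param n_subjects Number of subjects (default 15).
#' @param epochs Number of scan epochs (1 to 4; default 4).
#' @param density_distributions Tibble with columns `epoch`, `mean`, `sd`
#'   giving the per-epoch Normal distribution of true ChP water density;
#'   default [default_density_distributions()].
#' @param wm_density True white-matter water density of the phantom.
#' @param noise_sigma Rician noise scale relative to the noiseless WM signal
#'   (default 0.05).
#' @param gain_range Per-scan scanner gain is drawn log-uniformly from this
#'   interval (default `c(0.5, 2)`), exercising gain cancellation.
#' @param n_repro_subjects Subjects in the reproducibility sub-study
#'   (default 5; 0 disables it). Each contributes two back-to-back scans of
#'   the same true density, 10 minutes apart.
#' @param match_printed_times If `TRUE`, scan times within each epoch are
#'   re-centred so the cohort mean equals the reported mean scan time for
#'   that window; otherwise times are uniform within the window.
#' @param phantom A [phantom_spec()].
#' @param protocol A [spin_echo_protocol()].
#' @param tissues Tissue list from [default_tissues()]; ChP relaxation times
#'   are taken from it, densities come from the cohort draws.
#' @param actigraphy Baseline [actigraphy_spec()]; per-subject amplitude is
#'   drawn uniformly in `[0.7, 1.3]` x `amplitude` and acrophase uniformly
#'   in `[2.6, 3.1]` rad (nocturnal nadir), keeping the spec's noise and
#'   duration.
#' @param seed Master integer seed.
#' @return An object of class `chp_cohort`: a list with `scans` (tibble,
#'   one row per scan with a `volume` list-column), `mask` (shared truth
#'   label array), `subjects`, `actigraphy`, `phantom`, `protocol`,
#'   `tissues`, and `seed`.
#' @examples
#' \donttest{
#' co <- make_cohort(n_subjects = 2, epochs = 2, n_repro_subjects = 0,
#'                   seed = 1)
#' quantify_cohort(co)
#' }
#' @export
make_cohort <- function(n_subjects = 15, epochs = 4,
                        density_distributions = default_density_distributions(),
                        wm_density = 0.70, noise_sigma = 0.05,
                        gain_range = c(0.5, 2), n_repro_subjects = 5,
                        match_printed_times = FALSE,
                        phantom = phantom_spec(),
                        protocol = spin_echo_protocol(),
                        tissues = default_tissues(),
                        actigraphy = actigraphy_spec(),
                        seed = 1L) {
  check_number(n_subjects, "n_subjects", lower = 1)
  check_number(epochs, "epochs", lower = 1, upper = 4)
  check_number(n_repro_subjects, "n_repro_subjects", lower = 0,
               upper = n_subjects)
  stopifnot(all(c("epoch", "mean", "sd") %in% names(density_distributions)))
  dens <- dplyr::slice(dplyr::arrange(density_distributions, .data$epoch),
                       seq_len(epochs))
  windows <- dplyr::slice(epoch_windows(), seq_len(epochs))

  subj_ids <- sprintf("S%02d", seq_len(n_subjects))

  # subject-level draws (truth densities, rhythm parameters)
  subjects <- purrr::map_dfr(seq_len(n_subjects), function(i) {
    set.seed(derive_seed(seed, 1L, i))
    tibble(
      subject_id = subj_ids[i],
      hemisphere = sample(c("left", "right"), 1),
      amplitude = actigraphy$amplitude * runif(1, 0.7, 1.3),
      acrophase_rad = runif(1, 2.6, 3.1),
      repro_density = rnorm(1, dens$mean[1], dens$sd[1]),
      density = list(rnorm(epochs, dens$mean, dens$sd))
    )
  })

  truth <- subjects |>
    dplyr::select("subject_id", "density") |>
    tidyr::unnest_longer("density", values_to = "true_density",
                         indices_to = "epoch")

  # circadian scan schedule
  scans <- truth |>
    dplyr::left_join(windows, by = "epoch") |>
    dplyr::mutate(scan_type = "circadian")
  set.seed(derive_seed(seed, 2L))
  scans$timestamp_min <- runif(nrow(scans), scans$start_min, scans$end_min)
  if (isTRUE(match_printed_times)) {
    # re-centre each epoch's draws on the reported mean scan time,
    # compressing the spread just enough to stay inside the window
    scans <- scans |>
      dplyr::group_by(.data$epoch) |>
      dplyr::mutate(timestamp_min = {
        d <- .data$timestamp_min - mean(.data$timestamp_min)
        s <- 1
        if (min(d) < 0) s <- min(s, (.data$mean_min[1] - .data$start_min[1]) / -min(d))
        if (max(d) > 0) s <- min(s, (.data$end_min[1] - .data$mean_min[1]) / max(d))
        .data$mean_min + d * s
      }) |>
      dplyr::ungroup()
  }
  scans$gain <- exp(runif(nrow(scans), log(gain_range[1]), log(gain_range[2])))
  scans <- dplyr::select(scans, "subject_id", "scan_type", "epoch",
                         "timestamp_min", "gain", "true_density")

  # reproducibility sub-study: two same-session scans of one true density
  if (n_repro_subjects > 0) {
    set.seed(derive_seed(seed, 3L))
    rep_subj <- subj_ids[seq_len(n_repro_subjects)]
    t0 <- runif(n_repro_subjects, windows$start_min[1], windows$end_min[1] - 10)
    g <- exp(runif(2 * n_repro_subjects, log(gain_range[1]), log(gain_range[2])))
    repro <- tibble(
      subject_id = rep(rep_subj, each = 2),
      scan_type = "reproducibility",
      epoch = NA_integer_,
      timestamp_min = as.numeric(rbind(t0, t0 + 10)),
      gain = g,
      true_density = rep(subjects$repro_density[seq_len(n_repro_subjects)],
                         each = 2)
    )
    scans <- dplyr::bind_rows(scans, repro)
  }
  scans <- scans |>
    dplyr::arrange(.data$subject_id, .data$scan_type, .data$epoch,
                   .data$timestamp_min) |>
    dplyr::mutate(scan_id = sprintf("%s_%s%02d", .data$subject_id,
                                    substr(.data$scan_type, 1, 1),
                                    dplyr::row_number()),
                  .by = "subject_id") |>
    dplyr::relocate("scan_id")

  scans$phantom_seed <- purrr::map_int(seq_len(nrow(scans)),
                                       ~ derive_seed(seed, 4L, .x))
  scans$volume <- purrr::pmap(
    list(scans$true_density, scans$gain, scans$phantom_seed),
    function(d, g, s) {
      make_phantom(d, gain = g, noise_sigma = noise_sigma,
                   wm_density = wm_density, spec = phantom,
                   protocol = protocol, tissues = tissues, seed = s)$volume
    })

  acti <- purrr::map_dfr(seq_len(n_subjects), function(i) {
    sp <- actigraphy_spec(amplitude = subjects$amplitude[i],
                          acrophase_rad = subjects$acrophase_rad[i],
                          period_param = actigraphy$period_param,
                          noise_sd = actigraphy$noise_sd,
                          n_days = actigraphy$n_days)
    dplyr::mutate(make_actigraphy(sp, seed = derive_seed(seed, 5L, i)),
                  subject_id = subj_ids[i], .before = 1)
  })

  structure(
    list(scans = scans,
         mask = phantom_mask(phantom),
         subjects = dplyr::select(subjects, -"density", -"repro_density"),
         truth = truth,
         actigraphy = acti,
         phantom = phantom, protocol = protocol, tissues = tissues,
         wm_density = wm_density, noise_sigma = noise_sigma,
         seed = as.integer(seed)),
    class = "chp_cohort"
  )
}

#' @export
print.chp_cohort <- function(x, ...) {
  n_circ <- sum(x$scans$scan_type == "circadian")
  n_rep <- sum(x$scans$scan_type == "reproducibility")
  cat(sprintf(paste0("Synthetic ChP cohort: %d subjects, %d circadian scans",
                     " + %d reproducibility scans (seed %d)\n"),
              nrow(x$subjects), n_circ, n_rep, x$seed))
  cat(sprintf("  phantom grid %s at %s mm\n",
              paste(x$phantom$grid_shape, collapse = "x"),
              paste(x$phantom$voxel_size_mm, collapse = "x")))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes NIfTI-1 phantom volumes and the shared truth mask (voxel sizes in
#' the header), the scan schedule, subject table and actigraphy as CSV, and
#' a JSON snapshot of the generator configuration (including all seeds,
#' sufficient for exact regeneration).
#'
#' @param cohort A `chp_cohort`.
#' @param dir Output directory.
#' @param overwrite Refuse to write into a non-empty directory unless `TRUE`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, overwrite = FALSE) {
  stopifnot(inherits(cohort, "chp_cohort"))
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !isTRUE(overwrite)) {
    abort("Output directory is not empty; set `overwrite = TRUE`.",
          class = "chpwater_exists")
  }
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  vx <- cohort$phantom$voxel_size_mm
  as_img <- function(arr) {
    im <- RNifti::asNifti(arr)
    RNifti::pixdim(im) <- vx
    im
  }
  RNifti::writeNifti(as_img(cohort$mask), file.path(dir, "mask.nii.gz"))
  purrr::walk2(cohort$scans$volume, cohort$scans$scan_id, function(v, id) {
    RNifti::writeNifti(as_img(v), file.path(dir, "images",
                                            paste0(id, ".nii.gz")))
  })
  utils::write.csv(dplyr::select(cohort$scans, -"volume"),
                   file.path(dir, "schedule.csv"), row.names = FALSE)
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$actigraphy, file.path(dir, "actigraphy.csv"),
                   row.names = FALSE)
  cfg <- list(seed = cohort$seed, wm_density = cohort$wm_density,
              noise_sigma = cohort$noise_sigma,
              phantom = unclass(cohort$phantom),
              protocol = unclass(cohort$protocol))
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Quantify ChP water density from NIfTI files
#'
#' File-based entry point for the ratio quantification: reads a proton
#' density-weighted volume and an integer label mask (1 = ChP, 2 = WM ROI,
#' 3 = CSF) and returns the ROI means and calibrated density.
#'
#' @param image_path,mask_path Paths to NIfTI files on the same grid.
#' @param rho_wm Assumed white-matter water density.
#' @return One-row tibble with `si_chp`, `si_wm`, `rho_wm_assumed`,
#'   `rho_chp`, `above_physical`.
#' @export
quantify_nifti <- function(image_path, mask_path, rho_wm = 0.70) {
  vol <- as.array(RNifti::readNifti(image_path))
  mask_img <- as.array(RNifti::readNifti(mask_path))
  mask <- array(as.integer(round(mask_img)), dim = dim(mask_img))
  si_chp <- roi_mean(vol, mask, "chp")
  si_wm <- roi_mean(vol, mask, "wm")
  rho <- chp_water_density(si_chp, si_wm, rho_wm)
  tibble(si_chp = si_chp, si_wm = si_wm, rho_wm_assumed = rho_wm,
         rho_chp = rho, above_physical = rho > 1)
}
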