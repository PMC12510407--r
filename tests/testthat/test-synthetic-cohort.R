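test_that("phantom masks are disjoint and respect the geometry contract", {
  set.seed(3)
  for (i in 1:5) {
    sp <- phantom_spec(grid_shape = c(48, 32, 10),
                       ventricle_center_mm = c(runif(1, -3, -1), 0, 0),
                       ventricle_radii_mm = c(2.5, 2.5, runif(1, 4, 6)),
                       chp_center_mm = c(runif(1, -3, -1), 0, 0),
                       chp_radii_mm = c(0.8, 0.8, 2),
                       wm_roi_offset_mm = runif(1, 2, 3),
                       wm_roi_radius_mm = 1)
    m <- phantom_mask(sp)
    expect_setequal(unique(as.vector(m)), c(0L, 1L, 2L, 3L))
    # labels partition the grid: a voxel has exactly one label by construction
    q_vent <- m %in% c(1L, 3L)
    expect_true(all(m[m == 1L] == 1L))
    expect_false(any(m == 1L & m == 2L))
    expect_true(sum(m == 1L) > 0 && sum(m == 2L) > 0)
  }
  # ChP escaping the ventricle or WM ROI touching it must error
  expect_error(phantom_mask(small_phantom(chp_radii_mm = c(4, 4, 7))),
               class = "chpwater_geometry")
  expect_error(phantom_mask(small_phantom(wm_roi_offset_mm = 0)),
               class = "chpwater_geometry")
})

test_that("noiseless phantom reproduces the tissue signal ratio exactly", {
  ph <- make_phantom(0.9, gain = 1, noise_sigma = 0, spec = small_phantom(),
                     seed = 1)
  r <- roi_mean(ph$volume, ph$mask, "chp") / roi_mean(ph$volume, ph$mask, "wm")
  expect_equal(r, 0.9 / 0.7, tolerance = 1e-12)
})

test_that("phantom generation is deterministic and gain-invariant in ratio", {
  sp <- small_phantom()
  a <- make_phantom(0.9, noise_sigma = 0.05, spec = sp, seed = 42)
  b <- make_phantom(0.9, noise_sigma = 0.05, spec = sp, seed = 42)
  expect_identical(a$volume, b$volume)
  c2 <- make_phantom(0.9, noise_sigma = 0.05, spec = sp, seed = 43)
  expect_false(identical(a$volume, c2$volume))
  # doubling the gain with the same noise stream rescales the whole volume,
  # leaving the ROI-mean ratio unchanged
  g1 <- make_phantom(0.9, gain = 1, noise_sigma = 0.05, spec = sp, seed = 7)
  g2 <- make_phantom(0.9, gain = 2, noise_sigma = 0.05, spec = sp, seed = 7)
  r1 <- roi_mean(g1$volume, g1$mask, "chp") / roi_mean(g1$volume, g1$mask, "wm")
  r2 <- roi_mean(g2$volume, g2$mask, "chp") / roi_mean(g2$volume, g2$mask, "wm")
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("partial-volume mixing mode blurs boundaries but not ROI cores", {
  sp_pv <- small_phantom(partial_volume = TRUE)
  ph <- make_phantom(0.9, noise_sigma = 0, spec = sp_pv, seed = 1)
  ph0 <- make_phantom(0.9, noise_sigma = 0, spec = small_phantom(), seed = 1)
  expect_false(identical(ph$volume, ph0$volume))
  # mixed voxels lie between the pure class signals
  expect_true(all(ph$volume >= min(ph0$volume) - 1e-12 &
                    ph$volume <= max(ph0$volume) + 1e-12))
})

test_that("noiseless generate-quantify round trip recovers truth exactly", {
  co <- small_cohort(noise_sigma = 0, seed = 5)
  d <- quantify_cohort(co)
  expect_equal(d$rho_chp, d$true_density, tolerance = 1e-10)
})

test_that("cohort-level density recovery is unbiased at the default SNR", {
  errs <- unlist(lapply(1:20, function(s) {
    co <- small_cohort(n_subjects = 2, epochs = 2, seed = s)
    d <- quantify_cohort(co)
    d$rho_chp - d$true_density
  }))
  expect_lt(abs(mean(errs)), 0.005)
})

test_that("cohort structure matches the study design", {
  co <- make_cohort(n_subjects = 15, epochs = 4, n_repro_subjects = 5,
                    phantom = small_phantom(), seed = 2)
  expect_equal(sum(co$scans$scan_type == "circadian"), 60)
  expect_equal(sum(co$scans$scan_type == "reproducibility"), 10)
  # timestamps fall inside their epoch windows
  win <- epoch_windows()
  circ <- co$scans[co$scans$scan_type == "circadian", ]
  expect_true(all(circ$timestamp_min >= win$start_min[circ$epoch] &
                    circ$timestamp_min <= win$end_min[circ$epoch]))
  # reproducibility pairs share one true density, 10 minutes apart
  rep <- co$scans[co$scans$scan_type == "reproducibility", ]
  by_subj <- split(rep, rep$subject_id)
  for (r in by_subj) {
    expect_equal(r$true_density[1], r$true_density[2])
    expect_equal(diff(sort(r$timestamp_min)), 10)
  }
  # single-subject single-epoch degenerate design still works
  co1 <- make_cohort(n_subjects = 1, epochs = 1, n_repro_subjects = 0,
                     phantom = small_phantom(), seed = 3)
  expect_equal(nrow(co1$scans), 1)
})

test_that("zero-SD density distributions pin every scan to the epoch mean", {
  dd <- tibble::tibble(epoch = 1:2, mean = c(0.85, 0.92), sd = c(0, 0))
  co <- small_cohort(n_subjects = 3, epochs = 2, seed = 9,
                     density_distributions = dd)
  d <- quantify_cohort(co)
  expect_true(all(abs(d$rho_chp - dd$mean[d$epoch]) < 0.03))
  expect_equal(d$true_density, dd$mean[d$epoch])
})

test_that("match_printed_times recentres epoch means onto the study times", {
  co <- make_cohort(n_subjects = 15, epochs = 4, n_repro_subjects = 0,
                    match_printed_times = TRUE, phantom = small_phantom(),
                    seed = 4)
  circ <- co$scans[co$scans$scan_type == "circadian", ]
  m <- tapply(circ$timestamp_min, circ$epoch, mean)
  expect_equal(as.numeric(m), epoch_windows()$mean_min, tolerance = 1e-6)
})

test_that("actigraphy generator matches the cosinor contract", {
  # cosine at argument zero: E(0) = 2 * amplitude
  tr0 <- make_actigraphy(actigraphy_spec(amplitude = 1, acrophase_rad = 0,
                                         noise_sd = 0), seed = 1)
  expect_equal(tr0$met[tr0$t_min == 0], 2)
  # full-cycle parameterization attains 0 and 2a exactly once per day
  tr24 <- make_actigraphy(actigraphy_spec(amplitude = 1.5, acrophase_rad = 0,
                                          period_param = 720, noise_sd = 0,
                                          n_days = 5), seed = 1)
  expect_equal(min(tr24$met), 0, tolerance = 1e-12)
  expect_equal(max(tr24$met), 3, tolerance = 1e-12)
  # default half-period parameterization stays within [0, 2a]
  trd <- make_actigraphy(actigraphy_spec(amplitude = 1, noise_sd = 0), seed = 1)
  expect_true(all(trd$met >= 0 & trd$met <= 2))
  # the nadir falls between minute samples, so the minimum is O(dt^2) above 0
  expect_lt(min(trd$met), 1e-6)
  # length and determinism
  expect_equal(nrow(trd), 5 * 1440)
  expect_identical(make_actigraphy(actigraphy_spec(), seed = 8),
                   make_actigraphy(actigraphy_spec(), seed = 8))
  # noise is truncated at zero
  trn <- make_actigraphy(actigraphy_spec(amplitude = 0.5, noise_sd = 1),
                         seed = 2)
  expect_true(all(trn$met >= 0))
})

test_that("sleep efficiency is the asleep/in-bed ratio with guards", {
  expect_equal(sleep_efficiency(401.07, 457.88), 401.07 / 457.88)
  expect_error(sleep_efficiency(500, 400),
               class = "chpwater_invalid_parameter")
})
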