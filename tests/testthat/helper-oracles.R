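# Independent oracles and small fixtures used across the suite.

# Iterate the DRIVE cycle recursion to its fixed point, independently of the
# closed form in the package: excite (Mz -> 0, Mxy = Mz), readout decay over
# t_ro, optional tip-up restoring the decayed magnitude, free recovery over
# tr - t_ro.
drive_recursion_oracle <- function(t1, t2, tr, t_ro, drive = TRUE,
                                   tol = 1e-14, max_iter = 10000) {
  e2 <- exp(-t_ro / t2)
  e1 <- exp(-(tr - t_ro) / t1)
  mz <- 1
  for (i in seq_len(max_iter)) {
    post_readout <- if (drive) mz * e2 else 0
    mz_new <- 1 - (1 - post_readout) * e1
    if (abs(mz_new - mz) < tol) return(mz_new)
    mz <- mz_new
  }
  mz
}

# Brute-force O(n^2) Kendall tau-b with average-rank tie handling.
kendall_tau_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) next
      if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# Spearman rho as Pearson correlation of average ranks.
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Compact phantom geometry for fast tests (same topology as the default).
small_phantom <- function(...) {
  args <- list(grid_shape = c(48, 32, 10),
               voxel_size_mm = c(0.25, 0.25, 1.5),
               ventricle_center_mm = c(-2, 0, 0),
               ventricle_radii_mm = c(3, 3, 6),
               chp_center_mm = c(-2, 0, 0),
               chp_radii_mm = c(1, 1, 3),
               wm_roi_offset_mm = 3.5,
               wm_roi_radius_mm = 1.2)
  do.call(phantom_spec, utils::modifyList(args, list(...)))
}

small_cohort <- function(n_subjects = 2, epochs = 2, noise_sigma = 0.05,
                         seed = 1, ...) {
  make_cohort(n_subjects = n_subjects, epochs = epochs,
              noise_sigma = noise_sigma, n_repro_subjects = 0,
              phantom = small_phantom(), seed = seed, ...)
}

random_tissue <- function() {
  t1 <- runif(1, 300, 5000)
  tissue_properties("rnd", t1_ms = t1, t2_ms = runif(1, 40, min(t1, 2500)),
                    water_density = runif(1, 0.4, 1))
}
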