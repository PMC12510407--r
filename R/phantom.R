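#' Periventricular phantom geometry
#'
#' Stylized 3D geometry for the synthetic proton density-weighted scan: a
#' white-matter block containing an ellipsoidal CSF ventricle, an ellipsoidal
#' ChP blob strictly inside the ventricle, and a spherical white-matter ROI
#' placed `wm_roi_offset_mm` from the ventricle wall (mirroring ROI placement
#' ~10 mm from the ependyma). Coordinates are mm relative to the grid centre.
#'
#' @param grid_shape Integer vector of voxels per axis. The default
#'   `c(96, 64, 20)` gives one 20-slice block at the default voxel size.
#' @param voxel_size_mm Voxel edge lengths in mm; default
#'   `c(0.25, 0.25, 1.5)`, the acquisition resolution.
#' @param ventricle_center_mm,ventricle_radii_mm Ellipsoid centre and
#'   semi-axes of the CSF ventricle (mm).
#' @param chp_center_mm,chp_radii_mm Ellipsoid centre and semi-axes of the
#'   ChP blob (mm); must lie strictly inside the ventricle.
#' @param wm_roi_offset_mm Distance from the ventricle wall (along +x) to the
#'   centre of the white-matter ROI sphere (mm).
#' @param wm_roi_radius_mm Radius of the WM ROI sphere; the default 2.5 mm
#'   gives a volume of ~65 mm^3, matching the larger of the two ROI sizes
#'   considered for noise robustness.
#' @param partial_volume Logical; if `TRUE`, voxel signal is a linear mix of
#'   class signals over a 2x2x2 subgrid of the voxel instead of
#'   centre-of-voxel membership. Truth labels always use voxel centres.
#' @return An object of class `chp_phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96, 64, 20),
                         voxel_size_mm = c(0.25, 0.25, 1.5),
                         ventricle_center_mm = c(-6, 0, 0),
                         ventricle_radii_mm = c(4, 4, 10),
                         chp_center_mm = c(-6, 0, 0),
                         chp_radii_mm = c(1.5, 1.5, 5),
                         wm_roi_offset_mm = 10,
                         wm_roi_radius_mm = 2.5,
                         partial_volume = FALSE) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4),
            length(voxel_size_mm) == 3L, all(voxel_size_mm > 0),
            length(ventricle_radii_mm) == 3L, all(ventricle_radii_mm > 0),
            length(chp_radii_mm) == 3L, all(chp_radii_mm > 0),
            wm_roi_radius_mm > 0, wm_roi_offset_mm >= 0)
  structure(
    list(grid_shape = as.integer(grid_shape),
         voxel_size_mm = voxel_size_mm,
         ventricle_center_mm = ventricle_center_mm,
         ventricle_radii_mm = ventricle_radii_mm,
         chp_center_mm = chp_center_mm,
         chp_radii_mm = chp_radii_mm,
         wm_roi_offset_mm = wm_roi_offset_mm,
         wm_roi_radius_mm = wm_roi_radius_mm,
         partial_volume = isTRUE(partial_volume)),
    class = "chp_phantom_spec"
  )
}

# Mask label codes used throughout: 1 = ChP, 2 = WM ROI, 3 = CSF, 0 = bulk WM.
CHP_LABEL <- 1L
WM_LABEL <- 2L
CSF_LABEL <- 3L

wm_roi_center <- function(spec) {
  c(spec$ventricle_center_mm[1] + spec$ventricle_radii_mm[1] +
      spec$wm_roi_offset_mm,
    spec$ventricle_center_mm[2], spec$ventricle_center_mm[3])
}

# voxel-centre coordinate vectors (mm, grid-centred)
axis_coords <- function(n, dx) (seq_len(n) - (n + 1) / 2) * dx

# quadratic form (x-c)^2/r^2 summed over axes, as a full 3D array
ellipsoid_q <- function(spec, center, radii, offsets = c(0, 0, 0)) {
  n <- spec$grid_shape
  cx <- axis_coords(n[1], spec$voxel_size_mm[1]) + offsets[1]
  cy <- axis_coords(n[2], spec$voxel_size_mm[2]) + offsets[2]
  cz <- axis_coords(n[3], spec$voxel_size_mm[3]) + offsets[3]
  qx <- ((cx - center[1]) / radii[1])^2
  qy <- ((cy - center[2]) / radii[2])^2
  qz <- ((cz - center[3]) / radii[3])^2
  outer(outer(qx, qy, `+`), qz, `+`)
}

#' Build the truth label mask for a phantom geometry
#'
#' Returns a 3D integer array with labels 1 = ChP, 2 = white-matter ROI,
#' 3 = CSF (ventricle excluding ChP), 0 = bulk white matter, using
#' centre-of-voxel membership. Errors if the voxelized ChP is not fully
#' inside the ventricle, if the WM ROI intersects the ventricle, or if any
#' region is empty.
#'
#' @param spec A [phantom_spec()].
#' @return Integer array of dim `spec$grid_shape`.
#' @export
phantom_mask <- function(spec) {
  stopifnot(inherits(spec, "chp_phantom_spec"))
  in_vent <- ellipsoid_q(spec, spec$ventricle_center_mm,
                         spec$ventricle_radii_mm) <= 1
  in_chp <- ellipsoid_q(spec, spec$chp_center_mm, spec$chp_radii_mm) <= 1
  in_wm_roi <- ellipsoid_q(spec, wm_roi_center(spec),
                           rep(spec$wm_roi_radius_mm, 3)) <= 1
  if (any(in_chp & !in_vent)) {
    abort("ChP blob extends outside the ventricle.",
          class = "chpwater_geometry")
  }
  if (any(in_wm_roi & in_vent)) {
    abort("White-matter ROI overlaps the ventricle.",
          class = "chpwater_geometry")
  }
  if (!any(in_chp) || !any(in_wm_roi) || !any(in_vent & !in_chp)) {
    abort("Phantom geometry produced an empty region at this resolution.",
          class = "chpwater_geometry")
  }
  lab <- array(0L, dim = spec$grid_shape)
  lab[in_vent] <- CSF_LABEL
  lab[in_chp] <- CHP_LABEL
  lab[in_wm_roi] <- WM_LABEL
  lab
}

# per-class noiseless signal for one scan (gain included)
class_signals <- function(chp_density, wm_density, tissues, protocol, gain) {
  relax <- function(tis) {
    drive_steady_state(tis, protocol) * exp(-protocol$te_ms / tis$t2_ms)
  }
  c(wm  = gain * wm_density * relax(tissues$wm),
    csf = gain * tissues$csf$water_density * relax(tissues$csf),
    chp = gain * chp_density * relax(tissues$chp))
}

# class-membership fractions per voxel: either hard centre membership or a
# 2x2x2 subgrid linear mix
class_fractions <- function(spec) {
  if (!spec$partial_volume) {
    in_vent <- ellipsoid_q(spec, spec$ventricle_center_mm,
                           spec$ventricle_radii_mm) <= 1
    in_chp <- ellipsoid_q(spec, spec$chp_center_mm, spec$chp_radii_mm) <= 1
    f_chp <- in_chp * 1
    f_csf <- (in_vent & !in_chp) * 1
  } else {
    f_chp <- f_csf <- array(0, dim = spec$grid_shape)
    offs <- expand.grid(x = c(-0.25, 0.25), y = c(-0.25, 0.25),
                        z = c(-0.25, 0.25))
    for (i in seq_len(nrow(offs))) {
      o <- as.numeric(offs[i, ]) * spec$voxel_size_mm
      sv <- ellipsoid_q(spec, spec$ventricle_center_mm,
                        spec$ventricle_radii_mm, o) <= 1
      sc <- ellipsoid_q(spec, spec$chp_center_mm, spec$chp_radii_mm, o) <= 1
      f_chp <- f_chp + sc / 8
      f_csf <- f_csf + (sv & !sc) / 8
    }
  }
  list(chp = f_chp, csf = f_csf, wm = 1 - f_chp - f_csf)
}

#' Synthesize one proton density-weighted phantom scan
#'
#' Renders the phantom geometry with per-class steady-state spin-echo
#' signals (shared scanner gain across all tissues in the scan) and applies
#' Rician noise voxelwise: each voxel value is
#' \eqn{\sqrt{(S + n_1)^2 + n_2^2}} with \eqn{n_1, n_2 \sim N(0, \sigma^2)}
#' and \eqn{\sigma} = `noise_sigma` times the noiseless white-matter signal
#' at this scan's gain (so SNR is gain-invariant). With `noise_sigma = 0`
#' the volume is noiseless and the ChP/WM ROI-mean ratio equals the tissue
#' signal ratio exactly.
#'
#' @param chp_density True ChP water density for this scan (mL/mL).
#' @param gain Scanner gain A shared by all tissues in the scan.
#' @param noise_sigma Rician noise scale relative to the noiseless WM signal.
#' @param wm_density White-matter water density (mL/mL).
#' @param spec A [phantom_spec()].
#' @param protocol A [spin_echo_protocol()].
#' @param tissues Tissue list as from [default_tissues()]; only relaxation
#'   times of `chp` and the `csf` class are taken from it (densities come
#'   from `chp_density` / `wm_density`).
#' @param seed Integer seed; the same seed reproduces the volume
#'   bit-identically.
#' @return List with `volume` (numeric 3D array), `mask` (integer label
#'   array; 1 = ChP, 2 = WM ROI, 3 = CSF), and `spec`.
#' @examples
#' ph <- make_phantom(0.9, gain = 1, noise_sigma = 0,
#'                    spec = phantom_spec(grid_shape = c(32, 24, 8),
#'                                        ventricle_radii_mm = c(2, 2, 4),
#'                                        chp_radii_mm = c(0.8, 0.8, 2),
#'                                        wm_roi_offset_mm = 3,
#'                                        wm_roi_radius_mm = 1), seed = 1)
#' roi_mean(ph$volume, ph$mask, "chp") / roi_mean(ph$volume, ph$mask, "wm")
#' @export
make_phantom <- function(chp_density, gain = 1, noise_sigma = 0.05,
                         wm_density = 0.70,
                         spec = phantom_spec(),
                         protocol = spin_echo_protocol(),
                         tissues = default_tissues(),
                         seed = 1L) {
  check_number(chp_density, "chp_density", lower = 0, upper = 1.2,
               strict_lower = TRUE)
  check_number(gain, "gain", lower = 0, strict_lower = TRUE)
  check_number(noise_sigma, "noise_sigma", lower = 0)
  mask <- phantom_mask(spec)
  sig <- class_signals(chp_density, wm_density, tissues, protocol, gain)
  fr <- class_fractions(spec)
  vol <- fr$wm * sig[["wm"]] + fr$csf * sig[["csf"]] + fr$chp * sig[["chp"]]
  if (noise_sigma > 0) {
    sigma <- noise_sigma * sig[["wm"]]
    set.seed(as.integer(seed))
    n <- length(vol)
    vol <- sqrt((vol + rnorm(n, sd = sigma))^2 + rnorm(n, sd = sigma)^2)
    dim(vol) <- spec$grid_shape
  }
  list(volume = vol, mask = mask, spec = spec)
}
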