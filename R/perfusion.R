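#' pCASL quantification parameters
#'
#' Parameters of the simplified single-compartment solution to the
#' flow-modified Bloch equation for pseudo-continuous arterial spin labeling
#' (pCASL). Defaults are the study values: inversion efficiency
#' \eqn{\alpha = 0.85}, arterial blood T1 = 1.9 s, labeling duration
#' \eqn{\tau = 1.8} s, post-labeling delay w = 2.0 s, and the 6000 factor
#' converting mL/g/s to mL/100 g/min.
#'
#' @param inversion_efficiency pCASL inversion efficiency (0, 1].
#' @param t1_blood_s Arterial blood T1 in seconds.
#' @param label_duration_s Labeling duration in seconds.
#' @param post_label_delay_s Post-labeling delay in seconds.
#' @param unit_factor Unit conversion factor (6000).
#' @return Object of class `chp_pcasl_params`.
#' @export
pcasl_params <- function(inversion_efficiency = 0.85, t1_blood_s = 1.9,
                         label_duration_s = 1.8, post_label_delay_s = 2.0,
                         unit_factor = 6000) {
  check_number(inversion_efficiency, "inversion_efficiency", lower = 0,
               upper = 1, strict_lower = TRUE)
  check_number(t1_blood_s, "t1_blood_s", lower = 0, strict_lower = TRUE)
  check_number(label_duration_s, "label_duration_s", lower = 0,
               strict_lower = TRUE)
  check_number(post_label_delay_s, "post_label_delay_s", lower = 0)
  check_number(unit_factor, "unit_factor", lower = 0, strict_lower = TRUE)
  structure(
    list(inversion_efficiency = inversion_efficiency,
         t1_blood_s = t1_blood_s, label_duration_s = label_duration_s,
         post_label_delay_s = post_label_delay_s, unit_factor = unit_factor),
    class = "chp_pcasl_params"
  )
}

#' Reference water densities for perfusion calibration
#'
#' Literature water-density constants used in ASL calibration: arterial
#' blood 0.87, white matter 0.70, gray matter 0.89, CSF 1.0, and the ChP
#' value measured by the ratio method (0.895 by default).
#'
#' @param rho_chp,rho_blood,rho_wm,rho_gm,rho_csf Water densities in
#'   (0, 1.2] (mL water / mL tissue).
#' @return Named list of class `chp_water_densities`.
#' @export
water_densities <- function(rho_chp = 0.895, rho_blood = 0.87,
                            rho_wm = 0.70, rho_gm = 0.89, rho_csf = 1.0) {
  vals <- c(rho_chp = rho_chp, rho_blood = rho_blood, rho_wm = rho_wm,
            rho_gm = rho_gm, rho_csf = rho_csf)
  check_number(vals, "water densities", lower = 0, upper = 1.2,
               strict_lower = TRUE, allow_vector = TRUE)
  structure(as.list(vals), class = "chp_water_densities")
}

#' pCASL perfusion from the labeled signal difference
#'
#' Single-compartment pCASL quantification:
#' \deqn{f = 6000 \cdot \frac{\Delta M / M_{0,a}}
#'   {2 \alpha T_{1a} (1 - e^{-\tau/T_{1a}}) e^{-w/T_{1a}}}}
#' in mL/100 g/min. Linear in \eqn{\Delta M}; halving \eqn{M_{0,a}} doubles
#' the perfusion estimate, which is how water-density miscalibration
#' propagates.
#'
#' @param delta_m Label/control difference signal (arbitrary units,
#'   vectorized).
#' @param m0a Equilibrium arterial magnetization in the same units
#'   (positive).
#' @param params A [pcasl_params()].
#' @return Perfusion in mL/100 g/min.
#' @examples
#' pcasl_perfusion(1, 100)  # ~86.9 for the default parameters
#' @export
pcasl_perfusion <- function(delta_m, m0a, params = pcasl_params()) {
  stopifnot(inherits(params, "chp_pcasl_params"))
  check_number(delta_m, "delta_m", allow_vector = TRUE)
  if (!is.numeric(m0a) || anyNA(m0a) || any(m0a <= 0)) {
    abort("`m0a` must be positive.", class = "chpwater_invalid_calibration")
  }
  t1a <- params$t1_blood_s
  denom <- 2 * params$inversion_efficiency * t1a *
    (1 - exp(-params$label_duration_s / t1a)) *
    exp(-params$post_label_delay_s / t1a)
  params$unit_factor * (delta_m / m0a) / denom
}

#' Arterial equilibrium magnetization from a tissue reference
#'
#' Converts a tissue equilibrium magnetization into the arterial value via
#' the water-density ratio \eqn{\rho_{tissue}/\rho_a = M_{0,tissue}/M_{0,a}},
#' i.e. \eqn{M_{0,a} = M_{0,tissue} \, \rho_a / \rho_{tissue}}. Using the
#' tissue magnetization directly as \eqn{M_{0,a}} (the identical-density
#' assumption) corresponds to `rho_tissue == rho_blood`.
#'
#' @param m0_tissue Tissue equilibrium magnetization (arbitrary units).
#' @param rho_tissue Tissue water density (positive).
#' @param rho_blood Arterial blood water density (default 0.87).
#' @return Arterial equilibrium magnetization, same units as `m0_tissue`.
#' @export
m0a_from_tissue <- function(m0_tissue, rho_tissue, rho_blood = 0.87) {
  check_number(m0_tissue, "m0_tissue", allow_vector = TRUE)
  if (!is.numeric(rho_tissue) || anyNA(rho_tissue) || any(rho_tissue <= 0)) {
    abort("`rho_tissue` must be positive.", class = "chpwater_invalid_density")
  }
  check_number(rho_blood, "rho_blood", lower = 0, strict_lower = TRUE,
               allow_vector = TRUE)
  m0_tissue * rho_blood / rho_tissue
}

#' Perfusion error from a mis-assumed tissue water density
#'
#' For each actual perfusion value, computes the perfusion that would be
#' calculated if quantification assumed tissue water density `rho_assumed`
#' while the true value is `rho_true`:
#' \eqn{f_{calc} = f_{actual} \cdot \rho_{assumed} / \rho_{true}}. With
#' `rho_assumed = rho_blood` (the default) this encodes the common
#' identical-density assumption of prior ChP ASL work. The error is linear
#' in `f_actual` with slope \eqn{|1 - \rho_{assumed}/\rho_{true}|}, and is
#' algebraically identical to the difference of two [pcasl_perfusion()]
#' evaluations that calibrate with the two [m0a_from_tissue()] choices.
#'
#' @param f_actual Actual perfusion grid in mL/100 g/min (default 35-75).
#' @param rho_true True tissue water density (default 0.895, the measured
#'   ChP value).
#' @param rho_blood Arterial blood water density (default 0.87).
#' @param rho_assumed Water density assumed at quantification time
#'   (default `rho_blood`).
#' @return Tibble of class `chp_perfusion_sweep` with columns `f_actual`,
#'   `f_calc`, `abs_error`, `rel_error`; supports [autoplot()].
#' @examples
#' sw <- perfusion_error_sweep(f_actual = seq(35, 70, by = 5))
#' range(sw$abs_error)  # ~1.0 to ~2.0 mL/100 g/min
#' @export
perfusion_error_sweep <- function(f_actual = seq(35, 75, by = 1),
                                  rho_true = 0.895, rho_blood = 0.87,
                                  rho_assumed = rho_blood) {
  check_number(f_actual, "f_actual", lower = 0, allow_vector = TRUE)
  check_number(rho_true, "rho_true", lower = 0, strict_lower = TRUE)
  check_number(rho_assumed, "rho_assumed", lower = 0, strict_lower = TRUE)
  f_calc <- f_actual * rho_assumed / rho_true
  out <- tibble(f_actual = f_actual, f_calc = f_calc,
                abs_error = abs(f_calc - f_actual),
                rel_error = (f_calc - f_actual) / f_actual)
  class(out) <- c("chp_perfusion_sweep", class(out))
  attr(out, "rho") <- c(true = rho_true, assumed = rho_assumed,
                        blood = rho_blood)
  out
}
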