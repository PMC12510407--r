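#' Actigraphy trace specification
#'
#' Parameters of the cosinor-structured per-minute energy-expenditure (MET)
#' generator: \eqn{E(t) = \alpha (1 + \cos(\pi t / f + \phi))} evaluated at
#' each minute of day, repeated over `n_days`, plus additive Gaussian noise
#' truncated at zero. The default acrophase (2.9 rad) places the nadir in the
#' early morning hours, emulating nocturnal rest.
#'
#' @param amplitude Cosinor amplitude \eqn{\alpha} (MET units); the trace
#'   spans 0 to 2*alpha before noise.
#' @param acrophase_rad Acrophase \eqn{\phi} in radians, constrained to
#'   `[0, pi]`.
#' @param period_param Circadian period parameter f in minutes (default
#'   1720); the cosine argument is `pi * t / f`.
#' @param noise_sd Additive Gaussian noise SD (MET units).
#' @param n_days Number of recording days (5 to 7 typical; minimum 1).
#' @return An object of class `chp_actigraphy_spec`.
#' @export
actigraphy_spec <- function(amplitude = 1, acrophase_rad = 2.9,
                            period_param = 1720, noise_sd = 0.3,
                            n_days = 5) {
  check_number(amplitude, "amplitude", lower = 0)
  check_number(acrophase_rad, "acrophase_rad", lower = 0, upper = pi)
  check_number(period_param, "period_param", lower = 0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(n_days, "n_days", lower = 1)
  structure(
    list(amplitude = amplitude, acrophase_rad = acrophase_rad,
         period_param = period_param, noise_sd = noise_sd,
         n_days = as.integer(n_days)),
    class = "chp_actigraphy_spec"
  )
}

#' Generate a per-minute actigraphy (MET) trace
#'
#' @param spec An [actigraphy_spec()].
#' @param seed Integer seed for the noise stream.
#' @return A tibble with one row per minute (`n_days * 1440` rows) and
#'   columns `day`, `minute_of_day`, `t_min` (cumulative minutes), and `met`.
#' @examples
#' tr <- make_actigraphy(actigraphy_spec(noise_sd = 0), seed = 1)
#' range(tr$met)  # 0 to 2*amplitude over the covered phase range
#' @export
make_actigraphy <- function(spec = actigraphy_spec(), seed = 1L) {
  stopifnot(inherits(spec, "chp_actigraphy_spec"))
  n <- spec$n_days * 1440L
  t_min <- seq_len(n) - 1L
  minute_of_day <- t_min %% 1440L
  e <- cosinor_predict(minute_of_day, amplitude = spec$amplitude,
                       acrophase_rad = spec$acrophase_rad,
                       period_param = spec$period_param)
  if (spec$noise_sd > 0) {
    set.seed(as.integer(seed))
    e <- pmax(0, e + rnorm(n, sd = spec$noise_sd))
  }
  tibble(day = t_min %/% 1440L + 1L, minute_of_day = minute_of_day,
         t_min = t_min, met = e)
}

#' Sleep efficiency
#'
#' Ratio of time asleep to time in bed, the standard actigraphy-derived
#' sleep-quality summary (e.g. 401.07 min asleep over 457.88 min in bed
#' gives 0.876).
#'
#' @param time_asleep_min Minutes asleep (non-negative).
#' @param time_in_bed_min Minutes in bed (positive, at least `time_asleep_min`).
#' @return Unitless efficiency in `[0, 1]`, vectorized.
#' @export
sleep_efficiency <- function(time_asleep_min, time_in_bed_min) {
  check_number(time_asleep_min, "time_asleep_min", lower = 0,
               allow_vector = TRUE)
  check_number(time_in_bed_min, "time_in_bed_min", lower = 0,
               strict_lower = TRUE, allow_vector = TRUE)
  if (any(time_asleep_min > time_in_bed_min)) {
    abort("Time asleep cannot exceed time in bed.",
          class = "chpwater_invalid_parameter")
  }
  time_asleep_min / time_in_bed_min
}
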