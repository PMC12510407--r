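#' Evaluate the cosinor energy-expenditure model
#'
#' \deqn{E(t) = \alpha \, (1 + \cos(\pi t / f + \phi))}
#' with t the time of day in minutes, f the circadian period parameter
#' (default 1720 min) and \eqn{\phi \in [0, \pi]} the acrophase. Output lies
#' in `[0, 2*amplitude]`. The conventional 24-h parameterization
#' \eqn{2\pi t/1440} is obtained with `period_param = 720`.
#'
#' @param t_min Time of day in minutes (vectorized; values outside
#'   `[0, 1440)` are folded onto the day).
#' @param amplitude Amplitude \eqn{\alpha} (MET units), non-negative.
#' @param acrophase_rad Acrophase \eqn{\phi} in radians, in `[0, pi]`.
#' @param period_param Period parameter f in minutes.
#' @return Energy expenditure in MET units, same length as `t_min`.
#' @examples
#' cosinor_predict(0, amplitude = 1, acrophase_rad = 0)  # 2
#' @export
cosinor_predict <- function(t_min, amplitude, acrophase_rad,
                            period_param = 1720) {
  check_number(t_min, "t_min", allow_vector = TRUE)
  check_number(amplitude, "amplitude", lower = 0)
  check_number(acrophase_rad, "acrophase_rad", lower = 0, upper = pi)
  check_number(period_param, "period_param", lower = 0, strict_lower = TRUE)
  t_fold <- t_min %% 1440
  amplitude * (1 + cos(pi * t_fold / period_param + acrophase_rad))
}

cosinor_sse <- function(par, t, y, f) {
  r <- par[1] * (1 + cos(pi * t / f + par[2])) - y
  sum(r * r)
}

cosinor_sse_grad <- function(par, t, y, f) {
  arg <- pi * t / f + par[2]
  cs <- cos(arg)
  r <- par[1] * (1 + cs) - y
  c(2 * sum(r * (1 + cs)), -2 * par[1] * sum(r * sin(arg)))
}

#' Fit the cosinor model to an actigraphy trace
#'
#' Minimizes the squared error of the cosinor model over amplitude and
#' acrophase with the period parameter held fixed, under the bounds
#' `amplitude >= 0` and `acrophase_rad` in `[0, pi]`. Timestamps are folded
#' onto minutes-of-day before fitting (the model carries no day index), so
#' the fit depends on the (time, MET) pairs, not on row order. Optimization
#' uses bounded quasi-Newton (L-BFGS-B) from a deterministic multi-start
#' grid: nine acrophase starts spanning `[0, pi]`, amplitude initialized at
#' half the trace range; the best start wins and ties break toward the lower
#' acrophase.
#'
#' @param data Data frame with one row per sampled minute.
#' @param time,met Columns of `data` holding the timestamp (minutes) and the
#'   MET value (tidy-eval; defaults `minute_of_day`, `met`).
#' @param period_param Fixed period parameter f in minutes (default 1720;
#'   use 720 for the conventional 24-h cosine).
#' @return An object of class `chp_cosinor` with elements `amplitude`,
#'   `acrophase_rad`, `period_param`, `residual_sse`, `converged`,
#'   `degenerate`, `n_obs`, and a `starts` tibble recording every grid start
#'   and its achieved objective. Supports [tidy()], [glance()], [predict()]
#'   and [autoplot()].
#' @examples
#' tr <- make_actigraphy(actigraphy_spec(noise_sd = 0.2), seed = 2)
#' fit <- fit_cosinor(tr)
#' tidy(fit)
#' @export
fit_cosinor <- function(data, time = minute_of_day, met = met,
                        period_param = 1720) {
  t <- dplyr::pull(data, {{ time }}) %% 1440
  y <- dplyr::pull(data, {{ met }})
  if (length(y) < 1440) {
    abort("Need at least one full day (1440 samples) of actigraphy.",
          class = "chpwater_invalid_parameter")
  }
  check_number(period_param, "period_param", lower = 0, strict_lower = TRUE)

  new_fit <- function(a, phi, sse, converged, degenerate, starts) {
    structure(
      list(amplitude = a, acrophase_rad = phi, period_param = period_param,
           residual_sse = sse, converged = converged, degenerate = degenerate,
           n_obs = length(y), starts = starts,
           data = tibble(minute_of_day = t, met = y)),
      class = "chp_cosinor"
    )
  }

  if (sd(y) == 0) {
    # constant trace carries no rhythm: flag degenerate, amplitude -> 0
    return(new_fit(0, NA_real_, sum((y - 0)^2), FALSE, TRUE,
                   tibble(phi_start = numeric(), alpha_start = numeric(),
                          sse = numeric(), convergence = integer())))
  }

  alpha0 <- max(diff(range(y)) / 2, 1e-6)
  phi_grid <- seq(0, pi, length.out = 9)
  runs <- purrr::map(phi_grid, function(phi0) {
    opt <- optim(c(alpha0, phi0), fn = cosinor_sse, gr = cosinor_sse_grad,
                 t = t, y = y, f = period_param, method = "L-BFGS-B",
                 lower = c(0, 0), upper = c(Inf, pi),
                 control = list(factr = 1e4, maxit = 500))
    list(par = opt$par, sse = opt$value, convergence = opt$convergence,
         phi0 = phi0)
  })
  starts <- tibble(
    phi_start = phi_grid,
    alpha_start = alpha0,
    sse = purrr::map_dbl(runs, "sse"),
    convergence = purrr::map_int(runs, ~ as.integer(.x$convergence))
  )
  # best objective wins; ties resolved toward the lower fitted acrophase
  best_sse <- min(starts$sse)
  cand <- which(starts$sse <= best_sse * (1 + 1e-12))
  phis <- purrr::map_dbl(runs[cand], ~ .x$par[2])
  best <- runs[[cand[which.min(phis)]]]
  new_fit(best$par[1], best$par[2], best$sse,
          converged = best$convergence == 0, degenerate = FALSE, starts)
}

#' @export
print.chp_cosinor <- function(x, ...) {
  cat("Cosinor fit (f =", x$period_param, "min):",
      if (x$degenerate) "[degenerate]" else if (!x$converged) "[not converged]"
      else "", "\n")
  cat(sprintf("  amplitude = %.4f MET, acrophase = %s rad, SSE = %.4g (n = %d)\n",
              x$amplitude,
              if (is.na(x$acrophase_rad)) "NA" else sprintf("%.4f", x$acrophase_rad),
              x$residual_sse, x$n_obs))
  invisible(x)
}

#' @rdname fit_cosinor
#' @param x,object A `chp_cosinor` fit.
#' @param ... Unused.
#' @export
tidy.chp_cosinor <- function(x, ...) {
  tibble(term = c("amplitude", "acrophase_rad", "period_param"),
         estimate = c(x$amplitude, x$acrophase_rad, x$period_param))
}

#' @rdname fit_cosinor
#' @export
glance.chp_cosinor <- function(x, ...) {
  tibble(residual_sse = x$residual_sse, n_obs = x$n_obs,
         period_param = x$period_param, converged = x$converged,
         degenerate = x$degenerate)
}

#' @rdname fit_cosinor
#' @param newdata Optional data frame with a `minute_of_day` column.
#' @export
predict.chp_cosinor <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$minute_of_day else newdata$minute_of_day
  cosinor_predict(t, amplitude = object$amplitude,
                  acrophase_rad = object$acrophase_rad,
                  period_param = object$period_param)
}

#' Fit cosinor models per subject
#'
#' @param data Actigraphy data frame covering several subjects.
#' @param subject,time,met Columns identifying the subject and the
#'   (timestamp, MET) pairs.
#' @inheritParams fit_cosinor
#' @return Tibble with one row per subject: estimates, diagnostics, and the
#'   full fit object in a `fit` list-column.
#' @export
fit_cohort_cosinor <- function(data, subject = subject_id,
                               time = minute_of_day, met = met,
                               period_param = 1720) {
  data |>
    dplyr::group_by({{ subject }}) |>
    tidyr::nest() |>
    dplyr::ungroup() |>
    dplyr::mutate(
      fit = purrr::map(.data$data, fit_cosinor, time = {{ time }},
                       met = {{ met }}, period_param = period_param),
      amplitude = purrr::map_dbl(.data$fit, "amplitude"),
      acrophase_rad = purrr::map_dbl(.data$fit, "acrophase_rad"),
      residual_sse = purrr::map_dbl(.data$fit, "residual_sse"),
      converged = purrr::map_lgl(.data$fit, "converged")
    ) |>
    dplyr::select(-"data")
}

#' Re-reference scan times to individual circadian time
#'
#' Shifts clock timestamps by the time equivalent of the difference between
#' a subject's fitted acrophase and a reference acrophase (by convention the
#' cohort mean): \eqn{\Delta t = (\hat\phi - \phi_{ref}) f / \pi}, wrapped to
#' `[0, 1440)`. Two subjects whose acrophases differ by \eqn{\Delta\phi} map
#' the same clock time \eqn{\Delta\phi f/\pi} minutes apart.
#'
#' @param scan_times_min Clock times in minutes of day.
#' @param fit A converged `chp_cosinor` fit for the subject.
#' @param reference_acrophase_rad Reference acrophase in radians.
#' @return Adjusted times in minutes, wrapped to `[0, 1440)`.
#' @export
circadian_correct <- function(scan_times_min, fit, reference_acrophase_rad) {
  stopifnot(inherits(fit, "chp_cosinor"))
  if (!isTRUE(fit$converged)) {
    abort("Refusing circadian correction from an unconverged cosinor fit.",
          class = "chpwater_correction_refused")
  }
  check_number(scan_times_min, "scan_times_min", allow_vector = TRUE)
  check_number(reference_acrophase_rad, "reference_acrophase_rad")
  delta <- (fit$acrophase_rad - reference_acrophase_rad) *
    fit$period_param / pi
  (scan_times_min + delta) %% 1440
}

#' @rdname circadian_correct
#' @param adjusted_times_min Times previously produced by
#'   [circadian_correct()].
#' @export
circadian_uncorrect <- function(adjusted_times_min, fit,
                                reference_acrophase_rad) {
  stopifnot(inherits(fit, "chp_cosinor"))
  if (!isTRUE(fit$converged)) {
    abort("Refusing circadian correction from an unconverged cosinor fit.",
          class = "chpwater_correction_refused")
  }
  delta <- (fit$acrophase_rad - reference_acrophase_rad) *
    fit$period_param / pi
  (adjusted_times_min - delta) %% 1440
}
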