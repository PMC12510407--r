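test_that("cosinor evaluation matches the symbolic model", {
  expect_equal(cosinor_predict(0, amplitude = 1, acrophase_rad = 0), 2)
  expect_equal(cosinor_predict(0:1439, amplitude = 0, acrophase_rad = 1),
               rep(0, 1440))
  set.seed(31)
  for (i in 1:20) {
    a <- runif(1, 0, 3); phi <- runif(1, 0, pi); f <- runif(1, 700, 2000)
    t <- runif(5, 0, 1440)
    expect_equal(cosinor_predict(t, a, phi, f),
                 a * (1 + cos(pi * t / f + phi)), tolerance = 1e-12)
  }
  # output bounded by [0, 2a]
  e <- cosinor_predict(0:1439, 1.3, 2.2)
  expect_true(all(e >= 0 & e <= 2.6))
})

test_that("noiseless fits recover the generating parameters exactly", {
  for (phi in c(0.3, 1.6, 2.9)) {
    tr <- make_actigraphy(actigraphy_spec(amplitude = 1.1,
                                          acrophase_rad = phi,
                                          noise_sd = 0), seed = 1)
    fit <- fit_cosinor(tr)
    expect_true(fit$converged)
    expect_equal(fit$amplitude, 1.1, tolerance = 1e-6)
    expect_equal(fit$acrophase_rad, phi, tolerance = 1e-6)
  }
})

test_that("noisy fits recover acrophase within 0.1 rad and are optimal", {
  spec <- actigraphy_spec(amplitude = 1, acrophase_rad = 2.4, noise_sd = 0.3,
                          n_days = 5)
  tr <- make_actigraphy(spec, seed = 12)
  fit <- fit_cosinor(tr)
  expect_lt(abs(fit$acrophase_rad - 2.4), 0.1)
  # fitted SSE cannot exceed the SSE of the generating parameters
  sse_true <- sum((tr$met - cosinor_predict(tr$minute_of_day, 1, 2.4))^2)
  expect_lte(fit$residual_sse, sse_true)
  # each multi-start run improved (or matched) its own starting objective
  alpha0 <- diff(range(tr$met)) / 2
  sse_at <- function(a, phi) {
    sum((tr$met - cosinor_predict(tr$minute_of_day, a, phi))^2)
  }
  start_sse <- mapply(sse_at, fit$starts$alpha_start, fit$starts$phi_start)
  expect_true(all(fit$starts$sse <= start_sse + 1e-9))
})

test_that("fit depends on (time, MET) pairs, not row order", {
  tr <- make_actigraphy(actigraphy_spec(noise_sd = 0.2), seed = 3)
  fit1 <- fit_cosinor(tr)
  set.seed(1)
  fit2 <- fit_cosinor(tr[sample(nrow(tr)), ])
  expect_equal(fit1$amplitude, fit2$amplitude, tolerance = 1e-10)
  expect_equal(fit1$acrophase_rad, fit2$acrophase_rad, tolerance = 1e-10)
})

test_that("constant traces yield a flagged degenerate fit", {
  tr <- tibble::tibble(minute_of_day = rep(0:1439, 2), met = 1.5)
  fit <- fit_cosinor(tr)
  expect_true(fit$degenerate)
  expect_false(fit$converged)
  expect_equal(fit$amplitude, 0)
  expect_true(is.na(fit$acrophase_rad))
})

test_that("parameter recovery holds across simulated subjects", {
  set.seed(91)
  res <- lapply(1:12, function(i) {
    a <- runif(1, 0.7, 1.3); phi <- runif(1, 0.3, 2.9)
    tr <- make_actigraphy(actigraphy_spec(amplitude = a, acrophase_rad = phi,
                                          noise_sd = 0.3 * a), seed = 100 + i)
    fit <- fit_cosinor(tr)
    c(abs(fit$amplitude / a - 1), abs(fit$acrophase_rad - phi))
  })
  res <- do.call(rbind, res)
  expect_lt(median(res[, 1]), 0.05)
  expect_lt(median(res[, 2]), 0.1)
})

test_that("circadian correction shifts, wraps, and inverts consistently", {
  tr <- make_actigraphy(actigraphy_spec(acrophase_rad = 2.8, noise_sd = 0.2),
                        seed = 4)
  fit <- fit_cosinor(tr)
  times <- c(464, 737, 963, 1171)
  # identity when the reference equals the subject acrophase
  expect_equal(circadian_correct(times, fit, fit$acrophase_rad), times)
  # linear phase-to-time map: a reference offset shifts all times equally
  dphi <- 0.4
  shifted <- circadian_correct(times, fit, fit$acrophase_rad - dphi)
  expect_equal((shifted - times) %% 1440,
               rep(dphi * fit$period_param / pi, 4) %% 1440,
               tolerance = 1e-9)
  # round trip restores the inputs
  adj <- circadian_correct(times, fit, 2.0)
  expect_equal(circadian_uncorrect(adj, fit, 2.0), times %% 1440)
  # unconverged fits are refused
  bad <- fit; bad$converged <- FALSE
  expect_error(circadian_correct(times, bad, 2.0),
               class = "chpwater_correction_refused")
})

test_that("tidy, glance and predict expose the fit", {
  tr <- make_actigraphy(actigraphy_spec(noise_sd = 0.1), seed = 5)
  fit <- fit_cosinor(tr)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate"))
  expect_equal(td$estimate[td$term == "amplitude"], fit$amplitude)
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$n_obs, nrow(tr))
  p <- predict(fit, tibble::tibble(minute_of_day = c(0, 720)))
  expect_equal(p, cosinor_predict(c(0, 720), fit$amplitude,
                                  fit$acrophase_rad, fit$period_param))
})
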