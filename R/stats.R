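#' Mixed-effects model of ChP water density against scan time
#'
#' Fits the repeated-measures inferential layer: a linear mixed model with
#' per-subject random intercepts, in two complementary views of time.
#' Epoch is treated as a categorical group (`density ~ epoch + (1 |
#' subject)`), with each adjacent pair of epochs contrasted by a t-test
#' (no multiplicity adjustment); clock time is treated as continuous
#' (`density ~ I(time/60) + (1 | subject)`, slope per hour) to test for a
#' monotone time-of-day drift.
#'
#' @param data Data frame with one row per scan (e.g. from
#'   [quantify_cohort()]); reproducibility scans (if a `scan_type` column is
#'   present) are excluded.
#' @param density,time,epoch,subject Columns holding the quantified density,
#'   clock time in minutes, epoch index, and subject id (tidy-eval).
#' @return Object of class `chp_density_model` with elements
#'   `epoch_model` and `time_model` (`lmerMod` fits, `NULL` when the
#'   response is constant), `contrasts` (adjacent-epoch t-tests),
#'   `time_effect` (slope, Wald CI, Satterthwaite p), `epoch_descriptives`,
#'   and `degenerate`. Supports [tidy()] and [glance()].
#' @examples
#' \donttest{
#' co <- make_cohort(n_subjects = 4, epochs = 2, n_repro_subjects = 0, seed = 1)
#' fit_density_time_model(quantify_cohort(co))
#' }
#' @export
fit_density_time_model <- function(data, density = rho_chp,
                                   time = timestamp_min, epoch = epoch,
                                   subject = subject_id) {
  df <- data
  if ("scan_type" %in% names(df)) {
    df <- dplyr::filter(df, .data$scan_type == "circadian")
  }
  df <- tibble(
    density = dplyr::pull(df, {{ density }}),
    time_min = dplyr::pull(df, {{ time }}),
    epoch = factor(dplyr::pull(df, {{ epoch }})),
    subject = factor(dplyr::pull(df, {{ subject }}))
  )
  if (nlevels(df$epoch) < 2) {
    abort("Need at least two epochs to model a time effect.",
          class = "chpwater_model_degeneracy")
  }
  if (nlevels(df$subject) < 2) {
    abort("Need at least two subjects for a random-intercept model.",
          class = "chpwater_model_degeneracy")
  }

  descr <- df |>
    dplyr::group_by(.data$epoch) |>
    dplyr::summarise(density_descriptives(.data$density), .groups = "drop")

  adj <- tibble(epoch_a = head(levels(df$epoch), -1),
                epoch_b = levels(df$epoch)[-1])

  if (sd(df$density) == 0) {
    # constant response: variance components are all zero and every
    # contrast is exactly null
    contrasts <- dplyr::mutate(adj, estimate = 0, se = NA_real_,
                               t_statistic = 0, df = NA_real_, p_value = 1)
    time_effect <- tibble(term = "time_hr", estimate = 0, se = NA_real_,
                          conf_low = 0, conf_high = 0, p_value = 1)
    return(structure(
      list(epoch_model = NULL, time_model = NULL, contrasts = contrasts,
           time_effect = time_effect, epoch_descriptives = descr,
           degenerate = TRUE),
      class = "chp_density_model"
    ))
  }

  epoch_model <- lmerTest::lmer(density ~ epoch + (1 | subject), data = df,
                                REML = TRUE)
  emm <- emmeans::emmeans(epoch_model, "epoch")
  prs <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "none"))
  want <- sprintf("epoch%s - epoch%s", adj$epoch_a, adj$epoch_b)
  got <- gsub(" ", "", prs$contrast)
  idx <- match(gsub(" ", "", want), got)
  contrasts <- tibble(epoch_a = adj$epoch_a, epoch_b = adj$epoch_b,
                      estimate = prs$estimate[idx], se = prs$SE[idx],
                      t_statistic = prs$t.ratio[idx], df = prs$df[idx],
                      p_value = prs$p.value[idx])

  df$time_hr <- df$time_min / 60
  time_model <- lmerTest::lmer(density ~ time_hr + (1 | subject), data = df,
                               REML = TRUE)
  sm <- summary(time_model)$coefficients
  ci <- confint(time_model, parm = "time_hr", method = "Wald")
  time_effect <- tibble(term = "time_hr", estimate = sm["time_hr", "Estimate"],
                        se = sm["time_hr", "Std. Error"],
                        conf_low = ci[1, 1], conf_high = ci[1, 2],
                        p_value = sm["time_hr", "Pr(>|t|)"])

  structure(
    list(epoch_model = epoch_model, time_model = time_model,
         contrasts = contrasts, time_effect = time_effect,
         epoch_descriptives = descr, degenerate = FALSE),
    class = "chp_density_model"
  )
}

#' @export
print.chp_density_model <- function(x, ...) {
  cat("Mixed-effects density vs time-of-day model",
      if (x$degenerate) "[degenerate: constant response]", "\n")
  cat(sprintf("  time slope: %.3g per hour (95%% CI %.3g to %.3g, p = %.3g)\n",
              x$time_effect$estimate, x$time_effect$conf_low,
              x$time_effect$conf_high, x$time_effect$p_value))
  cat("  adjacent-epoch contrasts:\n")
  print(as.data.frame(x$contrasts), row.names = FALSE)
  invisible(x)
}

#' @rdname fit_density_time_model
#' @param x A `chp_density_model`.
#' @param ... Unused.
#' @export
tidy.chp_density_model <- function(x, ...) {
  dplyr::bind_rows(
    x$time_effect,
    dplyr::transmute(x$contrasts,
                     term = paste0("epoch", .data$epoch_a, " - epoch",
                                   .data$epoch_b),
                     estimate = .data$estimate, se = .data$se,
                     conf_low = NA_real_, conf_high = NA_real_,
                     p_value = .data$p_value)
  )
}

#' @rdname fit_density_time_model
#' @export
glance.chp_density_model <- function(x, ...) {
  if (x$degenerate) {
    return(tibble(sigma_subject = 0, sigma_resid = 0, degenerate = TRUE))
  }
  vc <- as.data.frame(lme4::VarCorr(x$epoch_model))
  tibble(sigma_subject = vc$sdcor[vc$grp == "subject"],
         sigma_resid = vc$sdcor[vc$grp == "Residual"],
         degenerate = FALSE)
}

#' Rank correlations between scan time and density
#'
#' Spearman's rank and Kendall's tau correlations with two-sided p-values
#' (average-rank tie handling, asymptotic p when ties are present), the
#' study's primary test for a time-of-day relationship.
#'
#' @param data Data frame of per-scan records.
#' @param time,density Columns with the time variable (clock or
#'   circadian-corrected minutes) and the quantified density.
#' @return Tibble with one row per method: `method`, `estimate`, `p_value`,
#'   `n`. Constant input yields `NA` estimates with a warning.
#' @examples
#' d <- data.frame(t = 1:10, rho = 0.9 + 0.001 * (1:10))
#' rank_correlations(d, t, rho)
#' @export
rank_correlations <- function(data, time = timestamp_min, density = rho_chp) {
  x <- dplyr::pull(data, {{ time }})
  y <- dplyr::pull(data, {{ density }})
  if (length(x) != length(y) || length(x) < 3) {
    abort("Need at least 3 paired observations.",
          class = "chpwater_invalid_parameter")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    warn("Constant input: rank correlations are undefined.",
         class = "chpwater_undefined_correlation")
    return(tibble(method = c("spearman", "kendall"),
                  estimate = NA_real_, p_value = NA_real_, n = length(x)))
  }
  sp <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  kd <- suppressWarnings(cor.test(x, y, method = "kendall", exact = FALSE))
  tibble(method = c("spearman", "kendall"),
         estimate = c(unname(sp$estimate), unname(kd$estimate)),
         p_value = c(sp$p.value, kd$p.value),
         n = length(x))
}
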