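#' Neuronal relative value from a chosen value cell, Task 1
#'
#' Bilinear OLS of the post-offer trial-type means:
#' r = theta0 + thetaA*qA*delta_choice_A + thetaB*qB*delta_choice_B.
#' If the cell encodes the chosen value, thetaA and thetaB are proportional
#' to the unit values of the two juices, so rho_neuronal = thetaA/thetaB.
#'
#' @param session a `choice_session` with spikes.
#' @param cell_id a chosen value cell.
#' @param config an [sc_config()].
#' @param window Task-1 window to use (default "post_offer").
#' @return list: `theta` (coefficients), `p` (theta p-values),
#'   `rho_neuronal`, `valid` (thetaA and thetaB both significant).
#' @export
fit_chosen_value_task1 <- function(session, cell_id, config = sc_config(),
                                   window = "post_offer") {
  resp <- compute_response(session, cell_id, "task1", window, config)
  ty <- resp$types
  d <- data.frame(
    r = ty$mean_rate,
    xA = ty$qA * (ty$choice == "A"),
    xB = ty$qB * (ty$choice == "B")
  )
  fit_theta_pair(d, config, label = paste("task1", cell_id))
}

#' Neuronal relative values from a chosen value cell, Task 2
#'
#' In the post-offer1 and post-offer2 windows, chosen value cells encode
#' the value currently on display independent of the juice type. Two
#' bilinear fits,
#' r1 = theta10 + theta1A*qA*delta_AB + theta1B*qB*delta_BA and
#' r2 = theta20 + theta2A*qA*delta_BA + theta2B*qB*delta_AB,
#' provide four neuronal measures of relative value:
#' rho_offer1 = theta1A/theta1B, rho_offer2 = theta2A/theta2B,
#' rho_AB = theta1A/theta2B, rho_BA = theta2A/theta1B, all conditioned on
#' the four slope coefficients differing significantly from zero. By
#' construction rho_AB*rho_BA = rho_offer1*rho_offer2 exactly.
#'
#' @inheritParams fit_chosen_value_task1
#' @return list: per-window fits, the four rho measures, `d_rho_neuronal`
#'   (rho_BA - rho_AB), `valid`.
#' @export
fit_chosen_value_task2 <- function(session, cell_id, config = sc_config()) {
  r1 <- compute_response(session, cell_id, "task2", "post_offer1", config)
  r2 <- compute_response(session, cell_id, "task2", "post_offer2", config)
  t1 <- r1$types
  d1 <- data.frame(
    r = t1$mean_rate,
    xA = t1$qA * (t1$order == "AB"),   # offer1 is A in AB trials
    xB = t1$qB * (t1$order == "BA")
  )
  t2 <- r2$types
  d2 <- data.frame(
    r = t2$mean_rate,
    xA = t2$qA * (t2$order == "BA"),   # offer2 is A in BA trials
    xB = t2$qB * (t2$order == "AB")
  )
  f1 <- fit_theta_pair(d1, config, label = paste("offer1", cell_id))
  f2 <- fit_theta_pair(d2, config, label = paste("offer2", cell_id))
  valid <- f1$valid && f2$valid
  out <- list(offer1 = f1, offer2 = f2, valid = valid,
              rho_offer1 = NA_real_, rho_offer2 = NA_real_,
              rho_AB = NA_real_, rho_BA = NA_real_,
              d_rho_neuronal = NA_real_)
  if (valid) {
    th1 <- f1$theta; th2 <- f2$theta
    out$rho_offer1 <- th1[["xA"]] / th1[["xB"]]
    out$rho_offer2 <- th2[["xA"]] / th2[["xB"]]
    out$rho_AB <- th1[["xA"]] / th2[["xB"]]
    out$rho_BA <- th2[["xA"]] / th1[["xB"]]
    out$d_rho_neuronal <- out$rho_BA - out$rho_AB
  }
  out
}

# Shared bilinear fit: r ~ xA + xB with validity = both slopes significant
# (p < tuning_alpha) and |t| above the configurable minimum.
fit_theta_pair <- function(d, config, label = "") {
  d <- d[!is.na(d$r), , drop = FALSE]
  if (nrow(d) < 4 || stats::sd(d$xA) == 0 || stats::sd(d$xB) == 0) {
    sc_log("chosen-value fit ", label, ": degenerate design", level = "WARN")
    return(list(theta = c(`(Intercept)` = NA_real_, xA = NA_real_,
                          xB = NA_real_),
                p = c(xA = NA_real_, xB = NA_real_),
                rho_neuronal = NA_real_, valid = FALSE))
  }
  fit <- stats::lm(r ~ xA + xB, data = d)
  sm <- summary(fit)$coefficients
  theta <- stats::coef(fit)
  p <- c(xA = sm["xA", "Pr(>|t|)"], xB = sm["xB", "Pr(>|t|)"])
  tv <- c(xA = sm["xA", "t value"], xB = sm["xB", "t value"])
  valid <- all(p < config$tuning_alpha) &&
    all(abs(tv) > config$min_theta_t) && theta[["xB"]] != 0
  list(theta = theta, p = p,
       rho_neuronal = if (valid) theta[["xA"]] / theta[["xB"]] else NA_real_,
       valid = valid)
}

#' Correlate neuronal order-bias fluctuations with the behavioral order bias
#'
#' Across chosen value cells with valid Task-2 fits, correlates
#' Delta-rho_neuronal = rho_BA - rho_AB with the session order bias
#' epsilon, and Deming-regresses rho_BA on rho_AB. The interquartile
#' outlier rule is applied to both variables before the population
#' statistics.
#'
#' @param fits data.frame with per-cell `rho_AB`, `rho_BA`,
#'   `d_rho_neuronal`, `epsilon`.
#' @param config an [sc_config()].
#' @return list: `cor` (correlations of Delta-rho with epsilon), `deming`
#'   (slope/intercept of rho_BA on rho_AB), `n_used`, `n_excluded`.
#' @export
order_bias_neuronal_correlation <- function(fits, config = sc_config()) {
  fits <- fits[is.finite(fits$d_rho_neuronal) & is.finite(fits$epsilon), ,
               drop = FALSE]
  if (nrow(fits) < 10) stop("needs >= 10 valid cells")
  keep <- iqr_filter(fits$d_rho_neuronal, config$iqr_multiplier,
                     config$quantile_type) &
    iqr_filter(fits$epsilon, config$iqr_multiplier, config$quantile_type)
  n_excl <- sum(!keep)
  if (n_excl > 0) {
    sc_log(n_excl, " cells excluded by the interquartile criterion")
  }
  f <- fits[keep, , drop = FALSE]
  list(
    cor = cor_both(f$epsilon, f$d_rho_neuronal),
    slope = stats::coef(stats::lm(d_rho_neuronal ~ epsilon, data = f))[[2]],
    deming = deming_regression(f$rho_AB, f$rho_BA),
    n_used = nrow(f), n_excluded = n_excl
  )
}

#' Scenario analysis: neuronal vs behavioral relative value
#'
#' Tests where the preference bias originates. Regresses the Task-2
#' neuronal relative value (rho_offer2 by default) on the behavioral
#' relative values of both tasks and tests each slope against 1; also
#' pairs rho_neuronal_Task1 with rho_neuronal_Task2 per cell. If Task-2
#' values are unchanged from Task 1 and the bias arises downstream of
#' value comparison (scenario 2), the regression on rho_Task1 is
#' indistinguishable from identity while the slope on rho_Task2 is below
#' 1; if values themselves shift in Task 2 (scenario 1), the pattern is
#' reversed.
#'
#' @param fits data.frame with per-cell `rho_neuronal_task1`,
#'   `rho_neuronal_task2`, `rho_behav_task1`, `rho_behav_task2` (invalid
#'   cells already removed).
#' @return list: per-reference regression (slope, se, p vs 1), paired
#'   t-test of the two neuronal measures, and the inferred `scenario`
#'   (1, 2 or NA at alpha = 0.05).
#' @export
scenario_regressions <- function(fits) {
  if (is.null(fits$rho_neuronal_task2) && !is.null(fits$rho_offer2)) {
    fits$rho_neuronal_task2 <- fits$rho_offer2   # pipeline table naming
  }
  fits <- fits[is.finite(fits$rho_neuronal_task2) &
                 is.finite(fits$rho_behav_task1) &
                 is.finite(fits$rho_behav_task2), , drop = FALSE]
  if (nrow(fits) < 5) stop("needs >= 5 valid cells")
  slope_test <- function(x, y) {
    fit <- stats::lm(y ~ x)
    sm <- summary(fit)$coefficients
    b <- sm["x", "Estimate"]; se <- sm["x", "Std. Error"]
    df <- fit$df.residual
    tstat <- (b - 1) / se
    list(slope = b, se = se,
         p_vs_1 = 2 * stats::pt(-abs(tstat), df),
         p_lt_1 = stats::pt(tstat, df),
         intercept = sm["(Intercept)", "Estimate"])
  }
  on_t1 <- slope_test(fits$rho_behav_task1, fits$rho_neuronal_task2)
  on_t2 <- slope_test(fits$rho_behav_task2, fits$rho_neuronal_task2)
  paired <- if (all(is.finite(fits$rho_neuronal_task1))) {
    stats::t.test(fits$rho_neuronal_task1, fits$rho_neuronal_task2,
                  paired = TRUE)
  } else NULL
  # paired comparisons of the Task-2 neuronal measure with each behavioral
  # measure: the reference the neuronal values align with wins
  p_vs_b1 <- stats::t.test(fits$rho_neuronal_task2, fits$rho_behav_task1,
                           paired = TRUE)
  p_vs_b2 <- stats::t.test(fits$rho_neuronal_task2, fits$rho_behav_task2,
                           paired = TRUE)
  d1 <- mean(fits$rho_neuronal_task2 - fits$rho_behav_task1)
  d2 <- mean(fits$rho_neuronal_task2 - fits$rho_behav_task2)
  # the neuronal measure must differ systematically from one behavioral
  # measure and align with the other; if both paired tests reach
  # significance, alignment goes to the measure with much the smaller gap
  scenario <- if (p_vs_b2$p.value < 0.05 && d2 < 0 &&
                  (p_vs_b1$p.value >= 0.05 || abs(d1) < abs(d2) / 2)) {
    2L
  } else if (p_vs_b1$p.value < 0.05 && d1 > 0 &&
             (p_vs_b2$p.value >= 0.05 || abs(d2) < abs(d1) / 2)) {
    1L
  } else {
    NA_integer_
  }
  list(on_task1 = on_t1, on_task2 = on_t2,
       paired_neuronal = paired,
       vs_behav_task1 = list(p = p_vs_b1$p.value, mean_diff = d1),
       vs_behav_task2 = list(p = p_vs_b2$p.value, mean_diff = d2),
       n = nrow(fits), scenario = scenario)
}
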