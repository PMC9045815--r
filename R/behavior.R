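#' Fit a choice model to one task's trials
#'
#' Fits a binary-response GLM of choice on the offers. Under the default
#' log-quantity-ratio probit, Task 1 uses
#' X = a0 + a1*log(qB/qA) and Task 2 adds an order term
#' X = a2 + a3*log(qB/qA) + a4*(delta_AB - delta_BA), i.e. two parallel
#' sigmoids for the two presentation orders. Derived measures:
#' rho = exp(-a0/a1) (relative value at indifference), eta = a1 (sigmoid
#' steepness), and for Task 2 the order bias epsilon = 2*rho*a4/a3 plus
#' order-specific relative values rho_AB = exp(-(a2+a4)/a3),
#' rho_BA = exp(-(a2-a4)/a3). The alternative "value_difference" regressor
#' uses X = a0*qA + a1*qB (no intercept).
#'
#' Forced-choice trials (one offer null) are excluded from log-ratio fits
#' (the log is undefined at 0) and retained in value-difference fits.
#' Complete or quasi-complete separation — choices perfectly ordered by the
#' regressor, the MLE diverging — is flagged; flagged fits carry no derived
#' relative value.
#'
#' @param trials trial data.frame (or a `choice_session`).
#' @param task "task1" or "task2".
#' @param link "probit" or "logit".
#' @param model "log_ratio" or "value_difference".
#' @return a `behavioral_fit`: coefficients, vcov, derived measures with
#'   delta-method standard errors, log-likelihood, McFadden pseudo-R2, BIC,
#'   convergence and separation flags.
#' @export
fit_choice_model <- function(trials, task = c("task1", "task2"),
                             link = c("probit", "logit"),
                             model = c("log_ratio", "value_difference")) {
  if (inherits(trials, "choice_session")) trials <- trials$trials
  task <- match.arg(task)
  link <- match.arg(link)
  model <- match.arg(model)
  tr <- trials[trials$task == task, , drop = FALSE]
  if (model == "log_ratio") {
    tr <- tr[tr$qA > 0 & tr$qB > 0, , drop = FALSE]
  }
  if (length(unique(paste(tr$qA, tr$qB))) < 2) {
    stop("insufficient data: < 2 offer types with usable trials")
  }
  y <- as.numeric(tr$choice == "B")
  if (model == "log_ratio") {
    dat <- data.frame(y = y, lr = log(tr$qB / tr$qA))
    form <- y ~ lr
  } else {
    dat <- data.frame(y = y, qA = tr$qA, qB = tr$qB)
    form <- y ~ 0 + qA + qB
  }
  if (task == "task2") {
    dat$od <- ifelse(tr$order == "AB", 1, -1)
    form <- stats::update(form, . ~ . + od)
  }
  fit <- suppressWarnings(
    stats::glm(form, family = stats::binomial(link = link), data = dat,
               control = list(maxit = 100, epsilon = 1e-8))
  )
  cf <- stats::coef(fit)
  vc <- stats::vcov(fit)
  separated <- !fit$converged || any(abs(cf) > 50) ||
    any(!is.finite(diag(vc))) || all(y == y[1])
  ll <- as.numeric(stats::logLik(fit))
  null_fit <- suppressWarnings(
    stats::glm(y ~ 1, family = stats::binomial(link = link), data = dat))
  r2_mcfadden <- 1 - ll / as.numeric(stats::logLik(null_fit))

  out <- list(task = task, link = link, model = model,
              coefficients = cf, se = sqrt(diag(vc)), vcov = vc,
              n_trials = nrow(tr), log_lik = ll, r2 = r2_mcfadden,
              bic = stats::BIC(fit), converged = fit$converged,
              separated = separated, glm = fit)
  if (!separated) {
    out <- c(out, derive_measures(cf, vc, task, model))
  }
  structure(out, class = "behavioral_fit")
}

# Derived behavioral measures with delta-method SEs.
derive_measures <- function(cf, vc, task, model) {
  if (model == "log_ratio") {
    a0 <- cf[["(Intercept)"]]; a1 <- cf[["lr"]]
    if (a1 <= 0) return(list(rho = NA_real_, eta = a1))
    nm <- names(cf)
    g_rho <- function(b) exp(-b[[1]] / b[[which(nm == "lr")]])
    m <- list(
      rho = exp(-a0 / a1), eta = a1,
      rho_se = delta_method_se(g_rho, cf, vc),
      eta_se = sqrt(vc["lr", "lr"])
    )
    if (task == "task2") {
      a4 <- cf[["od"]]
      i_lr <- which(nm == "lr"); i_od <- which(nm == "od")
      g_eps <- function(b) 2 * exp(-b[[1]] / b[[i_lr]]) * b[[i_od]] / b[[i_lr]]
      g_ab <- function(b) exp(-(b[[1]] + b[[i_od]]) / b[[i_lr]])
      g_ba <- function(b) exp(-(b[[1]] - b[[i_od]]) / b[[i_lr]])
      m$epsilon <- 2 * m$rho * a4 / a1
      m$epsilon_se <- delta_method_se(g_eps, cf, vc)
      m$rho_AB <- exp(-(a0 + a4) / a1)
      m$rho_BA <- exp(-(a0 - a4) / a1)
      m$rho_AB_se <- delta_method_se(g_ab, cf, vc)
      m$rho_BA_se <- delta_method_se(g_ba, cf, vc)
    }
    m
  } else {
    aA <- cf[["qA"]]; aB <- cf[["qB"]]
    if (aB <= 0) return(list(rho = NA_real_, eta = NA_real_))
    m <- list(rho = -aA / aB, eta = NA_real_)
    if (task == "task2") {
      a4 <- cf[["od"]]
      m$epsilon <- 2 * a4 / aB   # in units of juice B quanta
    }
    m
  }
}

#' @export
print.behavioral_fit <- function(x, ...) {
  cat("behavioral_fit:", x$link, x$model, "for", x$task,
      "(", x$n_trials, "trials )\n")
  if (x$separated) {
    cat("  SEPARATION flagged; derived measures unavailable\n")
  } else {
    cat(sprintf("  rho = %.3f, eta = %.3f", x$rho, x$eta))
    if (!is.null(x$epsilon)) cat(sprintf(", epsilon = %.3f", x$epsilon))
    cat("\n")
  }
  cat(sprintf("  logLik = %.2f, McFadden R2 = %.3f, BIC = %.2f\n",
              x$log_lik, x$r2, x$bic))
  invisible(x)
}

#' Order-bias measures from a Task-2 fit
#'
#' Returns epsilon = 2*rho_Task2*a4/a3 together with the order-specific
#' relative values and their difference rho_BA - rho_AB, which epsilon
#' approximates to first order in a4/a3.
#'
#' @param fit converged `behavioral_fit` for task2 (log-ratio model).
#' @return list `epsilon`, `rho_AB`, `rho_BA`, `rho_diff`.
#' @export
derive_order_bias <- function(fit) {
  stopifnot(inherits(fit, "behavioral_fit"))
  if (fit$task != "task2" || fit$model != "log_ratio") {
    stop("derive_order_bias needs a task2 log-ratio fit")
  }
  if (fit$separated) stop("fit is flagged for separation")
  a3 <- fit$coefficients[["lr"]]
  if (a3 <= 0) stop("invalid steepness: a3 <= 0")
  list(epsilon = fit$epsilon, rho_AB = fit$rho_AB, rho_BA = fit$rho_BA,
       rho_diff = fit$rho_BA - fit$rho_AB)
}

#' Independent sigmoids for the two presentation orders
#'
#' Relaxes the parallel-sigmoid assumption of the Task-2 model by fitting
#' AB and BA trials separately, and compares the 4-parameter independent
#' model to the 3-parameter parallel model by likelihood ratio.
#'
#' @param trials trial data.frame or `choice_session`.
#' @param link,model as in [fit_choice_model()].
#' @return list with `fit_AB`, `fit_BA` (each a Task-1-style fit on one
#'   order's trials), the parallel `fit_parallel`, and `lr_test`
#'   (statistic, df, p) for parallel vs independent.
#' @export
fit_independent_sigmoids <- function(trials, link = "probit",
                                     model = "log_ratio") {
  if (inherits(trials, "choice_session")) trials <- trials$trials
  t2 <- trials[trials$task == "task2", , drop = FALSE]
  if (!all(c("AB", "BA") %in% t2$order)) {
    stop("both presentation orders must be present")
  }
  one_order <- function(ord) {
    sub <- t2[t2$order == ord, , drop = FALSE]
    sub$task <- "task1"   # plain 2-parameter sigmoid on this order's trials
    sub$order <- "none"
    fit_choice_model(sub, "task1", link, model)
  }
  fit_ab <- one_order("AB")
  fit_ba <- one_order("BA")
  fit_par <- fit_choice_model(trials, "task2", link, model)
  stat <- 2 * ((fit_ab$log_lik + fit_ba$log_lik) - fit_par$log_lik)
  df <- (length(fit_ab$coefficients) + length(fit_ba$coefficients)) -
    length(fit_par$coefficients)
  list(fit_AB = fit_ab, fit_BA = fit_ba, fit_parallel = fit_par,
       lr_test = list(statistic = stat, df = df,
                      p = stats::pchisq(stat, df, lower.tail = FALSE)))
}

#' Compare the four choice-model variants
#'
#' Fits probit/logit crossed with log-ratio/value-difference regressors and
#' tabulates McFadden R2 and BIC per variant.
#'
#' @param trials trial data.frame or `choice_session`.
#' @param task "task1" or "task2".
#' @return data.frame with one row per variant.
#' @export
compare_models <- function(trials, task = "task1") {
  grid <- expand.grid(link = c("probit", "logit"),
                      model = c("log_ratio", "value_difference"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    f <- fit_choice_model(trials, task, grid$link[i], grid$model[i])
    data.frame(link = grid$link[i], model = grid$model[i], task = task,
               r2 = f$r2, bic = f$bic, log_lik = f$log_lik,
               rho = if (is.null(f$rho)) NA_real_ else f$rho,
               separated = f$separated)
  })
  do.call(rbind, rows)
}

#' Session bias summary
#'
#' Collects the behavioral measures of one session into a flat row:
#' rho and eta per task, order-specific relative values, order bias,
#' preference bias index PBI = 2*(rho_Task2 - rho_Task1)/(rho_Task2 +
#' rho_Task1) and the steepness difference Delta-eta.
#'
#' @param fit1,fit2 converged `behavioral_fit`s for task1 and task2.
#' @param session_id optional label.
#' @return one-row data.frame.
#' @export
session_bias_summary <- function(fit1, fit2, session_id = NA_character_) {
  if (fit1$separated || fit2$separated) stop("separated fit in summary")
  data.frame(
    session_id = session_id,
    rho_task1 = fit1$rho, rho_task2 = fit2$rho,
    rho_AB = fit2$rho_AB, rho_BA = fit2$rho_BA,
    eta_task1 = fit1$eta, eta_task2 = fit2$eta,
    epsilon = fit2$epsilon,
    pbi = 2 * (fit2$rho - fit1$rho) / (fit2$rho + fit1$rho),
    d_eta = fit2$eta - fit1$eta,
    stringsAsFactors = FALSE
  )
}

#' ANCOVA for order and preference biases across sessions
#'
#' Regresses the order-specific Task-2 relative values (rho_AB, rho_BA) on
#' the Task-1 relative value with the presentation order as covariate,
#' imposing parallel lines. A common slope significantly above 1 indicates
#' the preference bias (the task-2 inflation of rho grows with rho); a
#' nonzero intercept difference (BA above AB) indicates the order bias.
#'
#' @param summaries data.frame from [session_bias_summary()] rows (needs
#'   `rho_task1`, `rho_AB`, `rho_BA`).
#' @return list: `slope`, `intercept_AB`, `intercept_BA`,
#'   `intercept_diff`, `p_slope_gt1` (one-sided), `p_intercept_diff`
#'   (two-sided), and the underlying `lm` fit.
#' @export
ancova_preference_bias <- function(summaries) {
  if (nrow(summaries) < 3) stop("ancova needs >= 3 sessions")
  if (stats::sd(summaries$rho_task1) == 0) {
    stop("rank deficiency: constant rho_task1")
  }
  d <- data.frame(
    y = c(summaries$rho_AB, summaries$rho_BA),
    x = rep(summaries$rho_task1, 2),
    order = rep(c("AB", "BA"), each = nrow(summaries))
  )
  fit <- stats::lm(y ~ x + order, data = d)
  cf <- stats::coef(fit)
  sm <- summary(fit)$coefficients
  slope <- cf[["x"]]
  se_slope <- sm["x", "Std. Error"]
  df <- fit$df.residual
  list(
    slope = slope,
    intercept_AB = cf[["(Intercept)"]],
    intercept_BA = cf[["(Intercept)"]] + cf[["orderBA"]],
    intercept_diff = cf[["orderBA"]],
    p_slope_gt1 = stats::pt((slope - 1) / se_slope, df, lower.tail = FALSE),
    p_intercept_diff = sm["orderBA", "Pr(>|t|)"],
    fit = fit
  )
}
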