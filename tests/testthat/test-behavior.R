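test_that("derived measures follow the closed forms", {
  # rho = exp(-a0/a1): a0 = -3, a1 = 3 -> rho = e
  cf <- c("(Intercept)" = -3, lr = 3)
  vc <- diag(1e-6, 2); dimnames(vc) <- list(names(cf), names(cf))
  m <- seqchoice:::derive_measures(cf, vc, "task1", "log_ratio")
  expect_equal(m$rho, exp(1), tolerance = 1e-10)
  expect_equal(m$eta, 3)

  # order bias: a2 = -3, a3 = 3, a4 = 0.3
  cf2 <- c("(Intercept)" = -3, lr = 3, od = 0.3)
  vc2 <- diag(1e-6, 3); dimnames(vc2) <- list(names(cf2), names(cf2))
  m2 <- seqchoice:::derive_measures(cf2, vc2, "task2", "log_ratio")
  expect_equal(m2$epsilon, 2 * exp(1) * 0.1, tolerance = 1e-10)
  expect_equal(m2$rho_BA - m2$rho_AB, exp(1.1) - exp(0.9),
               tolerance = 1e-10)
  # epsilon approximates rho_BA - rho_AB to ~0.2% here
  expect_lt(abs(m2$epsilon - (m2$rho_BA - m2$rho_AB)) / m2$epsilon, 0.005)
})

test_that("epsilon approximation to rho_BA - rho_AB is first-order exact", {
  set.seed(42)
  for (i in 1:50) {
    a3 <- runif(1, 1, 6)
    a2 <- -a3 * log(runif(1, 1, 4))
    a4 <- runif(1, -0.1, 0.1) * a3   # |a4/a3| < 0.1
    cf <- c("(Intercept)" = a2, lr = a3, od = a4)
    vc <- diag(1e-8, 3); dimnames(vc) <- list(names(cf), names(cf))
    m <- seqchoice:::derive_measures(cf, vc, "task2", "log_ratio")
    diff <- m$rho_BA - m$rho_AB
    expect_lt(abs(m$epsilon - diff) / max(abs(m$epsilon), 0.05), 0.05)
    expect_equal(sign(m$epsilon), sign(a4))   # monotone transform
  }
})

test_that("probit recovers generating parameters within Wald intervals", {
  n_rep <- 30
  hit <- matrix(FALSE, n_rep, 3)
  for (i in seq_len(n_rep)) {
    rho <- runif(1, 1.5, 3.5); eta2 <- runif(1, 2, 4)
    eps <- runif(1, -0.4, 0.4)
    bp <- behavior_params(rho_task1 = rho, eta_task2 = eta2, epsilon = eps,
                          pref_shift = 1)
    s <- generate_choices(bp, seed = 700 + i)
    f1 <- fit_choice_model(s, "task1")
    f2 <- fit_choice_model(s, "task2")
    hit[i, ] <- c(abs(f1$rho - rho) < 1.96 * f1$rho_se,
                  abs(f2$eta - eta2) < 1.96 * f2$eta_se,
                  abs(f2$epsilon - eps) < 1.96 * f2$epsilon_se)
  }
  expect_gte(mean(hit[, 1]), 0.8)
  expect_gte(mean(hit[, 2]), 0.8)
  expect_gte(mean(hit[, 3]), 0.8)
})

test_that("derived measures are invariant to trial order", {
  bp <- behavior_params()
  s <- generate_choices(bp, seed = 77)
  f <- fit_choice_model(s, "task2")
  s2 <- s
  perm <- sample(nrow(s2$trials))
  s2$trials <- s2$trials[perm, ]
  f2 <- fit_choice_model(s2, "task2")
  expect_equal(f2$rho, f$rho, tolerance = 1e-8)
  expect_equal(f2$epsilon, f$epsilon, tolerance = 1e-8)
})

test_that("separation is flagged, not fatal", {
  ot <- data.frame(qA = c(0L, 1L, 1L, 1L), qB = c(1L, 0L, 4L, 6L))
  bp <- behavior_params(rho_task1 = 1.2, eta_task1 = 50, eta_task2 = 50,
                        epsilon = 0, pref_shift = 1, offer_types = ot,
                        n_trials_task1 = 60)
  s <- generate_choices(bp, seed = 13)   # all split types far above rho
  f <- fit_choice_model(s, "task1")
  expect_true(f$separated)
  expect_null(f$rho)
  expect_error(derive_order_bias(fit_choice_model(s, "task2")), "separation")
})

test_that("independent sigmoids agree with the parallel model on parallel truth", {
  bp <- behavior_params(epsilon = 0.3, pref_shift = 1,
                        n_trials_task1 = 400)
  s <- generate_choices(bp, seed = 19)
  res <- fit_independent_sigmoids(s)
  f2 <- res$fit_parallel
  se_ab <- sqrt(res$fit_AB$rho_se^2 + f2$rho_AB_se^2)
  se_ba <- sqrt(res$fit_BA$rho_se^2 + f2$rho_BA_se^2)
  expect_lt(abs(res$fit_AB$rho - f2$rho_AB), 3 * se_ab)
  expect_lt(abs(res$fit_BA$rho - f2$rho_BA), 3 * se_ba)
  expect_gt(res$lr_test$p, 0.001)   # parallel truth: no strong rejection
  # single-order input errors
  s_ab <- s
  s_ab$trials <- s_ab$trials[s_ab$trials$order != "BA", ]
  expect_error(fit_independent_sigmoids(s_ab), "both")
})

test_that("model comparison favors the generating model and ranks agree", {
  bics <- matrix(NA_real_, 20, 4)
  rho_probit <- rho_logit <- numeric(20)
  for (i in 1:20) {
    bp <- behavior_params(rho_task1 = runif(1, 1.5, 3.5))
    s <- generate_choices(bp, seed = 900 + i)
    tab <- compare_models(s, "task1")
    bics[i, ] <- tab$bic
    key <- paste(tab$link, tab$model)
    rho_probit[i] <- tab$rho[key == "probit log_ratio"]
    rho_logit[i] <- tab$rho[key == "logit log_ratio"]
  }
  med <- apply(bics, 2, median)
  # generating model is probit/log-ratio; log-ratio beats value-difference
  expect_lt(min(med[1:2]), min(med[3:4]))
  # probit- and logit-derived rho are nearly identical in rank
  expect_gt(cor(rho_probit, rho_logit, method = "spearman"), 0.95)
})

test_that("ANCOVA recovers exact parallel lines and the null", {
  x <- seq(1, 3, length.out = 20)
  summaries <- data.frame(rho_task1 = x,
                          rho_AB = 1.2 * x + 0.1,
                          rho_BA = 1.2 * x + 0.4)
  a <- ancova_preference_bias(summaries)
  expect_equal(a$slope, 1.2, tolerance = 1e-10)
  expect_equal(a$intercept_AB, 0.1, tolerance = 1e-10)
  expect_equal(a$intercept_BA, 0.4, tolerance = 1e-10)
  expect_equal(a$intercept_diff, 0.3, tolerance = 1e-10)

  set.seed(1)
  null_sum <- data.frame(rho_task1 = x,
                         rho_AB = x + rnorm(20, 0, 0.05),
                         rho_BA = x + rnorm(20, 0, 0.05))
  a0 <- ancova_preference_bias(null_sum)
  expect_gt(a0$p_slope_gt1, 0.05)
  expect_gt(a0$p_intercept_diff, 0.05)
  expect_error(ancova_preference_bias(
    data.frame(rho_task1 = rep(2, 5), rho_AB = 1:5, rho_BA = 1:5)),
    "rank")
})

test_that("IQR filter follows the Tukey rule", {
  v <- c(2, 2, 2, 3, 2, 2, 50)
  expect_equal(iqr_filter(v), v != 50)
  expect_true(all(iqr_filter(rep(7, 10))))   # IQR = 0 excludes nothing
  set.seed(4)
  u <- runif(1000)
  frac <- mean(!iqr_filter(u))
  expect_lt(frac, 0.025)   # uniform: ~0.7% outside the Tukey fences
  expect_error(iqr_filter(c(1, 2, 3)), "4")
})
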