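test_that("PSP kernel is causal, unit-area and flat for empty trains", {
  grid <- seq(0, 1, by = 0.001)
  tr <- smooth_spikes(0.5, grid, tau = 0.02)
  expect_true(all(tr[grid < 0.5] == 0))
  expect_equal(tr[grid == 0.5], 1 / 0.02, tolerance = 1e-6)
  # exponential decay with the right constant
  i1 <- which(grid == 0.52); i2 <- which(grid == 0.54)
  expect_equal(tr[i2] / tr[i1], exp(-0.02 / 0.02), tolerance = 1e-6)
  expect_equal(smooth_spikes(numeric(0), grid), numeric(length(grid)))
  # a long Poisson train has time-averaged trace ~ its rate
  set.seed(5)
  train <- sort(runif(30 * 100, 0, 100))
  g2 <- seq(10, 90, by = 0.01)
  expect_equal(mean(smooth_spikes(train, g2, 0.02)), 30, tolerance = 0.05)
})

test_that("AUC matches the concordant-pair oracle", {
  expect_equal(roc_auc(c(1, 2, 3), c(4, 5, 6)), 1)
  expect_equal(roc_auc(c(2, 2, 2), c(2, 2, 2)), 0.5)
  expect_equal(roc_auc(c(1, 3), c(2, 4)), 0.75)
  # random integer-count samples against brute force
  set.seed(10)
  for (i in 1:50) {
    x <- rpois(sample(2:6, 1), 3)
    y <- rpois(sample(2:6, 1), 4)
    expect_equal(roc_auc(x, y), auc_bruteforce(x, y), tolerance = 1e-12)
  }
})

test_that("circuit inhibition slope is recovered and null under c1 = 0", {
  est <- truth <- numeric(12)
  for (i in 1:12) {
    c1_true <- rep(c(-2, -1, 0), 4)[i]
    bp <- behavior_params(rho_task1 = 2.5, epsilon = 0, pref_shift = 1,
                          n_trials_task1 = 300)
    s <- generate_choices(bp, seed = 5000 + i)
    s <- generate_spikes(s, list(cell_params("cj", "chosen_juice_A",
                                             baseline = 12,
                                             c1_true = c1_true)),
                         seed = 5100 + i)
    ci <- fit_circuit_inhibition(s, "cj", rho = 2.5, e_juice = "A")
    est[i] <- ci$c1; truth[i] <- c1_true
  }
  expect_lt(max(abs(est - truth)), 8)            # single-cell sampling error
  expect_gt(t.test(est - truth)$p.value, 0.01)   # no systematic bias

  pop <- circuit_inhibition_population(est[truth == -2])
  expect_lt(pop$mean_c1, 0)
})

test_that("tertile split orders mean activity by offer1 value", {
  bp <- behavior_params(rho_task1 = 2.5, epsilon = 0, pref_shift = 1,
                        n_trials_task1 = 400)
  s <- generate_choices(bp, seed = 55)
  s <- generate_spikes(s, list(cell_params("cj", "chosen_juice_A",
                                           baseline = 14, c1_true = -6)),
                       seed = 56)
  tt <- circuit_inhibition_tertiles(s, "cj", rho = 2.5, e_juice = "A")
  expect_equal(tt$tertile, c("Q1", "Q2", "Q3"))
  expect_gt(tt$mean_rate[1], tt$mean_rate[3])   # inhibition: high V(O) low r
})

test_that("choice probability reflects the generated choice signal", {
  # rho near 1 so several offer types split choices evenly, giving the
  # per-type AUCs enough trials in both outcome groups
  bp <- behavior_params(rho_task1 = 1.2, eta_task1 = 3, eta_task2 = 2,
                        epsilon = 0, pref_shift = 1, n_trials_task1 = 320)
  s <- generate_choices(bp, seed = 65)
  s <- generate_spikes(s, list(
    cell_params("sep0", "chosen_juice_A", baseline = 12, cp_sep = 0),
    cell_params("sep8", "chosen_juice_A", baseline = 12, cp_sep = 10,
                cp_onset = 0.05, cp_ramp = 0.2)), seed = 66)
  cp0 <- choice_probability(s, "sep0", "A")
  expect_lt(abs(mean(cp0$cp_windows) - 0.5), 0.15)
  cp8 <- choice_probability(s, "sep8", "A")
  expect_gt(cp8$cp_windows[["late_offer2"]], 0.6)
  expect_lt(abs(cp8$cp_windows[["pre_offer1"]] - 0.5), 0.2)
  # all CPs are probabilities
  expect_true(all(cp8$timecourse$cp >= 0 & cp8$timecourse$cp <= 1))
  # the time course rises near the generated onset (offer2 is 1 s after
  # offer1 onset; divergence starts 0.05 s later)
  tc <- cp8$timecourse
  pre <- mean(tc$cp[tc$time > 0.3 & tc$time < 0.9])
  post <- mean(tc$cp[tc$time > 1.35 & tc$time < 1.6])
  expect_lt(pre, 0.62)
  expect_gt(post, 0.6)
  expect_gt(post - pre, 0.08)
})

test_that("label permutation centers CP on one half", {
  bp <- behavior_params(rho_task1 = 2, eta_task2 = 2, epsilon = 0,
                        pref_shift = 1, n_trials_task1 = 200)
  s <- generate_choices(bp, seed = 75)
  s <- generate_spikes(s, list(cell_params("cj", "chosen_juice_A",
                                           baseline = 12, cp_sep = 10)),
                       seed = 76)
  w <- cfg$cp_windows$late_offer2
  oe <- s$trials[s$trials$task == "task2" & s$trials$order == "BA", ]
  cnt <- seqchoice:::event_window_counts(s, "cj", oe, w)
  key <- paste(oe$qA, oe$qB)
  split_types <- names(which(
    tapply(oe$choice, key, function(x) min(table(factor(x, c("A", "B")))))
    >= 2))
  set.seed(7)
  perm_cp <- replicate(300, {
    mean(vapply(split_types, function(k) {
      sel <- key == k
      lab <- sample(oe$choice[sel])
      roc_auc(cnt[sel][lab != "A"], cnt[sel][lab == "A"])
    }, numeric(1)))
  })
  expect_lt(abs(mean(perm_cp) - 0.5), 3 * sd(perm_cp) / sqrt(300))
})

test_that("CP-PBI correlation appears only when coupled, and only around offer2", {
  build <- function(couple, seed_base) {
    rows <- list()
    set.seed(seed_base)
    shifts <- runif(14, 1.0, 1.35)
    for (i in seq_along(shifts)) {
      pbi_true <- 2 * (shifts[i] - 1) / (shifts[i] + 1)
      sep <- if (couple) max(1, 12 - 60 * pbi_true) else 8
      bp <- behavior_params(rho_task1 = 2, eta_task2 = 2.5, epsilon = 0,
                            pref_shift = shifts[i], n_trials_task1 = 160)
      s <- generate_choices(bp, seed = seed_base + i)
      s <- generate_spikes(s, list(cell_params("cj", "chosen_juice_A",
                                               baseline = 12,
                                               cp_sep = sep)),
                           seed = seed_base + 50 + i)
      f1 <- fit_choice_model(s, "task1"); f2 <- fit_choice_model(s, "task2")
      if (f1$separated || f2$separated) next
      cp <- choice_probability(s, "cj", "A")
      if (is.null(cp)) next
      rows[[length(rows) + 1L]] <- cbind(
        as.data.frame(as.list(cp$cp_windows)),
        data.frame(pbi = 2 * (f2$rho - f1$rho) / (f2$rho + f1$rho)))
    }
    do.call(rbind, rows)
  }
  coupled <- build(TRUE, 8000)
  cor_tab <- cp_pbi_correlation(coupled)
  expect_lt(cor_tab$pearson_r[cor_tab$window == "late_offer2"], 0)
  expect_lt(cor_tab$pearson_p[cor_tab$window == "late_offer2"], 0.05)
  expect_gt(cor_tab$pearson_p[cor_tab$window == "pre_offer1"], 0.05)

  uncoupled <- build(FALSE, 9000)
  cor_tab0 <- cp_pbi_correlation(uncoupled)
  expect_gt(cor_tab0$pearson_p[cor_tab0$window == "late_offer2"], 0.01)

  const <- coupled
  const$pbi <- 0.2
  expect_error(cp_pbi_correlation(const), "constant")
})
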