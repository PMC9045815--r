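test_that("tuning formulas: r_mean and activity range", {
  types <- data.frame(qA = 0:4, qB = 1, order = "none", choice = "A",
                      stringsAsFactors = FALSE)
  rho <- 1
  v <- eval_variable(types, "offer_value_A", rho)   # S = 0..4, S_max = 4
  types$mean_rate <- 2 + 1 * v
  f <- fit_tuning(types, "offer_value_A", rho, class_sign = 1)
  expect_equal(f$b0, 2, tolerance = 1e-10)
  expect_equal(f$b1, 1, tolerance = 1e-10)
  expect_equal(f$r_mean, 4, tolerance = 1e-10)
  expect_equal(f$dr, 4, tolerance = 1e-10)
  expect_true(f$significant)

  types$mean_rate <- rep(5, 5)            # b1 = 0 -> dr = 0
  f0 <- fit_tuning(types, "offer_value_A", rho, 1)
  expect_equal(f0$dr, 0)
  expect_false(f0$significant)

  types2 <- data.frame(qA = 0:3, qB = 1, order = "none", choice = "A",
                       stringsAsFactors = FALSE)
  types2$mean_rate <- 20 - 2 * eval_variable(types2, "offer_value_A", 1)
  fneg <- fit_tuning(types2, "offer_value_A", 1, class_sign = -1)
  expect_equal(fneg$dr, 6, tolerance = 1e-10)   # |b1 * S_max| = 2*3
  expect_true(fneg$significant)

  # dr invariant to adding a constant; r_mean shifts by it
  types$mean_rate <- 2 + 1 * v + 7
  fshift <- fit_tuning(types, "offer_value_A", rho, 1)
  expect_equal(fshift$dr, f$dr, tolerance = 1e-10)
  expect_equal(fshift$r_mean, f$r_mean + 7, tolerance = 1e-10)
})

make_cell_table <- function(pop, kept) {
  rows <- list()
  for (i in seq_along(pop$sessions)) {
    s <- pop$sessions[[i]]
    if (!s$session_id %in% kept$session_id) next
    for (k in seq_len(nrow(s$cells))) {
      cl <- s$cells$true_class[k]
      if (!cl %in% c("offer_value_A", "offer_value_B")) next
      rows[[length(rows) + 1L]] <- data.frame(
        session = i, cell_id = s$cells$cell_id[k],
        juice = if (cl == "offer_value_A") "A" else "B",
        sign = s$cells$sign[k], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

session_vec <- function(pop, kept, col) {
  v <- rep(NA_real_, length(pop$sessions))
  for (i in seq_along(pop$sessions)) {
    sid <- pop$sessions[[i]]$session_id
    if (sid %in% kept$session_id) v[i] <- kept[[col]][kept$session_id == sid]
  }
  v
}

test_that("range shrinks in task 2 while mean activity is preserved", {
  plan <- data.frame(cell_class = c("offer_value_A", "offer_value_B"),
                     sign = c(1, 1))
  pop <- generate_population(10, cell_plan = plan, seed = 51,
                             cell_args = list(task2_scale = 0.75))
  res <- run_pipeline(pop$sessions)
  ct <- make_cell_table(pop, res$kept_sessions)
  rho <- session_vec(pop, res$kept_sessions, "rho_task1")
  cmp <- compare_range_across_tasks(ct, pop$sessions, rho)
  expect_lt(cmp$tests$dr_wilcox_p, 0.01)
  expect_lt(cmp$tests$mean_dr_diff, 0)
  expect_gt(cmp$tests$r_mean_t_p, 0.05)

  # identical encoding across tasks: paired range difference is null
  # (higher SNR so the significance filter selects essentially all cells
  # and cannot bias the retained slope estimates)
  pop1 <- generate_population(10, cell_plan = plan, seed = 52,
                              cell_args = list(task2_scale = 1,
                                               slope = 2.5, baseline = 8))
  res1 <- run_pipeline(pop1$sessions)
  ct1 <- make_cell_table(pop1, res1$kept_sessions)
  rho1 <- session_vec(pop1, res1$kept_sessions, "rho_task1")
  cmp1 <- compare_range_across_tasks(ct1, pop1$sessions, rho1)
  # no material range change: the mean paired difference is small relative
  # to the task-1 range (single-trial type means make p-values heavy-tailed
  # at this n, so the null is asserted on the effect size)
  rel <- abs(cmp1$tests$mean_dr_diff) / mean(cmp1$pairs$dr_task1)
  expect_lt(rel, 0.15)
})

test_that("range-accuracy correlation behaves under coupling and the null", {
  # coupled: task2_scale varies across sessions and drives generated
  # eta_task2; the correlation of dr_diff with d_eta must be positive
  plan <- data.frame(cell_class = "offer_value_A", sign = 1)
  sessions <- list(); kept_rows <- list()
  set.seed(61)
  scales <- runif(14, 0.5, 1)
  for (i in seq_along(scales)) {
    bp <- behavior_params(rho_task1 = 2.5, eta_task1 = 5,
                          eta_task2 = 1.5 + 4 * scales[i],
                          epsilon = 0, pref_shift = 1)
    s <- generate_choices(bp, seed = 1500 + i)
    s$session_id <- sprintf("C%02d", i)
    s <- generate_spikes(s, list(cell_params(
      paste0("c", i), "offer_value_A", task2_scale = scales[i])),
      seed = 1600 + i)
    sessions[[i]] <- s
  }
  res <- run_pipeline(sessions)
  kept <- res$kept_sessions
  ct <- data.frame(session = match(kept$session_id,
                                   sapply(sessions, `[[`, "session_id")),
                   cell_id = paste0("c", match(kept$session_id,
                                               sapply(sessions, `[[`,
                                                      "session_id"))),
                   juice = "A", sign = 1)
  rho <- session_vec(list(sessions = sessions), kept, "rho_task1")
  cmp <- compare_range_across_tasks(ct, sessions, rho)
  d_eta <- kept$d_eta[match(cmp$pairs$cell_id, paste0(
    "c", match(kept$session_id, sapply(sessions, `[[`, "session_id"))))]
  pairs <- cmp$pairs
  pairs$d_eta <- d_eta
  out <- correlate_range_with_accuracy(pairs)
  expect_gt(out$pearson_r, 0)
  expect_lt(out$pearson_p, 0.05)

  # constant d_eta: undefined
  pairs$d_eta <- 1
  expect_error(correlate_range_with_accuracy(pairs), "constant")
})

test_that("no order effect at valuation under the default generator", {
  plan <- data.frame(cell_class = c("offer_value_A", "offer_value_B"),
                     sign = c(1, 1))
  pop <- generate_population(10, cell_plan = plan, seed = 71)
  res <- run_pipeline(pop$sessions)
  ct <- make_cell_table(pop, res$kept_sessions)
  rho <- session_vec(pop, res$kept_sessions, "rho_task1")
  eps <- session_vec(pop, res$kept_sessions, "epsilon")
  oe <- order_effect_offer_value(ct, pop$sessions, rho, eps)
  expect_gt(oe$tests$r_mean_t_p, 0.01)
  expect_gt(oe$tests$dr_t_p, 0.01)

  # positive control: +25% gain on the offer2 window is detected
  pop2 <- generate_population(10, cell_plan = plan, seed = 72,
                              cell_args = list(offer2_gain = 1.25))
  res2 <- run_pipeline(pop2$sessions)
  ct2 <- make_cell_table(pop2, res2$kept_sessions)
  rho2 <- session_vec(pop2, res2$kept_sessions, "rho_task1")
  eps2 <- session_vec(pop2, res2$kept_sessions, "epsilon")
  oe2 <- order_effect_offer_value(ct2, pop2$sessions, rho2, eps2)
  expect_lt(oe2$tests$dr_t_p, 0.05)
})

test_that("offer value tuning changes do not track rho under the default generator", {
  plan <- data.frame(cell_class = c("offer_value_A", "offer_value_B"),
                     sign = c(1, 1))
  pop <- generate_population(12, cell_plan = plan, seed = 81)
  res <- run_pipeline(pop$sessions)
  ct <- make_cell_table(pop, res$kept_sessions)
  rho <- session_vec(pop, res$kept_sessions, "rho_task1")
  out <- offer_value_tuning_vs_rho(ct, pop$sessions, rho)
  for (j in c("A", "B")) {
    expect_gt(out[[j]]$cor_b1$pearson_p, 0.01)
  }
  # scenario 1 (values shifted at valuation in task 2): the slope change
  # is positive on average for juice A cells
  pop1 <- generate_population(12, cell_plan = plan, seed = 82,
                              scenario = 1, pref_shift = 1.3,
                              cell_args = list(task2_scale = 1))
  res1 <- run_pipeline(pop1$sessions)
  ct1 <- make_cell_table(pop1, res1$kept_sessions)
  rho1 <- session_vec(pop1, res1$kept_sessions, "rho_task1")
  out1 <- offer_value_tuning_vs_rho(ct1, pop1$sessions, rho1)
  expect_lt(t.test(out1$A$cells$d_b1, alternative = "greater")$p.value,
            0.05)
})
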