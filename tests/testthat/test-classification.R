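test_that("signed R2 is +/-1 for exact linear responses and 0 when n.s.", {
  types <- data.frame(qA = c(0, 1, 1, 1, 2), qB = c(1, 0, 1, 2, 1),
                      order = "none", choice = c("B", "A", "A", "B", "A"),
                      stringsAsFactors = FALSE)
  rho <- 2
  v <- eval_variable(types, "offer_value_A", rho)
  types$mean_rate <- 2 + 3 * v
  reg <- regress_response(types, "offer_value_A", rho)
  expect_equal(reg$sr2, 1)
  expect_equal(reg$b1, 3, tolerance = 1e-10)

  types$mean_rate <- 10 - v
  expect_equal(regress_response(types, "offer_value_A", rho)$sr2, -1)

  # constant regressor: sR2 = 0 with a log, not an error
  types$mean_rate <- 2 + 3 * v
  one_order <- types[types$choice == "A", ]
  expect_equal(regress_response(one_order, "chosen_juice", rho)$sr2, 0)
})

test_that("null responses reach significance at the alpha rate", {
  set.seed(99)
  types <- data.frame(qA = rep(0:3, each = 3), qB = rep(0:2, 4),
                      order = "none", choice = "A",
                      stringsAsFactors = FALSE)
  types <- types[!(types$qA == 0 & types$qB == 0), ]
  types$choice[types$qA == 0] <- "B"
  hits <- 0; n_sim <- 400
  for (i in seq_len(n_sim)) {
    types$mean_rate <- rnorm(nrow(types), 10, 2)
    if (regress_response(types, "offer_value_A", 2.5)$sr2 != 0) {
      hits <- hits + 1
    }
  }
  expect_gt(hits / n_sim, 0.02)
  expect_lt(hits / n_sim, 0.09)
})

test_that("noiseless constructed cells classify to the expected classes", {
  s <- tiny_session(n_rep = 2)
  rho <- 2
  # offer value A+ in all task-1 windows
  for (w in names(cfg$windows_task1)) {
    s <- inject_spikes(s, "ova", "task1", cfg$windows_task1[[w]],
                       function(tr) 4 + 4 * rho * tr$qA)
  }
  c1 <- classify_task1(s, "ova", rho)
  expect_equal(c1$class, "offer_value_A+")

  # tuned only post-juice, to the chosen value: single window suffices
  s <- inject_spikes(s, "cvpj", "task1", cfg$windows_task1$post_juice,
                     function(tr) {
                       4 + 4 * (if (tr$choice == "A") rho * tr$qA else tr$qB)
                     })
  expect_equal(classify_task1(s, "cvpj", rho)$class, "chosen_value+")

  # no spikes anywhere: untuned
  expect_true(classify_task1(s, "silent", rho)$untuned)
})

test_that("task-2 sequences follow the variable-sequence table", {
  s <- tiny_session(n_rep = 2)
  rho <- 2
  w2 <- cfg$windows_task2
  # offer value A+ sequence: value of A when on display, chosen value A
  # post-juice (A-chosen trials only; flat elsewhere)
  s <- inject_spikes(s, "ova", "task2", w2$post_offer1,
                     function(tr) 4 + 4 * rho * tr$qA *
                       (tr$order == "AB"))
  s <- inject_spikes(s, "ova", "task2", w2$post_offer2,
                     function(tr) 4 + 4 * rho * tr$qA *
                       (tr$order == "BA"))
  s <- inject_spikes(s, "ova", "task2", w2$post_juice,
                     function(tr) 4 + 4 * rho * tr$qA *
                       (tr$choice == "A"))
  expect_equal(classify_task2(s, "ova", rho)$class, "offer_value_A+")

  # chosen juice A sequence: AB|BA+ then AB|BA-, chosen juice post-juice
  s <- inject_spikes(s, "cja", "task2", w2$post_offer1,
                     function(tr) 4 + 8 * (tr$order == "AB"))
  s <- inject_spikes(s, "cja", "task2", w2$post_offer2,
                     function(tr) 4 + 8 * (tr$order == "BA"))
  s <- inject_spikes(s, "cja", "task2", w2$post_juice,
                     function(tr) 4 + 8 * (tr$choice == "A"))
  expect_equal(classify_task2(s, "cja", rho)$class, "chosen_juice_A")

  expect_true(classify_task2(s, "silent", rho)$untuned)
})

test_that("joint classification resolves single-task evidence", {
  s <- tiny_session(n_rep = 2)
  rho <- 2
  # significant only in task 2 (chosen juice A sequence); flat in task 1
  w2 <- cfg$windows_task2
  s <- inject_spikes(s, "cj2", "task2", w2$post_offer1,
                     function(tr) 4 + 8 * (tr$order == "AB"))
  s <- inject_spikes(s, "cj2", "task2", w2$post_offer2,
                     function(tr) 4 + 8 * (tr$order == "BA"))
  s <- inject_spikes(s, "cj2", "task2", w2$post_juice,
                     function(tr) 4 + 8 * (tr$choice == "A"))
  for (w in names(cfg$windows_task1)) {
    s <- inject_spikes(s, "cj2", "task1", cfg$windows_task1[[w]],
                       function(tr) 6)
  }
  j <- classify_joint(s, "cj2", rho)
  expect_equal(j$class, "chosen_juice_A")
  expect_true(j$task1$untuned)

  # classification is invariant to uniform rate rescaling
  s2 <- s
  sp <- s2$spikes[s2$spikes$cell_id == "cj2", ]
  sp$time <- sp$time + 1e-4   # duplicate spikes, offset to keep sorting
  s2$spikes <- rbind(s2$spikes, sp)
  s2$spikes <- s2$spikes[order(s2$spikes$cell_id, s2$spikes$trial_id,
                               s2$spikes$time), ]
  j2 <- classify_joint(s2, "cj2", rho)
  expect_equal(j2$class, j$class)
})

test_that("labeled offer value cells classify correctly at reference SNR", {
  ok <- 0; n <- 8
  for (i in seq_len(n)) {
    bp <- behavior_params(rho_task1 = runif(1, 1.5, 3.5))
    s <- generate_choices(bp, seed = 1200 + i)
    s <- generate_spikes(s, list(cell_params("c", "offer_value_A")),
                         seed = 1300 + i)
    f1 <- fit_choice_model(s, "task1")
    if (classify_joint(s, "c", f1$rho)$class == "offer_value_A+") {
      ok <- ok + 1
    }
  }
  expect_gte(ok, n - 1)
})
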