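# Shared fixtures built in code; no data files.

options(seqchoice.verbose = FALSE)

# Minimal hand-built session: both tasks, deterministic event times, no
# spikes unless injected. Offer types chosen so both juices get picked.
tiny_session <- function(n_rep = 2, seed = 1) {
  set.seed(seed)
  ot <- data.frame(qA = c(1L, 0L, 1L, 1L, 1L, 2L, 3L),
                   qB = c(0L, 1L, 1L, 2L, 3L, 1L, 1L))
  t1 <- expand.grid(rep = seq_len(n_rep), i = seq_len(nrow(ot)))
  tr1 <- data.frame(task = "task1", qA = ot$qA[t1$i], qB = ot$qB[t1$i],
                    order = "none", stringsAsFactors = FALSE)
  t2 <- expand.grid(rep = seq_len(n_rep), ord = c("AB", "BA"),
                    i = seq_len(nrow(ot)))
  tr2 <- data.frame(task = "task2", qA = ot$qA[t2$i], qB = ot$qB[t2$i],
                    order = as.character(t2$ord), stringsAsFactors = FALSE)
  tr <- rbind(tr1, tr2)
  tr$trial_id <- seq_len(nrow(tr))
  # forced choices take the nonzero juice; split types alternate
  tr$choice <- ifelse(tr$qB == 0, "A",
                 ifelse(tr$qA == 0, "B",
                   ifelse(seq_len(nrow(tr)) %% 2 == 0, "A", "B")))
  is1 <- tr$task == "task1"
  ev <- seqchoice:::make_event_times("task1", nrow(tr),
                                     function(n) rep(0.5, n))
  ev[!is1, ] <- seqchoice:::make_event_times("task2", sum(!is1),
                                             function(n) rep(0.5, n))
  tr <- cbind(tr, ev)
  choice_session("tiny", offer_types = ot, trials = tr)
}

# Inject deterministic spikes so that a cell's rate in a given window is an
# exact function of the trial: count = rate * window length (must come out
# integer). Spikes are spread evenly inside the window.
inject_spikes <- function(session, cell_id, task, window_def, rate_fn) {
  tr <- session$trials[session$trials$task == task, , drop = FALSE]
  ev <- tr[[paste0("t_", window_def$event)]]
  t0 <- ev + window_def$start
  len <- window_def$end - window_def$start
  rows <- list()
  for (i in seq_len(nrow(tr))) {
    n <- round(rate_fn(tr[i, ]) * len)
    if (n <= 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      trial_id = tr$trial_id[i], cell_id = cell_id,
      time = t0[i] + (seq_len(n) - 0.5) / n * len)
  }
  add <- do.call(rbind, rows)
  session$spikes <- rbind(session$spikes, add)
  session$spikes <- session$spikes[order(session$spikes$cell_id,
                                         session$spikes$trial_id,
                                         session$spikes$time), , drop = FALSE]
  if (!cell_id %in% session$cells$cell_id) {
    session$cells <- rbind(session$cells,
                           data.frame(cell_id = cell_id)[
                             , names(session$cells), drop = FALSE])
  }
  session
}

# Brute-force AUC oracle: concordant-pair counting with 0.5 for ties.
auc_bruteforce <- function(x, y) {
  tot <- 0
  for (xi in x) for (yi in y) {
    tot <- tot + (yi > xi) + 0.5 * (yi == xi)
  }
  tot / (length(x) * length(y))
}

# Chosen-value fit table for a generated population (ground-truth chosen
# value cells), in the shape scenario_regressions() expects.
cv_fits_from_pop <- function(pop) {
  rows <- list()
  for (s in pop$sessions) {
    f1b <- fit_choice_model(s, "task1")
    f2b <- fit_choice_model(s, "task2")
    if (f1b$separated || f2b$separated) next
    for (cid in s$cells$cell_id[s$cells$true_class == "chosen_value"]) {
      f1 <- fit_chosen_value_task1(s, cid)
      f2 <- fit_chosen_value_task2(s, cid)
      if (!f1$valid || !f2$valid) next
      rows[[length(rows) + 1L]] <- data.frame(
        rho_neuronal_task1 = f1$rho_neuronal,
        rho_neuronal_task2 = f2$rho_offer2,
        rho_behav_task1 = f1b$rho, rho_behav_task2 = f2b$rho)
    }
  }
  do.call(rbind, rows)
}

# Standard config shared across tests
cfg <- sc_config()
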