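#' Causal postsynaptic-potential smoothing of a spike train
#'
#' Convolves spike times with a causal exponential kernel (decay time
#' constant tau, default 20 ms) that exerts influence only forward in
#' time. The kernel is normalized to unit area, so a Poisson train of rate
#' lambda has an expected trace of lambda sp/s.
#'
#' @param spike_times sorted numeric vector (seconds).
#' @param grid evaluation times (seconds).
#' @param tau kernel decay constant (seconds).
#' @return numeric trace, same length as `grid`.
#' @export
smooth_spikes <- function(spike_times, grid, tau = 0.020) {
  if (is.unsorted(spike_times)) stop("spike times must be sorted")
  if (length(spike_times) == 0) return(numeric(length(grid)))
  vapply(grid, function(t) {
    dt <- t - spike_times
    sum(exp(-dt[dt >= 0] / tau)) / tau
  }, numeric(1))
}

# Spike counts of one cell in a window anchored at an event, per trial of
# a trial subset. Returns counts (not rates).
event_window_counts <- function(session, cell_id, trials, window) {
  ev <- trials[[paste0("t_", window$event)]]
  t0 <- ev + window$start
  t1 <- ev + window$end
  sp <- session$spikes
  sp <- sp[sp$cell_id == cell_id & sp$trial_id %in% trials$trial_id, ,
           drop = FALSE]
  row <- match(sp$trial_id, trials$trial_id)
  inside <- sp$time >= t0[row] & sp$time < t1[row]
  tabulate(row[inside], nbins = nrow(trials))
}

#' Label the encoded juice of a chosen juice cell
#'
#' E is the juice eliciting the higher firing rate in the post-juice
#' window when chosen; ties break toward juice A (logged).
#'
#' @param session a `choice_session` with spikes.
#' @param cell_id the cell.
#' @param config an [sc_config()].
#' @return "A" or "B".
#' @export
label_encoded_juice <- function(session, cell_id, config = sc_config()) {
  tr <- session$trials
  w <- config$windows_task2$post_juice
  rates <- c(A = NA_real_, B = NA_real_)
  for (j in c("A", "B")) {
    sub <- tr[tr$choice == j, , drop = FALSE]
    if (nrow(sub) == 0) next
    cnt <- event_window_counts(session, cell_id, sub, w)
    rates[j] <- mean(cnt / (w$end - w$start))
  }
  if (anyNA(rates)) return(names(rates)[!is.na(rates)][1])
  if (rates["A"] == rates["B"]) {
    sc_log("cell ", cell_id, ": E/O tie broken toward juice A",
           level = "WARN")
    return("A")
  }
  names(rates)[which.max(rates)]
}

#' Circuit inhibition of a chosen juice cell
#'
#' In OE trials (the encoded juice offered second), the firing rate in a
#' 300 ms window starting 250 ms before offer2 onset is regressed on the
#' normalized value of offer1, r = c0 + c1 * V(O)/Delta-V_O, with Delta-V_O
#' the session value range of juice O. The slope c1 quantifies circuit
#' inhibition (negative = inhibition). Forced-choice trials are excluded.
#'
#' @param session a `choice_session` with spikes.
#' @param cell_id a chosen juice cell.
#' @param e_juice encoded juice ("A"/"B"); if NULL it is labeled from the
#'   data via [label_encoded_juice()].
#' @param rho session relative value (to express juice-A offers in common
#'   units).
#' @param config an [sc_config()].
#' @return list `c0`, `c1`, `n_trials`, `e_juice`; NULL (with a log) when
#'   fewer than 5 usable OE trials.
#' @export
fit_circuit_inhibition <- function(session, cell_id, rho, e_juice = NULL,
                                   config = sc_config()) {
  if (is.null(e_juice)) e_juice <- label_encoded_juice(session, cell_id,
                                                       config)
  o_juice <- setdiff(c("A", "B"), e_juice)
  tr <- session$trials
  oe_order <- if (e_juice == "A") "BA" else "AB"   # O first, E second
  oe <- tr[tr$task == "task2" & tr$order == oe_order &
             tr$qA > 0 & tr$qB > 0, , drop = FALSE]
  if (nrow(oe) < 5) {
    sc_log("cell ", cell_id, ": < 5 OE trials, circuit inhibition skipped",
           level = "WARN")
    return(NULL)
  }
  v_o <- if (o_juice == "A") rho * oe$qA else oe$qB
  dv <- juice_value_range(session, o_juice, rho)
  if (dv <= 0) stop("degenerate offer1 value range")
  w <- config$ci_window
  cnt <- event_window_counts(session, cell_id, oe, w)
  rate <- cnt / (w$end - w$start)
  xn <- v_o / dv
  if (stats::sd(xn) == 0) {
    sc_log("cell ", cell_id, ": constant offer1 value, skipped",
           level = "WARN")
    return(NULL)
  }
  fit <- stats::lm(rate ~ xn)
  list(c0 = stats::coef(fit)[[1]], c1 = stats::coef(fit)[[2]],
       n_trials = nrow(oe), e_juice = e_juice)
}

#' Population test of circuit inhibition
#'
#' Applies the interquartile outlier rule to the per-cell slopes and tests
#' mean(c1) < 0 by t-test and Wilcoxon signed-rank.
#'
#' @param c1 numeric vector of per-cell circuit-inhibition slopes.
#' @param config an [sc_config()].
#' @return list `mean_c1`, `t_p`, `wilcox_p` (one-sided, less), `n_used`,
#'   `n_excluded`.
#' @export
circuit_inhibition_population <- function(c1, config = sc_config()) {
  keep <- iqr_filter(c1, config$iqr_multiplier, config$quantile_type)
  x <- c1[keep]
  list(mean_c1 = mean(x),
       t_p = stats::t.test(x, alternative = "less")$p.value,
       wilcox_p = suppressWarnings(
         stats::wilcox.test(x, alternative = "less")$p.value),
       n_used = length(x), n_excluded = sum(!keep))
}

#' Tertile split of chosen juice activity by offer1 value
#'
#' Display-style summary mirroring the circuit-inhibition phenomenon:
#' OE trials are split into tertiles of V(O) and the mean rate in the
#' circuit-inhibition window is reported per tertile (Q1 low to Q3 high).
#'
#' @inheritParams fit_circuit_inhibition
#' @return data.frame tertile, mean_rate, n.
#' @export
circuit_inhibition_tertiles <- function(session, cell_id, rho,
                                        e_juice = NULL,
                                        config = sc_config()) {
  if (is.null(e_juice)) e_juice <- label_encoded_juice(session, cell_id,
                                                       config)
  o_juice <- setdiff(c("A", "B"), e_juice)
  oe_order <- if (e_juice == "A") "BA" else "AB"
  tr <- session$trials
  oe <- tr[tr$task == "task2" & tr$order == oe_order &
             tr$qA > 0 & tr$qB > 0, , drop = FALSE]
  v_o <- if (o_juice == "A") rho * oe$qA else oe$qB
  w <- config$ci_window
  rate <- event_window_counts(session, cell_id, oe, w) / (w$end - w$start)
  qs <- stats::quantile(v_o, c(1 / 3, 2 / 3), type = config$quantile_type)
  tert <- cut(v_o, c(-Inf, qs, Inf), labels = c("Q1", "Q2", "Q3"))
  data.frame(tertile = levels(tert),
             mean_rate = as.numeric(tapply(rate, tert, mean)),
             n = as.integer(table(tert)))
}

#' Choice probability of a chosen juice cell
#'
#' ROC analysis of raw spike counts in OE trials (no kernel smoothing).
#' For each split-choice offer type, trials are divided by the eventual
#' choice (E vs O) and the two count distributions are compared; the AUC
#' is computed per offer type and averaged (unweighted by default) to give
#' the cell's CP. Offer types where either choice has < 2 trials are
#' excluded. CP is computed on a sliding grid (100 ms windows, 25 ms
#' steps, anchored at offer1 onset) and in the four fixed 250 ms windows.
#'
#' @inheritParams fit_circuit_inhibition
#' @param t_range sliding-grid span in seconds relative to offer1 onset.
#' @param weighted if TRUE, offer-type AUCs are weighted by trial count.
#' @return a `cp_result`: `cp_windows` (named CP per fixed window),
#'   `timecourse` (data.frame time, cp), `offer_types` used, `e_juice`;
#'   NULL (logged) when no offer type qualifies.
#' @export
choice_probability <- function(session, cell_id, e_juice = NULL,
                               config = sc_config(),
                               t_range = c(-0.35, 2.6), weighted = FALSE) {
  if (is.null(e_juice)) e_juice <- label_encoded_juice(session, cell_id,
                                                       config)
  tr <- session$trials
  oe_order <- if (e_juice == "A") "BA" else "AB"
  oe <- tr[tr$task == "task2" & tr$order == oe_order, , drop = FALSE]
  oe$chose_e <- oe$choice == e_juice
  # qualifying offer types: split choices with >= 2 trials per outcome
  key <- paste(oe$qA, oe$qB)
  tab <- table(key, oe$chose_e)
  if (!all(c("TRUE", "FALSE") %in% colnames(tab))) {
    sc_log("cell ", cell_id, ": no split-choice offer types, CP undefined",
           level = "WARN")
    return(NULL)
  }
  ok_types <- rownames(tab)[tab[, "TRUE"] >= 2 & tab[, "FALSE"] >= 2]
  if (length(ok_types) == 0) {
    sc_log("cell ", cell_id, ": no qualifying offer types, CP undefined",
           level = "WARN")
    return(NULL)
  }
  oe <- oe[key %in% ok_types, , drop = FALSE]
  key <- paste(oe$qA, oe$qB)
  wts <- if (weighted) as.numeric(table(key)[ok_types]) else
    rep(1, length(ok_types))
  wts <- wts / sum(wts)

  cp_of_window <- function(window) {
    cnt <- event_window_counts(session, cell_id, oe, window)
    aucs <- vapply(ok_types, function(k) {
      sel <- key == k
      x <- cnt[sel & !oe$chose_e]   # O chosen (reference)
      y <- cnt[sel & oe$chose_e]    # E chosen
      roc_auc(x, y)
    }, numeric(1))
    sum(aucs * wts)
  }
  starts <- seq(t_range[1], t_range[2] - config$cp_sliding$width,
                by = config$cp_sliding$step)
  timecourse <- data.frame(
    time = starts + config$cp_sliding$width / 2,
    cp = vapply(starts, function(s) {
      cp_of_window(list(event = "offer1_on", start = s,
                        end = s + config$cp_sliding$width))
    }, numeric(1))
  )
  cp_windows <- vapply(config$cp_windows, cp_of_window, numeric(1))
  structure(list(cell_id = cell_id, e_juice = e_juice,
                 cp_windows = cp_windows, timecourse = timecourse,
                 offer_types = ok_types, n_trials = nrow(oe)),
            class = "cp_result")
}

#' @export
print.cp_result <- function(x, ...) {
  cat("cp_result: cell", x$cell_id, "(E =", x$e_juice, ")\n")
  print(round(x$cp_windows, 3))
  invisible(x)
}

#' Correlate choice probability with the preference bias index
#'
#' Per fixed CP window, correlates the per-cell CP with the session
#' preference bias index (PBI). A negative correlation around offer2
#' indicates that sessions with weaker early commitment to the choice
#' carry a larger preference bias.
#'
#' @param cp_table data.frame: one row per cell, columns per fixed window
#'   (`pre_offer1`, `late_offer2`, `early_wait`, `pre_juice`) and `pbi`.
#' @return data.frame: window, pearson/spearman r and p, slope.
#' @export
cp_pbi_correlation <- function(cp_table) {
  wins <- c("pre_offer1", "late_offer2", "early_wait", "pre_juice")
  if (stats::sd(cp_table$pbi) == 0) {
    stop("constant PBI across sessions: correlation undefined")
  }
  rows <- lapply(wins, function(w) {
    res <- cor_both(cp_table$pbi, cp_table[[w]])
    res$slope <- stats::coef(stats::lm(cp_table[[w]] ~ cp_table$pbi))[[2]]
    cbind(data.frame(window = w), res)
  })
  do.call(rbind, rows)
}

#' Population CP time course
#'
#' Averages per-cell CP traces on a common grid and tests mean(CP) > 0.5
#' per bin.
#'
#' @param cp_results list of `cp_result`.
#' @return data.frame time, mean_cp, se, p (one-sided t vs 0.5), n.
#' @export
cp_timecourse_population <- function(cp_results) {
  cp_results <- Filter(Negate(is.null), cp_results)
  if (!length(cp_results)) stop("no CP results")
  times <- cp_results[[1]]$timecourse$time
  mat <- vapply(cp_results, function(x) x$timecourse$cp,
                numeric(length(times)))
  mat <- matrix(mat, nrow = length(times))
  data.frame(
    time = times,
    mean_cp = rowMeans(mat),
    se = apply(mat, 1, stats::sd) / sqrt(ncol(mat)),
    p = apply(mat, 1, function(x) {
      if (stats::sd(x) == 0) return(NA_real_)
      stats::t.test(x, mu = 0.5, alternative = "greater")$p.value
    }),
    n = ncol(mat)
  )
}
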