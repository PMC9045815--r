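#' Build trial types for one task
#'
#' A trial type is the unit of neuronal-response averaging: in Task 1 the
#' combination (qA, qB, choice); in Task 2 (qA, qB, order, choice). Trial
#' types partition the task's trials exhaustively.
#'
#' @param session a `choice_session`.
#' @param task "task1" or "task2".
#' @return list with `types` (data.frame `type_id`, `qA`, `qB`, `order`,
#'   `choice`, `n`) and `membership` (integer type_id per task trial, named
#'   by trial_id).
#' @export
build_trial_types <- function(session, task = c("task1", "task2")) {
  task <- match.arg(task)
  tr <- session$trials[session$trials$task == task, , drop = FALSE]
  if (nrow(tr) == 0) {
    return(list(types = data.frame(type_id = integer(), qA = integer(),
                                   qB = integer(), order = character(),
                                   choice = character(), n = integer()),
                membership = integer()))
  }
  key <- if (task == "task1") {
    paste(tr$qA, tr$qB, tr$choice)
  } else {
    paste(tr$qA, tr$qB, tr$order, tr$choice)
  }
  uk <- sort(unique(key))
  id <- match(key, uk)
  first <- !duplicated(key)
  types <- data.frame(
    type_id = id[first], qA = tr$qA[first], qB = tr$qB[first],
    order = tr$order[first], choice = tr$choice[first],
    stringsAsFactors = FALSE
  )
  types <- types[order(types$type_id), , drop = FALSE]
  types$n <- as.integer(table(id))
  rownames(types) <- NULL
  membership <- stats::setNames(id, tr$trial_id)
  list(types = types, membership = membership)
}

# Per-trial firing rates of one cell in one window, for the trials of one
# task. Returns numeric vector aligned to the task's trial rows; trials
# whose window falls outside the trial span are NA (skipped with a log).
window_rates <- function(session, cell_id, task, window) {
  tr <- session$trials[session$trials$task == task, , drop = FALSE]
  ev_col <- paste0("t_", window$event)
  if (!ev_col %in% names(tr)) {
    stop("event ", window$event, " not defined for ", task)
  }
  t0 <- tr[[ev_col]] + window$start
  t1 <- tr[[ev_col]] + window$end
  bad <- is.na(t0) | t0 < 0 | t1 > tr$t_end
  if (any(bad, na.rm = TRUE)) {
    sc_log("cell ", cell_id, ": ", sum(bad), " trials skipped (window '",
           window$event, "' outside trial span)", level = "WARN")
  }
  sp <- session$spikes
  sp <- sp[sp$cell_id == cell_id & sp$trial_id %in% tr$trial_id, ,
           drop = FALSE]
  row <- match(sp$trial_id, tr$trial_id)
  inside <- sp$time >= t0[row] & sp$time < t1[row]
  counts <- tabulate(row[inside], nbins = nrow(tr))
  rates <- counts / (t1 - t0)
  rates[bad] <- NA_real_
  rates
}

#' Windowed neuronal response of one cell
#'
#' The firing rate of one cell in one time window as a function of the
#' trial type: spike count in the window divided by the window length,
#' averaged across the trials of each type.
#'
#' @param session a `choice_session` with spikes.
#' @param cell_id cell to analyze.
#' @param task "task1" or "task2".
#' @param window window name (must exist in the config for that task) or a
#'   `list(event, start, end)`.
#' @param config an [sc_config()].
#' @return a `neuronal_response`: list with `types` (trial-type table with
#'   `mean_rate` and `n`), `trial_rates` (per-trial rates), `trial_type`
#'   (per-trial type_id), plus identifiers.
#' @export
compute_response <- function(session, cell_id, task, window,
                             config = sc_config()) {
  wname <- if (is.character(window)) window else "custom"
  if (is.character(window)) {
    wins <- if (task == "task1") config$windows_task1 else config$windows_task2
    if (!window %in% names(wins)) {
      stop("window '", window, "' not defined for ", task)
    }
    window <- wins[[window]]
  }
  tt <- build_trial_types(session, task)
  rates <- window_rates(session, cell_id, task, window)
  ok <- !is.na(rates)
  means <- tapply(rates[ok], tt$membership[ok], mean)
  types <- tt$types
  types$mean_rate <- as.numeric(means[as.character(types$type_id)])
  types$n_used <- as.integer(
    table(factor(tt$membership[ok], levels = types$type_id)))
  structure(list(cell_id = cell_id, task = task, window = wname,
                 types = types, trial_rates = rates,
                 trial_type = tt$membership),
            class = "neuronal_response")
}

#' @export
print.neuronal_response <- function(x, ...) {
  cat("neuronal_response: cell", x$cell_id, "/", x$task, "/", x$window,
      "-", nrow(x$types), "trial types\n")
  invisible(x)
}

#' ANOVA screen for task-related activity
#'
#' One-way ANOVA (factor: trial type) of the per-trial firing rates of one
#' cell, per time window per task. A cell is task-related when any window
#' in either task passes p < `config$anova_alpha` (default 0.01). Trial
#' types with a single trial are excluded from the variance test.
#'
#' @param session a `choice_session` with spikes.
#' @param cell_id cell to screen.
#' @param config an [sc_config()].
#' @return list with `p_values` (data.frame task, window, p) and
#'   `task_related` flag.
#' @export
anova_screen <- function(session, cell_id, config = sc_config()) {
  rows <- list()
  for (task in c("task1", "task2")) {
    if (!any(session$trials$task == task)) next
    wins <- if (task == "task1") config$windows_task1 else config$windows_task2
    tt <- build_trial_types(session, task)
    for (wname in names(wins)) {
      rates <- window_rates(session, cell_id, task, wins[[wname]])
      grp <- tt$membership
      ok <- !is.na(rates)
      keep_types <- names(which(table(grp[ok]) >= 2))
      ok <- ok & as.character(grp) %in% keep_types
      p <- if (sum(ok) >= 4 && length(unique(grp[ok])) >= 2 &&
               stats::sd(rates[ok]) > 0) {
        stats::anova(stats::lm(rates[ok] ~ factor(grp[ok])))[["Pr(>F)"]][1]
      } else {
        NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        task = task, window = wname, p = p, stringsAsFactors = FALSE)
    }
  }
  pv <- do.call(rbind, rows)
  if (all(is.na(pv$p))) {
    sc_log("cell ", cell_id, " excluded: all windows degenerate",
           level = "WARN")
  }
  list(p_values = pv,
       task_related = any(pv$p < config$anova_alpha, na.rm = TRUE))
}
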