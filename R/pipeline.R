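#' Run the full analysis pipeline over a batch of sessions
#'
#' Stages: (1) per-session behavioral fits (probit, log-ratio) for both
#' tasks with derived measures; (2) interquartile filtering of unstable
#' sessions on the sigmoid steepness; (3) ANCOVA of the preference and
#' order biases; (4) per-cell ANOVA screen and joint classification;
#' (5) group analyses — cross-task activity range for offer value cells,
#' neuronal relative values and order-bias correlation for chosen value
#' cells, circuit inhibition and choice probability for chosen juice
#' cells. Stage failures are logged per session/cell and the pipeline
#' continues over the remaining items.
#'
#' @param sessions list of `choice_session` (or a directory containing
#'   session subdirectories readable by [read_session()]).
#' @param config an [sc_config()].
#' @param out_dir if non-NULL, CSV tables and a JSON summary are written
#'   there.
#' @return list of result tables: `behavior`, `kept_sessions`, `ancova`,
#'   `classification`, `chosen_value`, `circuit_inhibition`, `cp`,
#'   `summary`.
#' @export
run_pipeline <- function(sessions, config = sc_config(), out_dir = NULL) {
  if (is.character(sessions)) {
    dirs <- list.dirs(sessions, recursive = FALSE)
    sessions <- lapply(dirs, read_session)
  }
  if (length(sessions) < 1) stop("need >= 1 session")
  t_start <- Sys.time()

  # ---- stage 1: behavior ----
  beh <- list()
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    res <- tryCatch({
      f1 <- fit_choice_model(s, "task1")
      f2 <- fit_choice_model(s, "task2")
      if (f1$separated || f2$separated) {
        sc_log("session ", s$session_id,
               " flagged for separation; excluded downstream",
               level = "WARN")
        NULL
      } else {
        session_bias_summary(f1, f2, s$session_id)
      }
    }, error = function(e) {
      sc_log("session ", s$session_id, " behavior stage failed: ",
             conditionMessage(e), level = "ERROR")
      NULL
    })
    if (!is.null(res)) beh[[length(beh) + 1L]] <- res
  }
  behavior <- do.call(rbind, beh)
  if (is.null(behavior) || nrow(behavior) == 0) {
    stop("no session produced a usable behavioral fit")
  }

  # ---- stage 2: session stability filter on steepness ----
  if (nrow(behavior) >= 4) {
    keep <- iqr_filter(behavior$eta_task1, config$iqr_multiplier,
                       config$quantile_type) &
      iqr_filter(behavior$eta_task2, config$iqr_multiplier,
                 config$quantile_type)
  } else {
    keep <- rep(TRUE, nrow(behavior))
  }
  n_out <- sum(!keep)
  if (n_out > 0) {
    sc_log(n_out, " sessions excluded as steepness outliers (IQR rule)")
  }
  kept <- behavior[keep, , drop = FALSE]

  # ---- stage 3: ANCOVA ----
  ancova <- tryCatch({
    if (nrow(kept) >= 3) ancova_preference_bias(kept) else NULL
  }, error = function(e) {
    sc_log("ANCOVA failed: ", conditionMessage(e), level = "ERROR")
    NULL
  })

  # ---- stages 4-5: neuronal analyses ----
  by_id <- stats::setNames(sessions,
                           vapply(sessions, `[[`, character(1),
                                  "session_id"))
  cls_rows <- list(); cv_rows <- list(); ci_rows <- list(); cp_rows <- list()
  for (sid in kept$session_id) {
    s <- by_id[[sid]]
    if (nrow(s$spikes) == 0) next
    rho <- kept$rho_task1[kept$session_id == sid]
    cls <- tryCatch(classify_session(s, rho, config), error = function(e) {
      sc_log("session ", sid, " classification failed: ",
             conditionMessage(e), level = "ERROR")
      NULL
    })
    if (is.null(cls)) next
    cls$session_id <- sid
    cls_rows[[length(cls_rows) + 1L]] <- cls
    krow <- kept[kept$session_id == sid, ]
    for (k in seq_len(nrow(cls))) {
      if (!isTRUE(cls$task_related[k])) next
      cid <- cls$cell_id[k]
      cl <- cls$class[k]
      tryCatch({
        if (cl %in% c("chosen_value+", "chosen_value-")) {
          f1 <- fit_chosen_value_task1(s, cid, config)
          f2 <- fit_chosen_value_task2(s, cid, config)
          cv_rows[[length(cv_rows) + 1L]] <- data.frame(
            session_id = sid, cell_id = cid,
            rho_neuronal_task1 = f1$rho_neuronal,
            rho_offer1 = f2$rho_offer1, rho_offer2 = f2$rho_offer2,
            rho_AB = f2$rho_AB, rho_BA = f2$rho_BA,
            d_rho_neuronal = f2$d_rho_neuronal,
            valid = f1$valid && f2$valid,
            epsilon = krow$epsilon, rho_behav_task1 = krow$rho_task1,
            rho_behav_task2 = krow$rho_task2, pbi = krow$pbi,
            stringsAsFactors = FALSE)
        } else if (cl %in% c("chosen_juice_A", "chosen_juice_B")) {
          ej <- if (cl == "chosen_juice_A") "A" else "B"
          ci <- fit_circuit_inhibition(s, cid, rho, ej, config)
          if (!is.null(ci)) {
            ci_rows[[length(ci_rows) + 1L]] <- data.frame(
              session_id = sid, cell_id = cid, c0 = ci$c0, c1 = ci$c1,
              epsilon = krow$epsilon, stringsAsFactors = FALSE)
          }
          cp <- choice_probability(s, cid, ej, config)
          if (!is.null(cp)) {
            cp_rows[[length(cp_rows) + 1L]] <- cbind(
              data.frame(session_id = sid, cell_id = cid,
                         stringsAsFactors = FALSE),
              as.data.frame(as.list(cp$cp_windows)),
              data.frame(pbi = krow$pbi))
          }
        }
      }, error = function(e) {
        sc_log("cell ", cid, " (", cl, ") analysis failed: ",
               conditionMessage(e), level = "ERROR")
      })
    }
  }
  classification <- if (length(cls_rows)) do.call(rbind, cls_rows) else NULL
  chosen_value <- if (length(cv_rows)) do.call(rbind, cv_rows) else NULL
  circuit <- if (length(ci_rows)) do.call(rbind, ci_rows) else NULL
  cp_table <- if (length(cp_rows)) do.call(rbind, cp_rows) else NULL

  summary_list <- list(
    n_sessions = length(sessions),
    n_sessions_fitted = nrow(behavior),
    n_sessions_kept = nrow(kept),
    n_cells = if (is.null(classification)) 0L else nrow(classification),
    n_task_related = if (is.null(classification)) 0L else
      sum(classification$task_related),
    class_counts = if (is.null(classification)) NULL else
      as.list(table(classification$class)),
    ancova_slope = if (is.null(ancova)) NULL else ancova$slope,
    ancova_intercept_diff = if (is.null(ancova)) NULL else
      ancova$intercept_diff,
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  )
  sc_log(sprintf("pipeline done in %.1f s: %d/%d sessions kept",
                 summary_list$elapsed_s, nrow(kept), length(sessions)))

  out <- list(behavior = behavior, kept_sessions = kept, ancova = ancova,
              classification = classification, chosen_value = chosen_value,
              circuit_inhibition = circuit, cp = cp_table,
              summary = summary_list)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(behavior, file.path(out_dir, "behavior_fits.csv"),
                     row.names = FALSE)
    for (nm in c("classification", "chosen_value", "circuit_inhibition",
                 "cp")) {
      if (!is.null(out[[nm]])) {
        utils::write.csv(out[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                         row.names = FALSE)
      }
    }
    jsonlite::write_json(summary_list, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
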