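#' Linear tuning fit of a neuronal response
#'
#' Fits r = b0 + b1*S by OLS on trial-type means, where S is the encoded
#' variable in common value units. With S_max the session's maximum of S,
#' the mean activity is r_mean = b0 + b1*S_max/2 and the activity range is
#' Delta-r = |b1*S_max|. The tuning is significant when the slope differs
#' from zero (p < alpha) and its sign matches the cell's class sign.
#'
#' @param response `neuronal_response` (or its `$types`).
#' @param variable encoded variable name (see [eval_variable()]).
#' @param rho session relative value.
#' @param class_sign +1/-1 encoding sign of the cell's class.
#' @param alpha significance threshold (default 0.05).
#' @return a `tuning_fit` list: `b0`, `b1`, `p`, `s_max`, `r_mean`, `dr`,
#'   `significant`.
#' @export
fit_tuning <- function(response, variable, rho, class_sign = 1,
                       alpha = 0.05) {
  reg <- regress_response(response, variable, rho, alpha)
  types <- if (inherits(response, "neuronal_response")) response$types
           else response
  s <- eval_variable(types, variable, rho)
  s_max <- max(s, na.rm = TRUE)
  if (is.na(reg$b1)) {
    return(structure(list(b0 = NA_real_, b1 = NA_real_, p = NA_real_,
                          s_max = s_max, r_mean = NA_real_, dr = NA_real_,
                          significant = FALSE), class = "tuning_fit"))
  }
  structure(list(
    b0 = reg$b0, b1 = reg$b1, p = reg$p, s_max = s_max,
    r_mean = reg$b0 + reg$b1 * s_max / 2,
    dr = abs(reg$b1 * s_max),
    significant = !is.na(reg$p) && reg$p < alpha &&
      sign(reg$b1) == class_sign
  ), class = "tuning_fit")
}

# Encoded variable of an offer value cell in a given task-2 window given
# the trial domain where its juice is on display.
offer_value_task2_variable <- function(juice, window) {
  if (window == "post_offer1") {
    if (juice == "A") "offer_value_A_AB" else "offer_value_B_BA"
  } else {
    if (juice == "A") "offer_value_A_BA" else "offer_value_B_AB"
  }
}

#' Cross-task tuning comparison for offer value cells
#'
#' For each offer value cell (pooling juices and encoding signs), compares
#' the Task-1 post-offer tuning with the Task-2 post-offer1 and post-offer2
#' tunings. Task 2 contributes two observations per cell, each paired with
#' the same Task-1 response. Only pairs significant in both tasks enter.
#'
#' @param cell_table data.frame: `session` (index into `sessions`),
#'   `cell_id`, `juice` ("A"/"B"), `sign`.
#' @param sessions list of `choice_session`.
#' @param rho_by_session numeric: session relative values.
#' @param config an [sc_config()].
#' @return list with `pairs` (per cell x task-2 window: r_mean and dr in
#'   both tasks) and `tests` (paired t and Wilcoxon p for r_mean and dr).
#' @export
compare_range_across_tasks <- function(cell_table, sessions, rho_by_session,
                                       config = sc_config()) {
  rows <- list()
  for (i in seq_len(nrow(cell_table))) {
    ses <- sessions[[cell_table$session[i]]]
    rho <- rho_by_session[cell_table$session[i]]
    juice <- cell_table$juice[i]
    sgn <- cell_table$sign[i]
    cid <- cell_table$cell_id[i]
    var1 <- paste0("offer_value_", juice)
    r1 <- compute_response(ses, cid, "task1", "post_offer", config)
    f1 <- fit_tuning(r1, var1, rho, sgn, config$tuning_alpha)
    if (!f1$significant) next
    for (w in c("post_offer1", "post_offer2")) {
      r2 <- compute_response(ses, cid, "task2", w, config)
      f2 <- fit_tuning(r2, offer_value_task2_variable(juice, w), rho, sgn,
                       config$tuning_alpha)
      if (!f2$significant) next
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = cid, window2 = w,
        r_mean_task1 = f1$r_mean, r_mean_task2 = f2$r_mean,
        dr_task1 = f1$dr, dr_task2 = f2$dr,
        stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, rows)
  tests <- NULL
  if (!is.null(pairs) && nrow(pairs) >= 3) {
    tests <- list(
      r_mean_t_p = stats::t.test(pairs$r_mean_task2, pairs$r_mean_task1,
                                 paired = TRUE)$p.value,
      r_mean_wilcox_p = suppressWarnings(
        stats::wilcox.test(pairs$r_mean_task2, pairs$r_mean_task1,
                           paired = TRUE)$p.value),
      dr_t_p = stats::t.test(pairs$dr_task2, pairs$dr_task1,
                             paired = TRUE)$p.value,
      dr_wilcox_p = suppressWarnings(
        stats::wilcox.test(pairs$dr_task2, pairs$dr_task1,
                           paired = TRUE)$p.value),
      mean_dr_diff = mean(pairs$dr_task2 - pairs$dr_task1)
    )
  } else {
    sc_log("compare_range_across_tasks: < 3 qualifying pairs, tests skipped",
           level = "WARN")
  }
  list(pairs = pairs, tests = tests)
}

#' Correlate activity-range changes with choice-accuracy changes
#'
#' Correlates, across offer value cells, the cross-task difference in
#' activity range Delta-r_diff = Delta-r_Task2 - Delta-r_Task1 with the
#' session's steepness difference Delta-eta = eta_Task2 - eta_Task1.
#'
#' @param pairs the `pairs` table from [compare_range_across_tasks()], with
#'   a `d_eta` column giving each observation's session Delta-eta.
#' @return one-row data.frame from [cor_both()] plus the regression slope.
#' @export
correlate_range_with_accuracy <- function(pairs) {
  if (!"d_eta" %in% names(pairs)) stop("pairs needs a d_eta column")
  dd <- pairs$dr_task2 - pairs$dr_task1
  if (stats::sd(pairs$d_eta) == 0) {
    stop("constant Delta-eta: correlation undefined")
  }
  res <- cor_both(pairs$d_eta, dd)
  res$slope <- stats::coef(stats::lm(dd ~ pairs$d_eta))[[2]]
  res
}

#' Order effect on offer value tuning (EO vs OE)
#'
#' For each offer value cell, E denotes the encoded juice. The response to
#' E offered first (EO trials, post-offer1 window) is compared with the
#' response to E offered second (OE trials, post-offer2 window). If values
#' were inflated for the second offer, mean activity and/or activity range
#' should be higher in OE; the differences are also correlated with the
#' session order bias epsilon.
#'
#' @inheritParams compare_range_across_tasks
#' @param epsilon_by_session numeric, per-session order bias.
#' @return list `pairs`, `tests` (paired p-values), `cor_eps` (correlations
#'   of OE-EO differences with epsilon; NULL when < 3 cells).
#' @export
order_effect_offer_value <- function(cell_table, sessions, rho_by_session,
                                     epsilon_by_session,
                                     config = sc_config()) {
  rows <- list()
  for (i in seq_len(nrow(cell_table))) {
    ses <- sessions[[cell_table$session[i]]]
    rho <- rho_by_session[cell_table$session[i]]
    juice <- cell_table$juice[i]
    sgn <- cell_table$sign[i]
    cid <- cell_table$cell_id[i]
    # EO: E is offer1 -> post-offer1; OE: E is offer2 -> post-offer2
    r_eo <- compute_response(ses, cid, "task2", "post_offer1", config)
    f_eo <- fit_tuning(r_eo, offer_value_task2_variable(juice, "post_offer1"),
                       rho, sgn, config$tuning_alpha)
    r_oe <- compute_response(ses, cid, "task2", "post_offer2", config)
    f_oe <- fit_tuning(r_oe, offer_value_task2_variable(juice, "post_offer2"),
                       rho, sgn, config$tuning_alpha)
    if (!f_eo$significant || !f_oe$significant) next
    rows[[length(rows) + 1L]] <- data.frame(
      cell_id = cid,
      r_mean_EO = f_eo$r_mean, r_mean_OE = f_oe$r_mean,
      dr_EO = f_eo$dr, dr_OE = f_oe$dr,
      epsilon = epsilon_by_session[cell_table$session[i]],
      stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows)
  if (is.null(pairs) || nrow(pairs) < 3) {
    sc_log("order_effect_offer_value: < 3 qualifying cells, tests skipped",
           level = "WARN")
    return(list(pairs = pairs, tests = NULL, cor_eps = NULL))
  }
  tests <- list(
    r_mean_t_p = stats::t.test(pairs$r_mean_OE, pairs$r_mean_EO,
                               paired = TRUE)$p.value,
    dr_t_p = stats::t.test(pairs$dr_OE, pairs$dr_EO, paired = TRUE)$p.value,
    r_mean_wilcox_p = suppressWarnings(
      stats::wilcox.test(pairs$r_mean_OE, pairs$r_mean_EO,
                         paired = TRUE)$p.value),
    dr_wilcox_p = suppressWarnings(
      stats::wilcox.test(pairs$dr_OE, pairs$dr_EO, paired = TRUE)$p.value)
  )
  cor_eps <- if (stats::sd(pairs$epsilon) > 0) {
    list(r_mean = cor_both(pairs$epsilon, pairs$r_mean_OE - pairs$r_mean_EO),
         dr = cor_both(pairs$epsilon, pairs$dr_OE - pairs$dr_EO))
  } else NULL
  list(pairs = pairs, tests = tests, cor_eps = cor_eps)
}

#' Offer value tuning changes versus relative value
#'
#' For each offer value cell group (A and B separately, signs pooled),
#' computes the cross-task tuning changes Delta-b0 and Delta-b1 (Task 2
#' pooling trial types from the post-offer1 and post-offer2 windows) and
#' correlates them with the session relative value rho. A correlation here
#' would indicate value shifts at the valuation stage growing with rho.
#'
#' @inheritParams compare_range_across_tasks
#' @return list per juice group: `cells` table with `d_b0`, `d_b1`, `rho`,
#'   and correlations `cor_b0`, `cor_b1`.
#' @export
offer_value_tuning_vs_rho <- function(cell_table, sessions, rho_by_session,
                                      config = sc_config()) {
  out <- list()
  for (juice in c("A", "B")) {
    sub <- cell_table[cell_table$juice == juice, , drop = FALSE]
    rows <- list()
    for (i in seq_len(nrow(sub))) {
      ses <- sessions[[sub$session[i]]]
      rho <- rho_by_session[sub$session[i]]
      sgn <- sub$sign[i]
      cid <- sub$cell_id[i]
      var1 <- paste0("offer_value_", juice)
      f1 <- fit_tuning(compute_response(ses, cid, "task1", "post_offer",
                                        config),
                       var1, rho, sgn, config$tuning_alpha)
      # pool trial types from both task-2 offer windows
      r_po1 <- compute_response(ses, cid, "task2", "post_offer1", config)
      r_po2 <- compute_response(ses, cid, "task2", "post_offer2", config)
      t1 <- r_po1$types
      t1$S <- eval_variable(
        t1, offer_value_task2_variable(juice, "post_offer1"), rho)
      t2 <- r_po2$types
      t2$S <- eval_variable(
        t2, offer_value_task2_variable(juice, "post_offer2"), rho)
      pooled <- rbind(t1[!is.na(t1$S), c("S", "mean_rate")],
                      t2[!is.na(t2$S), c("S", "mean_rate")])
      if (nrow(pooled) < 3 || !f1$significant) next
      fit2 <- stats::lm(mean_rate ~ S, data = pooled)
      p2 <- summary(fit2)$coefficients["S", "Pr(>|t|)"]
      b2 <- stats::coef(fit2)
      if (is.na(p2) || p2 >= config$tuning_alpha ||
          sign(b2[["S"]]) != sgn) next
      # pool encoding signs: express changes in sign-corrected units
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = cid,
        d_b0 = sgn * (b2[["(Intercept)"]] - f1$b0),
        d_b1 = sgn * (b2[["S"]] - f1$b1),
        rho = rho, stringsAsFactors = FALSE)
    }
    cells <- do.call(rbind, rows)
    if (is.null(cells) || nrow(cells) < 3) {
      stop("offer_value_tuning_vs_rho: < 3 qualifying cells for juice ",
           juice)
    }
    out[[juice]] <- list(cells = cells,
                         cor_b0 = cor_both(cells$rho, cells$d_b0),
                         cor_b1 = cor_both(cells$rho, cells$d_b1))
  }
  out
}
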