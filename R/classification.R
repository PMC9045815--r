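#' Regressor variables for neuronal classification
#'
#' Evaluates a decision variable on a trial-type table. Value variables are
#' expressed in common units (units of juice B) using the session's
#' behavioral relative value: the value of qA quanta of juice A is rho*qA.
#' Binary variables take two levels (0/1). Several Task-2 variables are
#' restricted to a domain (e.g. "offer_value_A_AB" is defined on AB trials
#' only); outside the domain the returned value is NA and those trial types
#' drop out of the regression.
#'
#' Task-1 variables: `offer_value_A`, `offer_value_B`, `chosen_juice`
#' (1 for choice A), `chosen_value`.
#' Task-2 variables: `ab_ba` (1 for AB trials), `offer_value_A_AB`,
#' `offer_value_A_BA`, `offer_value_B_AB`, `offer_value_B_BA`,
#' `offer_value_1`, `offer_value_2`, `chosen_value`, `chosen_value_A`,
#' `chosen_value_B`, `chosen_juice`.
#'
#' @param types trial-type data.frame (`qA`, `qB`, `order`, `choice`).
#' @param variable variable name.
#' @param rho session relative value used to convert juice-A quantities to
#'   common value units.
#' @return numeric vector, NA outside the variable's domain.
#' @export
eval_variable <- function(types, variable, rho) {
  vA <- rho * types$qA
  vB <- types$qB
  ab <- types$order == "AB"
  chA <- types$choice == "A"
  switch(variable,
    offer_value_A = vA,
    offer_value_B = vB,
    chosen_juice = as.numeric(chA),
    chosen_value = ifelse(chA, vA, vB),
    ab_ba = as.numeric(ab),
    offer_value_A_AB = ifelse(ab, vA, NA_real_),
    offer_value_A_BA = ifelse(!ab, vA, NA_real_),
    offer_value_B_AB = ifelse(ab, vB, NA_real_),
    offer_value_B_BA = ifelse(!ab, vB, NA_real_),
    offer_value_1 = ifelse(ab, vA, vB),
    offer_value_2 = ifelse(ab, vB, vA),
    chosen_value_A = ifelse(chA, vA, NA_real_),
    chosen_value_B = ifelse(!chA, vB, NA_real_),
    stop("unknown variable: ", variable)
  )
}

#' Regress a neuronal response on a decision variable
#'
#' Ordinary least squares of the trial-type mean firing rates on the
#' variable. If the slope differs significantly from zero (p < alpha) the
#' variable "explains" the response and the signed R2 is
#' sR2 = sign(b1) * R2; otherwise sR2 = 0.
#'
#' @param response a `neuronal_response` (or its `$types` table).
#' @param variable variable name, see [eval_variable()].
#' @param rho session relative value.
#' @param alpha slope significance threshold (default 0.05).
#' @return list `b0`, `b1`, `p`, `r2`, `sr2`, `n_types`.
#' @export
regress_response <- function(response, variable, rho, alpha = 0.05) {
  types <- if (inherits(response, "neuronal_response")) response$types
           else response
  x <- eval_variable(types, variable, rho)
  y <- types$mean_rate
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3 || length(unique(x)) < 2) {
    sc_log("regress_response: degenerate regressor '", variable,
           "' (sR2 set to 0)", level = "WARN")
    return(list(b0 = NA_real_, b1 = NA_real_, p = NA_real_,
                r2 = NA_real_, sr2 = 0, n_types = length(x)))
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  b <- stats::coef(fit)
  p <- sm$coefficients["x", "Pr(>|t|)"]
  r2 <- sm$r.squared
  sr2 <- if (!is.na(p) && p < alpha) sign(b[["x"]]) * r2 else 0
  list(b0 = b[["(Intercept)"]], b1 = b[["x"]], p = p, r2 = r2, sr2 = sr2,
       n_types = length(x))
}

TASK1_VARIABLES <- c("offer_value_A", "offer_value_B", "chosen_juice",
                     "chosen_value")

# The eight Task-2 variable sequences: for each class, the window-specific
# variable and its predicted sign in post-offer1 / post-offer2 / post-juice.
task2_sequences <- function() {
  seqs <- list(
    "offer_value_A+" = list(
      post_offer1 = c("offer_value_A_AB", 1),
      post_offer2 = c("offer_value_A_BA", 1),
      post_juice = c("chosen_value_A", 1)),
    "offer_value_A-" = list(
      post_offer1 = c("offer_value_A_AB", -1),
      post_offer2 = c("offer_value_A_BA", -1),
      post_juice = c("chosen_value_A", -1)),
    "offer_value_B+" = list(
      post_offer1 = c("offer_value_B_BA", 1),
      post_offer2 = c("offer_value_B_AB", 1),
      post_juice = c("chosen_value_B", 1)),
    "offer_value_B-" = list(
      post_offer1 = c("offer_value_B_BA", -1),
      post_offer2 = c("offer_value_B_AB", -1),
      post_juice = c("chosen_value_B", -1)),
    "chosen_juice_A" = list(
      post_offer1 = c("ab_ba", 1),
      post_offer2 = c("ab_ba", -1),
      post_juice = c("chosen_juice", 1)),
    "chosen_juice_B" = list(
      post_offer1 = c("ab_ba", -1),
      post_offer2 = c("ab_ba", 1),
      post_juice = c("chosen_juice", -1)),
    "chosen_value+" = list(
      post_offer1 = c("offer_value_1", 1),
      post_offer2 = c("offer_value_2", 1),
      post_juice = c("chosen_value", 1)),
    "chosen_value-" = list(
      post_offer1 = c("offer_value_1", -1),
      post_offer2 = c("offer_value_2", -1),
      post_juice = c("chosen_value", -1))
  )
  seqs
}

# Candidate classes in deterministic tie-break priority order.
CLASS_CANDIDATES <- c("offer_value_A+", "offer_value_A-", "offer_value_B+",
                      "offer_value_B-", "chosen_juice_A", "chosen_juice_B",
                      "chosen_value+", "chosen_value-")

#' Classify a cell from its Task-1 responses
#'
#' For each of the four decision variables, sums the signed R2 across the
#' four Task-1 time windows; the cell is assigned to the variable and sign
#' with the maximum absolute sum. Cells with all sums equal to zero are
#' untuned.
#'
#' @param session a `choice_session` with spikes.
#' @param cell_id cell to classify.
#' @param rho session relative value (e.g. from the Task-1 probit fit).
#' @param config an [sc_config()].
#' @return list: `sums` (named per variable), `scores` (aligned score per
#'   class candidate, positive = consistent encoding), `class`, `untuned`.
#' @export
classify_task1 <- function(session, cell_id, rho, config = sc_config()) {
  sums <- stats::setNames(numeric(length(TASK1_VARIABLES)), TASK1_VARIABLES)
  for (wname in names(config$windows_task1)) {
    resp <- compute_response(session, cell_id, "task1", wname, config)
    for (v in TASK1_VARIABLES) {
      sums[v] <- sums[v] +
        regress_response(resp, v, rho, config$tuning_alpha)$sr2
    }
  }
  # aligned score per candidate: positive when the cell encodes that
  # class's variable with that class's sign
  scores <- c(
    "offer_value_A+" = sums[["offer_value_A"]],
    "offer_value_A-" = -sums[["offer_value_A"]],
    "offer_value_B+" = sums[["offer_value_B"]],
    "offer_value_B-" = -sums[["offer_value_B"]],
    "chosen_juice_A" = sums[["chosen_juice"]],
    "chosen_juice_B" = -sums[["chosen_juice"]],
    "chosen_value+" = sums[["chosen_value"]],
    "chosen_value-" = -sums[["chosen_value"]]
  )
  list(sums = sums, scores = scores,
       class = pick_class(scores), untuned = all(scores <= 0))
}

pick_class <- function(scores) {
  if (all(scores <= 0)) return("untuned")
  best <- max(scores)
  cand <- names(scores)[scores == best]
  if (length(cand) > 1) {
    cand <- CLASS_CANDIDATES[CLASS_CANDIDATES %in% cand][1]
    sc_log("classification tie broken by priority order -> ", cand,
           level = "WARN")
  }
  cand[1]
}

#' Classify a cell from its Task-2 responses
#'
#' For each of the eight variable sequences, regresses each window's
#' response on that sequence's window-specific variable and accumulates the
#' sign-aligned signed R2 (a window encoding the predicted variable with
#' the predicted sign adds positively; contradictory encoding subtracts).
#' The cell is assigned to the sequence with the maximum positive score.
#'
#' @inheritParams classify_task1
#' @return list: `scores` per sequence/class, `class`, `untuned`.
#' @export
classify_task2 <- function(session, cell_id, rho, config = sc_config()) {
  seqs <- task2_sequences()
  resps <- lapply(names(config$windows_task2), function(w) {
    compute_response(session, cell_id, "task2", w, config)
  })
  names(resps) <- names(config$windows_task2)
  # cache regressions: each (window, variable) pair used by any sequence
  cache <- new.env(parent = emptyenv())
  get_sr2 <- function(w, v) {
    key <- paste(w, v)
    if (is.null(cache[[key]])) {
      cache[[key]] <- regress_response(resps[[w]], v, rho,
                                       config$tuning_alpha)$sr2
    }
    cache[[key]]
  }
  scores <- vapply(seqs, function(sq) {
    sum(vapply(names(sq), function(w) {
      v <- sq[[w]][1]
      pred_sign <- as.numeric(sq[[w]][2])
      get_sr2(w, v) * pred_sign
    }, numeric(1)))
  }, numeric(1))
  list(scores = scores, class = pick_class(scores),
       untuned = all(scores <= 0))
}

#' Joint classification across both tasks
#'
#' Adds the Task-1 aligned score and the Task-2 sequence score of each
#' class candidate (the Table-correspondence pairing of Task-1 variables
#' with Task-2 sequences) and assigns the candidate with the maximum
#' positive final score.
#'
#' @inheritParams classify_task1
#' @return list with per-task results (`task1`, `task2`), `final_scores`,
#'   `class`, `untuned`.
#' @export
classify_joint <- function(session, cell_id, rho, config = sc_config()) {
  c1 <- classify_task1(session, cell_id, rho, config)
  c2 <- classify_task2(session, cell_id, rho, config)
  final <- c1$scores[CLASS_CANDIDATES] + c2$scores[CLASS_CANDIDATES]
  names(final) <- CLASS_CANDIDATES
  list(task1 = c1, task2 = c2, final_scores = final,
       class = pick_class(final), untuned = all(final <= 0))
}

#' Classify all cells of a session
#'
#' Runs the ANOVA screen and, for task-related cells, the joint
#' classification. Non-task-related cells are reported as such and not
#' classified.
#'
#' @param session a `choice_session` with spikes.
#' @param rho session relative value.
#' @param config an [sc_config()].
#' @return data.frame: cell_id, task_related, class (NA when not
#'   task-related), per-task classes, max final score.
#' @export
classify_session <- function(session, rho, config = sc_config()) {
  cells <- session$cells$cell_id
  rows <- lapply(cells, function(cid) {
    scr <- anova_screen(session, cid, config)
    if (!scr$task_related) {
      sc_log("cell ", cid, " not task-related; excluded from classification")
      return(data.frame(cell_id = cid, task_related = FALSE,
                        class = NA_character_, class_task1 = NA_character_,
                        class_task2 = NA_character_, final_score = NA_real_,
                        stringsAsFactors = FALSE))
    }
    j <- classify_joint(session, cid, rho, config)
    data.frame(cell_id = cid, task_related = TRUE, class = j$class,
               class_task1 = j$task1$class, class_task2 = j$task2$class,
               final_score = max(j$final_scores),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
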