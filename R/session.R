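#' Session objects
#'
#' A `choice_session` bundles the trial list for one experimental day (both
#' tasks interleaved), the spike times of simultaneously recorded cells, and
#' the session metadata. By convention juice A is the preferred juice.
#'
#' Components:
#' \describe{
#'   \item{session_id}{character scalar.}
#'   \item{juice_A, juice_B}{juice labels.}
#'   \item{quantum_uL}{juice volume per quantum (square), microliters.}
#'   \item{offer_types}{data.frame with integer columns `qA`, `qB`.}
#'   \item{trials}{data.frame, one row per trial: `trial_id`, `task`
#'     ("task1"/"task2"), `qA`, `qB`, `order` ("AB"/"BA"/"none"),
#'     `choice` ("A"/"B"), and event-time columns `t_<event>` in seconds on
#'     a per-trial clock starting at initial fixation (task 1: `offer_on`,
#'     `go`, `juice`; task 2: `offer1_on`, `offer1_off`, `offer2_on`,
#'     `offer2_off`, `targets_on`, `go`, `juice`), plus `t_end`.}
#'   \item{spikes}{data.frame `trial_id`, `cell_id`, `time` (seconds, same
#'     clock), sorted within trial and cell.}
#'   \item{cells}{data.frame `cell_id` plus optional ground-truth columns
#'     for synthetic data.}
#'   \item{truth}{optional list of generator ground truth (synthetic data).}
#' }
#'
#' @param session_id,juice_A,juice_B,quantum_uL,offer_types,trials,spikes,cells,truth
#'   see description.
#' @return a validated `choice_session`.
#' @export
choice_session <- function(session_id, juice_A = "A", juice_B = "B",
                           quantum_uL = 85, offer_types, trials,
                           spikes = NULL, cells = NULL, truth = NULL) {
  if (is.null(spikes)) {
    spikes <- data.frame(trial_id = integer(), cell_id = character(),
                         time = numeric())
  }
  if (is.null(cells)) {
    cells <- data.frame(cell_id = unique(spikes$cell_id))
  }
  s <- structure(
    list(session_id = as.character(session_id), juice_A = juice_A,
         juice_B = juice_B, quantum_uL = quantum_uL,
         offer_types = offer_types, trials = trials, spikes = spikes,
         cells = cells, truth = truth),
    class = "choice_session")
  validate_session(s)
  s
}

TASK1_EVENTS <- c("offer_on", "go", "juice")
TASK2_EVENTS <- c("offer1_on", "offer1_off", "offer2_on", "offer2_off",
                  "targets_on", "go", "juice")

#' Validate a session against the schema invariants
#'
#' Checks that every trial's offer type appears in the session's offer-type
#' set, that `order` is populated exactly for task-2 trials, that event
#' times are strictly increasing in task order, and that spike times are
#' sorted within trial and cell.
#'
#' @param session a `choice_session`.
#' @param auto_sort if `TRUE`, unsorted spikes are sorted (with a log
#'   message) instead of raising a validation error.
#' @return the (possibly spike-sorted) session, invisibly on success.
#' @export
validate_session <- function(session, auto_sort = FALSE) {
  tr <- session$trials
  req <- c("trial_id", "task", "qA", "qB", "order", "choice")
  miss <- setdiff(req, names(tr))
  if (length(miss)) {
    stop("schema error: trials missing columns ", paste(miss, collapse = ", "))
  }
  if (nrow(tr) < 1) stop("session must contain at least one trial")
  if (anyDuplicated(tr$trial_id)) stop("duplicate trial_id")
  if (!all(tr$task %in% c("task1", "task2"))) {
    stop("validation error: task must be task1 or task2")
  }
  bad <- which((tr$task == "task1") != (tr$order == "none"))
  if (length(bad)) {
    stop("validation error: order must be 'none' iff task1 (trial rows ",
         paste(utils::head(bad, 5), collapse = ", "), ")")
  }
  if (!all(tr$order %in% c("AB", "BA", "none"))) {
    stop("validation error: bad order value")
  }
  if (!all(tr$choice %in% c("A", "B"))) {
    stop("validation error: bad choice value")
  }
  key <- paste(tr$qA, tr$qB)
  okey <- paste(session$offer_types$qA, session$offer_types$qB)
  if (!all(key %in% okey)) {
    stop("validation error: trial offer type absent from offer_types")
  }
  if (any(tr$qA == 0 & tr$qB == 0)) {
    stop("validation error: null offer type [0, 0]")
  }
  forced <- tr$qA == 0 | tr$qB == 0
  wrong <- forced & ((tr$qA == 0 & tr$choice == "A") |
                     (tr$qB == 0 & tr$choice == "B"))
  if (any(wrong)) {
    stop("validation error: forced-choice trial with null choice")
  }
  for (task in c("task1", "task2")) {
    evs <- if (task == "task1") TASK1_EVENTS else TASK2_EVENTS
    cols <- paste0("t_", evs)
    rows <- tr$task == task
    if (!any(rows)) next
    miss <- setdiff(cols, names(tr))
    if (length(miss)) {
      stop("schema error: missing event columns ", paste(miss, collapse = ", "))
    }
    m <- as.matrix(tr[rows, cols])
    if (anyNA(m)) stop("validation error: NA event time for ", task)
    if (any(m[, -1, drop = FALSE] <= m[, -ncol(m), drop = FALSE])) {
      stop("validation error: event times not strictly increasing (", task, ")")
    }
  }
  sp <- session$spikes
  if (nrow(sp)) {
    if (!all(sp$trial_id %in% tr$trial_id)) {
      stop("validation error: spike with unknown trial_id")
    }
    o <- order(sp$cell_id, sp$trial_id, sp$time)
    sorted <- all(tapply(sp$time, paste(sp$cell_id, sp$trial_id),
                         function(x) !is.unsorted(x)))
    if (!sorted) {
      if (auto_sort) {
        session$spikes <- sp[o, , drop = FALSE]
        sc_log("spikes were unsorted; auto-sorted", level = "WARN")
      } else {
        stop("validation error: spikes not sorted (use auto_sort = TRUE)")
      }
    }
  }
  invisible(session)
}

#' @export
print.choice_session <- function(x, ...) {
  tr <- x$trials
  cat("choice_session ", x$session_id, ": ",
      sum(tr$task == "task1"), " task-1 + ",
      sum(tr$task == "task2"), " task-2 trials, ",
      nrow(x$offer_types), " offer types, ",
      nrow(x$cells), " cells, ",
      nrow(x$spikes), " spikes\n", sep = "")
  cat("  juices: A=", x$juice_A, " (preferred), B=", x$juice_B,
      "; quantum ", x$quantum_uL, " uL\n", sep = "")
  invisible(x)
}

#' Write a session to a directory
#'
#' Flat, diffable layout: `trials.csv` (one row per trial), `spikes.csv`
#' (long: trial_id, cell_id, spike time), `session.json` (metadata and
#' offer types), `cells.csv`. Times are written with sub-0.1 ms precision
#' so that the round trip through [read_session()] is lossless.
#'
#' @param session a valid `choice_session`.
#' @param path directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  validate_session(session)
  if (nrow(session$trials) == 0) stop("refusing to write an empty trial list")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("unwritable path: ", path)
  tr <- session$trials
  tcols <- grep("^t_", names(tr), value = TRUE)
  tr[tcols] <- lapply(tr[tcols], function(x) round(x, 5))
  utils::write.csv(tr, file.path(path, "trials.csv"), row.names = FALSE)
  sp <- session$spikes
  sp$time <- round(sp$time, 5)
  utils::write.csv(sp, file.path(path, "spikes.csv"), row.names = FALSE)
  utils::write.csv(session$cells, file.path(path, "cells.csv"),
                   row.names = FALSE)
  meta <- list(session_id = session$session_id, juice_A = session$juice_A,
               juice_B = session$juice_B, quantum_uL = session$quantum_uL,
               offer_types = session$offer_types)
  if (!is.null(session$truth)) meta$truth <- session$truth
  jsonlite::write_json(meta, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a session directory written by [write_session()]
#'
#' @param path session directory.
#' @param auto_sort passed to [validate_session()].
#' @return a `choice_session`.
#' @export
read_session <- function(path, auto_sort = FALSE) {
  for (f in c("trials.csv", "spikes.csv", "session.json")) {
    if (!file.exists(file.path(path, f))) {
      stop("schema error: missing ", f, " in ", path)
    }
  }
  meta <- jsonlite::read_json(file.path(path, "session.json"),
                              simplifyVector = TRUE)
  trials <- utils::read.csv(file.path(path, "trials.csv"),
                            stringsAsFactors = FALSE)
  spikes <- utils::read.csv(file.path(path, "spikes.csv"),
                            stringsAsFactors = FALSE)
  if (nrow(spikes) == 0) {
    spikes <- data.frame(trial_id = integer(), cell_id = character(),
                         time = numeric())
  }
  cells_path <- file.path(path, "cells.csv")
  cells <- if (file.exists(cells_path)) {
    utils::read.csv(cells_path, stringsAsFactors = FALSE)
  } else NULL
  s <- structure(
    list(session_id = meta$session_id, juice_A = meta$juice_A,
         juice_B = meta$juice_B, quantum_uL = meta$quantum_uL,
         offer_types = as.data.frame(meta$offer_types), trials = trials,
         spikes = spikes,
         cells = if (is.null(cells)) data.frame(cell_id = unique(spikes$cell_id)) else cells,
         truth = meta$truth),
    class = "choice_session")
  s <- validate_session(s, auto_sort = auto_sort)
  s
}
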