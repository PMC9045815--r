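#' Behavioral generator parameters
#'
#' Ground-truth parameters of the synthetic choice generator. The defaults
#' emulate a typical recording session: relative value rho around 2.5,
#' steeper sigmoid under simultaneous offers than under sequential offers,
#' a small order bias favoring the second offer, a modest preference bias
#' (task-2 inflation of rho), ~240 task-1 trials and 1.5 times as many
#' task-2 trials (~600 trials total).
#'
#' @param rho_task1 relative value of juice A in units of juice B (> 0).
#' @param eta_task1,eta_task2 sigmoid steepness per task (> 0).
#' @param epsilon order bias in value units of juice B; > 0 favors offer2.
#' @param pref_shift multiplicative task-2 shift of rho (preference bias);
#'   rho_task2 = pref_shift * rho_task1.
#' @param offer_types data.frame of integer `qA`, `qB` quantities; must
#'   contain forced (one quantity 0) and split-choice types.
#' @param n_trials_task1 number of task-1 trials.
#' @param task2_trial_ratio task-2 trials per task-1 trial (default 1.5).
#' @return a `behavior_params` list.
#' @export
behavior_params <- function(rho_task1 = 2.5, eta_task1 = 4, eta_task2 = 2.5,
                            epsilon = 0.3, pref_shift = 1.1,
                            offer_types = default_offer_types(),
                            n_trials_task1 = 240, task2_trial_ratio = 1.5) {
  stopifnot(rho_task1 > 0, eta_task1 > 0, eta_task2 > 0, pref_shift > 0,
            n_trials_task1 >= 1, task2_trial_ratio > 0)
  if (any(offer_types$qA == 0 & offer_types$qB == 0)) {
    stop("offer type [0, 0] rejected")
  }
  has_forced <- any(offer_types$qA == 0 | offer_types$qB == 0)
  has_split <- any(offer_types$qA > 0 & offer_types$qB > 0)
  if (!has_forced || !has_split) {
    stop("offer-type set must contain forced and split-choice types")
  }
  structure(list(rho_task1 = rho_task1, eta_task1 = eta_task1,
                 eta_task2 = eta_task2, epsilon = epsilon,
                 pref_shift = pref_shift, offer_types = offer_types,
                 n_trials_task1 = n_trials_task1,
                 task2_trial_ratio = task2_trial_ratio),
            class = "behavior_params")
}

#' Default offer-type set
#'
#' Ten offer types spanning quantity ratios 1/4 to 6 plus the two forced
#' types, covering indifference points for rho between ~1 and 4.
#' @return data.frame of `qA`, `qB`.
#' @export
default_offer_types <- function() {
  data.frame(
    qA = c(0L, 1L, 1L, 1L, 1L, 1L, 1L, 2L, 3L, 4L),
    qB = c(1L, 0L, 1L, 2L, 3L, 4L, 6L, 1L, 1L, 1L)
  )
}

#' Session-adapted offer-type set
#'
#' Emulates how quantity ranges are chosen in the experiments: offer types
#' are picked so that their log quantity ratios straddle the session's
#' indifference point, guaranteeing split choices on several types. Returns
#' the two forced types plus integer-quantity types whose log(qB/qA) are
#' closest to log(rho) plus a symmetric ladder of offsets.
#'
#' @param rho the session's relative value.
#' @param offsets log-ratio offsets around indifference.
#' @param max_qA,max_qB largest quantities available per juice.
#' @return data.frame of `qA`, `qB`.
#' @export
adaptive_offer_types <- function(rho,
                                 offsets = c(-1.5, -1, -0.6, -0.3, 0,
                                             0.3, 0.6, 1, 1.5),
                                 max_qA = 4, max_qB = 10) {
  stopifnot(rho > 0)
  cand <- expand.grid(qA = seq_len(max_qA), qB = seq_len(max_qB))
  lr <- log(cand$qB / cand$qA)
  pick <- vapply(offsets, function(d) {
    # prefer small quantities among near-equivalent ratios
    which.min(abs(lr - (log(rho) + d)) + 1e-3 * (cand$qA + cand$qB))
  }, integer(1))
  pick <- unique(pick)
  out <- rbind(data.frame(qA = c(0L, 1L), qB = c(1L, 0L)),
               data.frame(qA = as.integer(cand$qA[pick]),
                          qB = as.integer(cand$qB[pick])))
  rownames(out) <- NULL
  out
}

# Trial event-time templates (seconds on the per-trial clock; fixation at 0).
# Task 1: 0.5 s fixation + 0.5 s task cue, offers on at 1.0, go after a
# 1-1.5 s delay, juice 0.75 s after the saccade.
# Task 2: offer1 1.0-1.5, interoffer delay 0.5, offer2 2.0-2.5, wait 0.5,
# targets at 3.0, go after 0.5-1 s, juice 0.75 s later.
make_event_times <- function(task, n, rng_delay) {
  if (task == "task1") {
    offer_on <- rep(1.0, n)
    go <- offer_on + 1.0 + rng_delay(n) * 0.5
    juice <- go + 0.75
    data.frame(t_offer_on = offer_on, t_go = go, t_juice = juice,
               t_offer1_on = NA_real_, t_offer1_off = NA_real_,
               t_offer2_on = NA_real_, t_offer2_off = NA_real_,
               t_targets_on = NA_real_, t_end = juice + 0.6)
  } else {
    o1 <- rep(1.0, n)
    targets <- rep(3.0, n)
    go <- targets + 0.5 + rng_delay(n) * 0.5
    juice <- go + 0.75
    data.frame(t_offer_on = NA_real_, t_go = go, t_juice = juice,
               t_offer1_on = o1, t_offer1_off = o1 + 0.5,
               t_offer2_on = o1 + 1.0, t_offer2_off = o1 + 1.5,
               t_targets_on = targets, t_end = juice + 0.6)
  }
}

#' Generate the choices of one synthetic session
#'
#' Simulates both tasks of one session under the probit choice model.
#' Per trial, P(choice B) = Phi(eta * [log(qB/qA) - log rho_eff] +
#' a4 * (delta_AB - delta_BA)) where rho_eff is rho_task1 in Task 1 and
#' pref_shift * rho_task1 in Task 2, and the order-bias offset is
#' a4 = epsilon * eta_task2 / (2 * rho_task2) — the exact inverse of the
#' order-bias definition, so that the fitted epsilon recovers
#' `params$epsilon` in expectation. Forced choices always take the nonzero
#' offer. Presentation orders are counterbalanced within each offer type and
#' the two tasks are pseudorandomly interleaved.
#'
#' @param params a [behavior_params()] object.
#' @param seed integer RNG seed.
#' @param session_id label for the session.
#' @return a `choice_session` without spikes; the generating truth is kept
#'   in `$truth`.
#' @export
generate_choices <- function(params, seed = 1L, session_id = "synthetic") {
  stopifnot(inherits(params, "behavior_params"))
  set.seed(as.integer(seed))
  ot <- params$offer_types
  n_types <- nrow(ot)
  n1 <- params$n_trials_task1
  n2 <- round(n1 * params$task2_trial_ratio)

  # Balanced repetition of offer types within each task; task-2 orders
  # counterbalanced within offer type.
  idx1 <- rep(seq_len(n_types), length.out = n1)
  idx2 <- rep(seq_len(n_types), length.out = n2)
  t1 <- data.frame(task = "task1", qA = ot$qA[idx1], qB = ot$qB[idx1],
                   order = "none", stringsAsFactors = FALSE)
  grp2 <- split(seq_along(idx2), idx2)
  ord2 <- unlist(lapply(grp2, function(ii) {
    sample(rep(c("AB", "BA"), length.out = length(ii)))
  }), use.names = FALSE)
  t2 <- data.frame(task = "task2", qA = ot$qA[idx2], qB = ot$qB[idx2],
                   order = "none", stringsAsFactors = FALSE)
  t2$order[unlist(grp2, use.names = FALSE)] <- ord2
  tr <- rbind(t1, t2)
  tr <- tr[sample.int(nrow(tr)), , drop = FALSE]   # pseudorandom interleave
  rownames(tr) <- NULL
  tr$trial_id <- seq_len(nrow(tr))

  rho2 <- params$pref_shift * params$rho_task1
  a4 <- params$epsilon * params$eta_task2 / (2 * rho2)
  x <- ifelse(
    tr$task == "task1",
    params$eta_task1 * (log(tr$qB / tr$qA) - log(params$rho_task1)),
    params$eta_task2 * (log(tr$qB / tr$qA) - log(rho2)) +
      a4 * ifelse(tr$order == "AB", 1, -1)
  )
  p_b <- stats::pnorm(x)
  forced <- tr$qA == 0 | tr$qB == 0
  p_b[tr$qA == 0] <- 1
  p_b[tr$qB == 0] <- 0
  tr$choice <- ifelse(stats::runif(nrow(tr)) < p_b, "B", "A")

  ev <- make_event_times("task1", nrow(tr), stats::runif)
  is2 <- tr$task == "task2"
  ev[is2, ] <- make_event_times("task2", sum(is2), stats::runif)
  tr <- cbind(tr, ev)
  tr <- tr[c("trial_id", "task", "qA", "qB", "order", "choice",
             setdiff(names(tr), c("trial_id", "task", "qA", "qB", "order",
                                  "choice")))]

  choice_session(
    session_id = session_id, offer_types = ot, trials = tr,
    truth = list(rho_task1 = params$rho_task1, rho_task2 = rho2,
                 eta_task1 = params$eta_task1, eta_task2 = params$eta_task2,
                 epsilon = params$epsilon, pref_shift = params$pref_shift,
                 a4 = a4, seed = as.integer(seed))
  )
}
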