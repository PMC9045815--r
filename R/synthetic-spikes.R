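#' Cell generator parameters
#'
#' Ground truth for one synthetic neuron. Classes follow the standard OFC
#' taxonomy: offer value A/B (linear in the value of one juice, positive or
#' negative encoding), chosen juice A/B (binary encoding of the choice
#' outcome, plus circuit inhibition and choice-predictive divergence under
#' sequential offers), and chosen value (linear in the value currently on
#' display, then in the chosen value).
#'
#' @param cell_id label.
#' @param cell_class one of "offer_value_A", "offer_value_B",
#'   "chosen_juice_A", "chosen_juice_B", "chosen_value".
#' @param sign +1 or -1 encoding sign (value classes only).
#' @param baseline baseline rate, sp/s (>= 0).
#' @param slope tuning slope, sp/s per value unit (value classes).
#' @param amp binary modulation amplitude, sp/s (chosen juice classes).
#' @param task2_scale multiplicative slope scaling in Task 2 (< 1 emulates
#'   the weaker offer value signals under sequential offers).
#' @param c1_true circuit-inhibition gain, sp/s per normalized offer1 value
#'   (chosen juice cells; negative for inhibition).
#' @param cp_onset onset of choice-predictive divergence, seconds relative
#'   to offer2 onset.
#' @param cp_ramp ramp duration to the divergence plateau, seconds.
#' @param cp_sep plateau separation between traces for the two eventual
#'   choices, sp/s.
#' @param offer2_gain multiplicative gain on offer-period modulation in the
#'   post-offer2 window (1 = no order effect at valuation).
#' @param noise "poisson" (default) or "negbin"; `nb_size` is the
#'   negative-binomial size parameter when used.
#' @param nb_size negative binomial dispersion (counts; smaller = more
#'   overdispersed).
#' @return a `cell_params` list.
#' @export
cell_params <- function(cell_id, cell_class, sign = 1, baseline = 6,
                        slope = 1.5, amp = 6, task2_scale = 0.75,
                        c1_true = -2, cp_onset = 0.05, cp_ramp = 0.3,
                        cp_sep = 8, offer2_gain = 1,
                        noise = c("poisson", "negbin"), nb_size = 10) {
  cell_class <- match.arg(cell_class, c("offer_value_A", "offer_value_B",
                                        "chosen_juice_A", "chosen_juice_B",
                                        "chosen_value"))
  noise <- match.arg(noise)
  stopifnot(baseline >= 0, sign %in% c(-1, 1), task2_scale > 0)
  structure(list(cell_id = as.character(cell_id), cell_class = cell_class,
                 sign = sign, baseline = baseline, slope = slope, amp = amp,
                 task2_scale = task2_scale, c1_true = c1_true,
                 cp_onset = cp_onset, cp_ramp = cp_ramp, cp_sep = cp_sep,
                 offer2_gain = offer2_gain, noise = noise,
                 nb_size = nb_size),
            class = "cell_params")
}

# Offer values in common units (units of juice B): V_A = rho * qA, V_B = qB.
trial_values <- function(trials, rho) {
  va <- rho * trials$qA
  vb <- trials$qB
  ab <- trials$order == "AB"
  list(
    vA = va, vB = vb,
    v_offer1 = ifelse(ab, va, vb),
    v_offer2 = ifelse(ab, vb, va),
    v_chosen = ifelse(trials$choice == "A", va, vb)
  )
}

# Session value range of one juice (used to normalize circuit inhibition).
juice_value_range <- function(session, juice, rho) {
  q <- if (juice == "A") session$trials$qA else session$trials$qB
  v <- if (juice == "A") rho * q else q
  diff(range(v))
}

# Additive rate intervals for one cell across all trials of a session.
# Returns data.frame(trial, t0, t1, dr).
cell_rate_intervals <- function(session, cp, rho1, rho2) {
  tr <- session$trials
  n <- nrow(tr)
  is1 <- tr$task == "task1"
  v1 <- trial_values(tr, rho1)  # task-1 values
  v2 <- trial_values(tr, rho2)  # task-2 values (scenario-dependent rho)
  out <- list()
  add <- function(rows, t0, t1, dr) {
    keep <- rows & !is.na(t0) & !is.na(t1) & dr != 0
    if (!any(keep)) return(invisible(NULL))
    out[[length(out) + 1L]] <<- data.frame(
      trial = which(keep), t0 = t0[keep], t1 = t1[keep], dr = dr[keep])
    invisible(NULL)
  }
  cls <- cp$cell_class
  if (cls %in% c("offer_value_A", "offer_value_B")) {
    juice <- if (cls == "offer_value_A") "A" else "B"
    v_t1 <- if (juice == "A") v1$vA else v1$vB
    v_t2 <- if (juice == "A") v2$vA else v2$vB
    add(is1, tr$t_offer_on, tr$t_offer_on + 1.0, cp$sign * cp$slope * v_t1)
    first <- (tr$order == "AB") == (juice == "A")   # encoded juice is offer1
    s2 <- cp$sign * cp$slope * cp$task2_scale
    # constant offset preserving the mean activity across tasks: the range
    # shrinks by task2_scale but r_mean = b0 + b1*S_max/2 stays put
    s_max2 <- max(v_t2[!is1], 0)
    off2 <- cp$sign * cp$slope * (1 - cp$task2_scale) * s_max2 / 2
    add(!is1 & first, tr$t_offer1_on, tr$t_offer1_off,
        s2 * v_t2 + off2)
    add(!is1 & !first, tr$t_offer2_on, tr$t_offer2_off,
        s2 * cp$offer2_gain * v_t2 + off2)
  } else if (cls == "chosen_value") {
    s <- cp$sign * cp$slope
    add(is1, tr$t_offer_on, tr$t_offer_on + 1.0, s * v1$v_chosen)
    add(is1, tr$t_juice, tr$t_juice + 0.5, s * v1$v_chosen)
    add(!is1, tr$t_offer1_on, tr$t_offer1_off, s * v2$v_offer1)
    add(!is1, tr$t_offer2_on, tr$t_offer2_off,
        s * cp$offer2_gain * v2$v_offer2)
    add(!is1, tr$t_juice, tr$t_juice + 0.5, s * v2$v_chosen)
  } else {  # chosen juice cells
    e <- if (cls == "chosen_juice_A") "A" else "B"
    o <- setdiff(c("A", "B"), e)
    chose_e <- tr$choice == e
    add(is1, tr$t_offer_on, tr$t_offer_on + 1.0, ifelse(chose_e, cp$amp, 0))
    add(is1, tr$t_juice - 0.5, tr$t_juice + 0.5, ifelse(chose_e, cp$amp, 0))
    e_first <- (tr$order == "AB") == (e == "A")
    oe <- !is1 & !e_first                     # OE trials: E is offer2
    add(!is1 & e_first, tr$t_offer1_on, tr$t_offer1_off, rep(cp$amp, n))
    add(oe, tr$t_offer2_on, tr$t_offer2_off, rep(cp$amp, n))
    add(!is1, tr$t_juice, tr$t_juice + 0.5, ifelse(chose_e, cp$amp, 0))
    # circuit inhibition: negative offset proportional to the normalized
    # value of offer1 (the other juice) in OE trials, from offer1 offset
    # until just after offer2 onset
    dv_o <- juice_value_range(session, o, if (o == "A") rho2 else 1)
    v_o <- if (o == "A") rho2 * tr$qA else tr$qB
    if (dv_o > 0) {
      add(oe, tr$t_offer1_off, tr$t_offer2_on + 0.05,
          cp$c1_true * v_o / dv_o)
    }
    # choice-predictive divergence in OE trials: linear ramp from cp_onset
    # (relative to offer2 onset) to a plateau of +/- cp_sep/2 held to juice
    if (cp$cp_sep != 0) {
      n_steps <- 6L
      t_on <- tr$t_offer2_on + cp$cp_onset
      dir <- ifelse(chose_e, 1, -1) * cp$cp_sep / 2
      for (k in seq_len(n_steps)) {
        add(oe, t_on + (k - 1) / n_steps * cp$cp_ramp,
            t_on + k / n_steps * cp$cp_ramp,
            dir * (k - 0.5) / n_steps)
      }
      add(oe, t_on + cp$cp_ramp, tr$t_juice, dir)
    }
  }
  if (!length(out)) {
    return(data.frame(trial = integer(), t0 = numeric(), t1 = numeric(),
                      dr = numeric()))
  }
  do.call(rbind, out)
}

# Draw spikes for one cell given its additive intervals; piecewise-constant
# inhomogeneous point process (Poisson or negative binomial counts).
draw_cell_spikes <- function(session, cp, intervals) {
  tr <- session$trials
  n_clipped <- 0L
  res_t <- vector("list", nrow(tr))
  iv_by_trial <- split(intervals[c("t0", "t1", "dr")], intervals$trial)
  for (i in seq_len(nrow(tr))) {
    t_end <- tr$t_end[i]
    iv <- iv_by_trial[[as.character(i)]]
    if (is.null(iv)) {
      breaks <- c(0, t_end)
      rates <- cp$baseline
    } else {
      iv$t1 <- pmin(iv$t1, t_end)
      iv <- iv[iv$t1 > iv$t0, , drop = FALSE]
      breaks <- sort(unique(c(0, t_end, iv$t0, iv$t1)))
      breaks <- breaks[breaks >= 0 & breaks <= t_end]
      mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
      rates <- cp$baseline + vapply(mids, function(m) {
        sum(iv$dr[iv$t0 <= m & m < iv$t1])
      }, numeric(1))
    }
    neg <- rates < 0
    if (any(neg)) {
      n_clipped <- n_clipped + sum(neg)
      rates[neg] <- 0
    }
    lens <- diff(breaks)
    mu <- rates * lens
    counts <- if (cp$noise == "poisson") {
      stats::rpois(length(mu), mu)
    } else {
      stats::rnbinom(length(mu), mu = mu, size = cp$nb_size)
    }
    if (sum(counts) == 0) {
      res_t[[i]] <- numeric(0)
    } else {
      ts <- stats::runif(sum(counts),
                         rep(breaks[-length(breaks)], counts),
                         rep(breaks[-1], counts))
      res_t[[i]] <- sort(ts)
    }
  }
  if (n_clipped > 0) {
    sc_log("cell ", cp$cell_id, ": ", n_clipped,
           " rate segments clipped at 0", level = "WARN")
  }
  data.frame(
    trial_id = rep(tr$trial_id, lengths(res_t)),
    cell_id = cp$cell_id,
    time = unlist(res_t, use.names = FALSE)
  )
}

#' Attach synthetic spike trains to a session
#'
#' Simulates spike trains for a list of cells given the session's choices.
#' Per trial, each cell's rate is piecewise constant: baseline plus
#' class-specific modulations (see [cell_params()]). Spikes are drawn as an
#' inhomogeneous Poisson process. Under `scenario = 2` (default) the values
#' driving neuronal activity in Task 2 equal the Task-1 values — the
#' preference bias exists only in choices, downstream of valuation. Under
#' `scenario = 1` Task-2 neuronal values are shifted by the generating
#' `pref_shift`, i.e. the bias is injected at the valuation stage.
#'
#' @param session a `choice_session` with choices (e.g. from
#'   [generate_choices()]).
#' @param cells list of [cell_params()] objects.
#' @param seed integer RNG seed.
#' @param scenario 1 or 2 (see above).
#' @return the session with `spikes`, a populated `cells` table and the
#'   cell ground truth appended to `$truth`.
#' @export
generate_spikes <- function(session, cells, seed = 1L, scenario = 2) {
  stopifnot(inherits(session, "choice_session"), scenario %in% c(1, 2))
  if (inherits(cells, "cell_params")) cells <- list(cells)
  set.seed(as.integer(seed))
  rho1 <- session$truth$rho_task1
  if (is.null(rho1)) stop("session has no generating truth; spikes need rho")
  rho2 <- if (scenario == 1) session$truth$rho_task2 else rho1
  sp <- vector("list", length(cells))
  for (j in seq_along(cells)) {
    cp <- cells[[j]]
    iv <- cell_rate_intervals(session, cp, rho1, rho2)
    sp[[j]] <- draw_cell_spikes(session, cp, iv)
  }
  session$spikes <- do.call(rbind, sp)
  session$cells <- data.frame(
    cell_id = vapply(cells, `[[`, character(1), "cell_id"),
    true_class = vapply(cells, `[[`, character(1), "cell_class"),
    sign = vapply(cells, `[[`, numeric(1), "sign"),
    baseline = vapply(cells, `[[`, numeric(1), "baseline"),
    slope = vapply(cells, `[[`, numeric(1), "slope"),
    task2_scale = vapply(cells, `[[`, numeric(1), "task2_scale"),
    c1_true = vapply(cells, `[[`, numeric(1), "c1_true"),
    cp_sep = vapply(cells, `[[`, numeric(1), "cp_sep"),
    stringsAsFactors = FALSE
  )
  session$truth$scenario <- scenario
  session$truth$cells <- session$cells
  validate_session(session)
  session
}

#' Generate a synthetic population of sessions
#'
#' Draws per-session behavioral parameters from uniform ranges, generates
#' choices and spike trains, and (optionally) writes each session plus a
#' `ground_truth.json` manifest to disk. With a fixed seed the output is
#' fully deterministic.
#'
#' @param n_sessions number of sessions.
#' @param cell_plan data.frame with columns `cell_class` and `sign`
#'   describing the cells recorded in every session; default one offer
#'   value cell per juice, one chosen juice cell per juice and one chosen
#'   value cell, all positive.
#' @param rho_range,eta1_range,eta2_range,epsilon_range uniform ranges for
#'   the session-level behavioral parameters.
#' @param pref_shift task-2 preference-bias shift (common to all sessions).
#' @param n_trials_task1 task-1 trials per session.
#' @param scenario passed to [generate_spikes()].
#' @param seed integer RNG seed.
#' @param out_dir if non-NULL, sessions are written here (one directory
#'   each) together with `ground_truth.json`.
#' @param cell_args named list of overrides passed to [cell_params()].
#' @param spikes if `FALSE`, only choices are generated (fast).
#' @return list with `sessions` (list of `choice_session`) and `manifest`
#'   (data.frame, one row per cell with its session's truth).
#' @export
generate_population <- function(n_sessions,
                                cell_plan = default_cell_plan(),
                                rho_range = c(1, 4),
                                eta1_range = c(3, 6),
                                eta2_range = c(1.5, 4),
                                epsilon_range = c(-0.1, 0.5),
                                pref_shift = 1.1,
                                n_trials_task1 = 240,
                                scenario = 2,
                                seed = 1L,
                                out_dir = NULL,
                                cell_args = list(),
                                spikes = TRUE) {
  set.seed(as.integer(seed))
  draws <- data.frame(
    rho = stats::runif(n_sessions, rho_range[1], rho_range[2]),
    eta1 = stats::runif(n_sessions, eta1_range[1], eta1_range[2]),
    eta2 = stats::runif(n_sessions, eta2_range[1], eta2_range[2]),
    epsilon = stats::runif(n_sessions, epsilon_range[1], epsilon_range[2]),
    seed_choices = sample.int(.Machine$integer.max %/% 2, n_sessions),
    seed_spikes = sample.int(.Machine$integer.max %/% 2, n_sessions)
  )
  sessions <- vector("list", n_sessions)
  manifest <- list()
  for (i in seq_len(n_sessions)) {
    sid <- sprintf("S%03d", i)
    bp <- behavior_params(rho_task1 = draws$rho[i], eta_task1 = draws$eta1[i],
                          eta_task2 = draws$eta2[i],
                          epsilon = draws$epsilon[i],
                          pref_shift = pref_shift,
                          offer_types = adaptive_offer_types(draws$rho[i]),
                          n_trials_task1 = n_trials_task1)
    s <- generate_choices(bp, seed = draws$seed_choices[i], session_id = sid)
    if (spikes && nrow(cell_plan)) {
      cl <- lapply(seq_len(nrow(cell_plan)), function(j) {
        args <- c(list(cell_id = sprintf("%s_c%02d", sid, j),
                       cell_class = cell_plan$cell_class[j],
                       sign = cell_plan$sign[j]),
                  cell_args)
        if (cell_plan$sign[j] < 0 && is.null(cell_args$baseline) &&
            cell_plan$cell_class[j] %in%
              c("offer_value_A", "offer_value_B", "chosen_value")) {
          # negative-encoding cells fire most at zero value; raise baseline
          # above slope * session value range so the rate never clips at 0
          v_max <- max(draws$rho[i] * bp$offer_types$qA, bp$offer_types$qB)
          slope_j <- if (is.null(cell_args$slope)) 1.5 else cell_args$slope
          args$baseline <- 6 + slope_j * v_max
        }
        do.call(cell_params, args)
      })
      s <- generate_spikes(s, cl, seed = draws$seed_spikes[i],
                           scenario = scenario)
      mf <- s$cells
      mf$session_id <- sid
    } else {
      mf <- data.frame(session_id = character(0))
    }
    mf2 <- if (nrow(mf)) mf else data.frame(session_id = sid)
    mf2$rho_task1 <- draws$rho[i]
    mf2$rho_task2 <- draws$rho[i] * pref_shift
    mf2$eta_task1 <- draws$eta1[i]
    mf2$eta_task2 <- draws$eta2[i]
    mf2$epsilon <- draws$epsilon[i]
    manifest[[i]] <- mf2
    sessions[[i]] <- s
    if (!is.null(out_dir)) write_session(s, file.path(out_dir, sid))
  }
  manifest <- do.call(rbind, manifest)
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "ground_truth.json"),
                         dataframe = "rows", digits = NA, pretty = TRUE)
  }
  list(sessions = sessions, manifest = manifest)
}

#' @rdname generate_population
#' @export
default_cell_plan <- function() {
  data.frame(
    cell_class = c("offer_value_A", "offer_value_B", "chosen_juice_A",
                   "chosen_juice_B", "chosen_value"),
    sign = c(1, 1, 1, 1, 1),
    stringsAsFactors = FALSE
  )
}
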