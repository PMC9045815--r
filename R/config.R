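#' Analysis configuration
#'
#' Returns the full set of analysis constants. All defaults mirror the
#' experimental conventions for this paradigm, so an unmodified
#' configuration reproduces the reference analysis settings:
#' time windows of 0.5 s anchored at task events, an ANOVA screen at
#' p < 0.01, tuning significance at p < 0.05, a causal postsynaptic-
#' potential kernel with a 20 ms decay, a 300 ms circuit-inhibition window
#' starting 250 ms before the second offer, a 100 ms / 25 ms sliding grid
#' for choice probability plus four fixed 250 ms windows, and a 1.5x IQR
#' outlier rule with type-7 quantiles.
#'
#' Each time window is a list `(event, start, end)`: the window spans
#' `[t_event + start, t_event + end)` on the trial clock.
#'
#' @param ... named overrides for any top-level field.
#' @return an object of class `sc_config` (a named list).
#' @examples
#' cfg <- sc_config()
#' cfg$windows_task1$post_offer
#' @export
sc_config <- function(...) {
  cfg <- list(
    windows_task1 = list(
      post_offer = list(event = "offer_on", start = 0, end = 0.5),
      late_delay = list(event = "offer_on", start = 0.5, end = 1.0),
      pre_juice  = list(event = "juice", start = -0.5, end = 0),
      post_juice = list(event = "juice", start = 0, end = 0.5)
    ),
    windows_task2 = list(
      post_offer1 = list(event = "offer1_on", start = 0, end = 0.5),
      post_offer2 = list(event = "offer2_on", start = 0, end = 0.5),
      post_juice  = list(event = "juice", start = 0, end = 0.5)
    ),
    anova_alpha = 0.01,
    tuning_alpha = 0.05,
    kernel_tau = 0.020,
    ci_window = list(event = "offer2_on", start = -0.250, end = 0.050),
    cp_sliding = list(width = 0.100, step = 0.025),
    cp_windows = list(
      pre_offer1  = list(event = "offer1_on", start = -0.250, end = 0),
      late_offer2 = list(event = "offer2_off", start = -0.250, end = 0),
      early_wait  = list(event = "offer2_off", start = 0, end = 0.250),
      pre_juice   = list(event = "juice", start = -0.250, end = 0)
    ),
    iqr_multiplier = 1.5,
    quantile_type = 7,
    min_theta_t = 0,
    seed = NULL
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "sc_config")
}

validate_config <- function(cfg) {
  all_windows <- c(cfg$windows_task1, cfg$windows_task2,
                   list(cfg$ci_window), cfg$cp_windows)
  for (w in all_windows) {
    if (w$end <= w$start) stop("config window with non-positive length")
  }
  stopifnot(
    cfg$anova_alpha > 0, cfg$anova_alpha < 1,
    cfg$tuning_alpha > 0, cfg$tuning_alpha < 1,
    cfg$kernel_tau > 0,
    cfg$cp_sliding$width > 0, cfg$cp_sliding$step > 0,
    cfg$iqr_multiplier > 0
  )
  invisible(cfg)
}

#' Read a configuration from a JSON or YAML file
#'
#' Fields present in the file override the defaults of [sc_config()]; an
#' empty file reproduces the reference settings.
#'
#' @param path a `.json`, `.yaml` or `.yml` file.
#' @return an `sc_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("yaml package required to read YAML configs")
    }
    over <- yaml::read_yaml(path)
  } else {
    over <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(over)) over <- list()
  do.call(sc_config, over)
}

#' @export
print.sc_config <- function(x, ...) {
  cat("seqchoice analysis configuration\n")
  cat("  task 1 windows:", paste(names(x$windows_task1), collapse = ", "), "\n")
  cat("  task 2 windows:", paste(names(x$windows_task2), collapse = ", "), "\n")
  cat("  ANOVA screen alpha:", x$anova_alpha,
      " tuning alpha:", x$tuning_alpha, "\n")
  cat("  PSP kernel tau:", x$kernel_tau, "s\n")
  cat("  circuit-inhibition window:", x$ci_window$start, "to",
      x$ci_window$end, "s from", x$ci_window$event, "\n")
  cat("  CP sliding:", x$cp_sliding$width, "s width /",
      x$cp_sliding$step, "s step\n")
  invisible(x)
}
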