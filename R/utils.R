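#' @keywords internal
"_PACKAGE"

#' Package logging
#'
#' Writes a time-stamped message to standard error. Controlled by
#' `options(seqchoice.verbose = )`; exclusions and stage failures are always
#' reported through this channel so that pipeline runs are auditable.
#'
#' @param ... pieces pasted into the message.
#' @param level one of "INFO", "WARN", "ERROR".
#' @return invisibly, the message string.
#' @export
sc_log <- function(..., level = "INFO") {
  msg <- paste0("[", level, "] ", paste0(..., collapse = ""))
  if (isTRUE(getOption("seqchoice.verbose", TRUE))) {
    message(msg)
  }
  invisible(msg)
}

#' Tukey interquartile outlier filter
#'
#' Flags values below Q1 - multiplier*IQR or above Q3 + multiplier*IQR as
#' outliers. Quartiles use linear-interpolation quantiles (type 7) unless
#' another type is requested. A degenerate sample with IQR = 0 excludes
#' nothing.
#'
#' @param values numeric vector (length >= 4).
#' @param multiplier the IQR multiplier, default 1.5.
#' @param type quantile algorithm passed to [stats::quantile()].
#' @return logical keep-mask the same length as `values`; `NA` values are
#'   never kept.
#' @export
iqr_filter <- function(values, multiplier = 1.5, type = 7) {
  if (length(values) < 4) {
    stop("iqr_filter requires at least 4 values")
  }
  ok <- !is.na(values)
  q <- stats::quantile(values[ok], c(0.25, 0.75), type = type, names = FALSE)
  iqr <- q[2] - q[1]
  if (iqr == 0) {
    return(ok)
  }
  keep <- ok & values >= q[1] - multiplier * iqr &
    values <= q[2] + multiplier * iqr
  keep[is.na(keep)] <- FALSE
  keep
}

#' Deming regression
#'
#' Errors-in-variables straight line assuming a ratio `lambda` of the error
#' variances on the two axes (default 1, i.e. equal noise on x and y).
#'
#' @param x,y numeric vectors.
#' @param lambda ratio var(error y) / var(error x).
#' @return list with `slope` and `intercept`.
#' @export
deming_regression <- function(x, y, lambda = 1) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("deming_regression needs >= 3 finite points")
  mx <- mean(x); my <- mean(y)
  sxx <- mean((x - mx)^2)
  syy <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  if (sxy == 0) stop("deming_regression: zero covariance")
  slope <- (syy - lambda * sxx +
    sqrt((syy - lambda * sxx)^2 + 4 * lambda * sxy^2)) / (2 * sxy)
  list(slope = slope, intercept = my - slope * mx)
}

#' ROC area under the curve for two spike-count samples
#'
#' AUC of the ideal-observer ROC comparing two distributions of (integer)
#' spike counts, computed through the rank-sum identity AUC = U / (n1*n2)
#' with midrank handling of ties (a tied pair counts 0.5).
#'
#' @param x counts in the reference class (AUC < 0.5 when `x` tends larger).
#' @param y counts in the comparison class (AUC > 0.5 when `y` tends larger).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("roc_auc: both samples must be non-empty")
  r <- rank(c(x, y))
  u <- sum(r[(n1 + 1L):(n1 + n2)]) - n2 * (n2 + 1) / 2
  u / (n1 * n2)
}

# Delta-method standard error of g(coef) from a fitted model's vcov,
# with a numerically differentiated gradient.
delta_method_se <- function(g, coef, vcov, eps = 1e-6) {
  k <- length(coef)
  grad <- numeric(k)
  for (i in seq_len(k)) {
    h <- eps * max(1, abs(coef[i]))
    up <- coef; up[i] <- up[i] + h
    dn <- coef; dn[i] <- dn[i] - h
    grad[i] <- (g(up) - g(dn)) / (2 * h)
  }
  sqrt(drop(t(grad) %*% vcov %*% grad))
}

# Correlation pair (Pearson + Spearman) with p-values, as a one-row data.frame.
cor_both <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("cor_both needs >= 3 finite pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("cor_both: constant input, correlation undefined")
  }
  p <- stats::cor.test(x, y, method = "pearson")
  s <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  data.frame(
    n = length(x),
    pearson_r = unname(p$estimate), pearson_p = p$p.value,
    spearman_r = unname(s$estimate), spearman_p = s$p.value
  )
}
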