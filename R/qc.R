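#' Shewhart control limits for a QC series
#'
#' Estimates the chart centre (mean) and standard deviation (sample SD,
#' denominator n - 1) of an in-control pooled-serum measurement series, and
#' the +/- 1, 2, 3 SD control limits.
#'
#' @param values Numeric vector of control measurements (>= 10 unless
#'   reference limits are supplied elsewhere).
#' @return List with `center`, `sd` and `limits` (named numeric vector at
#'   -3s..-1s, center, 1s..3s).
#' @export
shewhart_limits <- function(values) {
  if (length(values) < 10) stop("need >= 10 control values", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0) stop("constant control series: SD is zero", call. = FALSE)
  center <- mean(values)
  limits <- center + c(-3, -2, -1, 0, 1, 2, 3) * s
  names(limits) <- c("-3s", "-2s", "-1s", "center", "+1s", "+2s", "+3s")
  list(center = center, sd = s, limits = limits)
}

#' Apply Westgard multi-rules to a control series
#'
#' Evaluates the four within-run Westgard rules on z-scores
#' `z_i = (value_i - center) / sd`:
#' \describe{
#'   \item{1:3s}{one point beyond 3 SD: `|z_i| > 3`}
#'   \item{2:2s}{two consecutive points beyond 2 SD on the same side}
#'   \item{4:1s}{four consecutive points beyond 1 SD on the same side}
#'   \item{10x}{ten consecutive points strictly on one side of the centre}
#' }
#' Each violation is reported at the index of the point completing the run.
#'
#' @param values Control measurements in run order.
#' @param center,sd Chart parameters (from [shewhart_limits()] or reference).
#' @return Data.frame with columns `rule` and `index` (1-based); zero rows if
#'   nothing fires.
#' @export
apply_westgard <- function(values, center, sd) {
  if (sd <= 0) stop("sd must be > 0", call. = FALSE)
  z <- (values - center) / sd
  n <- length(z)
  rules <- character(0)
  idx <- integer(0)
  flag <- function(rule, i) {
    rules <<- c(rules, rule)
    idx <<- c(idx, i)
  }
  run_same_side <- function(zs, lim, len, i) {
    i >= len && (all(zs[(i - len + 1):i] > lim) ||
                 all(zs[(i - len + 1):i] < -lim))
  }
  for (i in seq_len(n)) {
    if (abs(z[i]) > 3) flag("1:3s", i)
    if (run_same_side(z, 2, 2L, i)) flag("2:2s", i)
    if (run_same_side(z, 1, 4L, i)) flag("4:1s", i)
    if (run_same_side(z, 0, 10L, i)) flag("10x", i)
  }
  data.frame(rule = rules, index = idx, stringsAsFactors = FALSE)
}

#' Build a QC series object with limits and violations
#'
#' Convenience wrapper combining [shewhart_limits()] and [apply_westgard()].
#' The charted metric is whatever scalar is supplied per control run; the
#' pipeline charts the spectrum total ion current of the pooled-serum spot.
#'
#' @param values Control measurements in run order.
#' @param center,sd Optional externally supplied reference limits; estimated
#'   from `values` when omitted.
#' @return Object of class `qc_series`: list with `values`, `center`, `sd`,
#'   `limits`, `z`, `violations`.
#' @export
qc_series <- function(values, center = NULL, sd = NULL) {
  if (is.null(center) || is.null(sd)) {
    lim <- shewhart_limits(values)
    center <- lim$center
    sd <- lim$sd
    limits <- lim$limits
  } else {
    limits <- center + c(-3, -2, -1, 0, 1, 2, 3) * sd
    names(limits) <- c("-3s", "-2s", "-1s", "center", "+1s", "+2s", "+3s")
  }
  structure(list(values = values, center = center, sd = sd, limits = limits,
                 z = (values - center) / sd,
                 violations = apply_westgard(values, center, sd)),
            class = "qc_series")
}

#' @export
print.qc_series <- function(x, ...) {
  cat(sprintf("<qc_series> %d runs, center %.3g, sd %.3g, %d violation(s)\n",
              length(x$values), x$center, x$sd, nrow(x$violations)))
  if (nrow(x$violations)) print(x$violations)
  invisible(x)
}
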