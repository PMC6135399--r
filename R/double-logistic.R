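# The double-logistic growth/senescence model. On a thermal-time axis t
# (accumulated degree days), a growth logistic with inflection S and rate
# m_S is summed with a senescence logistic with inflection A and rate m_A,
# scaled between two asymptote parameters:
#
#   y(t) = y_min + (y_max - y_min) *
#          [ 1/(1 + exp(-m_S (t - S))) + 1/(1 + exp(m_A (t - A))) ]
#
# The asymptote parameters are empirical: published fits for chia carry
# y_min well below zero with y_max of similar magnitude, so no sign or
# ordering constraint is imposed.

dl_names <- c("y_min", "y_max", "m_s", "s", "m_a", "a")

#' Construct a double-logistic coefficient vector
#'
#' @param y_min,y_max Lower/upper asymptote parameters (g per plant for
#'   biomass, cm2 per plant for leaf area). Purely empirical; `y_max >
#'   y_min` is not required.
#' @param m_s Growth-rate parameter (per degree C day); the first logistic
#'   term uses exponent `-m_s * (t - s)`.
#' @param s Growth inflection point (degree C days).
#' @param m_a Senescence-rate parameter (per degree C day); the second term
#'   uses exponent `+m_a * (t - a)`.
#' @param a Senescence inflection point (degree C days).
#' @param variable Optional label, `"biomass"` or `"leaf_area"`.
#' @return Named numeric vector of length 6 with class `dl_coef`.
#' @export
dl_coef <- function(y_min, y_max, m_s, s, m_a, a, variable = NULL) {
  out <- c(y_min = y_min, y_max = y_max, m_s = m_s, s = s, m_a = m_a, a = a)
  check_number(out, "coefficients")
  class(out) <- "dl_coef"
  if (!is.null(variable)) {
    attr(out, "variable") <- match.arg(variable, c("biomass", "leaf_area"))
  }
  out
}

as_dl_coef <- function(coef) {
  if (inherits(coef, "dl_coef")) return(coef)
  coef <- unlist(coef)
  if (is.null(names(coef)) && length(coef) == 6L) names(coef) <- dl_names
  if (!all(dl_names %in% names(coef))) {
    stop("coefficients must carry names ", paste(dl_names, collapse = ", "),
         call. = FALSE)
  }
  coef <- coef[dl_names]
  check_number(coef, "coefficients")
  class(coef) <- "dl_coef"
  coef
}

#' Evaluate the double-logistic function
#'
#' Numerically safe for exponents of any magnitude (the logistic terms are
#' evaluated via [stats::plogis()]).
#'
#' @param t Thermal time (accumulated degree C days). Vectorized.
#' @param coef Coefficients from [dl_coef()], or any named vector/list with
#'   elements `y_min, y_max, m_s, s, m_a, a`.
#' @return Modelled biomass or leaf area at `t`.
#' @export
double_logistic <- function(t, coef) {
  coef <- as_dl_coef(coef)
  check_number(t, "t")
  p1 <- stats::plogis(coef[["m_s"]] * (t - coef[["s"]]))
  p2 <- stats::plogis(-coef[["m_a"]] * (t - coef[["a"]]))
  coef[["y_min"]] + (coef[["y_max"]] - coef[["y_min"]]) * (p1 + p2)
}

#' Analytic derivative of the double-logistic function
#'
#' Slope of the modelled trajectory with respect to thermal time; feeds the
#' functional growth indices.
#'
#' @inheritParams double_logistic
#' @return Derivative in variable units per degree C day.
#' @export
double_logistic_derivative <- function(t, coef) {
  coef <- as_dl_coef(coef)
  check_number(t, "t")
  p1 <- stats::plogis(coef[["m_s"]] * (t - coef[["s"]]))
  p2 <- stats::plogis(-coef[["m_a"]] * (t - coef[["a"]]))
  (coef[["y_max"]] - coef[["y_min"]]) *
    (coef[["m_s"]] * p1 * (1 - p1) - coef[["m_a"]] * p2 * (1 - p2))
}

#' Canonical parameter ordering
#'
#' The double logistic is invariant under exchanging the two terms,
#' `(m_s, s) <-> (-m_a, a)`. Fits can therefore return either labelling.
#' This helper relabels so that the growth inflection precedes the
#' senescence inflection (`s <= a`), making coefficient tables comparable.
#'
#' @param coef Coefficient vector.
#' @return Coefficient vector with `s <= a`, representing the same curve.
#' @export
dl_canonical <- function(coef) {
  coef <- as_dl_coef(coef)
  if (coef[["s"]] > coef[["a"]]) {
    coef[c("m_s", "s", "m_a", "a")] <-
      c(-coef[["m_a"]], coef[["a"]], -coef[["m_s"]], coef[["s"]])
  }
  coef
}

#' Heuristic starting values for a double-logistic fit
#'
#' Brackets the asymptotes 10% beyond the data range and places the
#' inflections at the first upward and last downward half-range crossings
#' of the (t-sorted) series; rate magnitudes are 4 divided by the local
#' quarter-to-three-quarter crossing width. A series with no upward
#' crossing (monotone decline, as the published chia coefficient sets
#' produce) is treated as two declining terms; a series that never crosses
#' downward gets its senescence inflection parked at `max(t)` and the
#' result is flagged.
#'
#' @param t,y Observation vectors (equal length, `length >= 8`).
#' @return A `dl_coef` vector with attributes `flagged` (logical) and
#'   `note`.
#' @export
initial_guess <- function(t, y) {
  check_number(t, "t")
  check_number(y, "y")
  if (length(t) != length(y)) stop("t and y lengths differ", call. = FALSE)
  if (length(t) < 8L) stop("need at least 8 points", call. = FALSE)
  o <- order(t)
  t <- t[o]
  y <- y[o]
  r <- max(y) - min(y)
  if (r <= 0) stop("constant y: no curve to initialize from", call. = FALSE)
  span <- diff(range(t))
  half <- min(y) + r / 2
  cross <- function(level, upward) {
    n <- length(y)
    if (upward) which(y[-n] < level & y[-1] >= level)
    else which(y[-n] >= level & y[-1] < level)
  }
  interp_at <- function(i, level) {
    # t where the segment [i, i+1] crosses `level`
    t[i] + (level - y[i]) / (y[i + 1] - y[i]) * (t[i + 1] - t[i])
  }
  up <- cross(half, TRUE)
  dn <- cross(half, FALSE)
  flagged <- FALSE
  note <- ""
  width_around <- function(at) {
    lo <- cross(min(y) + 0.25 * r, TRUE)
    hi <- cross(min(y) + 0.75 * r, TRUE)
    w <- if (length(lo) && length(hi)) abs(t[hi[1]] - t[lo[1]]) else span / 4
    max(w, span / 50)
  }
  if (length(up)) {
    s0 <- interp_at(up[1], half)
    m_s0 <- 4 / width_around(s0)
  } else {
    # monotone-declining series: first term declines too
    s0 <- if (length(dn)) interp_at(dn[1], half) else t[1] + span / 3
    m_s0 <- -4 / (span / 4)
  }
  if (length(dn)) {
    a0 <- interp_at(dn[length(dn)], half)
    m_a0 <- 4 / (span / 4)
  } else {
    a0 <- max(t)
    m_a0 <- 4 / (span / 4)
    flagged <- TRUE
    note <- "no downward half-range crossing; senescence inflection defaulted to max(t)"
  }
  out <- dl_coef(min(y) - 0.1 * r, max(y) + 0.1 * r, m_s0, s0, m_a0, a0)
  attr(out, "flagged") <- flagged
  attr(out, "note") <- note
  out
}
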