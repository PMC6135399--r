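# Classical (interval, Hunt) and functional (fitted-curve) growth indices.
# Rates are per calendar day, the conventional units; the reporting axis is
# thermal time, so interval midpoints carry both das and add.

#' Classical relative growth rate over an interval
#'
#' `RGR = (ln w2 - ln w1) / (t2 - t1)`, the rate of biomass gain per unit
#' biomass (g per g per day).
#'
#' @param w1,w2 Biomass at the interval ends (g), strictly positive.
#' @param t1,t2 Times in days, `t2 > t1`. Vectorized.
#' @return RGR in g g-1 d-1 (negative during senescence).
#' @export
classical_rgr <- function(w1, w2, t1, t2) {
  check_number(w1, "w1"); check_number(w2, "w2")
  check_number(t1, "t1"); check_number(t2, "t2")
  if (any(w1 <= 0) || any(w2 <= 0)) {
    stop("masses must be positive for the log-ratio", call. = FALSE)
  }
  if (any(t2 <= t1)) stop("t2 must exceed t1", call. = FALSE)
  (log(w2) - log(w1)) / (t2 - t1)
}

#' Classical net assimilation rate over an interval
#'
#' Hunt's interval formula `NAR = [(w2 - w1)/(t2 - t1)] *
#' [(ln a2 - ln a1)/(a2 - a1)]`, the rate of biomass increase per unit leaf
#' area. When the leaf areas at the two ends are (numerically) equal the
#' limit `(w2 - w1) / ((t2 - t1) * a1)` is used.
#'
#' @param w1,w2 Biomass (g), positive.
#' @param a1,a2 Leaf area (cm2), positive.
#' @param t1,t2 Times in days, `t2 > t1`.
#' @return NAR in g cm-2 d-1.
#' @export
classical_nar <- function(w1, w2, a1, a2, t1, t2) {
  for (nm in c("w1", "w2", "a1", "a2")) {
    v <- get(nm)
    check_number(v, nm)
    if (any(v <= 0)) stop(nm, " must be positive", call. = FALSE)
  }
  if (any(t2 <= t1)) stop("t2 must exceed t1", call. = FALSE)
  dw <- (w2 - w1) / (t2 - t1)
  la_term <- ifelse(abs(a2 - a1) < 1e-9, 1 / a1, (log(a2) - log(a1)) / (a2 - a1))
  dw * la_term
}

#' Ratio indices at a single observation
#'
#' Leaf-area ratio (LAR, cm2 g-1), the same quantity per kg (published for
#' chia under the name LWR, cm2 kg-1), and specific leaf weight
#' (SLW = leaf dry mass / leaf area, g cm-2). The identity
#' `slw * lar = dm_leaf / dm_total` (leaf mass fraction) holds by
#' construction.
#'
#' @param leaf_area Leaf area (cm2 per plant), positive.
#' @param dm_total Total dry mass (g per plant), positive.
#' @param dm_leaf Leaf dry mass (g per plant), non-negative.
#' @return Data frame with columns `lar`, `lwr`, `slw`.
#' @export
ratio_indices <- function(leaf_area, dm_total, dm_leaf) {
  check_number(leaf_area, "leaf_area")
  check_number(dm_total, "dm_total")
  check_number(dm_leaf, "dm_leaf")
  if (any(leaf_area <= 0) || any(dm_total <= 0)) {
    stop("leaf_area and dm_total must be positive", call. = FALSE)
  }
  lar <- leaf_area / dm_total
  data.frame(lar = lar, lwr = 1000 * lar, slw = dm_leaf / leaf_area)
}

#' Crop growth rate over an interval
#'
#' Biomass gain per unit ground area: `CGR = density * (w2 - w1)/(t2 - t1)`.
#' Negative values during senescence are preserved.
#'
#' @param w1,w2 Biomass per plant (g).
#' @param t1,t2 Times in days, `t2 > t1`.
#' @param density Plant density (plants per m2), positive.
#' @return CGR in g m-2 d-1.
#' @export
cgr <- function(w1, w2, t1, t2, density) {
  check_number(density, "density")
  if (any(density <= 0)) stop("density must be positive", call. = FALSE)
  if (any(t2 <= t1)) stop("t2 must exceed t1", call. = FALSE)
  density * (w2 - w1) / (t2 - t1)
}

#' Leaf area index
#'
#' @param leaf_area Leaf area per plant (cm2).
#' @param density Plant density (plants per m2).
#' @return Dimensionless LAI: `leaf_area * density / 1e4`.
#' @export
lai <- function(leaf_area, density) {
  check_number(leaf_area, "leaf_area")
  check_number(density, "density")
  leaf_area * density / 1e4
}

#' Treatment-mean trajectories from plant observations
#'
#' Averages the sampled plants of each treatment at each harvest, the basis
#' for interval (classical) indices on the plotted means.
#'
#' @param obs Plant-observation data frame (see [generate_plant_data()] for
#'   the dialect: `treatment, block, plant_id, das, add, leaf_area, dm_leaf,
#'   dm_stem, dm_root, dm_inflorescence, dm_total`).
#' @return Data frame of per-treatment, per-harvest means.
#' @export
harvest_means <- function(obs) {
  check_columns(obs, c("treatment", "das", "leaf_area", "dm_total", "dm_leaf"),
                "obs")
  num <- intersect(c("add", "leaf_area", "dm_leaf", "dm_stem", "dm_root",
                     "dm_inflorescence", "dm_total"), names(obs))
  agg <- stats::aggregate(obs[num],
                          by = list(treatment = obs$treatment, das = obs$das),
                          FUN = mean)
  agg[order(agg$treatment, agg$das), , drop = FALSE]
}

#' Interval (classical) growth indices along a mean trajectory
#'
#' Computes Hunt's interval indices between consecutive harvests of a
#' single-treatment mean trajectory. Rates are per calendar day; interval
#' midpoints are reported on both axes (das, and add by linear
#' interpolation when a thermal series is supplied). Ratio indices at the
#' midpoint are means of the endpoint ratios.
#'
#' @param means One treatment's rows from [harvest_means()] (columns `das`,
#'   `dm_total`, `leaf_area`, `dm_leaf`, optionally `add`).
#' @param density Plant density (plants per m2).
#' @param thermal Optional `thermal_time` series for midpoint `add` via
#'   [das_to_add()]; otherwise midpoint `add` is the mean of endpoint `add`
#'   values when present.
#' @return Data frame with columns `das`, `add`, `rgr`, `nar`, `lwr`,
#'   `lar`, `cgr`, `slw`, `lai` at interval midpoints.
#' @export
interval_indices <- function(means, density, thermal = NULL) {
  check_columns(means, c("das", "dm_total", "leaf_area", "dm_leaf"), "means")
  means <- means[order(means$das), , drop = FALSE]
  n <- nrow(means)
  if (n < 2L) stop("need at least two harvests", call. = FALSE)
  i1 <- seq_len(n - 1)
  i2 <- i1 + 1
  w1 <- means$dm_total[i1]; w2 <- means$dm_total[i2]
  a1 <- means$leaf_area[i1]; a2 <- means$leaf_area[i2]
  t1 <- means$das[i1]; t2 <- means$das[i2]
  mid_das <- (t1 + t2) / 2
  mid_add <- if (!is.null(thermal)) {
    das_to_add(thermal, mid_das)
  } else if (!is.null(means$add)) {
    (means$add[i1] + means$add[i2]) / 2
  } else {
    NA_real_
  }
  r1 <- ratio_indices(a1, w1, means$dm_leaf[i1])
  r2 <- ratio_indices(a2, w2, means$dm_leaf[i2])
  data.frame(
    das = mid_das,
    add = mid_add,
    rgr = classical_rgr(w1, w2, t1, t2),
    nar = classical_nar(w1, w2, a1, a2, t1, t2),
    lwr = (r1$lwr + r2$lwr) / 2,
    lar = (r1$lar + r2$lar) / 2,
    cgr = cgr(w1, w2, t1, t2, density),
    slw = (r1$slw + r2$slw) / 2,
    lai = (lai(a1, density) + lai(a2, density)) / 2
  )
}

#' Functional (instantaneous) growth indices from fitted curves
#'
#' Evaluates smooth index curves from fitted biomass and leaf-area
#' trajectories on a thermal-time grid: `RGR = W'/W`, `NAR = W'/A`,
#' `LAR = A/W` (so `RGR = NAR * LAR` holds exactly on the grid),
#' `CGR = density * W'`, and `SLW = leaf_fraction * W / A`. Rates are per
#' degree C day unless a thermal series is supplied, in which case the
#' local degree-days-per-day conversion puts them on a per-day basis.
#'
#' @param fit_biomass,fit_la Converged `dl_fit` objects for biomass and
#'   leaf area.
#' @param density Plant density (plants per m2).
#' @param t_grid Thermal-time grid (degree C days).
#' @param thermal Optional `thermal_time` series; when given, rates are
#'   converted to per-day using the local slope of add vs das.
#' @param leaf_fraction Leaf mass fraction of total biomass used for SLW:
#'   a constant, or a function of the grid, or `NULL` to skip SLW.
#' @return Data frame `add, (das,) biomass, leaf_area, rgr, nar, lar, lwr,
#'   cgr, slw, lai`.
#' @export
functional_indices <- function(fit_biomass, fit_la, density, t_grid,
                               thermal = NULL, leaf_fraction = NULL) {
  stopifnot(inherits(fit_biomass, "dl_fit"), inherits(fit_la, "dl_fit"))
  if (!fit_biomass$converged || !fit_la$converged) {
    stop("both fits must have converged", call. = FALSE)
  }
  check_number(t_grid, "t_grid")
  w <- double_logistic(t_grid, fit_biomass$coefficients)
  if (any(w <= 0)) {
    bad <- t_grid[w <= 0]
    stop("biomass curve non-positive at t = ",
         paste(utils::head(signif(bad, 5), 5), collapse = ", "),
         call. = FALSE)
  }
  a <- double_logistic(t_grid, fit_la$coefficients)
  wprime <- double_logistic_derivative(t_grid, fit_biomass$coefficients)
  out <- data.frame(add = t_grid)
  if (!is.null(thermal)) {
    # invert add -> das on the daily grid, then d(add)/d(das) locally
    das <- stats::approx(thermal$add, thermal$das, xout = t_grid,
                         method = "linear", ties = "ordered")$y
    eps <- 0.5
    das_lo <- pmax(das - eps, min(thermal$das))
    das_hi <- pmin(das + eps, max(thermal$das))
    k <- (das_to_add(thermal, das_hi) - das_to_add(thermal, das_lo)) /
      (das_hi - das_lo)
    wprime <- wprime * k  # g per day
    out$das <- das
  }
  lar_v <- a / w
  out$biomass <- w
  out$leaf_area <- a
  out$rgr <- wprime / w
  out$nar <- wprime / a
  out$lar <- lar_v
  out$lwr <- 1000 * lar_v
  out$cgr <- density * wprime
  out$slw <- if (is.null(leaf_fraction)) {
    NA_real_
  } else if (is.function(leaf_fraction)) {
    leaf_fraction(t_grid) * w / a
  } else {
    leaf_fraction * w / a
  }
  out$lai <- lai(a, density)
  out
}
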