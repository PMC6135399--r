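# Synthetic study-system generator: seeded daily weather with the climate
# structure of the two trial sites, and replicated plant-harvest datasets
# with the sampling design and noise magnitudes of the two trials
# (sowing-date trial: 2 dates x 5 replicates, harvests every 10-15 d from
# 24 DAS over a ~180 d season; irrigation trial: 100% vs 40% ETo x 6
# blocks, treatments from 54 DAS, ~151 d season).

#' Site climate profile
#'
#' Parameters of the sinusoidal-plus-noise daily weather generator. The
#' annual cycle peaks at `t_peak_doy` (mid-January for central Chile);
#' `tmax`/`tmin` sit half a diurnal range above/below the daily mean.
#'
#' @param name Site label.
#' @param latitude Degrees (south negative).
#' @param elevation m above sea level (drives the pressure column).
#' @param t_mean Mean annual temperature, degrees C.
#' @param t_amplitude Seasonal (annual-cycle) amplitude, degrees C.
#' @param t_peak_doy Day of year of the warmest day.
#' @param diurnal_range Mean tmax - tmin, degrees C.
#' @param t_noise_sd Daily temperature noise sd, degrees C.
#' @param u2_mean,u2_sd Wind at 2 m, m s-1.
#' @param rh_mean,rh_sd Mean relative humidity, percent.
#' @param rn_mean,rn_amplitude,rn_sd Net radiation annual mean, seasonal
#'   amplitude and daily noise, MJ m-2 d-1 (in phase with temperature).
#' @return List of class `site_profile`.
#' @export
site_profile <- function(name, latitude, elevation, t_mean, t_amplitude,
                         t_peak_doy = 15, diurnal_range = 12,
                         t_noise_sd = 1.5, u2_mean = 2, u2_sd = 0.5,
                         rh_mean = 60, rh_sd = 8, rn_mean = 10,
                         rn_amplitude = 5, rn_sd = 1.5) {
  stopifnot(t_amplitude >= 0, t_noise_sd >= 0, diurnal_range >= 0)
  structure(as.list(environment()), class = "site_profile")
}

#' Antumapu site profile (central Chile, warm temperate)
#'
#' Mean annual temperature 14 degrees C with January warmest; seasonal
#' amplitude and diurnal range set from Santiago climate normals. 420 m
#' elevation.
#' @return A `site_profile`.
#' @export
antumapu_profile <- function() {
  site_profile("Antumapu", latitude = -33.67, elevation = 420,
               t_mean = 14, t_amplitude = 6.5, t_peak_doy = 15,
               diurnal_range = 14, t_noise_sd = 1.5,
               u2_mean = 2, u2_sd = 0.5, rh_mean = 60, rh_sd = 8,
               rn_mean = 10, rn_amplitude = 5, rn_sd = 1.5)
}

#' Intihuasi site profile (Coquimbo, warm desert)
#'
#' Derived from the stated January mean maximum of 28 degrees C and July
#' mean minimum of 5 degrees C with a 13-degree diurnal range. 135 m
#' elevation.
#' @return A `site_profile`.
#' @export
intihuasi_profile <- function() {
  site_profile("Intihuasi", latitude = -29.99, elevation = 135,
               t_mean = 15.5, t_amplitude = 6, t_peak_doy = 15,
               diurnal_range = 13, t_noise_sd = 1.2,
               u2_mean = 2.5, u2_sd = 0.6, rh_mean = 70, rh_sd = 8,
               rn_mean = 11, rn_amplitude = 6, rn_sd = 1.5)
}

#' Generate a seeded daily weather series
#'
#' Sinusoidal annual cycle plus Gaussian daily noise for the temperatures
#' and net radiation; humidity and wind drawn around the profile means.
#' Fully deterministic for a fixed seed; with all noise sds at zero the
#' series lies exactly on the climatological sinusoid.
#'
#' @param profile A [site_profile()].
#' @param start_date First day (sowing date).
#' @param n_days Number of days.
#' @param seed RNG seed.
#' @return A weather data frame in the package dialect (`date, tmin, tmax,
#'   tmean, rh_mean, ea, u2, rn, g, pressure`).
#' @export
generate_weather <- function(profile, start_date, n_days, seed = 1L) {
  stopifnot(inherits(profile, "site_profile"), n_days >= 1)
  dates <- as.Date(start_date) + seq_len(n_days) - 1L
  doy <- as.integer(format(dates, "%j"))
  phase <- cos(2 * pi * (doy - profile$t_peak_doy) / 365.25)
  with_seed(seed, {
    tmean <- profile$t_mean + profile$t_amplitude * phase +
      stats::rnorm(n_days, 0, profile$t_noise_sd)
    half_range <- pmax(0, profile$diurnal_range / 2 +
                         stats::rnorm(n_days, 0, profile$t_noise_sd / 2))
    rh <- pmin(100, pmax(5, profile$rh_mean +
                           stats::rnorm(n_days, 0, profile$rh_sd)))
    u2 <- pmax(0, profile$u2_mean + stats::rnorm(n_days, 0, profile$u2_sd))
    rn <- profile$rn_mean + profile$rn_amplitude * phase +
      stats::rnorm(n_days, 0, profile$rn_sd)
    data.frame(
      date = dates,
      tmin = tmean - half_range,
      tmax = tmean + half_range,
      tmean = tmean,
      rh_mean = rh,
      ea = NA_real_,
      u2 = u2,
      rn = rn,
      g = 0,
      pressure = pressure_at_elevation(profile$elevation)
    )
  })
}

#' Published double-logistic coefficient sets for the chia trials
#'
#' The fitted coefficient rows (with their goodness-of-fit columns) for
#' biomass and leaf area under the two sowing dates (SD1, SD2) and the two
#' irrigation treatments (100% ETo IT1, 40% ETo IT2), as published for the
#' Chilean chia trials. These are empirical parameter vectors: evaluated
#' through [double_logistic()] they reproduce the fitted curves of the
#' source analysis, and they seed the round-trip recovery tests. Note that
#' `y_min` is strongly negative and `m_s` negative throughout; see the
#' methods vignette on interpreting them.
#'
#' @param variable `"biomass"`, `"leaf_area"`, or `"all"`.
#' @return Data frame with columns `variable, treatment, y_min, y_max,
#'   m_s, s, m_a, a, rmse, error, r2, p`.
#' @export
chia_reference_coefficients <- function(variable = c("all", "biomass",
                                                     "leaf_area")) {
  variable <- match.arg(variable)
  b <- data.frame(
    variable = "biomass",
    treatment = c("SD1", "SD2", "IT1", "IT2"),
    y_min = c(-67.742, -103.846, -35.275, -29.563),
    y_max = c(66.620, 102.889, 36.823, 30.584),
    m_s = c(-0.0041, -0.0039, -0.0213, -0.0209),
    s = c(1086.756, 1267.273, 558.557, 530.571),
    m_a = c(0.0088, 0.0085, 0.0289, 0.0121),
    a = c(1338.448, 1414.806, 704.103, 665.970),
    rmse = c(0.4906, 1.2865, 0.485, 0.243),
    error = c(0.542, 1.412, 0.573, 0.287),
    r2 = c(0.997, 0.986, 0.997, 0.998),
    p = c(0, 0, 0, 0)
  )
  l <- data.frame(
    variable = "leaf_area",
    treatment = c("SD1", "SD2", "IT1", "IT2"),
    y_min = c(-2109.352, -1573.041, -979.047, -604.942),
    y_max = c(2009.767, 1373.831, 1185.154, 674.837),
    m_s = c(-0.0051, -0.0059, -0.0303, -0.0232),
    s = c(721.877, 511.217, 569.297, 513.865),
    m_a = c(0.0101, 0.1472, 0.4217, 0.9289),
    a = c(1142.224, 1214.244, 668.279, 669.912),
    rmse = c(45.783, 60.966, 136.955, 35.809),
    error = c(50.774, 67.375, 147.663, 40.872),
    r2 = c(0.986, 0.977, 0.871, 0.977),
    p = c(0, 0, 0, 0)
  )
  out <- rbind(b, l)
  if (variable != "all") out <- out[out$variable == variable, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Pull one published row as a dl_coef vector.
reference_coef <- function(treatment, variable) {
  tab <- chia_reference_coefficients(variable)
  row <- tab[tab$treatment == treatment, ]
  if (nrow(row) != 1L) stop("unknown treatment ", treatment, call. = FALSE)
  dl_coef(row$y_min, row$y_max, row$m_s, row$s, row$m_a, row$a,
          variable = variable)
}

#' Figure-calibrated synthetic truth curves
#'
#' Synthetic double-logistic coefficient sets calibrated so that the
#' trajectories match the *described* behaviour of the trials (peak dry
#' mass near 30 g per plant around 1100-1150 ADD, peak leaf area 1160-1187
#' cm2 per plant near 1000 ADD, peak relative growth rate about
#' 0.15 / 0.11 g g-1 d-1 near 410 ADD for the two sowing dates, and the
#' smaller, earlier irrigation-trial trajectories). They are not fitted to
#' any raw data: they exist because the published coefficient rows,
#' evaluated through the printed model, do not reproduce the plotted
#' rise-and-fall trajectories (see the methods vignette), and realistic
#' trajectories are needed to exercise the growth-index layer.
#'
#' @param treatment `"SD1"`, `"SD2"`, `"IT1"` or `"IT2"`.
#' @param variable `"biomass"` or `"leaf_area"`.
#' @return A `dl_coef` vector.
#' @export
chia_calibrated_truth <- function(treatment, variable = c("biomass",
                                                          "leaf_area")) {
  variable <- match.arg(variable)
  sets <- list(
    biomass = list(
      SD1 = c(-30, 0.02, 0.016, 700, 0.015, 1300),
      SD2 = c(-30, 0.02, 0.012, 720, 0.015, 1300),
      IT1 = c(-30, 0.02, 0.016, 430, 0.010, 900),
      IT2 = NULL
    ),
    leaf_area = list(
      SD1 = c(-1361.793, 1, 0.011, 640, 0.010, 1120),
      SD2 = c(-1206.179, 1, 0.011, 640, 0.020, 1300),
      IT1 = c(-767, 1, 0.016, 420, 0.020, 800),
      IT2 = NULL
    )
  )
  if (treatment == "IT2") {
    # deficit treatment derived from IT1 by the published relative
    # reductions: 54% dry matter, 43% leaf area
    base <- chia_calibrated_truth("IT1", variable)
    red <- if (variable == "biomass") 0.54 else 0.43
    return(apply_deficit_effect(base, red))
  }
  v <- sets[[variable]][[treatment]]
  if (is.null(v)) stop("unknown treatment ", treatment, call. = FALSE)
  dl_coef(v[1], v[2], v[3], v[4], v[5], v[6], variable = variable)
}

#' Apply a deficit-irrigation effect to a truth curve
#'
#' Scales both asymptote parameters of a coefficient set by
#' `1 - reduction`, preserving the shape parameters (`m_s, s, m_a, a`).
#' Because the two asymptotes enter the model affinely, this scales the
#' whole trajectory: `y'(t) = (1 - reduction) * y(t)` at every t, so the
#' season maximum and the season integral both shrink by exactly the given
#' relative reduction. The published water-deficit effect is a 54%
#' decrease in total dry matter and a 43% decrease in leaf area.
#'
#' @param coef A `dl_coef` truth vector.
#' @param reduction Relative reduction in `[0, 1)`.
#' @return Modified `dl_coef`.
#' @export
apply_deficit_effect <- function(coef, reduction) {
  coef <- as_dl_coef(coef)
  check_number(reduction, "reduction")
  if (reduction < 0 || reduction >= 1) {
    stop("reduction must lie in [0, 1)", call. = FALSE)
  }
  coef[["y_min"]] <- (1 - reduction) * coef[["y_min"]]
  coef[["y_max"]] <- (1 - reduction) * coef[["y_max"]]
  coef
}

#' Trial design for the synthetic generator
#'
#' @param name Trial label.
#' @param treatments Named list; each element a list with `biomass` and
#'   `leaf_area` truth `dl_coef` vectors, `density` (plants m-2) and
#'   optionally `sowing_date`.
#' @param n_blocks Replicates (sowing-date trial 5) or blocks (irrigation
#'   trial 6).
#' @param n_plants Plants sampled per experimental unit per harvest (10).
#' @param first_harvest_das,cadence_days,season_days Harvest schedule:
#'   first harvest, interval (within the 10-15 d protocol band) and season
#'   length in days after sowing.
#' @param noise_sd Data frame `treatment, biomass, leaf_area` of Gaussian
#'   observation sds (g, cm2).
#' @param flowering_add Thermal time of flowering (degree C days), used by
#'   the organ-allocation schedule.
#' @return List of class `trial_design`.
#' @export
trial_design <- function(name, treatments, n_blocks, n_plants = 10,
                         first_harvest_das, cadence_days = 12,
                         season_days, noise_sd, flowering_add) {
  stopifnot(cadence_days >= 1, n_plants >= 1, n_blocks >= 1)
  structure(as.list(environment()), class = "trial_design")
}

#' Sowing-date trial design (SD1 vs SD2)
#'
#' Two sowing dates (7 and 31 December 2010), completely randomized with 5
#' replicates, 50 plants m-2, harvests every 12 days from 24 DAS over a
#' 181-day season. Observation noise defaults to the published fit RMSEs
#' (0.4906 / 1.2865 g; 45.783 / 60.966 cm2).
#'
#' @param truth `"calibrated"` (default; realistic rise-and-fall
#'   trajectories) or `"reference"` (the published coefficient rows used
#'   verbatim as truth).
#' @return A `trial_design`.
#' @export
sowing_date_design <- function(truth = c("calibrated", "reference")) {
  truth <- match.arg(truth)
  pick <- function(trt, var) {
    if (truth == "calibrated") chia_calibrated_truth(trt, var)
    else reference_coef(trt, var)
  }
  trial_design(
    name = "sowing_date",
    treatments = list(
      SD1 = list(biomass = pick("SD1", "biomass"),
                 leaf_area = pick("SD1", "leaf_area"),
                 density = 50, sowing_date = as.Date("2010-12-07")),
      SD2 = list(biomass = pick("SD2", "biomass"),
                 leaf_area = pick("SD2", "leaf_area"),
                 density = 50, sowing_date = as.Date("2010-12-31"))
    ),
    n_blocks = 5,
    n_plants = 10,
    first_harvest_das = 24,
    cadence_days = 12,
    season_days = 181,
    noise_sd = data.frame(treatment = c("SD1", "SD2"),
                          biomass = c(0.4906, 1.2865),
                          leaf_area = c(45.783, 60.966)),
    flowering_add = 1140
  )
}

#' Irrigation trial design (100% vs 40% ETo)
#'
#' Two irrigation fractions in 6 blocks, 60 plants m-2 (midpoint of the
#' 55-65 thinning band), treatments effective from 54 DAS, harvests every
#' 12 days from 54 DAS over a 151-day season; sown 23 January 2014.
#'
#' @inheritParams sowing_date_design
#' @return A `trial_design`.
#' @export
irrigation_design <- function(truth = c("calibrated", "reference")) {
  truth <- match.arg(truth)
  pick <- function(trt, var) {
    if (truth == "calibrated") chia_calibrated_truth(trt, var)
    else reference_coef(trt, var)
  }
  trial_design(
    name = "irrigation",
    treatments = list(
      IT1 = list(biomass = pick("IT1", "biomass"),
                 leaf_area = pick("IT1", "leaf_area"),
                 density = 60, sowing_date = as.Date("2014-01-23")),
      IT2 = list(biomass = pick("IT2", "biomass"),
                 leaf_area = pick("IT2", "leaf_area"),
                 density = 60, sowing_date = as.Date("2014-01-23"))
    ),
    n_blocks = 6,
    n_plants = 10,
    first_harvest_das = 54,
    cadence_days = 12,
    season_days = 151,
    noise_sd = data.frame(treatment = c("IT1", "IT2"),
                          biomass = c(0.485, 0.243),
                          leaf_area = c(136.955, 35.809)),
    flowering_add = 499
  )
}

# Organ allocation fractions (leaf, stem, root, inflorescence) as a smooth
# phenology-indexed schedule: vegetative allocation before flowering,
# ramping to reproductive allocation over the 300 degree-days after
# flowering. Rows sum to 1 exactly.
allocation_fractions <- function(add, flowering_add) {
  veg <- c(leaf = 0.45, stem = 0.40, root = 0.15, inflorescence = 0)
  rep_ <- c(leaf = 0.18, stem = 0.40, root = 0.12, inflorescence = 0.30)
  w <- pmin(1, pmax(0, (add - flowering_add) / 300))
  out <- outer(1 - w, veg) + outer(w, rep_)
  out / rowSums(out)
}

# Draw truth + Gaussian noise, redrawing (truncation, not clamping) any
# draw at or below `floor`.
rnorm_trunc <- function(n, mean, sd, floor) {
  if (sd == 0) return(pmax(mean, floor))
  x <- mean + stats::rnorm(n, 0, sd)
  for (i in seq_len(200)) {
    bad <- x <= floor
    if (!any(bad)) break
    x[bad] <- mean[bad] + stats::rnorm(sum(bad), 0, sd)
  }
  pmax(x, floor)
}

#' Generate replicated plant-harvest observations
#'
#' For each treatment, block and scheduled harvest, draws `n_plants`
#' destructive observations: total dry mass and leaf area are the truth
#' curves evaluated at the harvest's thermal time plus truncated Gaussian
#' noise (floored at 0.01 g / 1 cm2 by redrawing), and the organ masses
#' split the total by the phenology-indexed allocation schedule, so
#' `dm_total` equals the organ sum exactly. Deterministic for a fixed
#' seed.
#'
#' @param design A [trial_design()].
#' @param thermal A `thermal_time` series (from [accumulate_gdd()]), or a
#'   named list of one per treatment when sowing dates differ.
#' @param seed RNG seed.
#' @return Data frame with columns `treatment, block, plant_id, das, add,
#'   leaf_area, dm_leaf, dm_stem, dm_root, dm_inflorescence, dm_total`.
#' @export
generate_plant_data <- function(design, thermal, seed = 1L) {
  stopifnot(inherits(design, "trial_design"))
  harvest_das <- seq(design$first_harvest_das, design$season_days,
                     by = design$cadence_days)
  get_thermal <- function(trt) {
    th <- if (inherits(thermal, "thermal_time")) thermal else thermal[[trt]]
    if (is.null(th)) stop("no thermal series for treatment ", trt,
                          call. = FALSE)
    if (max(th$das) < max(harvest_das)) {
      stop("thermal series does not cover the season for ", trt,
           call. = FALSE)
    }
    th
  }
  with_seed(seed, {
    rows <- lapply(names(design$treatments), function(trt) {
      spec <- design$treatments[[trt]]
      th <- get_thermal(trt)
      add_h <- das_to_add(th, harvest_das)
      truth_b <- double_logistic(add_h, spec$biomass)
      truth_l <- double_logistic(add_h, spec$leaf_area)
      if (mean(truth_b > 0) < 0.5) {
        stop("biomass truth curve non-positive over most of the season for ",
             trt, call. = FALSE)
      }
      nz <- design$noise_sd[design$noise_sd$treatment == trt, ]
      per <- design$n_blocks * design$n_plants
      do.call(rbind, lapply(seq_along(harvest_das), function(h) {
        dm <- rnorm_trunc(per, rep(truth_b[h], per), nz$biomass, 0.01)
        la <- rnorm_trunc(per, rep(truth_l[h], per), nz$leaf_area, 1)
        fr <- allocation_fractions(rep(add_h[h], per), design$flowering_add)
        organs <- fr * dm
        data.frame(
          treatment = trt,
          block = rep(seq_len(design$n_blocks), each = design$n_plants),
          plant_id = rep(seq_len(design$n_plants), design$n_blocks),
          das = harvest_das[h],
          add = add_h[h],
          leaf_area = la,
          dm_leaf = organs[, "leaf"],
          dm_stem = organs[, "stem"],
          dm_root = organs[, "root"],
          dm_inflorescence = organs[, "inflorescence"],
          dm_total = rowSums(organs)
        )
      }))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
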