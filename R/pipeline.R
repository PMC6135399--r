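# End-to-end orchestration: simulate -> thermal -> ETo/irrigation -> fit
# -> indices -> stats -> report. All stages are thin wrappers over the
# exported module functions; the pipeline only sequences them, writes the
# intermediate tables and records a run manifest, so a run is reproducible
# from its seed alone.

#' Pipeline configuration
#'
#' @param site A [site_profile()].
#' @param design A [trial_design()].
#' @param tbase Base temperature for thermal time (degrees C).
#' @param fractions Named or unnamed numeric vector of irrigation
#'   fractions in (0, 1] (one irrigation schedule is produced per value).
#' @param trigger_mm Accumulated-ETo irrigation trigger (mm).
#' @param time_axis `"add"` (default) or `"das"`: the axis trajectories
#'   are fitted on.
#' @param restarts,seed Fitting restarts and the root seed; every random
#'   stage derives its own stream from the root seed.
#' @param outdir Output directory for the CSV/JSON artifacts, or `NULL`
#'   to skip writing.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(site = antumapu_profile(),
                            design = sowing_date_design(),
                            tbase = 10, fractions = c(1, 0.4),
                            trigger_mm = 8, time_axis = c("add", "das"),
                            restarts = 5, seed = 1L, outdir = NULL) {
  time_axis <- match.arg(time_axis)
  stopifnot(inherits(site, "site_profile"), inherits(design, "trial_design"),
            all(fractions > 0), all(fractions <= 1))
  structure(as.list(environment()), class = "pipeline_config")
}

# Derived per-stage seeds: fixed offsets from the root so stages are
# independent but jointly reproducible.
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000000L) * 1000L +
    match(stage, c("weather", "plants", "fit")) * 7L
}

#' Run the full analysis pipeline
#'
#' Executes every stage on synthetic inputs drawn from the configured site
#' and trial design: weather simulation, thermal-time accumulation, daily
#' ETo and irrigation schedules for each configured fraction, plant-data
#' generation, double-logistic fits of the treatment-mean biomass and
#' leaf-area trajectories, interval and functional growth indices,
#' per-harvest ANOVA + Duncan letters, and the correlation matrix among
#' functional indices. Writes one CSV per table plus a JSON manifest when
#' `outdir` is set; byte-identical outputs for a fixed seed.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a named list with every stage result (`weather`,
#'   `thermal`, `eto`, `irrigation`, `plants`, `fits`, `coefficients`,
#'   `interval_indices`, `functional_indices`, `stats`, `correlations`,
#'   `manifest`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  design <- config$design
  say <- function(...) if (!quiet) message("[chiagrowth] ", ...)
  t0 <- Sys.time()

  # -- weather + thermal (one series per distinct sowing date) ----------
  sow_dates <- vapply(design$treatments,
                      function(x) as.character(x$sowing_date),
                      character(1))
  season <- design$season_days + 1L
  weather <- list()
  thermal <- list()
  for (trt in names(design$treatments)) {
    sd_chr <- sow_dates[[trt]]
    if (is.null(weather[[sd_chr]])) {
      weather[[sd_chr]] <- generate_weather(
        config$site, as.Date(sd_chr), season,
        seed = stage_seed(config$seed, "weather") +
          match(sd_chr, unique(sow_dates))
      )
    }
    thermal[[trt]] <- accumulate_gdd(weather[[sd_chr]], tbase = config$tbase)
  }
  say("weather + thermal: ", length(weather), " series of ", season, " days")

  # -- ETo + irrigation (first sowing's weather drives the schedule) ----
  eto <- eto_from_weather(weather[[1]],
                          pressure = pressure_at_elevation(config$site$elevation))
  irrigation <- lapply(config$fractions, function(f) {
    schedule_irrigation(eto, fraction = f, trigger = config$trigger_mm)
  })
  names(irrigation) <- paste0("fraction_", config$fractions)
  say("eto + irrigation: ", nrow(eto), " days, ",
      paste(vapply(irrigation, nrow, integer(1)), collapse = "/"), " events")

  # -- plants -----------------------------------------------------------
  plants <- generate_plant_data(design, thermal,
                                seed = stage_seed(config$seed, "plants"))
  means <- harvest_means(plants)
  say("plants: ", nrow(plants), " observations, ",
      length(unique(plants$das)), " harvests")

  # -- fits -------------------------------------------------------------
  axis_col <- config$time_axis
  fits <- list()
  coef_rows <- list()
  for (trt in names(design$treatments)) {
    mt <- means[means$treatment == trt, ]
    for (var in c("biomass", "leaf_area")) {
      ycol <- if (var == "biomass") "dm_total" else "leaf_area"
      f <- fit_double_logistic(mt[[axis_col]], mt[[ycol]],
                               restarts = config$restarts,
                               seed = stage_seed(config$seed, "fit"),
                               variable = var)
      fits[[paste(trt, var, sep = ".")]] <- f
      coef_rows[[length(coef_rows) + 1L]] <-
        cbind(treatment = trt, variable = var, coef_row(f))
    }
  }
  coefficients <- do.call(rbind, coef_rows)
  for (var in c("biomass", "leaf_area")) {
    sub <- coefficients[coefficients$variable == var, ]
    avg <- average_coefficients(sub)
    coefficients <- rbind(coefficients,
                          cbind(treatment = "Average", variable = var, avg))
  }
  say("fits: ", length(fits), " trajectories")

  # -- indices ----------------------------------------------------------
  iv <- list()
  fx <- list()
  for (trt in names(design$treatments)) {
    mt <- means[means$treatment == trt, ]
    dens <- design$treatments[[trt]]$density
    iv[[trt]] <- cbind(treatment = trt,
                       interval_indices(mt, dens, thermal[[trt]]))
    fb <- fits[[paste0(trt, ".biomass")]]
    fl <- fits[[paste0(trt, ".leaf_area")]]
    grid <- seq(min(mt$add), max(mt$add), length.out = 101)
    fx[[trt]] <- tryCatch(
      cbind(treatment = trt,
            functional_indices(fb, fl, dens, grid, thermal = thermal[[trt]],
                               leaf_fraction = function(t) {
                                 allocation_fractions(t, design$flowering_add)[, "leaf"]
                               })),
      error = function(e) NULL)
  }
  interval_tab <- do.call(rbind, iv)
  functional_tab <- do.call(rbind, fx)
  say("indices: interval + functional")

  # -- stats ------------------------------------------------------------
  stats_rows <- list()
  for (d in sort(unique(plants$das))) {
    at <- plants[plants$das == d, ]
    for (resp in c("dm_total", "leaf_area")) {
      dr <- duncan_mrt(at$treatment, at[[resp]])
      an <- dr$anova
      stats_rows[[length(stats_rows) + 1L]] <- data.frame(
        das = d, response = resp,
        f = an$f[1], p = an$p[1],
        groups = paste(sprintf("%s=%.3g%s", dr$means$group, dr$means$mean,
                               dr$means$letters), collapse = "; ")
      )
    }
  }
  stats_tab <- do.call(rbind, stats_rows)
  correlations <- lapply(split(interval_tab, interval_tab$treatment),
                         function(x) {
                           correlation_matrix(x[c("rgr", "nar", "lwr", "cgr",
                                                  "slw")])
                         })
  say("stats: ", nrow(stats_tab), " per-harvest tests")

  manifest <- list(
    package = "chiagrowth",
    version = as.character(utils::packageVersion("chiagrowth")),
    seed = config$seed,
    site = config$site$name,
    design = design$name,
    tbase = config$tbase,
    fractions = config$fractions,
    trigger_mm = config$trigger_mm,
    time_axis = config$time_axis,
    n_plants_rows = nrow(plants),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  result <- list(weather = weather, thermal = thermal, eto = eto,
                 irrigation = irrigation, plants = plants,
                 harvest_means = means, fits = fits,
                 coefficients = coefficients,
                 interval_indices = interval_tab,
                 functional_indices = functional_tab,
                 stats = stats_tab, correlations = correlations,
                 manifest = manifest)

  if (!is.null(config$outdir)) {
    write_pipeline_outputs(result, config$outdir)
    say("wrote outputs to ", config$outdir)
  }
  invisible(result)
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) {
    utils::write.csv(x, file.path(outdir, paste0(name, ".csv")),
                     row.names = FALSE)
  }
  for (i in seq_along(result$weather)) {
    wr(result$weather[[i]], paste0("weather_", names(result$weather)[i]))
  }
  for (trt in names(result$thermal)) {
    th <- result$thermal[[trt]]
    wr(th[c("date", "das", "daily_gdd", "add")], paste0("thermal_", trt))
  }
  wr(result$eto, "eto")
  for (nm in names(result$irrigation)) wr(result$irrigation[[nm]],
                                          paste0("irrigation_", nm))
  wr(result$plants, "plants")
  wr(result$coefficients, "coefficients")
  wr(result$interval_indices, "interval_indices")
  if (!is.null(result$functional_indices)) {
    wr(result$functional_indices, "functional_indices")
  }
  wr(result$stats, "stats")
  jsonlite::write_json(result$manifest,
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
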