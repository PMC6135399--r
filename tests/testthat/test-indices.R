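test_that("interval RGR is the exact log-ratio rate", {
  expect_equal(classical_rgr(1, exp(1), 0, 1), 1)
  expect_equal(classical_rgr(5, 5, 0, 3), 0)
  # exactness for exponential growth on every interval
  r <- 0.13
  t <- c(0, 7, 19, 30, 44)
  w <- 0.5 * exp(r * t)
  for (i in 1:4) {
    expect_equal(classical_rgr(w[i], w[i + 1], t[i], t[i + 1]), r)
  }
  expect_error(classical_rgr(0, 1, 0, 1), "positive")
  expect_error(classical_rgr(1, 2, 3, 3), "t2")
})

test_that("interval NAR follows Hunt's formula with a stable equal-area limit", {
  # equal leaf areas: the limit (w2-w1)/(dt*a)
  expect_equal(classical_nar(1, 3, 100, 100, 0, 10), 2 / (10 * 100))
  expect_equal(classical_nar(2, 2, 80, 120, 0, 10), 0)
  set.seed(14)
  for (i in 1:10) {
    w1 <- runif(1, 0.5, 5); w2 <- runif(1, 0.5, 30)
    a1 <- runif(1, 50, 400); a2 <- runif(1, 50, 1200)
    t1 <- 0; t2 <- runif(1, 5, 20)
    manual <- ((w2 - w1) / (t2 - t1)) * ((log(a2) - log(a1)) / (a2 - a1))
    expect_equal(classical_nar(w1, w2, a1, a2, t1, t2), manual)
  }
  expect_error(classical_nar(1, 2, -5, 10, 0, 1), "positive")
})

test_that("ratio indices convert units consistently", {
  r <- ratio_indices(leaf_area = 100, dm_total = 10, dm_leaf = 4)
  expect_equal(r$lar, 10)
  expect_equal(r$lwr, 10000)
  expect_equal(r$slw, 0.04)
  # slw * lar recovers the leaf mass fraction, and lwr = 1000 * lar
  set.seed(15)
  la <- runif(20, 50, 1200); wt <- runif(20, 0.5, 40); wl <- 0.4 * wt
  rr <- ratio_indices(la, wt, wl)
  expect_equal(rr$slw * rr$lar, wl / wt)
  expect_equal(rr$lwr, 1000 * rr$lar)
  expect_error(ratio_indices(0, 1, 1), "positive")
})

test_that("crop growth rate scales by density and keeps its sign", {
  expect_equal(cgr(1, 2, 0, 1, density = 50), 50)
  expect_lt(cgr(10, 8, 0, 5, density = 50), 0)  # senescence stays negative
  expect_error(cgr(1, 2, 0, 1, density = -1), "positive")
})

test_that("LAI is leaf area per ground area", {
  expect_equal(lai(10000, 1), 1)
  expect_equal(lai(0, 50), 0)
  expect_equal(lai(1187, 50), 5.935)
})

test_that("functional indices satisfy RGR = NAR x LAR exactly on the grid", {
  tg <- seq(50, 1150, 25)
  fitb <- fit_double_logistic(tg, double_logistic(tg, cf_rise) + 10,
                              restarts = 0)
  cf_la <- dl_coef(100, 900, 0.015, 350, 0.02, 900)
  fitl <- fit_double_logistic(tg, double_logistic(tg, cf_la), restarts = 0)
  fx <- functional_indices(fitb, fitl, density = 50, t_grid = tg)
  expect_equal(fx$rgr, fx$nar * fx$lar)
  expect_equal(fx$lwr, 1000 * fx$lar)
  # max CGR where the biomass derivative is maximal, between s and a
  cfb <- fitb$coefficients
  peak <- fx$add[which.max(fx$cgr)]
  expect_gt(peak, cfb[["s"]] - 50)
  expect_lt(peak, cfb[["a"]] + 50)
  expect_equal(which.max(fx$cgr),
               which.max(double_logistic_derivative(tg, cfb)))
})

test_that("interval RGR equals the time-average of instantaneous RGR", {
  # quadrature oracle: ln W(t2) - ln W(t1) = integral of W'/W
  cf <- dl_coef(5, 40, 0.02, 300, 0.03, 800)
  t1 <- 100; t2 <- 500
  grid <- seq(t1, t2, length.out = 20001)
  rgr_inst <- double_logistic_derivative(grid, cf) / double_logistic(grid, cf)
  mean_inst <- sum((rgr_inst[-1] + rgr_inst[-length(grid)]) / 2 *
                     diff(grid)) / (t2 - t1)
  w1 <- double_logistic(t1, cf); w2 <- double_logistic(t2, cf)
  expect_equal(classical_rgr(w1, w2, t1, t2), mean_inst, tolerance = 1e-8)
})

test_that("classical indices converge to functional ones as intervals shrink", {
  cf <- dl_coef(5, 40, 0.02, 300, 0.03, 800)
  t0 <- 350
  inst <- double_logistic_derivative(t0, cf) / double_logistic(t0, cf)
  widths <- c(50, 10, 1)
  errs <- vapply(widths, function(h) {
    w1 <- double_logistic(t0 - h / 2, cf)
    w2 <- double_logistic(t0 + h / 2, cf)
    abs(classical_rgr(w1, w2, t0 - h / 2, t0 + h / 2) - inst)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-6)
})

test_that("harvest means and interval tables have the expected shape", {
  design <- sowing_date_design()
  w <- generate_weather(antumapu_profile(), "2010-12-07", 182, seed = 2)
  th <- accumulate_gdd(w)
  obs <- generate_plant_data(design, th, seed = 2)
  hm <- harvest_means(obs)
  expect_equal(nrow(hm), 2 * length(seq(24, 181, 12)))
  sd1 <- hm[hm$treatment == "SD1", ]
  iv <- interval_indices(sd1, density = 50, thermal = th)
  expect_equal(nrow(iv), nrow(sd1) - 1)
  expect_named(iv, c("das", "add", "rgr", "nar", "lwr", "lar", "cgr",
                     "slw", "lai"))
  expect_equal(iv$add, das_to_add(th, iv$das))
  expect_true(all(is.finite(iv$rgr)))
})

test_that("non-positive biomass on the grid is reported with offenders", {
  tg <- seq(0, 1200, 25)
  fitb <- fit_double_logistic(tg, double_logistic(tg, cf_rise) + 10,
                              restarts = 0)
  shifted <- fitb
  shifted$coefficients[["y_min"]] <- -100
  shifted$coefficients[["y_max"]] <- -60
  expect_error(functional_indices(shifted, fitb, 50, tg), "non-positive")
})
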