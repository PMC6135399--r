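ref_biomass <- chia_reference_coefficients("biomass")

test_that("double logistic matches a hand two-exponential evaluation", {
  # growth term sits exactly at 0.5 at its inflection
  cf <- dl_coef(0, 1, 0.02, 300, 0.03, 1e6)  # senescence pushed far out
  expect_equal(double_logistic(300, cf), 0.5 + 1 / (1 + exp(0.03 * (300 - 1e6))),
               tolerance = 1e-12)
  # zero range collapses to a constant
  flat <- dl_coef(7, 7, 0.02, 300, 0.03, 800)
  expect_equal(double_logistic(c(0, 500, 1400), flat), rep(7, 3))
  # published SD1 biomass row at t = 0, against explicit exponentials
  r <- ref_biomass[ref_biomass$treatment == "SD1", ]
  hand <- r$y_min + (r$y_max - r$y_min) *
    (1 / (1 + exp(-r$m_s * (0 - r$s))) + 1 / (1 + exp(r$m_a * (0 - r$a))))
  cf1 <- dl_coef(r$y_min, r$y_max, r$m_s, r$s, r$m_a, r$a)
  expect_equal(double_logistic(0, cf1), hand)
  # numerically safe far outside the data range
  expect_true(all(is.finite(double_logistic(c(-1e5, 1e5), cf1))))
})

test_that("analytic derivative agrees with central differences", {
  flat <- dl_coef(7, 7, 0.02, 300, 0.03, 800)
  expect_equal(double_logistic_derivative(seq(0, 1000, 100), flat),
               rep(0, 11))
  set.seed(2)
  ts <- runif(20, 0, 1400)
  h <- 1e-3
  fd <- (double_logistic(ts + h, cf_rise) - double_logistic(ts - h, cf_rise)) /
    (2 * h)
  an <- double_logistic_derivative(ts, cf_rise)
  # relative to the slope scale (pointwise relative error is meaningless
  # where the curve is flat and both estimates are ~0)
  expect_lt(max(abs(an - fd)) / max(abs(fd)), 1e-6)
  # at most two sign changes across the domain (rise then fall)
  sgn <- sign(double_logistic_derivative(seq(0, 1400, 5), cf_rise))
  sgn <- sgn[sgn != 0]
  expect_lte(sum(diff(sgn) != 0), 2)
})

test_that("canonicalization maps the term-swapped labelling onto the same curve", {
  cf <- as_swapped <- unclass(cf_rise)
  as_swapped[c("m_s", "s", "m_a", "a")] <-
    c(-cf[["m_a"]], cf[["a"]], -cf[["m_s"]], cf[["s"]])
  tg <- seq(0, 1200, 50)
  expect_equal(double_logistic(tg, as_swapped), double_logistic(tg, cf))
  back <- dl_canonical(as_swapped)
  expect_equal(unclass(back), cf)
})

test_that("heuristic starting values are order-invariant and lie in the basin", {
  tg <- seq(0, 1200, 40)
  y <- double_logistic(tg, cf_rise)
  g <- initial_guess(tg, y)
  set.seed(9)
  sh <- sample(length(tg))
  expect_equal(unclass(initial_guess(tg[sh], y[sh])), unclass(g))
  # basin of attraction: a fit from the heuristic recovers the truth
  fit <- fit_double_logistic(tg, y, restarts = 0)
  expect_lt(max(rel_err(unclass(fit$coefficients), unclass(cf_rise))), 1e-6)
  expect_error(initial_guess(tg, rep(3, length(tg))), "constant")
  expect_error(initial_guess(1:5, 1:5), "at least 8")
})

test_that("zero-noise data is a fixed point of the fitter", {
  r <- ref_biomass[ref_biomass$treatment == "IT2", ]
  truth <- dl_coef(r$y_min, r$y_max, r$m_s, r$s, r$m_a, r$a)
  tg <- seq(0, 800, 25)
  fit <- fit_double_logistic(tg, double_logistic(tg, truth), seed = 4)
  expect_true(fit$converged)
  expect_lt(max(rel_err(unclass(fit$coefficients),
                        unclass(dl_canonical(truth)))), 1e-6)
  expect_lt(fit$rmse, 1e-8)
  # SSE at the solution does not exceed SSE at the starting point
  y <- double_logistic(tg, truth)
  sse_init <- sum((y - double_logistic(tg, fit$init))^2)
  expect_lte(fit$sse, sse_init)
})

test_that("noisy published-magnitude data still gives near-unity R2", {
  r <- ref_biomass[ref_biomass$treatment == "SD1", ]
  truth <- dl_coef(r$y_min, r$y_max, r$m_s, r$s, r$m_a, r$a)
  tg <- seq(0, 1400, 25)
  set.seed(31)
  y <- double_logistic(tg, truth) + rnorm(length(tg), 0, 0.4906)
  fit <- fit_double_logistic(tg, y, seed = 31)
  expect_true(fit$converged)
  expect_gt(fit$r2, 0.98)
  expect_equal(fit$rmse^2 * fit$n, fit$error^2 * (fit$n - 6))
})

test_that("the damped solution beats a coarse lattice around the optimum", {
  tg <- seq(0, 1200, 40)
  set.seed(6)
  y <- double_logistic(tg, cf_rise) + rnorm(length(tg), 0, 0.5)
  fit <- fit_double_logistic(tg, y, seed = 6)
  sse <- function(p) sum((y - double_logistic(tg, p))^2)
  best_grid <- Inf
  cf <- unclass(fit$coefficients)
  steps <- c(0.95, 1, 1.05)
  for (f1 in steps) for (f2 in steps) for (f3 in steps) {
    for (f4 in steps) for (f5 in steps) for (f6 in steps) {
      p <- cf * c(f1, f2, f3, f4, f5, f6)
      best_grid <- min(best_grid, sse(p))
    }
  }
  expect_lte(fit$sse, best_grid + 1e-10)
})

test_that("goodness-of-fit columns follow their defining formulas", {
  set.seed(8)
  y <- rnorm(25, 10, 3)
  yhat <- y + rnorm(25, 0, 0.5)
  g <- goodness_of_fit(y, yhat)
  sse <- sum((y - yhat)^2)
  sst <- sum((y - mean(y))^2)
  expect_equal(g$rmse, sqrt(sse / 25))
  expect_equal(g$error, sqrt(sse / 19))
  expect_equal(g$r2, 1 - sse / sst)
  f <- ((sst - sse) / 5) / (sse / 19)
  expect_equal(g$p_value, pf(f, 5, 19, lower.tail = FALSE))
  perfect <- goodness_of_fit(y, y)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$r2, 1)
  expect_equal(goodness_of_fit(y, rep(mean(y), 25))$r2, 0)
  expect_error(goodness_of_fit(y[1:6], y[1:6]), "more observations")
})

test_that("coefficient-row averaging reproduces table arithmetic", {
  sd_rows <- ref_biomass[ref_biomass$treatment %in% c("SD1", "SD2"), ]
  avg <- average_coefficients(sd_rows)
  expect_equal(avg$y_max, mean(c(66.620, 102.889)))
  expect_equal(avg$y_min, (-67.742 + -103.846) / 2)
  one <- average_coefficients(sd_rows[1, ])
  expect_equal(one$s, sd_rows$s[1])
  expect_error(average_coefficients(list()), "empty")
})

test_that("paired coefficient comparison behaves at its limits", {
  tg <- seq(0, 1200, 40)
  y <- double_logistic(tg, cf_rise)
  fit <- fit_double_logistic(tg, y, restarts = 0)
  expect_equal(compare_fits(fit, fit), 1)
  # closed-form paired-t oracle on raw coefficient vectors
  a <- unclass(cf_rise)
  b <- a + c(100, 120, 0.01, 90, 0.01, 110)
  d <- a - b
  tval <- mean(d) / (sd(d) / sqrt(6))
  expect_equal(compare_fits(a, b), 2 * pt(abs(tval), 5, lower.tail = FALSE))
  # a large (non-uniform) separation is highly significant
  expect_lt(compare_fits(a, a + c(400, 500, 450, 520, 480, 510)), 0.05)
  # an exactly constant shift degenerates, with a warning
  expect_warning(p0 <- compare_fits(a, a + 500), "constant")
  expect_equal(p0, 0)
  # the two published sowing-date rows are declared not different
  r1 <- ref_biomass[ref_biomass$treatment == "SD1", ]
  r2 <- ref_biomass[ref_biomass$treatment == "SD2", ]
  cfa <- dl_coef(r1$y_min, r1$y_max, r1$m_s, r1$s, r1$m_a, r1$a)
  cfb <- dl_coef(r2$y_min, r2$y_max, r2$m_s, r2$s, r2$m_a, r2$a)
  expect_gt(compare_fits(cfa, cfb), 0.05)
})
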