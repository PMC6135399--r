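# Damped least-squares fitting of the double logistic, plus the
# goodness-of-fit summaries reported for each treatment (RMSE, residual
# standard error, R2 and the regression F-test p-value) and helpers for
# averaging and comparing coefficient sets.

#' Goodness-of-fit summaries for a fitted trajectory
#'
#' `rmse` is the residual root mean square with denominator `n`; `error`
#' the residual standard error with denominator `n - n_params`; `r2` the
#' coefficient of determination `1 - SSE/SST`; `p_value` comes from the
#' regression F-test with `(n_params - 1, n - n_params)` degrees of
#' freedom.
#'
#' @param y Observed values.
#' @param yhat Fitted values.
#' @param n_params Number of model parameters (6 for the double logistic).
#' @return List with `rmse`, `error`, `r2`, `p_value`.
#' @export
goodness_of_fit <- function(y, yhat, n_params = 6) {
  check_number(y, "y")
  check_number(yhat, "yhat")
  n <- length(y)
  if (length(yhat) != n) stop("y and yhat lengths differ", call. = FALSE)
  if (n <= n_params) {
    stop("need more observations than parameters (n > ", n_params, ")",
         call. = FALSE)
  }
  sse <- sum((y - yhat)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  df1 <- n_params - 1
  df2 <- n - n_params
  f <- if (sse > 0) ((sst - sse) / df1) / (sse / df2) else Inf
  list(
    rmse = sqrt(sse / n),
    error = sqrt(sse / df2),
    r2 = r2,
    p_value = stats::pf(f, df1, df2, lower.tail = FALSE)
  )
}

#' Fit the double logistic by Levenberg-Marquardt least squares
#'
#' Minimizes the residual sum of squares with damped (Levenberg-Marquardt)
#' least squares from a heuristic start ([initial_guess()]), its
#' term-swapped twin, and a number of seeded random restarts; the solution
#' with the lowest SSE wins (ties broken by first found). Fitted
#' coefficients are canonicalized to `s <= a` (see [dl_canonical()]).
#'
#' @param t Thermal time of the observations (degree C days); at least 7
#'   distinct values. Fitting on days after sowing instead is simply a
#'   matter of passing that axis.
#' @param y Observed biomass (g per plant) or leaf area (cm2 per plant).
#' @param init Optional starting coefficients; by default the heuristic
#'   guess is used.
#' @param max_iter Maximum Levenberg-Marquardt iterations per start.
#' @param tol Relative SSE-reduction convergence tolerance (also used as
#'   the ftol of the damped solver); step-norm tolerance is 1e-12.
#' @param restarts Number of random restarts around the starting point
#'   (default 5).
#' @param seed Seed for the restart perturbations; `NULL` leaves the RNG
#'   state alone.
#' @param lower,upper Optional box bounds (length-6, in
#'   `y_min, y_max, m_s, s, m_a, a` order). Unbounded by default: published
#'   chia fits carry negative `y_min` and negative `m_s`.
#' @param variable Optional label stored with the result.
#' @return An object of class `dl_fit`: a list with elements
#'   `coefficients` (canonicalized `dl_coef`), `rmse`, `error`, `r2`,
#'   `p_value`, `converged`, `n_iter`, `covariance` (6x6), `sse`, `n`,
#'   `fitted`, `residuals`, `data`, `init`, `message`.
#' @export
fit_double_logistic <- function(t, y, init = NULL, max_iter = 400,
                                tol = 1e-10, restarts = 5, seed = NULL,
                                lower = NULL, upper = NULL, variable = NULL) {
  check_number(t, "t")
  check_number(y, "y")
  if (length(t) != length(y)) stop("t and y lengths differ", call. = FALSE)
  if (length(unique(t)) < 7L) {
    stop("need at least 7 distinct t values to identify 6 parameters",
         call. = FALSE)
  }
  o <- order(t)
  t <- t[o]
  y <- y[o]
  g0 <- if (is.null(init)) {
    tryCatch(initial_guess(t, y), error = function(e) {
      stop("could not build a starting point: ", conditionMessage(e),
           call. = FALSE)
    })
  } else {
    as_dl_coef(init)
  }
  g0 <- unclass(g0)[dl_names]
  swap <- g0
  swap[c("m_s", "s", "m_a", "a")] <-
    c(-g0[["m_a"]], g0[["a"]], -g0[["m_s"]], g0[["s"]])
  starts <- list(g0, swap)
  if (restarts > 0) {
    span <- diff(range(t))
    starts <- c(starts, with_seed(seed, lapply(seq_len(restarts), function(i) {
      p <- g0
      p[c("m_s", "m_a")] <- p[c("m_s", "m_a")] * exp(stats::rnorm(2, 0, 0.5))
      p[c("s", "a")] <- p[c("s", "a")] + stats::rnorm(2, 0, span / 10)
      p[c("y_min", "y_max")] <- p[c("y_min", "y_max")] +
        stats::rnorm(2, 0, 0.05 * max(diff(range(y)), 1e-8))
      p
    })))
  }
  resid_fn <- function(p) y - double_logistic(t, setNames(p, dl_names))
  ctrl <- minpack.lm::nls.lm.control(maxiter = max_iter, ftol = tol,
                                     ptol = 1e-12)
  args <- list(fn = resid_fn, control = ctrl)
  if (!is.null(lower)) args$lower <- lower
  if (!is.null(upper)) args$upper <- upper
  best <- NULL
  for (p in starts) {
    f <- tryCatch(do.call(minpack.lm::nls.lm, c(list(par = p), args)),
                  error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || f$deviance < best$deviance)) {
      best <- f
    }
  }
  if (is.null(best)) stop("all starts failed in the damped solver",
                          call. = FALSE)
  coef <- dl_canonical(setNames(best$par, dl_names))
  if (!is.null(variable)) attr(coef, "variable") <- variable
  n <- length(y)
  yhat <- double_logistic(t, coef)
  gof <- goodness_of_fit(y, yhat, n_params = 6)
  sigma2 <- best$deviance / max(n - 6, 1)
  covariance <- tryCatch(sigma2 * solve(best$hessian / 2),
                         error = function(e) {
                           matrix(NA_real_, 6, 6,
                                  dimnames = list(dl_names, dl_names))
                         })
  rank_ok <- is.finite(covariance[1, 1])
  structure(list(
    coefficients = coef,
    variable = variable,
    rmse = gof$rmse,
    error = gof$error,
    r2 = gof$r2,
    p_value = gof$p_value,
    converged = best$info %in% 1:4,
    n_iter = best$niter,
    covariance = covariance,
    rank_deficient = !rank_ok,
    sse = best$deviance,
    n = n,
    fitted = yhat,
    residuals = y - yhat,
    data = data.frame(t = t, y = y),
    init = setNames(g0, dl_names),
    message = best$message
  ), class = "dl_fit")
}

#' @export
print.dl_fit <- function(x, ...) {
  cat("Double-logistic fit (", x$n, " points",
      if (!is.null(x$variable)) paste0(", ", x$variable), ")\n", sep = "")
  cf <- unclass(x$coefficients)
  attributes(cf) <- list(names = names(cf))
  print(round(cf, 4))
  cat(sprintf("RMSE %.4g  Error %.4g  R2 %.4f  p %.3g  %s in %d iter\n",
              x$rmse, x$error, x$r2, x$p_value,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Coefficient row of a fit, in reporting order
#'
#' @param fit A `dl_fit` object.
#' @return One-row data frame `y_min, y_max, m_s, s, m_a, a, rmse, error,
#'   r2, p` mirroring the published coefficient tables.
#' @export
coef_row <- function(fit) {
  stopifnot(inherits(fit, "dl_fit"))
  cf <- as.list(unclass(fit$coefficients))
  data.frame(cf, rmse = fit$rmse, error = fit$error, r2 = fit$r2,
             p = fit$p_value)
}

#' Element-wise average of coefficient rows
#'
#' Aggregates per-treatment fits into the "average" rows of a coefficient
#' table: the plain arithmetic mean of every coefficient and fit statistic.
#'
#' @param rows A list of `dl_fit` objects, or a data frame of numeric
#'   coefficient columns (e.g. from [chia_reference_coefficients()]).
#' @return One-row data frame of column means.
#' @export
average_coefficients <- function(rows) {
  if (inherits(rows, "dl_fit")) rows <- list(rows)
  if (is.list(rows) && !is.data.frame(rows)) {
    if (length(rows) == 0L) stop("empty list of fits", call. = FALSE)
    rows <- do.call(rbind, lapply(rows, coef_row))
  }
  if (!is.data.frame(rows) || nrow(rows) == 0L) {
    stop("need a non-empty data frame or list of fits", call. = FALSE)
  }
  num <- vapply(rows, is.numeric, logical(1))
  as.data.frame(lapply(rows[num], mean))
}

#' Compare two fitted coefficient sets by paired t-test
#'
#' Pairs the six coefficients of two fits and tests whether their mean
#' difference is zero (two-sided). Identical fits give p = 1 by the zero
#' difference convention; a constant non-zero shift (zero variance of the
#' differences) gives p = 0 with a warning. This coefficient-wise pairing
#' is one reading of how published double-logistic fits have been
#' compared; the methods vignette discusses the ambiguity.
#'
#' @param fit_a,fit_b `dl_fit` objects (both must have converged) or bare
#'   coefficient vectors.
#' @return Two-sided p-value.
#' @export
compare_fits <- function(fit_a, fit_b) {
  grab <- function(f, nm) {
    if (inherits(f, "dl_fit")) {
      if (!f$converged) stop(nm, " did not converge", call. = FALSE)
      unclass(f$coefficients)[dl_names]
    } else {
      unclass(as_dl_coef(f))[dl_names]
    }
  }
  d <- grab(fit_a, "fit_a") - grab(fit_b, "fit_b")
  if (all(d == 0)) return(1)
  s <- stats::sd(d)
  if (s == 0) {
    warning("coefficients differ by an exact constant; p-value degenerates to 0")
    return(0)
  }
  tval <- mean(d) / (s / sqrt(length(d)))
  2 * stats::pt(abs(tval), df = length(d) - 1, lower.tail = FALSE)
}
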