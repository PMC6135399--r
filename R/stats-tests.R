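# The statistical layer: one-way ANOVA per response per time point,
# Duncan's multiple range test at alpha = 0.05 for mean separation, and
# Pearson correlation matrices among growth indices.

normalize_groups <- function(groups, values = NULL) {
  if (is.list(groups) && !is.data.frame(groups)) {
    labels <- names(groups) %||% paste0("g", seq_along(groups))
    data.frame(
      value = unlist(groups, use.names = FALSE),
      group = factor(rep(labels, lengths(groups)), levels = labels)
    )
  } else {
    data.frame(value = values, group = factor(groups))
  }
}

#' One-way analysis of variance
#'
#' Standard between/within decomposition, computed through a linear-model
#' fit. Accepts either a named list of replicate vectors or paired
#' value/group vectors.
#'
#' @param groups Named list of numeric vectors, or a vector of group
#'   labels when `values` is supplied.
#' @param values Optional numeric response vector paired with `groups`.
#' @return Data frame of class `anova_table` with columns `source`, `df`,
#'   `sum_sq`, `mean_sq`, `f`, `p` (rows: treatment, residuals).
#' @export
one_way_anova <- function(groups, values = NULL) {
  d <- normalize_groups(groups, values)
  check_number(d$value, "values")
  if (nlevels(d$group) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(table(d$group) < 2L)) {
    stop("each group needs at least two replicates", call. = FALSE)
  }
  a <- stats::anova(stats::lm(value ~ group, data = d))
  out <- data.frame(
    source = c("treatment", "residuals"),
    df = a$Df,
    sum_sq = a$`Sum Sq`,
    mean_sq = a$`Mean Sq`,
    f = a$`F value`,
    p = a$`Pr(>F)`
  )
  class(out) <- c("anova_table", "data.frame")
  out
}

# Duncan's critical value for a span of p ordered means: the studentized
# range quantile at protection level (1 - alpha)^(p - 1).
duncan_q <- function(alpha, p, df) {
  stats::qtukey((1 - alpha)^(p - 1), nmeans = p, df = df)
}

#' Duncan's multiple range test
#'
#' Sorts the group means in descending order and compares every pair at a
#' span-dependent critical range `q_p * sqrt(MSE / n)`, where `q_p` is the
#' studentized-range quantile at Duncan's protection level
#' `(1 - alpha)^(p - 1)` for a span of `p` means and the ANOVA residual
#' degrees of freedom. Letters are assigned by the standard sweep over
#' maximal non-significant stretches, so letter runs are contiguous over
#' the sorted means. For two groups the test is equivalent to an LSD
#' t-test at `alpha`. Near-balanced designs use the harmonic mean of the
#' group sizes.
#'
#' @inheritParams one_way_anova
#' @param alpha Protection level, default 0.05.
#' @return List of class `duncan_result`: `means` (data frame sorted by
#'   descending mean with `group`, `mean`, `n`, `letters`), `alpha`,
#'   `mse`, `df_error`, `critical_range` (by span).
#' @export
duncan_mrt <- function(groups, values = NULL, alpha = 0.05) {
  d <- normalize_groups(groups, values)
  anova_tab <- one_way_anova(d$group, d$value)
  mse <- anova_tab$mean_sq[anova_tab$source == "residuals"]
  df_error <- anova_tab$df[anova_tab$source == "residuals"]
  if (df_error < 1) stop("no residual degrees of freedom", call. = FALSE)
  m <- tapply(d$value, d$group, mean)
  ns <- tapply(d$value, d$group, length)
  n_h <- length(ns) / sum(1 / ns)  # harmonic mean; = n when balanced
  ord <- order(m, decreasing = TRUE)
  m <- m[ord]
  ns <- ns[ord]
  k <- length(m)
  crit <- vapply(2:max(k, 2), function(p) {
    duncan_q(alpha, p, df_error) * sqrt(mse / n_h)
  }, numeric(1))
  names(crit) <- paste0("span", 2:max(k, 2))
  # significant difference between sorted positions i < j
  sig <- function(i, j) (m[i] - m[j]) > crit[j - i]
  # for each leading mean, the furthest mean it does not differ from;
  # maximal such stretches become the letter groups (contiguous by
  # construction, so letter sets are order-consistent)
  reach <- vapply(seq_len(k), function(i) {
    j <- i
    while (j < k && !sig(i, j + 1)) j <- j + 1
    as.integer(j)
  }, integer(1))
  stretches <- unique(lapply(seq_len(k), function(i) c(i, reach[i])))
  n_str <- length(stretches)
  keep <- vapply(seq_len(n_str), function(u) {
    !any(vapply(seq_len(n_str), function(v) {
      v != u && stretches[[v]][1] <= stretches[[u]][1] &&
        stretches[[v]][2] >= stretches[[u]][2]
    }, logical(1)))
  }, logical(1))
  stretches <- stretches[keep]
  letters_vec <- rep("", k)
  for (s_i in seq_along(stretches)) {
    rng <- stretches[[s_i]]
    lab <- letters[(s_i - 1) %% 26 + 1]
    idx <- rng[1]:rng[2]
    letters_vec[idx] <- paste0(letters_vec[idx], lab)
  }
  structure(list(
    means = data.frame(group = names(m), mean = as.numeric(m),
                       n = as.integer(ns), letters = letters_vec),
    alpha = alpha,
    mse = mse,
    df_error = df_error,
    critical_range = crit,
    anova = anova_tab
  ), class = "duncan_result")
}

#' @export
print.duncan_result <- function(x, ...) {
  cat(sprintf("Duncan multiple range test (alpha = %g, MSE = %.4g, df = %d)\n",
              x$alpha, x$mse, x$df_error))
  print(x$means, row.names = FALSE)
  invisible(x)
}

#' Pearson correlation matrix with p-values
#'
#' Pairwise Pearson correlations among named index series, with p-values
#' from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' A zero-variance series yields `NA` correlations and a warning, never a
#' silent 0.
#'
#' @param series Data frame (or named list of equal-length numeric
#'   vectors), `n >= 3` rows; rows with any `NA` are dropped.
#' @return List of class `correlation_matrix` with elements `r`, `p`
#'   (symmetric matrices, unit/zero diagonal) and `n`.
#' @export
correlation_matrix <- function(series) {
  d <- as.data.frame(series)
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 complete rows", call. = FALSE)
  if (ncol(d) < 2L) stop("need at least two series", call. = FALSE)
  sds <- vapply(d, stats::sd, numeric(1))
  if (any(sds == 0)) {
    warning("zero-variance series: ",
            paste(names(d)[sds == 0], collapse = ", "),
            "; correlations set to NA")
  }
  r <- suppressWarnings(stats::cor(d))
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  diag(r) <- ifelse(sds == 0, NA_real_, 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- 0
  structure(list(r = r, p = p, n = n), class = "correlation_matrix")
}
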