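#' Pearson correlation coefficient
#'
#' The covariance of the two variables (deviations from each mean
#' multiplied pairwise, summed, divided by N - 1) standardized by both
#' sample standard deviations.
#'
#' @param x,y numeric vectors of equal length >= 3, each with nonzero
#'   variance.
#' @return The coefficient r in \[-1, 1\].
#' @examples
#' pearson_r(1:4, c(2, 1, 4, 3))
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y))
    stop("'x' and 'y' must have equal length", call. = FALSE)
  if (length(x) < 3)
    stop("at least 3 observations are required", call. = FALSE)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  r <- stats::cov(x, y) / (sx * sy)
  max(-1, min(1, r))
}

#' Two-sided significance of a correlation
#'
#' Tests H0: rho = 0 with the t statistic
#' \eqn{t = r\sqrt{(N-2)/(1-r^2)}} on N - 2 degrees of freedom,
#' two-sided.
#'
#' @param r correlation coefficient.
#' @param n sample size (>= 3).
#' @param alpha significance level.
#' @return Logical flag; `|r| = 1` is flagged significant by convention
#'   (with a warning, the t statistic being unbounded).
#' @examples
#' cor_significant(0.642, 76, 0.01)  # TRUE
#' cor_significant(0.150, 76, 0.05)  # FALSE
#' @export
cor_significant <- function(r, n, alpha = 0.05) {
  if (n < 3) stop("'n' must be >= 3", call. = FALSE)
  if (abs(r) >= 1) {
    warning("|r| = 1: flagged significant by convention", call. = FALSE)
    return(TRUE)
  }
  t <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  p < alpha
}

#' Bootstrap settings for correlation confidence intervals
#'
#' @param n_resamples number of bootstrap resamples (>= 1).
#' @param confidence confidence level in percent (the 95 default yields
#'   percentile bounds at 2.5 and 97.5).
#' @param seed integer seed making the resampling deterministic.
#' @param degenerate_policy what to do when a resample has zero variance
#'   in either variable: `"redraw"` (draw a replacement resample, logged)
#'   or `"drop"` (discard it).
#' @return An object of class `caregap_bootstrap_config`.
#' @export
bootstrap_config <- function(n_resamples = 2000, confidence = 95,
                             seed = 1L,
                             degenerate_policy = c("redraw", "drop")) {
  if (n_resamples < 1) stop("'n_resamples' must be >= 1", call. = FALSE)
  if (confidence <= 0 || confidence >= 100)
    stop("'confidence' must lie strictly between 0 and 100", call. = FALSE)
  structure(list(n_resamples = as.integer(n_resamples),
                 confidence = confidence, seed = as.integer(seed),
                 degenerate_policy = match.arg(degenerate_policy)),
            class = "caregap_bootstrap_config")
}

#' Bootstrap percentile confidence interval for a correlation
#'
#' Resamples observation pairs (rows) with replacement, recomputes the
#' Pearson coefficient on each resample, and returns the empirical
#' percentile bounds (2.5 / 97.5 for a 95 percent level). Resampling pairs
#' jointly -- never the two variables independently -- is what makes the
#' interval one for the correlation. Deterministic given the seed.
#'
#' @param x,y numeric vectors as in [pearson_r()].
#' @param cfg a [bootstrap_config()].
#' @return Numeric `c(lower, upper)`, with attribute `n_degenerate` giving
#'   how many zero-variance resamples were redrawn or dropped.
#' @export
bootstrap_cor_ci <- function(x, y, cfg = bootstrap_config()) {
  r0 <- pearson_r(x, y)  # validates input
  n <- length(x)
  alpha <- (100 - cfg$confidence) / 200
  with_seed(cfg$seed, {
    rs <- numeric(cfg$n_resamples)
    n_degenerate <- 0L
    for (b in seq_len(cfg$n_resamples)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        xs <- x[idx]; ys <- y[idx]
        if (stats::sd(xs) > 0 && stats::sd(ys) > 0) {
          rs[b] <- stats::cor(xs, ys)
          break
        }
        n_degenerate <- n_degenerate + 1L
        if (cfg$degenerate_policy == "drop") {
          rs[b] <- NA_real_
          break
        }
      }
    }
    rs <- rs[!is.na(rs)]
    ci <- unname(stats::quantile(rs, c(alpha, 1 - alpha), type = 7))
    attr(ci, "n_degenerate") <- n_degenerate
    ci
  })
}

.strength_scale <- data.frame(
  label = c("negligible", "low", "moderate", "substantial",
            "very high", "near-perfect"),
  lower = c(0.00, 0.10, 0.30, 0.50, 0.70, 0.90),
  upper = c(0.09, 0.29, 0.49, 0.69, 0.89, 1.00),
  stringsAsFactors = FALSE)

#' Verbal strength label of a correlation
#'
#' Six-interval interpretation scale on `|r|`: 0.00--0.09 negligible,
#' 0.10--0.29 low, 0.30--0.49 moderate, 0.50--0.69 substantial,
#' 0.70--0.89 very high, 0.90--1.00 near-perfect. The moderate and
#' substantial intervals are the ones the study's interpretation leans on;
#' the remaining four complete the standard scale.
#'
#' @param r correlation coefficient(s) in \[-1, 1\].
#' @return Character vector of labels; each carries its interval as names
#'   via [strength_scale()].
#' @examples
#' interpret_r(c(0.642, 0.416, -0.55))
#' @export
interpret_r <- function(r) {
  if (any(abs(r) > 1)) stop("'r' must lie in [-1, 1]", call. = FALSE)
  a <- abs(r)
  idx <- findInterval(a, .strength_scale$lower)
  .strength_scale$label[idx]
}

#' @rdname interpret_r
#' @export
strength_scale <- function() .strength_scale

#' Pairwise correlation matrix over the district indicators
#'
#' Computes all unordered pairs over the indicator columns: Pearson r,
#' significance flags at the 0.05 and 0.01 levels, bootstrap percentile
#' confidence bounds and the verbal strength label. By convention the
#' accessibility indicators X4--X7 enter as their TOPSIS group closeness
#' values, so the matrix relates demand (X1), capacities (X2, X3) and the
#' achieved accessibility level.
#'
#' @param indicator_table data frame of numeric indicator columns, one row
#'   per district (>= 3 rows).
#' @param cfg a [bootstrap_config()]; each pair's resampling seed is
#'   derived deterministically from `cfg$seed` and the pair's position.
#' @param on_zero_variance `"error"` (a constant column makes the pair's
#'   correlation undefined and stops the computation) or `"na"` (the pair
#'   gets `NA` entries with a warning; used by batch runs so pathological
#'   synthetic inputs survive).
#' @return An object of class `caregap_correlations`: list with `pairs`
#'   (data frame `var_a`, `var_b`, `n`, `r`, `sig05`, `sig01`,
#'   `ci_lower`, `ci_upper`, `label`, one row per unordered pair plus the
#'   diagonal) and `matrix` (the symmetric r matrix with unit diagonal).
#' @export
correlation_matrix <- function(indicator_table,
                               cfg = bootstrap_config(),
                               on_zero_variance = c("error", "na")) {
  on_zero_variance <- match.arg(on_zero_variance)
  vars <- names(indicator_table)
  n <- nrow(indicator_table)
  if (n < 3) stop("at least 3 districts are required", call. = FALSE)
  k <- length(vars)
  rmat <- diag(1, k, k); dimnames(rmat) <- list(vars, vars)
  rows <- list()
  pair_no <- 0L
  for (i in seq_len(k)) for (j in i:k) {
    if (i == j) {
      rows[[length(rows) + 1L]] <- data.frame(
        var_a = vars[i], var_b = vars[j], n = n, r = 1,
        sig05 = NA, sig01 = NA, ci_lower = 1, ci_upper = 1,
        label = "near-perfect", stringsAsFactors = FALSE)
      next
    }
    pair_no <- pair_no + 1L
    x <- indicator_table[[i]]; y <- indicator_table[[j]]
    if (on_zero_variance == "na" &&
          (stats::sd(x) == 0 || stats::sd(y) == 0)) {
      warning(sprintf("undefined correlation (zero variance): %s-%s",
                      vars[i], vars[j]), call. = FALSE)
      rmat[i, j] <- rmat[j, i] <- NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        var_a = vars[i], var_b = vars[j], n = n, r = NA_real_,
        sig05 = NA, sig01 = NA, ci_lower = NA_real_, ci_upper = NA_real_,
        label = NA_character_, stringsAsFactors = FALSE)
      next
    }
    r <- pearson_r(x, y)
    pair_cfg <- cfg
    pair_cfg$seed <- (cfg$seed + 7919L * pair_no) %% .Machine$integer.max
    ci <- bootstrap_cor_ci(x, y, pair_cfg)
    rmat[i, j] <- rmat[j, i] <- r
    rows[[length(rows) + 1L]] <- data.frame(
      var_a = vars[i], var_b = vars[j], n = n, r = r,
      sig05 = cor_significant(r, n, 0.05),
      sig01 = cor_significant(r, n, 0.01),
      ci_lower = ci[1], ci_upper = ci[2],
      label = interpret_r(r), stringsAsFactors = FALSE)
  }
  structure(list(pairs = do.call(rbind, rows), matrix = rmat),
            class = "caregap_correlations")
}

#' @export
print.caregap_correlations <- function(x, ...) {
  cat("Pairwise Pearson correlations (",
      x$pairs$n[1], " districts):\n", sep = "")
  print(round(x$matrix, 3))
  invisible(x)
}

#' Assemble the association input table
#'
#' Binds the base indicators X1--X3 with the four TOPSIS group closeness
#' scores (as X4--X7), restricted to the districts present in the score
#' table.
#'
#' @param indicators output of [compute_indicators()].
#' @param group_scores output of [topsis_all_groups()].
#' @return Data frame with columns X1--X7, one row per ranked district.
#' @export
association_table <- function(indicators, group_scores) {
  sc <- group_scores$scores
  idx <- match(sc$district_id, indicators$district_id)
  data.frame(X1 = indicators$X1[idx], X2 = indicators$X2[idx],
             X3 = indicators$X3[idx],
             X4 = sc$X4ci, X5 = sc$X5ci, X6 = sc$X6ci, X7 = sc$X7ci,
             row.names = sc$district_id)
}
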