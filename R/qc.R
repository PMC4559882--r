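#' Cumulative distribution of triplicate variances
#'
#' Under the working model the sample variance s^2 of a technical
#' triplicate satisfies s^2 / sigma^2 ~ chi-square with nu = 2 degrees
#' of freedom, so its CDF is F(s^2) = 1 - exp(-s^2 / (2 sigma^2)).
#' `sigma` is the population-level replicate SD scale for the assay,
#' in Ct units.
#'
#' @param s2 numeric vector of variances (Ct^2), all >= 0.
#' @param sigma scale parameter, > 0.
#' @return Probabilities in `[0, 1]`, nondecreasing in `s2`.
#' @export
variance_cdf <- function(s2, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma) ||
      sigma <= 0) {
    stop_validation("sigma must be a single positive number")
  }
  if (any(s2 < 0, na.rm = TRUE)) stop_validation("variances must be >= 0")
  1 - exp(-s2 / (2 * sigma^2))
}

# Two-sided K-S distance between the empirical CDF of `s2_sorted`
# (pre-sorted) and variance_cdf(., sigma).
#' @noRd
ks_distance <- function(s2_sorted, sigma) {
  n <- length(s2_sorted)
  f <- 1 - exp(-s2_sorted / (2 * sigma^2))
  max(pmax(abs(f - seq_len(n) / n), abs(f - (seq_len(n) - 1) / n)))
}

# Asymptotic Kolmogorov survival function Q(lambda) =
# 2 sum_{k>=1} (-1)^(k-1) exp(-2 k^2 lambda^2).
#' @noRd
kolmogorov_q <- function(lambda) {
  if (lambda < 0.05) return(1)
  k <- 1:100
  q <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(q, 0), 1)
}

#' Fit the variance-law scale by Kolmogorov-Smirnov minimisation
#'
#' Estimates the population replicate SD `sigma` of an assay by
#' searching the scale that minimises the two-sided K-S distance `D`
#' between the empirical CDF of the observed triplicate variances and
#' the chi-square(2) law [variance_cdf()]. The K-S route is preferred
#' over the moment estimator sqrt(mean(s^2)) because it is far less
#' sensitive to the occasional wild triplicate.
#'
#' The search runs a coarse log-spaced grid over
#' `[1e-4 max(s), 10 max(s)]` and then refines with Brent minimisation
#' between the bracketing grid neighbours (tolerance 1e-6); the grid
#' stage guards against the shallow local minima the piecewise-smooth
#' D(sigma) profile can have. The goodness-of-fit p-value uses the
#' asymptotic Kolmogorov distribution at sqrt(n) D, with no correction
#' for the estimated scale (anti-conservative; reported as-is).
#'
#' @param variances numeric vector of triplicate variances s^2 (>= 1
#'   strictly positive value required).
#' @param assay optional assay name carried into the result.
#' @param tol Brent tolerance on sigma.
#' @return Object of class `ks_scale_fit`: list with `assay`, `sigma`,
#'   `D`, `p_value`, `n`.
#' @export
fit_variance_scale <- function(variances, assay = NA_character_,
                               tol = 1e-6) {
  v <- variances[is.finite(variances)]
  if (length(v) < 1 || any(v < 0)) {
    stop_validation("need at least one finite nonnegative variance")
  }
  if (all(v == 0)) {
    stop_degenerate("all variances are zero; scale is unidentifiable")
  }
  v <- sort(v)
  n <- length(v)
  s_max <- sqrt(max(v))
  lo <- 1e-4 * s_max
  hi <- 10 * s_max
  grid <- exp(seq(log(lo), log(hi), length.out = 256))
  d_grid <- vapply(grid, function(s) ks_distance(v, s), numeric(1))
  i <- which.min(d_grid)
  bracket <- c(grid[max(i - 1L, 1L)], grid[min(i + 1L, length(grid))])
  opt <- stats::optimize(function(s) ks_distance(v, s),
                         interval = bracket, tol = tol)
  # ties broken toward smaller sigma
  sigma <- opt$minimum
  D <- opt$objective
  if (d_grid[i] < D) {
    sigma <- grid[i]
    D <- d_grid[i]
  }
  structure(list(assay = assay, sigma = sigma, D = D,
                 p_value = kolmogorov_q(sqrt(n) * D), n = n),
            class = "ks_scale_fit")
}

#' @export
print.ks_scale_fit <- function(x, ...) {
  cat(sprintf("K-S variance-scale fit%s: sigma = %.4f, D = %.4f, p = %.3f, n = %d\n",
              if (is.na(x$assay)) "" else paste0(" [", x$assay, "]"),
              x$sigma, x$D, x$p_value, x$n))
  invisible(x)
}

#' @export
as_report.ks_scale_fit <- function(x, ...) {
  list(assay = x$assay, sigma = x$sigma, D = x$D,
       p = x$p_value, n = x$n)
}

#' Critical triplicate SD for variability-outlier flagging
#'
#' Under the chi-square(2) variance law, P(s > sigma_max) = alpha when
#' sigma_max = sqrt(-2 ln alpha) * sigma (about 2.448 sigma at
#' alpha = 0.05), so alpha is exactly the rate of valid triplicates
#' falsely flagged (type-I false alarms).
#'
#' @param sigma fitted population replicate SD (Ct units).
#' @param alpha significance level in (0, 1].
#' @return The critical SD, same units as `sigma`.
#' @export
variability_threshold <- function(sigma, alpha = 0.05) {
  if (!is.numeric(sigma) || any(sigma <= 0)) {
    stop_validation("sigma must be positive")
  }
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 1) {
    stop_validation("alpha must be in (0, 1]")
  }
  sqrt(-2 * log(alpha)) * sigma
}

#' Build a per-assay QC policy from fitted variance scales
#'
#' @param fits list of [fit_variance_scale()] results (named by assay,
#'   or carrying their own `assay` field).
#' @param alpha significance level for the critical SD.
#' @return Object of class `qc_policy`: data.frame with columns
#'   `assay`, `sigma`, `sigma_max`, plus attribute `alpha`.
#' @export
qc_policy <- function(fits, alpha = 0.05) {
  if (inherits(fits, "ks_scale_fit")) fits <- list(fits)
  assays <- vapply(seq_along(fits), function(i) {
    a <- fits[[i]]$assay
    if (is.na(a) && !is.null(names(fits))) a <- names(fits)[i]
    a
  }, character(1))
  if (anyNA(assays)) stop_validation("every fit must name its assay")
  pol <- data.frame(assay = assays,
                    sigma = vapply(fits, `[[`, numeric(1), "sigma"),
                    sigma_max = variability_threshold(
                      vapply(fits, `[[`, numeric(1), "sigma"), alpha),
                    stringsAsFactors = FALSE)
  structure(pol, alpha = alpha, class = c("qc_policy", "data.frame"))
}

#' Flag variability outliers in a cohort
#'
#' A triplicate is flagged when its sample SD `s` exceeds the assay's
#' critical value `sigma_max`. Flagged triplicates must be excluded
#' from all downstream fitting; [apply_qc()] does both steps.
#'
#' @param cohort a [qpcr_cohort()].
#' @param policy a [qc_policy()] covering every assay in the cohort.
#' @return Logical vector, one flag per cohort row, with attribute
#'   `outliers`: list of flagged sample ids per assay (sorted).
#' @export
flag_variability_outliers <- function(cohort, policy) {
  missing_assays <- setdiff(unique(cohort$assay), policy$assay)
  if (length(missing_assays) > 0) {
    stop_validation("policy lacks sigma_max for assay(s): %s",
                    paste(missing_assays, collapse = ", "))
  }
  smax <- stats::setNames(policy$sigma_max, policy$assay)
  flags <- cohort$s > smax[cohort$assay]
  outliers <- lapply(split(cohort$sample_id[flags], cohort$assay[flags]),
                     function(ids) sort(unique(ids)))
  attr(flags, "outliers") <- outliers
  flags
}

#' Run the full variance QC stage on a cohort
#'
#' Fits the chi-square(2) variance law per assay, derives sigma_max at
#' the requested significance level, flags variability outliers and
#' returns the cleaned cohort alongside the per-assay QC report.
#'
#' @param cohort a [qpcr_cohort()].
#' @param alpha significance level (default 0.05).
#' @return Object of class `qc_result`: list with `fits` (per assay),
#'   `policy`, `flags`, `cohort` (flagged rows removed) and `report`.
#' @export
apply_qc <- function(cohort, alpha = 0.05) {
  fits <- lapply(attr(cohort, "assays"), function(a) {
    fit_variance_scale(cohort$s[cohort$assay == a]^2, assay = a)
  })
  names(fits) <- attr(cohort, "assays")
  policy <- qc_policy(fits, alpha = alpha)
  flags <- flag_variability_outliers(cohort, policy)
  clean <- cohort[!flags, , drop = FALSE]
  attr(clean, "assays") <- attr(cohort, "assays")
  attr(clean, "priors") <- attr(cohort, "priors")
  class(clean) <- class(cohort)
  report <- lapply(names(fits), function(a) {
    f <- fits[[a]]
    ids <- attr(flags, "outliers")[[a]]
    list(sigma = f$sigma,
         sigma_max = policy$sigma_max[policy$assay == a],
         D = f$D, p = f$p_value, n = f$n,
         outlier_sample_ids = if (is.null(ids)) character(0) else ids)
  })
  names(report) <- names(fits)
  structure(list(fits = fits, policy = policy, flags = flags,
                 cohort = clean, report = report),
            class = "qc_result")
}

#' @export
as_report.qc_result <- function(x, ...) x$report

#' @export
print.qc_result <- function(x, ...) {
  for (a in names(x$fits)) {
    r <- x$report[[a]]
    cat(sprintf("%-10s sigma=%.3f sigma_max=%.3f D=%.3f p=%.3f n=%d outliers=%d\n",
                a, r$sigma, r$sigma_max, r$D, r$p, r$n,
                length(r$outlier_sample_ids)))
  }
  invisible(x)
}

#' Moment summary of triplicate variances
#'
#' Returns the root-mean-square sample SD, `mean(s^2)^(1/2)`, and the
#' fourth root of the variance of variances,
#' `(mean(s^4) - mean(s^2)^2)^(1/4)`. Under the chi-square(2) law both
#' approximate the population scale sigma, so their agreement with the
#' K-S fit is a consistency check on the variance model.
#'
#' @param variances numeric vector of variances (>= 2 values).
#' @return Named numeric: `rms_s`, `var_fourth_root`.
#' @export
variance_moment_summary <- function(variances) {
  v <- variances[is.finite(variances)]
  if (length(v) < 2) stop_validation("need at least 2 variances")
  m2 <- mean(v)
  m4 <- mean(v^2)
  c(rms_s = sqrt(m2), var_fourth_root = max(m4 - m2^2, 0)^(1 / 4))
}
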