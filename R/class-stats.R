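#' Fit a Gaussian to one class of a scalar measure
#'
#' Per-class distributions are modelled as normal with mean and SD
#' estimated by the sample mean and n-1 sample SD. Both carry standard
#' errors — se(mu) = sigma / sqrt(n) and se(sigma) =
#' sigma / sqrt(2 (n - 1)) — which feed the downstream threshold and
#' accuracy uncertainty propagation.
#'
#' @param values numeric vector (n >= 2 finite values).
#' @return Object of class `class_gaussian`: list with `mu`, `sigma`,
#'   `n`, `se_mu`, `se_sigma`.
#' @export
fit_class_gaussian <- function(values) {
  v <- values[is.finite(values)]
  n <- length(v)
  if (n < 2) stop_validation("need at least 2 finite values, got %d", n)
  sigma <- stats::sd(v)
  structure(list(mu = mean(v), sigma = sigma, n = n,
                 se_mu = sigma / sqrt(n),
                 se_sigma = sigma / sqrt(2 * (n - 1))),
            class = "class_gaussian")
}

#' Construct a class Gaussian from known parameters
#'
#' For working directly from published summary statistics (a mean, SD
#' and sample size) rather than raw values.
#'
#' @param mu mean (Ct units).
#' @param sigma SD (> 0).
#' @param n sample count (>= 2).
#' @return A `class_gaussian`, as from [fit_class_gaussian()].
#' @export
class_gaussian <- function(mu, sigma, n) {
  if (!is.finite(mu) || !is.finite(sigma) || sigma <= 0) {
    stop_validation("mu must be finite and sigma positive")
  }
  if (n < 2) stop_validation("n must be >= 2")
  structure(list(mu = mu, sigma = sigma, n = as.integer(n),
                 se_mu = sigma / sqrt(n),
                 se_sigma = sigma / sqrt(2 * (n - 1))),
            class = "class_gaussian")
}

#' @export
print.class_gaussian <- function(x, ...) {
  cat(sprintf("class Gaussian: mu = %.4f (se %.4f), sigma = %.4f (se %.4f), n = %d\n",
              x$mu, x$se_mu, x$sigma, x$se_sigma, x$n))
  invisible(x)
}

#' @export
as_report.class_gaussian <- function(x, ...) {
  list(mu = x$mu, sigma = x$sigma, n = x$n,
       se_mu = x$se_mu, se_sigma = x$se_sigma)
}

#' Shapiro-Wilk normality screen
#'
#' Thin wrapper over [stats::shapiro.test()] used to decide whether a
#' class histogram is consistent with a normal parent population
#' (screen passes when p >= 0.05). Zero-variance input is degenerate
#' and raises an error rather than returning the underlying test's
#' failure.
#'
#' @param values numeric vector, 3 <= n <= 5000.
#' @return The Shapiro-Wilk p-value.
#' @export
normality_screen <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 3 || length(v) > 5000) {
    stop_validation("normality screen needs 3 <= n <= 5000, got %d", length(v))
  }
  if (stats::sd(v) == 0) {
    stop_degenerate("all values identical; normality screen undefined")
  }
  stats::shapiro.test(v)$p.value
}

#' Welch two-sample separation test between classes
#'
#' Two-sided t-test with per-group variance estimates and the Welch
#' degrees-of-freedom correction, used to screen which measures
#' actually discriminate the two classes. The t statistic is signed so
#' that it is positive when the target mean exceeds the versus mean.
#'
#' @param values_target,values_versus numeric vectors (each n >= 2).
#' @param shapiro also report per-class Shapiro-Wilk p-values (needs
#'   n >= 3 per class).
#' @return Object of class `separation_report`: list with
#'   `t_statistic`, `welch_df`, `p_value` and (optionally) `shapiro_p`
#'   (named: target, versus).
#' @export
welch_separation <- function(values_target, values_versus, shapiro = TRUE) {
  vt <- values_target[is.finite(values_target)]
  vv <- values_versus[is.finite(values_versus)]
  if (length(vt) < 2 || length(vv) < 2) {
    stop_validation("each class needs >= 2 finite values")
  }
  if (stats::sd(vt) == 0 && stats::sd(vv) == 0) {
    if (mean(vt) == mean(vv)) {
      # identical degenerate samples: no evidence of separation
      res <- list(t_statistic = 0, welch_df = length(vt) + length(vv) - 2,
                  p_value = 1)
    } else {
      stop_degenerate("both classes have zero variance; Welch t undefined")
    }
  } else if (stats::sd(vt) == 0 || stats::sd(vv) == 0) {
    stop_degenerate("a class has zero variance; Welch t undefined")
  } else {
    tt <- stats::t.test(vt, vv, var.equal = FALSE)
    res <- list(t_statistic = unname(tt$statistic),
                welch_df = unname(tt$parameter),
                p_value = tt$p.value)
  }
  if (shapiro) {
    res$shapiro_p <- c(
      target = if (length(vt) >= 3 && stats::sd(vt) > 0)
        normality_screen(vt) else NA_real_,
      versus = if (length(vv) >= 3 && stats::sd(vv) > 0)
        normality_screen(vv) else NA_real_)
  }
  structure(res, class = "separation_report")
}

#' @export
print.separation_report <- function(x, ...) {
  cat(sprintf("Welch separation: t = %.3f, df = %.2f, p = %.3g\n",
              x$t_statistic, x$welch_df, x$p_value))
  if (!is.null(x$shapiro_p)) {
    cat(sprintf("  Shapiro-Wilk p: target %.3f, versus %.3f\n",
                x$shapiro_p["target"], x$shapiro_p["versus"]))
  }
  invisible(x)
}

#' Per-measure, per-class summary statistics table
#'
#' Builds the descriptive table underpinning measure selection: for
#' each requested measure and class it reports n, mean, SD, the
#' Shapiro-Wilk normality p, and the Welch separation p between
#' classes. Measures intended for classification should pass the
#' normality screen (p >= 0.05) in both classes; a Welch p >= 0.05 is
#' flagged with a warning entry because such a measure does not
#' discriminate and makes a poor classifier on its own.
#'
#' @param measures a `measure_table` from [normalize_cohort()].
#' @param measure_names character vector of measure columns.
#' @return data.frame with columns `measure`, `class`, `n`, `mean`,
#'   `sd`, `shapiro_p`, `welch_p`.
#' @export
class_stats_table <- function(measures, measure_names) {
  do.call(rbind, lapply(measure_names, function(m) {
    if (!m %in% names(measures)) stop_validation("unknown measure: %s", m)
    vt <- measures[[m]][measures$class_label == "target"]
    vv <- measures[[m]][measures$class_label == "versus"]
    vt <- vt[is.finite(vt)]
    vv <- vv[is.finite(vv)]
    sep <- welch_separation(vt, vv)
    do.call(rbind, lapply(c("target", "versus"), function(cl) {
      v <- if (cl == "target") vt else vv
      data.frame(measure = m, class = cl, n = length(v),
                 mean = mean(v), sd = stats::sd(v),
                 shapiro_p = unname(sep$shapiro_p[cl]),
                 welch_p = sep$p_value,
                 stringsAsFactors = FALSE)
    }))
  }))
}
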