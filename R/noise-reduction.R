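#' Pearson correlation between two measures
#'
#' Standard Pearson r with the two-sided t-based p-value for the null
#' hypothesis of no correlation, computed on complete pairs. Used to
#' find helper measures whose within-class fluctuations track the
#' discriminating measure and can therefore cancel part of its noise.
#'
#' @param a,b numeric vectors of equal length.
#' @param scope label carried into the result (`"overall"`,
#'   `"target"`, `"versus"`, ...).
#' @return Object of class `correlation_report`: list with `scope`,
#'   `r`, `p_value`, `n`.
#' @export
pearson_correlation <- function(a, b, scope = "overall") {
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 3) stop_validation("need >= 3 complete pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop_degenerate("constant input; correlation undefined")
  }
  ct <- stats::cor.test(a, b, method = "pearson")
  structure(list(scope = scope, r = unname(ct$estimate),
                 p_value = ct$p.value, n = length(a)),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("Pearson correlation [%s]: r = %.3f, p = %.3g, n = %d\n",
              x$scope, x$r, x$p_value, x$n))
  invisible(x)
}

#' Correlation table for a measure pair: overall and per class
#'
#' @param measures a `measure_table` from [normalize_cohort()].
#' @param a,b measure column names.
#' @return data.frame with columns `scope`, `r`, `p_value`, `n`.
#' @export
correlation_table <- function(measures, a, b) {
  for (m in c(a, b)) {
    if (!m %in% names(measures)) stop_validation("unknown measure: %s", m)
  }
  scopes <- list(overall = rep(TRUE, nrow(measures)),
                 target = measures$class_label == "target",
                 versus = measures$class_label == "versus")
  do.call(rbind, lapply(names(scopes), function(sc) {
    r <- pearson_correlation(measures[[a]][scopes[[sc]]],
                             measures[[b]][scopes[[sc]]], scope = sc)
    data.frame(scope = sc, r = r$r, p_value = r$p_value, n = r$n,
               stringsAsFactors = FALSE)
  }))
}

#' Closed-form noise-reduction coefficient
#'
#' For a linear admixture `y = y_a + c y_b` of a discriminating
#' measure `y_a` with a correlated, non-discriminating helper `y_b`,
#' the variance `sigma_a^2 + c^2 sigma_b^2 + 2 c r sigma_a sigma_b`
#' is minimised at `c = -r sigma_a / sigma_b`, shrinking the SD to
#' `sqrt(1 - r^2) sigma_a`. With r = 0 any nonzero c only inflates
#' the variance.
#'
#' @param r Pearson correlation between the two measures.
#' @param sigma_a SD of the discriminating measure.
#' @param sigma_b SD of the helper (> 0).
#' @return The coefficient c.
#' @export
noise_coefficient <- function(r, sigma_a, sigma_b) {
  if (!is.finite(sigma_b) || sigma_b <= 0) {
    stop_degenerate("helper SD must be positive")
  }
  -r * sigma_a / sigma_b
}

#' Pooled two-class mixture SD from class Gaussians
#'
#' The "overall" SD of a measure across both classes, treating the
#' cohort as a mixture weighted by class sizes and therefore
#' including the between-class mean spread — the quantity that pairs
#' with an overall (pooled-cohort) correlation coefficient.
#'
#' @param target,versus `class_gaussian` objects.
#' @return The mixture SD.
#' @export
pooled_mixture_sd <- function(target, versus) {
  w_t <- target$n / (target$n + versus$n)
  w_v <- 1 - w_t
  m <- w_t * target$mu + w_v * versus$mu
  sqrt(w_t * (target$sigma^2 + target$mu^2) +
         w_v * (versus$sigma^2 + versus$mu^2) - m^2)
}

#' Combine a base measure with a helper
#'
#' Computes `y = y_a + c y_b` per sample; samples missing either
#' measure yield `NA` and are listed in the `excluded` attribute.
#'
#' @param y_a,y_b numeric vectors (base and helper measures).
#' @param c admixture coefficient.
#' @return Numeric vector of combined values with attribute
#'   `excluded` (indices of incomplete pairs).
#' @export
combine_measures <- function(y_a, y_b, c) {
  out <- y_a + c * y_b
  excluded <- which(!(is.finite(y_a) & is.finite(y_b)))
  out[excluded] <- NA_real_
  attr(out, "excluded") <- excluded
  out
}

# Closed-form class summaries of y_a + c y_b over a grid of c, from
# sufficient statistics; used by the grid/objective machinery so the
# search costs O(grid), not O(grid * n).
#' @noRd
combination_class_stats <- function(a, b, labels, c_values) {
  stats_for <- function(keep) {
    av <- a[keep]; bv <- b[keep]
    n <- length(av)
    list(n = n, ma = mean(av), mb = mean(bv),
         va = stats::var(av), vb = stats::var(bv),
         cab = stats::cov(av, bv))
  }
  st <- stats_for(labels == "target")
  sv <- stats_for(labels == "versus")
  per_class <- function(s) {
    list(mean = s$ma + c_values * s$mb,
         var = s$va + c_values^2 * s$vb + 2 * c_values * s$cab,
         n = s$n)
  }
  list(target = per_class(st), versus = per_class(sv))
}

# Welch |t| over a grid of c, closed form.
#' @noRd
welch_t_profile <- function(a, b, labels, c_values) {
  cs <- combination_class_stats(a, b, labels, c_values)
  se2 <- cs$target$var / cs$target$n + cs$versus$var / cs$versus$n
  abs(cs$target$mean - cs$versus$mean) / sqrt(se2)
}

# Predicted Bayes accuracy (balanced priors) over a grid of c.
#' @noRd
accuracy_profile <- function(a, b, labels, c_values) {
  cs <- combination_class_stats(a, b, labels, c_values)
  vapply(seq_along(c_values), function(i) {
    sT <- sqrt(cs$target$var[i]); sV <- sqrt(cs$versus$var[i])
    if (!is.finite(sT) || !is.finite(sV) || sT <= 0 || sV <= 0) {
      return(NA_real_)
    }
    gT <- class_gaussian(cs$target$mean[i], sT, cs$target$n)
    gV <- class_gaussian(cs$versus$mean[i], sV, cs$versus$n)
    m <- tryCatch(fit_bayes_classifier(gT, gV), error = function(e) NULL)
    if (is.null(m)) return(NA_real_)
    hc <- sensitivity_specificity(m)
    (hc["H"] + hc["C"]) / 2
  }, numeric(1))
}

#' Optimise the admixture coefficient against class separation
#'
#' Searches c over a bounded grid (default [-5, 5] at step 0.01) with
#' local Brent refinement, maximising either the absolute Welch t
#' statistic between the classes of the combined measure (default) or
#' the predicted Bayes accuracy. Deterministic — no randomness
#' involved. The closed-form coefficient `-r sigma_a / sigma_b`
#' computed from the pooled-cohort correlation and mixture SDs is
#' reported alongside for comparison.
#'
#' @param y_a,y_b base and helper measure values.
#' @param labels class labels (`"target"`/`"versus"`).
#' @param objective `"welch_t"` or `"accuracy"`.
#' @param lower,upper,step grid specification for c.
#' @return Object of class `coefficient_fit`: list with `c_opt`,
#'   `objective`, `objective_value`, `c_closed_form` and the overall
#'   correlation used for the closed form.
#' @export
optimize_coefficient <- function(y_a, y_b, labels,
                                 objective = c("welch_t", "accuracy"),
                                 lower = -5, upper = 5, step = 0.01) {
  objective <- match.arg(objective)
  keep <- is.finite(y_a) & is.finite(y_b) &
    labels %in% c("target", "versus")
  a <- y_a[keep]; b <- y_b[keep]; lab <- labels[keep]
  if (length(unique(lab)) < 2) {
    stop_validation("both classes must be represented")
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop_degenerate("degenerate measures; cannot optimise coefficient")
  }
  prof_fun <- if (objective == "welch_t") welch_t_profile else
    accuracy_profile
  grid <- seq(lower, upper, by = step)
  prof <- prof_fun(a, b, lab, grid)
  i <- which.max(prof)
  bracket <- c(grid[max(i - 1L, 1L)], grid[min(i + 1L, length(grid))])
  opt <- stats::optimize(function(cc) prof_fun(a, b, lab, cc),
                         interval = bracket, maximum = TRUE,
                         tol = 1e-6)
  c_opt <- opt$maximum
  val <- opt$objective
  if (prof[i] > val) {
    c_opt <- grid[i]
    val <- prof[i]
  }

  r_all <- pearson_correlation(a, b)$r
  gA_t <- fit_class_gaussian(a[lab == "target"])
  gA_v <- fit_class_gaussian(a[lab == "versus"])
  gB_t <- fit_class_gaussian(b[lab == "target"])
  gB_v <- fit_class_gaussian(b[lab == "versus"])
  c_closed <- noise_coefficient(r_all,
                                pooled_mixture_sd(gA_t, gA_v),
                                pooled_mixture_sd(gB_t, gB_v))
  structure(list(c_opt = c_opt, objective = objective,
                 objective_value = val,
                 c_closed_form = c_closed, r_overall = r_all),
            class = "coefficient_fit")
}

#' @export
print.coefficient_fit <- function(x, ...) {
  cat(sprintf("admixture coefficient: c* = %.3f (%s = %.4g); closed form c = %.3f (r = %.3f)\n",
              x$c_opt, x$objective, x$objective_value,
              x$c_closed_form, x$r_overall))
  invisible(x)
}

#' Area under the ROC curve
#'
#' AUC of a score for separating target (positive) from versus
#' (negative), computed by the rank-sum formulation with midpoint
#' handling of ties — algebraically identical to the trapezoidal rule
#' over all score thresholds. Scores must be oriented so larger
#' values indicate the target class; an AUC below 0.5 triggers an
#' orientation warning rather than a silent flip.
#'
#' @param scores numeric scores.
#' @param labels class labels (`"target"`/`"versus"`).
#' @return The AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  keep <- is.finite(scores) & labels %in% c("target", "versus")
  s <- scores[keep]; lab <- labels[keep]
  n1 <- sum(lab == "target")
  n0 <- sum(lab == "versus")
  if (n1 == 0 || n0 == 0) {
    stop_validation("both classes must be present to compute an AUC")
  }
  r <- rank(s, ties.method = "average")
  auc <- (sum(r[lab == "target"]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (auc < 0.5) {
    warning("AUC < 0.5: scores appear oriented against the target class")
  }
  auc
}
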