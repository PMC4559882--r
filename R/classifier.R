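#' Quadratic discriminant coefficients for two Gaussian classes
#'
#' For target ~ N(mu_T, sigma_T^2) and versus ~ N(mu_V, sigma_V^2) the
#' log likelihood ratio is quadratic in the measure y with
#' coefficients
#' eta = 1/sigma_T^2 - 1/sigma_V^2,
#' beta = mu_T/sigma_T^2 - mu_V/sigma_V^2,
#' gamma = mu_T^2/sigma_T^2 - mu_V^2/sigma_V^2 + 2 ln(sigma_T/sigma_V).
#'
#' @param target,versus `class_gaussian` objects (see
#'   [class_gaussian()]).
#' @return Named numeric: `eta`, `beta`, `gamma`.
#' @export
quadratic_coefficients <- function(target, versus) {
  if (target$sigma <= 0 || versus$sigma <= 0) {
    stop_degenerate("class SDs must be positive")
  }
  st2 <- target$sigma^2
  sv2 <- versus$sigma^2
  c(eta = 1 / st2 - 1 / sv2,
    beta = target$mu / st2 - versus$mu / sv2,
    gamma = target$mu^2 / st2 - versus$mu^2 / sv2 +
      2 * log(target$sigma / versus$sigma))
}

# Solve eta y^2 - 2 beta y + const = 0 selecting the decision-relevant
# root: the real root inside [mu_V, mu_T] if exactly one lies there,
# otherwise the root closest to the midpoint of the class means. When
# |eta| is negligible relative to the curvatures the linear branch
# y = const / (2 beta) is used for numerical stability. Vectorised
# over the Gaussian parameters (used by the Monte-Carlo propagation).
#' @noRd
solve_quadratic_root <- function(eta, beta, const, mu_T, mu_V,
                                 eta_scale = pmax(abs(eta), 1)) {
  n <- max(length(eta), length(beta), length(const),
           length(mu_T), length(mu_V))
  eta <- rep_len(eta, n); beta <- rep_len(beta, n)
  const <- rep_len(const, n)
  mu_T <- rep_len(mu_T, n); mu_V <- rep_len(mu_V, n)
  eta_scale <- rep_len(eta_scale, n)

  out <- rep(NA_real_, n)
  linear <- abs(eta) < 1e-12 * eta_scale
  if (any(linear & abs(beta) == 0)) {
    stop_degenerate("identical class distributions; threshold undefined")
  }
  out[linear] <- const[linear] / (2 * beta[linear])

  q <- !linear
  if (any(q)) {
    disc <- beta[q]^2 - eta[q] * const[q]
    ok <- disc >= 0
    sq <- sqrt(pmax(disc, 0))
    r1 <- (beta[q] - sq) / eta[q]
    r2 <- (beta[q] + sq) / eta[q]
    lo <- pmin(mu_T[q], mu_V[q])
    hi <- pmax(mu_T[q], mu_V[q])
    in1 <- r1 >= lo & r1 <= hi
    in2 <- r2 >= lo & r2 <= hi
    mid <- (mu_T[q] + mu_V[q]) / 2
    pick <- ifelse(in1 & !in2, r1,
                   ifelse(in2 & !in1, r2,
                          ifelse(abs(r1 - mid) <= abs(r2 - mid), r1, r2)))
    pick[!ok] <- NA_real_
    out[q] <- pick
  }
  out
}

#' Fit the Gaussian Bayes classifier for one scalar measure
#'
#' Builds the two-class discriminator: the decision threshold chi is
#' the root of
#' `eta chi^2 - 2 beta chi + gamma - 2 ln(p_T/p_V) = 0`
#' lying between the class means (the boundary of two crossing
#' Gaussians relevant to classification), the point that maximises the
#' expected accuracy `p_c = p_T H + p_V C`. Class inputs may be
#' `class_gaussian` objects (e.g. from published summary statistics)
#' or raw numeric vectors.
#'
#' Measures whose target mean lies below the versus mean are
#' automatically sign-flipped before fitting (`orientation = -1`), so
#' the rule "y >= chi means target" always applies on the working
#' scale; all predict-type functions accept values on the original
#' scale and handle the flip internally.
#'
#' The threshold uncertainty `chi_se` comes from first-order error
#' propagation of the standard errors of (mu_T, sigma_T, mu_V,
#' sigma_V), with partial derivatives taken by central finite
#' differences (step `1e-4` of each SE) and contributions combined in
#' quadrature assuming independence.
#'
#' @param target,versus `class_gaussian` objects or numeric vectors.
#' @param prior_ratio p_T / p_V (> 0); 1 for balanced priors.
#' @param measure optional measure name, carried into reports.
#' @return Object of class `bayes_classifier`: list with `target`,
#'   `versus` (working-scale Gaussians), `orientation`, `prior_ratio`,
#'   `eta`, `beta`, `gamma`, `chi`, `chi_se`, `measure`.
#' @export
fit_bayes_classifier <- function(target, versus, prior_ratio = 1,
                                 measure = NA_character_) {
  if (is.numeric(target)) target <- fit_class_gaussian(target)
  if (is.numeric(versus)) versus <- fit_class_gaussian(versus)
  if (!is.finite(prior_ratio) || prior_ratio <= 0) {
    stop_validation("prior_ratio must be positive")
  }
  orientation <- if (target$mu < versus$mu) -1 else +1
  if (orientation < 0) {
    target <- class_gaussian(-target$mu, target$sigma, target$n)
    versus <- class_gaussian(-versus$mu, versus$sigma, versus$n)
  }
  co <- quadratic_coefficients(target, versus)
  const <- co["gamma"] - 2 * log(prior_ratio)
  eta_scale <- max(1 / target$sigma^2, 1 / versus$sigma^2)
  chi <- solve_quadratic_root(co["eta"], co["beta"], const,
                              target$mu, versus$mu, eta_scale)
  if (is.na(chi)) {
    stop(errorCondition("no real threshold root; classes infeasible",
                        class = c("qpcr_infeasible_error", "qpcr_error")))
  }
  chi_se <- propagate_threshold_se(target, versus, prior_ratio)
  structure(list(target = target, versus = versus,
                 orientation = orientation,
                 prior_ratio = prior_ratio,
                 eta = unname(co["eta"]), beta = unname(co["beta"]),
                 gamma = unname(co["gamma"]),
                 chi = unname(chi), chi_se = chi_se,
                 measure = measure),
            class = "bayes_classifier")
}

# First-order SE of the threshold (or an odds-level threshold) by
# central finite differences on the four Gaussian parameters.
#' @noRd
propagate_threshold_se <- function(target, versus, prior_ratio,
                                   odds_level = 1) {
  solve_at <- function(muT, sT, muV, sV) {
    st2 <- sT^2; sv2 <- sV^2
    eta <- 1 / st2 - 1 / sv2
    beta <- muT / st2 - muV / sv2
    gam <- muT^2 / st2 - muV^2 / sv2 + 2 * log(sT / sV)
    const <- gam - 2 * log(prior_ratio) + 2 * log(odds_level)
    solve_quadratic_root(eta, beta, const, muT, muV,
                         max(1 / st2, 1 / sv2))
  }
  p <- c(target$mu, target$sigma, versus$mu, versus$sigma)
  se <- c(target$se_mu, target$se_sigma, versus$se_mu, versus$se_sigma)
  var_sum <- 0
  for (i in 1:4) {
    h <- 1e-4 * se[i]
    if (h == 0) next
    up <- p; up[i] <- up[i] + h
    dn <- p; dn[i] <- dn[i] - h
    chi_up <- solve_at(up[1], up[2], up[3], up[4])
    chi_dn <- solve_at(dn[1], dn[2], dn[3], dn[4])
    if (is.na(chi_up) || is.na(chi_dn)) return(NA_real_)
    var_sum <- var_sum + ((chi_up - chi_dn) / (2 * h) * se[i])^2
  }
  sqrt(var_sum)
}

#' @export
print.bayes_classifier <- function(x, ...) {
  cat(sprintf("Gaussian Bayes classifier%s\n",
              if (is.na(x$measure)) "" else paste0(" [", x$measure, "]")))
  cat(sprintf("  target N(%.3f, %.3f^2) n=%d | versus N(%.3f, %.3f^2) n=%d%s\n",
              x$target$mu, x$target$sigma, x$target$n,
              x$versus$mu, x$versus$sigma, x$versus$n,
              if (x$orientation < 0) "  [measure sign-flipped]" else ""))
  cat(sprintf("  eta=%.5f beta=%.5f gamma=%.5f prior_ratio=%.3f\n",
              x$eta, x$beta, x$gamma, x$prior_ratio))
  cat(sprintf("  threshold chi = %.4f +/- %.4f (working scale)\n",
              x$chi, x$chi_se))
  invisible(x)
}

#' @export
as_report.bayes_classifier <- function(x, ...) {
  list(measure = x$measure,
       eta = x$eta, beta = x$beta, gamma = x$gamma,
       chi = x$chi, chi_se = x$chi_se,
       prior_ratio = x$prior_ratio, orientation = x$orientation,
       target = as_report(x$target), versus = as_report(x$versus))
}

#' Posterior odds that a sample belongs to the target class
#'
#' `rho = P_T / P_V = exp(-(eta y^2 - 2 beta y + gamma -
#' 2 ln(p_T/p_V)) / 2)`, the Bayes-theorem likelihood ratio scaled by
#' the priors; at the decision threshold the odds are exactly 1
#' (50:50).
#'
#' @param model a `bayes_classifier`.
#' @param y numeric values of the measure.
#' @param scale `"original"` (default) applies the model's
#'   orientation; `"working"` takes `y` on the possibly sign-flipped
#'   fitting scale on which `chi` is reported.
#' @return Odds (numeric, >= 0), vectorised over `y`.
#' @export
posterior_odds <- function(model, y, scale = c("original", "working")) {
  scale <- match.arg(scale)
  if (scale == "original") y <- model$orientation * y
  exp(-0.5 * (model$eta * y^2 - 2 * model$beta * y + model$gamma -
                2 * log(model$prior_ratio)))
}

#' Thresholds for posterior-odds reliability bands
#'
#' Solves the threshold equation at odds levels rho (default 1/9, 1,
#' 9), giving the working-scale points where the posterior odds cross
#' the band edges: `chi_10_90` (odds 1:9), `chi` (1:1), `chi_90_10`
#' (9:1). Each threshold carries a propagated SE; a level with no real
#' root is reported as `NA` (absent), not an error.
#'
#' @param model a `bayes_classifier`.
#' @param odds_levels numeric odds levels (> 0).
#' @return data.frame with columns `odds`, `chi`, `se`, and rownames
#'   `chi_10_90`, `chi`, `chi_90_10` for the standard levels.
#' @export
odds_thresholds <- function(model, odds_levels = c(1 / 9, 1, 9)) {
  eta_scale <- max(1 / model$target$sigma^2, 1 / model$versus$sigma^2)
  res <- lapply(odds_levels, function(rho) {
    const <- model$gamma - 2 * log(model$prior_ratio) + 2 * log(rho)
    chi <- solve_quadratic_root(model$eta, model$beta, const,
                                model$target$mu, model$versus$mu,
                                eta_scale)
    se <- if (is.na(chi)) NA_real_ else
      propagate_threshold_se(model$target, model$versus,
                             model$prior_ratio, odds_level = rho)
    c(chi = unname(chi), se = se)
  })
  out <- data.frame(odds = odds_levels,
                    chi = vapply(res, `[[`, numeric(1), "chi"),
                    se = vapply(res, `[[`, numeric(1), "se"))
  std <- c(`chi_10_90` = 1 / 9, `chi` = 1, `chi_90_10` = 9)
  rn <- names(std)[match(odds_levels, std)]
  rn[is.na(rn)] <- sprintf("odds_%g", odds_levels[is.na(rn)])
  rownames(out) <- rn
  out
}

#' Sensitivity and specificity of the fitted classifier
#'
#' Under the Gaussian class models, sensitivity
#' `H = Phi((mu_T - chi) / sigma_T)` and specificity
#' `C = Phi((chi - mu_V) / sigma_V)`, with Phi the standard normal
#' CDF.
#'
#' @param model a `bayes_classifier`.
#' @param chi decision threshold (working scale); defaults to the
#'   fitted optimum.
#' @return Named numeric: `H`, `C`.
#' @export
sensitivity_specificity <- function(model, chi = model$chi) {
  c(H = stats::pnorm((model$target$mu - chi) / model$target$sigma),
    C = stats::pnorm((chi - model$versus$mu) / model$versus$sigma))
}

#' Predicted accuracy of the classifier, with Monte-Carlo uncertainty
#'
#' Point estimate `p_c = p_T H + p_V C` at the optimal threshold. Its
#' standard error is propagated by Monte Carlo: the four class
#' parameters are drawn from independent normals at their standard
#' errors (SDs rejected to stay positive), the threshold re-solved and
#' `p_c` recomputed per draw; the SD of the draws is reported. The
#' Monte-Carlo route is used because `p_c` is flat in chi at the
#' optimum, which makes chained first-order propagation through chi
#' fragile.
#'
#' @param model a `bayes_classifier`.
#' @param n_draws Monte-Carlo draws (default 1e5).
#' @param seed RNG seed for the propagation (fixed default so reports
#'   are reproducible).
#' @return Named numeric: `p_c`, `p_c_se` (both on the 0-1 scale).
#' @export
predicted_accuracy <- function(model, n_draws = 1e5, seed = 1234L) {
  p_T <- model$prior_ratio / (1 + model$prior_ratio)
  p_V <- 1 - p_T
  hc <- sensitivity_specificity(model)
  p_c <- p_T * hc["H"] + p_V * hc["C"]

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  draw_pos <- function(m, s, n) {
    x <- stats::rnorm(n, m, s)
    while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), m, s)
    x
  }
  muT <- stats::rnorm(n_draws, model$target$mu, model$target$se_mu)
  sT <- draw_pos(model$target$sigma, model$target$se_sigma, n_draws)
  muV <- stats::rnorm(n_draws, model$versus$mu, model$versus$se_mu)
  sV <- draw_pos(model$versus$sigma, model$versus$se_sigma, n_draws)

  st2 <- sT^2; sv2 <- sV^2
  eta <- 1 / st2 - 1 / sv2
  beta <- muT / st2 - muV / sv2
  gam <- muT^2 / st2 - muV^2 / sv2 + 2 * log(sT / sV)
  const <- gam - 2 * log(model$prior_ratio)
  chi <- solve_quadratic_root(eta, beta, const, muT, muV,
                              pmax(1 / st2, 1 / sv2))
  pc_draws <- p_T * stats::pnorm((muT - chi) / sT) +
    p_V * stats::pnorm((chi - muV) / sV)
  pc_draws <- pc_draws[is.finite(pc_draws)]
  c(p_c = unname(p_c), p_c_se = stats::sd(pc_draws))
}

#' Band labels, ordered from target-reliable to versus-reliable
#' @noRd
odds_bands <- function() c("rho>9", "9>rho>1", "1>rho>1/9", "rho<1/9")

#' Classify samples and assign posterior-odds reliability bands
#'
#' Applies the decision rule (target when the working-scale value is
#' `>= chi`, versus otherwise; the boundary itself is called target,
#' at odds exactly 1) and places each sample in one of four odds
#' bands. Band edges are closed on the reliable side: odds exactly 9
#' fall in `rho>9`, odds exactly 1/9 in `rho<1/9`.
#'
#' @param model a `bayes_classifier`.
#' @param y numeric measure values on the original scale.
#' @return data.frame with columns `y`, `class` (`"target"`/
#'   `"versus"`), `odds`, `band`.
#' @export
classify_samples <- function(model, y) {
  y_work <- model$orientation * y
  odds <- posterior_odds(model, y_work, scale = "working")
  # edges are compared in log-odds with a tiny tolerance so that
  # values at a numerically solved band threshold land on the closed
  # (reliable) side of the edge
  lo <- log(odds)
  tol <- 1e-9
  band <- ifelse(lo >= log(9) - tol, "rho>9",
                 ifelse(lo >= -tol, "9>rho>1",
                        ifelse(lo > -log(9) + tol, "1>rho>1/9",
                               "rho<1/9")))
  data.frame(y = y,
             class = ifelse(y_work >= model$chi, "target", "versus"),
             odds = odds,
             band = factor(band, levels = odds_bands()),
             stringsAsFactors = FALSE)
}

#' Odds-banded confusion matrix and accuracies
#'
#' Cross-tabulates the true class against the four posterior-odds
#' bands. Two accuracies are derived: the plain accuracy (correct
#' calls over all classified samples) and the high-reliability
#' accuracy, counting only correct calls made at odds of at least 9:1
#' for the predicted class but still dividing by all classified
#' samples — so it reads as "fraction of the cohort that received a
#' correct, reliable call". Unlabeled samples are excluded and listed
#' in the `excluded` attribute.
#'
#' @param model a `bayes_classifier`.
#' @param y measure values (original scale).
#' @param labels true class labels (`"target"`/`"versus"`; anything
#'   else is excluded).
#' @return Object of class `banded_confusion`: list with `counts`
#'   (2 x 4 matrix), `n`, `accuracy`, `high_reliability_accuracy`,
#'   `excluded` (indices).
#' @export
banded_confusion <- function(model, y, labels) {
  keep <- labels %in% c("target", "versus")
  res <- classify_samples(model, y[keep])
  lab <- factor(labels[keep], levels = c("target", "versus"))
  counts <- table(truth = lab, band = res$band)
  counts <- unclass(as.matrix(counts))
  correct <- as.character(lab) == res$class
  reliable <- res$band %in% c("rho>9", "rho<1/9")
  structure(list(counts = counts, n = sum(keep),
                 accuracy = mean(correct),
                 high_reliability_accuracy = sum(correct & reliable) /
                   sum(keep),
                 excluded = which(!keep)),
            class = "banded_confusion")
}

#' @export
print.banded_confusion <- function(x, ...) {
  print(x$counts)
  cat(sprintf("accuracy: %.1f %%; high-reliability accuracy: %.1f %% (n = %d)\n",
              100 * x$accuracy, 100 * x$high_reliability_accuracy, x$n))
  invisible(x)
}

#' @export
as_report.banded_confusion <- function(x, ...) {
  cl <- lapply(seq_len(nrow(x$counts)), function(i) {
    as.list(stats::setNames(as.numeric(x$counts[i, ]),
                            colnames(x$counts)))
  })
  names(cl) <- rownames(x$counts)
  list(confusion = cl, n = x$n, accuracy = x$accuracy,
       high_reliability_accuracy = x$high_reliability_accuracy)
}

#' One-tailed bias-outlier probability
#'
#' A sample whose measure lies implausibly far from its class mean —
#' even though its triplicate variability passed QC — hints at a
#' biased triplicate rather than a true class member. The evidence is
#' the one-tailed Student-t tail probability of obtaining a value more
#' displaced from the class mean than `y`, with `t = (y - mu) / sigma`
#' and `n - 1` degrees of freedom. Values with p below a chosen level
#' (conventionally 0.01) are deemed bias outliers. The
#' prediction-interval variant divides by `sigma sqrt(1 + 1/n)` to
#' account for the uncertainty of the fitted mean.
#'
#' @param y measure value(s), on the scale of `gaussian`.
#' @param gaussian a `class_gaussian`.
#' @param prediction_interval use the `sqrt(1 + 1/n)` scaling.
#' @return One-tailed p-value(s) in (0, 0.5].
#' @export
bias_outlier_p <- function(y, gaussian, prediction_interval = FALSE) {
  scale <- gaussian$sigma *
    if (prediction_interval) sqrt(1 + 1 / gaussian$n) else 1
  t_stat <- (y - gaussian$mu) / scale
  stats::pt(-abs(t_stat), df = gaussian$n - 1)
}
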