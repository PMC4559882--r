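test_that("quadratic coefficients match their closed forms", {
  co <- quadratic_coefficients(class_gaussian(1, 1, 10),
                               class_gaussian(-1, 1, 10))
  expect_equal(unname(co), c(0, 2, 0))
  co2 <- quadratic_coefficients(class_gaussian(2.5, 1.3, 10),
                                class_gaussian(2.5, 1.3, 12))
  expect_equal(unname(co2), c(0, 0, 0))
  g <- gauss_yopt()
  co3 <- quadratic_coefficients(g$target, g$versus)
  expect_equal(unname(co3), c(-0.1136167, 1.6379198, 13.3406603),
               tolerance = 1e-6)
})

test_that("the threshold solves the quadratic and sits between the class means", {
  g <- gauss_yopt()
  m <- fit_bayes_classifier(g$target, g$versus)
  expect_equal(m$chi, 3.618351, tolerance = 1e-5)
  expect_equal(round(m$chi, 1), 3.6)
  # symmetric equal-variance case: midpoint
  ms <- fit_bayes_classifier(class_gaussian(1, 1, 10),
                             class_gaussian(-1, 1, 10))
  expect_equal(ms$chi, 0)
  # equal variances, unbalanced priors: linearised closed form
  pr <- 3
  me <- fit_bayes_classifier(class_gaussian(2, 1.2, 10),
                             class_gaussian(-1, 1.2, 10),
                             prior_ratio = pr)
  expect_equal(me$chi, 0.5 - 1.2^2 * log(pr) / 3, tolerance = 1e-9)
  expect_error(fit_bayes_classifier(class_gaussian(1, 2, 5),
                                    class_gaussian(1, 2, 5)),
               class = "qpcr_degenerate_error")
})

test_that("the root residual vanishes and agrees with the direct quadratic formula", {
  for (s in 1:20) {
    m <- random_model(s)
    resid <- m$eta * m$chi^2 - 2 * m$beta * m$chi + m$gamma -
      2 * log(m$prior_ratio)
    expect_lt(abs(resid), 1e-8)
    roots <- quad_roots_oracle(m$target$mu, m$target$sigma,
                               m$versus$mu, m$versus$sigma,
                               m$prior_ratio)
    expect_true(any(abs(roots - m$chi) < 1e-8))
  }
})

test_that("posterior odds are 1 at chi, prior_ratio for overlapping classes, 9 at the band edge", {
  for (s in 1:10) {
    m <- random_model(s)
    expect_lt(abs(posterior_odds(m, m$chi, scale = "working") - 1), 1e-9)
    th <- odds_thresholds(m)
    for (i in seq_len(nrow(th))) {
      if (is.na(th$chi[i])) next
      expect_equal(posterior_odds(m, th$chi[i], scale = "working"),
                   th$odds[i], tolerance = 1e-6)
    }
  }
  # near-coincident classes: odds collapse to the prior ratio for every y
  m0 <- fit_bayes_classifier(class_gaussian(1e-9, 1, 10),
                             class_gaussian(0, 1, 10), prior_ratio = 2)
  expect_equal(posterior_odds(m0, c(-3, 0, 3)), rep(2, 3),
               tolerance = 1e-6)
})

test_that("odds-band thresholds bracket chi and reproduce the published combined-measure bands", {
  g <- gauss_yopt()
  m <- fit_bayes_classifier(g$target, g$versus)
  th <- odds_thresholds(m)
  expect_equal(th["chi", "chi"], m$chi)
  expect_equal(th["chi_90_10", "chi"], 4.660563, tolerance = 1e-5)
  expect_equal(th["chi_10_90", "chi"], 2.512095, tolerance = 1e-5)
  expect_true(th["chi_10_90", "chi"] < m$chi &&
                m$chi < th["chi_90_10", "chi"])
  # symmetric case: band thresholds equidistant from chi
  ms <- fit_bayes_classifier(class_gaussian(1, 1, 10),
                             class_gaussian(-1, 1, 10))
  ths <- odds_thresholds(ms)
  expect_equal(ths["chi_90_10", "chi"] - ms$chi,
               ms$chi - ths["chi_10_90", "chi"])
})

test_that("sensitivity and specificity follow the normal CDF expressions", {
  g <- gauss_yopt()
  m <- fit_bayes_classifier(g$target, g$versus)
  expect_equal(unname(sensitivity_specificity(m, chi = m$target$mu)["H"]), 0.5)
  expect_equal(unname(sensitivity_specificity(m, chi = m$versus$mu)["C"]), 0.5)
  hc <- sensitivity_specificity(m)
  expect_equal(unname(hc), c(0.9579327, 0.9659216), tolerance = 1e-6)
})

test_that("predicted accuracy reproduces the published values with a plausible Monte-Carlo SE", {
  g <- gauss_yopt()
  m <- fit_bayes_classifier(g$target, g$versus)
  pa <- predicted_accuracy(m, n_draws = 2e4)
  expect_equal(unname(pa["p_c"]) * 100, 96.1, tolerance = 0.3)
  expect_gt(pa["p_c_se"], 0.01)
  expect_lt(pa["p_c_se"], 0.04)

  g2 <- gauss_dx205()
  m2 <- fit_bayes_classifier(g2$target, g2$versus)
  pa2 <- predicted_accuracy(m2, n_draws = 2e4)
  expect_equal(unname(pa2["p_c"]) * 100, 91.4, tolerance = 0.3)

  # overlapping classes: accuracy collapses to chance
  m0 <- fit_bayes_classifier(class_gaussian(1e-6, 1, 10),
                             class_gaussian(0, 1, 10))
  expect_equal(unname(predicted_accuracy(m0, n_draws = 1000)["p_c"]), 0.5,
               tolerance = 1e-5)
})

test_that("chi maximises the predicted accuracy locally", {
  for (s in 1:8) {
    m <- random_model(s)
    pc <- function(chi) {
      hc <- sensitivity_specificity(m, chi)
      pT <- m$prior_ratio / (1 + m$prior_ratio)
      pT * hc["H"] + (1 - pT) * hc["C"]
    }
    for (d in c(0.01, 0.1, 1.0)) {
      expect_gte(pc(m$chi), pc(m$chi + d) - 1e-12)
      expect_gte(pc(m$chi), pc(m$chi - d) - 1e-12)
    }
  }
})

test_that("raising the target prior never raises the threshold", {
  for (s in 1:8) {
    set.seed(s)
    gT <- class_gaussian(runif(1, 1, 5), runif(1, 0.5, 2), 20)
    gV <- class_gaussian(runif(1, -5, 0), runif(1, 0.5, 2), 20)
    chis <- vapply(c(0.25, 0.5, 1, 2, 4), function(pr) {
      fit_bayes_classifier(gT, gV, prior_ratio = pr)$chi
    }, numeric(1))
    expect_true(all(diff(chis) <= 1e-10))
  }
})

test_that("classification honours the boundary convention and band edges", {
  g <- gauss_yopt()
  m <- fit_bayes_classifier(g$target, g$versus)
  th <- odds_thresholds(m)
  at_chi <- classify_samples(m, m$chi)
  expect_equal(at_chi$class, "target")
  expect_equal(at_chi$odds, 1, tolerance = 1e-9)
  expect_equal(as.character(at_chi$band), "9>rho>1")
  above <- classify_samples(m, th["chi_90_10", "chi"] + 1e-9)
  expect_equal(as.character(above$band), "rho>9")
  at_edge <- classify_samples(m, th["chi_90_10", "chi"])
  expect_equal(as.character(at_edge$band), "rho>9")  # closed reliable side
  below <- classify_samples(m, m$chi - 1e-9)
  expect_equal(below$class, "versus")
})

test_that("banded confusion counts partition the cohort and yield both accuracies", {
  g <- gauss_yopt()
  m <- fit_bayes_classifier(g$target, g$versus)
  y <- c(7.2, 6.0, 4.0, 3.0, -1.0, 0.2, 5.0)
  lab <- c("target", "target", "target", "versus", "versus", "versus",
           "unknown")
  conf <- banded_confusion(m, y, lab)
  expect_equal(sum(conf$counts), 6)
  expect_equal(conf$n, 6)
  expect_equal(conf$excluded, 7L)
  expect_true(conf$accuracy >= 0 && conf$accuracy <= 1)
  expect_lte(conf$high_reliability_accuracy, conf$accuracy)
  # everything exactly at chi lands in the two central bands
  conf2 <- banded_confusion(m, rep(m$chi, 4),
                            c("target", "target", "versus", "versus"))
  expect_equal(sum(conf2$counts[, c("rho>9", "rho<1/9")]), 0)
})

test_that("training on large synthetic draws recovers the analytic threshold and accuracy", {
  set.seed(314)
  n <- 1e4
  yT <- rnorm(n, 6.9, 1.9)
  yV <- rnorm(n, 0.7, 1.6)
  m <- fit_bayes_classifier(yT, yV)
  expect_lt(abs(m$chi - 3.618351), 0.05)
  # empirical accuracy of classify() vs the Eq.-style prediction
  calls <- classify_samples(m, c(yT, yV))
  truth <- rep(c("target", "versus"), each = n)
  acc <- mean(calls$class == truth)
  pred <- unname(predicted_accuracy(m, n_draws = 1000)["p_c"])
  expect_lt(abs(acc - pred), 3 * sqrt(pred * (1 - pred) / (2 * n)))
})

test_that("auto-negated measures classify identically to manual negation", {
  set.seed(9)
  yT <- rnorm(200, 25.0, 1.4)   # reference-style: target mean BELOW versus
  yV <- rnorm(150, 25.8, 1.9)
  lab <- rep(c("target", "versus"), c(200, 150))
  y <- c(yT, yV)
  m_auto <- fit_bayes_classifier(yT, yV)
  m_flip <- fit_bayes_classifier(-yT, -yV)
  expect_equal(m_auto$orientation, -1)
  expect_equal(m_flip$orientation, +1)
  expect_equal(m_auto$chi, m_flip$chi)
  c_auto <- banded_confusion(m_auto, y, lab)
  c_flip <- banded_confusion(m_flip, -y, lab)
  expect_equal(c_auto$counts, c_flip$counts)
  expect_equal(c_auto$accuracy, c_flip$accuracy)
})

test_that("bias-outlier p is the one-tailed Student tail away from the class mean", {
  g <- class_gaussian(6.9, 1.9, 18)
  expect_equal(bias_outlier_p(6.9, g), 0.5)
  y99 <- 6.9 + 1.9 * qt(0.99, df = 17)
  expect_equal(bias_outlier_p(y99, g), 0.01, tolerance = 1e-10)
  expect_equal(bias_outlier_p(6.9 - 1.9 * qt(0.99, df = 17), g), 0.01,
               tolerance = 1e-10)
  # prediction-interval variant widens the scale, so p grows
  expect_gt(bias_outlier_p(y99, g, prediction_interval = TRUE),
            bias_outlier_p(y99, g))
  # a value ~5 class SDs out is flagged far below the 1 % level
  expect_lt(bias_outlier_p(6.9 - 5 * 1.9, g), 5e-4)
})
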