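test_that("Pearson correlation handles collinear, seeded and degenerate input", {
  x <- 1:10
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  set.seed(55)
  z1 <- rnorm(1e4); z2 <- rnorm(1e4)
  b <- 0.5 * z1 + sqrt(1 - 0.25) * z2
  cr <- pearson_correlation(z1, b)
  expect_lt(abs(cr$r - 0.5), 0.03)
  expect_lt(cr$p_value, 1e-10)
  expect_error(pearson_correlation(rep(1, 5), rnorm(5)),
               class = "qpcr_degenerate_error")
  expect_error(pearson_correlation(1:2, 2:1), class = "qpcr_validation_error")
})

test_that("correlation agrees with the reference implementation per scope", {
  cfg <- synthetic_config(n_target = 30, n_versus = 30,
                          variability_outlier_rate = 0)
  m <- normalize_cohort(generate_cohort(cfg, seed = 12), "U6")
  tab <- correlation_table(m, "dx_miR-205", "dx_miR-21")
  expect_equal(tab$scope, c("overall", "target", "versus"))
  for (sc in tab$scope) {
    keep <- if (sc == "overall") rep(TRUE, nrow(m)) else m$class_label == sc
    ref <- cor.test(m[["dx_miR-205"]][keep], m[["dx_miR-21"]][keep])
    expect_equal(tab$r[tab$scope == sc], unname(ref$estimate))
    expect_equal(tab$p_value[tab$scope == sc], ref$p.value)
  }
})

test_that("the closed-form coefficient and pooled SDs reproduce the published admixture", {
  expect_equal(noise_coefficient(0, 1.3, 0.7), 0)
  expect_equal(noise_coefficient(1, 2, 2), -1)
  expect_error(noise_coefficient(0.5, 1, 0), class = "qpcr_degenerate_error")
  # perfect cancellation: r = 1, equal SDs
  a <- rnorm(100); b <- a
  y <- combine_measures(a, b, noise_coefficient(1, sd(a), sd(b)))
  expect_equal(sd(y), 0)
  # pooled two-class mixture SDs of the printed class statistics
  sa <- pooled_mixture_sd(class_gaussian(1.7, 2.2, 18),
                          class_gaussian(-4.6, 2.4, 15))
  sb <- pooled_mixture_sd(class_gaussian(-6.5, 1.4, 18),
                          class_gaussian(-6.6, 2.4, 15))
  expect_equal(sa, 3.885702, tolerance = 1e-6)
  expect_equal(sb, 1.920873, tolerance = 1e-6)
  expect_equal(round(noise_coefficient(0.40, sa, sb), 1), -0.8)
})

test_that("combination arithmetic and exclusion of incomplete pairs", {
  y <- combine_measures(1.0, -6.0, -0.8)
  expect_equal(unname(y[1]), 5.8)
  a <- c(1, 2, NA, 4)
  b <- c(0.5, NA, 1, 2)
  y2 <- combine_measures(a, b, 0)
  expect_equal(attr(y2, "excluded"), c(2L, 3L))
  expect_equal(y2[c(1, 4)], a[c(1, 4)])  # c = 0 is the identity
})

test_that("variance reduction follows sqrt(1 - r^2) and r = 0 admixture is detrimental", {
  set.seed(60)
  n <- 1e4
  r <- 0.7
  z1 <- rnorm(n); z2 <- rnorm(n)
  a <- 2.0 * z1
  b <- 1.5 * (r * z1 + sqrt(1 - r^2) * z2)
  c_hat <- noise_coefficient(cor(a, b), sd(a), sd(b))
  ratio <- sd(combine_measures(a, b, c_hat)) / sd(a)
  expect_lt(abs(ratio - sqrt(1 - r^2)) / sqrt(1 - r^2), 0.05)
  # uncorrelated helper only inflates the variance
  set.seed(61)
  b0 <- rnorm(n)
  for (cc in c(-1, -0.3, 0.4, 1)) {
    expect_gte(var(combine_measures(a, b0, cc)), var(a) * 0.999)
  }
})

test_that("a class-balanced helper preserves the between-class mean separation", {
  set.seed(62)
  n <- 5000
  aT <- rnorm(n, 2, 1); aV <- rnorm(n, -2, 1)
  bT <- rnorm(n, 0, 1); bV <- rnorm(n, 0, 1)
  cc <- -0.6
  gap_before <- mean(aT) - mean(aV)
  gap_after <- mean(combine_measures(aT, bT, cc)) -
    mean(combine_measures(aV, bV, cc))
  expect_lt(abs(gap_after - gap_before), 0.1)
})

test_that("coefficient optimisation matches a brute-force grid oracle", {
  set.seed(63)
  n <- 2000
  rho <- 0.6
  z1T <- rnorm(n); z2T <- rnorm(n)
  z1V <- rnorm(n); z2V <- rnorm(n)
  aT <- 3 + 1.8 * z1T; aV <- -3 + 1.8 * z1V
  bT <- 1.2 * (rho * z1T + sqrt(1 - rho^2) * z2T)
  bV <- 1.2 * (rho * z1V + sqrt(1 - rho^2) * z2V)
  a <- c(aT, aV); b <- c(bT, bV)
  lab <- rep(c("target", "versus"), each = n)
  fit <- optimize_coefficient(a, b, lab)
  # within-class correlation with equal class SDs: c* ~ -rho sd(a)/sd(b)
  expect_lt(abs(fit$c_opt - (-rho * 1.8 / 1.2)) / (rho * 1.8 / 1.2), 0.10)
  # independent oracle: |Welch t| of the combined measure on a grid
  grid <- seq(-2, 0, by = 0.01)
  tvals <- vapply(grid, function(cc) {
    y <- a + cc * b
    abs(t.test(y[lab == "target"], y[lab == "versus"])$statistic)
  }, numeric(1))
  expect_lt(abs(fit$c_opt - grid[which.max(tvals)]), 0.01 + 1e-9)
})

test_that("an uncorrelated helper earns a near-zero coefficient", {
  set.seed(64)
  n <- 5000
  a <- c(rnorm(n, 2), rnorm(n, -2))
  b <- rnorm(2 * n)
  lab <- rep(c("target", "versus"), each = n)
  fit <- optimize_coefficient(a, b, lab)
  expect_lt(abs(fit$c_opt), 0.05)
})

test_that("AUC follows the rank-sum formulation and the reference implementation", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12),
                       rep(c("versus", "target"), each = 3)), 1)
  set.seed(65)
  s <- rnorm(5000)
  lab <- sample(c("target", "versus"), 5000, replace = TRUE)
  expect_lt(abs(suppressWarnings(roc_auc(s, lab)) - 0.5), 0.03)
  # cross-check against pROC on overlapping classes, with ties
  set.seed(66)
  s2 <- round(c(rnorm(200, 1), rnorm(200, 0)), 1)
  lab2 <- rep(c("target", "versus"), each = 200)
  auc_ref <- as.numeric(pROC::auc(pROC::roc(
    response = lab2, predictor = s2, levels = c("versus", "target"),
    direction = "<", quiet = TRUE)))
  expect_equal(roc_auc(s2, lab2), auc_ref, tolerance = 1e-12)
  expect_error(roc_auc(1:5, rep("target", 5)),
               class = "qpcr_validation_error")
  expect_warning(roc_auc(c(1, 2, 3, 4), c("target", "target", "versus", "versus")),
                 "oriented against")
})
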