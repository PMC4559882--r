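test_that("zero replicate noise yields exact latent triplicates", {
  cfg <- synthetic_config(sigma_rep = c(marker = 0, helper = 0,
                                        reference = 0),
                          variability_outlier_rate = 0,
                          bias_outlier_rate = 0)
  coh <- generate_cohort(cfg, seed = 2)
  expect_true(all(coh$s == 0))
  truth <- attr(coh, "truth")
  offs <- do.call(rbind, cfg$session_offsets)
  i <- coh$assay == "U6"
  expect_equal(coh$x[i],
               truth$x_reference + offs[coh$session[i], "reference"],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the same seed and config reproduce a bit-identical cohort", {
  cfg <- paper_like_config()
  c1 <- generate_cohort(cfg, seed = 77)
  c2 <- generate_cohort(cfg, seed = 77)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  c3 <- generate_cohort(cfg, seed = 78)
  expect_false(identical(c1$rep1, c3$rep1))
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_target = 0), class = "qpcr_validation_error")
  expect_error(synthetic_config(delta_correlation = c(target = 1.2,
                                                      versus = 0.5)),
               class = "qpcr_validation_error")
  expect_error(synthetic_config(variability_outlier_rate = 1.5),
               class = "qpcr_validation_error")
  expect_error(synthetic_config(marker_delta = list(
    target = c(mean = 1, sd = -1), versus = c(mean = 0, sd = 1))),
    class = "qpcr_validation_error")
})

test_that("the study-condition config carries the published parameters and round-trips", {
  cfg <- paper_like_config()
  expect_equal(unname(cfg$marker_delta$target), c(1.7, 2.2))
  expect_equal(unname(cfg$sigma_rep["reference"]), 0.19)
  expect_equal(unname(cfg$delta_correlation), c(0.49, 0.75))
  expect_equal(cfg$n_target + cfg$n_versus, 33)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  cfg2 <- read_config(path)
  expect_equal(unclass(cfg2), unclass(cfg), tolerance = 1e-12)
})

test_that("large generated cohorts recover the configured truth", {
  cfg <- synthetic_config(n_target = 1e4, n_versus = 1e4,
                          variability_outlier_rate = 0)
  coh <- generate_cohort(cfg, seed = 90)
  # replicate-noise scales via the K-S fit, per assay
  for (role in c("marker", "helper", "reference")) {
    a <- cfg$assays[[role]]
    fit <- fit_variance_scale(coh$s[coh$assay == a]^2)
    expect_lt(abs(fit$sigma - cfg$sigma_rep[[role]]) /
                cfg$sigma_rep[[role]], 0.05)
  }
  # marker-delta class Gaussians vs the analytic truth, within 3 SE
  m <- normalize_cohort(coh, "U6")
  truth <- analytic_combination_gaussians(cfg, c = 0)
  for (cl in c("target", "versus")) {
    g <- fit_class_gaussian(m[["dx_miR-205"]][m$class_label == cl])
    tg <- truth[[cl]]
    expect_lt(abs(g$mu - tg$mu), 3 * tg$sigma / sqrt(g$n))
    expect_lt(abs(g$sigma - tg$sigma), 3 * tg$sigma / sqrt(2 * (g$n - 1)))
  }
  # within-class delta correlation close to the configured value
  r_t <- cor(m[["dx_miR-205"]][m$class_label == "target"],
             m[["dx_miR-21"]][m$class_label == "target"])
  expect_lt(abs(r_t - cfg$delta_correlation[["target"]]), 0.05)
})

test_that("generated variances pass the chi-square(2) K-S fit in most seeds", {
  pass <- vapply(1:100, function(s) {
    cfg <- synthetic_config(variability_outlier_rate = 0)
    coh <- generate_cohort(cfg, seed = 2000 + s)
    fit <- fit_variance_scale(coh$s[coh$assay == "U6"]^2)
    fit$p_value > 0.05
  }, logical(1))
  expect_gte(mean(pass), 0.90)
})

test_that("injected variability outliers are flagged at an elevated rate", {
  cfg <- synthetic_config(n_target = 1500, n_versus = 1500,
                          variability_outlier_rate = 0.05,
                          variability_inflation = 6)
  coh <- generate_cohort(cfg, seed = 91)
  qc <- apply_qc(coh)
  truth <- attr(coh, "truth")
  flagged_ids <- unique(coh$sample_id[qc$flags])
  injected <- truth$sample_id[truth$variability_outlier]
  expect_gt(mean(injected %in% flagged_ids), 0.5)
  expect_gt(length(injected), 100)
})

test_that("injected bias outliers displace the marker measure detectably", {
  cfg <- synthetic_config(n_target = 400, n_versus = 400,
                          variability_outlier_rate = 0,
                          bias_outlier_rate = 0.05, bias_shift = 10)
  coh <- generate_cohort(cfg, seed = 92)
  m <- normalize_cohort(coh, "U6")
  truth <- attr(coh, "truth")
  biased <- truth$bias_outlier[match(m$sample_id, truth$sample_id)]
  gT <- fit_class_gaussian(m[["dx_miR-205"]][m$class_label == "target" &
                                               !biased])
  p_bias <- bias_outlier_p(m[["dx_miR-205"]][m$class_label == "target" &
                                               biased], gT)
  expect_gt(length(p_bias), 5)
  expect_gt(mean(p_bias < 0.01), 0.8)
})
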