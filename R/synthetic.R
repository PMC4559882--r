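#' Describe a synthetic qRT-PCR cohort
#'
#' Specifies the full generative model the analysis stack assumes:
#' per-class bivariate-normal normalized measures (marker and helper
#' delta-Ct, with a within-class correlation), an independent class
#' Gaussian for the reference assay, additive per-session instrument
#' offsets, replicate noise whose triplicate sample variances follow
#' the chi-square(2) law `s^2 / sigma_rep^2 ~ chi2(2)`, and
#' controllable rates of injected variability and bias outliers.
#'
#' Raw assay values are reconstructed as `x_marker = delta_marker +
#' x_ref` (and likewise for the helper), one consistent choice of the
#' joint law of raw measures. Replicate noise is drawn iid normal
#' with SD `sigma_rep * sqrt(2)`: for a triplicate,
#' `(n-1) s^2 / tau^2 ~ chi2(2)` with `tau` the replicate SD, so
#' `tau = sigma_rep sqrt(2)` makes `s^2 / sigma_rep^2` exactly
#' chi-square(2) — the convention under which `sigma_rep` is the
#' scale the QC stage fits and reports.
#'
#' Defaults reproduce the lung-tumor study conditions: 18 target / 15
#' versus samples; marker delta-Ct N(1.7, 2.2^2) vs N(-4.6, 2.4^2);
#' helper delta-Ct N(-6.5, 1.4^2) vs N(-6.6, 2.4^2) with within-class
#' correlations 0.49 / 0.75; reference N(25.0, 1.4^2) vs
#' N(25.8, 1.9^2); replicate scales 0.25 / 0.19 / 0.19 Ct; two equal
#' sessions with ~3 Ct offsets; a 3.5 % variability-outlier rate
#' (noise inflated 4x) and no bias outliers (bias outliers are an
#' application-set phenomenon, injected on demand).
#'
#' @param n_target,n_versus class sizes.
#' @param assays named character: `marker`, `helper`, `reference`.
#' @param marker_delta,helper_delta per-class `(mean, sd)` of the
#'   normalized measures: `list(target = c(mean, sd), versus = ...)`.
#' @param reference per-class `(mean, sd)` of the raw reference.
#' @param delta_correlation within-class Pearson correlation between
#'   the two normalized measures, named `target`/`versus`.
#' @param sigma_rep replicate-noise scales (Ct), named
#'   `marker`/`helper`/`reference`.
#' @param session_weights named numeric, sampling weight per session.
#' @param session_offsets list per session of per-assay additive
#'   offsets (Ct), names `marker`/`helper`/`reference`.
#' @param variability_outlier_rate,variability_inflation rate of
#'   triplicates with inflated replicate noise, and the inflation
#'   factor.
#' @param bias_outlier_rate,bias_shift rate of samples whose marker
#'   triplicate is jointly shifted (all three replicates) by
#'   `bias_shift` Ct with random sign.
#' @return Object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(
    n_target = 18, n_versus = 15,
    assays = c(marker = "miR-205", helper = "miR-21", reference = "U6"),
    marker_delta = list(target = c(mean = 1.7, sd = 2.2),
                        versus = c(mean = -4.6, sd = 2.4)),
    helper_delta = list(target = c(mean = -6.5, sd = 1.4),
                        versus = c(mean = -6.6, sd = 2.4)),
    reference = list(target = c(mean = 25.0, sd = 1.4),
                     versus = c(mean = 25.8, sd = 1.9)),
    delta_correlation = c(target = 0.49, versus = 0.75),
    sigma_rep = c(marker = 0.25, helper = 0.19, reference = 0.19),
    session_weights = c(I = 0.5, II = 0.5),
    session_offsets = list(
      I = c(marker = 0, helper = 0, reference = 0),
      II = c(marker = 2.8, helper = 3.0, reference = 2.4)),
    variability_outlier_rate = 0.035, variability_inflation = 4,
    bias_outlier_rate = 0, bias_shift = 8) {
  cfg <- list(n_target = as.integer(n_target),
              n_versus = as.integer(n_versus),
              assays = assays,
              marker_delta = marker_delta, helper_delta = helper_delta,
              reference = reference,
              delta_correlation = delta_correlation,
              sigma_rep = sigma_rep,
              session_weights = session_weights,
              session_offsets = session_offsets,
              variability_outlier_rate = variability_outlier_rate,
              variability_inflation = variability_inflation,
              bias_outlier_rate = bias_outlier_rate,
              bias_shift = bias_shift)
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

#' @noRd
validate_synthetic_config <- function(cfg) {
  if (cfg$n_target < 1 || cfg$n_versus < 1) {
    stop_validation("class sizes must be >= 1")
  }
  if (!all(c("marker", "helper", "reference") %in% names(cfg$assays))) {
    stop_validation("assays must name marker, helper and reference")
  }
  for (blk in c("marker_delta", "helper_delta", "reference")) {
    for (cl in c("target", "versus")) {
      p <- cfg[[blk]][[cl]]
      if (is.null(p) || length(p) != 2 || any(!is.finite(p)) || p[2] <= 0) {
        stop_validation("%s/%s must give finite (mean, sd > 0)", blk, cl)
      }
    }
  }
  if (any(abs(cfg$delta_correlation) >= 1)) {
    stop_validation("delta_correlation must lie in (-1, 1)")
  }
  if (any(cfg$sigma_rep < 0)) stop_validation("sigma_rep must be >= 0")
  if (!setequal(names(cfg$session_weights), names(cfg$session_offsets))) {
    stop_validation("session_weights and session_offsets must name the same sessions")
  }
  rates <- c(cfg$variability_outlier_rate, cfg$bias_outlier_rate)
  if (any(rates < 0 | rates > 1)) {
    stop_validation("outlier rates must lie in [0, 1]")
  }
  if (cfg$variability_inflation < 1) {
    stop_validation("variability_inflation must be >= 1")
  }
  invisible(cfg)
}

#' Study-condition synthetic configuration
#'
#' The [synthetic_config()] defaults, i.e. the generative description
#' matching the lung-tumor study: its class Gaussians, within-class
#' correlations, replicate-noise scales and session-offset pattern.
#'
#' @return A `synthetic_config`.
#' @export
paper_like_config <- function() synthetic_config()

#' Write / read a synthetic configuration as plain YAML
#'
#' @param config a `synthetic_config`.
#' @param path file path.
#' @return `write_config()`: `path` invisibly; `read_config()`: the
#'   `synthetic_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(lapply(unclass(config), function(x) {
    if (is.list(x)) lapply(x, as.list) else as.list(x)
  }), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unlist_named <- function(x) unlist(x)
  cfg <- list(
    n_target = raw$n_target[[1]], n_versus = raw$n_versus[[1]],
    assays = unlist_named(raw$assays),
    marker_delta = lapply(raw$marker_delta, unlist_named),
    helper_delta = lapply(raw$helper_delta, unlist_named),
    reference = lapply(raw$reference, unlist_named),
    delta_correlation = unlist_named(raw$delta_correlation),
    sigma_rep = unlist_named(raw$sigma_rep),
    session_weights = unlist_named(raw$session_weights),
    session_offsets = lapply(raw$session_offsets, unlist_named),
    variability_outlier_rate = raw$variability_outlier_rate[[1]],
    variability_inflation = raw$variability_inflation[[1]],
    bias_outlier_rate = raw$bias_outlier_rate[[1]],
    bias_shift = raw$bias_shift[[1]])
  do.call(synthetic_config, cfg)
}

#' Generate a synthetic triplicate cohort
#'
#' Draws a cohort from the generative model described by a
#' [synthetic_config()]: latent normalized measures per class
#' (bivariate normal), a latent reference value, reconstruction of
#' raw assay values, per-session offsets added to all assays,
#' triplicates built as latent value plus iid replicate noise of SD
#' `sigma_rep * sqrt(2)`, and optional injected variability outliers
#' (inflated replicate noise) and bias outliers (all three marker
#' replicates shifted jointly). Sessions are assigned
#' deterministically within each class, proportionally to the session
#' weights, so session is never confounded with class. The same
#' `(config, seed)` pair always yields a bit-identical cohort.
#'
#' @param config a `synthetic_config`.
#' @param seed integer RNG seed.
#' @return A [qpcr_cohort()], with attribute `truth`: data.frame of
#'   the latent per-sample values and injected-outlier flags.
#' @export
generate_cohort <- function(config, seed = 1L) {
  validate_synthetic_config(config)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)

  n <- config$n_target + config$n_versus
  cls <- rep(c("target", "versus"), c(config$n_target, config$n_versus))
  ids <- sprintf("S%04d", seq_len(n))

  # deterministic proportional session assignment within each class,
  # so session membership is never confounded with class
  w <- config$session_weights / sum(config$session_weights)
  session <- character(n)
  for (cl in c("target", "versus")) {
    pos <- which(cls == cl)
    m <- length(pos)
    idx <- findInterval((seq_len(m) - 0.5) / m, cumsum(c(0, w)),
                        rightmost.closed = TRUE)
    session[pos] <- names(w)[pmin(idx, length(w))]
  }

  par_of <- function(block, what) {
    vapply(cls, function(cl) config[[block]][[cl]][[what]], numeric(1))
  }
  rho <- unname(config$delta_correlation[cls])
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  d_marker <- par_of("marker_delta", "mean") +
    par_of("marker_delta", "sd") * z1
  d_helper <- par_of("helper_delta", "mean") +
    par_of("helper_delta", "sd") * (rho * z1 + sqrt(1 - rho^2) * z2)
  x_ref <- par_of("reference", "mean") +
    par_of("reference", "sd") * stats::rnorm(n)

  latent <- cbind(marker = d_marker + x_ref,
                  helper = d_helper + x_ref,
                  reference = x_ref)
  off <- do.call(rbind, config$session_offsets)[session, , drop = FALSE]
  latent <- latent + off[, colnames(latent)]

  var_out <- matrix(stats::runif(n * 3) < config$variability_outlier_rate,
                    nrow = n, dimnames = list(NULL, colnames(latent)))
  bias_out <- stats::runif(n) < config$bias_outlier_rate
  bias_sign <- sign(stats::rnorm(n))

  records <- do.call(rbind, lapply(c("marker", "helper", "reference"),
                                   function(role) {
    tau <- config$sigma_rep[[role]] * sqrt(2) *
      ifelse(var_out[, role], config$variability_inflation, 1)
    noise <- matrix(stats::rnorm(3 * n, 0, rep(tau, each = 3)),
                    ncol = 3, byrow = TRUE)
    vals <- latent[, role] + noise
    if (role == "marker") {
      vals <- vals + ifelse(bias_out, bias_sign * config$bias_shift, 0)
    }
    data.frame(sample_id = ids, class_label = cls, session = session,
               assay = unname(config$assays[[role]]),
               rep1 = vals[, 1], rep2 = vals[, 2], rep3 = vals[, 3],
               stringsAsFactors = FALSE)
  }))

  cohort <- qpcr_cohort(records)
  attr(cohort, "assays") <- unname(config$assays)
  attr(cohort, "truth") <- data.frame(
    sample_id = ids, class_label = cls, session = session,
    delta_marker = d_marker, delta_helper = d_helper, x_reference = x_ref,
    bias_outlier = bias_out,
    variability_outlier = apply(var_out, 1, any),
    stringsAsFactors = FALSE)
  cohort
}

#' Analytic class Gaussians of a combined measure under a config
#'
#' The exact population mean and SD, per class, of the measured
#' combination `delta_marker + c * delta_helper` implied by a
#' [synthetic_config()] — including the replicate-noise contribution
#' to the triplicate means (variance `2/3 sigma_rep^2` per assay, a
#' shared reference-noise covariance term) and the session-offset
#' mixture. Serves as the ground truth for parameter-recovery tests:
#' thresholds fitted on generated cohorts should approach the
#' threshold computed from these Gaussians.
#'
#' @param config a `synthetic_config`.
#' @param c admixture coefficient (0 for the marker delta alone).
#' @return list with `target` and `versus` `class_gaussian`s (class
#'   sizes carried from the config).
#' @export
analytic_combination_gaussians <- function(config, c = 0) {
  rep_var <- 2 / 3 * config$sigma_rep^2
  w <- config$session_weights / sum(config$session_weights)
  offs <- do.call(rbind, config$session_offsets)
  o_marker <- offs[, "marker"] - offs[, "reference"]
  o_helper <- offs[, "helper"] - offs[, "reference"]
  m_off <- c(marker = sum(w * o_marker), helper = sum(w * o_helper))
  v_off_m <- sum(w * o_marker^2) - m_off[["marker"]]^2
  v_off_h <- sum(w * o_helper^2) - m_off[["helper"]]^2
  cov_off <- sum(w * o_marker * o_helper) -
    m_off[["marker"]] * m_off[["helper"]]

  gaussian_for <- function(cl, n) {
    pm <- config$marker_delta[[cl]]
    ph <- config$helper_delta[[cl]]
    rho <- config$delta_correlation[[cl]]
    v_marker <- pm[["sd"]]^2 + rep_var[["marker"]] +
      rep_var[["reference"]] + v_off_m
    v_helper <- ph[["sd"]]^2 + rep_var[["helper"]] +
      rep_var[["reference"]] + v_off_h
    cov_mh <- rho * pm[["sd"]] * ph[["sd"]] + rep_var[["reference"]] +
      cov_off
    mu <- pm[["mean"]] + m_off[["marker"]] +
      c * (ph[["mean"]] + m_off[["helper"]])
    v <- v_marker + c^2 * v_helper + 2 * c * cov_mh
    class_gaussian(mu, sqrt(v), n)
  }
  list(target = gaussian_for("target", config$n_target),
       versus = gaussian_for("versus", config$n_versus))
}
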