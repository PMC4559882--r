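# Independent oracles and small fixture builders used across the suite.

# Brute-force K-S scale search: dense grid over sigma, independent of
# the package's minimiser.
grid_ks_sigma <- function(variances, sigmas = seq(1e-4, 1, by = 1e-4)) {
  v <- sort(variances)
  n <- length(v)
  i <- seq_len(n)
  d <- vapply(sigmas, function(s) {
    f <- 1 - exp(-v / (2 * s^2))
    max(pmax(abs(f - i / n), abs(f - (i - 1) / n)))
  }, numeric(1))
  list(sigma = sigmas[which.min(d)], D = min(d))
}

# Textbook Welch statistic, written out independently of stats::t.test.
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Direct quadratic-formula threshold, independent of the package's
# root-selection code: returns both roots.
quad_roots_oracle <- function(muT, sT, muV, sV, prior_ratio = 1,
                              odds = 1) {
  eta <- 1 / sT^2 - 1 / sV^2
  beta <- muT / sT^2 - muV / sV^2
  gam <- muT^2 / sT^2 - muV^2 / sV^2 + 2 * log(sT / sV)
  const <- gam - 2 * log(prior_ratio) + 2 * log(odds)
  disc <- beta^2 - eta * const
  if (abs(eta) < 1e-14) return(const / (2 * beta))
  c((beta - sqrt(disc)) / eta, (beta + sqrt(disc)) / eta)
}

# A tiny long-format cohort data.frame builder.
make_records <- function(sample_id, assay, reps, class_label = "target",
                         session = "I") {
  reps <- rbind(reps)
  data.frame(sample_id = sample_id, class_label = class_label,
             session = session, assay = assay,
             rep1 = reps[, 1], rep2 = reps[, 2],
             rep3 = if (ncol(reps) >= 3) reps[, 3] else NA_real_,
             stringsAsFactors = FALSE)
}

# Cohort where every triplicate is latent value + N(0, (sigma*sqrt(2))^2)
# noise, so s^2/sigma^2 ~ chi2(2); single assay.
noisy_cohort <- function(n, sigma, assay = "A", latent = 20,
                         class_label = "target", seed = 1) {
  set.seed(seed)
  reps <- matrix(rnorm(3 * n, latent, sigma * sqrt(2)), ncol = 3)
  qpcr_cohort(make_records(sprintf("S%05d", seq_len(n)), assay, reps,
                           class_label = class_label))
}

# Random well-posed two-class model for property loops.
random_model <- function(seed) {
  set.seed(seed)
  muV <- runif(1, -5, 5)
  muT <- muV + runif(1, 0.5, 8)
  sT <- runif(1, 0.5, 3)
  sV <- runif(1, 0.5, 3)
  pr <- exp(runif(1, -1, 1))
  fit_bayes_classifier(class_gaussian(muT, sT, sample(5:40, 1)),
                       class_gaussian(muV, sV, sample(5:40, 1)),
                       prior_ratio = pr)
}

# Summary-statistic class Gaussians used throughout: the printed
# per-class models of the combined measure and of the marker delta.
gauss_yopt <- function() list(target = class_gaussian(6.9, 1.9, 18),
                              versus = class_gaussian(0.7, 1.6, 15))
gauss_dx205 <- function() list(target = class_gaussian(1.7, 2.2, 18),
                               versus = class_gaussian(-4.6, 2.4, 15))
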