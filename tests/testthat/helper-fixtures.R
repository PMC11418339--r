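# Shared fixture builders. Everything is generated in code; expensive
# MCMC fits are cached per session so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

quiet_mcmc <- function(seed = 42L, chains = 2, warmup = 300, draws = 500) {
  mcmc_control(chains = chains, warmup = warmup, draws = draws, seed = seed)
}

# deterministic trajectory config: no noise, no events, no covariate
noiseless_config <- function(...) {
  sim_config(n_per_arm = 5,
             true_mu0 = -1, true_mu1 = -0.5,
             true_delta0 = -1, true_delta1 = -0.3,
             gamma_baseline = 0, sd_random_intercept = 0, sd_residual = 0,
             ice_hazard_per_week = 0, dropout_hazard_per_week = 0,
             period_effect = 0, seed = 11L, ...)
}

# hand-built single-patient external record for censoring tests
external_record <- function(id, visit_weeks, scores, baseline = 10,
                            source = "registry", ice_type = "none",
                            ice_week = NA_real_, thymectomy_week = NA_real_) {
  data.frame(patient_id = id, arm = "control", source = source,
             period = "double_blind", baseline_score = baseline,
             visit_week = visit_weeks, score = scores,
             cfb = scores - baseline, ice_type = ice_type,
             ice_week = ice_week, thymectomy_week = thymectomy_week,
             stringsAsFactors = FALSE)
}

# hand-built trial record for imputation tests
trial_record <- function(id, visit_weeks, scores, baseline = 10,
                         arm = "treated", ice_type = "none",
                         ice_week = NA_real_) {
  data.frame(patient_id = id, arm = arm, source = "trial",
             period = "double_blind", baseline_score = baseline,
             visit_week = visit_weeks, score = scores,
             cfb = scores - baseline, ice_type = ice_type,
             ice_week = ice_week, stringsAsFactors = FALSE)
}

# combined_fit skeleton around a given draw matrix, for estimand tests
fake_combined_fit <- function(draws, both_arms = TRUE, endpoint = "MG-ADL",
                              mean_function = "loglinear", chains = 2) {
  n <- nrow(draws)
  half <- n %/% 2
  samples <- coda::as.mcmc.list(list(
    coda::mcmc(draws[seq_len(half), , drop = FALSE]),
    coda::mcmc(draws[half + seq_len(half), , drop = FALSE])))
  structure(list(samples = samples,
                 spec = combined_spec(endpoint = endpoint),
                 prior = vague_prior(), mean_function = mean_function,
                 b_center = 10, both_arms = both_arms,
                 rhat = c(beta0_c = 1), converged = TRUE,
                 n_patients = 1L, n_rows = n, mcmc = quiet_mcmc()),
            class = "combined_fit")
}

# small two-arm dataset + combined fit, reused across estimand tests
small_combined_fit <- function() {
  cached("small_combined_fit", function() {
    cfg <- sim_config(n_per_arm = 40, seed = 7,
                      ice_hazard_per_week = 0, dropout_hazard_per_week = 0)
    ipd <- simulate_trial_ipd(cfg)
    fit_combined(ipd, vague_prior(), combined_spec(),
                 quiet_mcmc(seed = 7))
  })
}

# conjugate reduced setting: control arm only, sigma_u = 0, sigma_e known
conjugate_dataset <- function(n = 30, sigma_e = 2, seed = 5) {
  set.seed(seed)
  weeks <- c(1, 2, 4, 8, 12)
  # constant baseline: the covariate column is identically zero after
  # centring, so the fit reduces exactly to the bivariate regression the
  # closed form describes
  b <- rep(10, n)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cfb <- -1 - 0.4 * log(weeks) + rnorm(length(weeks), 0, sigma_e)
    data.frame(patient_id = sprintf("K%03d", i), arm = "control",
               source = "trial", period = "double_blind",
               baseline_score = b[i], visit_week = weeks,
               score = b[i] + cfb, cfb = cfb, ice_type = "none",
               ice_week = NA_real_, stringsAsFactors = FALSE)
  }))
}

# closed-form normal-normal posterior for (b0, b1) given known sigma_e,
# no random intercepts and a bivariate normal prior (independent oracle)
conjugate_posterior <- function(dat, prior, sigma_e) {
  X <- cbind(1, log(dat$visit_week))
  P0 <- solve(prior$covariance)
  prec <- P0 + crossprod(X) / sigma_e^2
  V <- solve(prec)
  m <- V %*% (P0 %*% prior$mean + crossprod(X, dat$cfb) / sigma_e^2)
  list(mean = as.numeric(m), cov = V)
}
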