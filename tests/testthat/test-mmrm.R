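# build a complete-data external block with known visit means, baseline
# slope and residual covariance (Cholesky draw)
make_mmrm_data <- function(n, weeks, mu, gamma = 0, Sigma = NULL,
                           baseline_sd = 2, seed = 1) {
  set.seed(seed)
  p <- length(weeks)
  b <- rnorm(n, 10, baseline_sd)
  b <- b - mean(b) + 10      # fix the mean so the centring point is known
  E <- if (is.null(Sigma)) matrix(0, n, p)
       else matrix(rnorm(n * p), n) %*% chol(Sigma)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cfb <- mu + gamma * (b[i] - 10) + E[i, ]
    data.frame(patient_id = sprintf("M%04d", i), arm = "control",
               source = "ext", period = "double_blind",
               baseline_score = b[i], visit_week = weeks,
               score = b[i] + cfb, cfb = cfb, ice_type = "none",
               ice_week = NA_real_, stringsAsFactors = FALSE)
  }))
}

test_that("zero-residual data recovers visit means and baseline slope exactly", {
  mu <- c(-1, -2, -3)
  dat <- make_mmrm_data(12, c(2, 4, 8), mu, gamma = 0.4)
  fit <- fit_weighted_mmrm(dat)
  expect_equal(unname(fit$visit_effects), mu, tolerance = 1e-6)
  expect_equal(fit$baseline_coefficient, 0.4, tolerance = 1e-6)
})

test_that("single-visit weighted fit equals the closed-form weighted ANCOVA", {
  set.seed(3)
  n <- 30
  b <- rnorm(n, 10, 2)
  w <- rep(c(1, 1, 2), length.out = n)
  y <- -2 + 0.3 * (b - 10) + rnorm(n, 0, 1.5)
  dat <- data.frame(patient_id = sprintf("Q%02d", 1:n), arm = "control",
                    source = "ext", period = "double_blind",
                    baseline_score = b, visit_week = 4, score = b + y,
                    cfb = y, ice_type = "none", ice_week = NA_real_)
  wt <- data.frame(patient_id = dat$patient_id, weight = w)
  fit <- fit_weighted_mmrm(dat, wt)
  # independent oracle: weighted least squares normal equations
  bw <- weighted.mean(b, w)
  X <- cbind(1, b - bw)
  beta_or <- solve(t(X) %*% (w * X), t(X) %*% (w * y))
  expect_equal(unname(fit$visit_effects), beta_or[1], tolerance = 1e-8)
  expect_equal(fit$baseline_coefficient, beta_or[2], tolerance = 1e-8)
})

test_that("diagonal-constrained fit on balanced complete data matches per-visit ANCOVA", {
  weeks <- c(2, 4, 8, 12)
  dat <- make_mmrm_data(80, weeks, c(-1, -1.5, -2, -2.2), gamma = 0.3,
                        Sigma = diag(c(1, 1.3, 1.6, 2)^2), seed = 8)
  fit <- fit_weighted_mmrm(dat, covariance = "diagonal")
  # with baseline centred at its mean, each LS mean is the raw visit mean
  for (k in seq_along(weeks)) {
    expect_equal(unname(fit$visit_effects[k]),
                 mean(dat$cfb[dat$visit_week == weeks[k]]),
                 tolerance = 1e-6)
  }
})

test_that("halving weights on duplicated patients reproduces the fit", {
  weeks <- c(2, 4, 8)
  Sigma <- 1.2^2 * diag(3) + 0.8
  dat <- make_mmrm_data(50, weeks, c(-1, -2, -2.5), gamma = 0.2,
                        Sigma = Sigma, seed = 12)
  fit1 <- fit_weighted_mmrm(dat)
  dup <- dat
  dup$patient_id <- paste0(dup$patient_id, "b")
  both <- rbind(dat, dup)
  wt <- data.frame(patient_id = unique(both$patient_id), weight = 0.5)
  fit2 <- fit_weighted_mmrm(both, wt)
  expect_equal(fit1$visit_effects, fit2$visit_effects, tolerance = 1e-6)
  expect_equal(fit1$baseline_coefficient, fit2$baseline_coefficient,
               tolerance = 1e-6)
  expect_equal(fit1$covariance, fit2$covariance, tolerance = 1e-5)
})

test_that("the unstructured optimum dominates the nested diagonal fit", {
  Sigma <- 1.5^2 * diag(3) + 1
  dat <- make_mmrm_data(60, c(2, 4, 8), c(-1, -2, -2.5), Sigma = Sigma,
                        seed = 15)
  un <- fit_weighted_mmrm(dat)
  dg <- fit_weighted_mmrm(dat, covariance = "diagonal")
  expect_gte(un$log_likelihood, dg$log_likelihood - 1e-6)
})

test_that("the covariance estimate converges to the generating covariance", {
  Sigma <- outer(c(1.4, 1.6, 1.8, 2.0), c(1.4, 1.6, 1.8, 2.0)) * 0.45
  diag(Sigma) <- c(1.4, 1.6, 1.8, 2.0)^2
  ok <- vapply(1:10, function(r) {
    dat <- make_mmrm_data(2000, c(2, 4, 8, 12), c(-1, -1.5, -2, -2.2),
                          gamma = 0.2, Sigma = Sigma, seed = 300 + r)
    fit <- fit_weighted_mmrm(dat)
    norm(fit$covariance - Sigma, "F") / norm(Sigma, "F") < 0.10
  }, logical(1))
  expect_gte(sum(ok), 9)
})

test_that("monotone missingness is handled through the observed-visit marginal", {
  Sigma <- 1.3^2 * diag(3) + 0.7
  dat <- make_mmrm_data(600, c(2, 4, 8), c(-1, -2, -2.5), Sigma = Sigma,
                        seed = 21)
  # drop the last visit for a third of the patients (MAR monotone)
  drop_ids <- unique(dat$patient_id)[seq(1, 600, by = 3)]
  dat <- dat[!(dat$patient_id %in% drop_ids & dat$visit_week == 8), ]
  fit <- fit_weighted_mmrm(dat)
  expect_true(fit$converged)
  expect_equal(unname(fit$visit_effects), c(-1, -2, -2.5), tolerance = 0.25)
})

test_that("ls_means shift linearly in the reference baseline", {
  dat <- make_mmrm_data(40, c(2, 4), c(-1, -2), gamma = 0.5,
                        Sigma = diag(2), seed = 30)
  fit <- fit_weighted_mmrm(dat)
  l0 <- ls_means(fit)
  l1 <- ls_means(fit, reference_baseline = fit$baseline_center + 1)
  expect_equal(l1$mean_cfb - l0$mean_cfb,
               rep(fit$baseline_coefficient, 2), tolerance = 1e-10)
  expect_error(ls_means(fit, reference_baseline = 30), "range")
  # null covariate (noise-free so gamma-hat is exactly 0): LS means equal
  # raw visit effects at any reference
  dat0 <- make_mmrm_data(40, c(2, 4), c(-1, -2), gamma = 0, seed = 31)
  fit0 <- fit_weighted_mmrm(dat0)
  l5 <- ls_means(fit0, reference_baseline = 5)
  expect_equal(l5$mean_cfb, unname(fit0$visit_effects), tolerance = 1e-6)
})

test_that("aggregate rows carry the source id, the ESS and the week-28 cap", {
  dat <- make_mmrm_data(40, c(4, 8, 16, 30), c(-1, -1.5, -2, -2.2),
                        Sigma = diag(4), seed = 33)
  wt <- data.frame(patient_id = unique(dat$patient_id),
                   weight = rep(c(1, 2), 20))
  fit <- fit_weighted_mmrm(dat, wt)
  agg <- aggregate_from_fit(fit, "registry-A")
  expect_equal(nrow(agg), 3)          # week 30 excluded
  expect_setequal(agg$visit_week, c(4, 8, 16))
  expect_true(all(agg$source_id == "registry-A"))
  expect_equal(unique(agg$n), effective_sample_size(rep(c(1, 2), 20)))
})

test_that("unidentifiable designs are rejected", {
  dat <- make_mmrm_data(3, c(2, 4, 8), c(-1, -2, -3), Sigma = diag(3))
  expect_error(fit_weighted_mmrm(dat), "fewer patients")
})
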