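#' MCMC sampler settings
#'
#' @param chains number of chains (>= 2 for diagnostics).
#' @param warmup adaptation/burn-in iterations per chain.
#' @param draws kept iterations per chain.
#' @param thin thinning interval.
#' @param seed integer seed; chain c uses `seed + c` for its RNG stream.
#' @return A `mcmc_control` list.
#' @export
mcmc_control <- function(chains = 4, warmup = 1000, draws = 1000,
                         thin = 1, seed = 1L) {
  if (chains < 1) stop_mg("'chains' must be >= 1")
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 draws = as.integer(draws), thin = as.integer(thin),
                 seed = as.integer(seed)), class = "mcmc_control")
}

# Run a JAGS model with reproducible per-chain RNG streams.
run_jags <- function(model_string, data, monitor, mcmc, inits_extra = NULL) {
  inits <- lapply(seq_len(mcmc$chains), function(c) {
    ini <- list(.RNG.name = "base::Mersenne-Twister",
                .RNG.seed = (mcmc$seed + c - 1L) %% .Machine$integer.max)
    if (!is.null(inits_extra)) ini <- c(ini, inits_extra(c))
    ini
  })
  jm <- rjags::jags.model(textConnection(model_string), data = data,
                          inits = inits, n.chains = mcmc$chains,
                          quiet = TRUE)
  update(jm, mcmc$warmup, progress.bar = "none")
  rjags::coda.samples(jm, monitor, n.iter = mcmc$draws * mcmc$thin,
                      thin = mcmc$thin, progress.bar = "none")
}

# Split-R-hat (classic Gelman-Rubin on split chains), floored at 1 so that
# identical chains report exactly 1; values below 1 are estimator noise.
split_rhat <- function(draw_list) {
  halves <- unlist(lapply(draw_list, function(x) {
    n <- length(x) %/% 2L
    list(x[seq_len(n)], x[n + seq_len(n)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (!is.finite(W) || W <= 0) return(1)
  max(1, sqrt(((n - 1) / n * W + B / n) / W))
}

rhat_from_mcmc <- function(samples, par) {
  split_rhat(lapply(samples, function(ch) as.numeric(ch[, par])))
}

#' Part 1: Bayesian meta-regression of aggregate control response
#'
#' Synthesises aggregate external control-arm summaries through a
#' measurement-error meta-regression on log time:
#' \deqn{y_{st} \sim N(\mu_0 + a_s + \mu_1 \log t,\ \mathrm{se}_{st}^2),
#'       \qquad a_s \sim N(0, \tau^2),}
#' with weakly informative hyperpriors on the score scale
#' (\eqn{\mu_0, \mu_1 \sim N(0, 10^2)}, \eqn{\tau \sim} half-normal(0,
#' 2)). Log time is the natural logarithm and is not centred, so
#' \eqn{\mu_0} is the control mean change from baseline at week 1.
#'
#' With a single source the intercept and its offset are confounded, so
#' \eqn{\tau} is fixed at 0 automatically (with a message); `tau_fixed`
#' forces any value.
#'
#' @param aggregate aggregate table (see [validate_aggregate()]).
#' @param mcmc a [mcmc_control()].
#' @param tau_fixed optional fixed between-source SD (e.g. 0 for the
#'   common-trajectory model).
#' @return Object of class `control_metareg` with `samples` (a
#'   `coda::mcmc.list` over `mu0`, `mu1`, `tau`, `a[s]`), posterior
#'   summary, per-parameter split R-hat, and `converged`
#'   (R-hat < 1.01 on `mu0` and `mu1`).
#' @export
fit_control_metareg <- function(aggregate, mcmc = mcmc_control(),
                                tau_fixed = NULL) {
  validate_aggregate(aggregate)
  if (length(unique(aggregate$visit_week)) < 2L)
    stop_mg("need >= 2 distinct visit weeks to identify the log-time slope")
  src <- factor(aggregate$source_id)
  S <- nlevels(src)
  if (S == 1L && is.null(tau_fixed)) {
    message("single source: between-source SD tau fixed at 0")
    tau_fixed <- 0
  }
  est_tau <- is.null(tau_fixed)
  jd <- list(K = nrow(aggregate), y = aggregate$mean_cfb,
             logt = log(aggregate$visit_week),
             prec_y = 1 / aggregate$se^2)
  if (est_tau || tau_fixed > 0) {
    jd$src <- as.integer(src)
    jd$S <- S
  }
  model <- if (est_tau) "
model {
  for (k in 1:K) { y[k] ~ dnorm(mu0 + a[src[k]] + mu1 * logt[k], prec_y[k]) }
  for (s in 1:S) { a[s] ~ dnorm(0, prec_tau) }
  mu0 ~ dnorm(0, 0.01)
  mu1 ~ dnorm(0, 0.01)
  tau ~ dnorm(0, 0.25) T(0,)
  prec_tau <- 1 / (tau * tau + 1.0E-12)
}" else if (!is.null(tau_fixed) && tau_fixed > 0) "
model {
  for (k in 1:K) { y[k] ~ dnorm(mu0 + a[src[k]] + mu1 * logt[k], prec_y[k]) }
  for (s in 1:S) { a[s] ~ dnorm(0, prec_tau) }
  mu0 ~ dnorm(0, 0.01)
  mu1 ~ dnorm(0, 0.01)
  prec_tau <- 1 / (tau_val * tau_val)
}" else "
model {
  for (k in 1:K) { y[k] ~ dnorm(mu0 + mu1 * logt[k], prec_y[k]) }
  mu0 ~ dnorm(0, 0.01)
  mu1 ~ dnorm(0, 0.01)
}"
  monitor <- c("mu0", "mu1")
  if (est_tau) monitor <- c(monitor, "tau", "a")
  if (!est_tau && tau_fixed > 0) {
    jd$tau_val <- tau_fixed
    monitor <- c(monitor, "a")
  }
  samples <- run_jags(model, jd, monitor, mcmc)
  rhats <- vapply(c("mu0", "mu1"), function(p) rhat_from_mcmc(samples, p),
                  numeric(1))
  structure(list(samples = samples,
                 summary = summary(samples)$statistics,
                 rhat = rhats,
                 converged = all(rhats < 1.01),
                 sources = levels(src),
                 tau_fixed = tau_fixed,
                 mcmc = mcmc), class = "control_metareg")
}

#' @export
print.control_metareg <- function(x, ...) {
  cat("Control trajectory meta-regression (", length(x$sources),
      " source(s))\n", sep = "")
  sel <- intersect(c("mu0", "mu1", "tau"), rownames(x$summary))
  print(round(x$summary[sel, c("Mean", "SD"), drop = FALSE], 4))
  cat("split R-hat: mu0 =", round(x$rhat["mu0"], 4),
      ", mu1 =", round(x$rhat["mu1"], 4),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' Construct a bivariate normal prior on the control trajectory
#'
#' @param mean length-2 vector (intercept at week 1, log-time slope).
#' @param covariance 2x2 symmetric positive-definite matrix.
#' @param weight borrowing weight in `[0, 1]` already embodied in the
#'   covariance (1 = full borrowing).
#' @return Object of class `borrow_prior`.
#' @export
gaussian_prior <- function(mean, covariance, weight = 1) {
  mean <- as.numeric(mean)
  covariance <- as.matrix(covariance)
  if (length(mean) != 2L || !all(dim(covariance) == 2L))
    stop_mg("prior is bivariate: mean length 2, covariance 2x2")
  if (max(abs(covariance - t(covariance))) > 1e-10)
    stop_mg("covariance must be symmetric")
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop_mg("covariance must be positive definite")
  if (weight < 0 || weight > 1) stop_mg("weight must lie in [0, 1]")
  structure(list(mean = setNames(mean, c("mu0", "mu1")),
                 covariance = covariance, weight = weight),
            class = "borrow_prior")
}

#' The configured vague prior
#'
#' Mean zero, independent components with variance `1e4` — the
#' non-informative prior corresponding to 100% down-weighting of the
#' external data.
#'
#' @param variance per-component variance (default 1e4).
#' @return A `borrow_prior` with `weight` 0.
#' @export
vague_prior <- function(variance = 1e4) {
  p <- gaussian_prior(c(0, 0), diag(variance, 2), weight = 1)
  p$weight <- 0
  p
}

#' @export
print.borrow_prior <- function(x, ...) {
  cat("Control-trajectory prior (borrowing weight ", x$weight, ")\n", sep = "")
  cat(sprintf("  mean: mu0 = %.4f, mu1 = %.4f\n", x$mean[1], x$mean[2]))
  cat(sprintf("  SDs:  %.4f, %.4f; corr %.3f\n",
              sqrt(x$covariance[1, 1]), sqrt(x$covariance[2, 2]),
              x$covariance[1, 2] / sqrt(prod(diag(x$covariance)))))
  invisible(x)
}

#' Moment-match the Part-1 posterior into a normal prior
#'
#' The posterior draws of \eqn{(\mu_0, \mu_1)} are summarised by their
#' sample mean and covariance, giving the informative prior for Part 2 at
#' full weight.
#'
#' @param fit a [fit_control_metareg()] object (or a two-column draw
#'   matrix with columns `mu0`, `mu1`).
#' @return A `borrow_prior` with `weight` 1.
#' @export
moment_match_prior <- function(fit) {
  draws <- if (inherits(fit, "control_metareg"))
    as.matrix(fit$samples)[, c("mu0", "mu1")] else as.matrix(fit)[, c("mu0", "mu1")]
  m <- colMeans(draws)
  V <- cov(draws)
  if (any(diag(V) < 1e-12))
    stop_mg("degenerate draws: zero posterior variance, cannot moment-match")
  gaussian_prior(m, V, weight = 1)
}

#' Down-weight a borrowing prior (normal power prior)
#'
#' For weight \eqn{w > 0} the covariance is inflated by \eqn{1/w} with
#' the mean unchanged — the exact normal-theory power prior, so a prior
#' "down-weighted by 30%" has weight 0.7 and every covariance entry
#' multiplied by 10/7. Weight 0 returns the configured [vague_prior()]
#' (100% down-weighting of the external data). Down-weighting composes
#' multiplicatively: weights `a` then `b` equal weight `a * b`.
#'
#' @param prior a `borrow_prior`.
#' @param weight borrowing fraction in `[0, 1]`.
#' @return A `borrow_prior`.
#' @export
downweight_prior <- function(prior, weight) {
  stopifnot(inherits(prior, "borrow_prior"))
  if (!is.numeric(weight) || length(weight) != 1L || is.na(weight) ||
      weight < 0 || weight > 1)
    stop_mg("weight must be a single number in [0, 1]")
  if (weight == 0) return(vague_prior())
  out <- gaussian_prior(prior$mean, prior$covariance / weight, weight = 1)
  out$weight <- prior$weight * weight
  out
}
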