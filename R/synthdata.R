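#' Simulation configuration for synthetic trial and registry data
#'
#' Bundles the parameters of the data-generating model that the analysis
#' assumes: a log-linear-in-time mean trajectory per arm, a baseline-score
#' covariate effect, patient-level random intercepts, residual noise,
#' intercurrent-event and dropout hazards, and an open-label period switch
#' at the end of the double-blind phase.
#'
#' The latent change-from-baseline mean for patient \eqn{i} in arm \eqn{g}
#' at week \eqn{t} is
#' \deqn{\mu_0 + \mu_1 \log t + 1[g=\mathrm{treated}](\delta_0 + \delta_1 \log t)
#'       + \gamma (b_i - \bar b) + \eta\, 1[t > t_{OL}] + u_i}
#' with \eqn{u_i \sim N(0, \sigma_u^2)} and residual noise
#' \eqn{N(0, \sigma_e^2)} added per visit.
#'
#' Defaults emulate a phase-III generalised myasthenia gravis trial on the
#' MG-ADL scale: the control trajectory reaches about -1.8 points at week
#' 12 and -2.0 at week 24, the treatment contrast about -2.3 and -2.55
#' points, and the placebo baseline distribution is mean 10.6, SD 3.5.
#'
#' @param n_per_arm patients per arm (default 100).
#' @param schedule strictly increasing positive visit weeks.
#' @param true_mu0,true_mu1 control intercept (at week 1, where
#'   \eqn{\log t = 0}) and slope per unit log week, in score points.
#' @param true_delta0,true_delta1 treatment contrasts on intercept and
#'   slope.
#' @param gamma_baseline coefficient of centred baseline score.
#' @param sd_random_intercept,sd_residual random-intercept and residual
#'   SDs in points.
#' @param baseline_mean,baseline_sd baseline score distribution.
#' @param ice_hazard_per_week per-week probability of a first intercurrent
#'   event (rescue/crisis/death) in the trial arms.
#' @param dropout_hazard_per_week per-week probability of monotone
#'   dropout (missing at random).
#' @param openlabel_start_week week after which trial visits are
#'   open-label; control patients contribute no data past this week.
#' @param period_effect additive open-label period effect in points.
#' @param endpoint score instrument, `"MG-ADL"` or `"QMG"`.
#' @param seed integer seed making generation reproducible.
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_per_arm = 20, seed = 1)
#' head(simulate_trial_ipd(cfg))
sim_config <- function(n_per_arm = 100,
                       schedule = c(1, 2, 4, 8, 12, 16, 20, 24),
                       true_mu0 = -1.0, true_mu1 = -0.31,
                       true_delta0 = -1.5, true_delta1 = -0.33,
                       gamma_baseline = 0.1,
                       sd_random_intercept = 2.5, sd_residual = 2.0,
                       baseline_mean = 10.6, baseline_sd = 3.5,
                       ice_hazard_per_week = 0.005,
                       dropout_hazard_per_week = 0.005,
                       openlabel_start_week = 12,
                       period_effect = 0,
                       endpoint = c("MG-ADL", "QMG"),
                       seed = 1L) {
  endpoint <- match.arg(endpoint)
  if (length(schedule) == 0L) stop_mg("'schedule' must contain at least one visit week")
  if (any(schedule <= 0)) stop_mg("all visit weeks must be > 0 (baseline week 0 is not a response visit)")
  if (is.unsorted(schedule, strictly = TRUE)) stop_mg("'schedule' must be strictly increasing")
  if (n_per_arm < 1) stop_mg("'n_per_arm' must be >= 1")
  if (sd_random_intercept < 0 || sd_residual < 0 || baseline_sd < 0)
    stop_mg("standard deviations must be >= 0")
  for (h in c(ice_hazard_per_week, dropout_hazard_per_week))
    if (h < 0 || h > 1) stop_mg("hazards must lie in [0, 1]")
  structure(list(
    n_per_arm = as.integer(n_per_arm), schedule = as.numeric(schedule),
    true_mu0 = true_mu0, true_mu1 = true_mu1,
    true_delta0 = true_delta0, true_delta1 = true_delta1,
    gamma_baseline = gamma_baseline,
    sd_random_intercept = sd_random_intercept, sd_residual = sd_residual,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    ice_hazard_per_week = ice_hazard_per_week,
    dropout_hazard_per_week = dropout_hazard_per_week,
    openlabel_start_week = openlabel_start_week,
    period_effect = period_effect,
    endpoint = endpoint, seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic-data configuration (", x$endpoint, ")\n", sep = "")
  cat("  n per arm:", x$n_per_arm, " visits:", paste(x$schedule, collapse = ", "), "\n")
  cat(sprintf("  control: mu0 = %.3g, mu1 = %.3g; contrasts: delta0 = %.3g, delta1 = %.3g\n",
              x$true_mu0, x$true_mu1, x$true_delta0, x$true_delta1))
  cat(sprintf("  baseline ~ N(%.3g, %.3g^2), gamma = %.3g, sd_u = %.3g, sd_e = %.3g\n",
              x$baseline_mean, x$baseline_sd, x$gamma_baseline,
              x$sd_random_intercept, x$sd_residual))
  invisible(x)
}

# Latent CFB mean at weeks t for one patient. `z` is the treated indicator.
latent_cfb_mean <- function(config, t, z, b_centered, u) {
  lt <- log(t)
  period <- as.numeric(t > config$openlabel_start_week)
  config$true_mu0 + config$true_mu1 * lt +
    z * (config$true_delta0 + config$true_delta1 * lt) +
    config$gamma_baseline * b_centered +
    config$period_effect * period + u
}

# Geometric first-event week on the integer grid 1, 2, ...; Inf if hazard 0.
draw_event_week <- function(n, hazard) {
  if (hazard <= 0) return(rep(Inf, n))
  if (hazard >= 1) return(rep(1, n))
  rgeom(n, hazard) + 1
}

empty_ipd <- function() {
  data.frame(patient_id = character(), arm = character(), source = character(),
             period = character(), baseline_score = numeric(),
             visit_week = numeric(), score = numeric(), cfb = numeric(),
             ice_type = character(), ice_week = numeric(),
             stringsAsFactors = FALSE)
}

# Core generator for one source/arm block. Trial ICEs blank post-event
# scores to NA (they are imputed by the estimand rule); dropout removes
# rows outright (missing at random).
simulate_arm_block <- function(config, ids, arm, source, weeks,
                               baseline_mean, baseline_sd,
                               apply_ice = TRUE) {
  n <- length(ids)
  z <- as.numeric(arm == "treated")
  rng <- instrument_range(config$endpoint)
  b <- pmin(pmax(rnorm(n, baseline_mean, baseline_sd), rng[1]), rng[2])
  u <- rnorm(n, 0, config$sd_random_intercept)
  ice_w <- if (apply_ice) draw_event_week(n, config$ice_hazard_per_week) else rep(Inf, n)
  drop_w <- draw_event_week(n, config$dropout_hazard_per_week)
  ice_kind <- sample(c("rescue", "crisis", "death"), n, replace = TRUE,
                     prob = c(0.5, 0.35, 0.15))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    t <- weeks
    # dropout truncates the record, but an ICE freezes it instead: post-ICE
    # visits are kept as missing scores so the failure rule can impute them
    if (is.finite(drop_w[i]) && drop_w[i] < ice_w[i]) t <- t[t < drop_w[i]]
    if (length(t) == 0L) next
    mu <- latent_cfb_mean(config, t, z, b[i] - config$baseline_mean, u[i])
    score <- pmin(pmax(b[i] + mu + rnorm(length(t), 0, config$sd_residual),
                       rng[1]), rng[2])
    cfb <- score - b[i]
    post_ice <- t >= ice_w[i]
    score[post_ice] <- NA_real_
    cfb[post_ice] <- NA_real_
    has_ice <- any(post_ice)
    out[[i]] <- data.frame(
      patient_id = ids[i], arm = arm, source = source,
      period = ifelse(t > config$openlabel_start_week, "open_label", "double_blind"),
      baseline_score = b[i], visit_week = t, score = score, cfb = cfb,
      ice_type = if (has_ice) ice_kind[i] else "none",
      ice_week = if (has_ice) ice_w[i] else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) return(empty_ipd())
  do.call(rbind, out)
}

#' Simulate trial individual patient data
#'
#' Generates long-format visits for a two-arm randomised trial under the
#' log-linear trajectory model described in [sim_config()]. Control
#' patients contribute no rows after `openlabel_start_week` (they cross
#' over to open-label active drug, which is why the external prior is
#' needed to predict the late control trajectory); treated patients
#' continue through the full schedule with `period` switching to
#' `"open_label"`.
#'
#' Visits at or after a patient's first intercurrent event are retained
#' with missing scores so that [impute_intercurrent()] can apply the
#' treatment-failure rule; dropout removes rows.
#'
#' @param config a [sim_config()] object.
#' @return A long-format `data.frame` with columns `patient_id`, `arm`,
#'   `source`, `period`, `baseline_score`, `visit_week`, `score`, `cfb`,
#'   `ice_type`, `ice_week` and attribute `endpoint`.
#' @export
simulate_trial_ipd <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ctl_weeks <- config$schedule[config$schedule <= config$openlabel_start_week]
  ctl <- simulate_arm_block(config,
                            sprintf("C%04d", seq_len(config$n_per_arm)),
                            "control", "trial", ctl_weeks,
                            config$baseline_mean, config$baseline_sd)
  trt <- simulate_arm_block(config,
                            sprintf("T%04d", seq_len(config$n_per_arm)),
                            "treated", "trial", config$schedule,
                            config$baseline_mean, config$baseline_sd)
  out <- rbind(ctl, trt)
  rownames(out) <- NULL
  attr(out, "endpoint") <- config$endpoint
  out
}

#' Simulate registry-like external control data
#'
#' Control-only individual patient data whose baseline distribution is
#' shifted relative to the trial (registry populations are typically less
#' severe at entry than trial enrollees), with thymectomy and rescue
#' events emitted so the censoring rules in [apply_censoring()] are
#' exercisable. Rescue events are recorded via `ice_type`/`ice_week` but
#' scores after rescue are retained — registries keep measuring, and the
#' censoring window (not failure imputation) handles them. Thymectomy
#' dates (weeks, possibly negative for pre-enrolment surgery) are carried
#' in an extra `thymectomy_week` column.
#'
#' @param config a [sim_config()]; `baseline_mean`/`baseline_sd` describe
#'   the external population (default the trial values — pass e.g.
#'   `baseline_mean = 8.2, baseline_sd = 2.4` for a registry-like shift).
#' @param shift additive offset applied to the baseline mean.
#' @param event_rates list with elements `thymectomy`, `rescue`
#'   (per-patient probabilities, default 0) and optional fixed
#'   `thymectomy_week`, `rescue_week`; when unset, event weeks are drawn
#'   uniformly (thymectomy over -26..26, rescue over the visit schedule).
#' @param source_id label stamped into the `source` column.
#' @return An IPD `data.frame` as in [simulate_trial_ipd()], plus
#'   `thymectomy_week`.
#' @export
simulate_external_ipd <- function(config, shift = 0,
                                  event_rates = list(thymectomy = 0, rescue = 0),
                                  source_id = "external") {
  stopifnot(inherits(config, "sim_config"))
  rates <- utils::modifyList(list(thymectomy = 0, rescue = 0,
                                  thymectomy_week = NULL, rescue_week = NULL),
                             event_rates)
  if (rates$thymectomy < 0 || rates$rescue < 0)
    stop_mg("event rates must be >= 0")
  set.seed(config$seed + 1L)
  weeks <- config$schedule[config$schedule <= 28]
  out <- simulate_arm_block(config,
                            sprintf("E%04d", seq_len(config$n_per_arm)),
                            "control", source_id, weeks,
                            config$baseline_mean + shift, config$baseline_sd,
                            apply_ice = FALSE)
  ids <- unique(out$patient_id)
  n <- length(ids)
  thy <- ifelse(runif(n) < rates$thymectomy,
                rates$thymectomy_week %||% sample(seq(-26, 26), n, replace = TRUE),
                NA_real_)
  resc <- ifelse(runif(n) < rates$rescue,
                 rates$rescue_week %||% sample(weeks, n, replace = TRUE),
                 NA_real_)
  idx <- match(out$patient_id, ids)
  out$thymectomy_week <- thy[idx]
  has_resc <- !is.na(resc[idx])
  out$ice_type[has_resc] <- "rescue"
  out$ice_week[has_resc] <- resc[idx][has_resc]
  attr(out, "endpoint") <- config$endpoint
  out
}

#' Simulate aggregate external control summaries
#'
#' Per-source, per-visit mean change from baseline with standard errors,
#' as extracted from published placebo arms: source intercept offsets
#' \eqn{a_s \sim N(0, \tau^2)} around a common log-time trajectory, and
#' observed means \eqn{y_{st} \sim N(\mu_0 + a_s + \mu_1 \log t,
#' \mathrm{se}_{st}^2)} with \eqn{\mathrm{se}_{st} =
#' \sigma/\sqrt{n_s}}. Rows are capped at week 28, the latest visit the
#' extraction window admits.
#'
#' @param n_sources number of external sources (>= 1).
#' @param per_source_n patients per source (drives the SEs).
#' @param schedule visit weeks common to all sources.
#' @param true_mu0,true_mu1 common control trajectory.
#' @param tau between-source SD of the intercept offsets (>= 0).
#' @param resid_sd within-source patient SD used to derive SEs
#'   (default 3.7 points, a typical CFB dispersion on these scales).
#' @param seed integer seed.
#' @return A `data.frame` with columns `source_id`, `visit_week`,
#'   `mean_cfb`, `se`, `n`.
#' @export
simulate_aggregate_sources <- function(n_sources, per_source_n,
                                       schedule = c(4, 8, 12, 16, 20, 24),
                                       true_mu0 = -1.0, true_mu1 = -0.31,
                                       tau = 0.3, resid_sd = 3.7, seed = 1L) {
  if (n_sources < 1) stop_mg("'n_sources' must be >= 1")
  if (tau < 0) stop_mg("'tau' must be >= 0")
  if (any(schedule <= 0)) stop_mg("visit weeks must be > 0")
  set.seed(seed)
  schedule <- schedule[schedule <= 28]
  if (length(schedule) == 0L) stop_mg("no visit weeks at or below week 28")
  a <- rnorm(n_sources, 0, tau)
  se <- resid_sd / sqrt(per_source_n)
  out <- do.call(rbind, lapply(seq_len(n_sources), function(s) {
    mu <- true_mu0 + a[s] + true_mu1 * log(schedule)
    data.frame(source_id = sprintf("S%02d", s), visit_week = schedule,
               mean_cfb = rnorm(length(schedule), mu, se),
               se = se, n = per_source_n, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
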