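#' Censoring rules for external control sources
#'
#' Encodes the comparability windows applied to external individual
#' patient data before modelling: visits within six months (26 weeks)
#' after a thymectomy and within four weeks after rescue therapy are
#' removed, and source-specific lead-in windows discard the early period
#' where co-medication changes dominate (13 weeks for a
#' prednisone-monotherapy source, 52 weeks for a thymectomy source).
#' Months are converted at 3 months = 13 weeks, 6 = 26, 12 = 52.
#'
#' @param post_thymectomy_weeks window after thymectomy (default 26).
#' @param post_rescue_weeks window after rescue therapy (default 4).
#' @param source_lead_in_weeks named numeric vector mapping source labels
#'   to lead-in windows; visits at or before the window are removed.
#' @return An object of class `censor_rules`.
#' @export
censor_rules <- function(post_thymectomy_weeks = 26,
                         post_rescue_weeks = 4,
                         source_lead_in_weeks = c("MGTX-prednisone" = 13,
                                                  "MGTX-thymectomy" = 52)) {
  if (post_thymectomy_weeks < 0 || post_rescue_weeks < 0 ||
      any(source_lead_in_weeks < 0))
    stop_mg("censoring durations must be >= 0")
  structure(list(post_thymectomy_weeks = post_thymectomy_weeks,
                 post_rescue_weeks = post_rescue_weeks,
                 source_lead_in_weeks = source_lead_in_weeks),
            class = "censor_rules")
}

#' Apply censoring rules to external IPD
#'
#' Removes visit rows inside the post-thymectomy window, the post-rescue
#' window and the source lead-in window; drops patients with no surviving
#' visit; and (by default) re-anchors the baseline at the first surviving
#' visit with a score, recomputing change from baseline against it. The
#' re-anchored visit row is retained in the output, flagged
#' `is_rebaseline_anchor` with `cfb` 0, and is excluded from model fits.
#' Surviving scores are never altered, only removed or re-referenced.
#'
#' @param external external IPD table (see [simulate_external_ipd()]);
#'   rescue events are read from `ice_type`/`ice_week` and thymectomy
#'   dates from a `thymectomy_week` column when present.
#' @param rules a [censor_rules()] object.
#' @param rebaseline `"first_surviving"` (default) re-anchors the
#'   baseline after censoring; `"original"` keeps the original baseline.
#' @param lead_in_sources optional character vector of source labels for
#'   which a lead-in rule is requested; labels without a rule raise an
#'   error. Defaults to sources present in both the data and the rules.
#' @return The censored IPD table.
#' @export
apply_censoring <- function(external, rules = censor_rules(),
                            rebaseline = c("first_surviving", "original"),
                            lead_in_sources = NULL) {
  stopifnot(inherits(rules, "censor_rules"))
  rebaseline <- match.arg(rebaseline)
  if (!is.null(lead_in_sources)) {
    unknown <- setdiff(lead_in_sources, names(rules$source_lead_in_weeks))
    if (length(unknown) > 0L)
      stop_mg("no lead-in rule for source label(s): ",
              paste(unknown, collapse = ", "))
  } else {
    lead_in_sources <- intersect(unique(external$source),
                                 names(rules$source_lead_in_weeks))
  }
  keep <- rep(TRUE, nrow(external))
  thy <- if ("thymectomy_week" %in% names(external))
    external$thymectomy_week else rep(NA_real_, nrow(external))
  has_thy <- !is.na(thy)
  keep[has_thy & external$visit_week >= thy &
         external$visit_week <= thy + rules$post_thymectomy_weeks] <- FALSE
  resc <- ifelse(external$ice_type == "rescue", external$ice_week, NA_real_)
  has_resc <- !is.na(resc)
  keep[has_resc & external$visit_week >= resc &
         external$visit_week <= resc + rules$post_rescue_weeks] <- FALSE
  for (src in lead_in_sources) {
    lead <- rules$source_lead_in_weeks[[src]]
    keep[external$source == src & external$visit_week <= lead] <- FALSE
  }
  out <- external[keep, , drop = FALSE]
  out$is_rebaseline_anchor <- logical(nrow(out))
  if (rebaseline == "first_surviving" && nrow(out) > 0L) {
    out <- out[order(out$patient_id, out$visit_week), , drop = FALSE]
    pieces <- split(out, out$patient_id)
    pieces <- lapply(pieces, function(p) {
      scored <- which(!is.na(p$score))
      if (length(scored) == 0L) return(p[0, , drop = FALSE])
      anchor <- scored[1]
      p$baseline_score <- p$score[anchor]
      p$cfb <- p$score - p$baseline_score
      p$is_rebaseline_anchor[anchor] <- TRUE
      p
    })
    out <- do.call(rbind, pieces)
  }
  # patients whose record was censored away entirely are dropped
  out <- out[!is.na(out$patient_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "endpoint") <- attr(external, "endpoint")
  out
}

#' Fit a propensity model for trial membership
#'
#' Logistic regression of the trial-membership indicator on baseline
#' MG-ADL and QMG scores, pooling external and trial patients. Patients
#' missing either baseline are excluded (their count is recorded).
#' Near-perfect separation is detected and raised as an error, since the
#' resulting odds weights would be degenerate.
#'
#' @param external_baselines,trial_baselines data frames with one row per
#'   patient and columns `patient_id`, `mgadl`, `qmg`.
#' @return Object of class `propensity_fit` with elements `coefficients`,
#'   `covariates`, `converged`, `propensities` (fitted trial-membership
#'   probability for each included external patient, named by id),
#'   `n_excluded`, and `overlap_warning`.
#' @export
fit_propensity <- function(external_baselines, trial_baselines) {
  req <- c("patient_id", "mgadl", "qmg")
  for (nm in list(external_baselines, trial_baselines))
    if (!all(req %in% names(nm)))
      stop_mg("baseline tables need columns: ", paste(req, collapse = ", "))
  ext <- external_baselines[, req]
  tri <- trial_baselines[, req]
  cc_ext <- complete.cases(ext[, c("mgadl", "qmg")])
  cc_tri <- complete.cases(tri[, c("mgadl", "qmg")])
  n_excluded <- sum(!cc_ext) + sum(!cc_tri)
  ext <- ext[cc_ext, ]
  tri <- tri[cc_tri, ]
  if (nrow(ext) < 2L || nrow(tri) < 2L)
    stop_mg("need at least 2 patients with both baselines in each pool")
  dat <- rbind(cbind(ext, in_trial = 0L), cbind(tri, in_trial = 1L))
  fit <- suppressWarnings(
    glm(in_trial ~ mgadl + qmg, data = dat, family = binomial()))
  p_all <- fitted(fit)
  if (!fit$converged || any(abs(coef(fit)[-1]) > 20) ||
      all(p_all > 1 - 1e-8 | p_all < 1e-8))
    stop_mg("propensity model shows (near-)perfect separation; ",
            "check overlap of the baseline covariates between pools")
  # crude support-overlap screen on each covariate
  overlap_warning <- NULL
  for (v in c("mgadl", "qmg")) {
    if (min(tri[[v]]) > max(ext[[v]]) || min(ext[[v]]) > max(tri[[v]])) {
      overlap_warning <- paste0("non-overlapping support on baseline ", v)
      warning(overlap_warning, call. = FALSE)
    }
  }
  p_ext <- p_all[seq_len(nrow(ext))]
  structure(list(coefficients = coef(fit),
                 covariates = c("mgadl", "qmg"),
                 converged = fit$converged,
                 propensities = setNames(p_ext, ext$patient_id),
                 trial_ids = tri$patient_id,
                 n_excluded = n_excluded,
                 overlap_warning = overlap_warning),
            class = "propensity_fit")
}

#' @export
print.propensity_fit <- function(x, ...) {
  cat("Propensity model for trial membership (logistic)\n")
  print(round(x$coefficients, 4))
  cat("external patients weighted:", length(x$propensities),
      " excluded for missing baselines:", x$n_excluded, "\n")
  if (!is.null(x$overlap_warning)) cat("warning:", x$overlap_warning, "\n")
  invisible(x)
}

#' Convert propensities into odds weights
#'
#' External patients receive the odds of trial membership,
#' \eqn{w_i = p_i / (1 - p_i)}, which reweights the external pool toward
#' the trial population; trial patients keep weight 1. The Kish effective
#' sample size of the external weights is attached.
#'
#' @param fit a converged [fit_propensity()] object.
#' @return Object of class `weight_table`: a `data.frame` with columns
#'   `patient_id`, `weight`, `pool`, and attribute `ess` (external pool).
#' @export
compute_odds_weights <- function(fit) {
  stopifnot(inherits(fit, "propensity_fit"))
  if (!fit$converged) stop_mg("propensity fit did not converge")
  p <- fit$propensities
  at_one <- p >= 1 - 1e-12
  if (any(at_one))
    stop_mg("propensity of 1 (infinite odds) for patient(s): ",
            paste(names(p)[at_one], collapse = ", "))
  w_ext <- p / (1 - p)
  out <- rbind(
    data.frame(patient_id = names(p), weight = as.numeric(w_ext),
               pool = "external", stringsAsFactors = FALSE),
    data.frame(patient_id = as.character(fit$trial_ids), weight = 1,
               pool = "trial", stringsAsFactors = FALSE))
  attr(out, "ess") <- effective_sample_size(w_ext)
  class(out) <- c("weight_table", "data.frame")
  out
}

#' Kish effective sample size of a weight vector
#'
#' \deqn{\mathrm{ESS} = (\sum_i w_i)^2 / \sum_i w_i^2.}
#' Scale-invariant; equals \eqn{n} iff the weights are constant.
#'
#' @param weights non-negative weights, not all zero.
#' @return A single number in \eqn{(0, n]}.
#' @export
#' @examples
#' effective_sample_size(c(1, 1, 2)) # 16/6
effective_sample_size <- function(weights) {
  if (any(weights < 0)) stop_mg("weights must be >= 0")
  s <- sum(weights)
  if (s == 0) stop_mg("all-zero weights have no effective sample size")
  s^2 / sum(weights^2)
}
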