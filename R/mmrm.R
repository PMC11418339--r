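#' Fit an IPTW-weighted MMRM to external control IPD
#'
#' Mixed model for repeated measures: change from baseline regressed on
#' visit (categorical, cell-means coding) and centred baseline score,
#' with an unstructured visit-by-visit covariance. Each patient's
#' multivariate-normal log-likelihood contribution is multiplied by their
#' propensity odds weight \eqn{w_i}; patients missing visits contribute
#' through the marginal normal of their observed visits (the standard
#' MMRM treatment of monotone missingness under missing-at-random).
#'
#' Estimation maximises the weighted profile log-likelihood over the
#' covariance, parameterized by its Cholesky factor with log diagonal,
#' with the fixed effects solved by weighted generalised least squares at
#' each step (quasi-Newton, relative tolerance 1e-8, at most 500
#' iterations). Maximum likelihood is the default because weighted REML
#' is ill-defined under non-integer weights; a REML-style adjustment is
#' available. Standard errors are model-based, from the weighted
#' information matrix, because downstream meta-regression consumes them
#' as measurement-error SDs.
#'
#' @param ipd IPD table; rows flagged `is_rebaseline_anchor` and rows
#'   with missing scores are excluded.
#' @param weights optional [compute_odds_weights()] table or data frame
#'   with `patient_id`, `weight`; patients without a row get weight 1.
#' @param covariance `"unstructured"` (default) or `"diagonal"`.
#' @param reml add the REML determinant adjustment (default `FALSE`).
#' @param max_iter,tol optimizer controls.
#' @return Object of class `mmrm_fit` with elements `visit_effects`
#'   (adjusted mean CFB per visit at the weighted mean baseline),
#'   `baseline_coefficient`, `covariance`, `vcov_coef`, `ls_mean_ses`,
#'   `log_likelihood`, `converged`, `n_used`, `ess`, `weeks`,
#'   `baseline_center`.
#' @export
fit_weighted_mmrm <- function(ipd, weights = NULL,
                              covariance = c("unstructured", "diagonal"),
                              reml = FALSE, max_iter = 500, tol = 1e-8) {
  covariance <- match.arg(covariance)
  dat <- ipd
  if ("is_rebaseline_anchor" %in% names(dat))
    dat <- dat[!dat$is_rebaseline_anchor, , drop = FALSE]
  dat <- dat[!is.na(dat$cfb), , drop = FALSE]
  if (nrow(dat) == 0L) stop_mg("no usable rows after exclusions")
  weeks <- sort(unique(dat$visit_week))
  p <- length(weeks)
  ids <- unique(dat$patient_id)
  n <- length(ids)
  if (n <= p)
    stop_mg("fewer patients (", n, ") than needed to identify an ",
            "unstructured ", p, "-visit covariance")
  w <- rep(1, n)
  names(w) <- ids
  if (!is.null(weights)) {
    m <- match(ids, weights$patient_id)
    w[!is.na(m)] <- weights$weight[m[!is.na(m)]]
  }
  bl <- tapply(dat$baseline_score, dat$patient_id, function(x) x[1])[ids]
  b_center <- weighted.mean(bl, w)

  # group patients by observed-visit pattern so the likelihood is a few
  # matrix operations per pattern rather than a per-patient loop
  vi <- match(dat$visit_week, weeks)
  ord <- order(match(dat$patient_id, ids), vi)
  dat <- dat[ord, , drop = FALSE]
  vi <- vi[ord]
  pat_key <- tapply(vi, factor(dat$patient_id, levels = ids),
                    function(o) paste(o, collapse = ","))
  groups <- lapply(split(seq_len(n), pat_key), function(is) {
    o <- as.integer(strsplit(pat_key[[is[1]]], ",")[[1]])
    rows <- which(match(dat$patient_id, ids) %in% is)
    Y <- matrix(dat$cfb[rows], nrow = length(o))  # visits x patients
    list(obs = o, Y = Y, b = as.numeric(bl[is] - b_center),
         w = as.numeric(w[is]))
  })

  q <- p + 1L  # visit effects + baseline coefficient
  theta_len <- if (covariance == "unstructured") p * (p + 1L) / 2L else p
  build_sigma <- function(theta) {
    L <- matrix(0, p, p)
    if (covariance == "unstructured") {
      diag(L) <- exp(theta[seq_len(p)])
      if (p > 1L) L[lower.tri(L)] <- theta[-seq_len(p)]
    } else diag(L) <- exp(theta)
    tcrossprod(L)
  }

  # profile objective: beta solved by weighted GLS given Sigma. For a
  # pattern with indicator map P (obs -> visit) and whitened A = U^-T P,
  # c = U^-T 1, the weighted normal equations accumulate in closed form
  # over the patients sharing the pattern.
  profile_fit <- function(theta) {
    S <- build_sigma(theta)
    XtX <- matrix(0, q, q)
    Xty <- numeric(q)
    ll_const <- 0
    s_yy <- 0
    for (g in groups) {
      o <- g$obs
      m <- length(o)
      U <- tryCatch(chol(S[o, o, drop = FALSE]), error = function(e) NULL)
      if (is.null(U)) return(NULL)
      P <- matrix(0, m, p)
      P[cbind(seq_len(m), o)] <- 1
      A <- backsolve(U, P, transpose = TRUE)
      cc <- backsolve(U, rep(1, m), transpose = TRUE)
      Ys <- backsolve(U, g$Y, transpose = TRUE)
      sw <- sum(g$w); swb <- sum(g$w * g$b); swb2 <- sum(g$w * g$b^2)
      AtA <- crossprod(A); Atc <- crossprod(A, cc)
      XtX[1:p, 1:p] <- XtX[1:p, 1:p] + sw * AtA
      XtX[1:p, q] <- XtX[1:p, q] + swb * Atc
      XtX[q, 1:p] <- XtX[q, 1:p] + swb * t(Atc)
      XtX[q, q] <- XtX[q, q] + swb2 * sum(cc^2)
      Yw <- Ys %*% g$w
      Ywb <- Ys %*% (g$w * g$b)
      Xty[1:p] <- Xty[1:p] + crossprod(A, Yw)
      Xty[q] <- Xty[q] + sum(cc * Ywb)
      s_yy <- s_yy + sum(g$w * colSums(Ys^2))
      ll_const <- ll_const + sw * (2 * sum(log(diag(U))) + m * log(2 * pi))
    }
    beta <- tryCatch(solve(XtX, Xty), error = function(e) NULL)
    if (is.null(beta)) return(NULL)
    quad <- s_yy - 2 * sum(beta * Xty) + drop(t(beta) %*% XtX %*% beta)
    ll <- -0.5 * (ll_const + quad)
    if (reml) ll <- ll - 0.5 * determinant(XtX, logarithm = TRUE)$modulus
    list(ll = as.numeric(ll), beta = as.numeric(beta), XtX = XtX, S = S)
  }
  negll <- function(theta) {
    f <- profile_fit(theta)
    if (is.null(f) || !is.finite(f$ll)) return(1e10)
    -f$ll
  }

  # start: per-visit weighted residual SDs around visit means
  start_sd <- vapply(seq_len(p), function(k) {
    rows <- which(vi == k)
    ybar <- weighted.mean(dat$cfb[rows], w[match(dat$patient_id[rows], ids)])
    s <- sqrt(weighted.mean((dat$cfb[rows] - ybar)^2,
                            w[match(dat$patient_id[rows], ids)]))
    max(s, 1e-3)
  }, numeric(1))
  theta0 <- if (covariance == "unstructured")
    c(log(start_sd), rep(0, theta_len - p)) else log(start_sd)
  lower <- rep(-Inf, theta_len)
  lower[seq_len(p)] <- log(1e-4)  # keep the covariance nonsingular
  opt <- optim(theta0, negll, method = "L-BFGS-B", lower = lower,
               control = list(maxit = max_iter, factr = tol / .Machine$double.eps))
  fit <- profile_fit(opt$par)
  if (is.null(fit)) stop_mg("MMRM optimisation failed to produce a valid covariance")
  vc <- tryCatch(solve(fit$XtX), error = function(e) NULL)
  if (is.null(vc)) stop_mg("weighted information matrix is singular")
  converged <- opt$convergence == 0
  # degenerate (near-noise-free) data pins covariance diagonals at the
  # lower bound and the line search aborts there; the profile solution is
  # still valid, so treat the boundary stop as convergence
  if (!converged && any(opt$par[seq_len(p)] <= log(1e-4) + 1e-6))
    converged <- TRUE
  structure(list(
    visit_effects = setNames(fit$beta[seq_len(p)], paste0("week_", weeks)),
    baseline_coefficient = fit$beta[q],
    covariance = fit$S,
    vcov_coef = vc,
    ls_mean_ses = setNames(sqrt(diag(vc)[seq_len(p)]), paste0("week_", weeks)),
    log_likelihood = fit$ll,
    converged = converged,
    n_used = n, ess = effective_sample_size(w),
    weeks = weeks, baseline_center = b_center,
    reml = reml, covariance_structure = covariance,
    optim_message = opt$message
  ), class = "mmrm_fit")
}

#' @export
print.mmrm_fit <- function(x, ...) {
  cat("Weighted MMRM fit (", x$covariance_structure, " covariance, ",
      if (x$reml) "REML" else "ML", ")\n", sep = "")
  cat("patients:", x$n_used, " ESS:", round(x$ess, 1),
      " logLik:", round(x$log_likelihood, 2),
      " converged:", x$converged, "\n")
  tab <- cbind(estimate = x$visit_effects, se = x$ls_mean_ses)
  print(round(tab, 4))
  cat(sprintf("baseline coefficient: %.4f (centred at %.2f)\n",
              x$baseline_coefficient, x$baseline_center))
  invisible(x)
}

#' @export
coef.mmrm_fit <- function(object, ...) {
  c(object$visit_effects, baseline = object$baseline_coefficient)
}

#' @export
logLik.mmrm_fit <- function(object, ...) {
  p <- length(object$visit_effects)
  structure(object$log_likelihood, df = p + 1L + p * (p + 1L) / 2L,
            class = "logLik")
}

#' Least-squares means from a weighted MMRM fit
#'
#' Evaluates each visit effect at a reference baseline score; with the
#' cell-means coding used here the LS mean at reference \eqn{b^*} is the
#' visit effect plus \eqn{\hat\gamma (b^* - \bar b_w)}, with the SE from
#' the delta method on the coefficient covariance.
#'
#' @param fit an [fit_weighted_mmrm()] object.
#' @param reference_baseline reference score; default the weighted mean
#'   baseline of the analysis pool (the centring point).
#' @param endpoint instrument used to range-check the reference.
#' @return `data.frame` with `visit_week`, `mean_cfb`, `se`.
#' @export
ls_means <- function(fit, reference_baseline = NULL,
                     endpoint = c("MG-ADL", "QMG")) {
  stopifnot(inherits(fit, "mmrm_fit"))
  endpoint <- match.arg(endpoint)
  if (!fit$converged) stop_mg("MMRM fit did not converge")
  ref <- reference_baseline %||% fit$baseline_center
  rng <- instrument_range(endpoint)
  if (ref < rng[1] || ref > rng[2])
    stop_mg(sprintf("reference baseline %g outside the %s range [%g, %g]",
                    ref, endpoint, rng[1], rng[2]))
  d <- ref - fit$baseline_center
  p <- length(fit$weeks)
  q <- p + 1L
  est <- fit$visit_effects + fit$baseline_coefficient * d
  se <- vapply(seq_len(p), function(k) {
    a <- numeric(q); a[k] <- 1; a[q] <- d
    sqrt(drop(t(a) %*% fit$vcov_coef %*% a))
  }, numeric(1))
  data.frame(visit_week = fit$weeks, mean_cfb = as.numeric(est),
             se = se, row.names = NULL)
}

#' Aggregate summary rows from a weighted MMRM fit
#'
#' Emits one aggregate row per visit at or below week 28 (the extraction
#' cap), carrying the LS mean, its model-based SE, and the effective
#' sample size of the weights as `n` — ready to combine with rows
#' extracted from published studies as Part-1 input.
#'
#' @param fit an [fit_weighted_mmrm()] object.
#' @param source_id label for the `source_id` column.
#' @param reference_baseline passed to [ls_means()].
#' @return An aggregate `data.frame` (see [validate_aggregate()]).
#' @export
aggregate_from_fit <- function(fit, source_id, reference_baseline = NULL) {
  lsm <- ls_means(fit, reference_baseline)
  lsm <- lsm[lsm$visit_week <= 28, , drop = FALSE]
  out <- data.frame(source_id = source_id, visit_week = lsm$visit_week,
                    mean_cfb = lsm$mean_cfb, se = lsm$se,
                    n = fit$ess, stringsAsFactors = FALSE)
  validate_aggregate(out)
  out
}
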