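#' @name ipd_io
#' @rdname ipd_io
#' @title Read and write individual patient data tables
#'
#' @description Long-format IPD tables are plain comma-separated UTF-8
#' files with a required header and `""` for absent values. The required
#' columns are `patient_id`, `arm`, `source`, `period`, `baseline_score`,
#' `visit_week`, `score`, `cfb`, `ice_type`, `ice_week`; extra columns
#' (e.g. `baseline_qmg`, `thymectomy_week`) round-trip unchanged.
#' Validation enforces the instrument range, label enumerations,
#' consistency of `cfb` with `score - baseline_score`, unique
#' `(patient_id, visit_week)` pairs and a single first intercurrent event
#' per patient.
#'
#' @param path file path.
#' @param ipd an IPD `data.frame`.
#' @param endpoint instrument whose range is enforced.
#' @return `read_ipd()` returns a validated IPD `data.frame` (with
#'   attribute `endpoint`); `write_ipd()` returns `path` invisibly.
NULL

ipd_required_cols <- c("patient_id", "arm", "source", "period",
                       "baseline_score", "visit_week", "score", "cfb",
                       "ice_type", "ice_week")

#' Validate an IPD table
#'
#' @inheritParams ipd_io
#' @return The table, invisibly, if valid; otherwise an error naming the
#'   offending column or rule.
#' @export
validate_ipd <- function(ipd, endpoint = c("MG-ADL", "QMG")) {
  endpoint <- match.arg(endpoint)
  missing_cols <- setdiff(ipd_required_cols, names(ipd))
  if (length(missing_cols) > 0L)
    stop_mg("IPD table is missing required column(s): ",
            paste(missing_cols, collapse = ", "))
  if (!all(ipd$arm %in% c("control", "treated")))
    stop_mg("'arm' must be 'control' or 'treated'")
  if (!all(ipd$period %in% c("double_blind", "open_label")))
    stop_mg("'period' must be 'double_blind' or 'open_label'")
  if (!all(ipd$ice_type %in% c("none", "rescue", "crisis", "death")))
    stop_mg("'ice_type' must be one of none/rescue/crisis/death")
  if (any(ipd$visit_week <= 0))
    stop_mg("'visit_week' must be > 0 (baseline is week 0 and is not a row)")
  rng <- instrument_range(endpoint)
  sc <- c(ipd$score, ipd$baseline_score)
  sc <- sc[!is.na(sc)]
  if (any(sc < rng[1] | sc > rng[2]))
    stop_mg(sprintf("scores outside the %s instrument range [%g, %g]",
                    endpoint, rng[1], rng[2]))
  obs <- !is.na(ipd$score) & !is.na(ipd$cfb)
  if (any(abs(ipd$cfb[obs] - (ipd$score[obs] - ipd$baseline_score[obs])) > 1e-8))
    stop_mg("'cfb' must equal score - baseline_score on observed rows")
  key <- paste(ipd$patient_id, ipd$visit_week)
  if (anyDuplicated(key))
    stop_mg("duplicated (patient_id, visit_week) rows")
  n_ice <- tapply(ipd$ice_week, ipd$patient_id,
                  function(w) length(unique(w[!is.na(w)])))
  if (any(n_ice > 1L))
    stop_mg("at most one first intercurrent event per patient")
  attr(ipd, "endpoint") <- endpoint
  invisible(ipd)
}

#' @rdname ipd_io
#' @export
read_ipd <- function(path, endpoint = c("MG-ADL", "QMG")) {
  endpoint <- match.arg(endpoint)
  x <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"),
                fileEncoding = "UTF-8")
  if ("ice_type" %in% names(x)) x$ice_type[is.na(x$ice_type)] <- "none"
  # all-empty numeric columns come back logical; restore their type
  for (col in intersect(c("baseline_score", "visit_week", "score", "cfb",
                          "ice_week", "thymectomy_week", "baseline_qmg"),
                        names(x)))
    x[[col]] <- as.numeric(x[[col]])
  validate_ipd(x, endpoint)
  attr(x, "endpoint") <- endpoint
  x
}

#' @rdname ipd_io
#' @export
write_ipd <- function(ipd, path, endpoint = attr(ipd, "endpoint") %||% "MG-ADL") {
  validate_ipd(ipd, endpoint)
  write.csv(ipd, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

aggregate_required_cols <- c("source_id", "visit_week", "mean_cfb", "se", "n")

#' Validate an aggregate summary table
#'
#' Per-source, per-visit mean change from baseline with standard error
#' and sample size, the Part-1 input. Standard errors must be positive
#' and visits must lie in (0, 28] weeks (the extraction window).
#'
#' @param agg aggregate `data.frame` with columns `source_id`,
#'   `visit_week`, `mean_cfb`, `se`, `n`.
#' @return The table, invisibly, if valid.
#' @export
validate_aggregate <- function(agg) {
  missing_cols <- setdiff(aggregate_required_cols, names(agg))
  if (length(missing_cols) > 0L)
    stop_mg("aggregate table is missing required column(s): ",
            paste(missing_cols, collapse = ", "))
  if (any(!is.finite(agg$se)) || any(agg$se <= 0))
    stop_mg("'se' must be finite and > 0")
  if (any(agg$visit_week <= 0 | agg$visit_week > 28))
    stop_mg("'visit_week' must lie in (0, 28]")
  invisible(agg)
}

#' @rdname validate_aggregate
#' @param path file path.
#' @export
read_aggregate <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                fileEncoding = "UTF-8")
  validate_aggregate(x)
  x
}

#' @rdname validate_aggregate
#' @export
write_aggregate <- function(agg, path) {
  validate_aggregate(agg)
  write.csv(agg, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}
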