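#' Exclusion reasons in reporting order
#'
#' The funnel order of the study's selection table: CT-DXA interval beyond
#' the window first, then no measurable T12-S1 axial cut, compression/burst
#' fracture, vertebroplasty/kyphoplasty, metal artifact, and osteolytic or
#' pathological change. Cases matching several reasons are attributed to the
#' first matching one.
#'
#' @return Character vector of the six reason labels.
#' @export
exclusion_reasons <- function() {
  c("interval_over_max", exclusion_flag_names)
}

#' Apply the study's selection and exclusion criteria
#'
#' A case is included exactly when its CT-DXA interval is at most
#' `max_interval_days` ("less than one month" implemented as <= 31 days,
#' configurable) and all five exclusion flags are false. Cases whose interval
#' cannot be computed (missing or unparseable dates) are routed to an
#' `unevaluable` bucket, never silently dropped.
#'
#' @param cases data.frame with columns `case_id`, either `interval_days` or
#'   both `ct_date` and `dxa_date`, and logical columns `flag_no_axial_cut`,
#'   `flag_fracture`, `flag_vertebro_kypho`, `flag_metal_artifact`,
#'   `flag_osteolytic`.
#' @param max_interval_days maximum allowed |DXA date - CT date| in days.
#' @return list with `included`, `excluded` (with a `reason` column) and
#'   `unevaluable` data.frames, plus `report`, a named integer vector of
#'   counts per reason in [exclusion_reasons()] order.
#' @export
filter_cohort <- function(cases, max_interval_days = 31) {
  stopifnot(is.data.frame(cases), "case_id" %in% names(cases))
  flag_cols <- paste0("flag_", exclusion_flag_names)
  missing_cols <- setdiff(flag_cols, names(cases))
  if (length(missing_cols) > 0) {
    stop(sprintf("missing exclusion flag columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if ("interval_days" %in% names(cases)) {
    interval <- suppressWarnings(abs(as.numeric(cases$interval_days)))
  } else if (all(c("ct_date", "dxa_date") %in% names(cases))) {
    ctd <- as.Date(cases$ct_date)
    dxd <- as.Date(cases$dxa_date)
    interval <- abs(as.numeric(dxd - ctd))
  } else {
    stop("cases need either `interval_days` or both `ct_date` and `dxa_date`",
         call. = FALSE)
  }
  unevaluable_idx <- is.na(interval)

  reasons <- exclusion_reasons()
  reason <- rep(NA_character_, nrow(cases))
  reason[!unevaluable_idx & interval > max_interval_days] <- reasons[1]
  for (k in seq_along(exclusion_flag_names)) {
    fl <- cases[[flag_cols[k]]]
    hit <- !unevaluable_idx & is.na(reason) & !is.na(fl) & fl
    reason[hit] <- reasons[k + 1L]
  }
  included_idx <- !unevaluable_idx & is.na(reason)

  excluded <- cases[!unevaluable_idx & !is.na(reason), , drop = FALSE]
  excluded$reason <- reason[!unevaluable_idx & !is.na(reason)]
  report <- vapply(reasons, function(r) sum(excluded$reason == r), integer(1))
  list(
    included = cases[included_idx, , drop = FALSE],
    excluded = excluded,
    unevaluable = cases[unevaluable_idx, , drop = FALSE],
    report = report
  )
}

#' Write an exclusion report as JSON
#'
#' @param filtered a [filter_cohort()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_exclusion_report <- function(filtered, path) {
  write_json_file(
    list(n_input = nrow(filtered$included) + nrow(filtered$excluded) +
           nrow(filtered$unevaluable),
         n_included = nrow(filtered$included),
         n_unevaluable = nrow(filtered$unevaluable),
         excluded_by_reason = as.list(filtered$report)),
    path
  )
}
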