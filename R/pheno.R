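# Binary response/remission phenotypes from longitudinal symptom scores:
# LOCF endpoint, >= 50 % reduction response, absolute remission cut-offs,
# and cohort eligibility rules.

remission_cutoff <- function(instrument) {
  switch(instrument, HRSD17 = 7, QIDS = 5,
         stopf("unknown instrument '%s'", instrument))
}

#' Last-observation-carried-forward endpoint of one score series
#'
#' @param weeks,scores Parallel vectors of assessment weeks (week 0 =
#'   baseline) and scores; missing visits may be absent or `NA`.
#' @param endpoint_week Scores after this week are ignored.
#' @return List with `baseline`, `endpoint` (last non-missing post-baseline
#'   score at or before `endpoint_week`), `eligible` and
#'   `reason_ineligible` (`NA` when eligible). A subject without a baseline
#'   or without any post-baseline observation is flagged ineligible, not
#'   errored.
#' @export
#' @examples
#' locf_endpoint(c(0, 2, 4), c(20, 12, NA), endpoint_week = 6)
locf_endpoint <- function(weeks, scores, endpoint_week) {
  ok <- !is.na(scores)
  baseline <- scores[ok & weeks == 0][1]
  if (is.na(baseline)) {
    return(list(baseline = NA_real_, endpoint = NA_real_, eligible = FALSE,
                reason_ineligible = "missing baseline"))
  }
  post <- ok & weeks > 0 & weeks <= endpoint_week
  if (!any(post)) {
    return(list(baseline = baseline, endpoint = NA_real_, eligible = FALSE,
                reason_ineligible = "no post-baseline observation"))
  }
  list(baseline = baseline,
       endpoint = scores[post][which.max(weeks[post])],
       eligible = TRUE, reason_ineligible = NA_character_)
}

#' Response call: at least 50 percent symptom reduction
#' @param baseline,endpoint Baseline and (LOCF) endpoint scores.
#' @return Logical; `TRUE` iff `(baseline - endpoint) / baseline >= 0.5`.
#' @export
call_response <- function(baseline, endpoint) {
  if (any(baseline == 0, na.rm = TRUE)) {
    stopf("baseline 0: percent reduction undefined")
  }
  (baseline - endpoint) / baseline >= 0.5
}

#' Remission call: endpoint at or below the instrument cut-off
#' @param endpoint LOCF endpoint score.
#' @param instrument `"HRSD17"` (cut-off 7) or `"QIDS"` (cut-off 5).
#' @return Logical.
#' @export
call_remission <- function(endpoint, instrument) {
  endpoint <= remission_cutoff(instrument)
}

#' Derive phenotypes for a cohort's score table
#'
#' Applies the LOCF rule per subject, the response and remission
#' definitions, and the cohort eligibility rules: both cohorts require
#' LOCF eligibility (baseline plus at least one post-baseline observation);
#' the replication cohort additionally requires a baseline QIDS score of at
#' least `min_baseline` (entry-severity criterion; no such threshold is
#' applied in the discovery cohort).
#'
#' @param scores Long tibble with `subject_id`, `week`, `score`.
#' @param instrument `"HRSD17"` or `"QIDS"`.
#' @param endpoint_week Cohort endpoint (6 for discovery, 12 for
#'   replication).
#' @param min_baseline Minimum baseline score, or `NULL` for none.
#' @return Tibble with one row per subject: `subject_id`, `baseline`,
#'   `endpoint`, `eligible`, `reason_ineligible`, `response`, `remission`
#'   (calls are `NA` for ineligible subjects).
#' @export
derive_phenotypes <- function(scores, instrument, endpoint_week,
                              min_baseline = NULL) {
  stopifnot(all(c("subject_id", "week", "score") %in% names(scores)))
  out <- scores |>
    group_by(.data$subject_id) |>
    summarise(res = list(locf_endpoint(.data$week, .data$score,
                                       endpoint_week)),
              .groups = "drop") |>
    mutate(
      baseline = purrr::map_dbl(.data$res, "baseline"),
      endpoint = purrr::map_dbl(.data$res, "endpoint"),
      eligible = purrr::map_lgl(.data$res, "eligible"),
      reason_ineligible = purrr::map_chr(.data$res, "reason_ineligible")
    ) |>
    select(-"res")
  if (!is.null(min_baseline)) {
    low <- !is.na(out$baseline) & out$baseline < min_baseline
    out$eligible[low] <- FALSE
    out$reason_ineligible[low] <- sprintf("baseline below %s", min_baseline)
  }
  resp <- rep(NA, nrow(out))
  ok <- out$eligible & !is.na(out$baseline) & out$baseline > 0
  resp[ok] <- call_response(out$baseline[ok], out$endpoint[ok])
  out$response <- resp
  rem <- rep(NA, nrow(out))
  rem[out$eligible] <- call_remission(out$endpoint[out$eligible], instrument)
  out$remission <- rem
  out
}
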