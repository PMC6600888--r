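#' Past-year drinker status from the gate questions
#'
#' A "preparatory" question asks about any alcohol in the past 12 months; if
#' the answer is no, a "check" question asks about drinking at special events
#' (sporting carnivals, weddings, funerals). A yes to either classifies the
#' person as a past-year drinker; non-drinkers are excluded from all
#' downstream analyses.
#'
#' @param prep_drank Logical answer to the preparatory question.
#' @param check_drank Logical answer to the check question; may be `NA` when
#'   `prep_drank` is `TRUE` (the check is then not asked).
#' @return `"drinker"` or `"non_drinker"`.
#' @export
drinker_status <- function(prep_drank, check_drank = NA) {
  if (is.na(prep_drank)) {
    stop_invalid("prep_drank", "must be answered")
  }
  if (isTRUE(prep_drank)) {
    return("drinker")
  }
  if (is.na(check_drank)) {
    stop_invalid("check_drank", "must be answered when prep_drank is no")
  }
  if (isTRUE(check_drank)) "drinker" else "non_drinker"
}

#' Dependence stratum from the three ICD-11 screening items
#'
#' Participants rating all three dependence experiences as never occurring
#' in the past year are classed non-dependent; any non-`never` rating at any
#' frequency classes them dependent. Used only as a sampling stratum - it
#' never enters risk computation.
#'
#' @param ratings Character vector of three frequency category tokens.
#' @return `"dependent"` or `"non_dependent"`.
#' @export
dependence_status <- function(ratings) {
  if (length(ratings) != 3 || anyNA(ratings)) {
    stop_invalid("ratings", "three dependence-item ratings are required")
  }
  for (r in ratings) check_category(r, "dependence rating")
  if (any(ratings != "never")) "dependent" else "non_dependent"
}

#' NHMRC guideline risk from Finnish-method consumption
#'
#' 2009 Australian NHMRC guidelines as applied here: long-term risk when
#' average consumption strictly exceeds 2 standard drinks per day
#' (guideline 1); short-term risk when strictly more than 4 standard drinks
#' were consumed on any single recorded drinking day (guideline 2). Exactly
#' 2.0/day or exactly 4.0 drinks is not at risk. The "any single day"
#' maximum is evaluated over the recorded (at most four) occasions, the only
#' per-occasion data the method collects.
#'
#' @param avg_drinks_per_day Average standard drinks per day.
#' @param max_single_occasion Largest recorded single-occasion quantity.
#' @return A risk-status list (`method = "finnish"`).
#' @export
nhmrc_risk <- function(avg_drinks_per_day, max_single_occasion) {
  if (any(!is.finite(c(avg_drinks_per_day, max_single_occasion))) ||
      avg_drinks_per_day < 0 || max_single_occasion < 0) {
    stop_invalid("consumption summary",
                 "finite non-negative estimates required (non-drinkers are excluded upstream)")
  }
  risk_status("finnish",
              short_term = max_single_occasion > 4,
              long_term = avg_drinks_per_day > 2)
}
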