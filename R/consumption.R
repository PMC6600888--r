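#' Grams of ethanol in a beverage entry
#'
#' Converts a container-based drinking record into grams of pure ethanol:
#' the poured volume (`volume_ml * fullness`) times the alcohol-by-volume
#' fraction, the participant's share of the pour, the number of containers,
#' and the density of ethanol (0.789 g/mL). All arguments are vectorised
#' and the result is linear in each factor.
#'
#' @param volume_ml Container volume in millilitres (> 0).
#' @param abv Alcohol by volume as a fraction in (0, 1).
#' @param fullness Fraction of the container that held drink, in \[0, 1\].
#' @param share Fraction of the poured amount the participant drank.
#' @param count Number of such containers (may be fractional).
#' @return Grams of ethanol consumed.
#' @examples
#' ethanol_grams(375, 0.048) # a full-strength 375 mL can: 14.2 g
#' @export
ethanol_grams <- function(volume_ml, abv, fullness = 1, share = 1, count = 1) {
  if (any(!is.finite(volume_ml)) || any(volume_ml <= 0)) {
    stop_invalid("volume_ml", "must be a positive volume in mL")
  }
  check_fraction(abv, "abv")
  check_fraction(fullness, "fullness")
  check_fraction(share, "share")
  if (any(!is.finite(count)) || any(count < 0)) {
    stop_invalid("count", "must be >= 0")
  }
  volume_ml * abv * fullness * share * count * ETHANOL_DENSITY
}

#' Convert grams of ethanol to Australian standard drinks
#'
#' One Australian standard drink contains 10 g of pure ethanol.
#'
#' @param grams Grams of ethanol (>= 0); vectorised.
#' @return Number of standard drinks.
#' @export
standard_drinks <- function(grams) {
  if (any(!is.finite(grams)) || any(grams < 0)) {
    stop_invalid("grams", "must be >= 0")
  }
  grams / GRAMS_PER_STANDARD_DRINK
}

#' Construct a drinking occasion
#'
#' An occasion is one drinking day, located `days_before_survey` days before
#' the interview. Quantity is carried either as a pre-computed standard-drink
#' total (the "drinks" dialect) or as a list of beverage entries (the
#' "beverage" dialect); exactly one of the two must be supplied.
#'
#' @param days_before_survey Non-negative integer day offset.
#' @param standard_drinks Standard-drink total for the day, or `NULL`.
#' @param entries Data frame of beverage entries with columns `product_id`,
#'   `container_volume_ml`, `fullness`, `count`, `share`, or `NULL`.
#' @return An object of class `drinking_occasion`.
#' @export
occasion <- function(days_before_survey, standard_drinks = NULL, entries = NULL) {
  if (!is.finite(days_before_survey) || days_before_survey < 0) {
    stop_invalid("days_before_survey", "must be a non-negative number of days")
  }
  if (is.null(standard_drinks) == is.null(entries)) {
    stop_invalid("occasion", "exactly one of `standard_drinks`, `entries` must be given")
  }
  if (!is.null(standard_drinks) &&
      (!is.finite(standard_drinks) || standard_drinks < 0)) {
    stop_invalid("standard_drinks", "must be >= 0")
  }
  structure(
    list(days_before_survey = days_before_survey,
         standard_drinks = standard_drinks,
         entries = entries),
    class = "drinking_occasion"
  )
}

#' Standard drinks consumed on one occasion
#'
#' Drinks-dialect occasions pass their total through unchanged; beverage
#' entries are converted through [ethanol_grams()] and [standard_drinks()]
#' using the ABV looked up in the product catalog.
#'
#' @param occ A [occasion()] object.
#' @param catalog Product catalog data frame with columns `product_id` and
#'   `abv` (fraction), as returned by [read_products()]. Only needed for
#'   beverage-dialect occasions.
#' @return Standard drinks for the occasion (>= 0).
#' @export
occasion_total_drinks <- function(occ, catalog = NULL) {
  stopifnot(inherits(occ, "drinking_occasion"))
  if (!is.null(occ$standard_drinks)) {
    return(occ$standard_drinks)
  }
  e <- occ$entries
  if (is.null(e) || nrow(e) == 0) {
    return(0)
  }
  if (is.null(catalog)) {
    stop_invalid("catalog", "required for beverage-dialect occasions")
  }
  idx <- match(e$product_id, catalog$product_id)
  if (anyNA(idx)) {
    missing <- unique(e$product_id[is.na(idx)])
    stop(sprintf("unknown product_id in catalog: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  grams <- ethanol_grams(e$container_volume_ml, catalog$abv[idx],
                         e$fullness, e$share, e$count)
  sum(standard_drinks(grams))
}
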