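#' Parameters for the synthetic survey cohort
#'
#' The generator emulates the statistical structure the screening analyses
#' assume: a stratified sample of non-drinkers, non-dependent and dependent
#' drinkers; intermittent occasion timing (exponential renewal per person);
#' heavy, right-skewed per-occasion quantities; and ordinal self-report with
#' optional adjacent-category misreporting.
#'
#' Defaults reflect the study conditions being emulated: a 200-person
#' stratified sample (20% non-drinkers; half of drinkers in the dependent
#' stratum), drinker frequency classes distributed 30.4 / 42.4 / 26.1 / 1.1
#' percent from rare through most-days drinking, and a median of 17
#' standard drinks per drinking occasion. Per-occasion quantity is
#' log-normal with a between-person spread (`sigma_between`, the spread of
#' usual quantity across drinkers) and a smaller within-person spread
#' (`sigma_within`, occasion-to-occasion variation). A small minority of
#' drinkers (`prop_light`) are genuinely light drinkers whose usual
#' quantity centres on `light_quantity_median` instead - without them no
#' single log-normal reproduces both the dominant 10+-drinks usual-quantity
#' category and the minority who never exceed 4 drinks. The defaults are
#' calibrated so the derived usual-quantity (AUDIT-2m) distribution matches
#' the emulated category margins.
#'
#' @param n_participants Cohort size.
#' @param prop_non_drinker Proportion of past-year non-drinkers.
#' @param prop_dependent Proportion of drinkers in the dependent stratum.
#' @param freq_class_probs Probabilities over the four drinker frequency
#'   classes (`lt_monthly`, `monthly_1_3`, `weekly_1_3`, `most_days`).
#' @param quantity_median Median standard drinks per drinking occasion
#'   among regular (heavy-pattern) drinkers.
#' @param sigma_between Between-person SD of log usual quantity.
#' @param sigma_within Within-person SD of log occasion quantity.
#' @param prop_light Proportion of drinkers in the light-drinking subgroup.
#' @param light_quantity_median Median standard drinks per occasion in the
#'   light subgroup.
#' @param noise_prob Probability a reported frequency category is perturbed
#'   to an adjacent level.
#' @param copy_prob Probability a drinker reports the most recent occasion's
#'   quantity for every earlier occasion (the App offered this shortcut).
#' @param bursty If `TRUE`, modulate the occasion process with a two-state
#'   on/off cycle (heavier clustering of occasions); off by default so the
#'   base process stays analysable.
#' @param window_days Past-year recall window in days.
#' @param seed Integer seed fixing all randomness of [generate_cohort()].
#' @return A validated list of class `cohort_params`.
#' @export
cohort_params <- function(n_participants = 200,
                          prop_non_drinker = 0.20,
                          prop_dependent = 0.50,
                          freq_class_probs = c(lt_monthly = 0.304,
                                               monthly_1_3 = 0.424,
                                               weekly_1_3 = 0.261,
                                               most_days = 0.011),
                          quantity_median = 17,
                          sigma_between = 0.62,
                          sigma_within = 0.30,
                          prop_light = 0.07,
                          light_quantity_median = 2.5,
                          noise_prob = 0,
                          copy_prob = 0,
                          bursty = FALSE,
                          window_days = SURVEY_WINDOW_DAYS,
                          seed = 1L) {
  if (n_participants < 1) stop_invalid("n_participants", "must be >= 1")
  check_fraction(prop_non_drinker, "prop_non_drinker")
  check_fraction(prop_dependent, "prop_dependent")
  if (length(freq_class_probs) != 4 ||
      !all(names(freq_class_probs) == FREQUENCY_CATEGORIES[2:5])) {
    stop_invalid("freq_class_probs",
                 "must be named lt_monthly, monthly_1_3, weekly_1_3, most_days")
  }
  if (abs(sum(freq_class_probs) - 1) > 1e-8) {
    stop_invalid("freq_class_probs", "must sum to 1")
  }
  if (quantity_median <= 0) stop_invalid("quantity_median", "must be > 0")
  if (light_quantity_median <= 0) {
    stop_invalid("light_quantity_median", "must be > 0")
  }
  check_fraction(prop_light, "prop_light")
  if (sigma_between < 0 || sigma_within < 0) {
    stop_invalid("sigma", "must be >= 0")
  }
  check_fraction(noise_prob, "noise_prob")
  check_fraction(copy_prob, "copy_prob")
  structure(as.list(environment()), class = "cohort_params")
}

# Latent-rate intervals (occasions/day) for each drinker frequency class.
# Cuts at once per month, once per week and 3.5 times per week; rare
# drinkers drank at least once in the window.
rate_bounds <- function(window_days = SURVEY_WINDOW_DAYS) {
  list(
    lt_monthly  = c(1 / window_days, 1 / DAYS_PER_MONTH),
    monthly_1_3 = c(1 / DAYS_PER_MONTH, 1 / 7),
    weekly_1_3  = c(1 / 7, 3.5 / 7),
    most_days   = c(3.5 / 7, 1)
  )
}

bin_rate <- function(rate_per_day) {
  if (rate_per_day >= 3.5 / 7) "most_days"
  else if (rate_per_day >= 1 / 7) "weekly_1_3"
  else if (rate_per_day >= 1 / DAYS_PER_MONTH) "monthly_1_3"
  else "lt_monthly"
}

#' Generate the drinking-occasion history for one drinker
#'
#' Occasions follow an exponential renewal process at `latent_rate`
#' (occasions/day) accumulated backwards from a stationary first offset,
#' which is truncated into the recall window (a past-year drinker has, by
#' definition, at least one in-window occasion). The whole in-window
#' history is returned; when fewer than four occasions fall inside the
#' window, generation continues past it (up to a ten-window lookback) so
#' that the four most recent occasions exist whenever the process yields
#' them. Quantities are i.i.d. log-normal around the person's usual
#' quantity. The survey itself records only the four most recent occasions
#' - [generate_cohort()] truncates accordingly.
#'
#' @param latent_rate Occasions per day (> 0).
#' @param mu_q Person-level mean of log quantity.
#' @param sigma_within Within-person SD of log quantity.
#' @param window_days Recall window in days.
#' @param copy_quantity If `TRUE`, earlier occasions copy the most recent
#'   occasion's quantity.
#' @param bursty If `TRUE`, each gap is drawn at triple or one-third the
#'   base rate with equal probability (a crude on/off burstiness).
#' @return Data frame with `occasion_rank` (1 = most recent),
#'   `days_before_survey`, `standard_drinks`.
#' @export
generate_occasions <- function(latent_rate, mu_q, sigma_within,
                               window_days = SURVEY_WINDOW_DAYS,
                               copy_quantity = FALSE, bursty = FALSE) {
  if (latent_rate <= 0) stop_invalid("latent_rate", "must be > 0")
  draw_gaps <- function(m) {
    r <- rep(latent_rate, m)
    if (bursty) r <- r * sample(c(3, 1 / 3), m, replace = TRUE)
    stats::rexp(m, r)
  }
  # stationary age of the most recent occasion, truncated into the window
  off1 <- stats::runif(1) * draw_gaps(1)
  tries <- 0
  while (off1 > window_days && tries < 50) {
    off1 <- stats::runif(1) * draw_gaps(1)
    tries <- tries + 1
  }
  if (off1 > window_days) off1 <- stats::runif(1, 0, window_days)
  cap <- 10 * window_days
  days <- off1
  repeat {
    last <- days[length(days)]
    if ((last > window_days && length(days) >= 4) || last > cap) break
    chunk <- max(8, ceiling(latent_rate * (window_days - last)))
    days <- c(days, last + cumsum(draw_gaps(chunk)))
  }
  days <- days[days <= cap]
  keep <- days <= window_days
  if (sum(keep) < 4) keep[seq_len(min(4, length(days)))] <- TRUE
  days <- days[keep]
  n <- length(days)
  q <- stats::rlnorm(n, meanlog = mu_q, sdlog = sigma_within)
  if (copy_quantity && n > 1) q[2:n] <- q[1]
  data.frame(
    occasion_rank = seq_len(n),
    days_before_survey = days,
    standard_drinks = q
  )
}

#' True-then-noisy questionnaire categories for a drinker
#'
#' The true AUDIT-1m category bins the latent occasion rate at once per
#' month, once per week and 3.5 times per week. The true AUDIT-3mV category
#' is `never` when no recorded in-window occasion exceeded 4 standard
#' drinks; otherwise it bins the latent rate of heavy (> 4 drink) occasions,
#' `latent_rate * P(quantity > 4)`, at the same cuts with `lt_monthly` as
#' the floor. Each reported category is then perturbed to an adjacent level
#' with probability `noise_prob` (AUDIT-1m never reports `never`, which the
#' questionnaire does not offer drinkers).
#'
#' @inheritParams generate_occasions
#' @param occasions Occasion data frame from [generate_occasions()].
#' @param noise_prob Adjacent-category perturbation probability.
#' @return List with `audit1m` and `audit3mv` category tokens.
#' @export
report_categories <- function(latent_rate, occasions, mu_q, sigma_within,
                              noise_prob = 0,
                              window_days = SURVEY_WINDOW_DAYS) {
  perturb <- function(cat, floor_cat) {
    if (noise_prob == 0 || stats::runif(1) >= noise_prob) return(cat)
    i <- match(cat, FREQUENCY_CATEGORIES)
    lo <- match(floor_cat, FREQUENCY_CATEGORIES)
    # single-step kernel; at a boundary the only legal step is taken, so a
    # perturbed report always differs from truth by exactly one level
    candidates <- intersect(c(i - 1L, i + 1L),
                            seq(lo, length(FREQUENCY_CATEGORIES)))
    j <- if (length(candidates) == 1) candidates else sample(candidates, 1)
    FREQUENCY_CATEGORIES[j]
  }
  a1 <- bin_rate(latent_rate)
  in_window <- occasions$days_before_survey <= window_days
  any_heavy <- any(occasions$standard_drinks[in_window] > 4)
  a3 <- if (!any_heavy) {
    "never"
  } else {
    p_heavy <- 1 - stats::plnorm(4, meanlog = mu_q, sdlog = sigma_within)
    cat5 <- bin_rate(latent_rate * p_heavy)
    if (cat5 == "never") "lt_monthly" else cat5
  }
  list(
    audit1m = perturb(a1, "lt_monthly"),
    audit3mv = if (a3 == "never") "never" else perturb(a3, "lt_monthly")
  )
}

sample_dependence_ratings <- function(dependent) {
  if (!dependent) {
    return(rep("never", 3))
  }
  # at least one symptom endorsed; first item forced non-never
  first <- sample(FREQUENCY_CATEGORIES[2:5], 1,
                  prob = c(0.4, 0.3, 0.2, 0.1))
  rest <- sample(FREQUENCY_CATEGORIES, 2, replace = TRUE,
                 prob = c(0.3, 0.3, 0.2, 0.15, 0.05))
  c(first, rest)
}

#' Generate a synthetic survey cohort
#'
#' @param params A [cohort_params()] object; `params$seed` fixes all
#'   randomness, so the same parameters always regenerate the identical
#'   cohort.
#' @return List of participant records. Each record has `person_id`, `sex`,
#'   `prep_drank`, `check_drank`, `dependence_ratings`, and for drinkers the
#'   latent `rate_per_day`, `mu_q`, `freq_class`, an `occasions` data frame
#'   and reported `audit1m` / `audit3mv` categories.
#' @export
generate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(params$seed)
  bounds <- rate_bounds(params$window_days)
  lapply(seq_len(params$n_participants), function(i) {
    sex <- sample(c("female", "male"), 1)
    is_drinker <- stats::runif(1) >= params$prop_non_drinker
    if (!is_drinker) {
      return(list(
        person_id = sprintf("p%04d", i), sex = sex,
        prep_drank = FALSE, check_drank = FALSE,
        dependence_ratings = rep("never", 3),
        occasions = NULL
      ))
    }
    dependent <- stats::runif(1) < params$prop_dependent
    freq_class <- sample(names(params$freq_class_probs), 1,
                         prob = params$freq_class_probs)
    b <- bounds[[freq_class]]
    rate <- stats::runif(1, b[1], b[2])
    med <- if (stats::runif(1) < params$prop_light) {
      params$light_quantity_median
    } else {
      params$quantity_median
    }
    mu_q <- stats::rnorm(1, log(med), params$sigma_between)
    occ <- generate_occasions(rate, mu_q, params$sigma_within,
                              params$window_days,
                              copy_quantity = stats::runif(1) < params$copy_prob,
                              bursty = params$bursty)
    occ <- occ[seq_len(min(4L, nrow(occ))), , drop = FALSE]  # survey records the last four
    rep_cat <- report_categories(rate, occ, mu_q, params$sigma_within,
                                 params$noise_prob, params$window_days)
    # the gate: a minority of intermittent drinkers initially say no and are
    # caught by the special-events check question
    prep <- stats::runif(1) >= ifelse(freq_class == "lt_monthly", 0.3, 0.02)
    list(
      person_id = sprintf("p%04d", i), sex = sex,
      prep_drank = prep, check_drank = if (prep) NA else TRUE,
      dependence_ratings = sample_dependence_ratings(dependent),
      rate_per_day = rate, mu_q = mu_q, freq_class = freq_class,
      occasions = occ,
      audit1m = rep_cat$audit1m, audit3mv = rep_cat$audit3mv
    )
  })
}

#' Compose a list of beverage entries realising a target standard-drink total
#'
#' Inverse of the beverage-to-drinks conversion, used for round-trip testing
#' and to express generated occasions in the beverage dialect: fills whole
#' containers of the first catalog product greedily, then one
#' partial-fullness container for the remainder, so that
#' [occasion_total_drinks()] recovers the target exactly (to 1e-9).
#'
#' @param target_drinks Standard drinks (>= 0).
#' @param catalog Product catalog data frame (`product_id`, `abv` fraction,
#'   `container_volume_ml` optional; 375 mL assumed when absent).
#' @return Data frame of beverage entries (zero rows when the target is 0).
#' @export
compose_beverages <- function(target_drinks, catalog) {
  if (is.null(catalog) || nrow(catalog) == 0) {
    stop_invalid("catalog", "must contain at least one product")
  }
  if (!is.finite(target_drinks) || target_drinks < 0) {
    stop_invalid("target_drinks", "must be >= 0")
  }
  empty <- data.frame(product_id = character(), container_volume_ml = numeric(),
                      fullness = numeric(), count = numeric(), share = numeric())
  if (target_drinks == 0) {
    return(empty)
  }
  p <- catalog[1, ]
  vol <- if ("container_volume_ml" %in% names(catalog)) p$container_volume_ml else 375
  per_container <- standard_drinks(ethanol_grams(vol, p$abv))
  n_full <- floor(target_drinks / per_container)
  frac <- (target_drinks - n_full * per_container) / per_container
  rows <- empty
  if (n_full > 0) {
    rows <- rbind(rows, data.frame(product_id = p$product_id,
                                   container_volume_ml = vol, fullness = 1,
                                   count = n_full, share = 1))
  }
  if (frac > 1e-12) {
    rows <- rbind(rows, data.frame(product_id = p$product_id,
                                   container_volume_ml = vol, fullness = frac,
                                   count = 1, share = 1))
  }
  rows
}
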