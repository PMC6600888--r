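#' Pipeline configuration
#'
#' Collects every tunable analysis constant in one validated object:
#' the frequency-category midpoints (occasions/day), the confidence-interval
#' method and level, the frequency condition for AUDIT-1m+2m short-term risk
#' (`"past_year"` or `"monthly"`), the variable correlated in the retention
#' grid, the sex-specific AUDIT-Cm thresholds, and the recall window.
#'
#' @param midpoints Named frequency-midpoint table (occasions/day).
#' @param ci_method Confidence-interval family; only `"clopper_pearson"`
#'   (exact) is implemented.
#' @param ci_level Confidence level.
#' @param short_term_min_frequency Frequency condition for AUDIT-1m+2m
#'   short-term risk.
#' @param retention_variable Variable correlated in the retention grid.
#' @param auditcm_thresholds Named at-risk cut-offs for the AUDIT-Cm total.
#' @param window_days Past-year recall window in days.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(midpoints = DEFAULT_FREQUENCY_MIDPOINTS,
                            ci_method = "clopper_pearson",
                            ci_level = 0.95,
                            short_term_min_frequency = c("past_year", "monthly"),
                            retention_variable = c("avg_drinks_per_day",
                                                   "drinks_per_occasion"),
                            auditcm_thresholds = c(female = 3, male = 4),
                            window_days = SURVEY_WINDOW_DAYS) {
  if (!identical(sort(names(midpoints)), sort(FREQUENCY_CATEGORIES))) {
    stop_invalid("midpoints", "must name all five frequency categories")
  }
  ci_method <- match.arg(ci_method)
  if (ci_level <= 0 || ci_level >= 1) stop_invalid("ci_level", "must be in (0,1)")
  structure(list(
    days_per_month = DAYS_PER_MONTH,
    midpoints = midpoints,
    ci_method = ci_method,
    ci_level = ci_level,
    short_term_min_frequency = match.arg(short_term_min_frequency),
    retention_variable = match.arg(retention_variable),
    auditcm_thresholds = auditcm_thresholds,
    window_days = window_days
  ), class = "pipeline_config")
}

yesno <- function(x) {
  ifelse(is.na(x) | x == "", NA, x == "yes")
}

#' Score one drinker's record
#'
#' Runs the full per-person analysis: Finnish-method consumption summary,
#' the three AUDIT-Cm item scores (AUDIT-2m derived from the usual-quantity
#' estimate), the sex-thresholded AUDIT-Cm total, and the risk flags under
#' each method.
#'
#' @param sex `"female"` or `"male"`.
#' @param audit1m,audit3mv Reported frequency category tokens.
#' @param days,quantities Occasion timing and standard-drink quantities,
#'   most recent first.
#' @param config A [pipeline_config()].
#' @return One-row data frame of estimates, scores and risk flags, or `NULL`
#'   when no occasion falls inside the recall window.
#' @export
score_participant <- function(sex, audit1m, audit3mv, days, quantities,
                              config = pipeline_config()) {
  cs <- consumption_summary(days, quantities, 4L, 4L, config$window_days)
  if (is.null(cs)) {
    return(NULL)
  }
  a1 <- score_audit1m(audit1m)
  a2 <- derive_audit2m(cs$drinks_per_occasion)
  a3 <- score_audit3mv(audit3mv)
  tot <- total_audit_cm(a1, a2, a3, sex, config$auditcm_thresholds)
  fin <- nhmrc_risk(cs$avg_drinks_per_day, cs$max_single_occasion)
  a12 <- audit12_risk(audit1m, a2, is_past_year_drinker = TRUE,
                      short_term_min_frequency = config$short_term_min_frequency,
                      midpoints = config$midpoints)
  a3r <- audit3_risk(audit3mv, midpoints = config$midpoints)
  cbind(
    data.frame(sex = sex),
    cs,
    data.frame(
      audit1m_score = a1, audit2m_score = a2, audit3mv_score = a3,
      auditcm_total = tot$total, auditcm_at_risk = tot$at_risk,
      finnish_short = fin$short_term, finnish_long = fin$long_term,
      finnish_any = fin$any_risk,
      audit12_short = a12$short_term, audit12_long = a12$long_term,
      audit12_any = a12$any_risk,
      audit3_short = a3r$short_term, audit3_long = a3r$long_term,
      audit3_any = a3r$any_risk
    )
  )
}

#' Run the end-to-end screening analysis
#'
#' Reads `responses.csv`, `occasions.csv` and (for the beverage dialect)
#' `products.csv` from `input_dir`; excludes past-year non-drinkers; scores
#' every drinker; cross-tabulates each index method (AUDIT-Cm total,
#' AUDIT-1m+2m, AUDIT-3mV) against the Finnish-method reference for any,
#' short-term and long-term risk; and computes the shortened-Finnish
#' retention grid with and without zero-variance drinkers. When
#' `output_dir` is given, writes `summary.csv`, `concordance.json`,
#' `retention.csv`, `retention_zero_variance_excluded.csv` and `log.txt`.
#'
#' @param input_dir Directory holding the input CSVs.
#' @param output_dir Output directory, or `NULL` to skip writing.
#' @param config A [pipeline_config()].
#' @return List with `summary` (per-drinker data frame), `concordance`
#'   (list of comparison results), `retention`, `retention_novar`, and
#'   `log` (exclusion accounting).
#' @export
run_pipeline <- function(input_dir, output_dir = NULL,
                         config = pipeline_config()) {
  responses <- read_responses(file.path(input_dir, "responses.csv"))
  occasions <- read_occasions(file.path(input_dir, "occasions.csv"))
  catalog <- if (identical(attr(occasions, "dialect"), "beverage")) {
    read_products(file.path(input_dir, "products.csv"))
  } else NULL
  occ <- resolve_occasions(occasions, catalog)

  orphans <- setdiff(unique(occ$person_id), responses$person_id)
  if (length(orphans) > 0) {
    stop(sprintf("occasions.csv references person_id absent from responses.csv: %s",
                 paste(orphans, collapse = ", ")), call. = FALSE)
  }

  status <- vapply(seq_len(nrow(responses)), function(i) {
    drinker_status(yesno(responses$prep_drank[i]),
                   yesno(responses$check_drank[i]))
  }, character(1))
  dep <- vapply(seq_len(nrow(responses)), function(i) {
    dependence_status(c(responses$dep1[i], responses$dep2[i],
                        responses$dep3[i]))
  }, character(1))

  n_total <- nrow(responses)
  drinkers <- responses[status == "drinker", , drop = FALSE]
  dep <- dep[status == "drinker"]

  rows <- list()
  n_no_window <- 0L
  for (i in seq_len(nrow(drinkers))) {
    pid <- drinkers$person_id[i]
    po <- occ[occ$person_id == pid, , drop = FALSE]
    po <- po[order(po$occasion_rank), ]
    row <- if (nrow(po) == 0) NULL else {
      score_participant(drinkers$sex[i], drinkers$audit1m[i],
                        drinkers$audit3mv[i], po$days_before_survey,
                        po$standard_drinks, config)
    }
    if (is.null(row)) {
      n_no_window <- n_no_window + 1L
      next
    }
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(person_id = pid, drinker_status = "drinker",
                 dependence_status = dep[i]),
      row)
  }
  summary_df <- if (length(rows) > 0) do.call(rbind, rows) else NULL

  concordance <- list()
  if (!is.null(summary_df)) {
    comparisons <- list(
      list(method = "audit_cm", flags = summary_df$auditcm_at_risk),
      list(method = "audit_12",
           flags = list(any = summary_df$audit12_any,
                        short = summary_df$audit12_short,
                        long = summary_df$audit12_long)),
      list(method = "audit_3",
           flags = list(any = summary_df$audit3_any,
                        short = summary_df$audit3_short,
                        long = summary_df$audit3_long))
    )
    refs <- list(any = summary_df$finnish_any,
                 short = summary_df$finnish_short,
                 long = summary_df$finnish_long)
    for (cmp in comparisons) {
      for (risk in names(refs)) {
        index_flags <- if (is.list(cmp$flags)) cmp$flags[[risk]] else cmp$flags
        tab <- cross_tabulate(index_flags, refs[[risk]])
        res <- tryCatch(sensitivity_specificity(tab, config$ci_level),
                        error = function(e) c(tab, list(
                          n = with(tab, tp + fn + fp + tn),
                          undefined = conditionMessage(e))))
        res$method <- cmp$method
        res$reference <- "finnish"
        res$risk_type <- risk
        concordance[[paste(cmp$method, risk, sep = "_")]] <- res
      }
    }
  }

  drinker_occ <- occ[occ$person_id %in% (if (is.null(summary_df)) character()
                                         else summary_df$person_id), ,
                     drop = FALSE]
  retention <- tryCatch(
    retention_grid(drinker_occ, config$retention_variable, config$window_days),
    error = function(e) NULL)
  novar <- exclude_zero_variance(drinker_occ, window_days = config$window_days)
  retention_novar <- tryCatch(
    retention_grid(novar$occasions, config$retention_variable,
                   config$window_days),
    error = function(e) NULL)

  log <- list(
    n_total = n_total,
    n_non_drinkers = sum(status == "non_drinker"),
    n_drinkers = nrow(drinkers),
    n_no_in_window_occasions = n_no_window,
    n_analysed = if (is.null(summary_df)) 0L else nrow(summary_df),
    n_retention_used = if (is.null(retention)) 0L else retention$n_used,
    n_retention_excluded_lt4 = if (is.null(retention)) NA_integer_ else
      retention$n_excluded,
    n_zero_variance_dropped = novar$n_dropped
  )

  result <- list(summary = summary_df, concordance = concordance,
                 retention = retention, retention_novar = retention_novar,
                 log = log)
  if (!is.null(output_dir)) {
    write_pipeline_outputs(result, output_dir)
  }
  result
}

retention_table <- function(ret) {
  g <- ret$grid
  do.call(rbind, lapply(1:4, function(kq) {
    data.frame(k_quantity = kq, k_frequency = 1:4,
               r_squared_percent = round(100 * g[kq, ], 1))
  }))
}

write_pipeline_outputs <- function(result, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(result$summary)) {
    out <- result$summary
    num <- vapply(out, is.numeric, logical(1)) &
      !names(out) %in% c("n_occasions", "k_quantity", "k_frequency",
                         "audit1m_score", "audit2m_score", "audit3mv_score",
                         "auditcm_total")
    out[num] <- lapply(out[num], function(x) signif(x, 8))
    utils::write.csv(out, file.path(output_dir, "summary.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  conc <- lapply(result$concordance, function(r) {
    if (!is.null(r$undefined)) return(r)
    r$sensitivity_pct <- sprintf("%.1f", 100 * r$sensitivity)
    r$specificity_pct <- sprintf("%.1f", 100 * r$specificity)
    r$ci_sensitivity <- unname(r$ci_sensitivity)
    r$ci_specificity <- unname(r$ci_specificity)
    r
  })
  jsonlite::write_json(conc, file.path(output_dir, "concordance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in c("retention", "retention_novar")) {
    if (!is.null(result[[nm]])) {
      f <- if (nm == "retention") "retention.csv" else
        "retention_zero_variance_excluded.csv"
      utils::write.csv(retention_table(result[[nm]]),
                       file.path(output_dir, f), row.names = FALSE,
                       quote = FALSE)
    }
  }
  log_lines <- sprintf("%s: %s", names(result$log),
                       vapply(result$log, as.character, character(1)))
  writeLines(log_lines, file.path(output_dir, "log.txt"))
  invisible(result)
}
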