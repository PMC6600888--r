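#' Read a beverage product catalog
#'
#' `products.csv` schema: `product_id,name,abv_percent` (header required,
#' UTF-8, '.' decimal separator; ABV stored as percent in files and held as
#' a fraction in memory — the conversion happens only at this boundary).
#'
#' @param path Path to `products.csv`.
#' @return Data frame with `product_id`, `name`, `abv` (fraction), and
#'   `container_volume_ml` when the file provides it.
#' @export
read_products <- function(path) {
  d <- read_schema(path, c("product_id", "name", "abv_percent"),
                   optional = "container_volume_ml")
  if (any(d$abv_percent <= 0) || any(d$abv_percent >= 100)) {
    stop(sprintf("%s: abv_percent must be in (0, 100)", path), call. = FALSE)
  }
  d$abv <- d$abv_percent / 100
  d$abv_percent <- NULL
  d
}

#' Read per-occasion drinking records
#'
#' Two dialects are accepted and auto-detected from the header. Drinks
#' dialect: `person_id,occasion_rank,days_before_survey,standard_drinks`.
#' Beverage dialect: `person_id,occasion_rank,days_before_survey,product_id,
#' container_volume_ml,fullness,count,share` (several rows may describe one
#' occasion). `occasion_rank` 1 is the most recent occasion.
#'
#' @param path Path to `occasions.csv`.
#' @return Data frame with a `dialect` attribute (`"drinks"` or
#'   `"beverage"`).
#' @export
read_occasions <- function(path) {
  header <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  drinks_cols <- c("person_id", "occasion_rank", "days_before_survey",
                   "standard_drinks")
  bev_cols <- c("person_id", "occasion_rank", "days_before_survey",
                "product_id", "container_volume_ml", "fullness", "count",
                "share")
  if (identical(header, drinks_cols)) {
    d <- read_schema(path, drinks_cols)
    if (any(d$standard_drinks < 0)) {
      stop(sprintf("%s: standard_drinks must be >= 0", path), call. = FALSE)
    }
    if (anyDuplicated(d[c("person_id", "occasion_rank")])) {
      stop(sprintf("%s: duplicate (person_id, occasion_rank)", path),
           call. = FALSE)
    }
    attr(d, "dialect") <- "drinks"
  } else if (identical(header, bev_cols)) {
    d <- read_schema(path, bev_cols)
    attr(d, "dialect") <- "beverage"
  } else {
    stop(sprintf(
      "%s: header matches neither occasions dialect;\n  drinks:   %s\n  beverage: %s",
      path, paste(drinks_cols, collapse = ","),
      paste(bev_cols, collapse = ",")), call. = FALSE)
  }
  if (any(d$days_before_survey < 0)) {
    stop(sprintf("%s: days_before_survey must be >= 0", path), call. = FALSE)
  }
  d
}

#' Read participant questionnaire responses
#'
#' Schema: `person_id,sex,prep_drank,check_drank,audit1m,audit3mv,dep1,dep2,
#' dep3`. Category columns use the tokens `never|lt_monthly|monthly_1_3|
#' weekly_1_3|most_days` (exact case); `sex` is `female|male`; the gate
#' answers are `yes|no` (`check_drank` may be empty when `prep_drank` is
#' `yes`; `audit1m`/`audit3mv` may be empty for non-drinkers).
#'
#' @param path Path to `responses.csv`.
#' @return Validated data frame.
#' @export
read_responses <- function(path) {
  cols <- c("person_id", "sex", "prep_drank", "check_drank", "audit1m",
            "audit3mv", "dep1", "dep2", "dep3")
  d <- read_schema(path, cols)
  if (anyDuplicated(d$person_id)) {
    stop(sprintf("%s: duplicate person_id", path), call. = FALSE)
  }
  check_tokens(d, path, "sex", c("female", "male"))
  check_tokens(d, path, "prep_drank", c("yes", "no"))
  check_tokens(d, path, "check_drank", c("yes", "no"), allow_empty = TRUE)
  for (col in c("audit1m", "audit3mv", "dep1", "dep2", "dep3")) {
    check_tokens(d, path, col, FREQUENCY_CATEGORIES, allow_empty = TRUE)
  }
  d
}

read_schema <- function(path, required, optional = character()) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  d <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                       fileEncoding = "UTF-8")
  missing <- setdiff(required, names(d))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  d <- d[intersect(c(required, optional), names(d))]
  numeric_cols <- intersect(
    c("occasion_rank", "days_before_survey", "standard_drinks",
      "abv_percent", "container_volume_ml", "fullness", "count", "share"),
    names(d))
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & d[[col]] != "")
    if (length(bad) > 0) {
      stop(sprintf("%s:%d: column `%s`: not a number: '%s'", path,
                   bad[1] + 1L, col, d[[col]][bad[1]]), call. = FALSE)
    }
    d[[col]] <- v
  }
  d
}

check_tokens <- function(d, path, col, allowed, allow_empty = FALSE) {
  v <- d[[col]]
  ok <- v %in% allowed | (allow_empty & (is.na(v) | v == ""))
  if (!all(ok)) {
    i <- which(!ok)[1]
    stop(sprintf("%s:%d: column `%s`: unknown token '%s' (expected: %s)",
                 path, i + 1L, col, v[i], paste(allowed, collapse = ", ")),
         call. = FALSE)
  }
  invisible(d)
}

#' Collapse beverage-dialect occasions to standard-drink totals
#'
#' @param occasions Occasions data frame from [read_occasions()].
#' @param catalog Product catalog from [read_products()] (needed only for
#'   the beverage dialect).
#' @return Drinks-dialect data frame (`person_id`, `occasion_rank`,
#'   `days_before_survey`, `standard_drinks`).
#' @export
resolve_occasions <- function(occasions, catalog = NULL) {
  if (identical(attr(occasions, "dialect"), "drinks") ||
      "standard_drinks" %in% names(occasions)) {
    return(occasions[c("person_id", "occasion_rank", "days_before_survey",
                       "standard_drinks")])
  }
  key <- interaction(occasions$person_id, occasions$occasion_rank, drop = TRUE)
  parts <- split(occasions, key)
  out <- do.call(rbind, lapply(parts, function(g) {
    occ <- occasion(g$days_before_survey[1], entries = g)
    data.frame(person_id = g$person_id[1],
               occasion_rank = g$occasion_rank[1],
               days_before_survey = g$days_before_survey[1],
               standard_drinks = occasion_total_drinks(occ, catalog))
  }))
  out <- out[order(out$person_id, out$occasion_rank), ]
  rownames(out) <- NULL
  out
}

cohort_responses_table <- function(cohort) {
  do.call(rbind, lapply(cohort, function(p) {
    drinker <- !is.null(p$occasions)
    data.frame(
      person_id = p$person_id, sex = p$sex,
      prep_drank = if (p$prep_drank) "yes" else "no",
      check_drank = if (is.na(p$check_drank)) "" else
        if (p$check_drank) "yes" else "no",
      audit1m = if (drinker) p$audit1m else "",
      audit3mv = if (drinker) p$audit3mv else "",
      dep1 = p$dependence_ratings[1],
      dep2 = p$dependence_ratings[2],
      dep3 = p$dependence_ratings[3]
    )
  }))
}

cohort_occasions_table <- function(cohort, dialect = c("drinks", "beverage"),
                                   catalog = NULL) {
  dialect <- match.arg(dialect)
  drinkers <- Filter(function(p) !is.null(p$occasions), cohort)
  if (length(drinkers) == 0) {
    cols <- if (dialect == "drinks") {
      c("person_id", "occasion_rank", "days_before_survey", "standard_drinks")
    } else {
      c("person_id", "occasion_rank", "days_before_survey", "product_id",
        "container_volume_ml", "fullness", "count", "share")
    }
    empty <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                           cols))
    return(empty)
  }
  tabs <- lapply(drinkers, function(p) {
    occ <- p$occasions
    if (dialect == "drinks") {
      cbind(person_id = p$person_id, occ)
    } else {
      do.call(rbind, lapply(seq_len(nrow(occ)), function(i) {
        entries <- compose_beverages(occ$standard_drinks[i], catalog)
        if (nrow(entries) == 0) {
          entries <- compose_beverages(1e-9, catalog)  # representable zero-ish
        }
        cbind(person_id = p$person_id,
              occasion_rank = occ$occasion_rank[i],
              days_before_survey = occ$days_before_survey[i],
              entries)
      }))
    }
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  if (dialect == "beverage") {
    out <- out[c("person_id", "occasion_rank", "days_before_survey",
                 "product_id", "container_volume_ml", "fullness", "count",
                 "share")]
  } else {
    out <- out[c("person_id", "occasion_rank", "days_before_survey",
                 "standard_drinks")]
  }
  out
}

#' Write a synthetic cohort to survey CSV files
#'
#' Writes `products.csv`, `occasions.csv` (in the requested dialect),
#' `responses.csv` and `provenance.json` (parameters, seed and md5 content
#' hashes) into `dir`.
#'
#' @param params A [cohort_params()] object.
#' @param dir Output directory (created if needed).
#' @param dialect Occasions dialect to write.
#' @param catalog Product catalog; defaults to the packaged example catalog.
#' @return Invisibly, the generated cohort.
#' @export
simulate_cohort_files <- function(params = cohort_params(), dir,
                                  dialect = c("drinks", "beverage"),
                                  catalog = default_catalog()) {
  dialect <- match.arg(dialect)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(params)
  prod_out <- data.frame(product_id = catalog$product_id, name = catalog$name,
                         abv_percent = catalog$abv * 100,
                         container_volume_ml = catalog$container_volume_ml)
  files <- c(products = file.path(dir, "products.csv"),
             occasions = file.path(dir, "occasions.csv"),
             responses = file.path(dir, "responses.csv"))
  utils::write.csv(prod_out, files["products"], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(cohort_occasions_table(cohort, dialect, catalog),
                   files["occasions"], row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort_responses_table(cohort), files["responses"],
                   row.names = FALSE, quote = FALSE)
  prov <- list(
    params = unclass(params)[setdiff(names(params), "")],
    dialect = dialect,
    content_md5 = as.list(tools::md5sum(unname(files)))
  )
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(cohort)
}

#' The packaged example product catalog
#'
#' A small catalog of common Australian beverage products (beer cans, wine,
#' cask wine, spirits) with container volumes, used by the beverage-dialect
#' writer and in examples. Synthetic: product names are generic, not a brand
#' database.
#'
#' @return Catalog data frame (`product_id`, `name`, `abv` fraction,
#'   `container_volume_ml`).
#' @export
default_catalog <- function() {
  read_products(system.file("extdata", "products.csv",
                            package = "grogscreen", mustWork = TRUE))
}
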