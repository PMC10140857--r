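# Domain tables, CSV readers/writers, validation, and the DRI <-> five-year
# age-band mapping. All tables are plain tibbles with documented schemas; the
# CSV dialect is UTF-8, comma-separated, header row mandatory, "." decimal.

#' Dietary Reference Intake (DRI) adult age groups
#'
#' Intake data are reported per sex and DRI age group; mortality and population
#' registries use five-year age bands. [band_to_dri()] joins the two.
#'
#' @format Character vector of the four adult DRI group labels.
#' @export
DRI_GROUPS <- c("19-30", "31-50", "51-70", "71+")

# Lower edges of the DRI groups on the real age line. Group "19-30" covers
# integer ages 19..30, i.e. the interval [19, 31), and so on.
.DRI_BREAKS <- c(19, 31, 51, 71)

# Representative age used when a per-group quantity needs an age (coefficient
# lookup in the energy-balance table): near-midpoint of each DRI group.
.DRI_REFERENCE_AGE <- c("19-30" = 25, "31-50" = 41, "51-70" = 61, "71+" = 76)

#' Disease groups used for reporting subtotals
#' @format Character vector of the five cause-of-death groups.
#' @export
CAUSE_GROUPS <- c("cardiovascular", "cancer", "diabetes", "renal", "liver")

#' Sex labels used in all strata
#' @format Character vector, `c("male", "female")`.
#' @export
SEXES <- c("male", "female")

# ---------------------------------------------------------------------------
# error helpers

stop_schema <- function(msg) abort(msg, class = "sugarcra_schema_error")
stop_unique <- function(msg) abort(msg, class = "sugarcra_uniqueness_error")
stop_reference <- function(msg) abort(msg, class = "sugarcra_reference_error")
stop_coverage <- function(msg) abort(msg, class = "sugarcra_coverage_error")
stop_domain <- function(msg) abort(msg, class = "sugarcra_domain_error")

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_schema(sprintf(
      "%s: missing required column(s): %s", what,
      paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

check_sex <- function(sex, what) {
  bad <- setdiff(unique(sex), SEXES)
  if (length(bad) > 0) {
    stop_schema(sprintf("%s: unknown sex value(s): %s", what,
                        paste(bad, collapse = ", ")))
  }
}

read_csv_strict <- function(path, what) {
  if (!file.exists(path)) {
    stop_schema(sprintf("%s: file not found: %s", what, path))
  }
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

# ---------------------------------------------------------------------------
# age-band helpers

#' Midpoint of a half-open age band
#'
#' Bands are half-open integer ranges `[age_lo, age_hi)`; the top band is
#' open-ended (`age_hi = NA`) and uses `age_lo + 2.5` as its midpoint.
#'
#' @param age_lo,age_hi Numeric vectors of band edges; `age_hi` may be `NA`.
#' @return Numeric vector of midpoints.
#' @export
band_midpoint <- function(age_lo, age_hi) {
  ifelse(is.na(age_hi), age_lo + 2.5, (age_lo + age_hi) / 2)
}

#' Map an age band (or single age) to its DRI group
#'
#' Each band is assigned to the DRI group containing its midpoint; exposure
#' values are later broadcast uniformly to all bands within a group. A single
#' age `a` may be given (omit `age_hi`), treated as the band `[a, a + 1)`.
#'
#' @param age_lo,age_hi Band edges; `age_hi = NA` marks the open-ended top
#'   band. If `age_hi` is omitted entirely, `age_lo` is interpreted as exact
#'   ages.
#' @param strict If `TRUE` (default), a midpoint below 19 years is an error
#'   (the model is adult-only); if `FALSE`, such bands map to `NA`.
#' @return Character vector of DRI group labels (see [DRI_GROUPS]).
#' @export
#' @examples
#' band_to_dri(30, 35) # "31-50"
#' band_to_dri(85, NA) # "71+"
band_to_dri <- function(age_lo, age_hi = age_lo + 1, strict = TRUE) {
  mid <- band_midpoint(age_lo, age_hi)
  idx <- findInterval(mid, .DRI_BREAKS)
  out <- ifelse(idx >= 1, DRI_GROUPS[pmax(idx, 1)], NA_character_)
  if (strict && anyNA(out)) {
    stop_domain(sprintf(
      "age band(s) with midpoint below 19 y are outside the adult model: %s",
      paste(sprintf("[%s,%s)", age_lo[is.na(out)],
                    ifelse(is.na(age_hi[is.na(out)]), "open",
                           age_hi[is.na(out)])), collapse = ", ")
    ))
  }
  out
}

dri_reference_age <- function(dri_group) {
  unname(.DRI_REFERENCE_AGE[dri_group])
}

#' Restrict records to adult age bands
#'
#' Keeps only rows whose age band maps to a DRI group (midpoint >= 19 y);
#' values of surviving rows are unchanged.
#'
#' @param records A tibble with `age_lo` and `age_hi` columns.
#' @return The filtered tibble.
#' @export
adult_filter <- function(records) {
  if (nrow(records) == 0) return(records)
  keep <- !is.na(band_to_dri(records$age_lo, records$age_hi, strict = FALSE))
  records[keep, , drop = FALSE]
}

#' Convert a standard error of the mean to a population SD
#'
#' Survey tables often print the SE of a stratum mean; the potential impact
#' fraction integrals need the population spread. `SD = SE * sqrt(n)` under
#' simple random sampling (real surveys have design effects; prefer a directly
#' estimated SD when available).
#'
#' @param se Standard error of the mean.
#' @param n Stratum sample size.
#' @export
se_to_sd <- function(se, n) {
  if (any(se < 0) || any(n <= 0)) stop_domain("se must be >= 0 and n > 0")
  se * sqrt(n)
}

# ---------------------------------------------------------------------------
# validators

validate_population <- function(df) {
  check_columns(df, c("sex", "age_lo", "age_hi", "population"), "population")
  check_sex(df$sex, "population")
  if (any(df$population < 0)) stop_domain("population: negative count")
  key <- paste(df$sex, df$age_lo)
  if (anyDuplicated(key)) {
    stop_unique(sprintf("population: duplicate stratum key(s): %s",
                        paste(unique(key[duplicated(key)]), collapse = "; ")))
  }
  # bands within one sex must be disjoint and sorted
  for (s in unique(df$sex)) {
    b <- df[df$sex == s, ]
    b <- b[order(b$age_lo), ]
    hi <- ifelse(is.na(b$age_hi), Inf, b$age_hi)
    if (any(b$age_lo >= hi)) stop_domain("population: empty or inverted band")
    if (nrow(b) > 1 && any(hi[-nrow(b)] > b$age_lo[-1])) {
      stop_domain(sprintf("population: overlapping bands for sex %s", s))
    }
    if (sum(is.na(b$age_hi)) > 1) {
      stop_domain("population: more than one open-ended band per sex")
    }
  }
  df
}

validate_causes <- function(df) {
  check_columns(df, c("cause_id", "name", "icd10", "group"), "causes")
  if (anyDuplicated(df$cause_id)) stop_unique("causes: duplicate cause_id")
  bad <- setdiff(unique(df$group), CAUSE_GROUPS)
  if (length(bad) > 0) {
    stop_schema(sprintf("causes: unknown group(s): %s",
                        paste(bad, collapse = ", ")))
  }
  df
}

validate_mortality <- function(df, causes) {
  check_columns(df, c("sex", "age_lo", "age_hi", "cause_id", "deaths"),
                "mortality")
  check_sex(df$sex, "mortality")
  if (any(df$deaths < 0)) stop_domain("mortality: negative death count")
  key <- paste(df$sex, df$age_lo, df$cause_id)
  if (anyDuplicated(key)) {
    stop_unique("mortality: duplicate (sex, age_band, cause_id) key")
  }
  unresolved <- setdiff(unique(df$cause_id), causes$cause_id)
  if (length(unresolved) > 0) {
    stop_reference(sprintf("mortality: cause_id(s) not present in causes: %s",
                           paste(unresolved, collapse = ", ")))
  }
  df
}

validate_exposure <- function(df, what = "exposure") {
  check_columns(df, c("sex", "dri_group", "mean_kcal", "se_kcal", "mean_bmi",
                      "sd_bmi", "mean_height_m"), what)
  check_sex(df$sex, what)
  bad <- setdiff(unique(df$dri_group), DRI_GROUPS)
  if (length(bad) > 0) {
    stop_schema(sprintf("%s: unknown dri_group(s): %s", what,
                        paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(paste(df$sex, df$dri_group))) {
    stop_unique(sprintf("%s: duplicate (sex, dri_group) cell", what))
  }
  with(df, {
    if (any(mean_kcal <= 0)) stop_domain(paste(what, ": mean_kcal must be > 0"))
    if (any(mean_bmi <= 10)) stop_domain(paste(what, ": mean_bmi must be > 10"))
    if (any(sd_bmi <= 0)) stop_domain(paste(what, ": sd_bmi must be > 0"))
    if (any(mean_height_m <= 1 | mean_height_m >= 2.5)) {
      stop_domain(paste(what, ": mean_height_m outside (1, 2.5)"))
    }
  })
  df
}

validate_scenario_pair <- function(baseline, counterfactual) {
  validate_exposure(baseline, "exposure (baseline)")
  validate_exposure(counterfactual, "exposure (counterfactual)")
  grid <- tidyr::expand_grid(sex = SEXES, dri_group = DRI_GROUPS)
  for (nm in c("baseline", "counterfactual")) {
    df <- if (nm == "baseline") baseline else counterfactual
    missing <- anti_join(grid, df, by = c("sex", "dri_group"))
    if (nrow(missing) > 0) {
      stop_coverage(sprintf(
        "exposure (%s): missing sex x DRI cell(s): %s", nm,
        paste(paste(missing$sex, missing$dri_group), collapse = "; ")
      ))
    }
  }
  hb <- baseline %>% arrange(.data$sex, .data$dri_group)
  hc <- counterfactual %>% arrange(.data$sex, .data$dri_group)
  if (any(abs(hb$mean_height_m - hc$mean_height_m) > 1e-9)) {
    stop_domain("scenario pair: heights must be identical across scenarios")
  }
  list(baseline = hb, counterfactual = hc)
}

validate_rr <- function(df, causes = NULL) {
  check_columns(df, c("cause_id", "sex", "rr_per_unit", "unit", "se_log_rr",
                      "ref_bmi"), "rr")
  bad <- setdiff(unique(df$sex), c(SEXES, "both"))
  if (length(bad) > 0) {
    stop_schema(sprintf("rr: sex must be male/female/both, got: %s",
                        paste(bad, collapse = ", ")))
  }
  with(df, {
    if (any(rr_per_unit <= 0)) stop_domain("rr: rr_per_unit must be > 0")
    if (any(unit <= 0)) stop_domain("rr: unit must be > 0")
    if (any(se_log_rr < 0)) stop_domain("rr: se_log_rr must be >= 0")
  })
  if (!is.null(causes)) {
    unresolved <- setdiff(unique(df$cause_id), causes$cause_id)
    if (length(unresolved) > 0) {
      stop_reference(sprintf("rr: cause_id(s) not present in causes: %s",
                             paste(unresolved, collapse = ", ")))
    }
  }
  # expanding "both" must not collide with sex-specific rows
  expanded <- expand_rr(df)
  if (anyDuplicated(paste(expanded$cause_id, expanded$sex))) {
    stop_unique("rr: duplicate (cause_id, sex) after expanding sex = 'both'")
  }
  df
}

# expand sex = "both" rows into one row per sex
expand_rr <- function(rr) {
  both <- rr %>% filter(.data$sex == "both")
  rest <- rr %>% filter(.data$sex != "both")
  bind_rows(
    rest,
    bind_rows(lapply(SEXES, function(s) mutate(both, sex = s)))
  )
}

# ---------------------------------------------------------------------------
# readers / writers

#' Read and validate one input table
#'
#' Schemas (CSV, comma-separated, header mandatory):
#' * population: `sex, age_lo, age_hi, population` (`age_hi` empty for the
#'   open-ended top band)
#' * mortality: `sex, age_lo, age_hi, cause_id, deaths`
#' * causes: `cause_id, name, icd10, group`
#' * exposure: `sex, dri_group, mean_kcal, se_kcal, mean_bmi, sd_bmi,
#'   mean_height_m`
#' * rr: `cause_id, sex, rr_per_unit, unit, se_log_rr, ref_bmi`
#'
#' @param path CSV file path.
#' @param causes Optional causes table for cross-reference validation.
#' @return A validated tibble.
#' @name readers
NULL

#' @rdname readers
#' @export
read_population <- function(path) {
  validate_population(read_csv_strict(path, "population"))
}

#' @rdname readers
#' @export
read_causes <- function(path) validate_causes(read_csv_strict(path, "causes"))

#' @rdname readers
#' @export
read_mortality <- function(path, causes) {
  validate_mortality(read_csv_strict(path, "mortality"), causes)
}

#' @rdname readers
#' @export
read_exposure <- function(path) {
  validate_exposure(read_csv_strict(path, "exposure"))
}

#' @rdname readers
#' @export
read_rr <- function(path, causes = NULL) {
  validate_rr(read_csv_strict(path, "rr"), causes)
}

#' Load and cross-validate a complete input bundle
#'
#' Reads all model inputs, validates each table, and checks cross-references:
#' every mortality `cause_id` must exist in the causes table, and both exposure
#' scenarios must cover every sex x DRI cell with identical heights.
#'
#' @param population_path,mortality_path,causes_path CSV paths (see
#'   [readers]).
#' @param exposure_baseline_path,exposure_counterfactual_path Exposure CSVs for
#'   the two scenarios.
#' @param rr_path Optional relative-risk specification CSV.
#' @return A `cra_bundle` list with elements `population`, `mortality`,
#'   `causes`, `scenarios` (list `baseline` / `counterfactual`) and `rr`
#'   (or `NULL`).
#' @export
load_inputs <- function(population_path, mortality_path, causes_path,
                        exposure_baseline_path, exposure_counterfactual_path,
                        rr_path = NULL) {
  causes <- read_causes(causes_path)
  bundle <- list(
    population = read_population(population_path),
    mortality = read_mortality(mortality_path, causes),
    causes = causes,
    scenarios = validate_scenario_pair(
      read_exposure(exposure_baseline_path),
      read_exposure(exposure_counterfactual_path)
    ),
    rr = if (!is.null(rr_path)) read_rr(rr_path, causes)
  )
  structure(bundle, class = "cra_bundle")
}

#' Assemble a bundle from in-memory tables
#'
#' Same validation as [load_inputs()] but on tibbles already in memory.
#'
#' @param population,mortality,causes,exposure_baseline,exposure_counterfactual,rr
#'   Tibbles following the schemas in [readers]; `rr` may be `NULL`.
#' @return A validated `cra_bundle`.
#' @export
as_bundle <- function(population, mortality, causes, exposure_baseline,
                      exposure_counterfactual, rr = NULL) {
  causes <- validate_causes(causes)
  structure(list(
    population = validate_population(population),
    mortality = validate_mortality(mortality, causes),
    causes = causes,
    scenarios = validate_scenario_pair(exposure_baseline,
                                       exposure_counterfactual),
    rr = if (!is.null(rr)) validate_rr(rr, causes)
  ), class = "cra_bundle")
}

#' Write a bundle back to CSV files
#'
#' Emits the exact schemas read by [load_inputs()]; a write/read round trip
#' reproduces identical values.
#'
#' @param bundle A `cra_bundle`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named character vector of file paths.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    population = file.path(dir, "population.csv"),
    mortality = file.path(dir, "mortality.csv"),
    causes = file.path(dir, "causes.csv"),
    exposure_baseline = file.path(dir, "exposure_baseline.csv"),
    exposure_counterfactual = file.path(dir, "exposure_counterfactual.csv")
  )
  readr::write_csv(bundle$population, paths["population"], na = "")
  readr::write_csv(bundle$mortality, paths["mortality"], na = "")
  readr::write_csv(bundle$causes, paths["causes"])
  readr::write_csv(bundle$scenarios$baseline, paths["exposure_baseline"])
  readr::write_csv(bundle$scenarios$counterfactual,
                   paths["exposure_counterfactual"])
  if (!is.null(bundle$rr)) {
    paths <- c(paths, rr = file.path(dir, "rr.csv"))
    readr::write_csv(bundle$rr, paths["rr"])
  }
  invisible(paths)
}

#' @export
print.cra_bundle <- function(x, ...) {
  cat("<cra_bundle>\n")
  cat(sprintf("  population : %d strata, %s persons\n",
              nrow(x$population), format(sum(x$population$population),
                                         big.mark = ",")))
  cat(sprintf("  mortality  : %d cells, %s deaths/yr\n", nrow(x$mortality),
              format(sum(x$mortality$deaths), big.mark = ",")))
  cat(sprintf("  causes     : %d (%s)\n", nrow(x$causes),
              paste(unique(x$causes$group), collapse = ", ")))
  cat(sprintf("  scenarios  : baseline + counterfactual, %d cells each\n",
              nrow(x$scenarios$baseline)))
  cat(sprintf("  rr         : %s\n",
              if (is.null(x$rr)) "none" else paste(nrow(x$rr), "specs")))
  invisible(x)
}
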