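# Counterfactual scenario builder: apply a systematic fractional free-sugars
# reduction (with a configurable calorie response) to dietary-recall microdata
# and summarize intakes per sex x DRI group.

#' Food categories recognised in recall microdata
#' @format Character vector of category tokens.
#' @export
FOOD_CATEGORIES <- c(
  "bakery", "beverages", "cereals_grains", "dairy", "desserts",
  "fats_vinegars", "fish_seafood", "fruits", "mixed_dishes", "sauces_dips",
  "snacks", "soups", "sugars_sweets", "vegetables"
)

#' Percent of total energy from free sugars
#'
#' `%TE = 100 * energy_factor * free_sugars_g_day / kcal_day`, with the
#' standard carbohydrate energy factor of 4 kcal/g by default.
#'
#' @param free_sugars_g_day Grams of free sugars per day.
#' @param kcal_day Total energy intake, kcal/day (must be positive).
#' @param energy_factor kcal per gram of sugar (default 4).
#' @return Percent of total energy (numeric).
#' @export
#' @examples
#' percent_te(56.2, 1858) # ~12.1
percent_te <- function(free_sugars_g_day, kcal_day,
                       energy_factor = ENERGY_KCAL_PER_G_SUGAR) {
  if (any(kcal_day <= 0)) stop_domain("percent_te: kcal_day must be > 0")
  if (energy_factor <= 0) stop_domain("percent_te: energy_factor must be > 0")
  100 * energy_factor * free_sugars_g_day / kcal_day
}

validate_recalls <- function(df) {
  check_columns(df, c("person_id", "sex", "age", "category", "free_sugars_g",
                      "energy_kcal"), "recalls")
  check_sex(df$sex, "recalls")
  bad <- setdiff(unique(df$category), FOOD_CATEGORIES)
  if (length(bad) > 0) {
    stop_schema(sprintf("recalls: unknown category token(s): %s",
                        paste(bad, collapse = ", ")))
  }
  with(df, {
    if (any(free_sugars_g < 0)) stop_domain("recalls: negative free_sugars_g")
    if (any(energy_kcal < 0)) stop_domain("recalls: negative energy_kcal")
    tol <- 1e-6 * pmax(energy_kcal, 1)
    if (any(ENERGY_KCAL_PER_G_SUGAR * free_sugars_g > energy_kcal + tol)) {
      stop_domain("recalls: sugar energy exceeds item energy")
    }
  })
  df
}

validate_rules <- function(df) {
  check_columns(df, c("category", "reduction_fraction", "calorie_response"),
                "rules")
  bad <- setdiff(unique(df$category), FOOD_CATEGORIES)
  if (length(bad) > 0) {
    stop_schema(sprintf("rules: unknown category token(s): %s",
                        paste(bad, collapse = ", ")))
  }
  with(df, {
    if (any(reduction_fraction < 0 | reduction_fraction > 1)) {
      stop_domain("rules: reduction_fraction outside [0, 1]")
    }
    if (any(calorie_response < 0)) stop_domain("rules: calorie_response < 0")
  })
  if (anyDuplicated(df$category)) stop_unique("rules: duplicate category")
  df
}

#' @rdname readers
#' @export
read_recalls <- function(path) validate_recalls(read_csv_strict(path, "recalls"))

#' @rdname readers
#' @export
read_rules <- function(path) validate_rules(read_csv_strict(path, "rules"))

#' Build a uniform reformulation rule table
#'
#' One rule per food category with the same reduction fraction `r` and calorie
#' response `kappa`.
#'
#' @param reduction_fraction Fraction of free sugars removed, in `[0, 1]`.
#' @param calorie_response kcal removed per kcal of free-sugar energy removed;
#'   1 means fully calorie-reducing, below 1 partial replacement by other
#'   components (fats, starches), above 1 co-removal of other energy.
#' @param categories Category tokens (default all of [FOOD_CATEGORIES]).
#' @return A rules tibble.
#' @export
uniform_rules <- function(reduction_fraction, calorie_response = 1,
                          categories = FOOD_CATEGORIES) {
  validate_rules(tibble(
    category = categories,
    reduction_fraction = reduction_fraction,
    calorie_response = calorie_response
  ))
}

#' Apply reformulation rules to food records
#'
#' For a record with free sugars `s` (g) and energy `E` (kcal), and a rule
#' with reduction `r` and calorie response `kappa`:
#' `s' = (1 - r) * s`, `E' = E - kappa * f * r * s` (with `f` the energy
#' factor), clamped from below at `f * s'` so an item never carries less energy
#' than its remaining sugar energy. Categories without a rule are unchanged
#' (`r = 0`); records with zero energy pass through unchanged.
#'
#' @param records Recall tibble (see [readers] for the schema).
#' @param rules Rules tibble; one row per category.
#' @param energy_factor kcal per gram of sugar (default 4).
#' @return `records` with reformulated `free_sugars_g` and `energy_kcal`.
#' @export
#' @examples
#' rec <- tibble::tibble(person_id = 1, sex = "female", age = 40,
#'                       category = "beverages", free_sugars_g = 10,
#'                       energy_kcal = 200)
#' apply_rule(rec, uniform_rules(0.2)) # 8 g, 192 kcal
apply_rule <- function(records, rules,
                       energy_factor = ENERGY_KCAL_PER_G_SUGAR) {
  rules <- validate_rules(rules)
  idx <- match(records$category, rules$category)
  r <- ifelse(is.na(idx), 0, rules$reduction_fraction[idx])
  kappa <- ifelse(is.na(idx), 1, rules$calorie_response[idx])
  s0 <- records$free_sugars_g
  e0 <- records$energy_kcal
  s1 <- (1 - r) * s0
  e1 <- pmax(e0 - kappa * energy_factor * r * s0, energy_factor * s1)
  zero <- e0 <= 0
  records$free_sugars_g <- ifelse(zero, s0, s1)
  records$energy_kcal <- ifelse(zero, e0, e1)
  records
}

#' Per-person baseline and counterfactual daily totals
#'
#' Sums each person's records before and after [apply_rule()].
#'
#' @inheritParams apply_rule
#' @return Tibble with one row per person: `person_id`, `sex`, `age`,
#'   `free_sugars_g_base`, `kcal_base`, `free_sugars_g_cf`, `kcal_cf`.
#' @export
build_counterfactual <- function(records, rules,
                                 energy_factor = ENERGY_KCAL_PER_G_SUGAR) {
  records <- validate_recalls(records)
  if (nrow(records) == 0) {
    return(tibble(person_id = character(), sex = character(), age = numeric(),
                  free_sugars_g_base = numeric(), kcal_base = numeric(),
                  free_sugars_g_cf = numeric(), kcal_cf = numeric()))
  }
  cf <- apply_rule(records, rules, energy_factor)
  base_tot <- records %>%
    group_by(.data$person_id, .data$sex, .data$age) %>%
    summarise(free_sugars_g_base = sum(.data$free_sugars_g),
              kcal_base = sum(.data$energy_kcal), .groups = "drop")
  cf_tot <- cf %>%
    group_by(.data$person_id) %>%
    summarise(free_sugars_g_cf = sum(.data$free_sugars_g),
              kcal_cf = sum(.data$energy_kcal), .groups = "drop")
  inner_join(base_tot, cf_tot, by = "person_id")
}

#' Summarize per-person totals into sex x DRI intake summaries
#'
#' Stratum means are equal-weight means of per-person daily totals, for the
#' baseline and counterfactual scenarios. Sex x DRI cells with no persons are
#' excluded with a warning.
#'
#' @param person_totals Output of [build_counterfactual()].
#' @param energy_factor kcal per gram of sugar, used for the `%TE` column.
#' @return Tibble with columns `scenario` (`baseline` / `counterfactual`),
#'   `sex`, `dri_group`, `n_persons`, `mean_free_sugars_g_day`,
#'   `mean_kcal_day`, `pct_te_free_sugars`.
#' @export
summarize_by_stratum <- function(person_totals,
                                 energy_factor = ENERGY_KCAL_PER_G_SUGAR) {
  pt <- person_totals %>%
    mutate(dri_group = band_to_dri(.data$age, .data$age + 1))
  long <- bind_rows(
    pt %>% mutate(scenario = "baseline",
                  fs = .data$free_sugars_g_base, kcal = .data$kcal_base),
    pt %>% mutate(scenario = "counterfactual",
                  fs = .data$free_sugars_g_cf, kcal = .data$kcal_cf)
  )
  out <- long %>%
    group_by(.data$scenario, .data$sex, .data$dri_group) %>%
    summarise(n_persons = dplyr::n(),
              mean_free_sugars_g_day = mean(.data$fs),
              mean_kcal_day = mean(.data$kcal), .groups = "drop") %>%
    mutate(pct_te_free_sugars = percent_te(.data$mean_free_sugars_g_day,
                                           .data$mean_kcal_day,
                                           energy_factor)) %>%
    arrange(.data$scenario, .data$sex, .data$dri_group)
  grid <- tidyr::expand_grid(sex = SEXES, dri_group = DRI_GROUPS)
  missing <- anti_join(grid,
                       out %>% filter(.data$scenario == "baseline"),
                       by = c("sex", "dri_group"))
  if (nrow(missing) > 0) {
    warn(sprintf("summarize_by_stratum: no persons in cell(s): %s",
                 paste(paste(missing$sex, missing$dri_group), collapse = "; ")))
  }
  out
}

#' Calibrate the calorie response to a target aggregate energy change
#'
#' Solves `kappa` in `delta_kcal = kappa * energy_factor * r * mean_fs` so a
#' uniform reformulation reproduces an observed aggregate calorie reduction.
#' For example, a 20% reduction applied to a 56.2 g/day mean that is observed
#' to remove 60 kcal/day implies `kappa ~= 1.33` (sugars partially co-removed
#' with other energy rather than replaced).
#'
#' @param mean_free_sugars_g Baseline mean free-sugars intake, g/day.
#' @param target_delta_kcal Observed/target mean calorie reduction, kcal/day.
#' @param reduction_fraction Uniform reduction fraction `r`.
#' @param energy_factor kcal per gram of sugar (default 4).
#' @return The scalar calorie response `kappa`.
#' @export
calibrate_kappa <- function(mean_free_sugars_g, target_delta_kcal,
                            reduction_fraction,
                            energy_factor = ENERGY_KCAL_PER_G_SUGAR) {
  if (mean_free_sugars_g <= 0 || reduction_fraction <= 0) {
    stop_domain("calibrate_kappa: needs positive mean sugars and reduction")
  }
  target_delta_kcal / (energy_factor * reduction_fraction * mean_free_sugars_g)
}

#' Derive counterfactual exposure means from recall-based intake summaries
#'
#' Applies the per-cell relative energy change measured in an intake summary
#' (from [summarize_by_stratum()]) to a baseline exposure table, yielding the
#' counterfactual exposure table for the scenario pair. BMI and height columns
#' are carried over unchanged: the CRA engine recomputes the counterfactual
#' BMI from the energy change through the BMI pathway.
#'
#' @param exposure_baseline Baseline exposure tibble (see [readers]).
#' @param intake_summary Output of [summarize_by_stratum()] covering all cells.
#' @return A counterfactual exposure tibble.
#' @export
counterfactual_exposure <- function(exposure_baseline, intake_summary) {
  validate_exposure(exposure_baseline)
  wide <- intake_summary %>%
    select("scenario", "sex", "dri_group", "mean_kcal_day") %>%
    tidyr::pivot_wider(names_from = "scenario",
                       values_from = "mean_kcal_day")
  if (!all(c("baseline", "counterfactual") %in% names(wide))) {
    stop_coverage("intake_summary must contain both scenarios")
  }
  out <- exposure_baseline %>%
    inner_join(wide, by = c("sex", "dri_group")) %>%
    mutate(mean_kcal = .data$mean_kcal *
             .data$counterfactual / .data$baseline) %>%
    select(-"baseline", -"counterfactual")
  if (nrow(out) < nrow(exposure_baseline)) {
    stop_coverage("intake_summary does not cover every exposure cell")
  }
  out
}
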