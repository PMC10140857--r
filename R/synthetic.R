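# Synthetic-data generator: complete, internally consistent input bundles
# (demographics, mortality, exposure summaries, recall microdata, RR
# fixtures) with known ground truth, emulating the structure of national
# nutrition-survey and mortality-registry inputs. All default RR values and
# per-cause death apportionments are synthetic fixtures, not estimates from
# any study.

# Table of the thirteen modelled causes. Deaths targets are national-scale
# annual counts; group totals follow published Canadian 2019 registry totals,
# per-cause splits within cardiovascular and cancer are synthetic.
default_causes <- function() {
  tibble(
    cause_id = c("ihd", "stroke", "heart_failure", "hypertensive",
                 "diabetes", "pancreas", "colorectum", "breast",
                 "endometrium", "gallbladder", "kidney", "renal_failure",
                 "liver_disease"),
    name = c("Ischemic heart disease", "Cerebrovascular disease",
             "Heart failure", "Hypertensive disease", "Diabetes mellitus",
             "Pancreatic cancer", "Colorectal cancer", "Breast cancer",
             "Endometrial cancer", "Gallbladder cancer", "Kidney cancer",
             "Chronic renal failure", "Liver disease"),
    icd10 = c("I20-I25", "I60-I69", "I50", "I10-I15", "E11;E14", "C25",
              "C18-C20", "C50", "C54.1", "C23", "C64", "N18", "K70;K74"),
    group = c(rep("cardiovascular", 4), "diabetes", rep("cancer", 6),
              "renal", "liver")
  )
}

default_cause_targets <- function() {
  c(ihd = 29500, stroke = 13200, heart_failure = 7500, hypertensive = 5462,
    diabetes = 6536, pancreas = 5300, colorectum = 9500, breast = 3500,
    endometrium = 1200, gallbladder = 560, kidney = 2000,
    renal_failure = 2118, liver_disease = 3659)
}

# Synthetic RR fixtures: plausible per-5-kg/m^2 relative risks with log-scale
# SEs; breast and endometrial cancer are female-only.
default_rr <- function() {
  tibble(
    cause_id = default_causes()$cause_id,
    sex = c(rep("both", 7), "female", "female", rep("both", 4)),
    rr_per_unit = c(1.27, 1.18, 1.41, 1.49, 1.60, 1.10, 1.08, 1.08, 1.50,
                    1.25, 1.30, 1.35, 1.35),
    unit = 5,
    se_log_rr = c(0.02, 0.03, 0.05, 0.06, 0.07, 0.03, 0.02, 0.04, 0.06,
                  0.08, 0.04, 0.09, 0.10),
    ref_bmi = 21
  )
}

# Baseline exposure targets per sex x DRI group: survey-style mean daily
# energy intakes (with SEs), mean BMI and mean height for the adult
# population the model emulates.
default_exposure_targets <- function() {
  tibble(
    sex = rep(c("male", "female"), each = 4),
    dri_group = rep(DRI_GROUPS, 2),
    n_survey = c(882, 2077, 2246, 1246, 897, 2288, 2420, 1556),
    mean_kcal = c(2023, 2037, 2054, 2091, 1515, 1567, 1642, 1658),
    se_kcal = c(44, 26, 29, 26, 35, 22, 19, 24),
    mean_bmi = c(25.69, 28.41, 28.98, 27.96, 25.02, 26.72, 27.74, 27.35),
    mean_height_m = c(1.76, 1.76, 1.74, 1.72, 1.64, 1.63, 1.61, 1.58)
  )
}

# Adult population counts per sex and five-year band (national scale,
# thousands rounded): a plausible age pyramid.
default_population <- function() {
  lo <- seq(20, 85, by = 5)
  counts <- c(1250, 1300, 1300, 1250, 1200, 1200, 1300, 1350, 1300, 1100,
              900, 700, 500, 350) * 1000
  bind_rows(
    tibble(sex = "male", age_lo = lo, age_hi = c(lo[-1], NA),
           population = round(counts * 0.99)),
    tibble(sex = "female", age_lo = lo, age_hi = c(lo[-1], NA),
           population = round(counts * 1.01))
  )
}

# expected energy share and relative free-sugar density per food category
default_category_profile <- function() {
  tibble(
    category = FOOD_CATEGORIES,
    energy_share = c(0.09, 0.09, 0.13, 0.08, 0.05, 0.03, 0.03, 0.06, 0.24,
                     0.025, 0.045, 0.025, 0.035, 0.05),
    sugar_density = c(0.25, 0.45, 0.12, 0.12, 0.50, 0.03, 0.005, 0.35,
                      0.03, 0.15, 0.12, 0.04, 0.90, 0.02)
  )
}

#' Configuration for the synthetic input generator
#'
#' Defaults emulate the study conditions of a national adult population:
#' 2 sexes x 4 DRI groups with baseline mean intakes between roughly 1515 and
#' 2091 kcal/day, mean BMI between 25 and 29 kg/m^2, free sugars contributing
#' ~12.1% of total energy, a systematic 20% free-sugars reduction, and a
#' calorie response calibrated so the aggregate energy reduction is about
#' 60 kcal/day (3.2%).
#'
#' @param seed Integer RNG seed.
#' @param n_persons Number of synthetic recall respondents (default 5000).
#' @param exposure_targets Tibble of per-cell baseline targets (see defaults).
#' @param sd_bmi Population BMI standard deviation, kg/m^2 (default 5.0);
#'   `0` requests degenerate point-mass BMI distributions (for oracle tests).
#' @param target_pct_te Target cohort free-sugars share of energy, percent.
#' @param kcal_cv Coefficient of variation of per-person daily energy.
#' @param reduction_fraction Uniform free-sugars reduction `r`.
#' @param calorie_response Calorie response `kappa`; default calibrated via
#'   [calibrate_kappa()] to an aggregate 60 kcal/day reduction from a
#'   56.2 g/day mean at `r = 0.2`.
#' @param population Population tibble (sex x five-year bands).
#' @param causes Causes tibble.
#' @param cause_deaths Named vector of per-cause annual death totals.
#' @param rr RR fixture tibble.
#' @param category_profile Category energy shares and relative sugar
#'   densities for recall generation.
#' @param mortality_age_slope Log-linear age slope of mortality rates per
#'   year (default 0.085, doubling roughly every 8 years).
#' @param male_mortality_ratio Male:female rate ratio for non-sex-specific
#'   causes.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L, n_persons = 5000,
                         exposure_targets = default_exposure_targets(),
                         sd_bmi = 5.0, target_pct_te = 12.1, kcal_cv = 0.30,
                         reduction_fraction = 0.2,
                         calorie_response = calibrate_kappa(56.2, 60, 0.2),
                         population = default_population(),
                         causes = default_causes(),
                         cause_deaths = default_cause_targets(),
                         rr = default_rr(),
                         category_profile = default_category_profile(),
                         mortality_age_slope = 0.085,
                         male_mortality_ratio = 1.4) {
  cfg <- list(seed = as.integer(seed), n_persons = n_persons,
              exposure_targets = exposure_targets, sd_bmi = sd_bmi,
              target_pct_te = target_pct_te, kcal_cv = kcal_cv,
              reduction_fraction = reduction_fraction,
              calorie_response = calorie_response, population = population,
              causes = causes, cause_deaths = cause_deaths, rr = rr,
              category_profile = category_profile,
              mortality_age_slope = mortality_age_slope,
              male_mortality_ratio = male_mortality_ratio)
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  tg <- cfg$exposure_targets
  if (any(tg$mean_kcal < 800 | tg$mean_kcal > 4000)) {
    stop_domain("synth_config: mean_kcal targets outside 800-4000 kcal/day")
  }
  if (any(tg$mean_bmi < 15 | tg$mean_bmi > 45)) {
    stop_domain("synth_config: mean_bmi targets outside 15-45 kg/m^2")
  }
  if (cfg$sd_bmi < 0) stop_domain("synth_config: sd_bmi must be >= 0")
  if (any(cfg$cause_deaths < 0)) stop_domain("synth_config: negative deaths")
  if (cfg$reduction_fraction < 0 || cfg$reduction_fraction > 1) {
    stop_domain("synth_config: reduction_fraction outside [0, 1]")
  }
  if (cfg$calorie_response < 0) stop_domain("synth_config: kappa < 0")
  if (cfg$target_pct_te > 0 && scaled_densities(cfg)$infeasible) {
    stop_domain(paste(
      "synth_config: target_pct_te infeasible - scaled sugar density would",
      "exceed 95% of a category's energy"))
  }
  invisible(cfg)
}

weighted_density <- function(cfg) {
  prof <- cfg$category_profile
  sum(prof$energy_share * prof$sugar_density) / sum(prof$energy_share)
}

# scale category sugar densities so the expected cohort %TE equals the target
scaled_densities <- function(cfg) {
  prof <- cfg$category_profile
  lambda <- (cfg$target_pct_te / 100) / weighted_density(cfg)
  d <- prof$sugar_density * lambda
  list(density = d, infeasible = any(d > 0.95))
}

#' Generate synthetic recall microdata
#'
#' Each synthetic respondent receives a sex and age drawn from the population
#' age pyramid, a gamma-distributed daily energy total around the stratum
#' target, Dirichlet-distributed energy shares over the food categories, and
#' beta-distributed free-sugar energy shares per category whose expectation
#' is scaled so the cohort free-sugars share of energy matches
#' `target_pct_te`. A zero target yields zero free sugars everywhere.
#'
#' @param config A [synth_config()].
#' @return A recall tibble (see [readers] for the schema).
#' @export
generate_recalls <- function(config) {
  cfg <- config
  set.seed(cfg$seed + 1L)
  n <- cfg$n_persons
  if (n == 0) {
    return(tibble(person_id = character(), sex = character(), age = numeric(),
                  category = character(), free_sugars_g = numeric(),
                  energy_kcal = numeric()))
  }
  pop <- adult_filter(cfg$population)
  idx <- sample.int(nrow(pop), n, replace = TRUE, prob = pop$population)
  sex <- pop$sex[idx]
  hi <- ifelse(is.na(pop$age_hi[idx]), pop$age_lo[idx] + 5, pop$age_hi[idx])
  age <- floor(runif(n, pop$age_lo[idx], hi))
  dri <- band_to_dri(age, age + 1)

  tg <- cfg$exposure_targets
  cell <- match(paste(sex, dri), paste(tg$sex, tg$dri_group))
  mean_kcal <- tg$mean_kcal[cell]
  shape <- 1 / cfg$kcal_cv^2
  total_kcal <- rgamma(n, shape = shape, rate = shape / mean_kcal)

  prof <- cfg$category_profile
  k <- nrow(prof)
  conc <- 20 # Dirichlet concentration for per-person energy shares
  g <- matrix(rgamma(n * k, shape = rep(prof$energy_share * conc, each = n)),
              n, k)
  shares <- g / rowSums(g)

  dens <- scaled_densities(cfg)$density
  beta_conc <- 30
  if (cfg$target_pct_te == 0) {
    sugar_share <- matrix(0, n, k)
  } else {
    m <- pmin(pmax(dens, 1e-6), 0.95)
    sugar_share <- matrix(
      rbeta(n * k, shape1 = rep(m * beta_conc, each = n),
            shape2 = rep((1 - m) * beta_conc, each = n)), n, k)
  }

  energy <- shares * total_kcal
  tibble(
    person_id = sprintf("p%05d", rep(seq_len(n), k)),
    sex = rep(sex, k),
    age = rep(age, k),
    category = rep(prof$category, each = n),
    free_sugars_g = as.vector(sugar_share * energy / ENERGY_KCAL_PER_G_SUGAR),
    energy_kcal = as.vector(energy)
  ) %>% arrange(.data$person_id, .data$category)
}

# deaths per (sex, band, cause): target totals distributed over strata by a
# log-linear age gradient and a male:female ratio, then Poisson sampled.
generate_mortality <- function(cfg) {
  set.seed(cfg$seed + 2L)
  pop <- cfg$population
  mid <- band_midpoint(pop$age_lo, pop$age_hi)
  rows <- list()
  for (i in seq_len(nrow(cfg$causes))) {
    cid <- cfg$causes$cause_id[i]
    target <- cfg$cause_deaths[[cid]]
    rr_sex <- cfg$rr$sex[match(cid, cfg$rr$cause_id)]
    sex_mult <- if (rr_sex == "female") {
      ifelse(pop$sex == "female", 1, 0)
    } else if (rr_sex == "male") {
      ifelse(pop$sex == "male", 1, 0)
    } else {
      ifelse(pop$sex == "male", cfg$male_mortality_ratio, 1)
    }
    w <- pop$population * sex_mult * exp(cfg$mortality_age_slope * (mid - 60))
    lambda <- target * w / sum(w)
    rows[[i]] <- tibble(sex = pop$sex, age_lo = pop$age_lo,
                        age_hi = pop$age_hi, cause_id = cid,
                        deaths = rpois(nrow(pop), lambda))
  }
  bind_rows(rows) %>% arrange(.data$cause_id, .data$sex, .data$age_lo)
}

#' Generate a complete synthetic input bundle
#'
#' Builds every input the pipeline needs: population, mortality, causes,
#' baseline and counterfactual exposure tables, RR fixtures, recall microdata
#' and the reformulation rules. The baseline exposure means are the
#' configured targets; the counterfactual energy means apply the analytic
#' expected reduction `kappa * r * pct_te/100 * mean_kcal` per cell (the
#' recall microdata reproduce the same reduction empirically, which is what
#' the scenario-builder tests check). A `sd_bmi` of 0 is written as a tiny
#' positive spread so the bundle still validates while the engine treats the
#' distributions as point masses.
#'
#' @param config A [synth_config()].
#' @param dir Optional directory; when given, all CSVs (bundle plus
#'   `recalls.csv` and `rules.csv`) are written there.
#' @return A list: the validated `bundle` (class `cra_bundle`), `recalls`,
#'   `rules`, and `paths` when `dir` was given.
#' @export
generate_bundle <- function(config, dir = NULL) {
  cfg <- config
  tg <- cfg$exposure_targets
  sd_bmi <- if (cfg$sd_bmi == 0) 1e-9 else cfg$sd_bmi
  exposure_base <- tibble(
    sex = tg$sex, dri_group = tg$dri_group, mean_kcal = tg$mean_kcal,
    se_kcal = tg$se_kcal, mean_bmi = tg$mean_bmi, sd_bmi = sd_bmi,
    mean_height_m = tg$mean_height_m
  )
  delta_frac <- cfg$calorie_response * cfg$reduction_fraction *
    cfg$target_pct_te / 100
  exposure_cf <- exposure_base %>%
    mutate(mean_kcal = .data$mean_kcal * (1 - delta_frac))

  mortality <- generate_mortality(cfg)
  recalls <- generate_recalls(cfg)
  rules <- uniform_rules(cfg$reduction_fraction, cfg$calorie_response)

  bundle <- as_bundle(cfg$population, mortality, cfg$causes, exposure_base,
                      exposure_cf, cfg$rr)
  out <- list(bundle = bundle, recalls = recalls, rules = rules)
  if (!is.null(dir)) {
    paths <- write_bundle(bundle, dir)
    paths <- c(paths, recalls = file.path(dir, "recalls.csv"),
               rules = file.path(dir, "rules.csv"))
    readr::write_csv(recalls, paths[["recalls"]])
    readr::write_csv(rules, paths[["rules"]])
    out$paths <- paths
  }
  out
}

#' Closed-form deaths averted for degenerate synthetic configurations
#'
#' Oracle for end-to-end parameter recovery: with point-mass BMI
#' distributions (`sd_bmi = 0`) the PIF for each cell is
#' `1 - RR(bmi') / RR(bmi)` exactly, so deaths averted are
#' `sum(deaths * (1 - RR(bmi')/RR(bmi)))` over mortality cells - no
#' quadrature involved. The counterfactual BMI uses the same energy-balance
#' parameters as the pipeline.
#'
#' @param config A [synth_config()] with `sd_bmi = 0`.
#' @param params An [energy_balance_params()].
#' @return List with `total` and `by_cause` (tibble `cause_id`, `averted`).
#' @export
analytic_truth <- function(config, params = energy_balance_params()) {
  cfg <- config
  if (cfg$sd_bmi != 0) {
    abort("analytic_truth: oracle requires a degenerate config (sd_bmi = 0)",
          class = "sugarcra_oracle_error")
  }
  gen <- generate_bundle(cfg)
  bundle <- gen$bundle
  cells <- bundle$scenarios$baseline %>%
    inner_join(select(bundle$scenarios$counterfactual, "sex", "dri_group",
                      mean_kcal_cf = "mean_kcal"),
               by = c("sex", "dri_group"))
  cells$bmi_cf <- counterfactual_mean_bmi(
    cells, cells$mean_kcal_cf - cells$mean_kcal, params)

  mort <- adult_filter(bundle$mortality)
  mort$dri_group <- band_to_dri(mort$age_lo, mort$age_hi)
  specs <- expand_rr(bundle$rr)
  mort <- mort %>%
    inner_join(select(cells, "sex", "dri_group", "mean_bmi", "bmi_cf"),
               by = c("sex", "dri_group")) %>%
    inner_join(specs, by = c("cause_id", "sex"))
  rr0 <- exp(log(mort$rr_per_unit) / mort$unit *
               pmax(0, mort$mean_bmi - mort$ref_bmi))
  rr1 <- exp(log(mort$rr_per_unit) / mort$unit *
               pmax(0, mort$bmi_cf - mort$ref_bmi))
  mort$averted <- mort$deaths * (1 - rr1 / rr0)
  list(
    total = sum(mort$averted),
    by_cause = mort %>% group_by(.data$cause_id) %>%
      summarise(averted = sum(.data$averted), .groups = "drop")
  )
}
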