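# Energy-intake -> BMI pathway: steady-state inversion of a Schofield-type
# linear resting-energy-expenditure relation scaled by a physical activity
# level, plus lognormal BMI distribution utilities.

# Schofield adult BMR coefficients, MJ/day: BMR = a * weight_kg + b.
default_eb_coefficients <- function() {
  tibble(
    sex = rep(c("male", "female"), each = 3),
    age_lo = rep(c(19, 30, 60), 2),
    age_hi = rep(c(30, 60, NA), 2),
    a_mj_per_kg = c(0.063, 0.048, 0.049, 0.062, 0.034, 0.038),
    b_mj = c(2.896, 3.653, 2.459, 2.036, 3.538, 2.755)
  )
}

#' Energy-balance parameters for the intake -> weight linkage
#'
#' Total energy expenditure is modelled as `PAL * (a * W + b)` MJ/day, a
#' Schofield-type linear basal-metabolic-rate relation scaled by a physical
#' activity level (PAL). At steady state, intake equals expenditure, so weight
#' is recovered from intake by inverting the relation
#' (see [weight_from_energy()]). The default coefficient table holds the
#' Schofield adult coefficients per sex and age range; both the table and the
#' PAL are user-replaceable, and a `"proportional"` fallback strategy
#' (`BMI' = BMI * E'/E`) is available for sensitivity checks.
#'
#' @param pal Physical activity level, dimensionless multiplier of BMR
#'   (default 1.6, a typical light-activity adult value).
#' @param coefficients Tibble `sex, age_lo, age_hi, a_mj_per_kg, b_mj`; age
#'   ranges must partition the adult range per sex (`age_hi = NA` open-ended).
#' @param kcal_per_mj kcal per megajoule (fixed physical constant, 239.006).
#' @param strategy `"steady_state"` (default) or `"proportional"`.
#' @return An `energy_balance_params` object.
#' @export
energy_balance_params <- function(pal = 1.6, coefficients = NULL,
                                  kcal_per_mj = KCAL_PER_MJ,
                                  strategy = c("steady_state", "proportional")) {
  strategy <- match.arg(strategy)
  if (pal <= 0) stop_domain("energy_balance_params: pal must be > 0")
  if (is.null(coefficients)) coefficients <- default_eb_coefficients()
  check_columns(coefficients, c("sex", "age_lo", "age_hi", "a_mj_per_kg",
                                "b_mj"), "energy_balance coefficients")
  if (any(coefficients$a_mj_per_kg <= 0)) {
    stop_domain("energy_balance_params: slope a must be > 0 in every row")
  }
  for (s in unique(coefficients$sex)) {
    rows <- coefficients[coefficients$sex == s, ]
    rows <- rows[order(rows$age_lo), ]
    hi <- ifelse(is.na(rows$age_hi), Inf, rows$age_hi)
    if (any(hi[-length(hi)] != rows$age_lo[-1]) || !is.infinite(hi[nrow(rows)])) {
      stop_domain(sprintf(
        "energy_balance_params: age ranges for sex %s must partition the adult range", s))
    }
  }
  structure(list(pal = pal, coefficients = coefficients,
                 kcal_per_mj = kcal_per_mj, strategy = strategy),
            class = "energy_balance_params")
}

#' Read energy-balance parameters from a YAML file
#'
#' Expected keys: `pal`, `strategy`, and `coefficients` (a list of rows with
#' `sex, age_lo, age_hi, a_mj_per_kg, b_mj`; `age_hi: null` marks the open
#' range).
#'
#' @param path YAML file path.
#' @return An [energy_balance_params()] object.
#' @export
read_energy_balance <- function(path) {
  raw <- yaml::read_yaml(path)
  coef <- if (!is.null(raw$coefficients)) {
    bind_rows(lapply(raw$coefficients, function(row) {
      tibble(sex = row$sex, age_lo = row$age_lo,
             age_hi = if (is.null(row$age_hi)) NA_real_ else row$age_hi,
             a_mj_per_kg = row$a_mj_per_kg, b_mj = row$b_mj)
    }))
  }
  energy_balance_params(
    pal = raw$pal %||% 1.6,
    coefficients = coef,
    strategy = raw$strategy %||% "steady_state"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

eb_lookup <- function(params, sex, age) {
  coef <- params$coefficients
  a <- numeric(length(sex))
  b <- numeric(length(sex))
  for (s in unique(sex)) {
    rows <- coef[coef$sex == s, ]
    rows <- rows[order(rows$age_lo), ]
    i <- findInterval(age[sex == s], rows$age_lo)
    if (any(i < 1)) {
      stop_domain(sprintf("no energy-balance coefficients for sex %s below age %s",
                          s, min(rows$age_lo)))
    }
    a[sex == s] <- rows$a_mj_per_kg[i]
    b[sex == s] <- rows$b_mj[i]
  }
  list(a = a, b = b)
}

#' Steady-state body weight implied by a daily energy intake
#'
#' Inverts `E = PAL * (a * W + b)`: `W = (E_MJ / PAL - b) / a`, with intake
#' converted from kcal/day to MJ/day. The inverse of [energy_of_weight()].
#' Note that absolute weights inherit any reporting bias in the intake data;
#' the CRA pipeline only uses weight *differences*, for which the intercept
#' cancels.
#'
#' @param energy_kcal_day Daily energy intake, kcal.
#' @param sex,age Stratum identifiers for the coefficient lookup.
#' @param params An [energy_balance_params()] object.
#' @return Body weight in kg.
#' @export
weight_from_energy <- function(energy_kcal_day, sex, age,
                               params = energy_balance_params()) {
  ab <- eb_lookup(params, sex, age)
  e_mj <- energy_kcal_day / params$kcal_per_mj
  w <- (e_mj / params$pal - ab$b) / ab$a
  if (any(w <= 0)) {
    bad <- which(w <= 0)[1]
    stop_domain(sprintf(
      "weight_from_energy: no positive steady-state weight for stratum (%s, age %s): intake %.0f kcal/day is below the modelled expenditure intercept",
      sex[bad], age[bad], energy_kcal_day[bad]))
  }
  w
}

#' Daily energy intake that sustains a body weight at steady state
#'
#' Forward relation `E = PAL * (a * W + b)`, returned in kcal/day.
#'
#' @param weight_kg Body weight, kg.
#' @inheritParams weight_from_energy
#' @export
energy_of_weight <- function(weight_kg, sex, age,
                             params = energy_balance_params()) {
  ab <- eb_lookup(params, sex, age)
  params$pal * (ab$a * weight_kg + ab$b) * params$kcal_per_mj
}

#' Counterfactual mean BMI after a change in mean energy intake
#'
#' Under the steady-state strategy, a change of `delta_kcal` in daily intake
#' changes weight by `W(E + delta) - W(E)` and BMI by that difference divided
#' by squared height. Under the proportional strategy,
#' `BMI' = BMI * (E + delta) / E`. An energy reduction always lowers BMI.
#'
#' @param exposure Exposure tibble rows (columns `sex`, `dri_group`,
#'   `mean_kcal`, `mean_bmi`, `mean_height_m`).
#' @param delta_kcal Change in mean daily intake, kcal (vector recycled over
#'   rows; negative = reduction).
#' @param params An [energy_balance_params()] object.
#' @return Numeric vector of counterfactual mean BMI, one per exposure row.
#' @export
counterfactual_mean_bmi <- function(exposure, delta_kcal,
                                    params = energy_balance_params()) {
  if (any(exposure$mean_height_m <= 0)) {
    stop_domain("counterfactual_mean_bmi: heights must be positive")
  }
  age <- dri_reference_age(exposure$dri_group)
  if (params$strategy == "proportional") {
    return(exposure$mean_bmi * (exposure$mean_kcal + delta_kcal) /
             exposure$mean_kcal)
  }
  w0 <- weight_from_energy(exposure$mean_kcal, exposure$sex, age, params)
  w1 <- weight_from_energy(exposure$mean_kcal + delta_kcal, exposure$sex, age,
                           params)
  exposure$mean_bmi + (w1 - w0) / exposure$mean_height_m^2
}

# ---------------------------------------------------------------------------
# lognormal BMI distributions

#' Lognormal BMI distribution from its mean and SD
#'
#' Moment matching: `sigma^2 = log(1 + sd^2/mean^2)`,
#' `mu = log(mean) - sigma^2/2`. The lognormal family (right-skewed, positive
#' support) is the package's BMI distribution model.
#'
#' @param mean,sd Population mean and standard deviation of BMI (kg/m^2),
#'   both positive.
#' @return A `bmi_distribution` object with fields `mu` and `sigma`.
#' @export
lognormal_from_moments <- function(mean, sd) {
  if (mean <= 0 || sd <= 0) {
    stop_domain("lognormal_from_moments: mean and sd must be positive")
  }
  sigma2 <- log(1 + sd^2 / mean^2)
  structure(list(mu = log(mean) - sigma2 / 2, sigma = sqrt(sigma2)),
            class = "bmi_distribution")
}

#' Analytic mean and SD of a `bmi_distribution`
#' @param dist A `bmi_distribution`.
#' @return List with `mean` and `sd`.
#' @export
distribution_moments <- function(dist) {
  m <- exp(dist$mu + dist$sigma^2 / 2)
  list(mean = m, sd = m * sqrt(exp(dist$sigma^2) - 1))
}

#' Shift a BMI distribution to a new mean, preserving relative spread
#'
#' Multiplies the distribution by `new_mean / old_mean`: `sigma` (and hence
#' the coefficient of variation) is unchanged and `mu` shifts by
#' `log(new_mean / old_mean)`, so the shifted mean equals the target exactly.
#'
#' @param dist A `bmi_distribution`.
#' @param new_mean Target mean (positive).
#' @return The shifted `bmi_distribution`.
#' @export
shift_distribution <- function(dist, new_mean) {
  if (new_mean <= 0) stop_domain("shift_distribution: new_mean must be > 0")
  old_mean <- distribution_moments(dist)$mean
  structure(list(mu = dist$mu + log(new_mean / old_mean), sigma = dist$sigma),
            class = "bmi_distribution")
}

#' @export
print.bmi_distribution <- function(x, ...) {
  m <- distribution_moments(x)
  cat(sprintf("<bmi_distribution lognormal mu=%.4f sigma=%.4f (mean %.2f, sd %.2f)>\n",
              x$mu, x$sigma, m$mean, m$sd))
  invisible(x)
}
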