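# In-code fixtures: a minimal two-cause bundle and small builders used across
# the suite. Everything is generated programmatically; no files are read.

tiny_causes <- function() {
  tibble::tibble(
    cause_id = c("ihd", "diabetes"),
    name = c("Ischemic heart disease", "Diabetes mellitus"),
    icd10 = c("I20-I25", "E11;E14"),
    group = c("cardiovascular", "diabetes")
  )
}

tiny_population <- function() {
  tibble::tibble(
    sex = rep(c("male", "female"), each = 3),
    age_lo = rep(c(20, 50, 75), 2),
    age_hi = rep(c(25, 55, NA), 2),
    population = c(100000, 90000, 40000, 110000, 95000, 50000)
  )
}

tiny_mortality <- function() {
  tibble::tibble(
    sex = rep(rep(c("male", "female"), each = 3), 2),
    age_lo = rep(c(20, 50, 75), 4),
    age_hi = rep(c(25, 55, NA), 4),
    cause_id = rep(c("ihd", "diabetes"), each = 6),
    deaths = c(10, 400, 1200, 5, 250, 1100, 4, 120, 500, 3, 100, 450)
  )
}

tiny_exposure <- function(mean_kcal_shift = 0) {
  grid <- tidyr::expand_grid(sex = c("male", "female"),
                             dri_group = sugarcra::DRI_GROUPS)
  tibble::tibble(
    sex = grid$sex,
    dri_group = grid$dri_group,
    mean_kcal = rep(c(2050, 1600), each = 4) + mean_kcal_shift,
    se_kcal = 25,
    mean_bmi = rep(c(28.5, 27.0), each = 4),
    sd_bmi = 4.8,
    mean_height_m = rep(c(1.75, 1.62), each = 4)
  )
}

tiny_rr <- function(se_log_rr = 0.05) {
  tibble::tibble(
    cause_id = c("ihd", "diabetes"),
    sex = "both",
    rr_per_unit = c(1.27, 1.60),
    unit = 5,
    se_log_rr = se_log_rr,
    ref_bmi = 21
  )
}

tiny_bundle <- function(delta_kcal = -60, se_log_rr = 0.05) {
  as_bundle(
    population = tiny_population(),
    mortality = tiny_mortality(),
    causes = tiny_causes(),
    exposure_baseline = tiny_exposure(),
    exposure_counterfactual = tiny_exposure(mean_kcal_shift = delta_kcal),
    rr = tiny_rr(se_log_rr)
  )
}

# brute-force Monte Carlo estimate of E[RR] over a truncated lognormal,
# independent of the quadrature implementation
brute_force_mean_rr <- function(dist, spec, n = 1e6, seed = 99) {
  set.seed(seed)
  x <- stats::rlnorm(n, dist$mu, dist$sigma)
  x <- x[x >= 10 & x <= 80]
  mean(exp(log(spec$rr_per_unit) / spec$unit * pmax(0, x - spec$ref_bmi)))
}

extdata <- function(...) {
  system.file("extdata", "canada2019", ..., package = "sugarcra",
              mustWork = TRUE)
}
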