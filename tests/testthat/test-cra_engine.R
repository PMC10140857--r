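# Relative risks, potential impact fractions, attribution and aggregation.

spec_12 <- list(cause_id = "ihd", sex = "both", rr_per_unit = 1.2, unit = 5,
                se_log_rr = 0, ref_bmi = 21)

test_that("relative_risk is log-linear above the reference and flat below", {
  expect_equal(relative_risk(21, spec_12), 1)
  expect_equal(relative_risk(26, spec_12), 1.2)
  expect_equal(relative_risk(15, spec_12), 1)
  expect_equal(relative_risk(31, spec_12), 1.2^2, tolerance = 1e-12)
  # continuous and non-decreasing
  b <- seq(15, 45, by = 0.25)
  rr <- relative_risk(b, spec_12)
  expect_true(all(diff(rr) >= 0))
})

test_that("pif vanishes for identical scenarios and flat relative risks", {
  d <- lognormal_from_moments(28, 5)
  expect_identical(pif(d, d, spec_12), 0)
  flat <- modifyList(spec_12, list(rr_per_unit = 1))
  d2 <- shift_distribution(d, 26)
  expect_equal(pif(d, d2, flat), 0)
})

test_that("quadrature pif converges to the point-mass closed form", {
  closed <- 1 - 1.2^(-0.4) # point masses at 30 and 28
  for (sd in c(1e-3, 1e-6, 1e-10)) {
    d1 <- lognormal_from_moments(30, sd)
    d2 <- lognormal_from_moments(28, sd)
    expect_equal(pif(d1, d2, spec_12), closed, tolerance = 1e-6)
  }
})

test_that("quadrature pif agrees with brute-force Monte Carlo integration", {
  cases <- list(
    list(mean = 28, sd = 5, new = 27, spec = spec_12),
    list(mean = 26, sd = 4, new = 25.2,
         spec = modifyList(spec_12, list(rr_per_unit = 1.6))),
    list(mean = 31, sd = 6, new = 30,
         spec = modifyList(spec_12, list(ref_bmi = 25)))
  )
  for (cs in cases) {
    d1 <- lognormal_from_moments(cs$mean, cs$sd)
    d2 <- shift_distribution(d1, cs$new)
    p_quad <- pif(d1, d2, cs$spec)
    p_mc <- 1 - brute_force_mean_rr(d2, cs$spec) /
      brute_force_mean_rr(d1, cs$spec)
    # 1e6 samples: agreement to ~3 Monte Carlo standard errors
    expect_lt(abs(p_quad - p_mc), 1e-3)
  }
})

test_that("Gauss-Legendre node evaluation matches adaptive quadrature", {
  # the fast Monte Carlo path and the point-estimate path must agree
  set.seed(42)
  for (i in 1:20) {
    mean <- runif(1, 24, 32)
    d1 <- lognormal_from_moments(mean, runif(1, 2, 7))
    d2 <- shift_distribution(d1, mean - runif(1, 0.2, 2))
    spec <- modifyList(spec_12, list(rr_per_unit = runif(1, 1.05, 1.8),
                                     ref_bmi = runif(1, 18, 25)))
    beta <- log(spec$rr_per_unit) / spec$unit
    n1 <- sugarcra:::rr_nodes(d1, spec$ref_bmi)
    n2 <- sugarcra:::rr_nodes(d2, spec$ref_bmi)
    p_nodes <- 1 - sugarcra:::mean_rr_beta(n2, beta) /
      sugarcra:::mean_rr_beta(n1, beta)
    expect_equal(p_nodes, pif(d1, d2, spec), tolerance = 1e-8)
  }
})

test_that("deaths_averted multiplies PIFs onto mortality cells", {
  mort <- tibble::tibble(sex = "male", age_lo = c(50, 75), age_hi = c(55, NA),
                         cause_id = "ihd", deaths = c(1000, 2000))
  pifs <- tibble::tibble(cause_id = "ihd", sex = "male",
                         dri_group = c("51-70", "71+"), pif = c(0.05, 0))
  out <- deaths_averted(mort, pifs)
  expect_equal(out$deaths_averted, c(50, 0))
  # negative PIF: negative deaths averted, not clamped
  pifs$pif <- c(-0.02, -0.02)
  expect_equal(deaths_averted(mort, pifs)$deaths_averted, c(-20, -40))
  # PIF for a cause with no mortality records is a reference error
  pifs$cause_id <- "stroke"
  expect_error(deaths_averted(mort, pifs), class = "sugarcra_reference_error")
})

test_that("combine_pathways multiplies complementary fractions", {
  expect_equal(combine_pathways(0.3), 0.3)
  expect_equal(combine_pathways(c(0, 0)), 0)
  expect_equal(combine_pathways(c(0.1, 0.2)), 0.28)
  expect_error(combine_pathways(c(0.5, 1)), class = "sugarcra_domain_error")
})

test_that("aggregation conserves mass and computes coherent shares", {
  b <- tiny_bundle(delta_kcal = -60, se_log_rr = 0)
  res <- run_cra(b)
  s <- res$summary
  for (sx in c("male", "female", "both")) {
    tot <- s$averted[s$level == "total" & s$sex == sx]
    # disjoint single-pathway causes: cause sums equal the total
    expect_equal(sum(s$averted[s$level == "cause" & s$sex == sx]), tot,
                 tolerance = 1e-9)
    # per-cause shares sum to 100
    expect_equal(sum(s$share_of_total[s$level == "cause" & s$sex == sx]),
                 100, tolerance = 0.2)
    # under-75 subtotal cannot exceed the total
    expect_lte(s$averted[s$level == "under_75" & s$sex == sx], tot)
  }
  # deaths_averted = pif * deaths cellwise
  cr <- res$cell_results
  expect_equal(cr$deaths_averted, cr$pif * cr$deaths, tolerance = 1e-12)
  # pct_of_actual consistent with raw tables
  tot_row <- s[s$level == "total" & s$sex == "both", ]
  expect_equal(tot_row$pct_of_actual,
               100 * tot_row$averted / sum(b$mortality$deaths),
               tolerance = 1e-9)
})

test_that("pif is positive for real reductions and grows with the cut", {
  # strictly positive PIF whenever the counterfactual mean is lower and
  # rr_per_unit > 1; deaths averted monotone in the calorie reduction
  totals <- vapply(c(-20, -60, -120, -200), function(dk) {
    res <- run_cra(tiny_bundle(delta_kcal = dk, se_log_rr = 0))
    expect_true(all(res$pif_table$pif > 0))
    by_cause <- res$summary
    by_cause$averted[by_cause$level == "total" & by_cause$sex == "both"]
  }, numeric(1))
  expect_true(all(diff(totals) > 0))
})

test_that("sex-specific relative risks only attribute within that sex", {
  rr <- tiny_rr(0)
  rr$sex <- c("both", "female")
  b <- as_bundle(tiny_population(), tiny_mortality(), tiny_causes(),
                 tiny_exposure(), tiny_exposure(-60), rr)
  res <- run_cra(b)
  male_diab <- res$summary[res$summary$id == "diabetes" &
                             res$summary$sex == "male", ]
  expect_equal(nrow(male_diab), 0) # no male diabetes attribution rows
  both_diab <- res$summary$averted[res$summary$level == "cause" &
                                     res$summary$id == "diabetes" &
                                     res$summary$sex == "both"]
  female_diab <- res$summary$averted[res$summary$level == "cause" &
                                       res$summary$id == "diabetes" &
                                       res$summary$sex == "female"]
  expect_equal(both_diab, female_diab, tolerance = 1e-12)
})
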