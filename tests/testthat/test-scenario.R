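# Reformulation scenario builder: %TE arithmetic, per-record rules,
# per-person totals, stratum summaries, and the calorie-response calibration.

one_record <- function(fs, kcal, category = "beverages") {
  tibble::tibble(person_id = "p1", sex = "female", age = 40,
                 category = category, free_sugars_g = fs, energy_kcal = kcal)
}

test_that("percent_te computes the share of energy from free sugars", {
  expect_equal(round(percent_te(56.2, 1858), 1), 12.1)
  expect_equal(percent_te(0, 2000), 0)
  expect_equal(percent_te(25, 2000), 5)
  expect_error(percent_te(10, 0), class = "sugarcra_domain_error")
})

test_that("apply_rule reformulates records with the clamped energy response", {
  out <- apply_rule(one_record(10, 200), uniform_rules(0.2, 1))
  expect_equal(out$free_sugars_g, 8)
  expect_equal(out$energy_kcal, 192)
  # r = 0 is the identity
  rec <- one_record(12.5, 300)
  expect_equal(apply_rule(rec, uniform_rules(0)), rec)
  # category without a rule is untouched
  out <- apply_rule(one_record(10, 200, "soups"),
                    uniform_rules(0.5, 1, categories = "beverages"))
  expect_equal(out$free_sugars_g, 10)
  # energy never drops below the remaining sugar energy (degenerate kappa)
  out <- apply_rule(one_record(40, 170), uniform_rules(0.2, 10))
  expect_equal(out$energy_kcal, 4 * out$free_sugars_g)
  # zero-energy records pass through unchanged
  rec0 <- one_record(0, 0)
  expect_equal(apply_rule(rec0, uniform_rules(0.9, 5)), rec0)
})

test_that("a uniform 20% reduction takes a 56.2 g/day mean to 44.9 g/day", {
  out <- apply_rule(one_record(56.2, 1858), uniform_rules(0.2))
  expect_equal(out$free_sugars_g, 44.96)
})

test_that("build_counterfactual sums per-person records in both scenarios", {
  recs <- tibble::tibble(
    person_id = "p1", sex = "male", age = 30,
    category = c("beverages", "bakery"),
    free_sugars_g = c(10, 5), energy_kcal = c(200, 300)
  )
  out <- build_counterfactual(recs, uniform_rules(0.2, 1))
  expect_equal(out$free_sugars_g_base, 15)
  expect_equal(out$kcal_base, 500)
  expect_equal(out$free_sugars_g_cf, 12)
  expect_equal(out$kcal_cf, 488)
  # empty record set -> empty totals
  expect_equal(nrow(build_counterfactual(recs[0, ], uniform_rules(0.2))), 0)
  # all-zero rules -> counterfactual equals baseline
  out0 <- build_counterfactual(recs, uniform_rules(0))
  expect_equal(out0$free_sugars_g_cf, out0$free_sugars_g_base)
  expect_equal(out0$kcal_cf, out0$kcal_base)
})

test_that("reformulation is monotone, conservative, and never adds sugars", {
  cfg <- synth_config(seed = 11, n_persons = 300)
  recs <- generate_recalls(cfg)
  # scenario consistency: per-record counterfactual sugars <= baseline
  for (r in c(0.1, 0.5, 1)) {
    out <- apply_rule(recs, uniform_rules(r, 1.2))
    expect_true(all(out$free_sugars_g <= recs$free_sugars_g + 1e-12))
  }
  # monotonicity: larger r never increases mean counterfactual kcal
  kcals <- vapply(c(0, 0.2, 0.4, 0.8, 1), function(r) {
    mean(build_counterfactual(recs, uniform_rules(r, 1))$kcal_cf)
  }, numeric(1))
  expect_true(all(diff(kcals) <= 1e-9))
  # conservation at kappa = 1 (no clamping at these intakes): energy removed
  # equals 4 kcal per gram of sugar removed
  out <- build_counterfactual(recs, uniform_rules(0.2, 1))
  removed_kcal <- sum(out$kcal_base - out$kcal_cf)
  removed_g <- sum(out$free_sugars_g_base - out$free_sugars_g_cf)
  expect_equal(removed_kcal, 4 * removed_g, tolerance = 1e-9)
})

test_that("summarize_by_stratum takes equal-weight means per sex x DRI cell", {
  recs <- tibble::tibble(
    person_id = c("a", "b"), sex = "male", age = c(35, 44),
    category = "mixed_dishes", free_sugars_g = c(20, 30),
    energy_kcal = c(1800, 1900)
  )
  out <- suppressWarnings(
    summarize_by_stratum(build_counterfactual(recs, uniform_rules(0)))
  )
  row <- out[out$scenario == "baseline" & out$dri_group == "31-50", ]
  expect_equal(row$mean_kcal_day, 1850)
  expect_equal(row$mean_free_sugars_g_day, 25)
  expect_equal(row$pct_te_free_sugars, percent_te(25, 1850))
  # single person: mean equals that person's totals
  single <- suppressWarnings(
    summarize_by_stratum(build_counterfactual(recs[1, ], uniform_rules(0)))
  )
  expect_equal(single$mean_kcal_day[1], 1800)
  # empty cells produce a warning
  expect_warning(
    summarize_by_stratum(build_counterfactual(recs, uniform_rules(0))),
    "no persons"
  )
})

test_that("stratum summaries recover the generator's configured %TE", {
  cfg <- synth_config(seed = 5, n_persons = 5000)
  recs <- generate_recalls(cfg)
  out <- summarize_by_stratum(build_counterfactual(recs, uniform_rules(0)))
  base <- out[out$scenario == "baseline", ]
  cohort_te <- sum(base$mean_free_sugars_g_day * base$n_persons) * 4 /
    sum(base$mean_kcal_day * base$n_persons) * 100
  expect_equal(cohort_te, cfg$target_pct_te, tolerance = 0.05)
})

test_that("calibrated kappa reproduces the published aggregate energy change", {
  kappa <- calibrate_kappa(56.2, 60, 0.2)
  expect_equal(kappa, 60 / (4 * 0.2 * 56.2))
  out <- apply_rule(one_record(56.2, 1858), uniform_rules(0.2, kappa))
  expect_equal(out$free_sugars_g, 44.96)
  expect_equal(out$energy_kcal, 1798)
})

test_that("counterfactual_exposure rescales baseline energy per cell", {
  cfg <- synth_config(seed = 3, n_persons = 2000)
  gen <- generate_bundle(cfg)
  totals <- build_counterfactual(gen$recalls, gen$rules)
  intakes <- summarize_by_stratum(totals)
  cf <- counterfactual_exposure(gen$bundle$scenarios$baseline, intakes)
  expect_equal(nrow(cf), 8)
  # relative change matches the recall-level relative change per cell
  wide <- tidyr::pivot_wider(
    dplyr::select(intakes, scenario, sex, dri_group, mean_kcal_day),
    names_from = scenario, values_from = mean_kcal_day)
  joined <- dplyr::inner_join(
    dplyr::inner_join(cf, gen$bundle$scenarios$baseline,
                      by = c("sex", "dri_group"), suffix = c("_cf", "_base")),
    wide, by = c("sex", "dri_group"))
  expect_equal(joined$mean_kcal_cf / joined$mean_kcal_base,
               joined$counterfactual / joined$baseline, tolerance = 1e-12)
})
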