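# Monte Carlo propagation of relative-risk uncertainty.

test_that("sample_rr draws lognormal RRs around the point estimate", {
  spec0 <- list(rr_per_unit = 1.3, se_log_rr = 0)
  expect_equal(sample_rr(spec0, 10), rep(1.3, 10))
  spec <- list(rr_per_unit = 1.3, se_log_rr = 0.1)
  set.seed(1); a <- sample_rr(spec, 1000)
  set.seed(1); b <- sample_rr(spec, 1000)
  expect_identical(a, b)
  # law of large numbers on the log scale
  set.seed(2)
  draws <- sample_rr(spec, 1e5)
  expect_equal(mean(log(draws)), log(1.3),
               tolerance = 4 * 0.1 / sqrt(1e5) / log(1.3))
})

test_that("percentile_interval interpolates order statistics", {
  # brute-force oracle: position p*(n-1)+1 between sorted values
  expect_equal(unname(percentile_interval(1:100)), c(3.475, 97.525))
  expect_equal(unname(percentile_interval(rep(7, 50))), c(7, 7))
  expect_equal(unname(percentile_interval(3.2)), c(3.2, 3.2))
  expect_error(percentile_interval(numeric(0)),
               class = "sugarcra_domain_error")
  # order invariance
  set.seed(3)
  x <- rnorm(333)
  expect_equal(percentile_interval(x), percentile_interval(sample(x)))
})

test_that("run_mc is deterministic and degenerates correctly at zero SE", {
  b0 <- tiny_bundle(se_log_rr = 0)
  cfg <- mc_config(iterations = 200, seed = 7)
  res0 <- run_mc(b0, cfg)
  expect_equal(res0$mc_mean, res0$point, tolerance = 1e-12)
  expect_equal(res0$ui_lo, res0$point, tolerance = 1e-12)
  expect_equal(res0$ui_hi - res0$ui_lo, rep(0, nrow(res0)))
  # same seed twice: identical results
  b <- tiny_bundle(se_log_rr = 0.08)
  r1 <- run_mc(b, cfg)
  r2 <- run_mc(b, cfg)
  expect_identical(r1, r2)
  # different seed: different draws
  r3 <- run_mc(b, mc_config(iterations = 200, seed = 8))
  expect_false(identical(r1$ui_lo, r3$ui_lo))
})

test_that("uncertainty interval width is non-decreasing in se_log_rr", {
  cfg <- mc_config(iterations = 500, seed = 11)
  widths <- vapply(c(0.02, 0.15), function(se) {
    res <- run_mc(tiny_bundle(se_log_rr = se), cfg)
    tot <- res[res$level == "total" & res$sex == "both", ]
    tot$ui_hi - tot$ui_lo
  }, numeric(1))
  expect_lt(widths[1], widths[2])
})

test_that("the linear MC fast path matches naive per-draw recomputation", {
  # dual route: rerun the deterministic pipeline with the RR values drawn at
  # each iteration and compare the totals draw for draw
  b <- tiny_bundle(se_log_rr = 0.1)
  cfg <- mc_config(iterations = 25, seed = 13, keep_draws = TRUE)
  res <- run_mc(b, cfg)
  draws <- attr(res, "draws")
  # replicate the draw sequence: one stream per RR row, ordered by cause, sex
  rr_ord <- dplyr::arrange(b$rr, cause_id, sex)
  set.seed(cfg$seed)
  rr_draws <- matrix(0, cfg$iterations, nrow(rr_ord))
  for (i in seq_len(nrow(rr_ord))) {
    rr_draws[, i] <- sample_rr(as.list(rr_ord[i, ]), cfg$iterations)
  }
  tot_col <- which(res$level == "total" & res$sex == "both")
  for (it in c(1, 7, 25)) {
    rr_it <- rr_ord
    rr_it$rr_per_unit <- rr_draws[it, ]
    rr_it$se_log_rr <- 0
    b_it <- b
    b_it$rr <- rr_it
    det <- run_cra(b_it)
    naive_tot <- det$summary$averted[det$summary$level == "total" &
                                       det$summary$sex == "both"]
    expect_equal(draws[it, tot_col], naive_tot, tolerance = 1e-7)
  }
})

test_that("point-mass single-cause UIs match the analytic quantiles", {
  # with degenerate BMI distributions the PIF is a monotone transform of the
  # normal log-RR draw, so the UI endpoints have a closed form
  cfg <- synth_config(seed = 21, n_persons = 0, sd_bmi = 0)
  gen <- generate_bundle(cfg)
  b <- gen$bundle
  b$rr <- b$rr[b$rr$cause_id == "ihd", ]
  b$mortality <- b$mortality[b$mortality$cause_id == "ihd", ]
  b$causes <- b$causes[b$causes$cause_id == "ihd", ]
  mc <- run_mc(b, mc_config(iterations = 1e5, seed = 31))
  tot <- mc[mc$level == "total" & mc$sex == "both", ]

  # analytic endpoints: deaths averted(beta) = sum_cells d * (1 - e^{beta*dB})
  det <- run_cra(b)
  cells <- det$cell_results
  cellinfo <- dplyr::inner_join(
    cells,
    dplyr::mutate(det$cells, d_bmi = bmi_cf - mean_bmi)[,
      c("sex", "dri_group", "d_bmi")],
    by = c("sex", "dri_group"))
  spec <- b$rr[1, ]
  averted_of_beta <- function(beta) {
    sum(cellinfo$deaths * (1 - exp(beta * cellinfo$d_bmi)))
  }
  z <- qnorm(c(0.025, 0.975))
  beta_q <- (log(spec$rr_per_unit) + z * spec$se_log_rr) / spec$unit
  # averted is increasing in beta (d_bmi < 0)
  expect_equal(tot$ui_lo, averted_of_beta(beta_q[1]), tolerance = 5e-3)
  expect_equal(tot$ui_hi, averted_of_beta(beta_q[2]), tolerance = 5e-3)
})

test_that("95% UIs cover truth-derived deaths averted at the nominal rate", {
  # repeated synthetic experiments: draw a "true" RR from the sampling
  # distribution, compute the implied deaths averted, and check UI coverage
  b <- tiny_bundle(se_log_rr = 0.1)
  spec <- as.list(b$rr[1, ]) # work with the single-cause ihd sub-model
  b$rr <- b$rr[1, ]
  b$mortality <- b$mortality[b$mortality$cause_id == "ihd", ]
  b$causes <- b$causes[1, ]
  det <- run_cra(b)
  cells <- det$cells
  cellinfo <- dplyr::inner_join(
    det$cell_results,
    dplyr::mutate(cells, d_bmi = bmi_cf - mean_bmi)[,
      c("sex", "dri_group", "d_bmi", "mean_bmi", "sd_bmi")],
    by = c("sex", "dri_group"))
  nodes <- lapply(seq_len(nrow(cells)), function(i) {
    list(base = sugarcra:::rr_nodes(cells$dist_base[[i]], spec$ref_bmi),
         cf = sugarcra:::rr_nodes(cells$dist_cf[[i]], spec$ref_bmi))
  })
  cell_of <- match(paste(cellinfo$sex, cellinfo$dri_group),
                   paste(cells$sex, cells$dri_group))
  deaths_by_cell <- tapply(cellinfo$deaths, cell_of, sum)
  used <- as.integer(names(deaths_by_cell))
  averted_for_betas <- function(betas) { # vectorized over draws
    out <- numeric(length(betas))
    for (j in seq_along(used)) {
      i <- used[j]
      p <- 1 - sugarcra:::mean_rr_beta(nodes[[i]]$cf, betas) /
        sugarcra:::mean_rr_beta(nodes[[i]]$base, betas)
      out <- out + deaths_by_cell[j] * p
    }
    out
  }
  set.seed(17)
  n_rep <- 500
  n_iter <- 1500
  covered <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    beta_true <- rnorm(1, log(spec$rr_per_unit), spec$se_log_rr) / spec$unit
    truth <- averted_for_betas(beta_true)
    beta_draws <- rnorm(n_iter, log(spec$rr_per_unit), spec$se_log_rr) /
      spec$unit
    ui <- percentile_interval(averted_for_betas(beta_draws))
    covered[r] <- truth >= ui[1] && truth <= ui[2]
  }
  expect_equal(mean(covered), 0.95, tolerance = 0.02 / 0.95)
})

test_that("the vary-exposures hook widens intervals and stays reproducible", {
  b <- tiny_bundle(se_log_rr = 0.05)
  cfg_on <- mc_config(iterations = 60, seed = 19, vary_exposures = TRUE)
  r1 <- run_mc(b, cfg_on)
  r2 <- run_mc(b, cfg_on)
  expect_identical(r1, r2)
  cfg_off <- mc_config(iterations = 60, seed = 19)
  r0 <- run_mc(b, cfg_off)
  tot_on <- r1[r1$level == "total" & r1$sex == "both", ]
  tot_off <- r0[r0$level == "total" & r0$sex == "both", ]
  expect_gt(tot_on$ui_hi - tot_on$ui_lo, tot_off$ui_hi - tot_off$ui_lo)
})

test_that("mc_config validates its invariants", {
  expect_error(mc_config(iterations = 0), class = "sugarcra_domain_error")
  expect_error(mc_config(percentiles = c(97.5, 2.5)),
               class = "sugarcra_domain_error")
})
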