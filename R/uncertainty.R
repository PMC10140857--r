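# Monte Carlo propagation of relative-risk parameter uncertainty through the
# whole pipeline, with percentile uncertainty intervals.

#' Monte Carlo configuration
#'
#' @param iterations Number of iterations (default 10000).
#' @param seed Integer RNG seed; `(seed, iterations)` fully determine the
#'   output.
#' @param percentiles Ordered pair of percentile levels for the uncertainty
#'   interval (default `c(2.5, 97.5)`).
#' @param vary_exposures If `TRUE`, also redraw the scenario mean energy
#'   intakes from `N(mean_kcal, se_kcal)` each iteration (off by default: the
#'   epidemiological RR parameters are the modelled source of uncertainty).
#' @param keep_draws Retain the per-iteration draws matrix in the result.
#' @return An `mc_config` list.
#' @export
mc_config <- function(iterations = 10000, seed = 1L,
                      percentiles = c(2.5, 97.5), vary_exposures = FALSE,
                      keep_draws = FALSE) {
  if (iterations < 1) stop_domain("mc_config: iterations must be >= 1")
  if (length(percentiles) != 2 || percentiles[1] <= 0 ||
      percentiles[2] >= 100 || percentiles[1] >= percentiles[2]) {
    stop_domain("mc_config: percentiles must satisfy 0 < lo < hi < 100")
  }
  list(iterations = as.integer(iterations), seed = as.integer(seed),
       percentiles = percentiles, vary_exposures = isTRUE(vary_exposures),
       keep_draws = isTRUE(keep_draws))
}

#' Read a Monte Carlo configuration from YAML
#'
#' Keys: `iterations`, `seed`, `percentiles` (2-vector), `vary_exposures`.
#' @param path YAML file path.
#' @export
read_mc_config <- function(path) {
  raw <- yaml::read_yaml(path)
  mc_config(
    iterations = raw$iterations %||% 10000,
    seed = raw$seed %||% 1L,
    percentiles = unlist(raw$percentiles %||% c(2.5, 97.5)),
    vary_exposures = raw$vary_exposures %||% FALSE
  )
}

#' Draw relative-risk values from their sampling distribution
#'
#' Lognormal on the RR scale: `draw = exp(N(log(rr_per_unit), se_log_rr^2))`.
#' With `se_log_rr = 0` every draw equals the point value. Uses the current
#' RNG state.
#'
#' @param spec Relative-risk specification (list/row with `rr_per_unit`,
#'   `se_log_rr`).
#' @param n Number of draws.
#' @return Numeric vector of RR draws.
#' @export
sample_rr <- function(spec, n = 1) {
  exp(rnorm(n, log(spec$rr_per_unit), spec$se_log_rr))
}

#' Percentile interval by interpolated order statistics
#'
#' Linear interpolation between order statistics at position
#' `h = p * (n - 1) + 1` (the convention also used by type-7 quantiles), which
#' is stable and well defined for any `n >= 1`; a single draw yields a
#' degenerate interval.
#'
#' @param draws Numeric vector of Monte Carlo draws (non-empty).
#' @param levels Percentile levels, default `c(2.5, 97.5)`.
#' @return Numeric vector `c(lo, hi)`.
#' @export
percentile_interval <- function(draws, levels = c(2.5, 97.5)) {
  if (length(draws) == 0) stop_domain("percentile_interval: empty draws")
  x <- sort(draws)
  n <- length(x)
  h <- levels / 100 * (n - 1) + 1
  lo <- floor(h)
  frac <- h - lo
  out <- x[lo] + frac * (x[pmin(lo + 1, n)] - x[lo])
  setNames(out, c("lo", "hi")[seq_along(out)])
}

#' Propagate RR uncertainty through the pipeline by Monte Carlo
#'
#' Performs `iterations` independent redraws of every relative-risk parameter
#' (log-normal on the RR scale), recomputes all PIFs and deaths averted per
#' draw, and reports - for every row of the aggregated table - the
#' deterministic point estimate, the Monte Carlo mean and the percentile
#' uncertainty interval. Negative draws of deaths averted are permitted (no
#' clamping).
#'
#' Because deaths averted are linear in the per-cell PIFs for the single BMI
#' pathway, the per-draw recomputation is carried out as a matrix product of
#' PIF draws (evaluated on fixed Gauss-Legendre quadrature nodes) with the
#' deaths-weight matrix of each reporting row; results are identical to
#' naively rerunning the pipeline per draw. With `vary_exposures = TRUE` the
#' exposure means are also redrawn and the cells are rebuilt each iteration.
#'
#' @param bundle A validated `cra_bundle` with an `rr` table.
#' @param config An [mc_config()].
#' @param params An [energy_balance_params()].
#' @return An `mc_result` tibble: the aggregated reporting rows with columns
#'   `point`, `mc_mean`, `ui_lo`, `ui_hi`; the draws matrix is attached as
#'   attribute `"draws"` when `keep_draws = TRUE`.
#' @export
run_mc <- function(bundle, config = mc_config(),
                   params = energy_balance_params()) {
  det <- run_cra(bundle, params)
  n_iter <- config$iterations

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  # one draw sequence per *original* RR row (a spec with sex = "both" is a
  # single epidemiological parameter: both sexes share its draws), in a fixed
  # deterministic order
  rr_src <- bundle$rr %>%
    arrange(.data$cause_id, .data$sex) %>%
    mutate(src = dplyr::row_number())
  log_draws <- matrix(0, n_iter, nrow(rr_src))
  for (i in seq_len(nrow(rr_src))) {
    log_draws[, i] <- log(sample_rr(as.list(rr_src[i, ]), n_iter))
  }
  specs <- expand_rr(rr_src) %>% arrange(.data$cause_id, .data$sex)
  # per-expanded-spec log-RR-per-BMI-unit draw columns
  beta_draws <- log_draws[, specs$src, drop = FALSE] /
    matrix(specs$unit, n_iter, nrow(specs), byrow = TRUE)

  agg_keys <- det$summary %>% select("level", "id", "group", "sex")

  if (!config$vary_exposures) {
    draws <- mc_linear_draws(det, specs, beta_draws, bundle)
  } else {
    draws <- mc_exposure_draws(det, specs, beta_draws, bundle, params, config)
  }
  # draws: n_iter x n reporting rows, ordered as det$summary

  ui <- apply(draws, 2, percentile_interval, levels = config$percentiles)
  out <- det$summary %>%
    mutate(point = .data$averted,
           mc_mean = colMeans(draws),
           ui_lo = ui[1, ], ui_hi = ui[2, ]) %>%
    select("level", "id", "group", "sex", "point", "mc_mean", "ui_lo",
           "ui_hi", "actual", "share_of_total", "pct_of_actual")
  if (config$keep_draws) attr(out, "draws") <- draws
  class(out) <- c("mc_result", class(out))
  out
}

# fast path: deaths averted linear in per-(cause,sex,dri) PIF draws
mc_linear_draws <- function(det, specs, beta_draws, bundle) {
  cells <- det$cells
  # weights: deaths per (cause, sex, dri) slice contributing to each
  # reporting row
  cr <- det$cell_results %>%
    left_join(select(bundle$causes, "cause_id", "group"), by = "cause_id")
  pif_key <- det$pif_table %>%
    mutate(k = dplyr::row_number()) %>%
    select("cause_id", "sex", "dri_group", "k")
  cr <- cr %>% inner_join(pif_key, by = c("cause_id", "sex", "dri_group"))

  n_k <- nrow(pif_key)
  n_iter <- nrow(beta_draws)
  P <- matrix(0, n_iter, n_k)
  # quadrature nodes per exposure cell, shared across causes
  node_cache <- list()
  cell_key <- paste(cells$sex, cells$dri_group)
  for (i in seq_len(nrow(det$pif_table))) {
    row <- det$pif_table[i, ]
    ci <- match(paste(row$sex, row$dri_group), cell_key)
    spec_i <- which(specs$cause_id == row$cause_id & specs$sex == row$sex)
    ref <- specs$ref_bmi[spec_i]
    ck <- paste(ci, ref)
    if (is.null(node_cache[[ck]])) {
      node_cache[[ck]] <- list(
        base = rr_nodes(cells$dist_base[[ci]], ref),
        cf = rr_nodes(cells$dist_cf[[ci]], ref)
      )
    }
    nd <- node_cache[[ck]]
    beta <- beta_draws[, spec_i]
    P[, i] <- 1 - mean_rr_beta(nd$cf, beta) / mean_rr_beta(nd$base, beta)
  }

  # reporting-row weights over pif cells
  summ <- det$summary
  W <- matrix(0, n_k, nrow(summ))
  for (r in seq_len(nrow(summ))) {
    rows <- cr
    if (summ$level[r] == "cause") rows <- rows[rows$cause_id == summ$id[r], ]
    if (summ$level[r] == "group") rows <- rows[rows$group == summ$id[r], ]
    if (summ$level[r] == "under_75") {
      rows <- rows[!is.na(rows$age_hi) & rows$age_hi <= 75, ]
    }
    if (summ$sex[r] != "both") rows <- rows[rows$sex == summ$sex[r], ]
    w <- tapply(rows$deaths, rows$k, sum)
    W[as.integer(names(w)), r] <- as.numeric(w)
  }
  P %*% W
}

# slow path: redraw exposure means each iteration and rebuild the cells
mc_exposure_draws <- function(det, specs, beta_draws, bundle, params, config) {
  n_iter <- nrow(beta_draws)
  summ <- det$summary
  draws <- matrix(0, n_iter, nrow(summ))
  base <- bundle$scenarios$baseline
  cf <- bundle$scenarios$counterfactual
  for (it in seq_len(n_iter)) {
    b <- bundle
    b$scenarios$baseline$mean_kcal <-
      rnorm(nrow(base), base$mean_kcal, base$se_kcal)
    b$scenarios$counterfactual$mean_kcal <-
      rnorm(nrow(cf), cf$mean_kcal, cf$se_kcal)
    cells_it <- scenario_cells(b, params)
    pif_table <- det$pif_table
    cell_key <- paste(cells_it$sex, cells_it$dri_group)
    for (i in seq_len(nrow(pif_table))) {
      row <- pif_table[i, ]
      ci <- match(paste(row$sex, row$dri_group), cell_key)
      spec_i <- which(specs$cause_id == row$cause_id & specs$sex == row$sex)
      nd_b <- rr_nodes(cells_it$dist_base[[ci]], specs$ref_bmi[spec_i])
      nd_c <- rr_nodes(cells_it$dist_cf[[ci]], specs$ref_bmi[spec_i])
      beta <- beta_draws[it, spec_i]
      pif_table$pif[i] <- 1 - mean_rr_beta(nd_c, beta) / mean_rr_beta(nd_b, beta)
    }
    cr <- deaths_averted(b$mortality, pif_table)
    agg <- aggregate_averted(cr, b$mortality, b$causes)
    draws[it, ] <- agg$averted
  }
  draws
}
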