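# CRA engine: log-linear relative-risk functions of BMI, potential impact
# fractions by numerical integration over lognormal BMI distributions,
# attribution of deaths averted per cause x sex x age band, and aggregation
# into reporting tables.

# Integration domain for BMI expectations (kg/m^2). Lognormal mass outside
# this range is negligible for human BMI distributions; expectations are
# normalized to the truncated mass so degenerate spreads behave continuously.
BMI_DOMAIN <- c(10, 80)

# sigma below this is treated as a point mass at the distribution mean
POINT_MASS_SIGMA <- 1e-8

#' Relative risk of death at a given BMI
#'
#' Log-linear above a reference BMI, flat (RR = 1) below it:
#' `RR(b) = exp(log(rr_per_unit) / unit * max(0, b - ref_bmi))`, so the RR is
#' `rr_per_unit` at `ref_bmi + unit` (conventionally a per-5-kg/m^2 RR from a
#' meta-analysis) and continuous, non-decreasing in BMI.
#'
#' @param bmi BMI value(s), kg/m^2.
#' @param spec A list/row with `rr_per_unit`, `unit`, `ref_bmi`.
#' @return Relative risk value(s).
#' @export
relative_risk <- function(bmi, spec) {
  exp(log(spec$rr_per_unit) / spec$unit * pmax(0, bmi - spec$ref_bmi))
}

# Integration limits in standard-normal space: with B = exp(mu + sigma*Z),
# the BMI domain and the reference BMI become z-values; beyond |z| = 12 the
# normal mass (< 2e-32) is negligible, keeping integrands well scaled even
# for near-degenerate spreads.
Z_CLIP <- 12

z_limits <- function(dist, ref_bmi) {
  z_lo <- (log(BMI_DOMAIN[1]) - dist$mu) / dist$sigma
  z_hi <- (log(BMI_DOMAIN[2]) - dist$mu) / dist$sigma
  z_ref <- if (ref_bmi <= BMI_DOMAIN[1]) z_lo
           else (log(ref_bmi) - dist$mu) / dist$sigma
  mass <- stats::pnorm(z_hi) - stats::pnorm(z_lo)
  if (mass <= 0) {
    abort("BMI distribution has no mass on the integration domain",
          class = "sugarcra_numerical_error")
  }
  list(
    # contribution of the flat RR = 1 region [lower domain edge, ref]
    below = (stats::pnorm(min(z_ref, z_hi)) - stats::pnorm(z_lo)) / mass,
    a = max(min(z_ref, z_hi), z_lo, -Z_CLIP),
    b = min(z_hi, Z_CLIP),
    mass = mass
  )
}

# E[RR(B)] for B ~ dist (lognormal), by adaptive quadrature in z-space over
# the BMI domain, normalized to the truncated mass. Below the reference BMI
# the integrand is exactly 1 and contributes a closed-form probability mass.
mean_rr <- function(dist, spec, rel_tol = 1e-8) {
  if (dist$sigma < POINT_MASS_SIGMA) {
    return(relative_risk(distribution_moments(dist)$mean, spec))
  }
  beta <- log(spec$rr_per_unit) / spec$unit
  if (beta == 0) return(1)
  zl <- z_limits(dist, spec$ref_bmi)
  upper <- 0
  if (zl$b > zl$a) {
    qres <- tryCatch(
      integrate(function(z) {
        stats::dnorm(z) *
          exp(beta * pmax(0, exp(dist$mu + dist$sigma * z) - spec$ref_bmi))
      }, lower = zl$a, upper = zl$b, rel.tol = rel_tol,
      subdivisions = 1000L),
      error = function(e) {
        abort(sprintf("mean_rr: quadrature failed (%s) for mu=%.4f sigma=%.4f beta=%.4f",
                      conditionMessage(e), dist$mu, dist$sigma, beta),
              class = "sugarcra_numerical_error")
      })
    upper <- qres$value / zl$mass
  }
  zl$below + upper
}

#' Potential impact fraction for one cause and stratum
#'
#' `PIF = 1 - E_cf[RR] / E_base[RR]`, the proportional reduction in deaths
#' when the BMI distribution moves from baseline to counterfactual.
#' Expectations are computed by adaptive quadrature over BMI in
#' `[10, 80]` kg/m^2 (relative tolerance `1e-8`); distributions with
#' negligible spread are evaluated in closed form at their mean, to which the
#' quadrature converges as `sd -> 0`.
#'
#' @param dist_baseline,dist_counterfactual `bmi_distribution` objects.
#' @param spec Relative-risk specification (list/row with `rr_per_unit`,
#'   `unit`, `ref_bmi`).
#' @param rel_tol Quadrature relative tolerance.
#' @return The PIF, a fraction in `(-Inf, 1]`; 0 for identical scenarios or a
#'   flat RR, negative if the counterfactual is worse.
#' @export
pif <- function(dist_baseline, dist_counterfactual, spec, rel_tol = 1e-8) {
  if (identical(dist_baseline[c("mu", "sigma")],
                dist_counterfactual[c("mu", "sigma")])) {
    return(0)
  }
  1 - mean_rr(dist_counterfactual, spec, rel_tol) /
    mean_rr(dist_baseline, spec, rel_tol)
}

# ---------------------------------------------------------------------------
# vectorized E[RR] over many RR draws (Monte Carlo fast path)
#
# For fixed distributions, E[RR](beta) = below_mass + sum_j w_j exp(beta *
# (b_j - ref)) on Gauss-Legendre nodes in quantile space; evaluating across a
# vector of beta draws is then a single matrix-vector product.

rr_nodes <- function(dist, ref_bmi, n_nodes = 160) {
  if (dist$sigma < POINT_MASS_SIGMA) {
    m <- distribution_moments(dist)$mean
    if (m <= ref_bmi) {
      return(list(below = 1, w = numeric(0), b_excess = numeric(0)))
    }
    return(list(below = 0, w = 1, b_excess = m - ref_bmi))
  }
  zl <- z_limits(dist, ref_bmi)
  if (zl$b <= zl$a) {
    return(list(below = zl$below, w = numeric(0), b_excess = numeric(0)))
  }
  gl <- pracma::gaussLegendre(n_nodes, zl$a, zl$b)
  list(below = zl$below,
       w = gl$w * stats::dnorm(gl$x) / zl$mass,
       b_excess = pmax(0, exp(dist$mu + dist$sigma * gl$x) - ref_bmi))
}

# beta: vector of log-RR-per-BMI-unit draws -> E[RR] per draw
mean_rr_beta <- function(nodes, beta) {
  if (length(nodes$b_excess) == 0) return(rep(nodes$below, length(beta)))
  if (length(nodes$b_excess) == 1) {
    return(nodes$below + nodes$w * exp(beta * nodes$b_excess)) # point mass
  }
  nodes$below + as.vector(crossprod(nodes$w, exp(outer(nodes$b_excess, beta))))
}

# ---------------------------------------------------------------------------

#' Deaths averted or delayed from PIFs and observed mortality
#'
#' Joins a PIF table (per cause, sex and DRI group) onto mortality records
#' (per cause, sex and five-year band; bands map to DRI groups by midpoint)
#' and multiplies cellwise: `deaths_averted = pif * deaths`. Negative PIFs
#' yield negative deaths averted (not clamped).
#'
#' @param mortality Mortality tibble (adult bands; others are dropped via
#'   [adult_filter()]).
#' @param pif_table Tibble with `cause_id`, `sex`, `dri_group`, `pif`.
#' @return Tibble per (cause, sex, band) with `dri_group`, `deaths`, `pif`,
#'   `deaths_averted`.
#' @export
deaths_averted <- function(mortality, pif_table) {
  mort <- adult_filter(mortality)
  mort$dri_group <- band_to_dri(mort$age_lo, mort$age_hi)
  missing <- setdiff(unique(pif_table$cause_id), unique(mort$cause_id))
  if (length(missing) > 0) {
    stop_reference(sprintf(
      "deaths_averted: no mortality records for cause(s): %s",
      paste(missing, collapse = ", ")))
  }
  mort %>%
    inner_join(pif_table, by = c("cause_id", "sex", "dri_group")) %>%
    mutate(deaths_averted = .data$pif * .data$deaths) %>%
    arrange(.data$cause_id, .data$sex, .data$age_lo)
}

#' Combine PIFs from several pathways for one cell
#'
#' `combined = 1 - prod(1 - pif_k)`: the survival-style multiplicative
#' combination that avoids double counting a death responsive to multiple
#' pathways. Identity for a single pathway.
#'
#' @param pifs Numeric vector of per-pathway PIFs, each `< 1`.
#' @return The combined PIF.
#' @export
combine_pathways <- function(pifs) {
  if (any(pifs >= 1)) stop_domain("combine_pathways: each pif must be < 1")
  1 - prod(1 - pifs)
}

#' Aggregate deaths averted into the reporting table
#'
#' Emits per-cause rows, disease-group subtotals, an under-75 subtotal (bands
#' lying entirely below 75 years), and the overall total - each for males,
#' females and both sexes - together with `share_of_total` (percent of the
#' same-sex total) and `pct_of_actual` (percent of observed deaths from the
#' corresponding causes). With the single BMI pathway and disjoint causes,
#' subtotals are plain sums; all accumulation is at full precision, rounding
#' happens only in [render_summary()].
#'
#' @param cell_results Output of [deaths_averted()].
#' @param mortality Full mortality tibble (denominators for `pct_of_actual`).
#' @param causes Causes tibble (for the group mapping).
#' @return Tibble with `level` (`cause` / `group` / `under_75` / `total`),
#'   `id`, `group`, `sex`, `averted`, `actual`, `share_of_total`,
#'   `pct_of_actual`.
#' @export
aggregate_averted <- function(cell_results, mortality, causes) {
  cells <- cell_results %>%
    left_join(select(causes, "cause_id", "group"), by = "cause_id")
  actual <- mortality %>%
    left_join(select(causes, "cause_id", "group"), by = "cause_id")

  sum_by <- function(df, value_col, keys) {
    df %>%
      group_by(dplyr::across(dplyr::all_of(keys))) %>%
      summarise(value = sum(.data[[value_col]]), .groups = "drop")
  }
  both_and_sexes <- function(df, value_col, keys) {
    per_sex <- sum_by(df, value_col, c(keys, "sex"))
    both <- sum_by(df, value_col, keys) %>% mutate(sex = "both")
    bind_rows(per_sex, both)
  }

  cause_rows <- both_and_sexes(cells, "deaths_averted", c("cause_id", "group")) %>%
    mutate(level = "cause", id = .data$cause_id) %>%
    left_join(both_and_sexes(actual, "deaths", c("cause_id")) %>%
                rename(actual = "value"),
              by = c("cause_id", "sex"))
  group_rows <- both_and_sexes(cells, "deaths_averted", "group") %>%
    mutate(level = "group", id = .data$group) %>%
    left_join(both_and_sexes(actual, "deaths", "group") %>%
                rename(actual = "value"),
              by = c("group", "sex"))
  u75 <- cells %>% filter(!is.na(.data$age_hi) & .data$age_hi <= 75)
  u75_rows <- both_and_sexes(u75, "deaths_averted", character(0)) %>%
    mutate(level = "under_75", id = "under_75", group = NA_character_,
           actual = NA_real_)
  total_rows <- both_and_sexes(cells, "deaths_averted", character(0)) %>%
    mutate(level = "total", id = "total", group = NA_character_) %>%
    left_join(both_and_sexes(actual, "deaths", character(0)) %>%
                rename(actual = "value") %>%
                select("sex", "actual"),
              by = "sex")

  out <- bind_rows(cause_rows, group_rows, u75_rows, total_rows) %>%
    rename(averted = "value") %>%
    select("level", "id", "group", "sex", "averted", "actual")
  totals <- out %>% filter(.data$level == "total") %>%
    select("sex", total_averted = "averted")
  out %>%
    left_join(totals, by = "sex") %>%
    mutate(
      share_of_total = ifelse(.data$total_averted == 0, NA_real_,
                              100 * .data$averted / .data$total_averted),
      pct_of_actual = ifelse(is.na(.data$actual) | .data$actual == 0,
                             NA_real_, 100 * .data$averted / .data$actual)
    ) %>%
    select(-"total_averted") %>%
    arrange(factor(.data$level, levels = c("cause", "group", "under_75",
                                           "total")),
            .data$id, factor(.data$sex, levels = c("male", "female", "both")))
}

# ---------------------------------------------------------------------------
# deterministic pipeline

# per-cell scenario table: baseline/cf kcal, counterfactual BMI, distributions
scenario_cells <- function(bundle, params) {
  base <- bundle$scenarios$baseline
  cf <- bundle$scenarios$counterfactual
  cells <- base %>%
    inner_join(select(cf, "sex", "dri_group", mean_kcal_cf = "mean_kcal"),
               by = c("sex", "dri_group"))
  cells$delta_kcal <- cells$mean_kcal_cf - cells$mean_kcal
  cells$bmi_cf <- counterfactual_mean_bmi(cells, cells$delta_kcal, params)
  cells$dist_base <- lapply(seq_len(nrow(cells)), function(i) {
    lognormal_from_moments(cells$mean_bmi[i], cells$sd_bmi[i])
  })
  cells$dist_cf <- lapply(seq_len(nrow(cells)), function(i) {
    shift_distribution(cells$dist_base[[i]], cells$bmi_cf[i])
  })
  cells
}

#' Run the deterministic CRA pipeline on a validated bundle
#'
#' For every exposure cell the counterfactual mean BMI is derived from the
#' energy change through the BMI pathway, the baseline BMI distribution is
#' shifted to that mean, PIFs are computed per relative-risk specification,
#' deaths averted are attributed per cause, sex and age band, and everything
#' is aggregated into the reporting table.
#'
#' @param bundle A `cra_bundle` with a non-`NULL` `rr` table.
#' @param params An [energy_balance_params()] object.
#' @return A `cra_result` list: `cells` (scenario cells with BMI shifts),
#'   `pif_table`, `cell_results` (per cause/sex/band) and `summary` (the
#'   aggregated table).
#' @export
run_cra <- function(bundle, params = energy_balance_params()) {
  if (is.null(bundle$rr)) stop_reference("run_cra: bundle has no rr table")
  cells <- scenario_cells(bundle, params)
  specs <- expand_rr(bundle$rr)
  pif_table <- bind_rows(lapply(seq_len(nrow(specs)), function(i) {
    spec <- as.list(specs[i, ])
    cc <- cells[cells$sex == spec$sex, ]
    tibble(
      cause_id = spec$cause_id, sex = spec$sex, dri_group = cc$dri_group,
      pif = vapply(seq_len(nrow(cc)), function(j) {
        pif(cc$dist_base[[j]], cc$dist_cf[[j]], spec)
      }, numeric(1))
    )
  }))
  cell_results <- deaths_averted(bundle$mortality, pif_table)
  structure(list(
    cells = cells,
    pif_table = pif_table,
    cell_results = cell_results,
    summary = aggregate_averted(cell_results, bundle$mortality, bundle$causes)
  ), class = "cra_result")
}

#' @export
print.cra_result <- function(x, ...) {
  tot <- x$summary %>% filter(.data$level == "total", .data$sex == "both")
  cat(sprintf("<cra_result: %.0f deaths averted or delayed (%.1f%% of actual)>\n",
              tot$averted, tot$pct_of_actual))
  invisible(x)
}
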