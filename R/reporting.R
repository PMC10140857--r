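# Reporting: summary-table rendering (text + CSV) for aggregated or Monte
# Carlo results, and share/ratio helpers usable on externally published
# summary tables.

#' Shares and percent-of-actual for an averted-deaths summary table
#'
#' Given per-row deaths averted and the observed deaths for the matching
#' causes, computes `share_of_total` (percent of the same-sex total row) and
#' `pct_of_actual` (percent of observed deaths). This is the same arithmetic
#' [aggregate_averted()] applies internally; exposing it allows recomputing
#' the derived ratios of any published summary table.
#'
#' @param averted Tibble with columns `level`, `id`, `sex`, `averted`; must
#'   contain a `level == "total"` row per sex present.
#' @param actual Optional tibble `id`, `sex`, `actual` with observed deaths.
#' @return `averted` with `share_of_total` and (if `actual` given)
#'   `pct_of_actual` columns.
#' @export
averted_shares <- function(averted, actual = NULL) {
  totals <- averted %>%
    filter(.data$level == "total") %>%
    select("sex", total_averted = "averted")
  if (nrow(totals) == 0) stop_domain("averted_shares: no total row")
  out <- averted %>%
    left_join(totals, by = "sex") %>%
    mutate(share_of_total = ifelse(
      .data$total_averted == 0, NA_real_,
      100 * .data$averted / .data$total_averted)) %>%
    select(-"total_averted")
  if (!is.null(actual)) {
    out <- out %>%
      left_join(select(actual, "id", "sex", "actual"),
                by = c("id", "sex")) %>%
      mutate(pct_of_actual = ifelse(
        is.na(.data$actual) | .data$actual == 0, NA_real_,
        100 * .data$averted / .data$actual))
  }
  out
}

fmt_n <- function(x) {
  ifelse(is.na(x), "", formatC(round(x), format = "d", big.mark = ","))
}
fmt_pct <- function(x) ifelse(is.na(x), "", sprintf("%.1f", x))
fmt_ui <- function(lo, hi) {
  ifelse(is.na(lo), "", sprintf("(%s, %s)", fmt_n(lo), fmt_n(hi)))
}

#' Render the summary table of deaths averted or delayed
#'
#' Produces the standard reporting layout: one row per cause with the mean
#' (and 95% UI when present) and the percent share per sex, group subtotal
#' rows, the under-75 subtotal, the overall total and percent-of-actual
#' rows. Deaths are rounded to integers and percentages to one decimal at
#' presentation only; the `data` element carries the unrounded cells and the
#' text and CSV renderings agree cell for cell.
#'
#' @param result An `mc_result` (from [run_mc()]), `cra_result` (from
#'   [run_cra()]) or their `summary` tibble.
#' @param causes Optional causes tibble to label rows with names and ICD-10
#'   codes.
#' @return An `averted_summary` list with `data` (tidy tibble) and `text`
#'   (character vector of rendered lines).
#' @export
render_summary <- function(result, causes = NULL) {
  df <- if (inherits(result, "cra_result")) result$summary else result
  if (!"point" %in% names(df)) {
    df <- df %>% mutate(point = .data$averted, mc_mean = NA_real_,
                        ui_lo = NA_real_, ui_hi = NA_real_)
  }
  wide <- df %>%
    select("level", "id", "group", "sex", "point", "mc_mean", "ui_lo",
           "ui_hi", "actual", "share_of_total", "pct_of_actual") %>%
    tidyr::pivot_wider(
      names_from = "sex",
      values_from = c("point", "mc_mean", "ui_lo", "ui_hi", "actual",
                      "share_of_total", "pct_of_actual")
    )
  label <- wide$id
  if (!is.null(causes)) {
    i <- match(wide$id, causes$cause_id)
    label <- ifelse(is.na(i), wide$id,
                    sprintf("%s (%s)", causes$name[i], causes$icd10[i]))
  }
  wide$label <- label

  mean_col <- function(w, s) {
    m <- w[[paste0("mc_mean_", s)]]
    ifelse(is.na(m), w[[paste0("point_", s)]], m)
  }
  line <- function(lbl, w, s3 = NULL) {
    sprintf("%-42s %10s %-16s %6s", lbl,
            fmt_n(mean_col(w, "both")),
            fmt_ui(w$ui_lo_both, w$ui_hi_both),
            fmt_pct(w$share_of_total_both))
  }
  order_groups <- c("cardiovascular", "diabetes", "cancer", "renal", "liver")
  lines <- c(sprintf("%-42s %10s %-16s %6s", "Cause of death", "Mean",
                     "(95% UI)", "%"),
             strrep("-", 78))
  zero_total <- isTRUE(all(mean_col(wide, "both")[wide$level == "total"] == 0))
  for (g in order_groups) {
    grow <- wide[wide$level == "group" & wide$id == g, ]
    crows <- wide[wide$level == "cause" & !is.na(wide$group) &
                    wide$group == g, ]
    if (nrow(grow) == 0 && nrow(crows) == 0) next
    if (nrow(grow) == 1) {
      lines <- c(lines, line(toupper(substring(g, 1, 1)) %+%
                               substring(g, 2), grow))
    }
    if (nrow(crows) > 1 || (nrow(crows) == 1 && crows$id[1] != g)) {
      for (i in seq_len(nrow(crows))) {
        lines <- c(lines, line("  " %+% crows$label[i], crows[i, ]))
      }
    }
    if (nrow(grow) == 1 && !is.na(grow$pct_of_actual_both)) {
      lines <- c(lines, sprintf("%-42s %10s %-16s",
                                "  actual deaths / % averted",
                                fmt_n(grow$actual_both),
                                fmt_pct(grow$pct_of_actual_both)))
    }
  }
  u75 <- wide[wide$level == "under_75", ]
  if (nrow(u75) == 1) lines <- c(lines, line("Total under 75", u75))
  tot <- wide[wide$level == "total", ]
  if (nrow(tot) == 1) {
    lines <- c(lines, strrep("-", 78), line("Total averted or delayed", tot))
    if (!is.na(tot$pct_of_actual_both)) {
      lines <- c(lines, sprintf("%-42s %10s %-16s",
                                "Actual deaths / % averted",
                                fmt_n(tot$actual_both),
                                fmt_pct(tot$pct_of_actual_both)))
    }
  }
  if (zero_total) {
    # suppress meaningless shares in the rendering when nothing is averted
    lines <- lines[!grepl("% averted", lines, fixed = TRUE)]
  }
  structure(list(data = df, text = lines), class = "averted_summary")
}

`%+%` <- function(a, b) paste0(a, b)

#' @export
print.averted_summary <- function(x, ...) {
  cat(x$text, sep = "\n")
  invisible(x)
}

#' Write a rendered summary to disk
#'
#' Writes `<stem>.csv` (the tidy unrounded cells) and `<stem>.txt` (the
#' rendered table).
#'
#' @param summary An `averted_summary` from [render_summary()].
#' @param stem Output path without extension.
#' @return Invisibly, the two paths.
#' @export
write_summary <- function(summary, stem) {
  csv <- paste0(stem, ".csv")
  txt <- paste0(stem, ".txt")
  readr::write_csv(summary$data, csv)
  writeLines(summary$text, txt)
  invisible(c(csv = csv, txt = txt))
}
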