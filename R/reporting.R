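#' Read a published-style prevalence table
#'
#' Reads a delimited (tab-separated) table whose first column labels the rows
#' (state or subgroup level) and whose remaining columns come in triples
#' `<cell>_est`, `<cell>_ci_low`, `<cell>_ci_high` — e.g. `self_reported_*`,
#' `corrected_total_*`, `corrected_men_*`, `corrected_women_*` — plus any
#' extra flag columns. Validates that labels are unique, numeric cells parse,
#' and every present triple satisfies `ci_low <= est <= ci_high`.
#'
#' @param path Path to the delimited file.
#' @return Tibble with attribute `"cells"` naming the detected cell groups.
#' @export
#' @examples
#' tab2 <- load_prevalence_table(bmibias_fixture("table2_severe_obesity_states.tsv"))
#' nrow(tab2) # 51: 50 states + District of Columbia
load_prevalence_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("No such file: %s.", path))
  }
  tab <- tryCatch(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort(sprintf("Cannot parse %s: %s", path, conditionMessage(e)))
  )
  if (nrow(tab) == 0 || ncol(tab) < 2) {
    abort(sprintf("%s does not look like a prevalence table (no rows or columns).", path))
  }
  prob <- readr::problems(tab)
  if (nrow(prob) > 0) {
    abort(sprintf(
      "Malformed cell in %s at row %d, column %d.",
      path, prob$row[1], prob$col[1]
    ))
  }
  label_col <- names(tab)[1]
  labels <- tab[[label_col]]
  if (anyDuplicated(labels)) {
    abort(sprintf(
      "Duplicate row label(s): %s.",
      paste(unique(labels[duplicated(labels)]), collapse = ", ")
    ))
  }
  cells <- unique(sub("_est$", "", grep("_est$", names(tab), value = TRUE)))
  for (cell in cells) {
    trio <- paste0(cell, c("_est", "_ci_low", "_ci_high"))
    if (!all(trio %in% names(tab))) next
    est <- tab[[trio[1]]]
    lo <- tab[[trio[2]]]
    hi <- tab[[trio[3]]]
    ok <- is.na(est) | (lo <= est & est <= hi)
    if (!all(ok, na.rm = TRUE) || any(is.na(ok) & !is.na(est))) {
      bad <- which(!ok)[1]
      abort(sprintf(
        "Inverted or inconsistent CI at row \"%s\", column %s.",
        labels[bad], cell
      ))
    }
  }
  attr(tab, "cells") <- cells
  attr(tab, "label_col") <- label_col
  tab
}

#' Write a prevalence table
#'
#' Writes in the same tab-separated schema that [load_prevalence_table()]
#' reads, so tables round-trip bit-identically.
#'
#' @param table Tibble (first column = row labels).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_prevalence_table <- function(table, path) {
  readr::write_tsv(table, path, progress = FALSE)
  invisible(path)
}

#' Path to a packaged table fixture
#'
#' @param name File name under the package's `extdata` directory.
#' @return Absolute path.
#' @export
bmibias_fixture <- function(name) {
  p <- system.file("extdata", name, package = "bmibias", mustWork = FALSE)
  if (!nzchar(p)) {
    abort(sprintf("No packaged fixture named %s.", name))
  }
  p
}

table_column <- function(table, column) {
  col <- paste0(column, "_est")
  if (!col %in% names(table)) {
    abort(sprintf("Unknown table column \"%s\".", column))
  }
  col
}

drop_dc <- function(table, include_dc) {
  if (include_dc) {
    return(table)
  }
  table[table[[1]] != "District of Columbia", , drop = FALSE]
}

#' Count rows above a prevalence threshold
#'
#' @param table A prevalence table (see [load_prevalence_table()]).
#' @param column Cell group, e.g. `"corrected_total"`.
#' @param threshold Estimates strictly greater than this are counted.
#' @param include_dc Count the District of Columbia row? Defaults to `FALSE`
#'   so counts match "n states" phrasing.
#' @return Integer count.
#' @export
count_above <- function(table, column, threshold, include_dc = FALSE) {
  col <- table_column(table, column)
  tab <- drop_dc(table, include_dc)
  sum(tab[[col]] > threshold, na.rm = TRUE)
}

#' Minimum and maximum of a table column, with row labels
#'
#' Ties are reported as all tied labels.
#'
#' @inheritParams count_above
#' @return List with `min` and `max`, each `list(labels =, value =)`.
#' @export
column_extremes <- function(table, column, include_dc = TRUE) {
  col <- table_column(table, column)
  tab <- drop_dc(table, include_dc)
  v <- tab[[col]]
  if (all(is.na(v))) {
    abort(sprintf("Column \"%s\" is empty.", column))
  }
  pick <- function(target) {
    list(
      labels = tab[[1]][which(!is.na(v) & v == target)],
      value = target
    )
  }
  list(min = pick(min(v, na.rm = TRUE)), max = pick(max(v, na.rm = TRUE)))
}

#' Flag rows significantly above a national estimate
#'
#' Re-tests each row of a published table against the national estimate using
#' standard errors recovered from the printed confidence intervals
#' ([se_from_ci()]): a z test of the row-minus-national difference assuming
#' independence. A row is flagged when its estimate exceeds the national one
#' and the test is significant at `alpha`. Because the question is
#' directional ("higher than the national average"), the default alternative
#' is one-sided `"greater"`, which reproduces the footnote markers of
#' published state tables from their printed CIs; `"two.sided"` is available
#' and flags slightly fewer borderline rows when estimates are only printed
#' to one decimal.
#'
#' @inheritParams count_above
#' @param national List or one-row table with `est`, `ci_low`, `ci_high` on
#'   the same scale as the table.
#' @param alpha Significance level.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return Character vector of flagged row labels.
#' @export
flag_above_national <- function(table, column, national, alpha = 0.05,
                                include_dc = FALSE,
                                alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  col <- table_column(table, column)
  lo_col <- paste0(column, "_ci_low")
  hi_col <- paste0(column, "_ci_high")
  tab <- drop_dc(table, include_dc)
  est <- tab[[col]]
  lo <- tab[[lo_col]]
  hi <- tab[[hi_col]]
  if (anyNA(c(est, lo, hi))) {
    abort(sprintf(
      "Missing CI for row \"%s\".",
      tab[[1]][which(is.na(est) | is.na(lo) | is.na(hi))[1]]
    ))
  }
  se_row <- se_from_ci(lo, hi)
  se_nat <- se_from_ci(national$ci_low, national$ci_high)
  z <- (est - national$est) / sqrt(se_row^2 + se_nat^2)
  p <- if (alternative == "greater") pnorm(-z) else 2 * pnorm(-abs(z))
  tab[[1]][est > national$est & p < alpha]
}

#' Relative underestimation of a corrected prevalence by self-report
#'
#' How far, in percent of the corrected value, the self-reported estimate
#' falls below the bias-corrected one:
#' `100 * (corrected - self_reported) / corrected`.
#'
#' @param self_reported_est,corrected_est Prevalence estimates on the same
#'   scale; `corrected_est` must be positive.
#' @param digits Rounding for reporting; headline figures round to integer
#'   percent.
#' @return Percent underestimation.
#' @export
#' @examples
#' relative_underestimation(5.3, 8.8) # 40
relative_underestimation <- function(self_reported_est, corrected_est,
                                     digits = 0) {
  if (any(corrected_est <= 0)) {
    abort("`corrected_est` must be positive.")
  }
  round(100 * (corrected_est - self_reported_est) / corrected_est, digits)
}
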