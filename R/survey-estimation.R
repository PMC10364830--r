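#' Classify severe (class III) obesity
#'
#' Severe obesity is BMI of 40 or higher; the boundary is inclusive.
#'
#' @param bmi Positive, finite BMI values.
#' @param threshold Cut point, default 40 kg/m^2.
#' @return Logical vector.
#' @export
#' @examples
#' classify_severe_obesity(c(39.999, 40, 55.2))
classify_severe_obesity <- function(bmi, threshold = 40) {
  if (length(bmi) == 0) {
    return(logical(0))
  }
  if (anyNA(bmi) || any(!is.finite(bmi)) || any(bmi <= 0)) {
    abort("`bmi` must be finite and positive (filter the cohort first).")
  }
  bmi >= threshold
}

#' Design-weighted prevalence with a logit-transformed confidence interval
#'
#' Estimates the weighted proportion \eqn{\hat p = \sum w_i x_i / \sum w_i}
#' with the weights-only linearization standard error
#' \eqn{se^2 = \sum w_i^2 (x_i - \hat p)^2 / (\sum w_i)^2}. The confidence
#' interval is built on the logit scale and mapped back to \[0, 1\], which
#' keeps bounds inside the unit interval for small prevalences; degenerate
#' estimates (all or no successes) get exact one-sided bounds based on the
#' effective sample size. With unit weights everything reduces to the
#' classical binomial linearization.
#'
#' @param records Tibble with a `sample_weight` column.
#' @param indicator Logical vector of length `nrow(records)`, or the name of
#'   a logical column in `records`.
#' @param domain Optional logical vector selecting the analysis domain;
#'   `NULL` keeps all records.
#' @param label Domain label carried into the output (and error messages).
#' @param conf_level Confidence level, default 0.95.
#' @return One-row tibble: `label`, `p_hat`, `se`, `ci_low`, `ci_high`,
#'   `n_unweighted`, `sum_weights`.
#' @export
#' @examples
#' recs <- tibble::tibble(bmi = c(42, 38), sample_weight = c(1, 3))
#' weighted_prevalence(recs, classify_severe_obesity(recs$bmi))
weighted_prevalence <- function(records, indicator, domain = NULL,
                                label = "overall", conf_level = 0.95) {
  if (is.character(indicator) && length(indicator) == 1) {
    indicator <- records[[indicator]]
  }
  x <- as.numeric(indicator)
  w <- records$sample_weight
  if (!is.null(domain)) {
    x <- x[domain]
    w <- w[domain]
  }
  if (length(x) == 0) {
    abort(sprintf("Domain \"%s\" is empty.", label))
  }
  if (anyNA(x) || anyNA(w) || any(w <= 0)) {
    abort("Indicator must be non-missing and weights positive.")
  }
  W <- sum(w)
  p <- sum(w * x) / W
  se <- sqrt(sum(w^2 * (x - p)^2)) / W
  z <- qnorm(1 - (1 - conf_level) / 2)
  n_eff <- W^2 / sum(w^2)
  alpha <- 1 - conf_level
  if (p <= 0) {
    ci <- c(0, 1 - (alpha / 2)^(1 / n_eff))
  } else if (p >= 1) {
    ci <- c((alpha / 2)^(1 / n_eff), 1)
  } else if (se == 0) {
    ci <- c(p, p)
  } else {
    l <- qlogis(p)
    se_l <- se / (p * (1 - p))
    ci <- plogis(c(l - z * se_l, l + z * se_l))
  }
  tibble::tibble(
    label = label, p_hat = p, se = se,
    ci_low = ci[1], ci_high = ci[2],
    n_unweighted = length(x), sum_weights = W
  )
}

#' Prevalence estimates by subgroup
#'
#' One weighted prevalence estimate per level of each grouping field, plus an
#' overall row. Group levels with no records are absent from the output, not
#' reported as zero.
#'
#' @param records Person records.
#' @param grouping Character vector of grouping columns (e.g. `"sex"`);
#'   empty for the overall estimate only.
#' @param indicator Logical vector or logical-column name; defaults to severe
#'   obesity classified from `bmi`.
#' @param conf_level Confidence level.
#' @return Tibble of prevalence rows with a `group` column naming the
#'   grouping field (`"overall"` for the overall row) and `label` the level.
#' @export
estimate_by_groups <- function(records, grouping = character(),
                               indicator = NULL, conf_level = 0.95) {
  unknown <- setdiff(grouping, names(records))
  if (length(unknown)) {
    abort(sprintf("Unknown grouping field(s): %s.", paste(unknown, collapse = ", ")))
  }
  if (is.null(indicator)) {
    indicator <- classify_severe_obesity(records$bmi)
  } else if (is.character(indicator) && length(indicator) == 1) {
    indicator <- records[[indicator]]
  }
  rows <- list(
    dplyr::mutate(
      weighted_prevalence(records, indicator, conf_level = conf_level),
      group = "overall", .before = 1
    )
  )
  for (g in grouping) {
    lv <- records[[g]]
    for (level in levels_or_unique(lv)) {
      sel <- !is.na(lv) & lv == level
      if (!any(sel)) next
      rows[[length(rows) + 1]] <- dplyr::mutate(
        weighted_prevalence(records, indicator,
          domain = sel,
          label = as.character(level), conf_level = conf_level
        ),
        group = g, .before = 1
      )
    }
  }
  dplyr::bind_rows(rows)
}

levels_or_unique <- function(x) {
  if (is.factor(x)) levels(x) else sort(unique(x[!is.na(x)]))
}

#' Compare two prevalence estimates
#'
#' Large-sample two-sided test of the difference between two (approximately
#' normal) prevalence estimates: \eqn{z = (\hat p_a - \hat p_b) /
#' \sqrt{se_a^2 + se_b^2}}. No multiplicity adjustment is applied. The test
#' is scale-consistent: estimates in percent with percent-scale SEs give the
#' same z and p as proportions.
#'
#' @param a,b One-row prevalence estimates (or lists) with fields `p_hat`
#'   (or `est`) and `se`, optionally `label`.
#' @param alpha Significance level for the `significant_at_05` flag.
#' @return One-row tibble: labels, `difference`, `z`, `p_value`,
#'   `significant_at_05`.
#' @export
compare_estimates <- function(a, b, alpha = 0.05) {
  get_est <- function(e) if (!is.null(e$p_hat)) e$p_hat else e$est
  pa <- get_est(a)
  pb <- get_est(b)
  sd_diff <- sqrt(a$se^2 + b$se^2)
  if (sd_diff == 0) {
    if (pa == pb) {
      z <- 0
      p <- 1
    } else {
      abort("Cannot compare estimates that both have zero standard error.")
    }
  } else {
    z <- (pa - pb) / sd_diff
    p <- 2 * pnorm(-abs(z))
  }
  tibble::tibble(
    label_a = a$label %||% "a", label_b = b$label %||% "b",
    difference = pa - pb, z = z, p_value = p,
    significant_at_05 = p < alpha
  )
}

#' Recover a standard error from a printed confidence interval
#'
#' Published tables print 95% CIs but not standard errors; for re-testing
#' their rows the SE is taken as the CI half-width over the normal quantile:
#' `se = (ci_high - ci_low) / (2 * 1.96)`.
#'
#' @param ci_low,ci_high Interval bounds, `ci_low < ci_high`.
#' @param conf_level Confidence level the interval was built at.
#' @return Standard error on the same scale as the bounds.
#' @export
#' @examples
#' se_from_ci(8.6, 9.0) # ~0.102
se_from_ci <- function(ci_low, ci_high, conf_level = 0.95) {
  if (any(ci_low >= ci_high)) {
    abort("`ci_low` must be below `ci_high`.")
  }
  (ci_high - ci_low) / (2 * qnorm(1 - (1 - conf_level) / 2))
}
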