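# Independent oracles used to freeze expected values. These deliberately
# re-derive quantities by enumeration / numerical integration, not through
# the package's own code paths.

# Empirical quantile of a unit-weight list under the tie-midpoint convention,
# computed by direct enumeration (explicit loops, no approx/rowsum).
oracle_quantile_expanded <- function(xe, p) {
  xs <- sort(xe)
  n <- length(xs)
  vals <- unique(xs)
  cnt <- vapply(vals, function(v) sum(xs == v), numeric(1))
  pos <- (cumsum(cnt) - cnt / 2) / n
  if (p <= pos[1]) {
    return(vals[1])
  }
  if (p >= pos[length(pos)]) {
    return(vals[length(vals)])
  }
  i <- max(which(pos <= p))
  vals[i] + (p - pos[i]) / (pos[i + 1] - pos[i]) * (vals[i + 1] - vals[i])
}

# Inverse of the above, same conventions (below min -> 0, above max -> 1).
oracle_rank_expanded <- function(xe, v) {
  xs <- sort(xe)
  n <- length(xs)
  vals <- unique(xs)
  cnt <- vapply(vals, function(x) sum(xs == x), numeric(1))
  pos <- (cumsum(cnt) - cnt / 2) / n
  if (v < vals[1]) {
    return(0)
  }
  if (v > vals[length(vals)]) {
    return(1)
  }
  if (v <= vals[1]) {
    return(pos[1])
  }
  i <- max(which(vals <= v))
  if (i == length(vals)) {
    return(pos[i])
  }
  pos[i] + (v - vals[i]) / (vals[i + 1] - vals[i]) * (pos[i + 1] - pos[i])
}

# Severe-obesity tail mass of a population config by numerical integration of
# the stated mixture density (the package uses the closed form instead).
oracle_mixture_tail <- function(config, threshold = 40) {
  mx <- config$mixtures
  total <- 0
  for (i in seq_len(nrow(mx))) {
    dens <- function(b) {
      (1 - mx$pi2[i]) * dlnorm(b, log(mx$m1[i]), mx$s1[i]) +
        mx$pi2[i] * dlnorm(b, log(mx$m2[i]), mx$s2[i])
    }
    share <- config$sex_shares[[mx$sex[i]]] * config$age_shares[[mx$age_group[i]]]
    total <- total + share *
      integrate(dens, threshold, Inf, rel.tol = 1e-10)$value
  }
  total
}

# Brute-force two-sample KS statistic at unit weights: sweep every pooled
# value and difference the step ECDFs directly.
oracle_ks_statistic <- function(x, y) {
  at <- sort(unique(c(x, y)))
  fa <- vapply(at, function(t) mean(x <= t), numeric(1))
  fb <- vapply(at, function(t) mean(y <= t), numeric(1))
  max(abs(fa - fb))
}

# Population config without exclusion-triggering noise, for tests that feed
# the correction machinery directly.
clean_config <- function(n, ...) {
  population_config(
    n = n,
    missingness_rates = c(
      sex = 0, age = 0, race_ethnicity = 0,
      height = 0, weight = 0
    ),
    pregnancy_rate = 0, implausible_rate = 0, ...
  )
}

# Minimal person-record tibble for hand-built examples.
make_records <- function(bmi,
                         sex = "female",
                         age_years = 40,
                         sample_weight = 1,
                         height_cm = 162,
                         pregnant = FALSE,
                         race_ethnicity = "nh_white",
                         provenance = "measured") {
  n <- length(bmi)
  tibble::tibble(
    id = sprintf("T%03d", seq_len(n)),
    sex = factor(rep_len(sex, n), levels = c("male", "female")),
    age_years = as.integer(rep_len(age_years, n)),
    age_group = age_group(as.integer(rep_len(age_years, n))),
    race_ethnicity = factor(rep_len(race_ethnicity, n),
      levels = c("hispanic", "nh_asian", "nh_black", "nh_white", "nh_other")
    ),
    state = rep_len("GA", n),
    locality = factor(rep_len("metropolitan", n),
      levels = c("metropolitan", "nonmetropolitan")
    ),
    pregnant = rep_len(pregnant, n),
    height_cm = rep_len(height_cm, n),
    weight_kg = bmi * (rep_len(height_cm, n) / 100)^2,
    bmi = bmi,
    sample_weight = rep_len(sample_weight, n),
    provenance = rep_len(provenance, n)
  )
}

# Stratum-wise worst absolute deviation between corrected and measured
# weighted quantiles over a probability grid.
worst_quantile_gap <- function(corrected, measured, probs) {
  worst <- 0
  for (sx in levels(measured$sex)) {
    for (ag in levels(measured$age_group)) {
      mi <- measured$sex == sx & measured$age_group == ag
      ci <- corrected$sex == sx & corrected$age_group == ag
      if (!any(mi) || !any(ci)) next
      gap <- max(abs(
        weighted_quantile(corrected$bmi[ci], probs, corrected$sample_weight[ci]) -
          weighted_quantile(measured$bmi[mi], probs, measured$sample_weight[mi])
      ))
      worst <- max(worst, gap)
    }
  }
  worst
}

footnote_b_states <- c(
  "Alabama", "Arkansas", "Delaware", "Georgia", "Indiana", "Iowa", "Kansas",
  "Kentucky", "Louisiana", "Michigan", "Mississippi", "Missouri", "Ohio",
  "Oklahoma", "South Carolina", "Tennessee", "West Virginia"
)
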