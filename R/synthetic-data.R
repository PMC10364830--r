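#' Parametric self-report bias model
#'
#' Defines the generative mechanism by which the synthetic surveys distort
#' measured BMI into self-reported BMI. Reported BMI is
#' `measured - (intercept + slope * max(0, measured - pivot) + sex_offset +
#' age_offset) + Normal(0, noise_sd)`, i.e. a baseline under-report that grows
#' linearly with measured BMI above a pivot, plus reporting noise. With
#' nonnegative components this reproduces the two qualitative facts about
#' self-reported anthropometry: reported BMI is biased downwards (weight
#' under-reported, height over-reported), and the bias is larger at higher
#' BMI. Bias is injected on the BMI scale directly, with reported weight
#' back-solved at unchanged height, so each record's height/weight/BMI triple
#' stays internally consistent.
#'
#' @param intercept Baseline under-report, BMI units (kg/m^2).
#' @param slope Additional under-report per BMI unit above `pivot`; must be
#'   nonnegative (and < 1 to keep reporting monotone in measured BMI).
#' @param pivot BMI at which the slope engages (default 25, the
#'   overweight threshold).
#' @param sex_offsets,age_offsets Named numeric offsets added to the bias for
#'   each sex / age group; the defaults make women and younger adults
#'   under-report more, the pattern seen in national survey comparisons.
#' @param noise_sd Standard deviation of reporting noise, BMI units.
#' @return An object of class `bias_model`.
#' @export
#' @examples
#' bias_model() # defaults
#' bias_model(intercept = 0, slope = 0, noise_sd = 0) # identity reporting
bias_model <- function(intercept = 0.4,
                       slope = 0.18,
                       pivot = 25,
                       sex_offsets = c(male = 0.1, female = 0.5),
                       age_offsets = c(
                         "18-34" = 0.30, "35-49" = 0.20,
                         "50-64" = 0.15, "65+" = 0
                       ),
                       noise_sd = 0.5) {
  if (!is.numeric(slope) || slope < 0) {
    abort("`slope` must be a nonnegative number (field: slope).")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    abort("`noise_sd` must be a nonnegative number (field: noise_sd).")
  }
  if (!all(.sexes %in% names(sex_offsets))) {
    abort("`sex_offsets` must name both sexes (field: sex_offsets).")
  }
  if (!all(.age_groups %in% names(age_offsets))) {
    abort("`age_offsets` must name all four age groups (field: age_offsets).")
  }
  structure(
    list(
      intercept = intercept, slope = slope, pivot = pivot,
      sex_offsets = sex_offsets, age_offsets = age_offsets,
      noise_sd = noise_sd
    ),
    class = "bias_model"
  )
}

# expected (noise-free) under-report for measured BMI in a given stratum
bias_delta <- function(bias, bmi, sex, age_group) {
  off_sex <- ifelse(is.na(sex), 0, unname(bias$sex_offsets[as.character(sex)]))
  off_age <- ifelse(is.na(age_group), 0,
    unname(bias$age_offsets[as.character(age_group)])
  )
  bias$intercept + bias$slope * pmax(0, bmi - bias$pivot) + off_sex + off_age
}

#' Default measured-BMI mixture parameters by stratum
#'
#' Each sex-by-age-group stratum draws measured BMI from a two-component
#' log-normal mixture: a bulk component around normal/overweight BMI and a
#' heavier right-tail component. The tail weights `pi2` were chosen once so
#' the analytic severe-obesity tail mass (BMI >= 40) of the stratum-share
#' weighted population is about 9% overall, about 11% among women and about
#' 6.5% among men, with a hump-shaped age profile — the order of magnitude
#' of measured US adult data.
#'
#' @return Tibble with one row per stratum: `sex`, `age_group`, bulk
#'   median/log-sd `m1`,`s1`, tail median/log-sd `m2`,`s2`, tail weight `pi2`.
#' @export
default_bmi_mixtures <- function() {
  tibble::tibble(
    sex = rep(.sexes, each = 4),
    age_group = rep(.age_groups, 2),
    m1 = rep(c(27.0, 26.0), each = 4),
    s1 = rep(c(0.165, 0.185), each = 4),
    m2 = rep(c(42, 43), each = 4),
    s2 = rep(c(0.16, 0.17), each = 4),
    pi2 = c(
      0.101, 0.110, 0.107, 0.045, # men by age group
      0.168, 0.183, 0.178, 0.079 # women by age group
    )
  )
}

#' Configuration of the synthetic survey population
#'
#' Bundles everything the generator needs: sample size, per-stratum measured
#' BMI mixtures, demographic composition, sampling-weight dispersion, and the
#' rates at which exclusion-triggering records (pregnancy, missing fields,
#' implausible anthropometrics) are injected completely at random.
#'
#' @param n Number of person records to draw (>= 1).
#' @param mixtures Tibble as returned by [default_bmi_mixtures()].
#' @param sex_shares,age_shares,race_shares Named non-negative shares summing
#'   to 1; age shares default to the composition of US adult survey data.
#' @param state_weights Allocation weights over the 51 jurisdictions (50
#'   states + DC); `NULL` means uniform.
#' @param metro_share Share of records in metropolitan counties.
#' @param weight_dispersion Coefficient of variation of the log-normal
#'   sampling weights (mean normalized to 1); 0 forces equal weights.
#' @param missingness_rates Named rates in \[0, 1\] for fields `sex`, `age`,
#'   `race_ethnicity`, `height`, `weight` set missing completely at random.
#' @param pregnancy_rate Probability that a woman aged under 50 is flagged
#'   pregnant.
#' @param implausible_rate Rate of records given biologically implausible
#'   height or weight.
#' @param seed Default seed used when the generator is called without one.
#' @return An object of class `population_config`.
#' @export
population_config <- function(n = 10000,
                              mixtures = default_bmi_mixtures(),
                              sex_shares = c(male = 0.5, female = 0.5),
                              age_shares = c(
                                "18-34" = 0.296, "35-49" = 0.229,
                                "50-64" = 0.251, "65+" = 0.224
                              ),
                              race_shares = c(
                                hispanic = 0.163, nh_asian = 0.055,
                                nh_black = 0.120, nh_white = 0.631,
                                nh_other = 0.031
                              ),
                              state_weights = NULL,
                              metro_share = 0.85,
                              weight_dispersion = 1,
                              missingness_rates = c(
                                sex = 0.002, age = 0.010,
                                race_ethnicity = 0.010,
                                height = 0.004, weight = 0.004
                              ),
                              pregnancy_rate = 0.005,
                              implausible_rate = 0.002,
                              seed = 1L) {
  cfg <- structure(
    list(
      n = n, mixtures = mixtures, sex_shares = sex_shares,
      age_shares = age_shares, race_shares = race_shares,
      state_weights = state_weights %||% rep(1 / 51, 51),
      metro_share = metro_share, weight_dispersion = weight_dispersion,
      missingness_rates = missingness_rates,
      pregnancy_rate = pregnancy_rate, implausible_rate = implausible_rate,
      seed = seed
    ),
    class = "population_config"
  )
  validate_population_config(cfg)
  cfg
}

validate_population_config <- function(cfg) {
  if (!is.numeric(cfg$n) || length(cfg$n) != 1 || is.na(cfg$n) || cfg$n < 1) {
    abort("`n` must be a positive integer (field: n).")
  }
  mx <- cfg$mixtures
  need <- c("sex", "age_group", "m1", "s1", "m2", "s2", "pi2")
  if (!all(need %in% names(mx)) ||
    !all(stratum_key(rep(.sexes, each = 4), rep(.age_groups, 2)) %in%
      stratum_key(mx$sex, mx$age_group))) {
    abort("`mixtures` must cover all 8 sex-by-age strata (field: mixtures).")
  }
  if (any(mx$pi2 < 0 | mx$pi2 > 1)) {
    abort("Mixture tail weights must lie in [0, 1] (field: mixtures$pi2).")
  }
  if (any(c(mx$m1, mx$m2) <= 0) || any(c(mx$s1, mx$s2) <= 0)) {
    abort("Mixture medians and log-sds must be positive (field: mixtures).")
  }
  check_shares <- function(x, field) {
    if (any(x < 0) || abs(sum(x) - 1) > 1e-8) {
      abort(sprintf(
        "`%s` must be non-negative and sum to 1 (field: %s).",
        field, field
      ))
    }
  }
  check_shares(cfg$sex_shares, "sex_shares")
  check_shares(cfg$age_shares, "age_shares")
  check_shares(cfg$race_shares, "race_shares")
  if (length(cfg$state_weights) != 51 || any(cfg$state_weights < 0) ||
    sum(cfg$state_weights) <= 0) {
    abort("`state_weights` must be 51 non-negative weights (field: state_weights).")
  }
  rates <- c(
    cfg$missingness_rates, cfg$pregnancy_rate, cfg$implausible_rate,
    cfg$metro_share
  )
  if (any(rates < 0 | rates > 1)) {
    abort("All rates must lie in [0, 1] (field: missingness_rates/pregnancy_rate/implausible_rate/metro_share).")
  }
  if (cfg$weight_dispersion < 0) {
    abort("`weight_dispersion` must be >= 0 (field: weight_dispersion).")
  }
  invisible(cfg)
}

#' Analytic severe-obesity tail mass of a population configuration
#'
#' Closed-form ground truth for the generator: the stratum-share weighted
#' probability that measured BMI meets the severe-obesity threshold under the
#' configured log-normal mixtures. This is the target that bias-corrected
#' prevalence estimates should recover.
#'
#' @param config A [population_config()].
#' @param threshold BMI cut point (default 40, severe / class III obesity).
#' @return Proportion in \[0, 1\].
#' @export
#' @examples
#' severe_obesity_truth(population_config())
severe_obesity_truth <- function(config, threshold = 40) {
  validate_population_config(config)
  mx <- config$mixtures
  share <- config$sex_shares[mx$sex] * config$age_shares[mx$age_group]
  tail2 <- function(m, s) 1 - plnorm(threshold, log(m), s)
  mass <- (1 - mx$pi2) * tail2(mx$m1, mx$s1) + mx$pi2 * tail2(mx$m2, mx$s2)
  sum(share * mass) / sum(share)
}

#' Generate a synthetic measured-anthropometry survey
#'
#' Draws `config$n` person records with measured height, weight and BMI from
#' the configured stratum mixtures, positive log-normal sampling weights
#' normalized to mean 1, and exclusion-triggering features (pregnancy flags,
#' missing fields, implausible anthropometrics) injected completely at
#' random. BMI is always `weight_kg / (height_cm / 100)^2` when both inputs
#' are present, and `NA` otherwise. Deterministic given `seed`.
#'
#' @param config A [population_config()].
#' @param seed Integer seed; defaults to the seed stored in the config.
#' @return Tibble of person records with columns `id`, `sex`, `age_years`,
#'   `age_group`, `race_ethnicity`, `state`, `locality`, `pregnant`,
#'   `height_cm`, `weight_kg`, `bmi`, `sample_weight`, `provenance`.
#' @export
#' @examples
#' pop <- generate_measured_population(population_config(n = 100), seed = 1)
generate_measured_population <- function(config, seed = config$seed) {
  validate_population_config(config)
  n <- as.integer(config$n)
  withr::with_seed(seed, {
    sex <- factor(
      sample(.sexes, n, replace = TRUE, prob = config$sex_shares[.sexes]),
      levels = .sexes
    )
    ag <- factor(
      sample(.age_groups, n,
        replace = TRUE,
        prob = config$age_shares[.age_groups]
      ),
      levels = .age_groups
    )
    lo <- c("18-34" = 18, "35-49" = 35, "50-64" = 50, "65+" = 65)[as.character(ag)]
    hi <- c("18-34" = 34, "35-49" = 49, "50-64" = 64, "65+" = 89)[as.character(ag)]
    age <- as.integer(floor(runif(n, lo, hi + 1)))

    mx <- config$mixtures
    key <- stratum_key(as.character(sex), as.character(ag))
    row <- match(key, stratum_key(mx$sex, mx$age_group))
    in_tail <- runif(n) < mx$pi2[row]
    bmi <- rlnorm(
      n,
      meanlog = log(ifelse(in_tail, mx$m2[row], mx$m1[row])),
      sdlog = ifelse(in_tail, mx$s2[row], mx$s1[row])
    )
    height <- rnorm(n,
      mean = ifelse(sex == "male", 175.5, 162.0),
      sd = ifelse(sex == "male", 7.1, 6.4)
    )
    weight <- bmi * (height / 100)^2

    race <- factor(
      sample(.race_levels, n,
        replace = TRUE,
        prob = config$race_shares[.race_levels]
      ),
      levels = .race_levels
    )
    state <- sample(.states, n, replace = TRUE, prob = config$state_weights)
    locality <- factor(
      ifelse(runif(n) < config$metro_share, "metropolitan", "nonmetropolitan"),
      levels = .localities
    )
    pregnant <- sex == "female" & !is.na(age) & age < 50 &
      runif(n) < config$pregnancy_rate

    if (config$weight_dispersion > 0) {
      s <- sqrt(log(1 + config$weight_dispersion^2))
      sw <- rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
    } else {
      sw <- rep(1, n)
    }

    # missingness completely at random
    mr <- config$missingness_rates
    rate <- function(f) if (f %in% names(mr)) mr[[f]] else 0
    sex[runif(n) < rate("sex")] <- NA
    drop_age <- runif(n) < rate("age")
    age[drop_age] <- NA
    ag[drop_age] <- NA
    race[runif(n) < rate("race_ethnicity")] <- NA
    height[runif(n) < rate("height")] <- NA
    weight[runif(n) < rate("weight")] <- NA

    # biologically implausible anthropometrics
    bad <- which(runif(n) < config$implausible_rate)
    if (length(bad)) {
      bad_h <- bad[runif(length(bad)) < 0.5]
      bad_w <- setdiff(bad, bad_h)
      height[bad_h] <- runif(length(bad_h), 20, 49)
      weight[bad_w] <- runif(length(bad_w), 5, 19)
    }

    tibble::tibble(
      id = sprintf("P%07d", seq_len(n)),
      sex = sex,
      age_years = age,
      age_group = ag,
      race_ethnicity = race,
      state = state,
      locality = locality,
      pregnant = pregnant,
      height_cm = height,
      weight_kg = weight,
      bmi = ifelse(is.na(height) | is.na(weight), NA_real_,
        weight / (height / 100)^2
      ),
      sample_weight = sw,
      provenance = "measured"
    )
  })
}

#' Distort a measured survey into a self-reported one
#'
#' Applies the parametric reporting-bias mechanism of [bias_model()] on the
#' BMI scale: each record's reported BMI is the measured BMI minus the
#' (stratum-specific, BMI-dependent) expected under-report, plus Gaussian
#' reporting noise. Reported weight is back-solved from reported BMI at
#' unchanged height so the anthropometric triple stays consistent. Ids,
#' demographics and sampling weights are preserved. Deterministic given
#' `seed`.
#'
#' @param records Person records with `provenance == "measured"` and `bmi`
#'   present for every row.
#' @param bias A [bias_model()].
#' @param seed Integer seed for the reporting noise.
#' @return The same records with `provenance = "self_reported"` and
#'   distorted `bmi` / `weight_kg`.
#' @export
apply_reporting_bias <- function(records, bias, seed = 1L) {
  stopifnot(inherits(bias, "bias_model"))
  if (!all(records$provenance == "measured")) {
    abort("`records` must all have provenance \"measured\".")
  }
  if (anyNA(records$bmi)) {
    bad <- records$id[which(is.na(records$bmi))]
    abort(sprintf(
      "Records with missing BMI cannot be distorted: %s%s.",
      paste(head(bad, 5), collapse = ", "),
      if (length(bad) > 5) ", ..." else ""
    ))
  }
  out <- records
  withr::with_seed(seed, {
    noise <- rnorm(nrow(records), 0, bias$noise_sd)
  })
  delta <- bias_delta(bias, records$bmi, records$sex, records$age_group)
  out$bmi <- records$bmi - delta + noise
  out$weight_kg <- out$bmi * (out$height_cm / 100)^2
  out$provenance <- "self_reported"
  out
}

#' Generate the paired-survey study design
#'
#' Draws three independent surveys from one generating process: a measured
#' reference survey (the examination-survey role), a self-reported reference
#' survey over the same period (used together with the measured reference to
#' estimate bias curves), and an independent self-reported target survey (the
#' survey whose BMI distribution is to be corrected). Records whose BMI is
#' missing in a self-reported draw are passed through with provenance flipped
#' but no distortion, since there is nothing to distort — they exercise the
#' exclusion filters downstream. Per-survey seeds are derived
#' deterministically from `seed`.
#'
#' @param config A [population_config()].
#' @param bias A [bias_model()].
#' @param seed Integer master seed.
#' @return Named list `measured_reference`, `self_reported_reference`,
#'   `self_reported_target`.
#' @export
#' @examples
#' surveys <- make_paired_surveys(population_config(n = 500), bias_model(), seed = 3)
make_paired_surveys <- function(config, bias, seed = config$seed) {
  validate_population_config(config)
  stopifnot(inherits(bias, "bias_model"))
  report_survey <- function(gen_seed, bias_seed) {
    pop <- generate_measured_population(config, gen_seed)
    has_bmi <- !is.na(pop$bmi)
    out <- pop
    if (any(has_bmi)) {
      out[has_bmi, ] <- apply_reporting_bias(pop[has_bmi, ], bias, bias_seed)
    }
    out$provenance <- "self_reported"
    out
  }
  list(
    measured_reference = generate_measured_population(
      config,
      derive_seed(seed, 1L)
    ),
    self_reported_reference = report_survey(
      derive_seed(seed, 2L), derive_seed(seed, 3L)
    ),
    self_reported_target = report_survey(
      derive_seed(seed, 4L), derive_seed(seed, 5L)
    )
  )
}
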