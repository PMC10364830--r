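test_that("population configs are validated field by field", {
  expect_error(population_config(n = 0), "n")
  expect_error(population_config(pregnancy_rate = 1.2), "rate")
  expect_error(population_config(weight_dispersion = -1), "weight_dispersion")
  expect_error(
    population_config(sex_shares = c(male = 0.7, female = 0.7)),
    "sex_shares"
  )
  bad_mix <- default_bmi_mixtures()
  bad_mix$pi2[3] <- 1.4
  expect_error(population_config(mixtures = bad_mix), "pi2")
})

test_that("generated populations honour weights, invariants and determinism", {
  cfg <- population_config(n = 1000, weight_dispersion = 0, seed = 7)
  pop <- generate_measured_population(cfg)
  expect_equal(nrow(pop), 1000)
  # zero dispersion forces equal weights
  expect_true(all(pop$sample_weight == pop$sample_weight[1]))
  expect_true(all(pop$sample_weight > 0))
  expect_true(all(pop$provenance == "measured"))
  # bmi is derived from height and weight wherever both are present
  ok <- !is.na(pop$height_cm) & !is.na(pop$weight_kg)
  expect_equal(pop$bmi[ok], pop$weight_kg[ok] / (pop$height_cm[ok] / 100)^2,
    tolerance = 1e-9
  )
  # age group is the bin containing age
  has_age <- !is.na(pop$age_years)
  expect_equal(
    as.character(pop$age_group[has_age]),
    as.character(age_group(pop$age_years[has_age]))
  )
  # pregnancy only among women under 50
  expect_true(all(pop$sex[pop$pregnant] == "female"))
  expect_true(all(pop$age_years[pop$pregnant] < 50, na.rm = TRUE))
  # determinism
  expect_identical(pop, generate_measured_population(cfg, seed = 7))
  expect_false(identical(pop$bmi, generate_measured_population(cfg, seed = 8)$bmi))
})

test_that("generated severe-obesity mass matches the analytic mixture tail", {
  cfg <- clean_config(100000, seed = 1)
  truth_closed <- severe_obesity_truth(cfg)
  truth_numint <- oracle_mixture_tail(cfg)
  # closed form and numerical integration of the stated density agree
  expect_equal(truth_closed, truth_numint, tolerance = 1e-8)
  pop <- generate_measured_population(cfg, seed = 1)
  emp <- sum(pop$sample_weight * (pop$bmi >= 40)) / sum(pop$sample_weight)
  expect_lt(abs(emp - truth_closed), 0.005)
})

test_that("reporting bias distorts BMI exactly as parameterized", {
  recs <- make_records(c(22, 30, 45), sex = "male", age_years = 70)
  # zero bias is the identity
  zero <- bias_model(
    intercept = 0, slope = 0, noise_sd = 0,
    sex_offsets = c(male = 0, female = 0),
    age_offsets = c("18-34" = 0, "35-49" = 0, "50-64" = 0, "65+" = 0)
  )
  expect_equal(apply_reporting_bias(recs, zero, seed = 1)$bmi, recs$bmi)
  # constant shift
  shift <- bias_model(
    intercept = 1, slope = 0, noise_sd = 0,
    sex_offsets = c(male = 0, female = 0),
    age_offsets = c("18-34" = 0, "35-49" = 0, "50-64" = 0, "65+" = 0)
  )
  expect_equal(apply_reporting_bias(recs, shift, seed = 1)$bmi, recs$bmi - 1)
  # hand arithmetic: 45 - (0.5 + 0.1 * 20) = 42.5
  hand <- bias_model(
    intercept = 0.5, slope = 0.1, pivot = 25, noise_sd = 0,
    sex_offsets = c(male = 0, female = 0),
    age_offsets = c("18-34" = 0, "35-49" = 0, "50-64" = 0, "65+" = 0)
  )
  out <- apply_reporting_bias(make_records(45), hand, seed = 1)
  expect_equal(out$bmi, 42.5)
  # reported weight is back-solved at unchanged height
  expect_equal(out$height_cm, 162)
  expect_equal(out$weight_kg, 42.5 * 1.62^2)
  expect_true(all(out$provenance == "self_reported"))
  # missing bmi is an error naming the record
  broken <- make_records(c(30, 40))
  broken$bmi[2] <- NA
  expect_error(apply_reporting_bias(broken, hand, seed = 1), "T002")
})

test_that("bias magnitude is non-decreasing in measured BMI when slope > 0", {
  recs <- make_records(sort(runif(200, 18, 60)), sex = "female", age_years = 40)
  noiseless <- bias_model(noise_sd = 0)
  rep <- apply_reporting_bias(recs, noiseless, seed = 1)
  gap <- recs$bmi - rep$bmi
  expect_true(all(diff(gap) >= -1e-12))
  expect_true(all(gap > 0))
})

test_that("paired surveys are deterministic and show the expected distortion", {
  cfg <- population_config(n = 4000, seed = 3)
  s1 <- make_paired_surveys(cfg, bias_model(), seed = 3)
  s2 <- make_paired_surveys(cfg, bias_model(), seed = 3)
  expect_identical(s1, s2)
  # weighted mean of the reported target sits below the measured reference
  wm <- function(d) {
    ok <- !is.na(d$bmi)
    sum(d$sample_weight[ok] * d$bmi[ok]) / sum(d$sample_weight[ok])
  }
  expect_lt(wm(s1$self_reported_target), wm(s1$measured_reference))
  # degenerate bias: reference pair indistinguishable in law
  zero <- bias_model(
    intercept = 0, slope = 0, noise_sd = 0,
    sex_offsets = c(male = 0, female = 0),
    age_offsets = c("18-34" = 0, "35-49" = 0, "50-64" = 0, "65+" = 0)
  )
  sz <- make_paired_surveys(clean_config(8000), zero, seed = 5)
  ks <- ks_compare(
    sz$self_reported_reference$bmi, sz$measured_reference$bmi,
    sz$self_reported_reference$sample_weight, sz$measured_reference$sample_weight
  )
  expect_gt(ks$p_value, 0.05)
})

test_that("naive reported severe-obesity prevalence is far below the measured truth", {
  cfg <- clean_config(100000, seed = 2)
  surveys <- make_paired_surveys(cfg, bias_model(), seed = 2)
  truth <- severe_obesity_truth(cfg)
  tgt <- surveys$self_reported_target
  naive <- sum(tgt$sample_weight * (tgt$bmi >= 40)) / sum(tgt$sample_weight)
  expect_lt(naive, 0.8 * truth)
})
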