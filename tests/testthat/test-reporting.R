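tab2 <- load_prevalence_table(bmibias_fixture("table2_severe_obesity_states.tsv"))
tab1 <- load_prevalence_table(bmibias_fixture("table1_severe_obesity_subgroups.tsv"))
national <- list(
  est = tab1$corrected_est[tab1$label == "Overall"],
  ci_low = tab1$corrected_ci_low[tab1$label == "Overall"],
  ci_high = tab1$corrected_ci_high[tab1$label == "Overall"]
)

test_that("the packaged state table parses with its published values", {
  expect_equal(nrow(tab2), 51) # 50 states + District of Columbia
  expect_equal(
    tab2$corrected_total_est[tab2$location == "West Virginia"], 13.2
  )
  expect_setequal(
    attr(tab2, "cells"),
    c("self_reported", "corrected_total", "corrected_men", "corrected_women")
  )
})

test_that("malformed prevalence tables are rejected with a location", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), tmp)
  expect_error(load_prevalence_table(tmp), "prevalence table|parse")
  writeLines(c(
    "location\tcorrected_total_est\tcorrected_total_ci_low\tcorrected_total_ci_high",
    "Ohio\t11.3\t10.5\t12.1", "Ohio\t11.3\t10.5\t12.1"
  ), tmp)
  expect_error(load_prevalence_table(tmp), "Duplicate")
  writeLines(c(
    "location\tcorrected_total_est\tcorrected_total_ci_low\tcorrected_total_ci_high",
    "Ohio\t11.3\t12.5\t12.1"
  ), tmp)
  expect_error(load_prevalence_table(tmp), "Ohio")
  expect_error(load_prevalence_table(file.path(tempdir(), "no-such.tsv")), "No such file")
})

test_that("threshold counts behave monotonically and respect the DC switch", {
  expect_equal(count_above(tab2, "corrected_total", Inf), 0)
  expect_equal(count_above(tab2, "corrected_total", 0), 50)
  expect_equal(count_above(tab2, "corrected_total", 0, include_dc = TRUE), 51)
  counts <- vapply(
    seq(0, 15, by = 0.5),
    function(t) count_above(tab2, "corrected_total", t), numeric(1)
  )
  expect_true(all(diff(counts) <= 0))
  expect_error(count_above(tab2, "corrected_banana", 10), "Unknown table column")
})

test_that("column extremes report values, labels and ties", {
  ext <- column_extremes(tab2, "corrected_total")
  expect_equal(ext$min$labels, "Massachusetts")
  expect_equal(ext$min$value, 5.5)
  expect_equal(ext$max$labels, "West Virginia")
  expect_equal(ext$max$value, 13.2)
  # published self-reported minimum is a two-state tie
  sr <- column_extremes(tab2, "self_reported")
  expect_setequal(sr$min$labels, c("Massachusetts", "Colorado"))
  expect_equal(sr$min$value, 3.3)
  one <- column_extremes(tab2[tab2$location == "Iowa", ], "corrected_total")
  expect_equal(one$min$value, one$max$value)
})

test_that("state flagging matches the published footnotes and its invariants", {
  flagged <- flag_above_national(tab2, "corrected_total", national)
  # one-sided default reproduces the published footnote set exactly
  expect_setequal(flagged, footnote_b_states)
  expect_setequal(flagged, tab2$location[tab2$sig_above_national])
  # flagged rows always sit above the national estimate
  expect_true(all(
    tab2$corrected_total_est[match(flagged, tab2$location)] > national$est
  ))
  # the national estimate is never flagged against itself
  self_row <- tibble::tibble(
    location = "National", corrected_total_est = national$est,
    corrected_total_ci_low = national$ci_low,
    corrected_total_ci_high = national$ci_high
  )
  expect_length(flag_above_national(self_row, "corrected_total", national), 0)
  # a row far below the national average is never flagged however tight its CI
  low_row <- tibble::tibble(
    location = "Lowland", corrected_total_est = 5,
    corrected_total_ci_low = 4.99, corrected_total_ci_high = 5.01
  )
  expect_length(flag_above_national(low_row, "corrected_total", national), 0)
  # two-sided testing of rounded printed CIs loses the two borderline states
  two_sided <- flag_above_national(tab2, "corrected_total", national,
    alternative = "two.sided"
  )
  expect_setequal(
    two_sided,
    setdiff(footnote_b_states, c("Delaware", "South Carolina"))
  )
  # missing CI errors with the row label
  broken <- tab2
  broken$corrected_total_ci_low[broken$location == "Iowa"] <- NA
  expect_error(flag_above_national(broken, "corrected_total", national), "Iowa")
})

test_that("relative underestimation follows its closed form", {
  expect_equal(relative_underestimation(7, 7), 0)
  expect_equal(relative_underestimation(4.4, 8.8), 50)
  expect_equal(relative_underestimation(5.3, 8.8, digits = 1), 39.8)
  expect_error(relative_underestimation(5, 0), "positive")
})

test_that("prevalence tables round-trip bit-identically through the writer", {
  tmp1 <- withr::local_tempfile(fileext = ".tsv")
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  write_prevalence_table(tab2, tmp1)
  back <- load_prevalence_table(tmp1)
  write_prevalence_table(back, tmp2)
  expect_identical(readLines(tmp1), readLines(tmp2))
  expect_equal(back$corrected_total_est, tab2$corrected_total_est)
})
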