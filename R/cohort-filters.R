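#' Cohort exclusion criteria
#'
#' Sequential exclusion rules applied to a survey before analysis: pregnant
#' respondents, missing required demographics, then missing or biologically
#' implausible anthropometrics (height below 50 cm or above 300 cm, weight
#' below 20 kg; the boundary values themselves are plausible and kept).
#'
#' @param exclude_pregnant Drop respondents flagged pregnant? Missing
#'   pregnancy status is treated as not pregnant.
#' @param required_fields Demographic fields that must be present, checked in
#'   order; allowed names are `"sex"`, `"age"`, `"race_ethnicity"`.
#' @param height_min_cm,height_max_cm,weight_min_kg Plausibility bounds.
#' @return An object of class `exclusion_criteria`.
#' @export
exclusion_criteria <- function(exclude_pregnant = TRUE,
                               required_fields = c(
                                 "sex", "age",
                                 "race_ethnicity"
                               ),
                               height_min_cm = 50,
                               height_max_cm = 300,
                               weight_min_kg = 20) {
  allowed <- c("sex", "age", "race_ethnicity")
  unknown <- setdiff(required_fields, allowed)
  if (length(unknown)) {
    abort(sprintf(
      "Unknown required field(s): %s. Allowed: %s.",
      paste(unknown, collapse = ", "), paste(allowed, collapse = ", ")
    ))
  }
  if (!(height_min_cm < height_max_cm)) {
    abort("`height_min_cm` must be below `height_max_cm`.")
  }
  if (weight_min_kg <= 0) {
    abort("`weight_min_kg` must be positive.")
  }
  structure(
    list(
      exclude_pregnant = exclude_pregnant,
      required_fields = required_fields,
      height_min_cm = height_min_cm,
      height_max_cm = height_max_cm,
      weight_min_kg = weight_min_kg
    ),
    class = "exclusion_criteria"
  )
}

#' Apply sequential cohort exclusions with an auditable log
#'
#' Excludes records in a fixed order — pregnant, then each missing required
#' demographic, then missing or implausible height/weight — counting every
#' record at the first criterion it fails only, so the log telescopes:
#' each step's `n_remaining` is the previous step's minus its `n_excluded`,
#' and the final `n_remaining` is the retained count. The retained set does
#' not depend on the ordering; only the attribution of the counts does.
#'
#' @param records Tibble of person records.
#' @param criteria An [exclusion_criteria()] object.
#' @param verbose Emit the log as messages?
#' @return List with `retained` (tibble of kept records) and `log`
#'   (tibble with columns `step`, `criterion`, `n_excluded`, `n_remaining`).
#' @export
#' @examples
#' pop <- generate_measured_population(population_config(n = 200), seed = 1)
#' res <- apply_exclusions(pop, exclusion_criteria())
#' res$log
apply_exclusions <- function(records, criteria = exclusion_criteria(),
                             verbose = FALSE) {
  stopifnot(inherits(criteria, "exclusion_criteria"))
  n <- nrow(records)
  field_cols <- c(
    sex = "sex", age = "age_years",
    race_ethnicity = "race_ethnicity"
  )
  fails <- list()
  if (isTRUE(criteria$exclude_pregnant)) {
    fails$pregnant <- !is.na(records$pregnant) & records$pregnant
  }
  for (f in criteria$required_fields) {
    fails[[paste0("missing_", f)]] <- is.na(records[[field_cols[[f]]]])
  }
  fails$anthropometrics <- is.na(records$height_cm) |
    is.na(records$weight_kg) |
    records$height_cm < criteria$height_min_cm |
    records$height_cm > criteria$height_max_cm |
    records$weight_kg < criteria$weight_min_kg
  fails$anthropometrics[is.na(fails$anthropometrics)] <- TRUE

  already <- rep(FALSE, n)
  steps <- names(fails)
  n_excl <- integer(length(steps))
  remaining <- n
  for (i in seq_along(steps)) {
    hit <- fails[[i]] & !already
    n_excl[i] <- sum(hit)
    already <- already | hit
    remaining <- remaining - n_excl[i]
  }
  log <- tibble::tibble(
    step = seq_along(steps),
    criterion = steps,
    n_excluded = n_excl,
    n_remaining = n - cumsum(n_excl)
  )
  if (verbose) {
    for (i in seq_len(nrow(log))) {
      message(sprintf(
        "exclusion %-22s removed %6d, %7d remaining",
        log$criterion[i], log$n_excluded[i], log$n_remaining[i]
      ))
    }
  }
  list(retained = records[!already, , drop = FALSE], log = log)
}
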