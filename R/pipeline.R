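#' Survey table input/output
#'
#' Person records are written as tab-separated text: one row per record, a
#' header row, UTF-8, `.` decimal separator and empty cells for missing
#' values. `read_survey_table()` restores the factor levels used throughout
#' the package.
#'
#' @param records Tibble of person records.
#' @param path File path.
#' @return `write_survey_table()` returns `path` invisibly;
#'   `read_survey_table()` the records tibble.
#' @export
write_survey_table <- function(records, path) {
  readr::write_tsv(records, path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname write_survey_table
#' @export
read_survey_table <- function(path) {
  tab <- readr::read_tsv(path,
    na = "", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      id = "c", sex = "c", age_years = "i", age_group = "c",
      race_ethnicity = "c", state = "c", locality = "c", pregnant = "l",
      height_cm = "d", weight_kg = "d", bmi = "d", sample_weight = "d",
      provenance = "c"
    )
  )
  tab$sex <- factor(tab$sex, levels = .sexes)
  tab$age_group <- factor(tab$age_group, levels = .age_groups)
  tab$race_ethnicity <- factor(tab$race_ethnicity, levels = .race_levels)
  tab$locality <- factor(tab$locality, levels = .localities)
  tab
}

#' Assemble a full pipeline run configuration
#'
#' @param population A [population_config()].
#' @param bias A [bias_model()].
#' @param exclusions An [exclusion_criteria()].
#' @param correction List of correction settings: `grid_size`, `spline`
#'   (`"smooth"` or `"natural"`), `tolerance` (BMI units, used for
#'   diagnostics), `isotonic`.
#' @param estimation List with `conf_level` and `alpha`.
#' @param report List with `threshold` (percent) and `include_dc`.
#' @param seed Master seed; every stage seed is derived from it.
#' @param output_dir Optional directory to write stage outputs into.
#' @return An object of class `run_config`.
#' @export
run_config <- function(population = population_config(),
                       bias = bias_model(),
                       exclusions = exclusion_criteria(),
                       correction = list(
                         grid_size = 99, spline = "natural",
                         tolerance = 0.1, isotonic = FALSE
                       ),
                       estimation = list(conf_level = 0.95, alpha = 0.05),
                       report = list(threshold = 10, include_dc = FALSE),
                       seed = 1L,
                       output_dir = NULL) {
  validate_population_config(population)
  stopifnot(inherits(bias, "bias_model"), inherits(exclusions, "exclusion_criteria"))
  if (is.null(seed) || is.na(seed)) {
    abort("`seed` must be present in the run configuration.")
  }
  defaults <- list(grid_size = 99, spline = "natural", tolerance = 0.1, isotonic = FALSE)
  correction <- utils::modifyList(defaults, correction)
  estimation <- utils::modifyList(list(conf_level = 0.95, alpha = 0.05), estimation)
  report <- utils::modifyList(list(threshold = 10, include_dc = FALSE), report)
  structure(
    list(
      population = population, bias = bias, exclusions = exclusions,
      correction = correction, estimation = estimation, report = report,
      seed = as.integer(seed), output_dir = output_dir
    ),
    class = "run_config"
  )
}

#' Read a declarative run configuration from YAML
#'
#' Any key left out falls back to the package defaults. Recognized top-level
#' keys: `population` (fields of [population_config()], except `mixtures`),
#' `bias` (fields of [bias_model()]), `exclusions`, `correction`,
#' `estimation`, `report`, `seed`, `output_dir`.
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  # YAML 1.1 would read the bare key `n` (and `y`) as a boolean; keep such
  # scalars literal while still converting real yes/no/true/false values
  bool_handler <- function(truth) {
    function(x) if (tolower(x) %in% c("true", "false", "yes", "no", "on", "off")) truth else x
  }
  y <- yaml::read_yaml(path, handlers = list(
    "bool#yes" = bool_handler(TRUE),
    "bool#no" = bool_handler(FALSE)
  ))
  as_named <- function(x) if (is.list(x)) unlist(x) else x
  pop_args <- y$population %||% list()
  for (f in c(
    "sex_shares", "age_shares", "race_shares", "missingness_rates",
    "state_weights"
  )) {
    if (!is.null(pop_args[[f]])) pop_args[[f]] <- as_named(pop_args[[f]])
  }
  bias_args <- y$bias %||% list()
  for (f in c("sex_offsets", "age_offsets")) {
    if (!is.null(bias_args[[f]])) bias_args[[f]] <- as_named(bias_args[[f]])
  }
  run_config(
    population = do.call(population_config, pop_args),
    bias = do.call(bias_model, bias_args),
    exclusions = do.call(exclusion_criteria, y$exclusions %||% list()),
    correction = y$correction %||% list(),
    estimation = y$estimation %||% list(),
    report = y$report %||% list(),
    seed = y$seed %||% 1L,
    output_dir = y$output_dir
  )
}

#' Run the full correction pipeline
#'
#' Executes generate, filter, fit curves, correct, validate and estimate as
#' one reproducible run: synthetic paired surveys are drawn, the sequential
#' exclusions applied to each, bias curves fitted from the filtered reference
#' pair, the filtered target survey corrected, the corrected-vs-measured
#' distributions compared with the weighted Kolmogorov-Smirnov test (pooled
#' and per stratum), and severe-obesity prevalence estimated before and after
#' correction, overall and by sex. Identical configuration and seed give an
#' identical manifest.
#'
#' @param config A [run_config()].
#' @return A list manifest: `seed`, `config_hash`, per-stage `counts`,
#'   exclusion logs, `ks` (pooled) and `ks_by_stratum`, `n_inversions`,
#'   `estimates` (prevalence table in percent), summary metrics
#'   (`truth_pct`, `self_reported_pct`, `corrected_pct`,
#'   `recovery_error_pp`, `naive_error_pp`), and `outputs` (paths written,
#'   when `output_dir` is set).
#' @export
#' @examples
#' cfg <- run_config(population = population_config(n = 2000), seed = 1)
#' manifest <- run_pipeline(cfg)
#' manifest$corrected_pct
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage \"%s\" failed: %s", name, conditionMessage(e)))
    })
  }

  surveys <- stage("generate", make_paired_surveys(
    config$population, config$bias,
    derive_seed(config$seed, 10L)
  ))
  filtered <- stage("filter", lapply(surveys, apply_exclusions, criteria = config$exclusions))
  meas <- filtered$measured_reference$retained
  self_ref <- filtered$self_reported_reference$retained
  target <- filtered$self_reported_target$retained

  curves <- stage("fit_curves", estimate_bias_curves(
    self_ref, meas,
    grid_size = config$correction$grid_size,
    spline = config$correction$spline
  ))
  corrected <- stage("correct", apply_correction(
    target, curves,
    isotonic = isTRUE(config$correction$isotonic)
  ))

  ks_pooled <- stage("validate", ks_compare(
    corrected$bmi, meas$bmi,
    corrected$sample_weight, meas$sample_weight
  ))
  ks_strata <- stage("validate", {
    keys <- unique(stratum_key(as.character(meas$sex), as.character(meas$age_group)))
    dplyr::bind_rows(lapply(sort(keys), function(k) {
      ci <- stratum_key(as.character(corrected$sex), as.character(corrected$age_group)) == k
      mi <- stratum_key(as.character(meas$sex), as.character(meas$age_group)) == k
      res <- ks_compare(
        corrected$bmi[ci], meas$bmi[mi],
        corrected$sample_weight[ci], meas$sample_weight[mi]
      )
      dplyr::mutate(res, stratum = k, .before = 1)
    }))
  })

  estimates <- stage("estimate", {
    cl <- config$estimation$conf_level
    rows <- dplyr::bind_rows(
      dplyr::mutate(
        estimate_by_groups(target, "sex", conf_level = cl),
        survey = "self_reported", .before = 1
      ),
      dplyr::mutate(
        estimate_by_groups(corrected, "sex", conf_level = cl),
        survey = "corrected", .before = 1
      )
    )
    dplyr::mutate(rows, dplyr::across(
      c("p_hat", "se", "ci_low", "ci_high"), ~ 100 * .x
    ))
  })

  truth <- severe_obesity_truth(config$population)
  self_pct <- estimates$p_hat[estimates$survey == "self_reported" &
    estimates$group == "overall"]
  corr_pct <- estimates$p_hat[estimates$survey == "corrected" &
    estimates$group == "overall"]

  manifest <- list(
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "output_dir")]),
    counts = tibble::tibble(
      survey = names(surveys),
      n_generated = unname(vapply(surveys, nrow, integer(1))),
      n_retained = unname(vapply(filtered, function(f) nrow(f$retained), integer(1))),
      n_excluded = unname(vapply(filtered, function(f) sum(f$log$n_excluded), integer(1)))
    ),
    exclusion_logs = lapply(filtered, `[[`, "log"),
    ks = ks_pooled,
    ks_by_stratum = ks_strata,
    n_inversions = attr(corrected, "n_inversions"),
    estimates = estimates,
    truth_pct = 100 * truth,
    self_reported_pct = self_pct,
    corrected_pct = corr_pct,
    recovery_error_pp = corr_pct - 100 * truth,
    naive_error_pp = self_pct - 100 * truth
  )

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(name) file.path(config$output_dir, name)
    write_survey_table(corrected, out("corrected_target.tsv"))
    readr::write_tsv(curves_to_table(curves), out("bias_curves.tsv"), progress = FALSE)
    readr::write_tsv(estimates, out("estimates.tsv"), progress = FALSE)
    jsonlite::write_json(
      manifest[c(
        "seed", "config_hash", "truth_pct", "self_reported_pct",
        "corrected_pct", "recovery_error_pp", "naive_error_pp",
        "n_inversions"
      )],
      out("manifest.json"),
      auto_unbox = TRUE, digits = NA
    )
    manifest$outputs <- vapply(
      c(
        "corrected_target.tsv", "bias_curves.tsv", "estimates.tsv",
        "manifest.json"
      ), out, character(1)
    )
  }
  manifest
}
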