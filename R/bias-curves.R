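#' Estimate quantile-specific self-report bias curves by stratum
#'
#' The core of the correction method. Within every sex-by-age-group stratum,
#' the raw bias at probability p is the difference between the weighted
#' quantiles of the measured and the self-reported reference surveys,
#' \eqn{\delta_{raw}(p) = Q_{meas}(p) - Q_{self}(p)}, evaluated on an equally
#' spaced grid in (0, 1) (default 99 percentiles, 0.01 to 0.99). A cubic
#' spline is then fitted to \eqn{(p, \delta_{raw}(p))} per stratum to give a
#' smooth bias curve over the whole BMI distribution; outside the grid the
#' curve is clamped to its endpoint values, since quantile differences are
#' unidentified beyond the observed tails.
#'
#' @param selfreported_ref,measured_ref Reference-period person records
#'   (complete `sex`, `age_group`, `bmi`, `sample_weight`); every stratum
#'   must be populated in both with at least two distinct BMI values.
#' @param grid_size Number of grid probabilities (>= 4); the grid is
#'   `seq_len(grid_size) / (grid_size + 1)`.
#' @param spline `"natural"` (the default) for a natural cubic interpolating
#'   spline through the raw differences — with reference surveys of realistic
#'   size the raw curve is already smooth, and interpolation preserves the
#'   quantile-matching property into the tails — or `"smooth"` for a cubic
#'   smoothing spline with generalized-cross-validated smoothness, which
#'   trades some tail fidelity for noise suppression in small references.
#' @param spar Optional smoothing parameter forwarded to
#'   [stats::smooth.spline()] when `spline = "smooth"`.
#' @return An object of class `bias_curves`: a named list (one element per
#'   stratum key `"sex:age_group"`) of `bias_curve` objects holding the
#'   stratum, grid, raw and smoothed deltas, and the fitted spline.
#' @export
#' @examples
#' surveys <- make_paired_surveys(population_config(
#'   n = 4000,
#'   missingness_rates = c(age = 0), pregnancy_rate = 0, implausible_rate = 0
#' ), bias_model(), seed = 1)
#' curves <- estimate_bias_curves(
#'   surveys$self_reported_reference,
#'   surveys$measured_reference
#' )
estimate_bias_curves <- function(selfreported_ref, measured_ref,
                                 grid_size = 99,
                                 spline = c("natural", "smooth"),
                                 spar = NULL) {
  spline <- match.arg(spline)
  if (grid_size < 4) {
    abort("`grid_size` must be at least 4.")
  }
  for (nm in c("selfreported_ref", "measured_ref")) {
    recs <- get(nm)
    if (anyNA(recs$bmi) || anyNA(recs$sex) || anyNA(recs$age_group)) {
      abort(sprintf(
        "`%s` must have complete bmi, sex and age_group (apply exclusions first).",
        nm
      ))
    }
  }
  grid <- seq_len(grid_size) / (grid_size + 1)
  curves <- list()
  for (sx in .sexes) {
    for (ag in .age_groups) {
      key <- stratum_key(sx, ag)
      s <- selfreported_ref[selfreported_ref$sex == sx &
        selfreported_ref$age_group == ag, ]
      m <- measured_ref[measured_ref$sex == sx & measured_ref$age_group == ag, ]
      if (nrow(s) == 0 || nrow(m) == 0 ||
        length(unique(s$bmi)) < 2 || length(unique(m$bmi)) < 2) {
        abort(sprintf(
          "Stratum %s needs at least 2 distinct BMI values in both references.",
          key
        ))
      }
      q_meas <- weighted_quantile(m$bmi, grid, m$sample_weight)
      q_self <- weighted_quantile(s$bmi, grid, s$sample_weight)
      delta_raw <- q_meas - q_self
      if (spline == "smooth") {
        fit <- smooth.spline(grid, delta_raw, cv = FALSE, spar = spar)
        fitted_fun <- smooth_predictor(fit)
      } else {
        fitted_fun <- splinefun(grid, delta_raw, method = "natural")
      }
      curves[[key]] <- structure(
        list(
          sex = sx, age_group = ag, grid = grid,
          delta_raw = delta_raw,
          delta_spline = fitted_fun(grid),
          fun = fitted_fun
        ),
        class = "bias_curve"
      )
    }
  }
  structure(curves, class = "bias_curves", spline = spline)
}

# factory so each curve's closure owns its fit (a for-loop body shares one
# frame, which would otherwise leave every closure pointing at the last fit)
smooth_predictor <- function(fit) {
  function(p) predict(fit, x = p)$y
}

#' Evaluate a bias curve at given probabilities
#'
#' Evaluates the stratum's fitted spline with clamped extrapolation:
#' probabilities outside the grid return the bias at the nearest grid
#' endpoint.
#'
#' @param curve A `bias_curve`.
#' @param p Probabilities in \[0, 1\].
#' @return Bias in BMI units at each `p`.
#' @export
eval_bias_curve <- function(curve, p) {
  stopifnot(inherits(curve, "bias_curve"))
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("`p` must lie in [0, 1].")
  }
  curve$fun(pmin(pmax(p, curve$grid[1]), curve$grid[length(curve$grid)]))
}

#' @export
print.bias_curve <- function(x, ...) {
  cat(sprintf(
    "<bias_curve %s: %d grid points, delta range [%.3f, %.3f] kg/m^2>\n",
    stratum_key(x$sex, x$age_group), length(x$grid),
    min(x$delta_spline), max(x$delta_spline)
  ))
  invisible(x)
}

#' Flatten bias curves to a delimited-friendly table
#'
#' @param curves A `bias_curves` collection.
#' @return Tibble with columns `sex`, `age_group`, `p`, `delta_raw`,
#'   `delta_spline`, one row per stratum and grid point.
#' @export
curves_to_table <- function(curves) {
  stopifnot(inherits(curves, "bias_curves"))
  dplyr::bind_rows(lapply(unname(curves), function(cv) {
    tibble::tibble(
      sex = cv$sex, age_group = cv$age_group, p = cv$grid,
      delta_raw = cv$delta_raw, delta_spline = cv$delta_spline
    )
  }))
}

#' Correct a self-reported survey with fitted bias curves
#'
#' For each record, the sample-weighted quantile rank of its self-reported
#' BMI is computed within its own sex-by-age-group stratum of the target
#' survey, the stratum's bias curve is evaluated at that rank, and the bias
#' is added: `corrected = reported + delta(rank)`. Record count, ids,
#' demographics and sampling weights are unchanged; only `bmi` moves. The
#' transformation is not guaranteed monotone, so the count of adjacent-rank
#' order inversions after correction is recorded in the `"n_inversions"`
#' attribute; `isotonic = TRUE` additionally applies a weighted isotonic
#' post-adjustment in rank order (off by default — diagnostics are preferred
#' to silent reordering).
#'
#' @param target Person records to correct (complete `sex`, `age_group`,
#'   `bmi`, `sample_weight`).
#' @param curves A `bias_curves` collection covering every occupied stratum.
#' @param isotonic Apply an isotonic post-adjustment to restore monotonicity?
#' @return The corrected records, with attribute `n_inversions`.
#' @export
apply_correction <- function(target, curves, isotonic = FALSE) {
  stopifnot(inherits(curves, "bias_curves"))
  if (anyNA(target$bmi) || anyNA(target$sex) || anyNA(target$age_group)) {
    abort("`target` must have complete bmi, sex and age_group (apply exclusions first).")
  }
  out <- target
  inversions <- 0L
  keys <- stratum_key(as.character(target$sex), as.character(target$age_group))
  for (key in unique(keys)) {
    if (is.null(curves[[key]])) {
      abort(sprintf("No bias curve for occupied stratum %s.", key))
    }
    idx <- which(keys == key)
    x <- target$bmi[idx]
    w <- target$sample_weight[idx]
    p <- weighted_rank(x, x, w)
    corrected <- x + eval_bias_curve(curves[[key]], p)
    o <- order(x)
    inversions <- inversions + sum(diff(corrected[o]) < 0)
    if (isotonic) {
      iso <- isoreg(seq_along(o), corrected[o])
      corrected[o] <- iso$yf
    }
    out$bmi[idx] <- corrected
  }
  out$weight_kg <- ifelse(is.na(out$height_cm), out$weight_kg,
    out$bmi * (out$height_cm / 100)^2
  )
  attr(out, "n_inversions") <- inversions
  out
}
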