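#' Normalize one compound of a kinetics series to its maximum
#'
#' Divides a compound's values by the series maximum of that compound, so
#' kinetics measured under different conditions or with different assays
#' become comparable dimensionless curves on [0, 1]. Censoring flags are
#' preserved (a censored 0 stays 0).
#'
#' @param series a `kinetics_series`.
#' @param compound one of `"biomass"`, `"phb"`, `"dpa"`, `"cry"`.
#' @return the series with that compound's column rescaled to max 1
#'   (values are then dimensionless fractions of the maximum).
#' @export
normalize_series <- function(series, compound = c("biomass", "phb", "dpa",
                                                  "cry")) {
  stopifnot(is.data.frame(series))
  compound <- match.arg(compound)
  col <- paste0(compound, "_g_per_l")
  if (!col %in% names(series)) stop("series is missing column: ", col)
  m <- max(series[[col]])
  if (!is.finite(m) || m <= 0)
    stop("cannot normalize '", compound,
         "': series maximum is not positive (all-zero series?)")
  series[[col]] <- series[[col]] / m
  series
}

#' Regress a kinetic parameter on initial glucose
#'
#' Ordinary least squares of one named model parameter on the initial
#' glucose concentration across fermentations, with the Pearson correlation
#' and its two-sided t-test. Across the four reference fermentations the
#' maximum concentrations of biomass, PHB and Cry and the critical times
#' scale linearly with initial glucose, while DPA_max shows no relationship.
#'
#' @param sets list of [biodynamic_params()] with `initial_glucose` set.
#' @param which parameter name as in [param_value()].
#' @return a one-row data frame of class `substrate_regression`:
#'   `parameter`, `slope`, `intercept`, `pearson_r`, `p_value`, `n`,
#'   `small_n` (TRUE when n < 5; with four fermentations the test is
#'   reported with that caveat).
#' @examples
#' parameter_substrate_regression(bt_param_sets(), "x_max")
#' @export
parameter_substrate_regression <- function(sets, which) {
  stopifnot(is.list(sets), length(sets) >= 3)
  glc <- vapply(sets, function(p) {
    stopifnot(inherits(p, "biodynamic_params"))
    if (is.null(p$initial_glucose)) NA_real_ else p$initial_glucose
  }, numeric(1))
  if (any(is.na(glc))) {
    who <- names(sets)[is.na(glc)]
    if (is.null(who) || !length(who)) who <- which(is.na(glc))
    stop("initial_glucose missing for set(s): ", paste(who, collapse = ", "))
  }
  y <- vapply(sets, param_value, numeric(1), which = which)
  fit <- stats::lm(y ~ glc)
  ct <- stats::cor.test(glc, y, method = "pearson",
                        alternative = "two.sided")
  out <- data.frame(parameter = which,
                    slope = unname(stats::coef(fit)[2]),
                    intercept = unname(stats::coef(fit)[1]),
                    pearson_r = unname(ct$estimate),
                    p_value = ct$p.value,
                    n = length(y),
                    small_n = length(y) < 5)
  class(out) <- c("substrate_regression", "data.frame")
  out
}

#' Monotone trend of the PHB-partition yields with initial glucose
#'
#' Spearman rank correlation of Y_Cry/PHB and Y_DPA/PHB with the initial
#' glucose concentration. Across the reference fermentations Y_Cry/PHB
#' rises monotonically with substrate while Y_DPA/PHB falls, i.e. endospore
#' formation takes its PHB share first and the surplus goes to Cry.
#'
#' @param sets list of >= 3 [biodynamic_params()] with distinct
#'   `initial_glucose` values (ties are rejected: ranks would be ambiguous).
#' @return a data frame with one row per yield: `yield`, `spearman_rho`,
#'   `trend` (`"increasing"`, `"decreasing"`, `"mixed"` or `"none"` for a
#'   constant yield), `n`.
#' @examples
#' yield_trend(bt_param_sets())
#' @export
yield_trend <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 3)
  glc <- vapply(sets, function(p) {
    if (is.null(p$initial_glucose)) NA_real_ else p$initial_glucose
  }, numeric(1))
  if (any(is.na(glc)))
    stop("initial_glucose missing for at least one parameter set")
  if (anyDuplicated(glc))
    stop("tied initial_glucose values: ranks are ambiguous")
  one <- function(key) {
    y <- vapply(sets, param_value, numeric(1), which = key)
    if (stats::sd(y) == 0)
      return(data.frame(yield = key, spearman_rho = NA_real_,
                        trend = "none", n = length(y)))
    rho <- stats::cor(glc, y, method = "spearman")
    trend <- if (rho == 1) "increasing" else if (rho == -1) "decreasing"
             else "mixed"
    data.frame(yield = key, spearman_rho = rho, trend = trend, n = length(y))
  }
  rbind(one("y_cry_phb"), one("y_dpa_phb"))
}
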