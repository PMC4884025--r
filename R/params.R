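#' Gompertz parameter triple
#'
#' One sigmoid term of the biodynamic model: the Gompertz curve
#' \eqn{A \exp(-\exp(-\mu (t - t_c)))} with asymptote \eqn{A} (g/L),
#' maximum specific rate \eqn{\mu} (1/h) and critical (inflection) time
#' \eqn{t_c} (h). At \eqn{t = t_c} the curve equals \eqn{A/e} and its slope
#' attains the maximum \eqn{\mu A / e}.
#'
#' @param asymptote maximum concentration reached, g/L; must be >= 0.
#' @param rate maximum specific rate, 1/h; must be > 0.
#' @param critical_time inflection time, hours since inoculation; any finite
#'   value (the curve is defined for all t).
#' @return an object of class `gompertz_params`.
#' @examples
#' gompertz_params(5.58, 0.78, 4.54)
#' @export
gompertz_params <- function(asymptote, rate, critical_time) {
  stopifnot(is.numeric(asymptote), length(asymptote) == 1L,
            is.numeric(rate), length(rate) == 1L,
            is.numeric(critical_time), length(critical_time) == 1L)
  if (!is.finite(asymptote) || asymptote < 0)
    stop("'asymptote' must be finite and >= 0, got ", asymptote)
  if (!is.finite(rate) || rate <= 0)
    stop("'rate' must be finite and > 0, got ", rate)
  if (!is.finite(critical_time))
    stop("'critical_time' must be finite, got ", critical_time)
  structure(list(asymptote = asymptote, rate = rate,
                 critical_time = critical_time),
            class = "gompertz_params")
}

#' Yield coefficients coupling the model equations
#'
#' Grams of product formed per gram of precursor consumed. DPA (the endospore
#' proxy) forms at the expense of vegetative biomass, and DPA and Cry protein
#' both form at the expense of PHB, the carbon/energy store laid down during
#' the transition phase.
#'
#' @param dpa_from_biomass g DPA formed per g biomass consumed (Y_DPA/X).
#' @param dpa_from_phb g DPA per g PHB (Y_DPA/PHB).
#' @param cry_from_phb g Cry per g PHB (Y_Cry/PHB).
#' @return an object of class `yield_coefficients`. All must be > 0.
#' @export
yield_coefficients <- function(dpa_from_biomass, dpa_from_phb, cry_from_phb) {
  vals <- c(dpa_from_biomass = dpa_from_biomass,
            dpa_from_phb = dpa_from_phb,
            cry_from_phb = cry_from_phb)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("yield coefficients must all be finite and strictly positive; got ",
         paste(names(vals)[!is.finite(vals) | vals <= 0], collapse = ", "))
  structure(as.list(vals), class = "yield_coefficients")
}

#' Full biodynamic parameter set
#'
#' The 15 parameters of the coupled model: one Gompertz triple per key
#' compound (biomass, PHB, DPA, Cry) plus the three yield coefficients,
#' optionally annotated with the fermentation label and the initial
#' glucose/soybean-meal concentrations of the culture medium.
#'
#' @param biomass,phb,dpa,cry [gompertz_params()] triples for each compound.
#' @param yields a [yield_coefficients()] object.
#' @param label free-text identifier, e.g. `"F1"`.
#' @param initial_glucose,initial_soybean starting substrate concentrations,
#'   g/L; optional, used by the cross-fermentation analyses.
#' @return an object of class `biodynamic_params`.
#' @seealso [bt_param_sets()] for the bundled reference sets.
#' @export
biodynamic_params <- function(biomass, phb, dpa, cry, yields, label = NULL,
                              initial_glucose = NULL, initial_soybean = NULL) {
  for (nm in c("biomass", "phb", "dpa", "cry")) {
    obj <- get(nm, inherits = FALSE)
    if (!inherits(obj, "gompertz_params"))
      stop("'", nm, "' must be a gompertz_params object")
  }
  if (!inherits(yields, "yield_coefficients"))
    stop("'yields' must be a yield_coefficients object")
  if (!is.null(initial_glucose)) {
    stopifnot(is.numeric(initial_glucose), length(initial_glucose) == 1L)
    if (!is.finite(initial_glucose) || initial_glucose < 0)
      stop("'initial_glucose' must be finite and >= 0")
  }
  if (!is.null(label)) stopifnot(is.character(label), length(label) == 1L)
  structure(list(biomass = biomass, phb = phb, dpa = dpa, cry = cry,
                 yields = yields, label = label,
                 initial_glucose = initial_glucose,
                 initial_soybean = initial_soybean),
            class = "biodynamic_params")
}

# canonical flat key order used by the config reader/writer and by
# param_value(); keys mirror the field nomenclature
.param_keys <- c("x_max", "mu_max", "t_c",
                 "phb_max", "mu_max_p", "t_c_p",
                 "dpa_max", "mu_max_d", "t_c_d",
                 "cry_max", "mu_max_c", "t_c_c",
                 "y_dpa_x", "y_dpa_phb", "y_cry_phb")

#' Extract one named parameter from a biodynamic parameter set
#'
#' @param params a [biodynamic_params()] object.
#' @param which one of `"x_max"`, `"mu_max"`, `"t_c"`, `"phb_max"`,
#'   `"mu_max_p"`, `"t_c_p"`, `"dpa_max"`, `"mu_max_d"`, `"t_c_d"`,
#'   `"cry_max"`, `"mu_max_c"`, `"t_c_c"`, `"y_dpa_x"`, `"y_dpa_phb"`,
#'   `"y_cry_phb"`.
#' @return a single numeric value.
#' @export
param_value <- function(params, which) {
  stopifnot(inherits(params, "biodynamic_params"))
  which <- match.arg(which, .param_keys)
  flat <- params_to_flat(params)
  flat[[which]]
}

# 15-parameter named numeric vector in canonical order
params_to_flat <- function(params) {
  g <- function(p) c(p$asymptote, p$rate, p$critical_time)
  out <- c(g(params$biomass), g(params$phb), g(params$dpa), g(params$cry),
           params$yields$dpa_from_biomass, params$yields$dpa_from_phb,
           params$yields$cry_from_phb)
  names(out) <- .param_keys
  out
}

flat_to_params <- function(flat, label = NULL, initial_glucose = NULL,
                           initial_soybean = NULL) {
  stopifnot(all(.param_keys %in% names(flat)))
  biodynamic_params(
    biomass = gompertz_params(flat[["x_max"]], flat[["mu_max"]], flat[["t_c"]]),
    phb     = gompertz_params(flat[["phb_max"]], flat[["mu_max_p"]], flat[["t_c_p"]]),
    dpa     = gompertz_params(flat[["dpa_max"]], flat[["mu_max_d"]], flat[["t_c_d"]]),
    cry     = gompertz_params(flat[["cry_max"]], flat[["mu_max_c"]], flat[["t_c_c"]]),
    yields  = yield_coefficients(flat[["y_dpa_x"]], flat[["y_dpa_phb"]],
                                 flat[["y_cry_phb"]]),
    label = label, initial_glucose = initial_glucose,
    initial_soybean = initial_soybean)
}

#' Reference parameter sets for the four calibration fermentations
#'
#' The published parameter sets estimated for four batch fermentations of
#' *B. thuringiensis* var. *kurstaki* HD-73 (labelled F1--F4) run at
#' increasing glucose--soybean meal levels (25.1/4.4 to 54.1/35.37 g/L) at a
#' fixed carbon:nitrogen ratio of 7:1. These are the generating truths for
#' the synthetic-data study and the inputs to the cross-fermentation
#' analyses.
#'
#' @return a named list of four [biodynamic_params()] objects
#'   (`F1`..`F4`), each carrying its `initial_glucose` and
#'   `initial_soybean`.
#' @examples
#' sets <- bt_param_sets()
#' sets$F1$biomass$asymptote  # 5.58 g/L
#' @export
bt_param_sets <- function() {
  tab <- list(
    #        Xmax  mu    tc    Pmax  mup   tcp   Dmax  mud   tcd    Cmax  muc   tcc    ydx     ydp   ycp   glc    soy
    F1 = c(5.58, 0.78, 4.54, 0.61, 1.07, 8.46, 0.17, 0.66, 14.12, 0.19, 0.20, 14.88, 0.025,  1.02, 0.19, 25.10,  4.40),
    F2 = c(8.58, 1.06, 4.12, 0.71, 0.89, 7.90, 0.18, 0.72, 12.94, 0.31, 0.42, 12.77, 0.030,  0.43, 2.53, 34.74, 14.73),
    F3 = c(10.09, 0.90, 4.95, 1.16, 0.95, 8.39, 0.16, 0.59, 15.77, 0.53, 0.40, 14.96, 0.018,  0.21, 4.92, 44.42, 25.05),
    F4 = c(13.07, 0.86, 6.58, 1.41, 1.02, 8.88, 0.16, 0.65, 14.32, 0.78, 0.33, 16.46, 0.0093, 0.15, 5.83, 54.10, 35.37))
  out <- lapply(names(tab), function(lab) {
    v <- tab[[lab]]
    flat <- stats::setNames(v[1:15], .param_keys)
    flat_to_params(flat, label = lab, initial_glucose = v[16],
                   initial_soybean = v[17])
  })
  stats::setNames(out, names(tab))
}

#' @export
print.gompertz_params <- function(x, ...) {
  cat(sprintf("Gompertz triple: asymptote %.4g g/L, rate %.4g 1/h, critical time %.4g h\n",
              x$asymptote, x$rate, x$critical_time))
  invisible(x)
}

#' @export
print.biodynamic_params <- function(x, ...) {
  cat("Biodynamic parameter set",
      if (!is.null(x$label)) paste0("'", x$label, "'"), "\n")
  if (!is.null(x$initial_glucose))
    cat(sprintf("  initial glucose %.4g g/L\n", x$initial_glucose))
  flat <- params_to_flat(x)
  for (i in seq(1, 12, by = 3))
    cat(sprintf("  %-8s A = %-7.4g mu = %-7.4g t_c = %.4g\n",
                c("biomass", "phb", "dpa", "cry")[(i + 2) / 3],
                flat[i], flat[i + 1], flat[i + 2]))
  cat(sprintf("  yields   Y_DPA/X = %.4g, Y_DPA/PHB = %.4g, Y_Cry/PHB = %.4g\n",
              flat[13], flat[14], flat[15]))
  invisible(x)
}
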