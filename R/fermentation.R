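# IUPAC 2021 standard atomic weights, rounded to 3 decimals; single source
# for all stoichiometric arithmetic
.atomic_masses <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007)

# single B. thuringiensis cell dry weight, picograms
.cell_weight_pg <- 2.3

#' Convert a cell count to biomass concentration
#'
#' Direct-count data (CFU per cm^3) are expressed as dry biomass using a
#' single-cell weight of 2.3 pg for *B. thuringiensis*:
#' count x 2.3e-12 g x 1000 cm^3/L.
#'
#' @param count cells (CFU) per cm^3; non-negative.
#' @return biomass in g/L.
#' @examples
#' cfu_to_biomass(1.65e9)  # 3.795 g/L
#' @export
cfu_to_biomass <- function(count) {
  stopifnot(is.numeric(count))
  if (any(!is.finite(count)) || any(count < 0))
    stop("'count' must be finite and >= 0")
  count * (.cell_weight_pg * 1e-12) * 1e3
}

#' Compound content as percent of dry cell weight
#'
#' The PHB or Cry content of a culture, reported as the maximum compound
#' concentration relative to the maximum biomass concentration of the same
#' run.
#'
#' @param compound_max maximum compound concentration, g/L.
#' @param biomass_max maximum biomass concentration, g/L; must be > 0.
#' @return percent (0-100 for compounds below biomass).
#' @examples
#' percent_dry_weight(0.78, 13.07)  # ~6% Cry of dry weight
#' @export
percent_dry_weight <- function(compound_max, biomass_max) {
  stopifnot(is.numeric(compound_max), is.numeric(biomass_max))
  if (any(biomass_max <= 0)) stop("'biomass_max' must be > 0")
  100 * compound_max / biomass_max
}

#' Culture phase boundaries from the fitted parameters
#'
#' The culture phases are read off the model in closed form: a Gompertz term
#' reaches the fraction f of its asymptote at
#' \eqn{t = t_c - \ln(-\ln f)/\mu}. With the default f = 0.05 the biomass
#' onset marks the end of the lag phase, the PHB onset the end of vegetative
#' growth (start of transition), and the DPA onset the end of transition
#' (start of sporulation, DPA being the endospore proxy).
#'
#' @param params a [biodynamic_params()] set.
#' @param onset_fraction fraction of the asymptote defining "onset",
#'   strictly in (0, 1); default 0.05.
#' @return a list of class `phase_boundaries`: `lag_end`,
#'   `vegetative_end`, `transition_end` (hours), `onset_fraction`.
#' @examples
#' phase_boundaries(bt_param_sets()$F1)  # lag ends ~3.1 h
#' @export
phase_boundaries <- function(params, onset_fraction = 0.05) {
  stopifnot(inherits(params, "biodynamic_params"),
            is.numeric(onset_fraction), length(onset_fraction) == 1L)
  if (!is.finite(onset_fraction) || onset_fraction <= 0 || onset_fraction >= 1)
    stop("'onset_fraction' must lie strictly in (0, 1)")
  onset <- function(p) p$critical_time - log(-log(onset_fraction)) / p$rate
  out <- list(lag_end = onset(params$biomass),
              vegetative_end = onset(params$phb),
              transition_end = onset(params$dpa),
              onset_fraction = onset_fraction)
  if (!(out$lag_end <= out$vegetative_end &&
        out$vegetative_end <= out$transition_end))
    warning("phase onsets are not ordered (lag <= vegetative <= transition) ",
            "for this parameter set")
  class(out) <- "phase_boundaries"
  out
}

#' @export
print.phase_boundaries <- function(x, ...) {
  cat(sprintf(paste0("Culture phases (onset = %.3g of asymptote):\n",
                     "  lag until %.2f h; vegetative growth until %.2f h;\n",
                     "  transition until %.2f h; sporulation thereafter\n"),
              x$onset_fraction, x$lag_end, x$vegetative_end,
              x$transition_end))
  invisible(x)
}

#' Elemental composition per C-mol
#'
#' Stoichiometric subscripts of a compound normalized to one carbon atom,
#' e.g. the standard biomass composition CH1.8O0.5N0.2 or glucose as CH2O.
#'
#' @param h,o,n subscripts of H, O, N per carbon; non-negative.
#' @param c carbon subscript; must equal 1 (C-mol basis).
#' @return a list of class `elemental_composition`.
#' @export
elemental_composition <- function(h, o = 0, n = 0, c = 1) {
  vals <- c(c = c, h = h, o = o, n = n)
  stopifnot(is.numeric(vals), all(is.finite(vals)))
  if (c != 1) stop("carbon subscript must be 1 (C-mol basis), got ", c)
  if (any(vals < 0)) stop("subscripts must be >= 0")
  structure(as.list(vals), class = "elemental_composition")
}

#' @rdname elemental_composition
#' @export
bt_biomass_composition <- function() elemental_composition(h = 1.8, o = 0.5,
                                                           n = 0.2)

#' @rdname elemental_composition
#' @export
glucose_composition <- function() elemental_composition(h = 2, o = 1)

cmol_mass <- function(comp) {
  comp$c * .atomic_masses[["C"]] + comp$h * .atomic_masses[["H"]] +
    comp$o * .atomic_masses[["O"]] + comp$n * .atomic_masses[["N"]]
}

#' Stoichiometric ceiling on the biomass yield
#'
#' Anaerobic carbon balance with every substrate carbon fixed into biomass
#' and no CO2 formed: the maximum Y_X/S is the ratio of the C-mol masses of
#' biomass and substrate. Any growth yield above this ceiling implies the
#' substrate in question is not the limiting one. For the standard biomass
#' composition CH1.8O0.5N0.2 against glucose (CH2O) the ceiling is
#' 24.626/30.026 = 0.820 g biomass/g glucose.
#'
#' @param biomass,substrate [elemental_composition()] objects (C-mol basis).
#' @return g biomass per g substrate.
#' @examples
#' max_anaerobic_yield(bt_biomass_composition(), glucose_composition())
#' @export
max_anaerobic_yield <- function(biomass = bt_biomass_composition(),
                                substrate = glucose_composition()) {
  stopifnot(inherits(biomass, "elemental_composition"),
            inherits(substrate, "elemental_composition"))
  ms <- cmol_mass(substrate)
  if (ms <= 0) stop("substrate C-mol mass must be > 0")
  cmol_mass(biomass) / ms
}

#' Classify a growth yield against a stoichiometric bound
#'
#' @param y_xs observed growth yield(s), g biomass/g substrate; >= 0.
#' @param bound stoichiometric ceiling, g/g (default the anaerobic
#'   glucose ceiling of [max_anaerobic_yield()]). The bound is closed:
#'   a yield equal to it is classified as within.
#' @return a data frame with columns `y_xs`, `bound`, `exceeds` (logical)
#'   and `classification` (`"within"`/`"exceeds"`).
#' @examples
#' check_yield_bound(c(0.25, 2.25))
#' @export
check_yield_bound <- function(y_xs, bound = max_anaerobic_yield()) {
  stopifnot(is.numeric(y_xs), is.numeric(bound), length(bound) == 1L)
  if (any(!is.finite(y_xs)) || any(y_xs < 0))
    stop("'y_xs' must be finite and >= 0")
  exceeds <- y_xs > bound
  data.frame(y_xs = y_xs, bound = bound, exceeds = exceeds,
             classification = ifelse(exceeds, "exceeds", "within"))
}
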