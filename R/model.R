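#' Evaluate a Gompertz curve
#'
#' The asymmetric sigmoid \eqn{A \exp(-\exp(-\mu (t - t_c)))}. Monotone
#' non-decreasing in t, tending to 0 as \eqn{t \to -\infty} and to the
#' asymptote as \eqn{t \to +\infty}; equals \eqn{A/e} at the critical time.
#'
#' @param t time(s) in hours since inoculation; any finite value(s).
#' @param p a [gompertz_params()] triple.
#' @return concentration(s) in g/L, same length as `t`.
#' @examples
#' gompertz_value(4.54, gompertz_params(5.58, 0.78, 4.54))  # 5.58 / e
#' @export
gompertz_value <- function(t, p) {
  stopifnot(inherits(p, "gompertz_params"), is.numeric(t))
  if (length(t) == 0L) stop("'t' must contain at least one time point")
  if (any(!is.finite(t))) stop("non-finite time values are not allowed")
  p$asymptote * exp(-exp(-p$rate * (t - p$critical_time)))
}

#' Key-compound concentrations of the biodynamic model
#'
#' The coupled model assigns one equation per key compound. DPA and Cry
#' protein are plain Gompertz sigmoids (sporulation runs as simultaneous,
#' parallel DPA and Cry production). Biomass is a two-term balance, Gompertz
#' growth minus the biomass consumed by endospore (DPA) formation:
#' \deqn{X(t) = X_{max} e^{-e^{-\mu_{max}(t - t_c)}} - DPA(t) / Y_{DPA/X}.}
#' PHB is likewise production minus consumption, PHB being the carbon and
#' energy source for both DPA and Cry formation:
#' \deqn{PHB(t) = PHB_{max} e^{-e^{-\mu_{maxp}(t - t_{cp})}}
#'   - DPA(t)/Y_{DPA/PHB} - Cry(t)/Y_{Cry/PHB}.}
#'
#' With realistic parameter sets the biomass and PHB equations go negative
#' late in culture (consumption outstrips the asymptote). The equations are
#' reported faithfully by default; `clamp = TRUE` reports negative values as
#' 0 and flags them via a `"clamped"` attribute, which is what an assay
#' would observe.
#'
#' @param t time(s), hours.
#' @param params a [biodynamic_params()] set.
#' @param clamp report negative biomass/PHB values as 0 (flagged)?
#' @return concentration(s), g/L. When `clamp = TRUE` the result carries a
#'   logical `"clamped"` attribute marking replaced values.
#' @name key_compounds
NULL

#' @rdname key_compounds
#' @export
dpa_at <- function(t, params) {
  stopifnot(inherits(params, "biodynamic_params"))
  gompertz_value(t, params$dpa)
}

#' @rdname key_compounds
#' @export
cry_at <- function(t, params) {
  stopifnot(inherits(params, "biodynamic_params"))
  gompertz_value(t, params$cry)
}

#' @rdname key_compounds
#' @export
biomass_at <- function(t, params, clamp = FALSE) {
  stopifnot(inherits(params, "biodynamic_params"))
  x <- gompertz_value(t, params$biomass) -
    dpa_at(t, params) / params$yields$dpa_from_biomass
  maybe_clamp(x, clamp)
}

#' @rdname key_compounds
#' @export
phb_at <- function(t, params, clamp = FALSE) {
  stopifnot(inherits(params, "biodynamic_params"))
  x <- gompertz_value(t, params$phb) -
    dpa_at(t, params) / params$yields$dpa_from_phb -
    cry_at(t, params) / params$yields$cry_from_phb
  maybe_clamp(x, clamp)
}

maybe_clamp <- function(x, clamp) {
  if (!clamp) return(x)
  flag <- x < 0
  x[flag] <- 0
  attr(x, "clamped") <- flag
  x
}

#' Simulate a full culture trajectory
#'
#' Evaluates all four key compounds on a time grid.
#'
#' @param params a [biodynamic_params()] set.
#' @param times strictly increasing time points, hours.
#' @param clamp report negative biomass/PHB as 0 (see [biomass_at()]).
#' @return a data frame of class `bt_trajectory` with columns `time_h`,
#'   `biomass_g_per_l`, `phb_g_per_l`, `dpa_g_per_l`, `cry_g_per_l`. When
#'   `clamp = TRUE` a logical matrix attribute `"clamped"` (one column per
#'   compound) marks values reported as 0 in place of a negative model
#'   value.
#' @examples
#' f1 <- bt_param_sets()$F1
#' simulate_kinetics(f1, seq(0, 20, by = 2))
#' @export
simulate_kinetics <- function(params, times, clamp = FALSE) {
  stopifnot(inherits(params, "biodynamic_params"), is.numeric(times))
  if (length(times) == 0L) stop("'times' must contain at least one point")
  if (any(!is.finite(times))) stop("non-finite time values are not allowed")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("'times' must be strictly increasing")
  x <- biomass_at(times, params, clamp = clamp)
  p <- phb_at(times, params, clamp = clamp)
  d <- dpa_at(times, params)
  cr <- cry_at(times, params)
  out <- data.frame(time_h = times,
                    biomass_g_per_l = as.numeric(x),
                    phb_g_per_l = as.numeric(p),
                    dpa_g_per_l = d,
                    cry_g_per_l = cr)
  if (clamp) {
    flags <- cbind(biomass = attr(x, "clamped"), phb = attr(p, "clamped"),
                   dpa = rep(FALSE, length(times)),
                   cry = rep(FALSE, length(times)))
    attr(out, "clamped") <- flags
  }
  class(out) <- c("bt_trajectory", "data.frame")
  out
}
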