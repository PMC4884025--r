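#' Study design for synthetic kinetics
#'
#' Describes the sampling and measurement process of the batch fermentations
#' the model was calibrated on: sampling every 2 h over a ~20 h culture,
#' multiplicative assay noise, per-compound technical replicates (PHB and
#' Cry assayed in quadruplicate, DPA photoluminescence in duplicate, biomass
#' by direct count once), and detection-limit censoring that reproduces the
#' early-culture non-detect windows (no PHB in the first ~6 h, no DPA/Cry in
#' the first ~10-14 h).
#'
#' @param t_start,t_end culture window, hours.
#' @param sampling_interval hours between samples (default 2).
#' @param noise_relative_sd relative SD of the multiplicative measurement
#'   noise per replicate (default 0.05). The assays' true error magnitudes
#'   are not reported; 5\% is a declared assumption.
#' @param detection_limits named g/L limits per compound below which a
#'   measurement is recorded as 0.
#' @param replicates named counts of technical replicates averaged per time
#'   point.
#' @param seed integer RNG seed; identical seeds give identical series.
#' @return a list of class `study_design`.
#' @export
study_design <- function(t_start = 0, t_end = 20, sampling_interval = 2,
                         noise_relative_sd = 0.05,
                         detection_limits = c(biomass = 0.01, phb = 0.05,
                                              dpa = 0.01, cry = 0.02),
                         replicates = c(biomass = 1, phb = 4, dpa = 2,
                                        cry = 4),
                         seed = 20141114) {
  stopifnot(t_end > t_start, sampling_interval > 0, noise_relative_sd >= 0)
  detection_limits <- detection_limits[.compounds]
  replicates <- replicates[.compounds]
  if (any(is.na(detection_limits)) || any(detection_limits < 0))
    stop("'detection_limits' must give a non-negative limit for each of: ",
         paste(.compounds, collapse = ", "))
  if (any(is.na(replicates)) || any(replicates < 1))
    stop("'replicates' must give a count >= 1 for each of: ",
         paste(.compounds, collapse = ", "))
  structure(list(t_start = t_start, t_end = t_end,
                 sampling_interval = sampling_interval,
                 noise_relative_sd = noise_relative_sd,
                 detection_limits = detection_limits,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "study_design")
}

# run code with a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

# kinetics series container: data frame + censoring flags
kinetics_series <- function(times, biomass, phb, dpa, cry, censored = NULL,
                            label = NULL) {
  n <- length(times)
  vals <- cbind(biomass = biomass, phb = phb, dpa = dpa, cry = cry)
  stopifnot(nrow(vals) == n)
  if (n > 1L && any(diff(times) <= 0))
    stop("'times' must be strictly increasing")
  if (any(vals < 0)) stop("observed concentrations must be >= 0")
  if (is.null(censored)) {
    censored <- vals == 0
  } else {
    censored <- as.matrix(censored)
    stopifnot(identical(dim(censored), dim(vals)))
    colnames(censored) <- .compounds
    if (any(vals[censored] != 0))
      stop("censored values must be recorded as exactly 0")
  }
  out <- data.frame(time_h = times, biomass_g_per_l = vals[, "biomass"],
                    phb_g_per_l = vals[, "phb"], dpa_g_per_l = vals[, "dpa"],
                    cry_g_per_l = vals[, "cry"])
  attr(out, "censored") <- censored
  attr(out, "label") <- label
  class(out) <- c("kinetics_series", "data.frame")
  out
}

#' Generate a synthetic kinetics series
#'
#' Evaluates the clamped model trajectory on the design's sampling grid,
#' then emulates the measurement process: each time point is the average of
#' the design's technical replicates, each replicate drawn as
#' \eqn{v (1 + \epsilon)} with \eqn{\epsilon \sim N(0, sd)}; negative
#' averages are clamped to 0; averages below the compound's detection limit
#' are recorded as 0 and flagged as censored. The noise is multiplicative
#' because the compounds span two orders of magnitude (biomass ~13 g/L vs
#' DPA ~0.17 g/L); an additive model at biomass scale would drown the
#' minor compounds.
#'
#' @param params a [biodynamic_params()] generating truth.
#' @param design a [study_design()].
#' @return a `kinetics_series` data frame (columns `time_h`,
#'   `biomass_g_per_l`, `phb_g_per_l`, `dpa_g_per_l`, `cry_g_per_l`) with a
#'   logical `"censored"` attribute. Identical seed, identical output.
#' @examples
#' kin <- generate_kinetics(bt_param_sets()$F1, study_design(seed = 1))
#' head(kin)
#' @export
generate_kinetics <- function(params, design) {
  stopifnot(inherits(params, "biodynamic_params"),
            inherits(design, "study_design"))
  times <- seq(design$t_start, design$t_end, by = design$sampling_interval)
  traj <- simulate_kinetics(params, times, clamp = TRUE)
  truth <- cbind(biomass = traj$biomass_g_per_l, phb = traj$phb_g_per_l,
                 dpa = traj$dpa_g_per_l, cry = traj$cry_g_per_l)
  n <- length(times)
  obs <- with_seed(design$seed, {
    o <- truth
    for (j in seq_along(.compounds)) {
      r <- design$replicates[j]
      eps <- matrix(stats::rnorm(n * r, 0, design$noise_relative_sd), nrow = r)
      draws <- rep(truth[, j], each = r) * (1 + eps)
      o[, j] <- colMeans(matrix(draws, nrow = r))
    }
    o
  })
  obs[obs < 0] <- 0
  censored <- sweep(obs, 2, design$detection_limits, `<`)
  obs[censored] <- 0
  kinetics_series(times, obs[, "biomass"], obs[, "phb"], obs[, "dpa"],
                  obs[, "cry"], censored = censored, label = params$label)
}

#' Generate the four-fermentation synthetic study
#'
#' One synthetic series per reference parameter set (F1--F4), with
#' per-fermentation seeds derived deterministically from the design seed so
#' the four series are reproducible but mutually independent.
#'
#' @param design a [study_design()]; its `seed` anchors all four series.
#' @param sets named list of generating truths (default [bt_param_sets()]).
#' @return a named list of `kinetics_series`.
#' @export
generate_study_set <- function(design = study_design(),
                               sets = bt_param_sets()) {
  stopifnot(inherits(design, "study_design"), length(sets) >= 1)
  out <- lapply(seq_along(sets), function(i) {
    d <- design
    d$seed <- derive_seed(design$seed, i)
    generate_kinetics(sets[[i]], d)
  })
  stats::setNames(out, names(sets))
}

# deterministic sub-seed, kept inside 32-bit integer range
derive_seed <- function(seed, index) {
  as.integer((abs(as.numeric(seed)) %% 268435455) * 8 + index)
}
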