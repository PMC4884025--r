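# shared fixtures and the (cached) 20-seed recovery study used by both the
# estimation property tests and the acceptance checks

param_keys <- c("x_max", "mu_max", "t_c", "phb_max", "mu_max_p", "t_c_p",
                "dpa_max", "mu_max_d", "t_c_d", "cry_max", "mu_max_c",
                "t_c_c", "y_dpa_x", "y_dpa_phb", "y_cry_phb")

flat_params <- function(params) {
  vapply(param_keys, function(k) param_value(params, k), numeric(1))
}

.recovery_cache <- new.env(parent = emptyenv())

# median recovered parameter vector per reference set over 20 noise seeds
# (2-h grid 0-20 h, 5% multiplicative noise, replicate averaging, staged fit)
recovery_medians <- function() {
  if (!is.null(.recovery_cache$res)) return(.recovery_cache$res)
  sets <- bt_param_sets()
  res <- lapply(sets, function(p) {
    rec <- vapply(1:20, function(s) {
      kin <- generate_kinetics(p, study_design(seed = 1000 + s))
      flat_params(fit_biodynamic(kin)$params)
    }, numeric(length(param_keys)))
    apply(rec, 1, stats::median)
  })
  .recovery_cache$res <- res
  res
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
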