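#!/usr/bin/env Rscript
# Fit the biodynamic model to the synthetic study and quantify parameter
# recovery over repeated noise realizations.
#
# Output: results/fits/<label>.cfg        fitted parameter sets
#         results/fit_diagnostics.csv     per-compound SSE and R^2
#         results/recovery_medians.csv    median recovered value over 20
#                                         noise seeds vs generating truth

library(btbiodyn)

dir.create("results/fits", recursive = TRUE, showWarnings = FALSE)
sets <- bt_param_sets()
keys <- c("x_max", "mu_max", "t_c", "phb_max", "mu_max_p", "t_c_p",
          "dpa_max", "mu_max_d", "t_c_d", "cry_max", "mu_max_c", "t_c_c",
          "y_dpa_x", "y_dpa_phb", "y_cry_phb")
flat <- function(p) vapply(keys, function(k) param_value(p, k), numeric(1))

# single-study fits (staged, then joint refinement)
study <- generate_study_set(study_design())
diag_rows <- list()
for (lab in names(study)) {
  fit <- fit_biodynamic(study[[lab]], fit_settings(strategy = "joint"))
  write_parameters(fit$params, file.path("results/fits",
                                         paste0(lab, ".cfg")))
  diag_rows[[lab]] <- data.frame(
    label = lab, compound = names(fit$r_squared),
    sse = unname(fit$sse[names(fit$r_squared)]),
    r_squared = unname(fit$r_squared))
  message(sprintf("%s: total SSE %.4g, per-compound R^2 %s", lab,
                  fit$sse[["total"]],
                  paste(sprintf("%.3f", fit$r_squared), collapse = " ")))
}
diagnostics <- do.call(rbind, diag_rows)
utils::write.csv(diagnostics, "results/fit_diagnostics.csv",
                 row.names = FALSE)
message(sprintf("minimum R^2 across the %d compound fits: %.2f%%",
                nrow(diagnostics), 100 * min(diagnostics$r_squared)))

# 20-seed recovery study (staged fits, as used for validation)
rows <- list()
for (lab in names(sets)) {
  truth <- flat(sets[[lab]])
  rec <- vapply(1:20, function(s) {
    kin <- generate_kinetics(sets[[lab]], study_design(seed = 1000 + s))
    flat(fit_biodynamic(kin)$params)
  }, numeric(length(keys)))
  med <- apply(rec, 1, stats::median)
  rows[[lab]] <- data.frame(label = lab, parameter = keys, truth = truth,
                            median_recovered = med,
                            rel_error = (med - truth) / truth)
}
recovery <- do.call(rbind, rows)
utils::write.csv(recovery, "results/recovery_medians.csv",
                 row.names = FALSE)
message("note: the PHB-consumption split (Y_DPA/PHB, Y_Cry/PHB) is not ",
        "identifiable from these censored 11-point series; see the ",
        "methods vignette")
message("recovery summary written to results/recovery_medians.csv")
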