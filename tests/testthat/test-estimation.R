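f_sets <- bt_param_sets()

test_that("fit_gompertz recovers a noiseless sigmoid to 1e-6 relative", {
  p <- gompertz_params(5.58, 0.78, 4.54)
  t <- seq(0, 20, 2)
  fit <- fit_gompertz(t, gompertz_value(t, p))
  expect_true(fit$converged)
  expect_lt(rel_err(fit$params$asymptote, 5.58), 1e-6)
  expect_lt(rel_err(fit$params$rate, 0.78), 1e-6)
  expect_lt(rel_err(fit$params$critical_time, 4.54), 1e-6)
  expect_lt(fit$sse, 1e-12)
})

test_that("fit_gompertz recovers a noisy sigmoid within 10%", {
  p <- gompertz_params(0.71, 0.89, 7.90)
  t <- seq(0, 20, 2)
  set.seed(11)
  y <- gompertz_value(t, p) * (1 + rnorm(length(t), 0, 0.05))
  fit <- fit_gompertz(t, y)
  expect_lt(rel_err(fit$params$asymptote, 0.71), 0.10)
  expect_lt(rel_err(fit$params$rate, 0.89), 0.10)
  expect_lt(rel_err(fit$params$critical_time, 7.90), 0.10)
})

test_that("fit_gompertz rejects degenerate and insufficient input", {
  expect_error(fit_gompertz(c(0, 2, 4, 6), rep(0, 4)), "degenerate")
  expect_error(fit_gompertz(c(0, 2, 4, 6), rep(3.3, 4)), "degenerate")
  expect_error(fit_gompertz(c(0, 2, 4), c(0, 1, 2)), "insufficient")
  expect_error(fit_gompertz(c(0, 2, 4, 6), c(0, 1, NA, NA)), "insufficient")
})

test_that("r_squared follows its definition", {
  obs <- c(1, 2, 3)
  expect_identical(r_squared(obs, obs), 1)
  expect_identical(r_squared(obs, rep(mean(obs), 3)), 0)
  expect_equal(r_squared(obs, c(1, 2, 4)), 0.5, tolerance = 1e-15)
  # worse than the mean goes negative
  expect_lt(r_squared(obs, c(3, 1, 2)), 0)
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_error(r_squared(1, 1), "at least 2")
})

test_that("noiseless trajectories are recovered to machine-level SSE", {
  t <- seq(0, 20, 2)
  for (lab in c("F1", "F3")) {
    truth <- f_sets[[lab]]
    traj <- as.data.frame(simulate_kinetics(truth, t))
    st <- fit_settings(clamp_predictions = FALSE)
    fit <- fit_biodynamic(traj, st)
    expect_lt(fit$sse["total"], 1e-10)
    expect_lt(max(rel_err(flat_params(fit$params), flat_params(truth))),
              1e-4)
  }
})

test_that("joint refinement never worsens the staged total SSE", {
  for (seed in c(7, 21)) {
    kin <- generate_kinetics(f_sets$F2, study_design(seed = seed))
    staged <- fit_biodynamic(kin, fit_settings(strategy = "staged"))
    joint <- fit_biodynamic(kin, fit_settings(strategy = "joint"))
    expect_lte(joint$sse[["total"]], staged$sse[["total"]] * (1 + 1e-10))
  }
})

test_that("fit is equivariant under a 5-hour time shift", {
  kin <- generate_kinetics(f_sets$F2, study_design(seed = 7))
  shifted <- kin
  shifted$time_h <- shifted$time_h + 5
  a <- fit_biodynamic(kin)
  b <- fit_biodynamic(shifted)
  fa <- flat_params(a$params)
  fb <- flat_params(b$params)
  tc_keys <- c("t_c", "t_c_p", "t_c_d", "t_c_c")
  expect_equal(unname(fb[tc_keys] - fa[tc_keys]), rep(5, 4),
               tolerance = 1e-6)
  other <- setdiff(param_keys, tc_keys)
  expect_lt(max(rel_err(fb[other], fa[other])), 1e-5)
})

test_that("missing compound columns are reported by name", {
  kin <- generate_kinetics(f_sets$F1, study_design(seed = 5))
  kin$cry_g_per_l <- NULL
  expect_error(fit_biodynamic(kin), "cry_g_per_l")
})

test_that("a degenerate compound fails its stage, the rest still fit", {
  kin <- generate_kinetics(f_sets$F1, study_design(seed = 3))
  kin$cry_g_per_l[] <- 0
  cens <- attr(kin, "censored")
  cens[, "cry"] <- TRUE
  attr(kin, "censored") <- cens
  fit <- fit_biodynamic(kin)
  expect_match(fit$stage_status[["cry"]], "degenerate")
  expect_false(fit$converged[["cry"]])
  expect_true(all(fit$converged[c("biomass", "phb", "dpa")]))
  expect_identical(fit$params$cry$asymptote, 0)
})

test_that("identifiable parameters are recovered across the noisy study", {
  # median over 20 noise seeds, staged fits, per reference set. The PHB
  # consumption split (Y_DPA/PHB, Y_Cry/PHB) and, for the low-substrate F1,
  # the PHB/Cry triples are not statistically identifiable under this
  # censored 11-point design, so they are not part of this property.
  med <- recovery_medians()
  for (lab in names(f_sets)) {
    truth <- flat_params(f_sets[[lab]])
    m <- med[[lab]]
    expect_lt(rel_err(m["x_max"], truth["x_max"]), 0.05)
    expect_lt(rel_err(m["dpa_max"], truth["dpa_max"]), 0.05)
    expect_lt(rel_err(m["mu_max"], truth["mu_max"]), 0.15)
    expect_lt(rel_err(m["y_dpa_x"], truth["y_dpa_x"]), 0.15)
    for (k in c("t_c", "t_c_p", "t_c_d", "t_c_c"))
      expect_lt(rel_err(m[k], truth[k]), 0.15)
  }
  # at higher substrate the PHB and Cry asymptotes are identifiable too
  for (lab in c("F2", "F3", "F4")) {
    truth <- flat_params(f_sets[[lab]])
    m <- med[[lab]]
    expect_lt(rel_err(m["phb_max"], truth["phb_max"]), 0.05)
    expect_lt(rel_err(m["cry_max"], truth["cry_max"]), 0.05)
  }
})
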