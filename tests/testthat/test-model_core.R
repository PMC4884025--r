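# Frozen expected values below were computed with an independent
# high-precision (symbolic) evaluation of the closed forms.

f_sets <- bt_param_sets()

test_that("Gompertz curve hits its defining landmarks", {
  # value at the critical time is asymptote/e, exactly
  p <- gompertz_params(5.58, 0.78, 4.54)
  expect_equal(gompertz_value(4.54, p), 5.58 / exp(1), tolerance = 1e-14)
  # F1 Cry sigmoid at its critical time 14.88
  expect_equal(gompertz_value(14.88, f_sets$F1$cry), 0.19 / exp(1),
               tolerance = 1e-14)
  # closed-form evaluation away from the landmarks
  expect_equal(gompertz_value(10, p), 5.5016580863344908, tolerance = 1e-13)
  # limits
  expect_equal(gompertz_value(1e6, p), 5.58, tolerance = 1e-14)
  expect_lt(gompertz_value(-1e3, p), 1e-300)
  expect_error(gompertz_value(NA_real_, p), "non-finite")
  expect_error(gompertz_value(numeric(0), p), "at least one")
})

test_that("Gompertz identity at t_c and monotonicity hold for random draws", {
  set.seed(101)
  for (i in 1:1000) {
    p <- gompertz_params(runif(1, 0.01, 20), runif(1, 0.05, 3),
                         runif(1, -5, 25))
    expect_equal(gompertz_value(p$critical_time, p), p$asymptote / exp(1),
                 tolerance = 1e-12)
  }
  set.seed(102)
  for (i in 1:200) {
    p <- gompertz_params(runif(1, 0.01, 20), runif(1, 0.05, 3),
                         runif(1, -5, 25))
    t12 <- sort(runif(2, -10, 40))
    expect_lte(gompertz_value(t12[1], p), gompertz_value(t12[2], p))
  }
})

test_that("parameter constructors enforce their invariants", {
  expect_error(gompertz_params(-1, 0.5, 4), "asymptote")
  expect_error(gompertz_params(1, 0, 4), "rate")
  expect_error(gompertz_params(1, 0.5, Inf), "critical_time")
  expect_error(yield_coefficients(0.02, -1, 0.2), "positive")
  expect_error(yield_coefficients(0, 1, 0.2), "positive")
  expect_silent(biodynamic_params(gompertz_params(1, 1, 1),
                                  gompertz_params(1, 1, 1),
                                  gompertz_params(1, 1, 1),
                                  gompertz_params(1, 1, 1),
                                  yield_coefficients(0.1, 0.2, 0.3)))
  expect_error(biodynamic_params(gompertz_params(1, 1, 1),
                                 gompertz_params(1, 1, 1),
                                 gompertz_params(1, 1, 1),
                                 gompertz_params(1, 1, 1),
                                 yield_coefficients(0.1, 0.2, 0.3),
                                 initial_glucose = -3), "initial_glucose")
})

test_that("DPA and Cry are plain sigmoids of their triples", {
  t <- c(0, 5, 12, 14.12, 20)
  expect_identical(dpa_at(t, f_sets$F1), gompertz_value(t, f_sets$F1$dpa))
  expect_identical(cry_at(t, f_sets$F2), gompertz_value(t, f_sets$F2$cry))
  # long-time limits are the published maxima
  expect_equal(dpa_at(1e6, f_sets$F1), 0.17, tolerance = 1e-12)
  expect_equal(cry_at(1e6, f_sets$F4), 0.78, tolerance = 1e-12)
  # at t_c the curve is at asymptote/e
  expect_equal(dpa_at(14.12, f_sets$F1), 0.17 / exp(1), tolerance = 1e-14)
  expect_equal(cry_at(16.46, f_sets$F4), 0.78 / exp(1), tolerance = 1e-14)
  # the double exponential underflows at t = 0 for F1 DPA: the value is
  # ~1e-4844, i.e. exactly 0 in double precision
  expect_identical(dpa_at(0, f_sets$F1), 0)
  expect_equal(cry_at(12, f_sets$F2), 0.077847698136989629,
               tolerance = 1e-13)
})

test_that("biomass equation is growth minus endospore consumption", {
  f1 <- f_sets$F1
  # death term underflows at the growth critical time
  expect_equal(biomass_at(4.54, f1), 2.0527672817366482, tolerance = 1e-13)
  # late culture: consumption exceeds the asymptote, the raw equation goes
  # negative
  expect_equal(biomass_at(20, f1), -1.0811567396028374, tolerance = 1e-12)
  clamped <- biomass_at(20, f1, clamp = TRUE)
  expect_identical(as.numeric(clamped), 0)
  expect_true(attr(clamped, "clamped"))
  # with a zero-asymptote DPA term the curve is pure Gompertz growth
  no_spore <- biodynamic_params(f1$biomass, f1$phb, gompertz_params(0, 1, 0),
                                f1$cry, f1$yields)
  t <- seq(0, 20, 0.5)
  expect_equal(biomass_at(t, no_spore), gompertz_value(t, f1$biomass),
               tolerance = 1e-14)
})

test_that("PHB equation is production minus DPA and Cry consumption", {
  expect_equal(phb_at(11, f_sets$F3), 1.0659464682974881, tolerance = 1e-13)
  # algebraic long-time limit: PHB_max - DPA_max/Y_DPA/PHB - Cry_max/Y_Cry/PHB
  expect_equal(phb_at(1e6, f_sets$F1), 0.61 - 0.17 / 1.02 - 0.19 / 0.19,
               tolerance = 1e-12)
  f1 <- f_sets$F1
  no_prod <- biodynamic_params(f1$biomass, f1$phb, gompertz_params(0, 1, 0),
                               gompertz_params(0, 1, 0), f1$yields)
  t <- seq(0, 20, 0.5)
  expect_equal(phb_at(t, no_prod), gompertz_value(t, f1$phb),
               tolerance = 1e-14)
})

test_that("conservation identities hold to 1e-12 relative with clamp off", {
  t <- seq(0, 20, 0.25)
  for (p in f_sets) {
    growth <- gompertz_value(t, p$biomass)
    lhs_x <- biomass_at(t, p) + dpa_at(t, p) / p$yields$dpa_from_biomass
    expect_equal(lhs_x, growth, tolerance = 1e-12)
    prod <- gompertz_value(t, p$phb)
    lhs_p <- phb_at(t, p) + dpa_at(t, p) / p$yields$dpa_from_phb +
      cry_at(t, p) / p$yields$cry_from_phb
    expect_equal(lhs_p, prod, tolerance = 1e-12)
  }
})

test_that("biomass increases pointwise with Y_DPA/X (smaller death term)", {
  set.seed(103)
  f1 <- f_sets$F1
  t <- seq(0, 20, 1)
  for (i in 1:20) {
    y1 <- runif(1, 0.005, 0.05)
    y2 <- y1 * runif(1, 1.1, 3)
    p1 <- biodynamic_params(f1$biomass, f1$phb, f1$dpa, f1$cry,
                            yield_coefficients(y1, 1.02, 0.19))
    p2 <- biodynamic_params(f1$biomass, f1$phb, f1$dpa, f1$cry,
                            yield_coefficients(y2, 1.02, 0.19))
    expect_true(all(biomass_at(t, p2) >= biomass_at(t, p1)))
  }
})

test_that("simulate_kinetics matches single-point evaluation elementwise", {
  t <- seq(0, 20, 2)
  traj <- simulate_kinetics(f_sets$F1, t)
  expect_equal(nrow(traj), 11L)
  for (i in seq_along(t)) {
    expect_identical(traj$biomass_g_per_l[i], biomass_at(t[i], f_sets$F1))
    expect_identical(traj$phb_g_per_l[i], phb_at(t[i], f_sets$F1))
    expect_identical(traj$dpa_g_per_l[i], dpa_at(t[i], f_sets$F1))
    expect_identical(traj$cry_g_per_l[i], cry_at(t[i], f_sets$F1))
  }
  # random grids against the brute-force oracle
  set.seed(104)
  for (k in 1:10) {
    p <- f_sets[[sample(4, 1)]]
    tg <- sort(runif(7, 0, 25))
    traj <- simulate_kinetics(p, tg)
    expect_equal(traj$dpa_g_per_l, gompertz_value(tg, p$dpa))
    expect_true(all(traj$dpa_g_per_l >= 0 &
                      traj$dpa_g_per_l <= p$dpa$asymptote))
    expect_true(all(traj$cry_g_per_l >= 0 &
                      traj$cry_g_per_l <= p$cry$asymptote))
  }
})

test_that("simulate_kinetics validates inputs and degenerate cases", {
  expect_error(simulate_kinetics(f_sets$F1, numeric(0)), "at least one")
  expect_error(simulate_kinetics(f_sets$F1, c(0, 2, 2, 4)), "increasing")
  expect_error(simulate_kinetics(f_sets$F1, c(4, 2)), "increasing")
  # single point at t_c agrees with biomass_at
  one <- simulate_kinetics(f_sets$F1, 4.54)
  expect_identical(one$biomass_g_per_l, biomass_at(4.54, f_sets$F1))
  # all-zero asymptotes give an identically zero trajectory
  z <- gompertz_params(0, 1, 0)
  pz <- biodynamic_params(z, z, z, z, yield_coefficients(1, 1, 1))
  traj <- simulate_kinetics(pz, seq(0, 10, 2))
  expect_true(all(as.matrix(traj[, -1]) == 0))
})

test_that("clamped trajectories flag exactly the negative model values", {
  t <- seq(0, 20, 2)
  traj <- simulate_kinetics(f_sets$F1, t, clamp = TRUE)
  raw <- simulate_kinetics(f_sets$F1, t)
  flags <- attr(traj, "clamped")
  expect_identical(unname(flags[, "biomass"]), raw$biomass_g_per_l < 0)
  expect_identical(unname(flags[, "phb"]), raw$phb_g_per_l < 0)
  expect_false(any(flags[, c("dpa", "cry")]))
  expect_true(all(traj$biomass_g_per_l >= 0))
  expect_identical(traj$biomass_g_per_l[raw$biomass_g_per_l >= 0],
                   raw$biomass_g_per_l[raw$biomass_g_per_l >= 0])
})
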