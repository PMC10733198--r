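test_that("1-compartment IV bolus matches the closed form", {
  m <- one_cpt()                          # CL 1, Vc 10
  tt <- c(0, 1, 5, 10, 30, 60, 120)
  s <- simulate_plasma(m, dose_event(1000), tt)
  expect_equal(s$conc_ng_ml, 100 * exp(-0.1 * tt), tolerance = 1e-12)
  expect_equal(s$conc_ng_ml[1], 100)
  expect_equal(s$conc_u_ng_ml, s$conc_ng_ml * m$fu_plasma)
})

test_that("2-compartment IV matches the bi-exponential closed form", {
  CL <- 1; Vc <- 10; Q <- 0.5; Vp <- 20; dose <- 1000
  m <- two_cpt(CL, Vc, Q, Vp)
  # macro-constant oracle
  k10 <- CL / Vc; k12 <- Q / Vc; k21 <- Q / Vp
  s <- k10 + k12 + k21
  al <- (s + sqrt(s^2 - 4 * k10 * k21)) / 2
  be <- (s - sqrt(s^2 - 4 * k10 * k21)) / 2
  A <- dose / Vc * (al - k21) / (al - be)
  B <- dose / Vc * (k21 - be) / (al - be)
  tt <- c(1, 5, 10, 30, 60, 120, 240, 480)
  sim <- simulate_plasma(m, dose_event(dose), tt)
  oracle <- A * exp(-al * tt) + B * exp(-be * tt)
  expect_rel_equal(sim$conc_ng_ml, oracle, 1e-6)
})

test_that("AUC(0-inf) equals dose/CL within 0.5% for fixture models", {
  # horizons scaled to each model's terminal half-life
  horizon <- c(colchicine = 20000, topotecan = 1500,
               methotrexate = 2500, cefadroxil = 600)
  for (nm in names(horizon)) {
    m <- plasma_models(nm)[[1]]
    m$iiv <- lapply(m$iiv, function(x) 0)   # typical-value curve
    dose <- dose_from_mg_kg(m$dose_mg_kg)
    tt <- seq(0, horizon[[nm]], length.out = 4001)
    s <- simulate_plasma(m, dose_event(dose), tt)
    a <- auc_inf(s$time_min, s$conc_ng_ml)
    expect_rel_equal(a$auc, dose / m$CL, 0.005)
  }
})

test_that("mass balance holds at every output time", {
  m <- two_cpt()
  sys <- cnspbpk:::.plasma_system(m)
  inp <- cnspbpk:::.plasma_inputs(m, sys, list(dose_event(1000)))
  tt <- seq(0, 600, by = 5)
  sol <- cnspbpk:::solve_linear_system(sys$A, numeric(2), tt,
                                       boluses = inp$boluses,
                                       cumulative = TRUE)
  eliminated <- m$CL / m$Vc * sol$integral[sys$central, ]
  total <- colSums(sol$state) + eliminated
  expect_lt(max(abs(total - 1000)) / 1000, 1e-6)
})

test_that("superposition: doubling the dose doubles concentrations", {
  m <- plasma_models("prexasertib")[[1]]    # 2-cpt SC with depot
  tt <- seq(0, 360, by = 10)
  s1 <- simulate_plasma(m, dose_event(1e5), tt, seed = 5)
  s2 <- simulate_plasma(m, dose_event(2e5), tt, seed = 5)
  expect_equal(s2$conc_ng_ml, 2 * s1$conc_ng_ml, tolerance = 1e-10)
})

test_that("all packaged parameter sets simulate with positive Cmax", {
  for (nm in names(plasma_models())) {
    m <- plasma_models(nm)[[1]]
    s <- suppressMessages(
      simulate_plasma(m, dose_event(dose_from_mg_kg(m$dose_mg_kg)),
                      seq(0, 720, by = 5)))
    expect_gt(max(s$conc_ng_ml), 0)
    expect_true(all(is.finite(s$conc_ng_ml)))
  }
})

test_that("zero-order release precedes first-order absorption", {
  m <- plasma_models("quinidine")[[1]]     # D0 = 10 min, ka = 2.61
  s <- simulate_plasma(m, dose_event(1e6), c(0, 2, 5, 10, 20, 60))
  expect_equal(s$conc_ng_ml[1], 0)
  expect_true(all(diff(s$conc_ng_ml[1:4]) > 0))
})

test_that("residual error model reproduces its stated variances", {
  # no noise: observations equal predictions
  expect_equal(add_residual_error(c(10, 20), list(prop = 0, add = 0)),
               c(10, 20))
  # proportional: sd = pred * sqrt(sigma2) (sigma2 = 0.05 -> sd 22.36)
  x <- add_residual_error(rep(100, 1e5), list(prop = 0.05, add = 0),
                          seed = 3)
  expect_rel_equal(stats::sd(x), 100 * sqrt(0.05), 0.02)
  # combined: var = pred^2 s2p + s2a
  y <- add_residual_error(rep(50, 1e5), list(prop = 0.02, add = 9),
                          seed = 4)
  expect_rel_equal(stats::var(y), 50^2 * 0.02 + 9, 0.03)
})

test_that("IIV simulation is reproducible and spread by omega", {
  m <- one_cpt(iiv = list(CL = 0.1))
  tt <- c(30, 60)
  a <- simulate_plasma(m, dose_event(1000), tt, n_subjects = 20, seed = 9)
  b <- simulate_plasma(m, dose_event(1000), tt, n_subjects = 20, seed = 9)
  expect_identical(a, b)
  expect_gt(stats::sd(a$conc_ng_ml[a$time_min == 60]), 0)
  # omega = 0, one subject: deterministic
  d1 <- simulate_plasma(one_cpt(), dose_event(1000), tt)
  d2 <- simulate_plasma(one_cpt(), dose_event(1000), tt)
  expect_identical(d1, d2)
})

test_that("plasma forcing function matches simulation and decays", {
  m <- plasma_models("cefadroxil")[[1]]     # no IIV: typical = individual
  dose <- dose_event(dose_from_mg_kg(36))
  f <- plasma_forcing(m, dose)
  tt <- seq(0, 360, by = 7.3)
  s <- simulate_plasma(m, dose, tt)
  expect_lt(max(abs(f(tt) - s$conc_u_ng_ml)), 1e-8 * max(s$conc_u_ng_ml))
  # zero before the first dose
  flate <- plasma_forcing(m, dose_event(1e5, time_min = 60))
  expect_equal(flate(c(0, 30, 59.9)), c(0, 0, 0))
  # all fixtures eliminate: forcing -> 0 after ~40 terminal half-lives
  for (nm in names(plasma_models())) {
    mi <- plasma_models(nm)[[1]]
    fi <- plasma_forcing(mi, dose_event(dose_from_mg_kg(mi$dose_mg_kg)))
    lam <- min(abs(Re(eigen(cnspbpk:::.plasma_system(mi)$A,
                            only.values = TRUE)$values)))
    t_late <- 40 * log(2) / lam
    expect_lt(fi(t_late), 1e-6 * max(fi(seq(1, 720, by = 1))))
  }
})

test_that("model constructor enforces its invariants", {
  expect_error(plasma_pk_model(CL = 1, Vc = 10, Q2 = 0.5, Vp2 = 0),
               "jointly")
  expect_error(plasma_pk_model(CL = -1, Vc = 10))
  expect_error(plasma_pk_model(CL = 1, Vc = 10, iiv = list(CL = -0.1)),
               "IIV")
  expect_error(dose_event(-5), "amount_ng")
})

test_that("noise-free 1-cpt data are recovered to 4 significant figures", {
  m <- one_cpt()
  tt <- c(2, 5, 8, 12, 17, 23, 30, 38, 47, 57, 68, 80)
  obs <- simulate_plasma(m, dose_event(1000), tt)
  fit <- fit_plasma_model(obs, dose_event(1000),
                          structure = list(n_compartments = 1, route = "IV",
                                           error_model = "proportional",
                                           ka = FALSE))
  expect_rel_equal(fit$estimates[["CL"]], 1, 1e-4)
  expect_rel_equal(fit$estimates[["Vc"]], 10, 1e-4)
})

test_that("noisy pooled fit recovers CL and Vc within 15%", {
  m <- one_cpt()
  tt <- c(5, 10, 15, 30, 60, 90, 120, 180, 240, 300)
  sim <- simulate_plasma(m, dose_event(1000), tt, n_subjects = 8, seed = 1)
  noisy <- add_residual_error(sim, list(prop = 0.01), seed = 2)
  fit <- fit_plasma_model(noisy, dose_event(1000),
                          structure = list(n_compartments = 1, route = "IV",
                                           error_model = "proportional",
                                           ka = FALSE))
  expect_rel_equal(fit$estimates[["CL"]], 1, 0.15)
  expect_rel_equal(fit$estimates[["Vc"]], 10, 0.15)
  expect_true(is.finite(fit$ofv))
})

test_that("likelihood-ratio comparison is calibrated under the null", {
  # 1-cpt truth; the 2-cpt extension should rarely win by > 3.84
  m <- one_cpt(residual = list(prop = 0.01))
  tt <- c(5, 10, 15, 30, 60, 90, 120, 180, 240, 300)
  ok <- 0L
  for (r in 1:50) {
    sim <- simulate_plasma(m, dose_event(1000), tt, n_subjects = 5,
                           seed = 100 + r)
    noisy <- add_residual_error(sim, list(prop = 0.01), seed = 200 + r)
    f1 <- fit_plasma_model(noisy, dose_event(1000),
                           structure = list(n_compartments = 1, route = "IV",
                                            error_model = "proportional",
                                            ka = FALSE), n_starts = 1)
    f2 <- fit_plasma_model(noisy, dose_event(1000),
                           structure = list(n_compartments = 2, route = "IV",
                                            error_model = "proportional",
                                            ka = FALSE), n_starts = 1)
    if (f1$ofv - f2$ofv < 3.84) ok <- ok + 1L
  }
  expect_gte(ok, 45L)   # >= 90% of 50 replicates
})

test_that("insufficient data and depot misuse raise errors", {
  m <- one_cpt()
  obs <- simulate_plasma(m, dose_event(1000), c(5, 10))
  expect_error(fit_plasma_model(obs, dose_event(1000)), "observations")
  expect_message(
    simulate_plasma(plasma_pk_model(CL = 1, Vc = 10, route = "IP"),
                    dose_event(1000), c(0, 10)),
    "instantaneous")
})
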