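test_that("auc_inf is exact on a monoexponential curve", {
  tt <- seq(0, 100, by = 2)
  cc <- 100 * exp(-0.1 * tt)
  a <- auc_inf(tt, cc)
  expect_rel_equal(a$auc, 1000, 1e-3)      # 100/0.1
  expect_rel_equal(a$lambda_z, 0.1, 1e-6)
  expect_true(a$extrap_frac > 0 && a$extrap_frac < 1)
  # non-decreasing tail is rejected
  expect_error(auc_inf(c(0, 10, 20, 30), c(10, 5, 4, 4.5)),
               "not monotonically decreasing")
})

test_that("kpuu_from_auc reproduces trivial and scaled ratios", {
  tt <- seq(0, 120, by = 2)
  pl <- data.frame(time_min = tt, conc_ng_ml = 80 * exp(-0.05 * tt))
  expect_equal(kpuu_from_auc(pl, pl)$kpuu, 1.0)
  ec <- pl; ec$conc_ng_ml <- 0.21 * pl$conc_ng_ml   # topotecan-like ratio
  expect_equal(kpuu_from_auc(pl, ec)$kpuu, 0.21, tolerance = 1e-10)
})

test_that("AUC ratio equals CL_in/CL_out for a 1-cpt brain model", {
  # plasma 100 e^{-0.1 t}; brain dA/dt = CL_in Cp - (CL_out/V) A
  tt <- seq(0, 400, by = 0.5)
  cl_in <- 0.003; cl_out <- 0.01; V <- 0.067
  kb <- cl_out / V
  pl <- data.frame(time_min = tt, conc_ng_ml = 100 * exp(-0.1 * tt))
  ce <- cl_in * 100 / (kb - 0.1) * (exp(-0.1 * tt) - exp(-kb * tt)) / V
  ec <- data.frame(time_min = tt[-1], conc_ng_ml = ce[-1])
  expect_rel_equal(kpuu_from_auc(pl, ec)$kpuu, 0.3, 0.01)
})

test_that("AUC-ratio and clearance-ratio agree on random linear systems", {
  set.seed(17)
  for (i in 1:10) {
    kel <- stats::runif(1, 0.02, 0.2)
    cl_in <- stats::runif(1, 1e-3, 5e-2)
    cl_out <- stats::runif(1, 1e-3, 5e-2)
    V <- stats::runif(1, 0.05, 0.5)
    kb <- cl_out / V
    if (abs(kb - kel) < 1e-3) next
    tt <- seq(0, 30 / min(kel, kb), length.out = 2000)
    pl <- data.frame(time_min = tt, conc_ng_ml = 100 * exp(-kel * tt))
    ce <- cl_in * 100 / (kb - kel) * (exp(-kel * tt) - exp(-kb * tt)) / V
    ec <- data.frame(time_min = tt[-1], conc_ng_ml = ce[-1])
    expect_rel_equal(kpuu_from_auc(pl, ec)$kpuu, cl_in / cl_out, 0.01)
  }
})

test_that("asymmetry factors encode Kp,uu with one active side", {
  expect_equal(unclass(asymmetry_factors(1))[c("AF_in", "AF_out")],
               list(AF_in = 1, AF_out = 1))
  af <- asymmetry_factors(0.09)            # prexasertib
  expect_equal(af$AF_in, 1)
  expect_equal(round(af$AF_out, 2), 11.11)
  af2 <- asymmetry_factors(0.0121)         # phenobarbital
  expect_equal(round(af2$AF_out, 1), 82.6)
  af3 <- asymmetry_factors(2.5)
  expect_equal(af3$AF_in, 2.5); expect_equal(af3$AF_out, 1)
  expect_error(asymmetry_factors(0), "positive")
  expect_error(asymmetry_factors(-1), "positive")
  # identity AF_in/AF_out = Kpuu over (0, inf); at most one factor > 1
  set.seed(5)
  for (k in exp(stats::runif(20, -5, 3))) {
    af <- asymmetry_factors(k)
    expect_equal(af$AF_in / af$AF_out, k, tolerance = 1e-12)
    expect_true(af$AF_in >= 1 && af$AF_out >= 1)
    expect_lte(sum(c(af$AF_in, af$AF_out) > 1), 1)
  }
  # switchable convention
  afc <- asymmetry_factors(0.2, convention = "influx_only")
  expect_equal(afc$AF_in, 0.2)
})

test_that("brain clearances are exactly identified from noise-free data", {
  pm <- one_cpt()
  V <- 0.067; cl_in <- 0.01; cl_out <- 0.05; kb <- cl_out / V
  tt <- c(1, 2, 3, 5, 7, 10, 15, 20, 30, 45, 60, 90, 120, 180, 240)
  ce <- cl_in * 100 / (kb - 0.1) * (exp(-0.1 * tt) - exp(-kb * tt)) / V
  est <- estimate_bbb_clearances(pm, dose_event(1000),
                                 data.frame(time_min = tt, conc_ng_ml = ce),
                                 V_brain_apparent = V)
  expect_rel_equal(est$CL_in, cl_in, 1e-4)
  expect_rel_equal(est$CL_out, cl_out, 1e-4)
  # cross-validation against the AUC-ratio method on the same curves
  ttd <- seq(0, 400, by = 0.5)
  ced <- cl_in * 100 / (kb - 0.1) * (exp(-0.1 * ttd) - exp(-kb * ttd)) / V
  aucr <- kpuu_from_auc(
    data.frame(time_min = ttd, conc_ng_ml = 100 * exp(-0.1 * ttd)),
    data.frame(time_min = ttd[-1], conc_ng_ml = ced[-1]))
  expect_rel_equal(est$kpuu, aucr$kpuu, 0.01)
})

test_that("Kp,uu is recovered within 10% at 5% residual noise", {
  pm <- one_cpt()
  V <- 0.067; cl_in <- 0.01; cl_out <- 0.05; kb <- cl_out / V
  tt <- c(1, 2, 3, 5, 7, 10, 15, 20, 30, 45, 60, 90, 120, 180, 240)
  ce <- cl_in * 100 / (kb - 0.1) * (exp(-0.1 * tt) - exp(-kb * tt)) / V
  noisy <- add_residual_error(rep(ce, 4), list(prop = 0.0025), seed = 7)
  est <- estimate_bbb_clearances(
    pm, dose_event(1000),
    data.frame(time_min = rep(tt, 4), conc_ng_ml = noisy),
    V_brain_apparent = V)
  expect_rel_equal(est$kpuu, 0.2, 0.10)
})

test_that("packaged Kp,uu table carries values and provenance", {
  k <- kpuu_table()
  expect_equal(nrow(k), 10)
  expect_true(all(k$kpuu_bbb > 0))
  expect_true(all(k$method %in% c("literature", "estimated")))
  expect_equal(k$kpuu_bbb[k$name == "phenobarbital"], 0.0121)
  expect_equal(k$method[k$name == "cefadroxil"], "estimated")
})
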