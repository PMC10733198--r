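phys <- mouse_physiology()

test_that("clearance assembly is symmetric, linear and auditable", {
  drug <- neutral_drug()
  cl <- assemble_clearances(phys, drug)
  # AF (1,1), pH equal on both BBB faces: influx = efflux per pathway
  expect_equal(cl$AF_in * (cl$CL_BBB_trans * cl$fn$plasma + cl$CL_BBB_para),
               cl$AF_out * (cl$CL_BBB_trans * cl$fn$ecf + cl$CL_BBB_para))
  # doubling SA_BBB doubles both passive BBB clearances
  cl2 <- assemble_clearances(phys_override(phys, SA_BBB = 2 * 19.76), drug)
  expect_equal(cl2$CL_BBB_trans, 2 * cl$CL_BBB_trans)
  expect_equal(cl2$CL_BBB_para, 2 * cl$CL_BBB_para)
  # independent arithmetic oracle for the quinidine fixture
  q <- cns_drugs("quinidine")[[1]]
  clq <- assemble_clearances(phys, q)
  expect_equal(clq$CL_BBB_trans, q$p_trans * 19.76 * 0.998)
  expect_equal(clq$CL_BCSFB_trans, q$p_trans * 9.88 * 0.998)
  expect_equal(clq$CL_BBB_para,
               9.9e-5 * 324^(-0.453) * 60 / 0.7e-4 * 19.76 * 0.006)
  expect_equal(clq$CL_BCSFB_para,
               9.9e-5 * 324^(-0.453) * 60 / 1.7e-4 * 9.88 * 0.05)
  expect_equal(clq$CL_BCM, q$p_trans * phys_value(phys, "SA_BCM"))
  expect_equal(clq$CL_LYS, q$p_trans * 540)
  # missing permeability is a hard error
  expect_error(assemble_clearances(phys, drug_record("x", 300, 1)),
               "p_trans")
})

test_that("rate function conserves mass and has the declared structure", {
  model <- cns_model(phys, base_drug(kpuu = 0.3))
  f <- cns_rate_function(model)
  expect_equal(f(0, numeric(8)), setNames(rep(0, 8), rownames(model$A)))
  set.seed(11)
  for (i in 1:5) {
    x <- stats::runif(8, 0, 100)
    cu <- stats::runif(1, 0, 50)
    dx <- cns_rate_function(model, function(t) cu)(0, x)
    source_flux <- model$flows[["Q_CBF"]] * cu
    sink_flux <- drop(model$sink_row %*% x)
    expect_equal(sum(dx), source_flux - sink_flux, tolerance = 1e-10)
  }
  # finite-difference Jacobian equals the assembled matrix (linearity)
  J <- vapply(1:8, function(j) {
    e <- numeric(8); e[j] <- 1e-3
    (f(0, e) - f(0, numeric(8))) / 1e-3
  }, numeric(8))
  expect_equal(unname(J), unname(model$A), tolerance = 1e-8)
  # sparsity: no direct ECF<->CSF or plasma-side shortcut edges
  A <- model$A
  expect_equal(A["ECF", "LV"], 0)
  expect_equal(A["LYS", "ECF"], 0)
  expect_equal(A["SAS", "MV"], 0)
  expect_gt(A["CM", "ECF"], 0)     # ECF bulk flow enters the cisterna magna
})

test_that("uniform conditions equilibrate every compartment with plasma", {
  model <- cns_model(uniform_physiology(), neutral_drug(),
                     af = asymmetry_factors(1))
  sim <- simulate_cns(model, 50, t_end = 3e5, n_grid = 61)
  expect_rel_equal(sim$conc["ECF", 61], 50, 1e-3)
  ss <- steady_state_kpuu(model)
  expect_rel_equal(unname(ss[c("MV", "ECF", "ICF", "LYS")]), 1, 1e-3)
})

test_that("steady state reproduces the calibrated Kp,uu within 0.1%", {
  phys0 <- phys_override(phys, Q_ECF = 1e-12)
  for (k in c(0.0121, 0.09, 0.21, 0.628)) {
    model <- cns_model(phys0, neutral_drug(), af = asymmetry_factors(k))
    ss <- steady_state_kpuu(model)
    expect_rel_equal(unname(ss["ECF"]), k, 1e-3)
  }
})

test_that("long simulation agrees with the direct steady-state solve", {
  model <- cns_model(phys, base_drug(kpuu = 0.21))
  ss <- steady_state_kpuu(model)
  sim <- simulate_cns(model, 80, t_end = 3e5, n_grid = 41)
  expect_rel_equal(sim$conc[, 41] / 80, unname(ss), 1e-3)
})

test_that("ECF steady state follows CL_in/(CL_out + Q_ECF) exactly", {
  model <- cns_model(phys, neutral_drug(), af = asymmetry_factors(0.21))
  cl <- model$clearances
  cl_in <- cl$AF_in * (cl$CL_BBB_trans * cl$fn$plasma + cl$CL_BBB_para)
  cl_out <- cl$AF_out * (cl$CL_BBB_trans * cl$fn$ecf + cl$CL_BBB_para)
  ss <- steady_state_kpuu(model)
  closed <- cl_in / (cl_out + model$flows[["Q_ECF"]])
  expect_rel_equal(unname(ss["ECF"] / ss["MV"]), closed, 1e-9)
})

test_that("pH-partition ratios match closed forms at steady state", {
  for (mk in list(base_drug, acid_drug)) {
    d <- mk()
    model <- cns_model(phys, d, af = asymmetry_factors(1))
    ss <- steady_state_kpuu(model)
    # lysosome (total) over unbound cytosol
    expect_rel_equal(unname(ss["LYS"] / ss["ICF"]),
                     fraction_neutral(7.2, d) / fraction_neutral(5.5, d),
                     0.01)
    # unbound ICF over ECF
    expect_rel_equal(unname(ss["ICF"] / ss["ECF"]),
                     fraction_neutral(7.4, d) / fraction_neutral(7.2, d),
                     0.01)
  }
})

test_that("simulation is linear in the forcing and grid-stable", {
  model <- cns_model(phys, base_drug(kpuu = 0.14))
  s1 <- simulate_cns(model, 10, t_end = 600, n_grid = 61)
  s2 <- simulate_cns(model, 30, t_end = 600, n_grid = 61)
  expect_rel_equal(as.vector(s2$conc[, -1]), as.vector(3 * s1$conc[, -1]),
                   1e-9)
  # refining the output grid does not change shared points
  s3 <- simulate_cns(model, 10, t_end = 600, n_grid = 121)
  shared <- match(s1$times, s3$times)
  expect_rel_equal(as.vector(s3$conc[, shared][, -1]),
                   as.vector(s1$conc[, -1]), 1e-9)
})

test_that("plasma-coupled simulations conserve mass for all 10 drugs", {
  for (nm in names(plasma_models())) {
    pm <- plasma_models(nm)[[1]]
    drug <- cns_drugs(nm)[[1]]
    model <- cns_model(phys, drug)
    f <- suppressMessages(
      plasma_forcing(pm, dose_event(dose_from_mg_kg(pm$dose_mg_kg))))
    sim <- simulate_cns(model, f, t_end = 360, n_grid = 49)
    expect_lt(max(abs(sim$mass_balance_rel)), 1e-6)
    expect_gt(max(sim$conc["ECF", ]), 0)
    expect_true(all(sim$conc >= -1e-9 * max(sim$conc)))
  }
})

test_that("tidy export carries every compartment at every time", {
  model <- cns_model(phys, neutral_drug())
  sim <- simulate_cns(model, 5, t_end = 60, n_grid = 13)
  df <- as.data.frame(sim)
  expect_equal(nrow(df), 8 * 13)
  expect_setequal(unique(df$compartment),
                  c("MV", "ECF", "ICF", "LYS", "LV", "TFV", "CM", "SAS"))
})
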