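# Monte Carlo probability of target attainment and the closed-form oracle.

test_that("closed-form PTA matches the analytic normal-CDF arithmetic", {
  cfg <- pta_config()
  # CRRT typical clearance, 500 mg: Phi(2.205) ~ 0.986
  expect_equal(pta_closed_form(0.386, 500, cfg, omega_cl = 0.091),
               stats::pnorm(log(500 / (666 * 0.386)) / sqrt(0.091)),
               tolerance = 1e-12)
  expect_equal(pta_closed_form(0.386, 500, cfg, omega_cl = 0.091), 0.986,
               tolerance = 1e-3)
  # dose exactly at the target threshold -> one half
  tvcl <- 0.386
  expect_equal(pta_closed_form(tvcl, 666 * tvcl, cfg, omega_cl = 0.091), 0.5)
  # degenerate variability: step function
  expect_equal(pta_closed_form(tvcl, 666 * tvcl * 1.01, cfg, omega_cl = 0), 1)
  expect_equal(pta_closed_form(tvcl, 666 * tvcl * 0.99, cfg, omega_cl = 0), 0)
})

test_that("Monte Carlo PTA agrees with the closed-form oracle per cell", {
  m <- final_model()
  cfg <- pta_config(n_subjects = 1000)
  cells <- expand.grid(dose = c(400, 700), ccr = c(20, 90, NA))
  for (i in seq_len(nrow(cells))) {
    g <- if (is.na(cells$ccr[i])) renal_group(crrt = TRUE) else
      renal_group(cells$ccr[i])
    tvcl <- unname(typical_clearance(m, daptopk:::group_covs(g)))
    mc <- simulate_group(m, pk_regimen(cells$dose[i]), g, cfg, seed = 40 + i)
    cf <- 100 * pta_closed_form(tvcl, cells$dose[i], cfg, omega_cl = 0.091)
    expect_lt(abs(mc$pta_pct - cf), 3)
  }
})

test_that("degenerate population gives a step-function PTA", {
  m0 <- pop_model(omega = c(CL = 1e-12, VC = 1e-12, VP = 1e-12))
  cfg <- pta_config(n_subjects = 200)
  g <- renal_group(crrt = TRUE)
  hi <- simulate_group(m0, pk_regimen(666 * 0.386 * 1.05), g, cfg, seed = 1)
  lo <- simulate_group(m0, pk_regimen(666 * 0.386 * 0.95), g, cfg, seed = 1)
  expect_equal(hi$pta_pct, 100)
  expect_equal(lo$pta_pct, 0)
})

test_that("PTA is monotone in dose and in renal function", {
  m <- final_model()
  cfg <- pta_config(n_subjects = 500)
  grid <- pta_grid(m, doses = c(400, 500, 600, 700),
                   groups = list(renal_group(20), renal_group(60),
                                 renal_group(120)),
                   cfg = cfg, seed = 3)
  for (g in unique(grid$group)) {
    p <- grid$pta_pct[grid$group == g][order(grid$dose[grid$group == g])]
    expect_true(all(diff(p) >= 0))
  }
  for (d in unique(grid$dose)) {
    p <- grid$pta_pct[grid$dose == d][match(c("CCR20", "CCR60", "CCR120"),
                                            grid$group[grid$dose == d])]
    expect_true(all(diff(p) <= 0))
  }
})

test_that("doubling MIC is exactly equivalent to halving dose", {
  cfg1 <- pta_config(mic = 1)
  cfg2 <- pta_config(mic = 2)
  expect_equal(pta_closed_form(0.386, 250, cfg1, 0.091),
               pta_closed_form(0.386, 500, cfg2, 0.091), tolerance = 1e-12)
  m <- final_model()
  g <- renal_group(60)
  a <- simulate_group(m, pk_regimen(250), g, cfg1, seed = 11)
  b <- simulate_group(m, pk_regimen(500), g, cfg2, seed = 11)
  expect_equal(a$pta_pct, b$pta_pct)
})

test_that("safety exceedance never exceeds efficacy attainment", {
  m <- final_model()
  cfg <- pta_config(n_subjects = 500)
  grid <- pta_grid(m, doses = c(500, 700),
                   groups = list(renal_group(30), renal_group(crrt = TRUE)),
                   cfg = cfg, seed = 13)
  expect_true(all(grid$auc_safety_pct <= grid$pta_pct))
})

test_that("median steady-state AUC24 equals dose over typical clearance", {
  m <- final_model()
  cfg <- pta_config(n_subjects = 10000)
  g <- simulate_group(m, pk_regimen(500), renal_group(crrt = TRUE), cfg,
                      seed = 17)
  expect_equal(g$median_auc24, 500 / 0.386, tolerance = 0.01)
})

test_that("alternate AUC definitions bracket sensibly and the grid has full shape", {
  m <- final_model()
  g <- renal_group(60)
  ss <- simulate_group(m, pk_regimen(500), g,
                       pta_config(n_subjects = 300), seed = 19)
  d1 <- simulate_group(m, pk_regimen(500), g,
                       pta_config(n_subjects = 300, auc_def = "day1"),
                       seed = 19)
  k7 <- simulate_group(m, pk_regimen(500), g,
                       pta_config(n_subjects = 300, auc_def = "interval_k",
                                  k = 7), seed = 19)
  # day-1 exposure is below steady state; a late interval approaches it
  expect_lt(d1$median_auc24, ss$median_auc24)
  expect_lt(abs(k7$median_auc24 / ss$median_auc24 - 1), 0.05)

  grid <- pta_grid(m, doses = c(400, 500, 600, 700),
                   cfg = pta_config(n_subjects = 100), seed = 23)
  expect_equal(nrow(grid), 4 * 7)
  wide <- pta_wide(grid, "pta_pct")
  expect_equal(dim(wide), c(4, 2 + 7))
  expect_true(all(grid$pta_pct >= 0 & grid$pta_pct <= 100))
  expect_true(all(grid$median_auc24 > 0))
})
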