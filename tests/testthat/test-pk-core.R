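# Closed-form two-compartment kinetics.

test_that("micro and hybrid rate constants follow the standard reparameterization", {
  pk <- typical_crrt_pk()
  mc <- micro_constants(pk)
  expect_equal(mc$k10, 0.386 / 4.14, tolerance = 1e-12)
  expect_equal(mc$k12, 2.09 / 4.14, tolerance = 1e-12)
  expect_equal(mc$k21, 2.09 / 3.52, tolerance = 1e-12)

  hc <- hybrid_constants(mc)
  # frozen from the quadratic-root oracle on k10, k12, k21 above
  expect_equal(hc$alpha, 1.1434013, tolerance = 1e-6)
  expect_equal(hc$beta, 0.0484163, tolerance = 1e-5)
  expect_gt(hc$alpha, hc$beta)
  # Vieta identities
  expect_equal(hc$alpha + hc$beta, mc$k10 + mc$k12 + mc$k21, tolerance = 1e-12)
  expect_equal(hc$alpha * hc$beta, mc$k10 * mc$k21, tolerance = 1e-12)

  # identity case and decoupled limits
  mc1 <- micro_constants(pk_params(1, 1, 1, 1))
  expect_equal(unname(unlist(mc1)), c(1, 1, 1))
  expect_warning(pkq0 <- pk_params(1, 2, 1, 0), "one-compartment")
  mcq0 <- micro_constants(pkq0)
  expect_equal(mcq0$k12, 0)
  expect_equal(mcq0$k21, 0)
  hcq0 <- hybrid_constants(mcq0)
  expect_equal(hcq0$alpha, mcq0$k10, tolerance = 1e-12)
  expect_equal(hcq0$beta, 0)
})

test_that("parameter validation rejects non-positive or non-finite values", {
  expect_error(pk_params(-1, 4, 3, 2), "positive")
  expect_error(pk_params(1, 0, 3, 2), "positive")
  expect_error(pk_params(1, NA, 3, 2), "finite")
  expect_error(pk_regimen(500, 0.4, 0.5), "interval > duration")
  expect_error(dose_events(0, -500, 0.5), "amount")
  expect_error(pk_concentration(-1, typical_crrt_pk(), dose_events(0, 500, 0.5)),
               "t must be")
})

test_that("concentration is causal, linear in dose, and matches the ODE oracle", {
  pk <- typical_crrt_pk()
  doses <- dose_events(c(0, 24, 48), 500, 0.5)
  expect_equal(pk_concentration(0, pk, dose_events(10, 500, 0.5)), 0)

  tt <- c(0.25, 0.5, 1, 6, 23.9, 24.5, 30, 49, 72)
  c1 <- pk_concentration(tt, pk, doses)
  doses2 <- dose_events(c(0, 24, 48), 1000, 0.5)
  expect_equal(pk_concentration(tt, pk, doses2), 2 * c1, tolerance = 1e-12)

  skip_if_not_installed("deSolve")
  tt_dense <- sort(c(seq(0.05, 168, by = 0.7), 0.5, 24.5))
  d7 <- regimen_doses(pk_regimen(500, 24, 0.5, n_doses = 7))
  c_ode <- ode_concentration(tt_dense, pk, d7)
  c_cf <- pk_concentration(tt_dense, pk, d7)
  expect_lt(max(abs(c_cf - c_ode) / pmax(c_ode, 1e-9)), 1e-3)
})

test_that("closed form matches the ODE oracle on random parameter sets", {
  skip_if_not_installed("deSolve")
  set.seed(20240)
  doses <- dose_events(c(0, 24), 500, 0.5)
  tt <- c(0.25, 0.5, 2, 8, 23.9, 24.5, 30, 47.9)
  typ <- c(0.386, 4.14, 3.52, 2.09)
  for (i in 1:100) {
    p <- typ * exp(stats::runif(4, -log(10), log(10)))
    pk <- pk_params(p[1], p[2], p[3], p[4])
    c_cf <- pk_concentration(tt, pk, doses)
    c_ode <- ode_concentration(tt, pk, doses)
    expect_lt(max(abs(c_cf - c_ode) / pmax(abs(c_ode), 1e-8)), 1e-3)
  }
})

test_that("interval AUC is exact, additive, and conserves mass", {
  pk <- typical_crrt_pk()
  d1 <- dose_events(0, 400, 0.5)
  # AUC(0, Inf) = dose / CL
  expect_equal(auc_interval(pk, d1, 0, Inf), 400 / 0.386, tolerance = 1e-10)
  # near-bolus 24-h AUC, frozen from the biexponential closed form
  expect_equal(auc_interval(pk, dose_events(0, 400, 1e-6), 0, 24), 725.33,
               tolerance = 1e-4)
  # additivity over abutting intervals at random split points
  doses <- regimen_doses(pk_regimen(500, 24, 0.5, n_doses = 7))
  set.seed(1)
  for (i in 1:10) {
    ab <- sort(stats::runif(2, 0, 170))
    expect_equal(auc_interval(pk, doses, 0, ab[1]) +
                   auc_interval(pk, doses, ab[1], ab[2]),
                 auc_interval(pk, doses, 0, ab[2]), tolerance = 1e-10)
  }
  # conservation for an irregular schedule
  dd <- dose_events(c(0, 7, 30), c(500, 250, 700), c(0.5, 1, 0.25))
  expect_equal(pk$CL * auc_interval(pk, dd, 0, Inf), sum(dd$amount),
               tolerance = 1e-8)
  expect_error(auc_interval(pk, d1, 5, 5), "t0 < t1")
})

test_that("AUC agrees with numeric quadrature of the ODE solution", {
  skip_if_not_installed("deSolve")
  pk <- typical_crrt_pk()
  doses <- dose_events(0, 400, 0.5)
  q <- stats::integrate(function(t) pk_concentration(t, pk, doses), 0, 24,
                        rel.tol = 1e-10, subdivisions = 500L)
  expect_equal(auc_interval(pk, doses, 0, 24), q$value, tolerance = 1e-8)
})

test_that("steady-state metrics follow the accumulation geometry", {
  pk <- typical_crrt_pk()
  reg <- pk_regimen(500, 24, 0.5)
  ss <- steady_state_metrics(pk, reg)
  expect_equal(ss$auc_ss, 500 / 0.386, tolerance = 1e-12)
  # long-horizon explicit superposition oracle for the trough
  n <- 200
  dlong <- dose_events((seq_len(n) - 1) * 24, 500, 0.5)
  cmin_sup <- pk_concentration(n * 24 - 1e-9, pk, dlong)
  expect_equal(ss$cmin_ss, cmin_sup, tolerance = 5e-3)
  # cmax at end of infusion
  cmax_sup <- pk_concentration((n - 1) * 24 + 0.5, pk, dlong)
  expect_equal(ss$cmax_ss, cmax_sup, tolerance = 5e-3)
  # no accumulation in the long-interval limit
  ss_inf <- steady_state_metrics(pk, pk_regimen(500, 1e6, 0.5))
  expect_lt(ss_inf$cmin_ss, 1e-10)
  # trough strictly increases as the interval shrinks
  taus <- c(48, 24, 12, 8)
  cmins <- vapply(taus, function(tau)
    steady_state_metrics(pk, pk_regimen(500, tau, 0.5))$cmin_ss, numeric(1))
  expect_true(all(diff(cmins) > 0))
})

test_that("the two-compartment solution collapses to one compartment as Q -> 0", {
  CL <- 0.386; VC <- 4.14
  doses <- dose_events(0, 500, 0.5)
  tt <- c(0.25, 0.5, 2, 8, 24)
  k <- CL / VC
  rate <- 500 / 0.5
  one_cmt <- ifelse(tt <= 0.5,
                    rate / (k * VC) * (1 - exp(-k * tt)),
                    rate / (k * VC) * (1 - exp(-k * 0.5)) * exp(-k * (tt - 0.5)))
  pk_small_q <- pk_params(CL, VC, 3.52, 1e-8)
  expect_equal(pk_concentration(tt, pk_small_q, doses), one_cmt,
               tolerance = 1e-5)
})
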