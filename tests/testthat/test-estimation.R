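# FOCE-I / Laplace estimation machinery.

test_that("empirical Bayes mode is zero for data at the typical profile", {
  m <- toy_model()
  ds <- toy_dataset(m, seed = 1, n = 2)
  # replace DVs by exact typical predictions
  for (id in unique(ds$ID)) {
    sel <- ds$ID == id & ds$EVID == 0
    cov <- ds[ds$ID == id, ][1, c("CRRT", "CCR")]
    pk <- individual_params(m, cov)
    ds$DV[sel] <- pk_concentration(ds$TIME[sel], pk, dose_events(c(0, 24), 500, 0.5))
  }
  r <- map_eta(ds, m, 1)
  expect_true(r$converged)
  expect_lt(abs(r$eta[["CL"]]), 1e-6)
})

test_that("infinite prior precision forces the mode to zero", {
  m <- toy_model()
  ds <- toy_dataset(m, seed = 2, n = 2)
  m_tight <- pop_model(theta = m$theta, omega = c(CL = 1e-10),
                       sigma = m$sigma, spec = toy_spec())
  r <- map_eta(ds, m_tight, 1)
  expect_lt(abs(r$eta[["CL"]]), 1e-4)
})

test_that("the inner mode matches an independent one-dimensional oracle", {
  m <- toy_model()
  ds <- toy_dataset(m, seed = 3, n = 2)
  obs <- ds[ds$ID == 1 & ds$EVID == 0 & ds$MDV == 0, ]
  doses <- dose_events(c(0, 24), 500, 0.5)
  sa2 <- m$sigma[["add"]]
  w2 <- m$omega["CL", "CL"]
  g <- function(e) {
    f <- pk_concentration(obs$TIME,
                          daptopk:::new_pk_params(0.4 * exp(e), 5, 1, 0),
                          doses)
    sum((obs$DV - f)^2 / sa2 + log(sa2)) + e^2 / w2
  }
  oracle <- stats::optimize(g, c(-5, 5), tol = 1e-12)
  r <- map_eta(ds, m, 1)
  expect_equal(unname(r$eta[["CL"]]), oracle$minimum, tolerance = 1e-6)
})

test_that("the Laplace OFV agrees with the quadrature oracle", {
  m <- toy_model(omega_cl = 0.2, sigma_add = 20)
  ds <- toy_dataset(m, seed = 4, n = 3)
  r <- foce_ofv(ds, m)
  expect_lt(abs(r$ofv - quadrature_m2ll(ds, m)), 0.1)
  # near-linear regime: tiny IIV makes the approximation essentially exact
  # (limited by the finite-difference hessian step, not the Laplace error)
  m_lin <- toy_model(omega_cl = 1e-4, sigma_add = 20)
  r_lin <- foce_ofv(ds, m_lin)
  expect_lt(abs(r_lin$ofv - quadrature_m2ll(ds, m_lin)), 1e-4)
})

test_that("OFV is additive over subjects and deterministic", {
  m <- final_model()
  ds <- generate_dataset(cohort_config(n_subjects = 6), m, seed = 10)
  r1 <- foce_ofv(ds, m)
  ds2 <- ds
  ds2$ID <- ds2$ID + 100
  both <- rbind(ds, ds2)
  r2 <- foce_ofv(both, m)
  expect_equal(r2$ofv, 2 * r1$ofv, tolerance = 1e-9)
  expect_identical(foce_ofv(ds, m)$ofv, r1$ofv)
})

test_that("information criteria identities hold, including the p = 0 edge", {
  ic <- information_criteria(100, 0, 50)
  expect_equal(ic$AIC, 100)
  expect_equal(ic$BIC, 100)
  ic2 <- information_criteria(200, 5, 100)
  expect_equal(ic2$AIC, 200 + 10)
  expect_equal(ic2$BIC, 200 + 5 * log(100))
})

test_that("shrinkage formula and its degenerate cases", {
  om <- diag(c(CL = 0.09), 1)
  dimnames(om) <- list("CL", "CL")
  etas <- matrix(c(-0.3, 0.3), 2, 1, dimnames = list(NULL, "CL"))
  s <- eta_shrinkage(etas, om)
  expect_equal(unname(s), 100 * (1 - stats::sd(etas[, 1]) / 0.3))
  zero <- matrix(0, 5, 1, dimnames = list(NULL, "CL"))
  expect_equal(unname(eta_shrinkage(zero, om)), 100)
  expect_error(eta_shrinkage(zero[1, , drop = FALSE], om), "2 subjects")
})

test_that("near-noise-free data recover the generating fixed effects within 1%", {
  m_tiny <- pop_model(omega = c(CL = 1e-6, VC = 1e-6, VP = 1e-6),
                      sigma = c(prop = 1e-8, add = 1e-4))
  ds <- generate_dataset(cohort_config(n_subjects = 16, retention = 1),
                         m_tiny, seed = 20)
  init <- pop_model(theta = c(NR = 0.3, R = 0.1, CL_CRRT = 0.3, VC = 5,
                              VP = 2.8, Q = 1.6),
                    omega = c(CL = 1e-4, VC = 1e-4, VP = 1e-4),
                    sigma = c(prop = 1e-6, add = 1e-2))
  fit <- fit_popmodel(ds, init, fit_control(se = FALSE))
  est <- fit$estimates[c("NR", "R", "CL_CRRT", "VC", "VP", "Q")]
  truth <- c(0.229, 0.148, 0.386, 4.14, 3.52, 2.09)
  expect_lt(max(abs(est / truth - 1)), 0.01)
  # information-criteria invariants hold exactly on the fit
  expect_equal(fit$aic, fit$ofv + 2 * fit$p)
  expect_equal(fit$bic, fit$ofv + fit$p * log(fit$n_obs))
})

test_that("the fit improves on (or matches) the initial objective", {
  m <- toy_model()
  ds <- toy_dataset(m, seed = 6, n = 12)
  init <- pop_model(theta = c(CL = 0.6, VC = 7), omega = c(CL = 0.3),
                    sigma = c(prop = 0, add = 40), spec = toy_spec())
  f <- fit_popmodel(ds, init, fit_control(se = FALSE))
  expect_lte(f$ofv, foce_ofv(ds, init)$ofv)
  expect_true(f$converged)
})

test_that("standard errors are finite and scale-consistent on a toy fit", {
  m <- toy_model()
  ds <- toy_dataset(m, seed = 7, n = 25)
  f <- fit_popmodel(ds, m, fit_control(se = TRUE))
  expect_false(is.null(f$se))
  expect_true(all(is.finite(f$se[c("CL", "VC")])))
  expect_true(all(f$rse[c("CL", "VC")] > 0 & f$rse[c("CL", "VC")] < 100))
  tab <- fit_parameter_table(f)
  expect_true(all(c("parameter", "estimate", "rse_pct") %in% names(tab)))
})

test_that("structural comparison selects the generating compartment count", {
  ds2 <- generate_dataset(cohort_config(), final_model(), seed = 21)
  cmp2 <- compare_structural(ds2)
  expect_equal(cmp2$choice, "two-compartment")
  expect_gt(cmp2$delta_ofv, 3.84)

  sp1 <- pk_model_spec(n_cmt = 1)
  m1 <- pop_model(theta = c(NR = 0.229, R = 0.148, CL_CRRT = 0.386, VC = 6),
                  omega = c(CL = 0.091, VC = 0.114),
                  sigma = c(prop = 0.018, add = 10), spec = sp1)
  ds1 <- generate_dataset(cohort_config(), m1, seed = 22)
  cmp1 <- compare_structural(ds1)
  expect_equal(cmp1$choice, "one-compartment")
  # the richer model cannot fit worse than the nested one (up to optimizer
  # termination tolerance)
  expect_gte(cmp1$delta_ofv + 0.01, 0)
})

test_that("stepwise selects a real renal effect and rejects a null sex effect", {
  ds <- generate_dataset(cohort_config(), final_model(), seed = 23)
  sw <- stepwise_covariates(
    ds,
    candidates = list(list(param = "CL", cov = "CCR"),
                      list(param = "VP", cov = "SEX")),
    control = fit_control(se = FALSE))
  expect_true("CL~CCR" %in% sw$selected)
  expect_false("VP~SEX" %in% sw$selected)
  fw <- sw$trace[sw$trace$phase == "forward" & sw$trace$action == "accepted", ]
  expect_true(all(fw$delta_ofv > 3.84))
  bw <- sw$trace[sw$trace$phase == "backward" & sw$trace$action == "retained", ]
  expect_true(all(bw$delta_ofv > 6.635))
})

test_that("bootstrap medians track the point estimates and CIs widen with noise", {
  m <- toy_model()
  ds <- toy_dataset(m, seed = 8, n = 25)
  fit <- fit_popmodel(ds, m, fit_control(se = FALSE))
  b1 <- bootstrap_fit(ds, fit, n_boot = 40, seed = 99)
  b1b <- bootstrap_fit(ds, fit, n_boot = 40, seed = 99)
  expect_identical(b1$summary, b1b$summary) # same seed, same resamples
  expect_lt(abs(b1$summary["CL", "median"] / fit$estimates[["CL"]] - 1), 0.10)

  # inflate residual noise 4x in the generating model and re-run
  m4 <- toy_model(sigma_add = 4 * 16)
  ds4 <- toy_dataset(m4, seed = 8, n = 25)
  fit4 <- fit_popmodel(ds4, m4, fit_control(se = FALSE))
  b4 <- bootstrap_fit(ds4, fit4, n_boot = 40, seed = 99)
  expect_gt(b4$summary["sigma_add", "hi"] - b4$summary["sigma_add", "lo"],
            b1$summary["sigma_add", "hi"] - b1$summary["sigma_add", "lo"])
})
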