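# Covariate model, lognormal IIV, combined residual error, forward simulation.

test_that("typical clearance follows the CRRT / renal-slope structure", {
  m <- final_model()
  expect_equal(unname(typical_clearance(m, data.frame(CRRT = TRUE, CCR = NA))),
               0.386)
  expect_equal(unname(typical_clearance(m, data.frame(CRRT = TRUE, CCR = 120))),
               0.386) # CRRT clearance ignores CCR
  expect_equal(unname(typical_clearance(m, data.frame(CRRT = FALSE, CCR = 54))),
               0.229 + 0.148, tolerance = 1e-12)
  expect_equal(unname(typical_clearance(m, data.frame(CRRT = FALSE, CCR = 1e-9))),
               0.229, tolerance = 1e-6)
  expect_error(typical_clearance(m, data.frame(CRRT = FALSE, CCR = NA)), "CCR")

  # affine and strictly increasing in CCR for non-CRRT subjects
  ccr <- c(10, 40, 54, 90, 150)
  cl <- typical_clearance(m, data.frame(CRRT = FALSE, CCR = ccr))
  expect_true(all(diff(cl) > 0))
  expect_equal(unname(diff(cl) / diff(ccr)), rep(0.148 / 54, 4), tolerance = 1e-12)
})

test_that("no covariate other than CCR/CRRT alters the final-model parameters", {
  m <- final_model()
  base <- data.frame(CRRT = FALSE, CCR = 54, AGE = 57, SEX = 1, WT = 64,
                     BMI = 23, ALB = 33, SOFA = 12, APACHE = 24, ECMO = 0)
  alt <- transform(base, AGE = 30, SEX = 0, WT = 120, BMI = 40, ALB = 20,
                   SOFA = 19, APACHE = 47, ECMO = 1)
  expect_equal(typical_params(m, base), typical_params(m, alt))
})

test_that("individual parameters apply lognormal IIV on CL, VC, VP only", {
  m <- final_model()
  cov <- data.frame(CRRT = TRUE, CCR = NA)
  p0 <- individual_params(m, cov, c(CL = 0, VC = 0, VP = 0))
  expect_equal(c(p0$CL, p0$VC, p0$VP, p0$Q), c(0.386, 4.14, 3.52, 2.09))
  p2 <- individual_params(m, cov, c(CL = log(2)))
  expect_equal(p2$CL, 2 * 0.386, tolerance = 1e-12)
  expect_equal(c(p2$VC, p2$VP, p2$Q), c(4.14, 3.52, 2.09))
})

test_that("population median of simulated clearance equals the typical value", {
  m <- final_model()
  set.seed(77)
  etas <- daptopk:::draw_etas(m$omega, 1e5)
  cl <- 0.386 * exp(etas[, "CL"])
  expect_equal(stats::median(cl), 0.386, tolerance = 0.01)
})

test_that("residual error SD follows the combined model", {
  expect_equal(residual_sd(0), sqrt(38.095), tolerance = 1e-12)
  # proportional-dominant limit
  expect_equal(residual_sd(1e6) / 1e6, sqrt(0.018), tolerance = 1e-4)
  preds <- seq(0, 100, by = 5)
  expect_true(all(diff(residual_sd(preds)) >= 0))
  expect_error(residual_sd(-1), "pred")
})

test_that("simulation is reproducible and degenerates to the typical profile", {
  spec <- pk_model_spec()
  m0 <- pop_model(omega = c(CL = 0, VC = 0, VP = 0),
                  sigma = c(prop = 0, add = 0), spec = spec)
  cov <- data.frame(CRRT = TRUE, CCR = NA)
  doses <- regimen_doses(pk_regimen(500, 24, 0.5, n_doses = 2))
  tt <- c(0.5, 2, 24, 26)
  s0 <- simulate_observations(m0, cov, doses, tt, seed = 1)
  expect_equal(s0$dv, pk_concentration(tt, typical_crrt_pk(), doses))

  m <- final_model()
  s1 <- simulate_observations(m, cov, doses, tt, seed = 5)
  s2 <- simulate_observations(m, cov, doses, tt, seed = 5)
  s3 <- simulate_observations(m, cov, doses, tt, seed = 6)
  expect_identical(s1$dv, s2$dv)
  expect_false(any(s1$dv == s3$dv))
})

test_that("simulated variance at a fixed time matches the error model", {
  m <- final_model()
  cov <- data.frame(CRRT = TRUE, CCR = NA)
  doses <- dose_events(0, 500, 0.5)
  # freeze eta at 0 to isolate residual variance
  m_noiiv <- pop_model(omega = c(CL = 1e-12, VC = 1e-12, VP = 1e-12),
                       sigma = m$sigma)
  set.seed(99)
  dv <- replicate(1e4, simulate_observations(m_noiiv, cov, doses, 8)$dv)
  pred <- pk_concentration(8, typical_crrt_pk(), doses)
  expect_equal(stats::var(dv), pred^2 * 0.018 + 38.095, tolerance = 0.05)
})

test_that("BLQ flagging marks values below LLOQ and negative draws", {
  m <- pop_model(sigma = c(prop = 0, add = 38.095))
  cov <- data.frame(CRRT = TRUE, CCR = NA)
  set.seed(3)
  # very late time point: prediction near zero, additive noise dominates
  s <- simulate_observations(m, cov, dose_events(0, 500, 0.5),
                             rep(2000, 200))
  expect_true(all(s$blq[s$dv < 0.05]))
  expect_true(any(s$dv < 0)) # negative draws preserved, only flagged
})

test_that("steady-state AUC24 for fixed covariates is lognormal around dose/TVCL", {
  m <- final_model()
  set.seed(123)
  etas <- daptopk:::draw_etas(m$omega, 1e4)
  auc <- 500 / (0.386 * exp(etas[, "CL"]))
  ks <- stats::ks.test(log(auc), "pnorm", mean = log(500 / 0.386),
                       sd = sqrt(0.091))
  expect_gt(ks$p.value, 0.01)
})

test_that("model config serialization round-trips bit-exactly", {
  spec <- pk_model_spec(effects = list(list(param = "VP", cov = "SEX",
                                            form = "catmult", ref = 1)))
  m <- pop_model(theta = c(NR = 0.229, R = 0.148, CL_CRRT = 0.386, VC = 4.14,
                           VP = 3.52, Q = 2.09, beta_VP_SEX = 1.4),
                 spec = spec)
  f <- withr::local_tempfile(fileext = ".cfg")
  write_model_config(m, f)
  m2 <- read_model_config(f)
  expect_identical(m$theta, m2$theta)
  expect_identical(m$omega, m2$omega)
  expect_identical(m$sigma, m2$sigma)
  expect_equal(m$spec, m2$spec)
})
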