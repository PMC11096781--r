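# Shared fixtures, built in code.

# final published model (the generating truth for recovery experiments)
final_model <- function() pop_model()

final_truth <- function() {
  c(NR = 0.229, R = 0.148, CL_CRRT = 0.386, VC = 4.14, VP = 3.52, Q = 2.09,
    omega_CL = 0.091, omega_VC = 0.114, omega_VP = 0.202,
    sigma_prop = 0.018, sigma_add = 38.095)
}

typical_crrt_pk <- function() pk_params(CL = 0.386, VC = 4.14, VP = 3.52, Q = 2.09)

# neutral starting values for recovery fits (off-truth on purpose)
recovery_init <- function() {
  pop_model(theta = c(NR = 0.3, R = 0.1, CL_CRRT = 0.3, VC = 5, VP = 3, Q = 1.5),
            omega = c(CL = 0.05, VC = 0.05, VP = 0.1),
            sigma = c(prop = 0.04, add = 20))
}

# light one-compartment toy population (fast fits; used for calibration and
# oracle checks)
toy_spec <- function() {
  pk_model_spec(n_cmt = 1, crrt_cl = FALSE, ccr_on_cl = FALSE,
                iiv = "CL", error = "additive")
}

toy_model <- function(omega_cl = 0.1, sigma_add = 16) {
  pop_model(theta = c(CL = 0.4, VC = 5), omega = c(CL = omega_cl),
            sigma = c(prop = 0, add = sigma_add), spec = toy_spec())
}

# assemble a study dataset from per-subject simulated observations
assemble_dataset <- function(covs, doses, sims) {
  rows <- lapply(seq_len(nrow(covs)), function(i) {
    sim <- sims[[i]]
    d <- rbind(
      data.frame(ID = covs$ID[i], TIME = doses$start_time, EVID = 1L,
                 AMT = doses$amount, RATE = doses$amount / doses$duration,
                 DV = NA_real_, MDV = 1L, BLQ = 0L),
      data.frame(ID = covs$ID[i], TIME = sim$time, EVID = 0L, AMT = NA_real_,
                 RATE = NA_real_, DV = sim$dv, MDV = as.integer(sim$blq),
                 BLQ = as.integer(sim$blq)))
    d <- d[order(d$TIME, d$EVID), ]
    cbind(d, covs[rep(i, nrow(d)), setdiff(names(covs), "ID"), drop = FALSE])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("study_dataset", "data.frame")
  out
}

# small fast cohort simulated from `model` on a sparse design
toy_dataset <- function(model, seed, n = 30,
                        times = c(0.5, 2, 8, 24, 24.5, 47.9),
                        doses = dose_events(c(0, 24), 500, 0.5)) {
  set.seed(seed)
  covs <- sample_covariates(cohort_config(n_subjects = n, retention = 1))
  sims <- lapply(seq_len(n), function(i)
    simulate_observations(model, covs[i, ], doses, times))
  assemble_dataset(covs, doses, sims)
}

# exact marginal -2 log likelihood of the one-eta toy by adaptive quadrature
quadrature_m2ll <- function(ds, m) {
  doses <- dose_events(c(0, 24), 500, 0.5)
  sa <- sqrt(m$sigma[["add"]])
  w <- sqrt(m$omega["CL", "CL"])
  total <- 0
  for (id in unique(ds$ID)) {
    obs <- ds[ds$ID == id & ds$EVID == 0 & ds$MDV == 0, ]
    lik <- function(u) vapply(u, function(e) {
      f <- pk_concentration(obs$TIME,
                            daptopk:::new_pk_params(0.4 * exp(e), 5, 1, 0),
                            doses)
      exp(sum(stats::dnorm(obs$DV, f, sa, log = TRUE)) +
            stats::dnorm(e, 0, w, log = TRUE))
    }, numeric(1))
    q <- stats::integrate(lik, -6 * w, 6 * w, rel.tol = 1e-11)
    total <- total - 2 * log(q$value)
  }
  total
}

# numeric ODE oracle for the two-compartment infusion model (deSolve)
ode_concentration <- function(times, pk, doses) {
  mc <- micro_constants(pk)
  rhs <- function(t, A, p) {
    rate <- sum(ifelse(t > doses$start_time &
                         t <= doses$start_time + doses$duration,
                       doses$amount / doses$duration, 0))
    list(c(rate - (mc$k10 + mc$k12) * A[1] + mc$k21 * A[2],
           mc$k12 * A[1] - mc$k21 * A[2]))
  }
  out <- deSolve::ode(c(0, 0), c(0, times), rhs, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12, hmax = 0.25)
  out[-1, 2] / pk$VC
}
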