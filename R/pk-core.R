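#' Individual two-compartment disposition parameters
#'
#' Container for the disposition parameters of the two-compartment model used
#' throughout the package: total clearance `CL` (L/h), central volume `VC`
#' (L), peripheral volume `VP` (L) and intercompartmental clearance `Q` (L/h).
#'
#' @param CL total clearance, L/h (> 0)
#' @param VC central volume of distribution, L (> 0)
#' @param VP peripheral volume of distribution, L (> 0)
#' @param Q intercompartmental clearance, L/h (>= 0; `Q = 0` collapses the
#'   model to one-compartment kinetics and is flagged with a warning)
#' @return an object of class `pk_params`
#' @examples
#' pk_params(CL = 0.386, VC = 4.14, VP = 3.52, Q = 2.09)
#' @export
pk_params <- function(CL, VC, VP, Q) {
  vals <- c(CL = CL, VC = VC, VP = VP, Q = Q)
  if (any(!is.finite(vals))) stop("pk_params: all parameters must be finite")
  if (CL <= 0 || VC <= 0 || VP <= 0) {
    stop("pk_params: CL, VC and VP must be strictly positive")
  }
  if (Q < 0) stop("pk_params: Q must be non-negative")
  if (Q == 0) warning("Q = 0: one-compartment degeneracy")
  structure(as.list(vals), class = "pk_params")
}

# internal constructor: same invariants, no degeneracy warning (used where
# a one-compartment structure is intentional)
new_pk_params <- function(CL, VC, VP, Q) {
  structure(list(CL = CL, VC = VC, VP = VP, Q = Q), class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat("Two-compartment PK parameters:\n")
  cat(sprintf("  CL = %.4g L/h, VC = %.4g L, VP = %.4g L, Q = %.4g L/h\n",
              x$CL, x$VC, x$VP, x$Q))
  invisible(x)
}

#' Micro rate constants of the two-compartment model
#'
#' Reparameterizes `(CL, VC, VP, Q)` as first-order rate constants:
#' `k10 = CL/VC` (elimination), `k12 = Q/VC` (central to peripheral) and
#' `k21 = Q/VP` (peripheral to central), all in 1/h.
#'
#' @param pk a [pk_params()] object
#' @return named list with `k10`, `k12`, `k21`
#' @export
micro_constants <- function(pk) {
  stopifnot(inherits(pk, "pk_params"))
  list(k10 = pk$CL / pk$VC, k12 = pk$Q / pk$VC, k21 = pk$Q / pk$VP)
}

#' Hybrid (macro) rate constants
#'
#' The fast (`alpha`) and slow (`beta`) hybrid disposition rate constants,
#' i.e. the roots of `s^2 - (k10 + k12 + k21) s + k10 k21 = 0` with
#' `alpha >= beta`. Computed with a cancellation-safe quadratic (large root
#' directly, small root via Vieta's product identity).
#'
#' @param mc micro constants as returned by [micro_constants()]
#' @return named list with `alpha`, `beta` (1/h)
#' @export
hybrid_constants <- function(mc) {
  stopifnot(all(c("k10", "k12", "k21") %in% names(mc)))
  s <- mc$k10 + mc$k12 + mc$k21
  p <- mc$k10 * mc$k21
  disc <- s * s - 4 * p
  if (disc < 0) {
    if (disc < -1e-10 * s * s) stop("hybrid_constants: negative discriminant")
    disc <- 0
  }
  alpha <- (s + sqrt(disc)) / 2
  beta <- if (alpha > 0) p / alpha else 0
  list(alpha = alpha, beta = beta)
}

#' Dose events (zero-order infusions)
#'
#' Builds a table of infusion events. In the study design daptomycin 500 mg
#' was infused over 0.5 h once daily.
#'
#' @param start_time infusion start times, h since first-dose start (>= 0)
#' @param amount dose amounts, mg (> 0)
#' @param duration infusion durations, h (> 0)
#' @return data.frame of class `dose_events` with columns `start_time`,
#'   `amount`, `duration`
#' @export
dose_events <- function(start_time, amount, duration) {
  n <- max(length(start_time), length(amount), length(duration))
  d <- data.frame(start_time = rep_len(start_time, n),
                  amount = rep_len(amount, n),
                  duration = rep_len(duration, n))
  if (any(!is.finite(unlist(d)))) stop("dose_events: non-finite input")
  if (any(d$start_time < 0)) stop("dose_events: start_time must be >= 0")
  if (any(d$amount <= 0)) stop("dose_events: amount must be > 0")
  if (any(d$duration <= 0)) stop("dose_events: duration must be > 0")
  class(d) <- c("dose_events", "data.frame")
  d
}

#' Multiple-dose regimen
#'
#' @param dose dose per administration, mg
#' @param interval dosing interval tau, h (must exceed `duration`)
#' @param duration infusion duration, h
#' @param n_doses number of doses (ignored when `steady_state = TRUE`)
#' @param steady_state logical; if `TRUE` the regimen denotes the
#'   steady-state condition of indefinite repeated dosing
#' @return object of class `pk_regimen`
#' @export
pk_regimen <- function(dose, interval = 24, duration = 0.5, n_doses = 7,
                       steady_state = FALSE) {
  if (!(interval > duration && duration > 0)) {
    stop("pk_regimen: need interval > duration > 0")
  }
  if (dose <= 0) stop("pk_regimen: dose must be > 0")
  structure(list(dose = dose, interval = interval, duration = duration,
                 n_doses = n_doses, steady_state = steady_state),
            class = "pk_regimen")
}

#' Expand a regimen into explicit dose events
#' @param regimen a [pk_regimen()]
#' @return a [dose_events()] table
#' @export
regimen_doses <- function(regimen) {
  stopifnot(inherits(regimen, "pk_regimen"))
  dose_events(start_time = (seq_len(regimen$n_doses) - 1) * regimen$interval,
              amount = regimen$dose, duration = regimen$duration)
}

#' Central concentration under multi-dose zero-order infusion
#'
#' Closed-form solution of the two-compartment disposition model with
#' zero-order input, superposed over all dose events (linear kinetics).
#' Both the during-infusion and post-infusion branches are exact; the
#' infusion is never approximated by a bolus.
#'
#' @param t times, h since first-dose start (>= 0); vectorized
#' @param pk a [pk_params()] object
#' @param doses a [dose_events()] table (non-empty)
#' @return central-compartment concentrations, mg/L
#' @export
pk_concentration <- function(t, pk, doses) {
  stopifnot(inherits(pk, "pk_params"))
  doses <- as_dose_events(doses)
  if (nrow(doses) == 0L) stop("pk_concentration: doses must be non-empty")
  if (any(t < 0)) stop("pk_concentration: t must be >= 0")
  cpp_conc2(as.numeric(t), doses$start_time, doses$amount, doses$duration,
            pk$CL, pk$VC, pk$VP, pk$Q)
}

as_dose_events <- function(doses) {
  if (inherits(doses, "pk_regimen")) return(regimen_doses(doses))
  if (!inherits(doses, "dose_events")) {
    doses <- dose_events(doses$start_time, doses$amount, doses$duration)
  }
  doses
}

#' Interval area under the concentration-time curve
#'
#' Exact closed-form integral of [pk_concentration()] over `[t0, t1]`,
#' obtained from the per-exponential-term antiderivatives; `t1 = Inf` is
#' allowed and satisfies `CL * AUC(0, Inf) = total dose`.
#'
#' @param pk a [pk_params()] object
#' @param doses a [dose_events()] table
#' @param t0,t1 integration limits, h, with `0 <= t0 < t1 <= Inf`
#' @return AUC, mg*h/L
#' @export
auc_interval <- function(pk, doses, t0, t1) {
  stopifnot(inherits(pk, "pk_params"))
  doses <- as_dose_events(doses)
  if (!(t0 >= 0 && t0 < t1)) stop("auc_interval: need 0 <= t0 < t1")
  cpp_auc2(doses$start_time, doses$amount, doses$duration,
           pk$CL, pk$VC, pk$VP, pk$Q, t0, t1)
}

#' Steady-state exposure metrics for a repeated infusion regimen
#'
#' Geometric-series accumulation of the closed-form solution gives the
#' steady-state interval AUC (`= dose/CL` exactly for linear kinetics),
#' the trough just before the next dose (`cmin_ss`) and the end-of-infusion
#' peak (`cmax_ss`).
#'
#' @param pk a [pk_params()] object
#' @param regimen a [pk_regimen()]
#' @return list with `auc_ss` (mg*h/L), `cmin_ss`, `cmax_ss` (mg/L)
#' @export
steady_state_metrics <- function(pk, regimen) {
  stopifnot(inherits(pk, "pk_params"), inherits(regimen, "pk_regimen"))
  mco <- cpp_macro_coefs(pk$CL, pk$VC, pk$VP, pk$Q)
  lam <- mco[c("alpha", "beta")]
  cc <- mco[c("c1", "c2")]
  tau <- regimen$interval
  tinf <- regimen$duration
  rate <- regimen$dose / tinf
  # steady-state amplitude of each exponential term at end of infusion,
  # accumulated over all previous doses
  amp <- ifelse(cc == 0, 0,
                rate * cc / lam * (1 - exp(-lam * tinf)) / (1 - exp(-lam * tau)))
  cmax <- sum(amp)
  cmin <- sum(amp * exp(-lam * (tau - tinf)))
  list(auc_ss = regimen$dose / pk$CL, cmin_ss = cmin, cmax_ss = cmax)
}
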