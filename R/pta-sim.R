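## Monte Carlo dosing simulations: probability of target attainment
## (AUC24/MIC >= 666 at MIC 1 mg/L) and safety-threshold fractions
## (AUC24/MIC >= 1422; steady-state trough >= 24.3 mg/L) over the
## dose x renal-function grid.

#' Renal function group for dose simulations
#'
#' Either a fixed creatinine clearance (20/30/40/60/90/120 mL/min in the
#' study grid) without CRRT, or the CRRT group.
#'
#' @param ccr creatinine clearance, mL/min (ignored when `crrt = TRUE`)
#' @param crrt logical
#' @return object of class `renal_group`
#' @export
renal_group <- function(ccr = NULL, crrt = FALSE) {
  if (crrt) {
    if (!is.null(ccr)) stop("renal_group: give either ccr or crrt = TRUE")
    return(structure(list(label = "CRRT", ccr = NA_real_, crrt = TRUE),
                     class = "renal_group"))
  }
  stopifnot(is.numeric(ccr), ccr > 0)
  structure(list(label = sprintf("CCR%g", ccr), ccr = ccr, crrt = FALSE),
            class = "renal_group")
}

#' Standard simulation groups of the study
#' @return list of [renal_group()]s: CCR 20, 30, 40, 60, 90, 120 and CRRT
#' @export
standard_groups <- function() {
  c(lapply(c(20, 30, 40, 60, 90, 120), renal_group), list(renal_group(crrt = TRUE)))
}

#' PTA simulation configuration
#'
#' @param n_subjects virtual subjects per group (1000 in the study)
#' @param mic minimal inhibitory concentration, mg/L (1 in the study)
#' @param target efficacy target on AUC24/MIC (>= 666)
#' @param auc_safety upper safety bound on AUC24/MIC (1422)
#' @param cmin_safety steady-state trough safety bound, mg/L (24.3)
#' @param auc_def AUC24 definition: `"steady_state"` (dose/CL, exact for
#'   linear kinetics), `"day1"` (integral over the first 24 h) or
#'   `"interval_k"` (the `k`-th dosing interval)
#' @param k interval index for `auc_def = "interval_k"`
#' @param residual add residual error to the exposure metric (off by
#'   default: exposures are model-predicted, not measured)
#' @return list of class `pta_config`
#' @export
pta_config <- function(n_subjects = 1000, mic = 1, target = 666,
                       auc_safety = 1422, cmin_safety = 24.3,
                       auc_def = c("steady_state", "day1", "interval_k"),
                       k = 2, residual = FALSE) {
  auc_def <- match.arg(auc_def)
  stopifnot(n_subjects >= 1, mic > 0)
  structure(list(n_subjects = n_subjects, mic = mic, target = target,
                 auc_safety = auc_safety, cmin_safety = cmin_safety,
                 auc_def = auc_def, k = k, residual = residual),
            class = "pta_config")
}

group_covs <- function(group) {
  data.frame(CRRT = group$crrt, CCR = if (group$crrt) NA_real_ else group$ccr)
}

#' Monte Carlo simulation of one dose x renal-function cell
#'
#' Draws `n_subjects` eta vectors from the model's IIV distribution
#' (covariates fixed at the group's nominal renal function), computes each
#' subject's AUC24 under the configured definition plus the steady-state
#' trough, and summarizes target attainment and safety fractions.
#'
#' @param model a [pop_model()]
#' @param regimen a [pk_regimen()]
#' @param group a [renal_group()]
#' @param cfg a [pta_config()]
#' @param seed integer seed
#' @return one-row data.frame: `group`, `dose`, `median_auc24` (mg*h/L),
#'   `pta_pct`, `pta_mcse_pct` (Monte-Carlo standard error),
#'   `auc_safety_pct` (fraction at or above the AUC safety bound),
#'   `cmin_safety_pct` (fraction at or above the trough bound)
#' @export
simulate_group <- function(model, regimen, group, cfg = pta_config(), seed = 1) {
  set.seed(seed)
  covs <- group_covs(group)
  tv <- typical_params(model, covs)
  n <- cfg$n_subjects
  etas <- draw_etas(model$omega, n)
  iiv <- model$spec$iiv
  fac <- function(p) if (p %in% iiv) exp(etas[, p]) else rep(1, n)
  cl <- tv[1, "CL"] * fac("CL")
  vc <- tv[1, "VC"] * fac("VC")
  vp <- tv[1, "VP"] * fac("VP")
  qq <- rep(tv[1, "Q"], n)
  auc <- switch(cfg$auc_def,
                steady_state = regimen$dose / cl,
                day1 = , interval_k = {
                  t0 <- if (cfg$auc_def == "day1") 0 else (cfg$k - 1) * regimen$interval
                  nd <- max(regimen$n_doses, if (cfg$auc_def == "day1") 1 else cfg$k)
                  doses <- dose_events((seq_len(nd) - 1) * regimen$interval,
                                       regimen$dose, regimen$duration)
                  vapply(seq_len(n), function(i)
                    cpp_auc2(doses$start_time, doses$amount, doses$duration,
                             cl[i], vc[i], vp[i], qq[i],
                             t0, t0 + regimen$interval),
                    numeric(1))
                })
  cmin <- vapply(seq_len(n), function(i) {
    steady_state_metrics(pk_params(cl[i], vc[i], max(vp[i], 1e-8), qq[i]),
                         regimen)$cmin_ss
  }, numeric(1))
  ratio <- auc / cfg$mic
  pta <- mean(ratio >= cfg$target)
  data.frame(group = group$label, dose = regimen$dose,
             median_auc24 = stats::median(auc),
             pta_pct = 100 * pta,
             pta_mcse_pct = 100 * sqrt(pta * (1 - pta) / n),
             auc_safety_pct = 100 * mean(ratio >= cfg$auc_safety),
             cmin_safety_pct = 100 * mean(cmin >= cfg$cmin_safety))
}

#' Closed-form PTA under the steady-state AUC definition
#'
#' With lognormal clearance variability only, `AUC24 = dose/CL` is
#' lognormal and
#' `PTA = Phi( log(dose / (target * MIC * TVCL)) / omega_CL )`.
#' Serves as the analytic oracle for [simulate_group()].
#'
#' @param tvcl typical clearance, L/h
#' @param dose daily dose, mg
#' @param cfg a [pta_config()] (steady-state definition)
#' @param omega_cl variance of the lognormal clearance effect
#' @return PTA as a fraction in `[0, 1]`
#' @export
pta_closed_form <- function(tvcl, dose, cfg = pta_config(), omega_cl = 0.091) {
  if (cfg$auc_def != "steady_state") {
    stop("pta_closed_form: only the steady_state definition has a closed form")
  }
  if (omega_cl == 0) {
    return(as.numeric(dose / (cfg$target * cfg$mic * tvcl) >= 1))
  }
  stats::pnorm(log(dose / (cfg$target * cfg$mic * tvcl)) / sqrt(omega_cl))
}

#' Full dose x renal-function PTA grid
#'
#' @param model a [pop_model()]
#' @param doses daily doses, mg (study grid: 400, 500, 600, 700)
#' @param groups list of [renal_group()]s (default [standard_groups()])
#' @param cfg a [pta_config()]
#' @param seed integer seed (each cell uses an independent substream)
#' @param interval,duration regimen interval and infusion duration, h
#' @return data.frame of class `pta_table`, one row per dose x group with
#'   the columns of [simulate_group()]
#' @export
pta_grid <- function(model, doses = c(400, 500, 600, 700),
                     groups = standard_groups(), cfg = pta_config(),
                     seed = 1, interval = 24, duration = 0.5) {
  rows <- list()
  cell <- 0L
  for (d in doses) {
    for (g in groups) {
      cell <- cell + 1L
      rows[[cell]] <- simulate_group(model, pk_regimen(d, interval, duration),
                                     g, cfg, seed = seed + cell)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pta_table", "data.frame")
  out
}

#' Reshape a PTA grid into the study's wide table layout
#'
#' Rows: metric x dose; columns: the renal-function groups.
#'
#' @param grid a `pta_table` from [pta_grid()]
#' @param metric `"median_auc24"` or `"pta_pct"`
#' @return wide-format data.frame
#' @export
pta_wide <- function(grid, metric = c("median_auc24", "pta_pct")) {
  metric <- match.arg(metric)
  groups <- unique(grid$group)
  doses <- sort(unique(grid$dose))
  out <- data.frame(metric = metric, dose = doses)
  for (g in groups) {
    out[[g]] <- vapply(doses, function(d)
      grid[[metric]][grid$dose == d & grid$group == g][1], numeric(1))
  }
  out
}
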