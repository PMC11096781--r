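## Synthetic ICU cohort generator: covariate distributions, dosing and the
## days-1/3/5/7 sampling design of the daptomycin study, so every pipeline
## stage can be exercised on data whose generating truth is known.

#' Cockcroft-Gault creatinine clearance
#'
#' `CCR = (140 - age) * weight / (72 * SCr[mg/dL])`, times 0.85 for
#' females; serum creatinine is supplied in umol/L and converted internally
#' (1 mg/dL = 88.4 umol/L).
#'
#' @param age years (must be < 140)
#' @param weight kg
#' @param scr serum creatinine, umol/L
#' @param sex "male"/"female" (or 1 = male, 0 = female)
#' @return creatinine clearance, mL/min
#' @examples
#' cockcroft_gault(40, 70, 88.4, "male") # 97.22
#' @export
cockcroft_gault <- function(age, weight, scr, sex) {
  if (any(age <= 0 | weight <= 0 | scr <= 0)) {
    stop("cockcroft_gault: inputs must be positive")
  }
  if (any(age >= 140)) stop("cockcroft_gault: age must be < 140")
  male <- if (is.character(sex) || is.factor(sex)) {
    as.character(sex) == "male"
  } else {
    as.numeric(sex) == 1
  }
  ccr <- (140 - age) * weight / (72 * scr / 88.4)
  ifelse(male, ccr, 0.85 * ccr)
}

#' Cohort configuration
#'
#' Defaults reproduce the study cohort: 64 ICU subjects, 39 on CRRT, 43
#' male; age 57.5 +/- 16.5 y; weight median 64.5 kg in 45-170; serum
#' creatinine median 106 umol/L in 21.7-845.4; derived creatinine clearance
#' clamped to 8.3-200.2 mL/min; 500 mg q24h 0.5-h infusions; LLOQ
#' 0.05 mg/L; observations thinned with retention 737/1472 so the expected
#' observation count matches the study's 737.
#'
#' The shape parameters of the lognormal weight and creatinine marginals
#' (`wt_sdlog`, `scr_sdlog`) are not reported by the study and are fixed
#' here by calibration to the printed medians/ranges.
#'
#' @param n_subjects cohort size
#' @param crrt_frac,male_frac fractions on CRRT / male (assigned as exact
#'   counts by random permutation)
#' @param age_mean,age_sd,age_range normal age distribution (truncated)
#' @param wt_median,wt_sdlog,wt_range lognormal weight (truncated)
#' @param scr_median,scr_sdlog,scr_range lognormal serum creatinine
#'   (truncated)
#' @param ccr_range clamp range for derived creatinine clearance
#' @param bmi_median,bmi_sdlog,bmi_range lognormal body-mass index
#' @param alb_mean,alb_sd,alb_range normal albumin
#' @param sofa_range,apache_range uniform integer severity scores
#' @param ecmo_frac fraction on ECMO
#' @param dose,interval,duration dosing regimen (mg, h, h)
#' @param lloq assay lower limit of quantification, mg/L
#' @param retention independent Bernoulli retention probability per nominal
#'   observation
#' @return list of class `cohort_config`
#' @export
cohort_config <- function(n_subjects = 64,
                          crrt_frac = 39 / 64, male_frac = 43 / 64,
                          age_mean = 57.5, age_sd = 16.5, age_range = c(18, 95),
                          wt_median = 64.5, wt_sdlog = 0.18, wt_range = c(45, 170),
                          scr_median = 106, scr_sdlog = 0.75,
                          scr_range = c(21.7, 845.4),
                          ccr_range = c(8.3, 200.2),
                          bmi_median = 23, bmi_sdlog = 0.15, bmi_range = c(16.5, 52.5),
                          alb_mean = 32.8, alb_sd = 5, alb_range = c(19.6, 46.8),
                          sofa_range = c(4, 19), apache_range = c(12, 47),
                          ecmo_frac = 6 / 64,
                          dose = 500, interval = 24, duration = 0.5,
                          lloq = DAPTO_LLOQ, retention = 737 / 1472) {
  stopifnot(crrt_frac >= 0, crrt_frac <= 1, male_frac >= 0, male_frac <= 1,
            retention > 0, retention <= 1, n_subjects >= 1)
  structure(as.list(environment()), class = "cohort_config")
}

# inverse-CDF truncated draws (exact, one uniform per draw)
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

rtrunc_lnorm <- function(n, meanlog, sdlog, lo, hi) {
  u <- stats::runif(n, stats::plnorm(lo, meanlog, sdlog),
                    stats::plnorm(hi, meanlog, sdlog))
  stats::qlnorm(u, meanlog, sdlog)
}

#' Draw a table of subject covariates
#'
#' Marginals are independent except creatinine clearance, which is computed
#' deterministically from age/weight/creatinine/sex via [cockcroft_gault()]
#' and clamped to the configured range. CRRT and sex are assigned as exact
#' counts by random permutation.
#'
#' @param config a [cohort_config()]
#' @param n number of subjects (defaults to `config$n_subjects`)
#' @param seed optional integer seed (`NULL` uses the ambient RNG stream)
#' @return data.frame with columns `ID`, `AGE`, `SEX` (1 = male), `WT`,
#'   `BMI`, `SCR`, `CCR`, `ALB`, `SOFA`, `APACHE`, `CRRT`, `ECMO`
#' @export
sample_covariates <- function(config = cohort_config(),
                              n = config$n_subjects, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cf <- config
  exact_flags <- function(frac) {
    k <- round(frac * n)
    sample(c(rep(1L, k), rep(0L, n - k)))
  }
  sex <- exact_flags(cf$male_frac)
  crrt <- exact_flags(cf$crrt_frac)
  ecmo <- exact_flags(cf$ecmo_frac)
  age <- rtrunc_norm(n, cf$age_mean, cf$age_sd, cf$age_range[1], cf$age_range[2])
  wt <- rtrunc_lnorm(n, log(cf$wt_median), cf$wt_sdlog,
                     cf$wt_range[1], cf$wt_range[2])
  scr <- rtrunc_lnorm(n, log(cf$scr_median), cf$scr_sdlog,
                      cf$scr_range[1], cf$scr_range[2])
  bmi <- rtrunc_lnorm(n, log(cf$bmi_median), cf$bmi_sdlog,
                      cf$bmi_range[1], cf$bmi_range[2])
  alb <- rtrunc_norm(n, cf$alb_mean, cf$alb_sd, cf$alb_range[1], cf$alb_range[2])
  sofa <- sample(cf$sofa_range[1]:cf$sofa_range[2], n, replace = TRUE)
  apache <- sample(cf$apache_range[1]:cf$apache_range[2], n, replace = TRUE)
  ccr <- cockcroft_gault(age, wt, scr, sex)
  ccr <- pmin(pmax(ccr, cf$ccr_range[1]), cf$ccr_range[2])
  data.frame(ID = seq_len(n), AGE = age, SEX = sex, WT = wt, BMI = bmi,
             SCR = scr, CCR = ccr, ALB = alb, SOFA = sofa, APACHE = apache,
             CRRT = crrt, ECMO = ecmo)
}

#' The study's nominal sampling schedule
#'
#' Day 1: samples at 0, 0.5, 1, 2, 4, 8, 12 and 24 h after the end of the
#' infusion ("after infusion" interpreted as end-of-infusion; a sample at
#' infusion start would be pre-dose, which day 3 lists separately). Day 3:
#' a pre-dose sample plus the same eight offsets. Days 5 and 7: pre-dose
#' plus 0.5 and 4 h after infusion. 23 nominal samples per complete
#' subject.
#'
#' @return list with components `day1`, `day3`, `day5`, `day7` (offsets in
#'   h after end of infusion; `pre` marks a pre-dose sample)
#' @export
sampling_schedule <- function() {
  post <- c(0, 0.5, 1, 2, 4, 8, 12, 24)
  list(day1 = list(pre = FALSE, post = post),
       day3 = list(pre = TRUE, post = post),
       day5 = list(pre = TRUE, post = c(0.5, 4)),
       day7 = list(pre = TRUE, post = c(0.5, 4)))
}

#' Dose events and nominal sample times for one subject
#'
#' q24h dose events on days 1-7 plus the 23 nominal observation times of
#' [sampling_schedule()], in absolute hours since the first infusion start.
#'
#' @param schedule a [sampling_schedule()]
#' @param regimen a [pk_regimen()] (500 mg q24h over 0.5 h by default)
#' @return list with `doses` (a [dose_events()] table) and `times`
#'   (sorted nominal observation hours)
#' @export
build_design <- function(schedule = sampling_schedule(),
                         regimen = pk_regimen(500, 24, 0.5, n_doses = 7)) {
  doses <- regimen_doses(regimen)
  day_no <- as.integer(sub("day", "", names(schedule)))
  times <- unlist(lapply(seq_along(schedule), function(i) {
    start <- (day_no[i] - 1) * regimen$interval
    eoi <- start + regimen$duration
    c(if (schedule[[i]]$pre) start, eoi + schedule[[i]]$post)
  }))
  list(doses = doses, times = sort(unname(times)))
}

#' Generate a complete synthetic study dataset
#'
#' Full pipeline: [sample_covariates()] then [build_design()] then
#' [simulate_observations()] per subject, then independent Bernoulli
#' thinning of observation rows at the configured retention probability
#' (737/1472 by default, calibrating the expected observation count to the
#' study's 737). The generating truth (per-subject etas and individual
#' parameters) is attached as `attr(x, "truth")` for recovery tests.
#'
#' @param config a [cohort_config()]
#' @param model a [pop_model()] (defaults to the final published model)
#' @param seed integer seed (required: the generator is fully deterministic
#'   given the seed)
#' @return a `study_dataset` data.frame in NONMEM-style long format (see
#'   [read_dataset()] for the column contract)
#' @export
generate_dataset <- function(config = cohort_config(), model = pop_model(),
                             seed) {
  if (missing(seed)) stop("generate_dataset: an explicit seed is required")
  set.seed(seed)
  covs <- sample_covariates(config)
  design <- build_design(regimen = pk_regimen(config$dose, config$interval,
                                              config$duration, n_doses = 7))
  n <- nrow(covs)
  rows <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    sim <- simulate_observations(model, covs[i, ], design$doses, design$times,
                                 lloq = config$lloq)
    keep <- stats::runif(nrow(sim)) <= config$retention
    sim <- sim[keep, , drop = FALSE]
    dose_rows <- data.frame(ID = covs$ID[i], TIME = design$doses$start_time,
                            EVID = 1L, AMT = design$doses$amount,
                            RATE = design$doses$amount / design$doses$duration,
                            DV = NA_real_, MDV = 1L, BLQ = 0L)
    obs_rows <- data.frame(ID = covs$ID[i], TIME = sim$time, EVID = 0L,
                           AMT = NA_real_, RATE = NA_real_,
                           DV = sim$dv, MDV = as.integer(sim$blq),
                           BLQ = as.integer(sim$blq))
    sub <- rbind(dose_rows, obs_rows)
    sub <- sub[order(sub$TIME, sub$EVID), , drop = FALSE] # pre-dose obs precede the dose
    rows[[i]] <- cbind(sub, covs[rep(i, nrow(sub)),
                                 setdiff(names(covs), "ID"), drop = FALSE])
    eta <- attr(sim, "eta")
    pk <- attr(sim, "pk")
    tr <- data.frame(ID = covs$ID[i])
    for (nm in names(eta)) tr[[paste0("eta_", nm)]] <- unname(eta[[nm]])
    tr$CL <- unname(pk$CL); tr$VC <- unname(pk$VC)
    tr$VP <- unname(pk$VP); tr$Q <- unname(pk$Q)
    truth[[i]] <- tr
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  attr(out, "truth") <- truth
  class(out) <- c("study_dataset", "data.frame")
  out
}
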