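## Nonlinear mixed-effects estimation: FOCE-I / Laplace objective, outer
## maximum-likelihood fit, information criteria, shrinkage, structural and
## covariate model comparison, subject-resampling bootstrap.
##
## Objective convention: the OFV is the full -2 log (approximate) marginal
## likelihood, including all 2*pi constants (NONMEM's OFV omits
## n_obs*log(2*pi); the AIC/BIC identities are unaffected because the
## constant is model-independent for a fixed dataset).

# -- dataset -> per-subject computational pack -------------------------------

pack_subjects <- function(dataset) {
  stopifnot(is.data.frame(dataset))
  ids <- unique(dataset$ID)
  subjects <- vector("list", length(ids))
  covcols <- intersect(c("AGE", "SEX", "WT", "BMI", "SCR", "CCR", "ALB",
                         "SOFA", "APACHE", "CRRT", "ECMO"), names(dataset))
  covs <- dataset[match(ids, dataset$ID), covcols, drop = FALSE]
  covs$CRRT <- as.logical(covs$CRRT)
  rownames(covs) <- NULL
  for (i in seq_along(ids)) {
    d <- dataset[dataset$ID == ids[i], , drop = FALSE]
    dose <- d[d$EVID == 1, , drop = FALSE]
    obs <- d[d$EVID == 0 & d$MDV == 0, , drop = FALSE]
    if (nrow(dose) == 0L) stop("subject ", ids[i], " has no dose rows")
    subjects[[i]] <- list(t = as.numeric(obs$TIME), y = as.numeric(obs$DV),
                          dstart = as.numeric(dose$TIME),
                          damt = as.numeric(dose$AMT),
                          ddur = as.numeric(dose$AMT / dose$RATE))
  }
  list(subjects = subjects, covs = covs, ids = ids,
       n_obs = sum(vapply(subjects, function(s) length(s$t), integer(1))))
}

eta_index_for <- function(spec) {
  # structural param (CL, VC, VP, Q) -> 0-based position in the eta vector
  m <- match(c("CL", "VC", "VP", "Q"), spec$iiv) - 1L
  m[is.na(m)] <- -1L
  as.integer(m)
}

# -- parameter vector layout -------------------------------------------------

par_layout <- function(model) {
  spec <- model$spec
  thn <- theta_names(spec)
  trans <- ifelse(grepl("^beta_", thn), "id", "log")
  # categorical multiplicative factors are positive -> log scale
  for (e in spec$effects) {
    if (e$form == "catmult") trans[thn == effect_theta_name(e)] <- "log"
  }
  omn <- paste0("omega_", spec$iiv)
  sgn <- switch(spec$error,
                combined = c("sigma_prop", "sigma_add"),
                additive = "sigma_add",
                proportional = "sigma_prop")
  list(names = c(thn, omn, sgn),
       trans = c(trans, rep("log", length(omn) + length(sgn))),
       n_theta = length(thn), theta_names = thn,
       omega_names = omn, sigma_names = sgn)
}

encode_pars <- function(model, layout) {
  x <- numeric(length(layout$names))
  th <- model$theta[layout$theta_names]
  om <- diag(model$omega)
  sg <- model$sigma
  raw <- c(th, om,
           if ("sigma_prop" %in% layout$sigma_names) sg[["prop"]],
           if ("sigma_add" %in% layout$sigma_names) sg[["add"]])
  ifelse(layout$trans == "log", log(pmax(raw, 1e-12)), raw)
}

decode_pars <- function(x, model, layout) {
  raw <- ifelse(layout$trans == "log", exp(x), x)
  names(raw) <- layout$names
  th <- raw[seq_len(layout$n_theta)]
  names(th) <- layout$theta_names
  d <- length(layout$omega_names)
  om <- model$omega
  diag(om) <- raw[layout$omega_names]
  sg <- c(prop = 0, add = 0)
  if ("sigma_prop" %in% layout$sigma_names) sg["prop"] <- raw[["sigma_prop"]]
  if ("sigma_add" %in% layout$sigma_names) sg["add"] <- raw[["sigma_add"]]
  m <- model
  m$theta <- th
  m$omega <- om
  m$sigma <- sg
  m
}

# -- FOCE-I / Laplace objective ----------------------------------------------

#' FOCE-I / Laplace objective function value
#'
#' Computes the -2 log marginal likelihood of a population model for a
#' dataset by the Laplace approximation around each subject's empirical
#' Bayes mode, with the residual variance evaluated at the eta-conditional
#' prediction (the eta-eps interaction of FOCE-I). By default the Laplace
#' determinant uses a finite-difference hessian of the exact conditional
#' objective (`"numeric"`); the cheaper FOCE-I (Fisher/Gauss-Newton) hessian
#' is available with `hessian = "gn"`.
#'
#' The value includes all 2*pi normalization constants, i.e. it is a genuine
#' -2 log likelihood (NONMEM's OFV differs by the fixed constant
#' `n_obs * log(2*pi)`).
#'
#' @param dataset a study dataset (see [read_dataset()]); BLQ/MDV rows are
#'   excluded from the likelihood
#' @param model a [pop_model()]
#' @param hessian "numeric" (default) or "gn"
#' @param eta_init optional warm-start matrix of etas (subjects x etas)
#' @return list with `ofv`, `etas` (empirical Bayes modes), `ll`
#'   (per-subject -2 log likelihood), `converged` (per-subject inner flag),
#'   `n_obs`
#' @export
foce_ofv <- function(dataset, model, hessian = c("numeric", "gn"),
                     eta_init = NULL) {
  hessian <- match.arg(hessian)
  pack <- pack_subjects(dataset)
  foce_ofv_packed(pack, model, hessian, eta_init)
}

foce_ofv_packed <- function(pack, model, hessian = "numeric", eta_init = NULL) {
  spec <- model$spec
  tv <- typical_params(model, pack$covs)
  d <- length(spec$iiv)
  if (is.null(eta_init)) eta_init <- matrix(0, length(pack$subjects), d)
  om <- model$omega
  if (any(diag(om) <= 0)) stop("foce_ofv: singular Omega; drop zero-variance etas from the model")
  if (all(model$sigma == 0)) stop("foce_ofv: residual variances must not both be 0")
  res <- cpp_foce_ofv(pack$subjects, tv, eta_index_for(spec), om,
                      model$sigma[["prop"]], model$sigma[["add"]],
                      eta_init, if (hessian == "numeric") 1L else 0L,
                      100L, 1e-9)
  colnames(res$etas) <- spec$iiv
  res$n_obs <- pack$n_obs
  res
}

#' Empirical Bayes eta for one subject
#'
#' Mode of the conditional distribution of the subject's random effects:
#' minimizes `sum_j [(y_j - f_j(eta))^2/V_j(eta) + log V_j(eta)] +
#' eta' Omega^-1 eta` with `V_j` the residual variance at the
#' eta-conditional prediction.
#'
#' @param dataset a study dataset
#' @param model a [pop_model()]
#' @param id subject identifier (must have >= 1 usable observation)
#' @return list with `eta` (named), `converged`, `objective`
#' @export
map_eta <- function(dataset, model, id) {
  pack <- pack_subjects(dataset)
  i <- match(id, pack$ids)
  if (is.na(i)) stop("map_eta: no subject with ID ", id)
  if (length(pack$subjects[[i]]$t) == 0L) {
    stop("map_eta: subject ", id, " has no usable observations")
  }
  tv <- typical_params(model, pack$covs)
  d <- length(model$spec$iiv)
  res <- cpp_map_eta(pack$subjects[[i]], tv, i - 1L,
                     eta_index_for(model$spec), model$omega,
                     model$sigma[["prop"]], model$sigma[["add"]],
                     numeric(d), 100L, 1e-9)
  eta <- as.numeric(res$eta)
  names(eta) <- model$spec$iiv
  if (!res$converged) eta[] <- 0 # flagged fallback
  list(eta = eta, converged = res$converged, objective = res$g)
}

#' Information criteria from an objective function value
#'
#' `AIC = OFV + 2p`, `BIC = OFV + p log(n_obs)` with `p` counting every
#' estimated fixed effect and variance parameter.
#'
#' @param ofv objective function value (-2 log likelihood)
#' @param p number of estimated parameters (>= 0)
#' @param n_obs number of observations (needed for BIC)
#' @return list with `AIC` and `BIC`
#' @export
information_criteria <- function(ofv, p, n_obs = NULL) {
  stopifnot(p >= 0)
  list(AIC = ofv + 2 * p,
       BIC = if (is.null(n_obs)) NA_real_ else ofv + p * log(n_obs))
}

#' Eta shrinkage
#'
#' `100 * (1 - SD(eta_hat)/omega)` per random effect; near-100% shrinkage
#' means the data carry little subject-level information for that
#' parameter.
#'
#' @param etas matrix of empirical Bayes etas (subjects x effects)
#' @param omega IIV covariance matrix (or named vector of variances)
#' @return named vector of shrinkage percentages (NA where `omega` is 0)
#' @export
eta_shrinkage <- function(etas, omega) {
  w2 <- if (is.matrix(omega)) diag(omega) else omega
  if (nrow(etas) < 2L) stop("eta_shrinkage: need >= 2 subjects")
  sds <- apply(etas, 2, stats::sd)
  out <- 100 * (1 - sds / sqrt(w2))
  out[w2 == 0] <- NA_real_
  out
}

# -- outer maximum likelihood fit --------------------------------------------

#' Control settings for [fit_popmodel()]
#'
#' @param rel_tol relative convergence tolerance of the outer optimizer
#' @param max_iter outer iteration cap
#' @param hessian Laplace hessian flavor ("gn" = FOCE-I, "numeric")
#' @param se compute standard errors from a finite-difference hessian of
#'   the objective (adds ~2p^2 objective evaluations)
#' @param multi_start number of jittered restarts tried on non-convergence
#' @param bound_factor box bounds for positive parameters:
#'   `[init/bound_factor_lo, init*bound_factor_hi]` on the log scale
#' @param grad outer finite-difference gradient: "central" (accurate,
#'   2p evaluations) or "forward" (p evaluations; used for bulk refits such
#'   as bootstrap replicates)
#' @export
fit_control <- function(rel_tol = 1e-8, max_iter = 500,
                        hessian = "numeric", se = TRUE, multi_start = 3,
                        bound_factor = c(1e4, 1e3),
                        grad = c("central", "forward")) {
  grad <- match.arg(grad)
  list(rel_tol = rel_tol, max_iter = max_iter, hessian = hessian, se = se,
       multi_start = multi_start, bound_factor = bound_factor, grad = grad)
}

#' Fit a population model by FOCE-I / Laplace maximum likelihood
#'
#' Minimizes [foce_ofv()] over the fixed effects, IIV variances and residual
#' variances. Positive parameters are optimized on the log scale within box
#' bounds around the initial values; covariate-effect slopes are optimized
#' on the natural scale. On apparent non-convergence the fit is restarted
#' from jittered initials.
#'
#' @param dataset a study dataset
#' @param init a [pop_model()] holding initial values and the model
#'   structure to estimate
#' @param control a [fit_control()] list
#' @param quiet suppress progress messages
#' @return an object of class `pk_fit`: the fitted [pop_model()] in
#'   `$model`, plus `ofv`, `aic`, `bic`, `etas`, `shrinkage`, `se`, `rse`,
#'   `converged`, `n_obs`, `n_subjects`, `iterations`
#' @export
fit_popmodel <- function(dataset, init = pop_model(), control = fit_control(),
                         quiet = TRUE) {
  pack <- pack_subjects(dataset)
  fit_packed(pack, init, control, quiet)
}

fit_packed <- function(pack, init, control = fit_control(), quiet = TRUE,
                       x_start = NULL, eta_start = NULL) {
  layout <- par_layout(init)
  d <- length(init$spec$iiv)
  warm <- new.env(parent = emptyenv())
  warm$etas <- if (is.null(eta_start)) {
    matrix(0, length(pack$subjects), d)
  } else {
    eta_start
  }
  warm$last_x <- NULL
  warm$last_v <- NA_real_
  neval <- 0L
  obj <- function(x) {
    m <- decode_pars(x, init, layout)
    res <- try(foce_ofv_packed(pack, m, control$hessian, warm$etas),
               silent = TRUE)
    neval <<- neval + 1L
    if (inherits(res, "try-error") || !is.finite(res$ofv)) return(1e10)
    warm$etas <- res$etas
    warm$last_x <- x
    warm$last_v <- res$ofv
    res$ofv
  }
  grad <- function(x) {
    g <- numeric(length(x))
    h <- 1e-5 * pmax(1, abs(x))
    if (control$grad == "forward") {
      f0 <- if (!is.null(warm$last_x) && identical(warm$last_x, x)) {
        warm$last_v
      } else {
        obj(x)
      }
      for (i in seq_along(x)) {
        xp <- x; xp[i] <- x[i] + h[i]
        g[i] <- (obj(xp) - f0) / h[i]
      }
    } else {
      for (i in seq_along(x)) {
        xp <- x; xp[i] <- x[i] + h[i]
        xm <- x; xm[i] <- x[i] - h[i]
        g[i] <- (obj(xp) - obj(xm)) / (2 * h[i])
      }
    }
    g
  }
  x0 <- if (is.null(x_start)) encode_pars(init, layout) else x_start
  lower <- ifelse(layout$trans == "log", x0 - log(control$bound_factor[1]), -20)
  upper <- ifelse(layout$trans == "log", x0 + log(control$bound_factor[2]), 20)
  run1 <- function(x0i) {
    stats::nlminb(x0i, obj, gradient = grad, lower = lower, upper = upper,
                  control = list(rel.tol = control$rel_tol,
                                 iter.max = control$max_iter,
                                 eval.max = 4 * control$max_iter))
  }
  opt <- run1(x0)
  tries <- 1L
  while ((opt$convergence != 0 && !grepl("relative convergence|X-convergence|both X.*relative",
                                         opt$message %||% "")) &&
         tries < control$multi_start) {
    jit <- x0 + stats::rnorm(length(x0), 0, 0.2)
    jit <- pmin(pmax(jit, lower), upper)
    opt2 <- run1(jit)
    if (is.finite(opt2$objective) && opt2$objective < opt$objective) opt <- opt2
    tries <- tries + 1L
  }
  model_hat <- decode_pars(opt$par, init, layout)
  final <- foce_ofv_packed(pack, model_hat, control$hessian, warm$etas)
  p <- length(opt$par)
  ic <- information_criteria(final$ofv, p, pack$n_obs)
  se <- rse <- NULL
  if (isTRUE(control$se)) {
    H <- fd_hessian(obj, opt$par)
    covx <- try(2 * solve(H), silent = TRUE) # OFV = -2logL -> cov = 2 H^-1
    if (!inherits(covx, "try-error") && all(is.finite(covx))) {
      vx <- diag(covx)
      vx[vx < 0] <- NA_real_
      se_x <- sqrt(vx)
      est_raw <- ifelse(layout$trans == "log", exp(opt$par), opt$par)
      se <- ifelse(layout$trans == "log", se_x * est_raw, se_x)
      rse <- 100 * se / abs(est_raw)
      names(se) <- names(rse) <- layout$names
    }
  }
  estimates <- ifelse(layout$trans == "log", exp(opt$par), opt$par)
  names(estimates) <- layout$names
  structure(list(model = model_hat, estimates = estimates, ofv = final$ofv,
                 aic = ic$AIC, bic = ic$BIC, p = p, n_obs = pack$n_obs,
                 n_subjects = length(pack$subjects),
                 etas = final$etas,
                 shrinkage = eta_shrinkage(final$etas, model_hat$omega),
                 se = se, rse = rse,
                 converged = opt$convergence == 0 ||
                   grepl("relative convergence|X-convergence", opt$message %||% ""),
                 message = opt$message, iterations = opt$iterations,
                 n_eval = neval, layout = layout, pack = pack,
                 control = control),
            class = "pk_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fd_hessian <- function(f, x, h = NULL) {
  p <- length(x)
  if (is.null(h)) h <- 1e-4 * pmax(1, abs(x))
  H <- matrix(0, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    xp <- x; xp[i] <- x[i] + h[i]
    xm <- x; xm[i] <- x[i] - h[i]
    H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / h[i]^2
    for (j in seq_len(i - 1L)) {
      xpp <- x; xpp[i] <- x[i] + h[i]; xpp[j] <- x[j] + h[j]
      xpm <- x; xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
      xmp <- x; xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
      xmm <- x; xmm[i] <- x[i] - h[i]; xmm[j] <- x[j] - h[j]
      H[i, j] <- H[j, i] <-
        (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[i] * h[j])
    }
  }
  H
}

#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf("FOCE-I/Laplace fit: %d subjects, %d observations\n",
              x$n_subjects, x$n_obs))
  cat(sprintf("OFV = %.3f, AIC = %.3f, BIC = %.3f (p = %d)%s\n",
              x$ofv, x$aic, x$bic, x$p,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  tab <- data.frame(estimate = signif(x$estimates, 4))
  if (!is.null(x$rse)) tab$rse_pct <- signif(x$rse, 3)
  print(tab)
  cat("shrinkage %:", paste(sprintf("%s %.1f", names(x$shrinkage), x$shrinkage),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Parameter table of a fit, Table-2 style
#'
#' @param fit a `pk_fit`
#' @param boot optional `pk_boot` result to append bootstrap medians/CIs
#' @return data.frame with estimate, RSE%, shrinkage% (and bootstrap
#'   columns when given)
#' @export
fit_parameter_table <- function(fit, boot = NULL) {
  nm <- names(fit$estimates)
  shr <- rep(NA_real_, length(nm))
  onm <- paste0("omega_", names(fit$shrinkage))
  shr[match(onm, nm)] <- fit$shrinkage
  tab <- data.frame(parameter = nm, estimate = unname(fit$estimates),
                    rse_pct = if (is.null(fit$rse)) NA_real_ else unname(fit$rse),
                    shrinkage_pct = shr)
  if (!is.null(boot)) {
    i <- match(nm, rownames(boot$summary))
    tab$boot_median <- boot$summary[i, "median"]
    tab$boot_lo <- boot$summary[i, "lo"]
    tab$boot_hi <- boot$summary[i, "hi"]
  }
  tab
}

# -- structural model comparison ---------------------------------------------

#' Compare one- and two-compartment structural models
#'
#' Fits both structures to the same dataset (same covariate structure on
#' clearance) and selects by AIC.
#'
#' @param dataset a study dataset
#' @param init2 initial [pop_model()] for the two-compartment fit
#' @param init1 initial [pop_model()] for the one-compartment fit (defaults
#'   to the two-compartment initials with the peripheral compartment
#'   removed)
#' @param control a [fit_control()]
#' @return list with `fit1`, `fit2`, `delta_ofv` (OFV1 - OFV2),
#'   `delta_aic` (AIC2 - AIC1) and `choice`
#' @export
compare_structural <- function(dataset, init2 = pop_model(), init1 = NULL,
                               control = fit_control(se = FALSE)) {
  if (is.null(init1)) {
    sp2 <- init2$spec
    sp1 <- pk_model_spec(n_cmt = 1, crrt_cl = sp2$crrt_cl,
                         ccr_on_cl = sp2$ccr_on_cl, ccr_ref = sp2$ccr_ref,
                         error = sp2$error)
    th <- init2$theta[intersect(theta_names(sp1), names(init2$theta))]
    om <- diag(init2$omega)[sp1$iiv]
    init1 <- pop_model(theta = th, omega = om, sigma = init2$sigma, spec = sp1)
  }
  fit2 <- fit_popmodel(dataset, init2, control)
  fit1 <- fit_popmodel(dataset, init1, control)
  if (!fit1$converged || !fit2$converged) {
    warning("compare_structural: at least one fit did not converge")
  }
  list(fit1 = fit1, fit2 = fit2,
       delta_ofv = fit1$ofv - fit2$ofv,
       delta_aic = fit2$aic - fit1$aic,
       choice = if (fit2$aic < fit1$aic) "two-compartment" else "one-compartment")
}

# -- stepwise covariate selection --------------------------------------------

#' Default covariate candidate set
#'
#' Candidates screened on clearance: BMI, WT, AGE, SEX, CCR, ALB, SOFA,
#' APACHE; on central and peripheral volume: WT and SEX.
#' @return list of `list(param, cov)` entries
#' @export
default_candidates <- function() {
  cl <- lapply(c("BMI", "WT", "AGE", "SEX", "CCR", "ALB", "SOFA", "APACHE"),
               function(cv) list(param = "CL", cov = cv))
  v <- unlist(lapply(c("VC", "VP"), function(p) {
    lapply(c("WT", "SEX"), function(cv) list(param = p, cov = cv))
  }), recursive = FALSE)
  c(cl, v)
}

candidate_label <- function(cand) paste(cand$param, cand$cov, sep = "~")

# build the model spec + initial model with a candidate added
add_candidate <- function(model, cand, covs) {
  spec <- model$spec
  th <- model$theta
  if (cand$param == "CL" && cand$cov == "CCR") {
    if (spec$ccr_on_cl) return(NULL) # already present
    spec$ccr_on_cl <- TRUE
    base <- if ("CL" %in% names(th)) th[["CL"]] else 0.3
    th <- th[setdiff(names(th), "CL")]
    th <- c(NR = unname(base) * 0.6, R = unname(base) * 0.4, th)
  } else {
    form <- if (cand$cov == "SEX") "catmult" else
      if (cand$param == "CL") "additive" else "linfac"
    ref <- if (form == "catmult") 1 else stats::median(covs[[cand$cov]], na.rm = TRUE)
    e <- list(param = cand$param, cov = cand$cov, form = form, ref = ref)
    if (any(vapply(spec$effects, function(x)
      x$param == e$param && x$cov == e$cov, logical(1)))) return(NULL)
    spec$effects <- c(spec$effects, list(e))
    init_val <- if (form == "catmult") 1 else if (form == "additive") 0.01 else 0.01
    th <- c(th, stats::setNames(init_val, effect_theta_name(e)))
  }
  pop_model(theta = th, omega = model$omega, sigma = model$sigma, spec = spec)
}

drop_candidate <- function(model, cand) {
  spec <- model$spec
  th <- model$theta
  if (cand$param == "CL" && cand$cov == "CCR") {
    spec$ccr_on_cl <- FALSE
    base <- unname(th[["NR"]] + th[["R"]])
    th <- th[setdiff(names(th), c("NR", "R"))]
    th <- c(CL = base, th)
  } else {
    lab <- paste("beta", cand$param, cand$cov, sep = "_")
    keep <- !vapply(spec$effects, function(x)
      x$param == cand$param && x$cov == cand$cov, logical(1))
    spec$effects <- spec$effects[keep]
    th <- th[setdiff(names(th), lab)]
  }
  pop_model(theta = th, omega = model$omega, sigma = model$sigma, spec = spec)
}

#' Stepwise covariate selection (forward inclusion / backward elimination)
#'
#' Greedy forward phase: in each round every remaining candidate is added
#' to the current model and refitted; the candidate with the largest OFV
#' drop is accepted while `dOFV > 3.84` (chi-square 1 df, alpha 0.05; ties
#' broken by fewest added parameters, then declaration order). Backward
#' phase: an included covariate is removed when its removal raises the OFV
#' by less than 6.635 (alpha 0.01).
#'
#' @param dataset a study dataset
#' @param candidates list of `list(param, cov)` candidates
#'   (default [default_candidates()])
#' @param base initial [pop_model()] of the covariate-free base structure
#'   (CRRT switch retained as a structural feature)
#' @param control a [fit_control()]
#' @param forward_cut,backward_cut OFV-change thresholds (3.84 / 6.635)
#' @return list with `final` (fitted `pk_fit`), `selected` (labels),
#'   `trace` (data.frame of every step)
#' @export
stepwise_covariates <- function(dataset, candidates = default_candidates(),
                                base = NULL,
                                control = fit_control(se = FALSE),
                                forward_cut = 3.84, backward_cut = 6.635) {
  pack <- pack_subjects(dataset)
  if (is.null(base)) {
    spec0 <- pk_model_spec(ccr_on_cl = FALSE)
    base <- pop_model(theta = c(CL = 0.35, CL_CRRT = 0.386, VC = 4, VP = 3.5,
                                Q = 2),
                      spec = spec0)
  }
  cur_fit <- fit_packed(pack, base, control)
  cur_model <- cur_fit$model
  included <- list()
  remaining <- candidates
  trace <- list()
  note <- function(phase, cand, dofv, action) {
    trace[[length(trace) + 1L]] <<-
      data.frame(phase = phase, candidate = candidate_label(cand),
                 delta_ofv = dofv, action = action)
  }
  repeat { # forward
    if (length(remaining) == 0L) break
    fits <- vector("list", length(remaining))
    dofv <- rep(-Inf, length(remaining))
    npar <- rep(NA_integer_, length(remaining))
    for (i in seq_along(remaining)) {
      cand_model <- add_candidate(cur_model, remaining[[i]], pack$covs)
      if (is.null(cand_model)) next
      f <- try(fit_packed(pack, cand_model, control), silent = TRUE)
      if (inherits(f, "try-error") || !is.finite(f$ofv)) {
        note("forward", remaining[[i]], NA_real_, "skipped (fit failed)")
        next
      }
      fits[[i]] <- f
      dofv[i] <- cur_fit$ofv - f$ofv
      npar[i] <- f$p
    }
    ok <- which(is.finite(dofv) & dofv > forward_cut)
    if (length(ok) == 0L) {
      for (i in seq_along(remaining)) {
        if (is.finite(dofv[i])) note("forward", remaining[[i]], dofv[i], "rejected")
      }
      break
    }
    best <- ok[order(-dofv[ok], npar[ok], ok)][1]
    for (i in seq_along(remaining)) {
      if (!is.finite(dofv[i])) next
      note("forward", remaining[[i]], dofv[i],
           if (i == best) "accepted" else "not selected this round")
    }
    included <- c(included, remaining[best])
    cur_fit <- fits[[best]]
    cur_model <- cur_fit$model
    remaining <- remaining[-best]
  }
  repeat { # backward
    if (length(included) == 0L) break
    dofv <- rep(Inf, length(included))
    fits <- vector("list", length(included))
    for (i in seq_along(included)) {
      red_model <- drop_candidate(cur_model, included[[i]])
      f <- try(fit_packed(pack, red_model, control), silent = TRUE)
      if (inherits(f, "try-error") || !is.finite(f$ofv)) next
      fits[[i]] <- f
      dofv[i] <- f$ofv - cur_fit$ofv # OFV increase caused by removal
    }
    weakest <- which.min(dofv)
    if (dofv[weakest] < backward_cut) {
      note("backward", included[[weakest]], dofv[weakest], "removed")
      cur_fit <- fits[[weakest]]
      cur_model <- cur_fit$model
      included <- included[-weakest]
    } else {
      for (i in seq_along(included)) {
        if (is.finite(dofv[i])) note("backward", included[[i]], dofv[i], "retained")
      }
      break
    }
  }
  list(final = cur_fit,
       selected = vapply(included, candidate_label, character(1)),
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(phase = character(), candidate = character(),
                    delta_ofv = numeric(), action = character()))
}

# -- bootstrap ----------------------------------------------------------------

#' Subject-resampling bootstrap of a population fit
#'
#' Resamples subjects with replacement (original cohort size), refits each
#' resample starting from the original estimates, and summarizes the
#' replicate estimates by medians and 2.5-97.5 percentile intervals.
#'
#' @param dataset a study dataset
#' @param fit a fitted `pk_fit` (used for the model structure and as warm
#'   start); alternatively a [pop_model()] to be fit first
#' @param n_boot number of bootstrap replicates (1000 in the study; smaller
#'   values trade precision for runtime)
#' @param seed integer seed for the resampling
#' @param control a [fit_control()] for the replicate fits; the default
#'   trades a little per-replicate optimizer polish (Gauss-Newton Laplace
#'   hessian, forward-difference gradient, looser tolerance) for the
#'   throughput needed to run hundreds of refits — replicate estimates are
#'   dominated by resampling noise, not by the last digits of convergence
#' @return object of class `pk_boot`: `summary` matrix (median, lo, hi per
#'   parameter), `estimates` matrix of replicate estimates, `n_failed`
#' @export
bootstrap_fit <- function(dataset, fit, n_boot = 1000, seed = 1,
                          control = fit_control(rel_tol = 1e-5, se = FALSE,
                                                multi_start = 1,
                                                hessian = "gn",
                                                grad = "forward",
                                                max_iter = 150)) {
  if (inherits(fit, "pop_model")) fit <- fit_popmodel(dataset, fit, control)
  stopifnot(inherits(fit, "pk_fit"))
  pack0 <- fit$pack
  n <- length(pack0$subjects)
  layout <- fit$layout
  x_hat <- encode_pars(fit$model, layout)
  set.seed(seed)
  est <- matrix(NA_real_, n_boot, length(layout$names),
                dimnames = list(NULL, layout$names))
  failed <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    packb <- list(subjects = pack0$subjects[idx],
                  covs = pack0$covs[idx, , drop = FALSE],
                  ids = seq_len(n),
                  n_obs = sum(vapply(pack0$subjects[idx],
                                     function(s) length(s$t), integer(1))))
    fb <- try(fit_packed(packb, fit$model, control, x_start = x_hat,
                         eta_start = fit$etas[idx, , drop = FALSE]),
              silent = TRUE)
    if (inherits(fb, "try-error") || !is.finite(fb$ofv) || !fb$converged) {
      failed <- failed + 1L
      next
    }
    est[b, ] <- fb$estimates
  }
  if (failed > 0.1 * n_boot) {
    warning(sprintf("bootstrap_fit: %d of %d replicates failed", failed, n_boot))
  }
  ok <- stats::complete.cases(est)
  summ <- t(apply(est[ok, , drop = FALSE], 2, stats::quantile,
                  probs = c(0.5, 0.025, 0.975), names = FALSE))
  colnames(summ) <- c("median", "lo", "hi")
  structure(list(summary = summ, estimates = est[ok, , drop = FALSE],
                 n_boot = n_boot, n_failed = failed, seed = seed),
            class = "pk_boot")
}

#' @export
print.pk_boot <- function(x, ...) {
  cat(sprintf("Bootstrap: %d replicates (%d failed)\n", x$n_boot, x$n_failed))
  print(signif(x$summary, 4))
  invisible(x)
}
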