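#' Structural / covariate model specification
#'
#' Describes which structural model is used (one- or two-compartment), how
#' clearance depends on renal function, which additional covariate effects
#' are active, and which parameters carry inter-individual variability (IIV).
#'
#' The final daptomycin model uses a CRRT switch on clearance plus a renal
#' slope in non-CRRT subjects:
#' `CL = CL_CRRT` on CRRT, `CL = NR + R * CCR/ccr_ref` otherwise, with
#' `ccr_ref = 54` mL/min (the cohort median, a fixed constant, not
#' estimated).
#'
#' Screened covariate effects (used by [stepwise_covariates()]) are given as
#' `list(param, cov, form, ref)` entries:
#' * `form = "additive"` (clearance): `CL += theta * cov/ref` (non-CRRT
#'   branch only; CRRT clearance is its own regime),
#' * `form = "linfac"` (volumes): `V *= 1 + theta * (cov - ref)/ref`,
#' * `form = "catmult"` (categorical): `P *= theta^I(cov)`.
#'
#' @param n_cmt 1 or 2 compartments
#' @param crrt_cl logical; CRRT structural switch on clearance
#' @param ccr_on_cl logical; renal (creatinine-clearance) slope on the
#'   non-CRRT clearance
#' @param ccr_ref reference creatinine clearance, mL/min
#' @param effects list of screened covariate-effect descriptors (see above)
#' @param iiv names of structural parameters with lognormal IIV
#' @param error residual-error model: "combined", "additive" or
#'   "proportional"
#' @return object of class `pk_model_spec`
#' @export
pk_model_spec <- function(n_cmt = 2, crrt_cl = TRUE, ccr_on_cl = TRUE,
                          ccr_ref = 54, effects = list(),
                          iiv = if (n_cmt == 2) c("CL", "VC", "VP") else c("CL", "VC"),
                          error = c("combined", "additive", "proportional")) {
  error <- match.arg(error)
  stopifnot(n_cmt %in% c(1, 2), ccr_ref > 0)
  params <- if (n_cmt == 2) c("CL", "VC", "VP", "Q") else c("CL", "VC")
  if (!all(iiv %in% params)) stop("pk_model_spec: iiv names must be structural parameters")
  for (e in effects) {
    stopifnot(all(c("param", "cov", "form") %in% names(e)))
    if (!e$param %in% setdiff(params, "Q")) {
      stop("pk_model_spec: covariate effects allowed on CL, VC, VP only")
    }
    if (!e$form %in% c("additive", "linfac", "catmult")) {
      stop("pk_model_spec: unknown effect form ", e$form)
    }
  }
  structure(list(n_cmt = n_cmt, crrt_cl = crrt_cl, ccr_on_cl = ccr_on_cl,
                 ccr_ref = ccr_ref, effects = effects, iiv = iiv,
                 error = error),
            class = "pk_model_spec")
}

effect_theta_name <- function(e) paste("beta", e$param, e$cov, sep = "_")

#' Names of the fixed effects implied by a model specification
#' @param spec a [pk_model_spec()]
#' @return character vector of theta names
#' @export
theta_names <- function(spec) {
  cl <- if (spec$ccr_on_cl) c("NR", "R") else "CL"
  if (spec$crrt_cl) cl <- c(cl, "CL_CRRT")
  nm <- c(cl, "VC", if (spec$n_cmt == 2) c("VP", "Q"))
  c(nm, vapply(spec$effects, effect_theta_name, character(1)))
}

#' Population pharmacokinetic model
#'
#' Bundles fixed effects (theta), IIV variances (Omega), residual variances
#' (Sigma) and the covariate-model structure. Defaults are the final
#' published daptomycin model for critically ill patients.
#'
#' @param theta named fixed effects; defaults `NR = 0.229`, `R = 0.148`,
#'   `CL_CRRT = 0.386` (L/h), `VC = 4.14`, `VP = 3.52` (L), `Q = 2.09` (L/h)
#' @param omega named vector of IIV variances (lognormal scale) or a full
#'   positive semi-definite matrix with dimnames matching `spec$iiv`;
#'   defaults `CL = 0.091`, `VC = 0.114`, `VP = 0.202`
#' @param sigma residual variances `c(prop = , add = )`; defaults
#'   `prop = 0.018` (dimensionless) and `add = 38.095` ((mg/L)^2)
#' @param spec a [pk_model_spec()]
#' @param variance_scale "variance" (default, NONMEM convention: `omega` and
#'   `sigma` entries are variances) or "sd" (entries are standard
#'   deviations, squared on input)
#' @return object of class `pop_model`
#' @examples
#' m <- pop_model()
#' typical_clearance(m, data.frame(CRRT = FALSE, CCR = 54))
#' @export
pop_model <- function(theta = NULL, omega = NULL, sigma = NULL,
                      spec = pk_model_spec(),
                      variance_scale = c("variance", "sd")) {
  variance_scale <- match.arg(variance_scale)
  if (is.null(theta)) {
    theta <- c(NR = 0.229, R = 0.148, CL_CRRT = 0.386, VC = 4.14,
               VP = 3.52, Q = 2.09)
  }
  need <- theta_names(spec)
  if (!all(need %in% names(theta))) {
    stop("pop_model: theta must contain ", paste(need, collapse = ", "))
  }
  theta <- theta[need]
  base_idx <- !grepl("^beta_", names(theta))
  if (any(theta[base_idx] <= 0)) stop("pop_model: structural thetas must be > 0")
  if (is.null(omega)) omega <- c(CL = 0.091, VC = 0.114, VP = 0.202)[spec$iiv]
  if (is.matrix(omega)) {
    if (is.null(rownames(omega))) dimnames(omega) <- list(spec$iiv, spec$iiv)
    om <- omega
  } else {
    if (is.null(names(omega))) names(omega) <- spec$iiv
    om <- diag(omega[spec$iiv], nrow = length(spec$iiv))
    dimnames(om) <- list(spec$iiv, spec$iiv)
  }
  if (variance_scale == "sd") om <- om * om # diagonal SDs squared
  ev <- eigen(om, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10)) stop("pop_model: omega must be positive semi-definite")
  if (is.null(sigma)) sigma <- c(prop = 0.018, add = 38.095)
  if (variance_scale == "sd") sigma <- sigma^2
  sigma <- switch(spec$error,
                  combined = c(prop = unname(sigma["prop"]), add = unname(sigma["add"])),
                  additive = c(prop = 0, add = unname(sigma[["add"]])),
                  proportional = c(prop = unname(sigma[["prop"]]), add = 0))
  if (any(sigma < 0)) stop("pop_model: residual variances must be >= 0")
  # (an all-zero sigma is allowed for noise-free simulation; estimation
  # rejects it)
  structure(list(theta = theta, omega = om, sigma = sigma, spec = spec),
            class = "pop_model")
}

#' @export
print.pop_model <- function(x, ...) {
  cat(sprintf("Population PK model (%d-compartment%s)\n", x$spec$n_cmt,
              if (x$spec$crrt_cl) ", CRRT clearance switch" else ""))
  cat("theta:\n")
  print(round(x$theta, 4))
  cat("omega (IIV variances):\n")
  print(round(x$omega, 4))
  cat(sprintf("sigma: prop = %.4g, add = %.4g\n", x$sigma["prop"], x$sigma["add"]))
  invisible(x)
}

#' Typical (population) clearance for a subject
#'
#' `CL = CL_CRRT` for subjects on CRRT; otherwise
#' `CL = NR + R * CCR/ccr_ref`, the renal + non-renal decomposition of the
#' final model (CCR in mL/min, `ccr_ref = 54` by default).
#'
#' @param model a [pop_model()] (or its theta with a default spec)
#' @param cov data.frame (or list) with at least `CRRT` (logical) and, for
#'   non-CRRT subjects, `CCR` (mL/min)
#' @return typical clearance(s), L/h
#' @export
typical_clearance <- function(model, cov) {
  stopifnot(inherits(model, "pop_model"))
  typical_params(model, as.data.frame(cov))[, "CL"]
}

#' Typical structural parameters for one or more subjects
#'
#' @param model a [pop_model()]
#' @param covs data.frame of covariates, one row per subject
#' @return numeric matrix with columns `CL`, `VC`, `VP`, `Q`
#' @export
typical_params <- function(model, covs) {
  stopifnot(inherits(model, "pop_model"))
  spec <- model$spec
  th <- model$theta
  covs <- as.data.frame(covs)
  n <- nrow(covs)
  crrt <- if ("CRRT" %in% names(covs)) as.logical(covs$CRRT) else rep(FALSE, n)
  if (spec$ccr_on_cl) {
    ccr <- covs$CCR
    if (any(!crrt & (is.na(ccr) | ccr <= 0))) {
      stop("typical_params: CCR required (positive) for non-CRRT subjects")
    }
    cl_other <- th["NR"] + th["R"] * ccr / spec$ccr_ref
    cl_other[is.na(cl_other)] <- 0 # CRRT rows may lack CCR; overwritten below
  } else {
    cl_other <- rep(th["CL"], n)
  }
  cl <- if (spec$crrt_cl) ifelse(crrt, th["CL_CRRT"], cl_other) else cl_other
  vc <- rep(th[["VC"]], n)
  vp <- if (spec$n_cmt == 2) rep(th[["VP"]], n) else rep(1, n)
  q <- if (spec$n_cmt == 2) rep(th[["Q"]], n) else rep(0, n)
  for (e in spec$effects) {
    b <- th[[effect_theta_name(e)]]
    x <- covs[[e$cov]]
    if (is.null(x)) stop("typical_params: covariate ", e$cov, " not in data")
    x <- as.numeric(x)
    upd <- function(v) {
      switch(e$form,
             additive = v + b * x / e$ref,
             linfac = v * (1 + b * (x - e$ref) / e$ref),
             catmult = v * b^x)
    }
    if (e$param == "CL") {
      # clearance effects modify the non-CRRT branch only
      mod <- upd(cl)
      cl <- ifelse(crrt, cl, mod)
    } else if (e$param == "VC") {
      vc <- upd(vc)
    } else if (e$param == "VP") {
      vp <- upd(vp)
    }
  }
  out <- cbind(CL = pmax(cl, 1e-8), VC = pmax(vc, 1e-8),
               VP = pmax(vp, 1e-8), Q = pmax(q, 0))
  out
}

#' Individual parameters from typical values and random effects
#'
#' Applies lognormal IIV: `P_i = TV_P * exp(eta_P)` for each parameter in
#' `spec$iiv`; parameters without IIV (Q in the final model) equal their
#' typical values.
#'
#' @param model a [pop_model()]
#' @param cov single-subject covariates (list or one-row data.frame)
#' @param eta named numeric vector of random effects (names in `spec$iiv`);
#'   missing entries are taken as 0
#' @return a [pk_params()] object
#' @export
individual_params <- function(model, cov, eta = numeric(0)) {
  tv <- typical_params(model, as.data.frame(cov))
  if (nrow(tv) != 1L) stop("individual_params: cov must describe one subject")
  full <- stats::setNames(numeric(length(model$spec$iiv)), model$spec$iiv)
  if (length(eta)) {
    if (is.null(names(eta))) names(eta) <- model$spec$iiv[seq_along(eta)]
    full[names(eta)] <- eta
  }
  fac <- function(p) if (p %in% names(full)) exp(full[[p]]) else 1
  # unname: single-row matrix extraction carries dimnames along
  new_pk_params(CL = unname(tv[1, "CL"] * fac("CL")),
                VC = unname(tv[1, "VC"] * fac("VC")),
                VP = unname(max(tv[1, "VP"] * fac("VP"), 1e-8)),
                Q = unname(tv[1, "Q"]))
}

#' Residual-error standard deviation
#'
#' Combined additive + proportional model:
#' `sd(pred) = sqrt(pred^2 * sigma2_prop + sigma2_add)`.
#'
#' @param pred model-predicted concentration(s), mg/L (>= 0)
#' @param sigma residual variances `c(prop = , add = )`
#' @return standard deviation(s), mg/L
#' @export
residual_sd <- function(pred, sigma = c(prop = 0.018, add = 38.095)) {
  if (any(pred < 0)) stop("residual_sd: pred must be >= 0")
  sqrt(pred^2 * sigma[["prop"]] + sigma[["add"]])
}

#' Lower limit of quantification of the daptomycin assay, mg/L
#' @export
DAPTO_LLOQ <- 0.05

#' Simulate observations for one subject
#'
#' Draws one eta vector for the subject and independent residual errors per
#' observation: `DV = C(t) * (1 + eps_prop) + eps_add`. Simulated values
#' below the assay LLOQ (0.05 mg/L), including negative draws from the
#' additive error, are flagged BLQ (not truncated), preserving the symmetry
#' of the error model.
#'
#' @param model a [pop_model()]
#' @param cov single-subject covariates
#' @param doses a [dose_events()] table or [pk_regimen()]
#' @param sample_times observation times, h
#' @param seed optional integer seed (if `NULL`, the current RNG stream is
#'   used so callers can manage seeding)
#' @param lloq lower limit of quantification, mg/L
#' @return data.frame with `time`, `ipred` (subject's true concentration),
#'   `dv`, `blq`, plus the drawn `eta` as an attribute
#' @export
simulate_observations <- function(model, cov, doses, sample_times,
                                  seed = NULL, lloq = DAPTO_LLOQ) {
  if (!is.null(seed)) set.seed(seed)
  eta <- draw_etas(model$omega, 1)[1, ]
  names(eta) <- model$spec$iiv
  pk <- individual_params(model, cov, eta)
  doses <- as_dose_events(doses)
  f <- pk_concentration(sample_times, pk, doses)
  eps_p <- stats::rnorm(length(f), 0, sqrt(model$sigma[["prop"]]))
  eps_a <- stats::rnorm(length(f), 0, sqrt(model$sigma[["add"]]))
  dv <- f * (1 + eps_p) + eps_a
  blq <- dv < lloq
  out <- data.frame(time = sample_times, ipred = f, dv = dv, blq = blq)
  attr(out, "eta") <- eta
  attr(out, "pk") <- pk
  out
}

# multivariate normal draws (n x d) from covariance omega
draw_etas <- function(omega, n) {
  d <- nrow(omega)
  if (all(omega == 0)) return(matrix(0, n, d, dimnames = list(NULL, rownames(omega))))
  ev <- eigen(omega, symmetric = TRUE)
  rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), d) %*% t(ev$vectors)
  z <- matrix(stats::rnorm(n * d), n, d)
  out <- z %*% rt
  colnames(out) <- rownames(omega)
  out
}

#' Write / read a population model as a plain-text config
#'
#' Key/value serialization with 17 significant digits so that
#' `read_model_config(write_model_config(m, f))` round-trips bit-exactly.
#'
#' @param model a [pop_model()]
#' @param path file path
#' @return `path`, invisibly (writer); a [pop_model()] (reader)
#' @export
write_model_config <- function(model, path) {
  stopifnot(inherits(model, "pop_model"))
  num <- function(x) sprintf("%.17g", x)
  sp <- model$spec
  lines <- c(
    sprintf("n_cmt=%d", sp$n_cmt),
    sprintf("crrt_cl=%d", as.integer(sp$crrt_cl)),
    sprintf("ccr_on_cl=%d", as.integer(sp$ccr_on_cl)),
    sprintf("ccr_ref=%s", num(sp$ccr_ref)),
    sprintf("iiv=%s", paste(sp$iiv, collapse = ",")),
    sprintf("error=%s", sp$error),
    vapply(sp$effects, function(e)
      sprintf("effect=%s:%s:%s:%s", e$param, e$cov, e$form, num(e$ref)),
      character(1)),
    sprintf("theta.%s=%s", names(model$theta), num(model$theta)),
    sprintf("omega.%s.%s=%s",
            rep(rownames(model$omega), ncol(model$omega)),
            rep(colnames(model$omega), each = nrow(model$omega)),
            num(as.vector(model$omega))),
    sprintf("sigma.%s=%s", names(model$sigma), num(model$sigma))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
  get1 <- function(k) vals[keys == k][1]
  effects <- lapply(vals[keys == "effect"], function(v) {
    p <- strsplit(v, ":", fixed = TRUE)[[1]]
    list(param = p[1], cov = p[2], form = p[3], ref = as.numeric(p[4]))
  })
  spec <- pk_model_spec(n_cmt = as.integer(get1("n_cmt")),
                        crrt_cl = get1("crrt_cl") == "1",
                        ccr_on_cl = get1("ccr_on_cl") == "1",
                        ccr_ref = as.numeric(get1("ccr_ref")),
                        effects = effects,
                        iiv = strsplit(get1("iiv"), ",", fixed = TRUE)[[1]],
                        error = get1("error"))
  pick <- function(prefix) {
    sel <- startsWith(keys, prefix)
    stats::setNames(as.numeric(vals[sel]), sub(prefix, "", keys[sel], fixed = TRUE))
  }
  theta <- pick("theta.")
  sigma <- pick("sigma.")
  om_raw <- pick("omega.")
  d <- length(spec$iiv)
  om <- matrix(0, d, d, dimnames = list(spec$iiv, spec$iiv))
  for (nm in names(om_raw)) {
    ij <- strsplit(nm, ".", fixed = TRUE)[[1]]
    om[ij[1], ij[2]] <- om_raw[[nm]]
  }
  pop_model(theta = theta, omega = om, sigma = sigma, spec = spec)
}
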