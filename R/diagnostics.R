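## Goodness-of-fit quantities (PRED / IPRED / CWRES) and the visual
## predictive check.

# jacobian of the subject's prediction wrt eta, central differences
subject_jacobian <- function(subj, tvrow, eta_idx, eta, h = 1e-5) {
  d <- length(eta)
  f_at <- function(e) {
    par <- tvrow
    for (p in seq_len(4)) {
      if (eta_idx[p] >= 0) par[p] <- par[p] * exp(e[eta_idx[p] + 1L])
    }
    cpp_conc2(subj$t, subj$dstart, subj$damt, subj$ddur,
              par[1], par[2], par[3], par[4])
  }
  J <- matrix(0, length(subj$t), d)
  for (k in seq_len(d)) {
    ep <- eta; ep[k] <- eta[k] + h
    em <- eta; em[k] <- eta[k] - h
    J[, k] <- (f_at(ep) - f_at(em)) / (2 * h)
  }
  list(J = J, f = f_at(eta), f0 = f_at(numeric(d)))
}

#' Goodness-of-fit quantities
#'
#' Per-observation population prediction `PRED` (eta = 0), individual
#' prediction `IPRED` (at the empirical Bayes eta) and conditional weighted
#' residuals `CWRES`. CWRES uses the FOCE-I linearization around the
#' empirical Bayes mode: the observation vector is whitened by the
#' model-implied marginal covariance `J Omega J' + diag(V(eta_hat))` of the
#' model linearized at `eta_hat`, with mean `f(eta_hat) - J eta_hat`.
#'
#' @param fit a `pk_fit` from [fit_popmodel()] (or a [pop_model()] together
#'   with `dataset`, in which case empirical Bayes etas are computed first)
#' @param dataset the study dataset the fit was obtained from (only needed
#'   when `fit` is a [pop_model()])
#' @return data.frame with `ID`, `TIME`, `DV`, `PRED`, `IPRED`, `CWRES`
#' @export
gof_quantities <- function(fit, dataset = NULL) {
  if (inherits(fit, "pop_model")) {
    if (is.null(dataset)) stop("gof_quantities: dataset required with a pop_model")
    pack <- pack_subjects(dataset)
    model <- fit
    res <- foce_ofv_packed(pack, model)
    etas <- res$etas
  } else {
    stopifnot(inherits(fit, "pk_fit"))
    pack <- fit$pack
    model <- fit$model
    etas <- fit$etas
  }
  tv <- typical_params(model, pack$covs)
  eta_idx <- eta_index_for(model$spec)
  sp2 <- model$sigma[["prop"]]
  sa2 <- model$sigma[["add"]]
  om <- model$omega
  out <- vector("list", length(pack$subjects))
  for (i in seq_along(pack$subjects)) {
    s <- pack$subjects[[i]]
    if (length(s$t) == 0L) next
    jb <- subject_jacobian(s, tv[i, ], eta_idx, etas[i, ])
    v <- pmax(sp2 * jb$f^2 + sa2, 1e-12)
    Sig <- jb$J %*% om %*% t(jb$J) + diag(v, length(v))
    mu <- jb$f - as.numeric(jb$J %*% etas[i, ])
    L <- tryCatch(chol(Sig), error = function(e)
      stop("gof_quantities: singular marginal covariance for subject ",
           pack$ids[i]))
    cwres <- backsolve(L, s$y - mu, transpose = TRUE)
    out[[i]] <- data.frame(ID = pack$ids[i], TIME = s$t, DV = s$y,
                           PRED = jb$f0, IPRED = jb$f, CWRES = cwres)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Visual predictive check
#'
#' Simulates `n_rep` replicate datasets on the observed design (same
#' subjects, dose histories and observation times; new etas and residual
#' errors per replicate), bins observations by nominal time, and compares
#' the observed 5th/50th/95th percentiles per bin with the simulation-based
#' 90% confidence band for each percentile.
#'
#' Binning is by the nominal scheduled times (the design is a fixed rich
#' schedule); observed times are mapped to the nearest nominal bin.
#'
#' @param fit a `pk_fit`, or a [pop_model()] (with `dataset`)
#' @param dataset required when `fit` is a [pop_model()]
#' @param n_rep number of simulation replicates (1000 in the study)
#' @param seed integer seed
#' @param probs percentiles summarized per bin
#' @param ci level of the simulation band (0.90)
#' @param min_bin bins with fewer observations are flagged
#' @return object of class `vpc_result`: data.frame `table` with one row
#'   per bin x percentile (`bin`, `n`, `prob`, `observed`, `lo`, `med`,
#'   `hi`, `flagged`), plus `n_rep`
#' @export
vpc <- function(fit, dataset = NULL, n_rep = 1000, seed = 1,
                probs = c(0.05, 0.5, 0.95), ci = 0.90, min_bin = 5) {
  if (inherits(fit, "pop_model")) {
    if (is.null(dataset)) stop("vpc: dataset required with a pop_model")
    pack <- pack_subjects(dataset)
    model <- fit
  } else {
    stopifnot(inherits(fit, "pk_fit"))
    pack <- fit$pack
    model <- fit$model
  }
  set.seed(seed)
  tv <- typical_params(model, pack$covs)
  eta_idx <- eta_index_for(model$spec)
  nsub <- length(pack$subjects)
  all_t <- unlist(lapply(pack$subjects, `[[`, "t"))
  all_y <- unlist(lapply(pack$subjects, `[[`, "y"))
  bins <- sort(unique(round(all_t, 6)))
  bin_of <- function(t) bins[pmax(1, findInterval(t, c(-Inf, bins[-1] - diff(bins) / 2)))]
  obs_bin <- bin_of(all_t)
  nobs_per <- vapply(pack$subjects, function(s) length(s$t), integer(1))
  total_obs <- sum(nobs_per)
  d <- ncol(model$omega)
  # percentile matrix per replicate: bins x probs
  sim_pct <- array(NA_real_, c(length(bins), length(probs), n_rep))
  sp <- sqrt(model$sigma[["prop"]])
  sa <- sqrt(model$sigma[["add"]])
  for (r in seq_len(n_rep)) {
    etas <- draw_etas(model$omega, nsub)
    ysim <- numeric(total_obs)
    pos <- 0L
    for (i in seq_len(nsub)) {
      s <- pack$subjects[[i]]
      ni <- nobs_per[i]
      if (ni == 0L) next
      par <- tv[i, ]
      for (p in seq_len(4)) {
        if (eta_idx[p] >= 0) par[p] <- par[p] * exp(etas[i, eta_idx[p] + 1L])
      }
      f <- cpp_conc2(s$t, s$dstart, s$damt, s$ddur, par[1], par[2], par[3], par[4])
      ysim[pos + seq_len(ni)] <-
        f * (1 + stats::rnorm(ni, 0, sp)) + stats::rnorm(ni, 0, sa)
      pos <- pos + ni
    }
    for (k in seq_along(bins)) {
      sel <- obs_bin == bins[k]
      sim_pct[k, , r] <- stats::quantile(ysim[sel], probs, names = FALSE)
    }
  }
  alpha <- (1 - ci) / 2
  tab <- do.call(rbind, lapply(seq_along(bins), function(k) {
    sel <- obs_bin == bins[k]
    obs_q <- stats::quantile(all_y[sel], probs, names = FALSE)
    band <- apply(sim_pct[k, , , drop = FALSE], 2,
                  stats::quantile, probs = c(alpha, 0.5, 1 - alpha),
                  names = FALSE)
    data.frame(bin = bins[k], n = sum(sel), prob = probs, observed = obs_q,
               lo = band[1, ], med = band[2, ], hi = band[3, ],
               flagged = sum(sel) < min_bin)
  }))
  rownames(tab) <- NULL
  structure(list(table = tab, n_rep = n_rep, probs = probs, ci = ci),
            class = "vpc_result")
}

#' @export
print.vpc_result <- function(x, ...) {
  cat(sprintf("VPC: %d bins, %d simulation replicates, %d%% bands\n",
              length(unique(x$table$bin)), x$n_rep, round(100 * x$ci)))
  inside <- with(x$table[!x$table$flagged, ],
                 mean(observed >= lo & observed <= hi))
  cat(sprintf("observed percentile points inside their band: %.1f%%\n",
              100 * inside))
  invisible(x)
}

#' Fraction of observed VPC percentile points inside their simulation band
#' @param x a `vpc_result`
#' @param drop_flagged exclude bins with fewer than `min_bin` observations
#' @return proportion in `[0, 1]`
#' @export
vpc_coverage <- function(x, drop_flagged = TRUE) {
  tab <- x$table
  if (drop_flagged) tab <- tab[!tab$flagged, , drop = FALSE]
  mean(tab$observed >= tab$lo & tab$observed <= tab$hi)
}

#' Write a VPC table to CSV
#' @param x a `vpc_result`
#' @param path output file
#' @export
write_vpc <- function(x, path) {
  utils::write.csv(x$table, path, row.names = FALSE)
  invisible(path)
}
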