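#' @title Model evaluation tools
#' @description Visual predictive check, nonparametric bootstrap and
#'   goodness-of-fit residuals for fitted population PK models.
#' @name model-evaluation
NULL

# Time after the most recent dose start (the nominal sampling clock of the
# study design); observations before any dose keep their absolute time.
.time_after_dose <- function(subject) {
  o <- subject$observations
  vapply(o$time, function(tt) {
    prior <- subject$doses$start[subject$doses$start <= tt + 1e-9]
    if (!length(prior)) tt else tt - max(prior)
  }, numeric(1))
}

# Percentile convention used throughout model evaluation: linear
# interpolation of order statistics (stats::quantile type 7).
.pct <- function(x, p) quantile(x, p, type = 7, names = FALSE)

#' Visual predictive check
#'
#' Simulates `n_sim` replicate datasets under the model with the original
#' design (each subject's doses, sampling times and covariates), including
#' residual error, and compares observed percentiles with
#' simulation-based confidence bands.  Observations are binned at the
#' nominal sampling times (time after dose start), which are fixed by the
#' study design; for each bin the 5th, 50th and 95th observed percentiles
#' are overlaid on the 90% band (5th-95th percentile across simulations) of
#' the same statistic.  A bin/percentile combination whose observed value
#' exits its band flags model misspecification.  Negative simulated
#' concentrations are retained (generative fidelity).
#'
#' @param dataset A [pk_dataset()].
#' @param model A [population_model()].
#' @param n_sim Number of simulated datasets (>= 100; the reference analysis
#'   used 1000).
#' @param seed Optional integer seed.
#' @return An object of class `pk_vpc`: data.frame `bins` with observed
#'   percentiles, band limits and an `outside` flag count, plus `n_sim`.
#' @export
vpc <- function(dataset, model, n_sim = 1000, seed = NULL) {
  stopifnot(inherits(dataset, "pk_dataset"))
  if (n_sim < 100) stop("n_sim must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  subs <- dataset$subjects
  tad <- conc <- keep <- list()
  for (s in subs) {
    use <- !s$observations$excluded & !is.na(s$observations$concentration)
    tad[[s$id]] <- round(.time_after_dose(s)[use], 6)
    conc[[s$id]] <- s$observations$concentration[use]
  }
  bins <- sort(unique(unlist(tad)))
  obs_tad <- unlist(tad)
  obs_conc <- unlist(conc)
  probs <- c(0.05, 0.5, 0.95)
  obs_pct <- t(vapply(bins, function(b) {
    v <- obs_conc[obs_tad == b & !is.na(obs_conc)]
    if (length(v) == 0) rep(NA_real_, 3) else .pct(v, probs)
  }, numeric(3)))
  sim_stats <- array(NA_real_, c(n_sim, length(bins), 3))
  for (r in seq_len(n_sim)) {
    sim_conc <- unlist(lapply(subs, function(s) {
      use <- !s$observations$excluded & !is.na(s$observations$concentration)
      simulate_subject(model, s$covariates, s$doses,
                       s$observations$time[use],
                       with_residual = TRUE)$observations$concentration
    }))
    for (b in seq_along(bins)) {
      v <- sim_conc[obs_tad == bins[b]]
      if (length(v)) sim_stats[r, b, ] <- .pct(v, probs)
    }
  }
  out <- data.frame(tad = rep(bins, each = 3),
                    percentile = rep(c(5, 50, 95), length(bins)),
                    observed = as.vector(t(obs_pct)))
  out$lower <- out$upper <- NA_real_
  for (b in seq_along(bins)) for (q in 1:3) {
    v <- sim_stats[, b, q]
    v <- v[!is.na(v)]
    row <- (b - 1) * 3 + q
    if (length(v)) {
      out$lower[row] <- .pct(v, 0.05)
      out$upper[row] <- .pct(v, 0.95)
    }
  }
  empty <- is.na(out$observed)
  if (any(empty)) {
    warning("dropping ", sum(empty)/3, " empty VPC bin(s)")
    out <- out[!empty, , drop = FALSE]
  }
  out$outside <- out$observed < out$lower | out$observed > out$upper
  structure(list(bins = out, n_sim = n_sim), class = "pk_vpc")
}

#' @export
print.pk_vpc <- function(x, ...) {
  cat(sprintf("VPC: %d bins x 3 percentiles from %d simulations; %d outside the 90%% band\n",
              length(unique(x$bins$tad)), x$n_sim, sum(x$bins$outside)))
  invisible(x)
}

#' @export
plot.pk_vpc <- function(x, log = "", ...) {
  b <- x$bins
  graphics::plot(NA, xlim = range(b$tad), ylim = range(c(b$observed, b$lower,
                                                         b$upper), na.rm = TRUE),
                 xlab = "Time after dose (h)",
                 ylab = "Concentration (mg/l)", log = log, ...)
  for (q in c(5, 50, 95)) {
    sub <- b[b$percentile == q, ]
    graphics::polygon(c(sub$tad, rev(sub$tad)), c(sub$lower, rev(sub$upper)),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
    graphics::lines(sub$tad, sub$observed, lwd = 2,
                    lty = if (q == 50) 1 else 2)
  }
  invisible(x)
}

#' Nonparametric bootstrap of a population fit
#'
#' Resamples subjects (not individual observations) with replacement to the
#' original subject count, refits the model on each resample (warm-started
#' from the original estimates), and summarizes each parameter by the median
#' and the 5th-95th percentile interval across successful fits.  A resample
#' counts as unsuccessful when the optimizer fails to converge or an IIV
#' variance collapses onto its boundary.
#'
#' @param dataset A [pk_dataset()].
#' @param spec A [model_spec()].
#' @param n_boot Number of bootstrap resamples.
#' @param init A [population_model()]; usually the original point estimates.
#' @param seed Optional integer seed.
#' @param control A [fit_control()].
#' @return An object of class `pk_bootstrap`: `estimates` (matrix of
#'   per-resample parameter estimates), `summary` (median and 90% interval
#'   per parameter), `n_success`, `n_fail`.
#' @export
bootstrap_fit <- function(dataset, spec, n_boot, init, seed = NULL,
                          control = fit_control()) {
  stopifnot(inherits(dataset, "pk_dataset"), n_boot >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- length(dataset$subjects)
  rows <- list()
  n_fail <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    subs <- dataset$subjects[idx]
    for (j in seq_along(subs)) subs[[j]]$id <- sprintf("B%d", j)
    bdat <- structure(list(subjects = subs, lloq = dataset$lloq,
                           metadata = dataset$metadata), class = "pk_dataset")
    fit <- tryCatch(fit_population(bdat, spec, init, control),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged || fit$boundary) {
      n_fail <- n_fail + 1L
      next
    }
    rows[[length(rows) + 1]] <- .flatten_model_params(fit$model)
  }
  if (n_fail > n_boot / 2)
    stop("bootstrap aborted: ", n_fail, " of ", n_boot, " fits unsuccessful")
  est <- do.call(rbind, rows)
  summ <- data.frame(
    parameter = colnames(est),
    median = apply(est, 2, median),
    lower5 = apply(est, 2, .pct, 0.05),
    upper95 = apply(est, 2, .pct, 0.95), row.names = NULL)
  structure(list(estimates = est, summary = summ,
                 n_success = nrow(est), n_fail = n_fail),
            class = "pk_bootstrap")
}

.flatten_model_params <- function(model) {
  out <- c(model$theta,
           setNames(vapply(model$covariate_laws, function(l) l$theta_beta,
                           numeric(1)),
                    vapply(model$covariate_laws, function(l)
                      paste0("beta_", l$param, "_", l$covariate), character(1))),
           setNames(model$omega2[model$omega2 > 0],
                    paste0("omega2_", names(model$omega2)[model$omega2 > 0])),
           sigma_add = unname(model$sigma["add"]),
           sigma_prop = unname(model$sigma["prop"]))
  out
}

#' @export
print.pk_bootstrap <- function(x, ...) {
  cat(sprintf("Nonparametric bootstrap: %d successful, %d unsuccessful\n",
              x$n_success, x$n_fail))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Goodness-of-fit residual table
#'
#' Per-observation predictions and residuals from a converged fit:
#' population predictions (`pred`, at `eta = 0`), individual predictions
#' (`ipred`, at the empirical Bayes etas), individual weighted residuals
#' `iwres = (obs - ipred) / sqrt(var(ipred))`, and conditional weighted
#' residuals (`cwres`) from the first-order conditional linearization: the
#' subject's residual vector is decorrelated by the Cholesky factor of
#' `G Omega G' + diag(var(ipred))`, where `G` is the Jacobian of the
#' prediction with respect to eta at the mode and the expectation is
#' `f(eta_hat) - G eta_hat`.
#'
#' @param dataset A [pk_dataset()].
#' @param fit A converged `pk_fit`.
#' @return A data.frame with columns `id`, `time`, `observed`, `pred`,
#'   `ipred`, `iwres`, `cwres`.
#' @export
gof_residuals <- function(dataset, fit) {
  stopifnot(inherits(fit, "pk_fit"))
  if (!fit$converged) stop("gof_residuals needs a converged fit")
  model <- fit$model
  enames <- .eta_names(model)
  out <- list()
  for (s in dataset$subjects) {
    o <- .fit_observations(s)
    if (!nrow(o)) next
    eta <- fit$ebe[s$id, ]
    f_of <- function(e) {
      p <- individual_params(model, eta = setNames(e, enames),
                             cov = s$covariates)
      if (model$n_compartments == 2) .conc_doses(o$time, p, s$doses)
      else .cpp_conc_profile(o$time, s$doses$start, s$doses$duration,
                             s$doses$rate, c(p$V1, p$CL), 1L)
    }
    ipred <- f_of(eta)
    pred <- f_of(rep(0, length(enames)))
    vi <- residual_variance(pmax(ipred, 0), model$sigma)
    iwres <- (o$concentration - ipred) / sqrt(vi)
    G <- vapply(seq_along(enames), function(m) {
      h <- 1e-5
      ep <- em <- eta
      ep[m] <- eta[m] + h
      em[m] <- eta[m] - h
      (f_of(ep) - f_of(em)) / (2 * h)
    }, numeric(nrow(o)))
    G <- matrix(G, nrow = nrow(o))
    Omega <- diag(model$omega2[enames], length(enames))
    Vy <- G %*% Omega %*% t(G) + diag(vi, nrow(o))
    Ey <- ipred - as.vector(G %*% eta)
    L <- t(chol(Vy))
    cwres <- as.vector(forwardsolve(L, o$concentration - Ey))
    out[[s$id]] <- data.frame(id = s$id, time = o$time,
                              observed = o$concentration, pred = pred,
                              ipred = ipred, iwres = iwres, cwres = cwres,
                              stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
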