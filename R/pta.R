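#' Dosing regimen
#'
#' @param dose Dose amount per administration (mg).
#' @param tau Dosing interval (h), e.g. 8 or 12.
#' @param duration Infusion duration (h), e.g. 0.5, 1 or 3; must be shorter
#'   than `tau`.
#' @return An object of class `dosing_regimen`.
#' @examples
#' dosing_regimen(1000, 8, 1)
#' @export
dosing_regimen <- function(dose = 1000, tau = 8, duration = 1) {
  if (dose <= 0) stop("dose must be positive")
  if (duration >= tau) stop("infusion duration must be shorter than tau")
  structure(list(dose = dose, tau = tau, duration = duration),
            class = "dosing_regimen")
}

#' Fraction of the dosing interval spent above a threshold
#'
#' The Lebesgue measure of `{t in [0, tau] : C(t) > mic}` divided by `tau`,
#' for a concentration profile over one (steady-state) dosing interval.
#' Crossings of the threshold are bracketed on an evaluation grid and
#' refined by root finding to `1e-6` h.
#'
#' @param profile A function of time (h) returning concentration (mg/l),
#'   evaluable on `[0, tau]`.
#' @param mic Threshold concentration (mg/l).
#' @param tau Interval length (h).
#' @param n_grid Number of bracketing grid points.
#' @return Fraction in `[0, 1]`.
#' @examples
#' fraction_time_above_mic(function(t) 10 * exp(-0.1 * t), mic = 5, tau = 8)
#' @export
fraction_time_above_mic <- function(profile, mic, tau, n_grid = 257) {
  tg <- seq(0, tau, length.out = n_grid)
  cg <- profile(tg)
  .frac_above_grid(profile, cg, tg, mic, tau)
}

# Shared crossing-refinement core: cg are profile values on grid tg.
.frac_above_grid <- function(profile, cg, tg, mic, tau) {
  above <- cg > mic
  if (all(above)) return(1)
  if (!any(above)) return(0)
  flips <- which(above[-1] != above[-length(above)])
  cross <- vapply(flips, function(i) {
    uniroot(function(t) profile(t) - mic, lower = tg[i], upper = tg[i + 1],
            f.lower = cg[i] - mic, f.upper = cg[i + 1] - mic,
            tol = 1e-6)$root
  }, numeric(1))
  knots <- c(0, cross, tau)
  mids <- (knots[-1] + knots[-length(knots)]) / 2
  sum((knots[-1] - knots[-length(knots)])[profile(mids) > mic]) / tau
}

#' Monte Carlo probability of target attainment
#'
#' Simulates `n_subjects` individuals from the population model at a fixed
#' albumin concentration (etas drawn from the IIV distribution, no residual
#' error -- the target is evaluated on the model-predicted individual
#' profile), computes each subject's steady-state fraction of the dosing
#' interval above MIC, and reports the percentage attaining the target
#' fraction for every MIC on the grid.
#'
#' @param model A [population_model()], e.g.
#'   [meropenem_reference_model()].
#' @param regimen A [dosing_regimen()].
#' @param albumin Serum albumin (g/l) at which individuals are simulated.
#' @param target_fraction Required fraction of the interval above MIC: 0.4
#'   for the classical carbapenem target, 1.0 for trough-above-MIC.
#' @param mic_grid MIC grid (mg/l); default two-fold ladder 0.064-64.
#' @param n_subjects Number of simulated subjects (>= 100; default 1000).
#' @param seed Optional integer seed.
#' @param covariates Extra covariates forwarded to the covariate laws (for
#'   models with laws on covariates other than albumin).
#' @return An object of class `pta_result` with components `mic`, `pta`
#'   (percent), `target_fraction`, `albumin`, `regimen`, `n_subjects`,
#'   `seed`.
#' @examples
#' \donttest{
#' pta <- simulate_pta(meropenem_reference_model(), dosing_regimen(1000, 8, 1),
#'                     albumin = 24.6, target_fraction = 0.4,
#'                     n_subjects = 200, seed = 1)
#' }
#' @export
simulate_pta <- function(model, regimen, albumin,
                         target_fraction = 0.4,
                         mic_grid = mic_ladder(),
                         n_subjects = 1000, seed = NULL,
                         covariates = list()) {
  stopifnot(inherits(model, "population_model"),
            inherits(regimen, "dosing_regimen"))
  if (n_subjects < 100) stop("n_subjects must be at least 100")
  if (target_fraction <= 0 || target_fraction > 1)
    stop("target_fraction must lie in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  enames <- .eta_names(model)
  eta <- matrix(rnorm(n_subjects * length(enames)), n_subjects) %*%
    diag(sqrt(model$omega2[enames]), length(enames))
  colnames(eta) <- enames
  cov <- modifyList(covariates, list(albumin = albumin))
  frac <- .tmic_fractions(model, eta, cov, regimen, mic_grid)
  pta <- 100 * colMeans(frac >= target_fraction - 1e-12)
  structure(list(mic = mic_grid, pta = pta,
                 target_fraction = target_fraction, albumin = albumin,
                 regimen = regimen, n_subjects = n_subjects, seed = seed),
            class = "pta_result")
}

#' Default two-fold MIC ladder
#'
#' The exact two-fold dilution series starting at `from`, truncated at `to`:
#' the top rung is capped to `to` itself (64 mg/l by default), so the grid
#' spans the full reported MIC range.
#'
#' @param from,to Grid end points (mg/l).
#' @return Numeric vector `0.064, 0.128, ..., 32.768, 64`.
#' @export
mic_ladder <- function(from = 0.064, to = 64) {
  g <- from * 2^(0:30)
  c(g[g < to], to)
}

# fraction of the steady-state interval above each MIC for every eta row
.tmic_fractions <- function(model, eta, cov, regimen, mic_grid) {
  n <- nrow(eta)
  frac <- matrix(NA_real_, n, length(mic_grid))
  tg <- sort(unique(c(seq(0, regimen$tau, length.out = 257),
                      regimen$duration)))
  for (i in seq_len(n)) {
    p <- individual_params(model, eta = eta[i, ], cov = cov)
    pr <- function(t) .conc_ss(t, p, regimen$dose, regimen$tau,
                               regimen$duration)
    cg <- pr(tg)
    for (m in seq_along(mic_grid))
      frac[i, m] <- .frac_above_grid(pr, cg, tg, mic_grid[m], regimen$tau)
  }
  frac
}

#' @export
print.pta_result <- function(x, ...) {
  cat(sprintf("PTA (%.0f%%T>MIC target), %d subjects, %g mg q%gh %gh infusion, albumin %.1f g/l\n",
              100 * x$target_fraction, x$n_subjects, x$regimen$dose,
              x$regimen$tau, x$regimen$duration, x$albumin))
  print(data.frame(mic = x$mic, pta = round(x$pta, 1)), row.names = FALSE)
  invisible(x)
}

#' @export
plot.pta_result <- function(x, ...) {
  graphics::plot(x$mic, x$pta, log = "x", type = "b", pch = 16,
                 xlab = "MIC (mg/l)", ylab = "PTA (%)", ylim = c(0, 100), ...)
  graphics::abline(h = 90, lty = 2)
  invisible(x)
}

#' PTA as a function of albumin concentration
#'
#' Runs [simulate_pta()] at a single MIC over a grid of albumin values
#' spanning the observed study range.  Under the reference model the PTA is
#' non-increasing in albumin: lower albumin inflates the central volume,
#' prolonging the terminal phase.
#'
#' @inheritParams simulate_pta
#' @param mic Single MIC (mg/l).
#' @param albumin_grid Albumin values (g/l).
#' @return A data.frame with columns `albumin` and `pta`.
#' @export
pta_vs_albumin <- function(model, regimen, target_fraction, mic,
                           albumin_grid = seq(15.6, 31.8, by = 2.025),
                           n_subjects = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pta <- vapply(albumin_grid, function(a) {
    simulate_pta(model, regimen, albumin = a,
                 target_fraction = target_fraction, mic_grid = mic,
                 n_subjects = n_subjects)$pta
  }, numeric(1))
  data.frame(albumin = albumin_grid, pta = pta)
}

#' Highest MIC attaining a PTA level
#'
#' Finds the largest MIC at which the PTA curve stays at or above `level`,
#' interpolating linearly in log2-MIC between adjacent grid points.  If the
#' curve never reaches the level the result is censored below the grid
#' (`-Inf` with `censored = "below"`); if it stays above the level on the
#' whole grid the top-of-grid MIC is returned flagged `censored = "above"`.
#'
#' @param pta_result A `pta_result` from [simulate_pta()].
#' @param level PTA level in percent (default 90).
#' @return A list with `mic` (mg/l) and `censored` (`"no"`, `"below"` or
#'   `"above"`).
#' @export
mic_at_pta <- function(pta_result, level = 90) {
  stopifnot(inherits(pta_result, "pta_result"))
  mic <- pta_result$mic
  pta <- pta_result$pta
  if (length(mic) < 2) stop("mic_at_pta needs a PTA curve over a MIC grid")
  if (all(pta >= level))
    return(list(mic = mic[length(mic)], censored = "above"))
  if (pta[1] < level)
    return(list(mic = -Inf, censored = "below"))
  i <- max(which(pta >= level))
  l2 <- log2(mic[i]) + (level - pta[i]) * (log2(mic[i + 1]) - log2(mic[i])) /
    (pta[i + 1] - pta[i])
  list(mic = 2^l2, censored = "no")
}

#' Dose multiplier to reach a PTA level at a MIC breakpoint
#'
#' By linearity of the kinetics, multiplying the dose by `fr` shifts the PTA
#' curve to `PTA_fr(mic) = PTA_1(mic / fr)`; the fold-increase in dose
#' needed to attain `level` percent PTA at `mic_breakpoint` is therefore
#' `mic_breakpoint / mic_at_pta(level)`.
#'
#' @inheritParams simulate_pta
#' @param mic_breakpoint Clinical MIC breakpoint (mg/l), default 2.
#' @param level Required PTA (percent), default 90.
#' @return A list with `multiplier`, the underlying `mic90` and the
#'   `pta_result` used.
#' @export
dose_multiplier <- function(model, regimen, albumin, target_fraction = 1,
                            mic_breakpoint = 2, level = 90,
                            mic_grid = mic_ladder(), n_subjects = 1000,
                            seed = NULL) {
  ptares <- simulate_pta(model, regimen, albumin = albumin,
                         target_fraction = target_fraction,
                         mic_grid = mic_grid, n_subjects = n_subjects,
                         seed = seed)
  m90 <- mic_at_pta(ptares, level)
  if (m90$censored != "no")
    stop("PTA level ", level, "% is censored ", m90$censored,
         " the MIC grid; cannot form a dose multiplier")
  list(multiplier = mic_breakpoint / m90$mic, mic90 = m90$mic,
       pta_result = ptares)
}

#' Rescale a PTA curve to a different dose
#'
#' Exact re-indexing of the MIC grid under dose-linearity: with dose-scaling
#' factor `fr = dose / 1000`, the PTA at MIC `m` under the new dose equals
#' the PTA at `m / fr` under the reference dose, so the curve is carried
#' over with its MIC grid multiplied by `fr`.
#'
#' @param pta_result A `pta_result`.
#' @param fr Dose-scaling factor (> 0), `dose / 1000` for a 1 g reference.
#' @return A new `pta_result` with rescaled MIC grid and dose.
#' @export
shift_pta_for_dose <- function(pta_result, fr) {
  stopifnot(inherits(pta_result, "pta_result"), fr > 0)
  out <- pta_result
  out$mic <- pta_result$mic * fr
  out$regimen$dose <- pta_result$regimen$dose * fr
  out
}

#' PTA with parameter uncertainty from bootstrap replicates
#'
#' Recomputes the PTA curve for each bootstrap parameter set and summarizes
#' the curves pointwise by the median and the 5th-95th percentile band,
#' propagating parameter uncertainty into the attainment probabilities.
#'
#' @param boot_params A matrix or data.frame of bootstrap parameter sets
#'   (columns as produced by [bootstrap_fit()]: `V1`, `CL`, `Q`, `V2`,
#'   optional `beta_V1_albumin`, `omega2_*`, `sigma_*`), or a
#'   `pk_bootstrap` object.
#' @param template_model A [population_model()] supplying the model
#'   structure (covariate law forms, references) for every set.
#' @inheritParams simulate_pta
#' @param n_subjects Simulated subjects per bootstrap set.
#' @return A data.frame with columns `mic`, `median`, `lower5`, `upper95`.
#' @export
pta_with_uncertainty <- function(boot_params, template_model, regimen,
                                 albumin, target_fraction,
                                 mic_grid = mic_ladder(), n_subjects = 500,
                                 seed = NULL) {
  if (inherits(boot_params, "pk_bootstrap")) boot_params <- boot_params$estimates
  boot_params <- as.matrix(boot_params)
  if (!is.null(seed)) set.seed(seed)
  # common random numbers: one standard-normal eta block shared by every
  # parameter set, so the band reflects parameter uncertainty only (and
  # identical sets give an exactly zero-width band)
  enames <- .eta_names(template_model)
  z <- matrix(rnorm(n_subjects * length(enames)), n_subjects)
  curves <- matrix(NA_real_, nrow(boot_params), length(mic_grid))
  for (b in seq_len(nrow(boot_params))) {
    m <- .model_from_flat(boot_params[b, ], template_model)
    eta <- z %*% diag(sqrt(m$omega2[enames]), length(enames))
    colnames(eta) <- enames
    frac <- .tmic_fractions(m, eta, list(albumin = albumin), regimen,
                            mic_grid)
    curves[b, ] <- 100 * colMeans(frac >= target_fraction - 1e-12)
  }
  data.frame(mic = mic_grid,
             median = apply(curves, 2, median),
             lower5 = apply(curves, 2, .pct, 0.05),
             upper95 = apply(curves, 2, .pct, 0.95))
}

# Rebuild a population model from a flat named parameter vector, using a
# template for structure (covariate-law forms and references).
.model_from_flat <- function(par, template) {
  m <- template
  for (nm in names(template$theta))
    if (nm %in% names(par)) m$theta[nm] <- par[[nm]]
  for (j in seq_along(m$covariate_laws)) {
    l <- m$covariate_laws[[j]]
    key <- paste0("beta_", l$param, "_", l$covariate)
    if (key %in% names(par)) m$covariate_laws[[j]]$theta_beta <- par[[key]]
  }
  for (nm in names(m$omega2)) {
    key <- paste0("omega2_", nm)
    if (key %in% names(par)) m$omega2[nm] <- par[[key]]
  }
  if ("sigma_add" %in% names(par)) m$sigma["add"] <- par[["sigma_add"]]
  if ("sigma_prop" %in% names(par)) m$sigma["prop"] <- par[["sigma_prop"]]
  m
}
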