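#' Covariate law on a population parameter
#'
#' Describes how a subject-level covariate scales the typical value of one
#' structural parameter.  Three forms are supported, all evaluated
#' multiplicatively on the typical value `theta_P`:
#' \describe{
#'   \item{power}{`theta_P * (COV / ref)^theta_beta` -- `ref` is the
#'     covariate reference (study median), frozen at model-build time.}
#'   \item{linear}{`theta_P * (1 + theta_beta * (COV - ref))`.}
#'   \item{indicator}{`theta_P * (1 + theta_beta * IND)` for a 0/1 covariate.}
#' }
#' Both continuous forms equal `theta_P` exactly at `COV == ref`.
#'
#' @param param Target parameter name: one of `"V1"`, `"CL"`, `"Q"`, `"V2"`.
#' @param covariate Covariate name as stored in the subject covariate list
#'   (lower case, e.g. `"albumin"`).
#' @param form `"power"`, `"linear"` or `"indicator"`.
#' @param theta_beta Regression/power coefficient.
#' @param ref Covariate reference value (required for the continuous forms;
#'   must be positive for the power form).
#' @return An object of class `covariate_law`.
#' @examples
#' covariate_law("V1", "albumin", "power", theta_beta = -2.87, ref = 24.6)
#' @export
covariate_law <- function(param, covariate,
                          form = c("power", "linear", "indicator"),
                          theta_beta, ref = NA_real_) {
  form <- match.arg(form)
  param <- match.arg(param, c("V1", "CL", "Q", "V2"))
  if (form == "power" && (!is.finite(ref) || ref <= 0))
    stop("the power form needs a positive covariate reference value")
  if (form == "linear" && !is.finite(ref))
    stop("the linear form needs a covariate reference value")
  structure(list(param = param, covariate = covariate, form = form,
                 theta_beta = theta_beta, ref = ref),
            class = "covariate_law")
}

#' Population pharmacokinetic model
#'
#' Bundles the fixed effects (typical parameter values), the log-normal
#' inter-individual variability (IIV) variances, the combined
#' additive + proportional residual-error model and the covariate laws.
#' Individual parameters follow `P_i = theta_P * c_i * exp(eta_P)` where
#' `c_i` is the product of the covariate-law factors and
#' `eta_P ~ N(0, omega2_P)`; parameters with `omega2 == 0` carry no random
#' effect.  Observed concentrations follow
#' `C_obs = C1 * (1 + eps_prop) + eps_add` with independent normal errors.
#'
#' @param theta Named numeric vector of typical values; `c(V1=, CL=, Q=,
#'   V2=)` for the two-compartment model, `c(V1=, CL=)` for one compartment.
#' @param omega2 Named numeric vector of IIV variances (log scale); names
#'   must be a subset of the names of `theta`.  A value of exactly 0 fixes
#'   the IIV of that parameter to zero (no eta).
#' @param sigma Numeric vector `c(add = , prop = )`: the SD of the additive
#'   component (mg/l) and of the proportional component (dimensionless).
#' @param covariate_laws List of [covariate_law()] objects.
#' @param n_compartments 1 or 2.
#' @return An object of class `population_model`.
#' @seealso [meropenem_reference_model()] for the bundled reference
#'   estimates.
#' @export
population_model <- function(theta, omega2 = NULL, sigma = c(add = 0, prop = 0),
                             covariate_laws = list(), n_compartments = 2) {
  pnames <- if (n_compartments == 2) c("V1", "CL", "Q", "V2") else c("V1", "CL")
  if (!all(pnames %in% names(theta)))
    stop("theta must carry named entries ", paste(pnames, collapse = ", "))
  theta <- theta[pnames]
  if (any(theta <= 0)) stop("typical volumes and clearances must be positive")
  if (is.null(omega2)) omega2 <- setNames(rep(0, length(pnames)), pnames)
  full <- setNames(rep(0, length(pnames)), pnames)
  full[names(omega2)] <- omega2
  if (any(full < 0)) stop("IIV variances must be non-negative")
  sigma <- c(add = unname(sigma["add"]), prop = unname(sigma["prop"]))
  if (any(is.na(sigma)) || any(sigma < 0) || all(sigma == 0))
    stop("sigma must have non-negative 'add' and 'prop' entries, not both 0")
  for (law in covariate_laws) {
    if (!inherits(law, "covariate_law")) stop("covariate_laws must be covariate_law objects")
    if (!law$param %in% pnames)
      stop("covariate law targets unknown parameter ", law$param)
  }
  structure(list(theta = theta, omega2 = full, sigma = sigma,
                 covariate_laws = covariate_laws,
                 n_compartments = n_compartments),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf("Population PK model (%d-compartment)\n", x$n_compartments))
  cat("  theta:", paste(sprintf("%s = %.4g", names(x$theta), x$theta),
                        collapse = ", "), "\n")
  cat("  omega2:", paste(sprintf("%s = %.4g (%.1f %%CV)", names(x$omega2),
                                 x$omega2, omega2_to_cv(x$omega2)),
                         collapse = ", "), "\n")
  cat(sprintf("  sigma: add = %.4g mg/l, prop = %.4g\n",
              x$sigma["add"], x$sigma["prop"]))
  for (law in x$covariate_laws)
    cat(sprintf("  %s ~ %s (%s, theta_beta = %.4g, ref = %.4g)\n",
                law$param, law$covariate, law$form, law$theta_beta, law$ref))
  invisible(x)
}

#' Reference population model for meropenem during CRRT
#'
#' The final population estimates bundled with the package: typical values
#' `V1 = 27.9 l`, `V2 = 33.7 l`, `CL = 15.1 l/h`, `Q = 21.1 l/h` for a
#' patient with serum albumin 24.6 g/l, an albumin power law on the central
#' volume `V1_i = 27.9 * (ALB_i / 24.6)^-2.87 * exp(eta)`, log-normal IIV of
#' 53.1 / 43.7 / 85.6 %CV on V1 / CL / V2 (IIV on Q fixed to zero), and a
#' combined residual error with additive SD 0.881 mg/l and proportional SD
#' 24.1 %CV.
#'
#' @return A [population_model()].
#' @examples
#' mod <- meropenem_reference_model()
#' individual_params(mod, cov = list(albumin = 24.6))
#' @export
meropenem_reference_model <- function() {
  population_model(
    theta = c(V1 = 27.9, CL = 15.1, Q = 21.1, V2 = 33.7),
    omega2 = c(V1 = cv_to_omega2(53.1), CL = cv_to_omega2(43.7), Q = 0,
               V2 = cv_to_omega2(85.6)),
    sigma = c(add = 0.881, prop = 0.241),
    covariate_laws = list(
      covariate_law("V1", "albumin", "power", theta_beta = -2.87, ref = 24.6))
  )
}

# Names of the parameters carrying a random effect, in fixed order.
.eta_names <- function(model) {
  names(model$omega2)[model$omega2 > 0]
}

# Multiplicative covariate factor per structural parameter for one subject.
.cov_factors <- function(model, cov) {
  fac <- setNames(rep(1, length(model$theta)), names(model$theta))
  for (law in model$covariate_laws) {
    v <- cov[[law$covariate]]
    if (is.null(v) || is.na(v))
      stop("covariate '", law$covariate, "' required by the law on ",
           law$param, " is missing")
    fac[law$param] <- fac[law$param] * switch(
      law$form,
      power = (v / law$ref)^law$theta_beta,
      linear = 1 + law$theta_beta * (v - law$ref),
      indicator = 1 + law$theta_beta * v)
  }
  fac
}

#' Individual structural parameters
#'
#' Applies the covariate laws to the typical values and then the log-normal
#' random effects: `P_i = theta_P * c_i(cov) * exp(eta_P)`.
#'
#' @param model A [population_model()].
#' @param eta Named numeric vector of random effects; entries default to 0
#'   and etas on zero-variance parameters must be 0.
#' @param cov Named list of covariate values for the subject.
#' @return A [structural_params()] object (or its one-compartment analogue
#'   as a plain list when `n_compartments == 1`).
#' @examples
#' m <- meropenem_reference_model()
#' individual_params(m, eta = c(V1 = 0.1), cov = list(albumin = 15.6))
#' @export
individual_params <- function(model, eta = NULL, cov = list()) {
  stopifnot(inherits(model, "population_model"))
  full_eta <- setNames(rep(0, length(model$theta)), names(model$theta))
  if (!is.null(eta)) {
    if (is.null(names(eta))) names(eta) <- .eta_names(model)[seq_along(eta)]
    full_eta[names(eta)] <- eta
  }
  if (any(!is.finite(full_eta))) stop("eta must be finite")
  p <- model$theta * .cov_factors(model, cov) * exp(full_eta)
  if (any(p <= 0))
    stop("covariate laws produced a non-positive parameter; check linear-law coefficients")
  if (model$n_compartments == 2)
    structural_params(V1 = p[["V1"]], V2 = p[["V2"]], CL = p[["CL"]], Q = p[["Q"]])
  else
    structure(list(V1 = p[["V1"]], CL = p[["CL"]]), class = "one_cpt_params")
}

#' Residual error variance at a predicted concentration
#'
#' Variance of an observation under the combined error model
#' `C_obs = pred * (1 + eps_prop) + eps_add`:
#' `sigma_add^2 + pred^2 * sigma_prop^2`.
#'
#' @param pred Predicted concentration(s), mg/l; must be non-negative.
#' @param sigma Numeric vector `c(add = , prop = )` of SDs, or a
#'   [population_model()] from which `sigma` is taken.
#' @return Residual variance(s), (mg/l)^2.
#' @examples
#' residual_variance(10, c(add = 0.881, prop = 0.241))
#' @export
residual_variance <- function(pred, sigma) {
  if (inherits(sigma, "population_model")) sigma <- sigma$sigma
  if (any(pred < 0)) stop("predicted concentrations must be non-negative")
  unname(sigma["add"])^2 + pred^2 * unname(sigma["prop"])^2
}

#' Convert between log-normal IIV variance and percent CV
#'
#' The coefficient of variation of a log-normal random effect with log-scale
#' variance `omega2` is `100 * sqrt(exp(omega2) - 1)` percent; the two
#' functions are exact inverses.
#'
#' @param cv_percent CV in percent.
#' @param omega2 Log-scale variance.
#' @return The converted value.
#' @examples
#' cv_to_omega2(53.1)
#' omega2_to_cv(cv_to_omega2(53.1))
#' @export
cv_to_omega2 <- function(cv_percent) {
  if (any(cv_percent < 0)) stop("CV must be non-negative")
  log(1 + (cv_percent / 100)^2)
}

#' @rdname cv_to_omega2
#' @export
omega2_to_cv <- function(omega2) {
  if (any(omega2 < 0)) stop("omega2 must be non-negative")
  100 * sqrt(exp(omega2) - 1)
}

#' Simulate one subject's observations from a population model
#'
#' Draws the random effects `eta ~ N(0, Omega)` (zero-variance entries are
#' exactly 0), builds the individual parameters, evaluates the concentration
#' profile for the dosing schedule, and optionally adds residual error
#' according to the combined error model.  Simulated observations may be
#' negative through the additive error component; they are returned as-is to
#' preserve the generative model (relevant for predictive checks).
#'
#' Randomness comes from the current R random number generator; seed with
#' `set.seed()` for reproducibility.
#'
#' @param model A [population_model()].
#' @param cov Named list of covariates for the subject.
#' @param schedule An [infusion_schedule()].
#' @param times Observation times (h).
#' @param with_residual Add residual error? (default `TRUE`).
#' @param eta Optional fixed eta vector (named); drawn when `NULL`.
#' @return A list with `observations` (data.frame `time`, `concentration`),
#'   `eta` (the drawn random effects) and `params` (individual
#'   [structural_params()]).
#' @export
simulate_subject <- function(model, cov, schedule, times,
                             with_residual = TRUE, eta = NULL) {
  enames <- .eta_names(model)
  if (is.null(eta)) {
    eta <- setNames(rnorm(length(enames), 0, sqrt(model$omega2[enames])),
                    enames)
  }
  p <- individual_params(model, eta = eta, cov = cov)
  conc <- if (model$n_compartments == 2) .conc_doses(times, p, schedule)
  else .cpp_conc_profile(times, schedule$start, schedule$duration,
                         schedule$rate, c(p$V1, p$CL), 1L)
  if (with_residual) {
    conc <- conc * (1 + rnorm(length(conc), 0, model$sigma["prop"])) +
      rnorm(length(conc), 0, model$sigma["add"])
  }
  list(observations = data.frame(time = times, concentration = conc),
       eta = eta, params = p)
}

#' Write / read a population model as JSON
#'
#' Serializes the model in a human-readable layout mirroring a standard
#' parameter table: typical values, IIV variances with %CV convenience
#' fields, residual SDs and covariate laws.
#'
#' @param model A [population_model()].
#' @param path File path.
#' @return `write_model_json` returns `path` invisibly; `read_model_json`
#'   returns the reconstructed [population_model()].
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "population_model"))
  obj <- list(
    n_compartments = model$n_compartments,
    theta = as.list(model$theta),
    omega2 = as.list(model$omega2),
    iiv_cv_percent = as.list(omega2_to_cv(model$omega2)),
    sigma = list(add = unname(model$sigma["add"]),
                 prop = unname(model$sigma["prop"])),
    covariate_laws = lapply(model$covariate_laws, function(l)
      list(param = l$param, covariate = l$covariate, form = l$form,
           theta_beta = l$theta_beta, ref = l$ref)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  laws <- lapply(obj$covariate_laws, function(l)
    covariate_law(l$param, l$covariate, l$form, l$theta_beta,
                  l$ref %||% NA_real_))
  population_model(
    theta = unlist(obj$theta),
    omega2 = unlist(obj$omega2),
    sigma = c(add = obj$sigma$add, prop = obj$sigma$prop),
    covariate_laws = laws,
    n_compartments = obj$n_compartments)
}
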