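# Shared oracles and fixture builders.  These deliberately use the R-level
# closed-form profile (itself pinned against the ODE integrator) rather than
# the compiled estimation path, so likelihood checks cross two independent
# implementations.

# Penalized deviance g(eta) for a single subject with one random effect on
# `eta_param`, matching the estimator's definition including constants.
toy_g <- function(eta, model, eta_param, doses, times, y, cov = list()) {
  ev <- setNames(eta, eta_param)
  p <- individual_params(model, eta = ev, cov = cov)
  f <- concentration_profile(p, doses, times)
  v <- residual_variance(f, model$sigma)
  o2 <- model$omega2[[eta_param]]
  sum(log(2 * pi * v) + (y - f)^2 / v) + eta^2 / o2 + log(2 * pi * o2)
}

# -2 log marginal likelihood by adaptive quadrature over a single eta.
quad_ofv <- function(model, eta_param, doses, times, y, cov = list(),
                     half_width = 8) {
  integrand <- function(e) vapply(e, function(x)
    exp(-0.5 * toy_g(x, model, eta_param, doses, times, y, cov)), numeric(1))
  w <- half_width * sqrt(model$omega2[[eta_param]])
  -2 * log(integrate(integrand, -w, w, rel.tol = 1e-10)$value)
}

# Toy model: IIV on one parameter only.
toy_model <- function(eta_param = "V1", omega2 = 0.25,
                      sigma = c(add = 0.5, prop = 0.15)) {
  o2 <- c(V1 = 0, CL = 0, Q = 0, V2 = 0)
  o2[eta_param] <- omega2
  population_model(theta = c(V1 = 27.9, CL = 15.1, Q = 21.1, V2 = 33.7),
                   omega2 = o2, sigma = sigma)
}

ref_structural <- function() structural_params(27.9, 33.7, 15.1, 21.1)

# Random but physiologic parameter draw for property tests.
random_structural <- function() {
  structural_params(V1 = runif(1, 5, 120), V2 = runif(1, 5, 120),
                    CL = runif(1, 2, 40), Q = runif(1, 2, 60))
}

# Small synthetic dataset with a known generating model, for fit tests.
small_cohort <- function(n = 12, seed = 1, model = meropenem_reference_model(),
                         n_first_dose = ceiling(n / 2)) {
  generate_cohort(cohort_config(n_subjects = n, true_model = model,
                                n_first_dose = n_first_dose), seed = seed)
}

final_spec <- function() {
  model_spec(covariate_laws = list(
    covariate_law("V1", "albumin", "power", -1, ref = 24.6)))
}
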