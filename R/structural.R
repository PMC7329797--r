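#' Structural two-compartment parameters for one individual
#'
#' Kinetic constants of the disposition model: meropenem distributes between
#' a central compartment (volume `V1`, l) and a peripheral compartment
#' (volume `V2`, l) connected by the inter-compartmental clearance `Q` (l/h),
#' and is eliminated from the central compartment by the CRRT circuit with
#' clearance `CL` (l/h).  CRRT is the only elimination route modelled; renal
#' and non-renal clearance are not represented.
#'
#' @param V1 Central volume of distribution (l).
#' @param V2 Peripheral volume of distribution (l).
#' @param CL Systemic (CRRT) clearance (l/h).
#' @param Q Inter-compartmental clearance (l/h).
#' @return An object of class `structural_params`.
#' @examples
#' structural_params(V1 = 27.9, V2 = 33.7, CL = 15.1, Q = 21.1)
#' @export
structural_params <- function(V1, V2, CL, Q) {
  vals <- c(V1 = V1, CL = CL, Q = Q, V2 = V2)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all structural parameters (V1, V2, CL, Q) must be strictly positive")
  structure(as.list(vals), class = "structural_params")
}

#' @export
print.structural_params <- function(x, ...) {
  cat(sprintf("Two-compartment parameters: V1 = %.4g l, V2 = %.4g l, CL = %.4g l/h, Q = %.4g l/h\n",
              x$V1, x$V2, x$CL, x$Q))
  invisible(x)
}

# micro constants and bi-exponential machinery ------------------------------

.micro_constants <- function(p) {
  list(k10 = p$CL / p$V1, k12 = p$Q / p$V1, k21 = p$Q / p$V2)
}

#' Macro (bi-exponential) disposition constants
#'
#' Roots of the characteristic quadratic of the linear two-compartment
#' system, `x^2 - (k10 + k12 + k21) x + k10 k21 = 0`, together with the
#' fractional coefficients of the central-compartment unit-bolus response
#' `C(t) = (A exp(-alpha t) + B exp(-beta t)) / V1` with `A + B = 1`.
#'
#' For strictly positive parameters the discriminant equals
#' `(k10 - k21)^2 + k12^2 + 2 k12 (k10 + k21) > 0`, so the two rates are
#' always real and distinct (`alpha > beta > 0`); a repeated root cannot
#' occur.
#'
#' @param p A [structural_params()] object.
#' @return A list with elements `alpha`, `beta` (1/h) and bolus coefficients
#'   `A`, `B` (dimensionless, summing to 1).
#' @examples
#' macro_constants(structural_params(27.9, 33.7, 15.1, 21.1))
#' @export
macro_constants <- function(p) {
  stopifnot(inherits(p, "structural_params"))
  k <- .micro_constants(p)
  s <- k$k10 + k$k12 + k$k21
  disc <- sqrt(s^2 - 4 * k$k10 * k$k21)
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  list(alpha = alpha, beta = beta,
       A = (alpha - k$k21) / disc, B = (k$k21 - beta) / disc)
}

# Concentration from a superposition of zero-order infusions.  `doses` is a
# data.frame(start, duration, rate).  Single expression covers both branches:
# with s = t - start, u = min(s, D), v = max(s - D, 0),
#   contribution = (R/V1) * sum_x (coef_x / x) (1 - e^{-x u}) e^{-x v}.
.conc_doses <- function(times, p, doses) {
  mac <- macro_constants(p)
  out <- numeric(length(times))
  for (d in seq_len(nrow(doses))) {
    s <- times - doses$start[d]
    live <- s > 0
    if (!any(live)) next
    u <- pmin(s[live], doses$duration[d])
    v <- pmax(s[live] - doses$duration[d], 0)
    acc <- 0
    for (term in list(c(mac$A, mac$alpha), c(mac$B, mac$beta)))
      acc <- acc + (term[1] / term[2]) * (1 - exp(-term[2] * u)) * exp(-term[2] * v)
    out[live] <- out[live] + (doses$rate[d] / p$V1) * acc
  }
  out
}

# Steady-state concentration within one dosing interval [0, tau), infusion of
# duration D at rate R starting at t = 0.  Geometric accumulation of the
# post-infusion exponentials of all earlier doses.
.conc_ss <- function(times, p, dose, tau, duration) {
  mac <- macro_constants(p)
  rate <- dose / duration
  out <- numeric(length(times))
  for (term in list(c(mac$A, mac$alpha), c(mac$B, mac$beta))) {
    x <- term[2]
    r <- exp(-x * tau)
    u <- pmin(times, duration)
    v <- pmax(times - duration, 0)
    out <- out + (rate * term[1] / (x * p$V1)) *
      ((1 - exp(-x * u)) * exp(-x * v) +
         (1 - exp(-x * duration)) * exp(-x * (times - duration)) * r / (1 - r))
  }
  out
}

#' Infusion schedule
#'
#' An ordered set of zero-order infusion events.  Each event carries its
#' start time (h), amount (mg) and duration (h); the rate (mg/h) is
#' `amount / duration`.
#'
#' @param start Numeric vector of infusion start times (h).
#' @param amount Numeric vector of dose amounts (mg).
#' @param duration Numeric vector of infusion durations (h).
#' @return A data.frame with columns `start`, `amount`, `duration`, `rate`,
#'   ordered by start time.
#' @examples
#' infusion_schedule(start = c(0, 8, 16), amount = 1000, duration = 1)
#' @export
infusion_schedule <- function(start, amount, duration) {
  df <- data.frame(start = start, amount = amount, duration = duration)
  if (any(df$amount <= 0)) stop("dose amounts must be positive")
  if (any(df$duration <= 0)) stop("infusion durations must be positive")
  if (any(df$start < 0)) stop("dose start times must be non-negative")
  df$rate <- df$amount / df$duration
  df[order(df$start), , drop = FALSE]
}

#' Central-compartment concentration profile
#'
#' Closed-form central concentration after an arbitrary schedule of
#' zero-order infusions, by superposition of the bi-exponential solution of
#' the two-compartment system.  This is the production evaluation path;
#' [ode_oracle()] provides an independent numerical reference.
#'
#' @param p A [structural_params()] object.
#' @param schedule A schedule from [infusion_schedule()] (or any data.frame
#'   with columns `start`, `duration`, `rate`).
#' @param times Non-negative times (h) at which to evaluate.
#' @return Numeric vector of central concentrations (mg/l).
#' @examples
#' p <- structural_params(27.9, 33.7, 15.1, 21.1)
#' concentration_profile(p, infusion_schedule(0, 1000, 1), times = 0:8)
#' @export
concentration_profile <- function(p, schedule, times) {
  stopifnot(inherits(p, "structural_params"))
  if (any(times < 0)) stop("times must be non-negative")
  .conc_doses(times, p, schedule)
}

#' Steady-state concentration profile over one dosing interval
#'
#' Periodic steady state for repeated identical infusions every `tau` hours,
#' computed by geometric-series accumulation of the exponential terms.  The
#' result agrees with brute-force superposition of many repeated doses (see
#' the structural test suite).
#'
#' @param p A [structural_params()] object.
#' @param dose Dose amount (mg).
#' @param tau Dosing interval (h).
#' @param duration Infusion duration (h); must be shorter than `tau`.
#' @param times Times within `[0, tau]` (h), measured from infusion start.
#' @return Numeric vector of central concentrations (mg/l).
#' @examples
#' p <- structural_params(27.9, 33.7, 15.1, 21.1)
#' steady_state_profile(p, dose = 1000, tau = 8, duration = 1,
#'                      times = seq(0, 8, by = 2))
#' @export
steady_state_profile <- function(p, dose, tau, duration, times) {
  stopifnot(inherits(p, "structural_params"))
  if (duration >= tau)
    stop("infusion duration must be shorter than the dosing interval tau")
  if (any(times < 0 | times > tau))
    stop("times must lie within one dosing interval [0, tau]")
  .conc_ss(times, p, dose, tau, duration)
}

#' Numerical reference solution of the two-compartment infusion model
#'
#' Integrates the mass-balance system
#' `V1 dC1/dt = -Q C1 + Q C2 - CL C1 + R(t)` and
#' `V2 dC2/dt = Q C1 - Q C2` with `deSolve::lsoda`, splitting the
#' integration at every infusion on/off boundary so the discontinuous input
#' rate `R(t)` is handled exactly.  Intended as an independent oracle for
#' [concentration_profile()] in tests, not as a production path.
#'
#' @inheritParams concentration_profile
#' @param rel_tol Relative tolerance of the integrator (must be `<= 1e-8`).
#' @return Numeric vector of central concentrations (mg/l) at `times`.
#' @export
ode_oracle <- function(p, schedule, times, rel_tol = 1e-10) {
  stopifnot(inherits(p, "structural_params"))
  if (rel_tol > 1e-8) stop("rel_tol must be <= 1e-8 for an oracle solution")
  if (any(times < 0)) stop("times must be non-negative")
  if (nrow(schedule) == 0 || all(schedule$rate == 0))
    return(numeric(length(times)))
  rate_at <- function(t) {
    on <- t >= schedule$start & t < schedule$start + schedule$duration
    sum(schedule$rate[on])
  }
  deriv <- function(t, y, parms) {
    list(c((-p$Q * y[1] + p$Q * y[2] - p$CL * y[1] + rate_at(t)) / p$V1,
           (p$Q * y[1] - p$Q * y[2]) / p$V2))
  }
  breaks <- sort(unique(c(0, schedule$start,
                          schedule$start + schedule$duration, times)))
  breaks <- breaks[breaks <= max(times)]
  sol <- deSolve::lsoda(c(C1 = 0, C2 = 0), breaks, deriv, parms = NULL,
                        rtol = rel_tol, atol = rel_tol * 1e-2)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE solver failed: istate = ", attr(sol, "istate")[1])
  sol[match(times, sol[, "time"]), "C1"]
}
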