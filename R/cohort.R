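#' Configuration of a synthetic study cohort
#'
#' Describes the virtual trial the generator emulates: adult ICU patients on
#' CRRT receiving 1 g meropenem as a 1-h infusion every 8 h, with arterial
#' samples drawn just before and 15, 30, 45, 60, 75, 90, 120, 180, 240 and
#' 480 min after the start of one monitored infusion.  A configurable
#' fraction of the cohort is sampled around the first dose; the remainder is
#' sampled at steady state after several days of therapy (the generator
#' administers enough preceding doses to pass ten terminal half-lives).
#' Covariates are drawn to match the observed demographics: albumin from a
#' scaled Beta distribution on 15.6-31.8 g/l with median 24.6, body weight
#' uniform on 60-100 kg, age from a left-skewed scaled Beta on 36-79 years,
#' and sepsis status with probability increasing as albumin falls.
#'
#' @param n_subjects Cohort size (default 19).
#' @param true_model The generating [population_model()]; defaults to
#'   [meropenem_reference_model()].
#' @param regimen A [dosing_regimen()] (default 1000 mg q8h, 1-h infusion).
#' @param sampling_times Sampling times within one interval (h from infusion
#'   start).
#' @param n_first_dose How many subjects are sampled at the first dose
#'   (default 9; the rest are sampled at steady state).
#' @param albumin_range,albumin_median Range and median (g/l) of the albumin
#'   distribution.
#' @param weight_range Body-weight range (kg).
#' @param age_range Age range (years).
#' @param contamination_rate Expected number of spurious positive predose
#'   records per observation (default 0); contamination is applied to the
#'   predose sample of first-dose subjects.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 19,
                          true_model = meropenem_reference_model(),
                          regimen = dosing_regimen(1000, 8, 1),
                          sampling_times = c(0, 0.25, 0.5, 0.75, 1, 1.25,
                                             1.5, 2, 3, 4, 8),
                          n_first_dose = round(9 * n_subjects / 19),
                          albumin_range = c(15.6, 31.8),
                          albumin_median = 24.6,
                          weight_range = c(60, 100),
                          age_range = c(36, 79),
                          contamination_rate = 0) {
  if (n_first_dose > n_subjects) stop("n_first_dose cannot exceed n_subjects")
  if (contamination_rate < 0 || contamination_rate > 1)
    stop("contamination_rate must lie in [0, 1]")
  if (any(sampling_times < 0) || any(sampling_times > regimen$tau))
    stop("sampling times must lie within one dosing interval")
  structure(list(n_subjects = n_subjects, true_model = true_model,
                 regimen = regimen, sampling_times = sort(sampling_times),
                 n_first_dose = n_first_dose,
                 albumin_range = albumin_range,
                 albumin_median = albumin_median,
                 weight_range = weight_range, age_range = age_range,
                 contamination_rate = contamination_rate),
            class = "cohort_config")
}

# Shape parameters of a Beta(a, b) on [0, 1] whose median equals `q` given
# a; solved once per call (cheap) rather than frozen, so non-default ranges
# keep the requested median.
.beta_b_for_median <- function(q, a) {
  uniroot(function(b) qbeta(0.5, a, b) - q, c(0.05, 200), tol = 1e-10)$root
}

#' Generate a synthetic study cohort with known ground truth
#'
#' Draws covariates, random effects and residual errors from the generating
#' model and returns both the event-record dataset and the underlying truth
#' (per-subject etas and structural parameters) for estimator validation.
#' Predose samples of drug-naive subjects are recorded as 0 mg/l (no drug,
#' no assay signal) unless contamination is requested, in which case a
#' contaminated record receives a spurious positive concentration.
#' Steady-state subjects receive six preceding doses (48 h of therapy, more
#' than ten terminal half-lives of the typical patient) before the monitored
#' interval.
#'
#' @param config A [cohort_config()].
#' @param seed Optional integer seed.
#' @return A list of class `simulated_cohort`: `dataset` (a
#'   [pk_dataset()]), `truth` (data.frame of etas, structural parameters and
#'   covariates per subject) and `config`.
#' @examples
#' sim <- generate_cohort(cohort_config(n_subjects = 4), seed = 1)
#' design_summary(sim$dataset)
#' @export
generate_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_subjects
  model <- config$true_model
  reg <- config$regimen
  # covariates
  alb_q <- (config$albumin_median - config$albumin_range[1]) /
    diff(config$albumin_range)
  alb <- config$albumin_range[1] + diff(config$albumin_range) *
    rbeta(n, 2, .beta_b_for_median(alb_q, 2))
  wt <- runif(n, config$weight_range[1], config$weight_range[2])
  age_q <- 0.72  # study median 67 on range 36-79
  age <- config$age_range[1] + diff(config$age_range) *
    rbeta(n, 3, .beta_b_for_median(age_q, 3))
  sepsis <- rbinom(n, 1, plogis((config$albumin_median - alb) / 2))
  first_dose <- seq_len(n) <= config$n_first_dose
  n_prior <- 6L  # 48 h of q8h therapy before the monitored interval
  eta_rows <- params_rows <- vector("list", n)
  subjects <- vector("list", n)
  n_obs_total <- n * length(config$sampling_times)
  p_contam <- if (config$n_first_dose > 0)
    min(1, config$contamination_rate * n_obs_total / config$n_first_dose)
  else 0
  for (i in seq_len(n)) {
    offset <- if (first_dose[i]) 0 else n_prior * reg$tau
    doses <- infusion_schedule(start = seq(0, offset, by = reg$tau),
                               amount = reg$dose, duration = reg$duration)
    times <- offset + config$sampling_times
    cov <- list(albumin = alb[i], weight = wt[i], age = age[i],
                sepsis = sepsis[i])
    sim <- simulate_subject(model, cov, doses, times, with_residual = TRUE)
    conc <- sim$observations$concentration
    conc[conc < 0] <- 0.05  # assay floor: reported below LLOQ, flagged later
    if (first_dose[i]) {
      # drug-naive predose sample: no analyte, recorded as a missing DV
      pre <- abs(times - 0) < 1e-9
      conc[pre] <- NA_real_
      if (p_contam > 0 && any(pre) && runif(1) < p_contam)
        conc[pre] <- runif(sum(pre), 0.5, 3)
    }
    obs <- data.frame(time = times, concentration = conc)
    subjects[[i]] <- subject_record(sprintf("S%02d", i), doses, obs, cov)
    eta_rows[[i]] <- sim$eta
    params_rows[[i]] <- unlist(sim$params[c("V1", "CL", "Q", "V2")])
  }
  dataset <- pk_dataset(subjects, lloq = 0.1,
                        metadata = list(source = "synthetic", units = "h, mg/l"))
  truth <- data.frame(id = vapply(subjects, function(s) s$id, character(1)),
                      first_dose = first_dose,
                      albumin = alb, weight = wt, age = age, sepsis = sepsis,
                      do.call(rbind, params_rows),
                      eta = do.call(rbind, eta_rows))
  structure(list(dataset = dataset, truth = truth, config = config),
            class = "simulated_cohort")
}

#' Summarize the design of a PK dataset
#'
#' @param dataset A [pk_dataset()].
#' @return A list with subject/observation counts, the split between
#'   first-dose and steady-state sampling, exclusion/below-LLOQ counts and
#'   covariate medians and ranges.
#' @export
design_summary <- function(dataset) {
  stopifnot(inherits(dataset, "pk_dataset"))
  subs <- dataset$subjects
  n_obs <- vapply(subs, function(s) nrow(s$observations), integer(1))
  n_dose <- vapply(subs, function(s) nrow(s$doses), integer(1))
  cov_names <- unique(unlist(lapply(subs, function(s) names(s$covariates))))
  covs <- lapply(cov_names, function(nm) {
    v <- vapply(subs, function(s) {
      x <- s$covariates[[nm]]
      if (is.null(x) || !is.numeric(x)) NA_real_ else x
    }, numeric(1))
    if (all(is.na(v))) NULL
    else c(median = median(v, na.rm = TRUE), min = min(v, na.rm = TRUE),
           max = max(v, na.rm = TRUE))
  })
  names(covs) <- cov_names
  list(n_subjects = length(subs),
       n_observations = sum(n_obs),
       n_excluded = sum(vapply(subs, function(s) sum(s$observations$excluded),
                               integer(1))),
       n_below_lloq = sum(vapply(subs, function(s)
         sum(s$observations$below_lloq), integer(1))),
       n_first_dose = sum(n_dose == 1),
       n_steady_state = sum(n_dose > 1),
       covariates = covs[!vapply(covs, is.null, logical(1))])
}
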