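#' @title Event-record PK datasets
#'
#' @description
#' The package stores concentration-time data in the event-record form used
#' throughout pharmacometrics: each subject carries an ordered set of dose
#' events (zero-order infusions), an ordered set of observations, and a set
#' of covariates.  Internal units are fixed: time in hours, concentration in
#' mg/l (equivalently ug/ml) and dose amounts in mg, so that clearances are
#' in l/h.
#'
#' @param id Subject identifier (coerced to character).
#' @param doses A data.frame with columns `start` (h), `amount` (mg) and
#'   `duration` (h); `rate` (mg/h) is derived as `amount / duration` when
#'   absent.
#' @param observations A data.frame with columns `time` (h) and
#'   `concentration` (mg/l); flag columns `below_lloq`, `excluded` and
#'   `exclude_reason` are added when absent.
#' @param covariates Named list of subject-level covariates (e.g. `albumin`
#'   in g/l, `weight` in kg).
#' @return `subject_record()` returns an object of class `subject_record`.
#' @name pk-data
NULL

#' @rdname pk-data
#' @export
subject_record <- function(id, doses, observations, covariates = list()) {
  if (!is.data.frame(doses)) doses <- as.data.frame(doses)
  if (!is.data.frame(observations)) observations <- as.data.frame(observations)
  if (nrow(doses) > 0) {
    if (is.null(doses$rate)) doses$rate <- doses$amount / doses$duration
    bad <- abs(doses$rate * doses$duration - doses$amount) >
      1e-9 * pmax(doses$amount, 1)
    if (any(bad)) stop("dose rate * duration must equal amount")
    if (any(doses$amount <= 0) || any(doses$duration <= 0))
      stop("dose amount and duration must be positive")
    if (any(doses$start < 0) || is.unsorted(doses$start))
      stop("dose times must be non-negative and sorted")
  }
  if (nrow(observations) > 0) {
    if (any(observations$time < 0) || is.unsorted(observations$time))
      stop("observation times must be non-negative and sorted")
    cc <- observations$concentration
    if (any(!is.na(cc) & cc < 0))
      stop("observed concentrations must be non-negative")
  }
  for (fl in c("below_lloq", "excluded"))
    if (is.null(observations[[fl]])) observations[[fl]] <- rep(FALSE, nrow(observations))
  if (is.null(observations$exclude_reason))
    observations$exclude_reason <- rep(NA_character_, nrow(observations))
  structure(list(id = as.character(id), doses = doses,
                 observations = observations, covariates = covariates),
            class = "subject_record")
}

#' Assemble a PK dataset
#'
#' @param subjects List of [subject_record()] objects with unique ids.
#' @param lloq Lower limit of quantitation of the assay (mg/l); observations
#'   with `0 < concentration < lloq` are flagged `below_lloq` and are skipped
#'   by the estimation routines (flag-and-discard handling).
#' @param metadata Optional named list (units, provenance notes).
#' @return An object of class `pk_dataset`.
#' @export
pk_dataset <- function(subjects, lloq = 0.1, metadata = list()) {
  ids <- vapply(subjects, function(s) s$id, character(1))
  if (anyDuplicated(ids)) stop("subject ids must be unique")
  nobs <- sum(vapply(subjects, function(s) nrow(s$observations), integer(1)))
  if (nobs == 0) stop("dataset must contain at least one observation")
  subjects <- lapply(subjects, function(s) {
    o <- s$observations
    o$below_lloq <- !is.na(o$concentration) & o$concentration > 0 &
      o$concentration < lloq
    s$observations <- o
    s
  })
  structure(list(subjects = subjects, lloq = lloq, metadata = metadata),
            class = "pk_dataset")
}

#' @export
print.pk_dataset <- function(x, ...) {
  ns <- length(x$subjects)
  no <- sum(vapply(x$subjects, function(s) nrow(s$observations), integer(1)))
  nexcl <- sum(vapply(x$subjects, function(s) sum(s$observations$excluded),
                      integer(1)))
  cat(sprintf("PK dataset: %d subjects, %d observations (%d excluded), LLOQ %.3g mg/l\n",
              ns, no, nexcl, x$lloq))
  invisible(x)
}

.required_cols <- c("ID", "TIME", "AMT", "RATE", "DV", "EVID", "MDV")

#' Read a NONMEM-style event-record dataset
#'
#' Parses a rectangular CSV with the de facto pharmacometric event-record
#' layout: columns `ID, TIME, AMT, RATE, DV, EVID, MDV` plus any number of
#' covariate columns; `"."` or empty cells denote missing values.  Rows with
#' `EVID == 1` become dose events (infusion duration `AMT / RATE`); rows
#' with `EVID == 0` and `MDV == 0` become observations.  An optional `EXCL`
#' flag column (with `EXCLREASON`) round-trips record exclusions.
#'
#' @param path Path to the CSV file.
#' @param lloq Assay lower limit of quantitation (mg/l) used to flag
#'   below-LLOQ observations.
#' @param time_units `"hours"` (default) or `"minutes"`; times are converted
#'   to hours internally.
#' @return A [pk_dataset()].
#' @export
read_pk_dataset <- function(path, lloq = 0.1,
                            time_units = c("hours", "minutes")) {
  time_units <- match.arg(time_units)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  miss <- setdiff(.required_cols, names(raw))
  if (length(miss))
    stop("event-record file is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  num <- function(x) suppressWarnings(as.numeric(ifelse(x %in% c(".", ""), NA, x)))
  tab <- data.frame(ID = raw$ID, TIME = num(raw$TIME), AMT = num(raw$AMT),
                    RATE = num(raw$RATE), DV = num(raw$DV),
                    EVID = num(raw$EVID), MDV = num(raw$MDV),
                    stringsAsFactors = FALSE)
  if (time_units == "minutes") tab$TIME <- tab$TIME / 60
  bad_amt <- which(!is.na(tab$AMT) & tab$AMT < 0)
  if (length(bad_amt))
    stop("negative AMT in row ", bad_amt[1])
  bad_dv <- which(!is.na(tab$DV) & tab$DV < 0)
  if (length(bad_dv))
    stop("negative DV in row ", bad_dv[1])
  excl <- if (!is.null(raw$EXCL)) num(raw$EXCL) == 1 else rep(FALSE, nrow(raw))
  reason <- if (!is.null(raw$EXCLREASON))
    ifelse(raw$EXCLREASON %in% c(".", ""), NA_character_, raw$EXCLREASON)
  else rep(NA_character_, nrow(raw))
  covcols <- setdiff(names(raw), c(.required_cols, "EXCL", "EXCLREASON"))
  subjects <- lapply(unique(tab$ID), function(id) {
    rows <- tab$ID == id
    sub <- tab[rows, , drop = FALSE]
    dr <- sub$EVID == 1
    doses <- data.frame(start = sub$TIME[dr], amount = sub$AMT[dr],
                        duration = sub$AMT[dr] / sub$RATE[dr])
    obr <- sub$EVID == 0
    dv <- sub$DV[obr]
    dv[!is.na(sub$MDV[obr]) & sub$MDV[obr] == 1] <- NA_real_  # MDV=1: no DV
    obs <- data.frame(time = sub$TIME[obr], concentration = dv,
                      excluded = excl[rows][obr],
                      exclude_reason = reason[rows][obr])
    covs <- lapply(covcols, function(cc) {
      v <- num(raw[[cc]][rows])
      if (all(is.na(v))) {
        ch <- raw[[cc]][rows]
        ch[ch %in% c(".", "")][1]
      } else v[!is.na(v)][1]
    })
    names(covs) <- tolower(covcols)
    subject_record(id, doses[order(doses$start), , drop = FALSE],
                   obs[order(obs$time), , drop = FALSE], covs)
  })
  pk_dataset(subjects, lloq = lloq,
             metadata = list(source = path, time_units = "hours"))
}

#' Flatten a PK dataset to an event-record table
#'
#' @param x A [pk_dataset()].
#' @param ... Unused.
#' @return A data.frame in `ID, TIME, AMT, RATE, DV, EVID, MDV, EXCL,
#'   EXCLREASON, <covariates>` layout, times in hours.
#' @export
as.data.frame.pk_dataset <- function(x, ...) {
  rows <- lapply(x$subjects, function(s) {
    covs <- s$covariates
    covdf <- if (length(covs))
      as.data.frame(lapply(covs, function(v) v %||% NA), check.names = FALSE)
    else NULL
    dose_rows <- if (nrow(s$doses)) data.frame(
      ID = s$id, TIME = s$doses$start, AMT = s$doses$amount,
      RATE = s$doses$rate, DV = NA_real_, EVID = 1, MDV = 1,
      EXCL = 0, EXCLREASON = NA_character_, stringsAsFactors = FALSE)
    obs_rows <- if (nrow(s$observations)) data.frame(
      ID = s$id, TIME = s$observations$time, AMT = NA_real_, RATE = NA_real_,
      DV = s$observations$concentration, EVID = 0,
      MDV = as.integer(is.na(s$observations$concentration)),
      EXCL = as.integer(s$observations$excluded),
      EXCLREASON = s$observations$exclude_reason, stringsAsFactors = FALSE)
    out <- rbind(dose_rows, obs_rows)
    out <- out[order(out$TIME, -out$EVID), , drop = FALSE]
    if (!is.null(covdf)) out <- cbind(out, covdf[rep(1, nrow(out)), , drop = FALSE])
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  names(res) <- c(names(res)[1:9], toupper(names(res)[-(1:9)]))
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a PK dataset as an event-record CSV
#'
#' The written file round-trips through [read_pk_dataset()]: numeric fields
#' are preserved to full double precision and exclusion flags/reasons are
#' kept in `EXCL` / `EXCLREASON` columns.
#'
#' @param dataset A [pk_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pk_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "pk_dataset"))
  df <- as.data.frame(dataset)
  for (nm in names(df))
    if (is.numeric(df[[nm]])) df[[nm]] <- format(df[[nm]], digits = 17,
                                                 trim = TRUE, scientific = FALSE)
  df[is.na(df) | df == "NA"] <- "."
  ok <- tryCatch({ write.csv(df, path, row.names = FALSE, quote = FALSE); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok)) stop("could not write dataset to '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}

#' Exclude positive predose concentrations
#'
#' Flags observations taken at the start of a subject's very first recorded
#' dose that are nonetheless positive.  Such samples cannot reflect the
#' modelled dosing history for a drug-naive subject and are treated as
#' outliers; the records are retained with `excluded = TRUE` and reason
#' `"predose-positive"` rather than deleted, so exclusion reports stay
#' reproducible.  Subjects sampled during ongoing therapy (recorded prior
#' doses before the sampled interval) legitimately have positive troughs at
#' dose start and are untouched.  The operation is idempotent.
#'
#' @param dataset A [pk_dataset()].
#' @return A list with elements `dataset` (flagged copy) and `report`
#'   (data.frame of subject, time and concentration for each exclusion).
#' @export
exclude_predose_positive <- function(dataset) {
  stopifnot(inherits(dataset, "pk_dataset"))
  report <- list()
  dataset$subjects <- lapply(dataset$subjects, function(s) {
    if (nrow(s$doses) == 0) return(s)
    t0 <- min(s$doses$start)
    prior <- any(s$doses$start < t0 - 1e-9)  # by construction FALSE; kept explicit
    if (prior) return(s)
    o <- s$observations
    hit <- abs(o$time - t0) < 1e-9 & !is.na(o$concentration) &
      o$concentration > 0
    if (any(hit)) {
      o$excluded[hit] <- TRUE
      o$exclude_reason[hit] <- "predose-positive"
      s$observations <- o
      report[[length(report) + 1]] <<- data.frame(
        subject = s$id, time = o$time[hit],
        concentration = o$concentration[hit], stringsAsFactors = FALSE)
    }
    s
  })
  report <- if (length(report)) do.call(rbind, report)
  else data.frame(subject = character(), time = numeric(),
                  concentration = numeric(), stringsAsFactors = FALSE)
  list(dataset = dataset, report = report)
}

# Observations usable for estimation: not excluded, not below LLOQ, non-missing.
.fit_observations <- function(subject) {
  o <- subject$observations
  o[!o$excluded & !o$below_lloq & !is.na(o$concentration), , drop = FALSE]
}
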