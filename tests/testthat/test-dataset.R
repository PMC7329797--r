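# Event-record I/O, unit handling, LLOQ flagging and the predose-positive
# exclusion rule.

write_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("a minimal dose + observation table parses into one subject", {
  path <- write_fixture(c(
    "ID,TIME,AMT,RATE,DV,EVID,MDV,ALB",
    "1,0,1000,1000,.,1,1,24.6",
    "1,0.5,.,.,30.2,0,0,24.6",
    "1,2,.,.,12.1,0,0,24.6"))
  d <- read_pk_dataset(path, lloq = 0.1)
  expect_length(d$subjects, 1)
  s <- d$subjects[[1]]
  expect_equal(nrow(s$doses), 1)
  expect_equal(s$doses$duration, 1)       # AMT / RATE
  expect_equal(s$doses$rate, 1000)
  expect_equal(nrow(s$observations), 2)
  expect_equal(s$observations$concentration, c(30.2, 12.1))
  expect_equal(s$covariates$alb, 24.6)
})

test_that("minute-scale files are converted to hours", {
  path <- write_fixture(c(
    "ID,TIME,AMT,RATE,DV,EVID,MDV",
    "1,0,1000,1000,.,1,1",
    "1,480,.,.,2.4,0,0"))
  d <- read_pk_dataset(path, lloq = 0.1, time_units = "minutes")
  expect_equal(d$subjects[[1]]$observations$time, 8)
  expect_equal(d$subjects[[1]]$doses$duration, 1)  # AMT/RATE stays in hours
})

test_that("below-LLOQ observations are flagged, not dropped", {
  path <- write_fixture(c(
    "ID,TIME,AMT,RATE,DV,EVID,MDV",
    "1,0,1000,1000,.,1,1",
    "1,6,.,.,0.05,0,0",
    "1,8,.,.,0,0,0"))
  d <- read_pk_dataset(path, lloq = 0.1)
  o <- d$subjects[[1]]$observations
  expect_equal(o$below_lloq, c(TRUE, FALSE))  # a recorded 0 is not 0 < c < lloq
  expect_equal(nrow(o), 2)
})

test_that("malformed files raise informative errors", {
  path <- write_fixture(c("ID,TIME,DV", "1,0,1"))
  expect_error(read_pk_dataset(path), "mandatory column")
  path2 <- write_fixture(c(
    "ID,TIME,AMT,RATE,DV,EVID,MDV",
    "1,0,-5,1000,.,1,1"))
  expect_error(read_pk_dataset(path2), "negative AMT in row 1")
  path3 <- write_fixture(c(
    "ID,TIME,AMT,RATE,DV,EVID,MDV",
    "1,1,.,.,-2,0,0"))
  expect_error(read_pk_dataset(path3), "negative DV")
})

test_that("predose-positive samples of drug-naive subjects are excluded", {
  naive <- subject_record("A", data.frame(start = 0, amount = 1000,
                                          duration = 1),
                          data.frame(time = c(0, 2),
                                     concentration = c(1.2, 15)))
  ongoing <- subject_record("B", data.frame(start = c(0, 8, 16),
                                            amount = 1000, duration = 1),
                            data.frame(time = c(16, 18),
                                       concentration = c(8, 20)))
  d <- pk_dataset(list(naive, ongoing))
  res <- exclude_predose_positive(d)
  expect_equal(nrow(res$report), 1)
  expect_equal(res$report$subject, "A")
  expect_equal(res$report$concentration, 1.2)
  oA <- res$dataset$subjects[[1]]$observations
  expect_true(oA$excluded[1])
  expect_equal(oA$exclude_reason[1], "predose-positive")
  expect_false(oA$excluded[2])
  # the ongoing-therapy subject's positive trough at its own dose time stays
  expect_false(any(res$dataset$subjects[[2]]$observations$excluded))
})

test_that("exclusion is idempotent and vacuous without time-zero samples", {
  s <- subject_record("C", data.frame(start = 0, amount = 1000, duration = 1),
                      data.frame(time = c(1, 2), concentration = c(20, 11)))
  d <- pk_dataset(list(s))
  r1 <- exclude_predose_positive(d)
  expect_equal(nrow(r1$report), 0)
  expect_identical(as.data.frame(r1$dataset), as.data.frame(d))
  naive <- subject_record("A", data.frame(start = 0, amount = 1000,
                                          duration = 1),
                          data.frame(time = c(0, 2),
                                     concentration = c(1.2, 15)))
  r2 <- exclude_predose_positive(pk_dataset(list(naive)))
  r3 <- exclude_predose_positive(r2$dataset)
  expect_identical(as.data.frame(r3$dataset), as.data.frame(r2$dataset))
})

test_that("datasets round-trip through the event-record CSV losslessly", {
  set.seed(101)
  for (seed in 1:3) {
    sim <- generate_cohort(cohort_config(n_subjects = 5,
                                         contamination_rate = 0.02),
                           seed = seed)
    d <- exclude_predose_positive(sim$dataset)$dataset
    path <- withr::local_tempfile(fileext = ".csv")
    write_pk_dataset(d, path)
    d2 <- read_pk_dataset(path, lloq = d$lloq)
    expect_equal(length(d2$subjects), length(d$subjects))
    for (i in seq_along(d$subjects)) {
      a <- d$subjects[[i]]; b <- d2$subjects[[i]]
      expect_identical(b$id, a$id)
      expect_equal(b$doses$start, a$doses$start, tolerance = 1e-12)
      expect_equal(b$doses$amount, a$doses$amount, tolerance = 1e-12)
      expect_equal(b$doses$duration, a$doses$duration, tolerance = 1e-12)
      expect_equal(b$observations$time, a$observations$time,
                   tolerance = 1e-12)
      expect_equal(b$observations$concentration,
                   a$observations$concentration, tolerance = 1e-12)
      expect_identical(b$observations$excluded, a$observations$excluded)
      expect_identical(b$observations$below_lloq, a$observations$below_lloq)
      expect_equal(b$covariates$albumin, a$covariates$albumin,
                   tolerance = 1e-12)
    }
  }
})

test_that("a subject without observations survives the round trip", {
  s1 <- subject_record("E", data.frame(start = 0, amount = 1000, duration = 1),
                       data.frame(time = numeric(), concentration = numeric()))
  s2 <- subject_record("F", data.frame(start = 0, amount = 1000, duration = 1),
                       data.frame(time = 2, concentration = 14))
  d <- pk_dataset(list(s1, s2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_pk_dataset(d, path)
  d2 <- read_pk_dataset(path)
  expect_length(d2$subjects, 2)
  expect_equal(nrow(d2$subjects[[1]]$observations), 0)
  expect_equal(nrow(d2$subjects[[1]]$doses), 1)
})

test_that("storing times in minutes or hours yields identical records", {
  sim <- generate_cohort(cohort_config(n_subjects = 3), seed = 9)
  d <- sim$dataset
  path_h <- withr::local_tempfile(fileext = ".csv")
  write_pk_dataset(d, path_h)
  tab <- read.csv(path_h, colClasses = "character")
  num <- suppressWarnings(as.numeric(tab$TIME))
  tab$TIME <- format(num * 60, digits = 17, trim = TRUE, scientific = FALSE)
  # minutes file needs RATE unchanged (mg/h); only TIME is rescaled
  path_m <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, path_m, row.names = FALSE, quote = FALSE)
  d_h <- read_pk_dataset(path_h)
  d_m <- read_pk_dataset(path_m, time_units = "minutes")
  for (i in seq_along(d_h$subjects))
    expect_equal(d_m$subjects[[i]]$observations$time,
                 d_h$subjects[[i]]$observations$time, tolerance = 1e-12)
})

test_that("dataset invariants are enforced", {
  expect_error(subject_record("X", data.frame(start = 0, amount = 1000,
                                              duration = 1, rate = 500),
                              data.frame(time = 1, concentration = 1)),
               "rate")
  expect_error(subject_record("X", data.frame(start = 0, amount = 1000,
                                              duration = 1),
                              data.frame(time = c(2, 1),
                                         concentration = c(1, 2))),
               "sorted")
  s <- subject_record("X", data.frame(start = 0, amount = 1000, duration = 1),
                      data.frame(time = 1, concentration = 5))
  expect_error(pk_dataset(list(s, s)), "unique")
})
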