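# Two-compartment infusion kinetics: closed form, macro constants, steady
# state, and agreement with the independent ODE integration.

test_that("macro constants solve the characteristic quadratic", {
  p <- ref_structural()
  mac <- macro_constants(p)
  # roots computed independently via polyroot on the characteristic quadratic
  expect_equal(mac$alpha, 1.7274382355, tolerance = 1e-9)
  expect_equal(mac$beta, 0.1961655636, tolerance = 1e-9)
  k10 <- p$CL / p$V1; k12 <- p$Q / p$V1; k21 <- p$Q / p$V2
  expect_equal(mac$alpha * mac$beta, k10 * k21, tolerance = 1e-10)
  expect_equal(mac$alpha + mac$beta, k10 + k12 + k21, tolerance = 1e-10)
  expect_equal(mac$A + mac$B, 1, tolerance = 1e-12)
  # algebraic identity alpha*beta*V1*V2 = CL*Q
  expect_equal(mac$alpha * mac$beta * p$V1 * p$V2, p$CL * p$Q,
               tolerance = 1e-10)
  expect_gt(mac$alpha, mac$beta)
  expect_gt(mac$beta, 0)
})

test_that("macro constants approach the one-compartment limit as Q -> 0", {
  p <- structural_params(V1 = 27.9, V2 = 33.7, CL = 15.1, Q = 1e-7)
  mac <- macro_constants(p)
  expect_equal(mac$alpha, p$CL / p$V1, tolerance = 1e-6)
})

test_that("non-positive structural parameters are rejected", {
  expect_error(structural_params(-1, 33.7, 15.1, 21.1), "positive")
  expect_error(structural_params(27.9, 33.7, 0, 21.1), "positive")
})

test_that("closed-form profile matches the ODE oracle on the typical patient", {
  p <- ref_structural()
  sch <- infusion_schedule(0, 1000, 1)
  tt <- c(0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6, 8)
  cf <- concentration_profile(p, sch, tt)
  od <- ode_oracle(p, sch, tt)
  expect_lt(max(abs(cf - od) / od), 1e-6)
})

test_that("closed form and ODE oracle agree on random parameter draws", {
  set.seed(401)
  sch <- infusion_schedule(c(0, 8), 1000, 1)
  tt <- c(0.5, 1, 2.5, 7, 9, 12)
  for (i in 1:30) {
    p <- random_structural()
    cf <- concentration_profile(p, sch, tt)
    od <- ode_oracle(p, sch, tt)
    expect_lt(max(abs(cf - od) / pmax(od, 1e-12)), 1e-6)
  }
})

test_that("profile starts at zero and is linear in dose", {
  p <- ref_structural()
  sch1 <- infusion_schedule(0, 1000, 1)
  sch2 <- infusion_schedule(0, 2000, 1)
  tt <- c(0, 0.5, 1, 3, 8)
  c1 <- concentration_profile(p, sch1, tt)
  c2 <- concentration_profile(p, sch2, tt)
  expect_identical(c1[1], 0)
  expect_identical(c2, 2 * c1)
  expect_error(concentration_profile(p, sch1, c(-1, 2)), "non-negative")
})

test_that("profile is continuous at the end of the infusion", {
  p <- ref_structural()
  sch <- infusion_schedule(0, 1000, 1)
  cmax <- concentration_profile(p, sch, 1)
  gap <- abs(diff(concentration_profile(p, sch, c(1 - 1e-12, 1 + 1e-12))))
  expect_lt(gap, 1e-10 * cmax)
})

test_that("mass balance: clearance times AUC recovers the dose", {
  p <- ref_structural()
  sch <- infusion_schedule(0, 1000, 1)
  auc <- integrate(function(t) concentration_profile(p, sch, t), 0, Inf,
                   rel.tol = 1e-10)$value
  expect_equal(p$CL * auc, 1000, tolerance = 1e-6)
})

test_that("mass balance holds through time in the ODE solution", {
  # V1 C1 + V2 C2 + eliminated = infused, checked by augmenting the oracle
  p <- ref_structural()
  deriv <- function(t, y, parms) {
    rate <- if (t < 1) 1000 else 0
    list(c((-p$Q * y[1] + p$Q * y[2] - p$CL * y[1] + rate) / p$V1,
           (p$Q * y[1] - p$Q * y[2]) / p$V2,
           p$CL * y[1],                      # cumulative eliminated
           rate))                            # cumulative infused
  }
  sol <- deSolve::lsoda(c(0, 0, 0, 0), c(0, 0.5, 1, 2, 5, 10), deriv,
                        parms = NULL, rtol = 1e-10, atol = 1e-10)
  held <- p$V1 * sol[-1, 2] + p$V2 * sol[-1, 3] + sol[-1, 4]
  expect_lt(max(abs(held - sol[-1, 5]) / sol[-1, 5]), 1e-8)
})

test_that("steady-state profile obeys the AUC = dose / CL identity", {
  p <- ref_structural()
  tg <- seq(0, 8, length.out = 28801)  # 1-second grid
  css <- steady_state_profile(p, 1000, 8, 1, tg)
  auc <- sum(diff(tg) * (css[-1] + css[-length(css)]) / 2)
  expect_equal(auc, 1000 / 15.1, tolerance = 1e-6)
})

test_that("steady state equals brute-force superposition of many doses", {
  set.seed(402)
  for (i in 1:5) {
    p <- random_structural()
    t_half <- log(2) / macro_constants(p)$beta
    n_dose <- ceiling(30 * t_half / 8) + 2  # truncation ~2^-30, below the 1e-6 gate
    many <- infusion_schedule(seq(0, (n_dose - 1) * 8, 8), 1000, 1)
    tt <- c(0.5, 1, 4, 7.5)
    direct <- concentration_profile(p, many, (n_dose - 1) * 8 + tt)
    ss <- steady_state_profile(p, 1000, 8, 1, tt)
    expect_lt(max(abs(direct - ss) / ss), 1e-6)
  }
})

test_that("steady state accumulates relative to a single dose", {
  p <- ref_structural()
  tt <- c(0.5, 2, 7.9)
  single <- concentration_profile(p, infusion_schedule(0, 1000, 1), tt)
  ss <- steady_state_profile(p, 1000, 8, 1, tt)
  expect_true(all(ss >= single))
  # tau -> infinity: steady state collapses onto the single-dose profile
  ss_inf <- steady_state_profile(p, 1000, 1e6, 1, tt)
  expect_equal(ss_inf, single, tolerance = 1e-9)
  expect_error(steady_state_profile(p, 1000, 8, 9, tt), "shorter")
})

test_that("ODE oracle is self-consistent and handles the zero-dose case", {
  p <- ref_structural()
  sch <- infusion_schedule(0, 1000, 1)
  tt <- c(0.5, 2, 6)
  coarse <- ode_oracle(p, sch, tt, rel_tol = 1e-8)
  fine <- ode_oracle(p, sch, tt, rel_tol = 1e-11)
  expect_lt(max(abs(coarse - fine) / fine), 1e-7)
  zero <- infusion_schedule(0, 1, 1)
  zero$rate <- 0
  expect_identical(ode_oracle(p, zero, tt), c(0, 0, 0))
  expect_error(ode_oracle(p, sch, tt, rel_tol = 1e-6), "1e-8")
})

test_that("infusion schedules validate their events", {
  expect_error(infusion_schedule(0, -5, 1), "positive")
  expect_error(infusion_schedule(0, 1000, 0), "positive")
  sch <- infusion_schedule(c(8, 0), 1000, 1)
  expect_equal(sch$start, c(0, 8))  # ordered
  expect_equal(sch$rate, c(1000, 1000))
})
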