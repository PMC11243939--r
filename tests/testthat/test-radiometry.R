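# Expected values below were frozen from independent closed-form evaluation
# of the estimator, the uncertainty budget and the detection-limit formula.

test_that("activity estimator matches closed-form evaluation", {
  cal <- detector_calibration(epsilon = 0.35)
  # independent evaluation: 0.04 * exp(ln2*72/64.2) / (0.35*0.7*1*0.5)
  expect_equal(activity_concentration(0.05, 0.01, 72, 0.7, 0.5, cal),
               0.04 * 2^(72 / 64.2) / 0.1225, tolerance = 1e-12)
  expect_equal(round(activity_concentration(0.05, 0.01, 72, 0.7, 0.5, cal), 4),
               0.7104)
  # zero net rate and vanishing decay factor
  expect_equal(activity_concentration(0.02, 0.02, 50, 0.7, 0.5, cal), 0)
  expect_equal(activity_concentration(0.05, 0.01, 0, 0.7, 0.5, cal),
               0.04 / 0.1225)
  # negative net rate clamps to zero
  expect_equal(activity_concentration(0.01, 0.02, 10, 0.7, 0.5, cal), 0)
})

test_that("uncertainty budget combines in quadrature with the half-life term", {
  cal <- detector_calibration(epsilon = 0.35, u_epsilon_rel = 0.03,
                              d_eta_rel = 0.01)
  dT_rel <- log(2) * 72 * 0.05 / 64.2^2
  expect_equal(dT_rel, 6.054e-4, tolerance = 1e-3)
  dA <- activity_uncertainty(0.7104, dR_rel = 0.05, t_sep_h = 72,
                             d_eta_s_rel = 0.04, dm_rel = 0.001,
                             dT_half_h = 0.05, cal = cal)
  expect_equal(dA, 0.7104 * sqrt(0.05^2 + dT_rel^2 + 0.03^2 + 0.04^2 +
                                   0.01^2 + 0.001^2), tolerance = 1e-12)
  expect_equal(round(dA, 4), 0.0507)
  expect_equal(activity_uncertainty(0, 0.05), 0)
  expect_equal(activity_uncertainty(1, 0), 0)
})

test_that("detection limit matches the Currie form and is monotone", {
  cal <- detector_calibration(epsilon = 0.35)
  expect_equal(minimum_detectable_activity(0, 5400, 5400, 1, 1, cal),
               2.71 / 1890)
  expect_equal(round(minimum_detectable_activity(0.01, 5400, 5400, 0.7, 0.5, cal), 4),
               0.0558)
  # halving via counting time with fixed background counts
  expect_equal(minimum_detectable_activity(0.01, 5400, 10800, 0.7, 0.5, cal) /
                 minimum_detectable_activity(0.01, 5400, 5400, 0.7, 0.5, cal),
               0.5)
  # property: decreasing in efficiency, yield, mass, time; increasing in R0
  set.seed(99)
  for (i in 1:50) {
    eps <- runif(1, 0.1, 0.9); ys <- runif(1, 0.3, 1); m <- runif(1, 0.1, 2)
    ts <- runif(1, 1000, 10000); r0 <- runif(1, 0.001, 0.1)
    base <- minimum_detectable_activity(r0, 5400, ts, ys, m,
                                        detector_calibration(epsilon = eps))
    expect_lt(minimum_detectable_activity(r0, 5400, ts * 1.3, ys, m,
                                          detector_calibration(epsilon = eps)), base)
    expect_lt(minimum_detectable_activity(r0, 5400, ts, min(ys * 1.2, 1), m,
                                          detector_calibration(epsilon = eps)), base)
    expect_lt(minimum_detectable_activity(r0, 5400, ts, ys, m * 1.5,
                                          detector_calibration(epsilon = eps)), base)
    expect_gt(minimum_detectable_activity(r0 * 2, 5400, ts, ys, m,
                                          detector_calibration(epsilon = eps)), base)
  }
})

test_that("ingrowth fraction follows the closed form and reaches equilibrium", {
  expect_equal(ingrowth_fraction(0), 0)
  expect_equal(ingrowth_fraction(64.2), 0.5)
  expect_equal(round(ingrowth_fraction(336), 4), 0.9734)
  expect_gte(ingrowth_fraction(14 * 24), 0.97)
  t <- seq(0, 500, by = 10)
  expect_true(all(diff(ingrowth_fraction(t)) > 0))
  expect_error(ingrowth_fraction(-1), "non-negative")
})

test_that("sampling-date correction undoes parent decay", {
  expect_equal(decay_correct(1.5, 0), 1.5)
  expect_equal(decay_correct(1, 28.8 * 365.25), 2)
  # closed form: exp(ln2 * (30/365.25) / 28.8)
  expect_equal(decay_correct(1, 30), 1.0019787, tolerance = 1e-6)
})

test_that("record reduction censors at the reference-basis detection limit", {
  cal <- detector_calibration()
  recs <- rbind(example_record(R = 0.05),             # well above MDA
                example_record(R = 0.0102),           # marginal net rate
                example_record(R = 0.005))            # below background
  out <- reduce_counting_records(recs, cal)
  expect_equal(out$censored, c(FALSE, TRUE, TRUE))
  expect_equal(out$A[1], 0.7104, tolerance = 1e-4)
  expect_equal(out$dA_expanded[1], 2 * out$dA[1])
  # censored rows report the bound (reference-basis MDA), not an estimate
  mda_ref <- minimum_detectable_activity(0.01, 5400, 5400, 0.7, 0.5, cal) *
    2^(72 / 64.2)
  expect_equal(out$A[2], mda_ref)
  expect_true(is.na(out$dA[2]))
})

test_that("estimator is unbiased under the Poisson counting model", {
  set.seed(123)
  cal <- detector_calibration()
  A_true <- 2.5; eta_s <- 0.75; m <- 0.5; tS <- 5400; R0 <- 0.01; tsep <- 24
  mu <- A_true * cal$epsilon * eta_s * m * 2^(-tsep / 64.2)
  n <- 1e4
  Ns <- rpois(n, (mu + R0) * tS); N0 <- rpois(n, R0 * tS)
  A_hat <- activity_concentration(Ns / tS, N0 / tS, tsep, eta_s, m, cal)
  se <- sd(A_hat) / sqrt(n)
  expect_lt(abs(mean(A_hat) - A_true), 3 * se)
})
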