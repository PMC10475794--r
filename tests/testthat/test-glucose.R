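test_that("meal_response superposes, normalizes to the height, and shifts", {
  p <- glucose_params(0.9, 0.6, 0.6, 0.9, 0.1,
                      heights = c(lunch = 1.2, snack = 0.4))
  tt <- seq(0, 96, by = 0.05)
  # single meal: the response maximum equals its height (by construction);
  # evaluate at the analytic peak time, where the dense grid only bounds it
  pk <- wearssm:::cpp_impulse2_peak(p$A11, p$A12, p$A21, p$A22)
  r_pk <- meal_response(p, meal_log(10, "lunch"), 10 + pk$s_peak)
  expect_equal(r_pk, 1.2, tolerance = 1e-9)
  r1 <- meal_response(p, meal_log(10, "lunch"), tt)
  expect_lte(max(r1), 1.2 + 1e-9)
  expect_true(all(r1[tt <= 10] == 0))
  # linear superposition: two-event log equals the sum of single events
  ml <- meal_log(c(10, 40), c("lunch", "snack"))
  r2 <- meal_response(p, ml, tt)
  expect_equal(r2, r1 + meal_response(p, meal_log(40, "snack"), tt),
               tolerance = 1e-12)
  # identical meals 48 h apart: the second response replays the first
  p2 <- glucose_params(1, 0.7, 0.7, 1, 0.1, heights = c(m = 1))
  r3 <- meal_response(p2, meal_log(c(0, 48), c("m", "m")), seq(0, 96, 0.1))
  first <- r3[seq(0, 48, 0.1) * 10 + 1]
  second <- r3[(seq(48, 96, 0.1)) * 10 + 1]
  expect_equal(second, first, tolerance = 1e-9)
  # unknown label errors
  expect_error(meal_response(p, meal_log(1, "tea"), tt), "tea")
  # deterministic: repeated evaluation is bit-identical
  expect_identical(r2, meal_response(p, ml, tt))
})

test_that("circadian_baseline peaks at phi with amplitude A1", {
  expect_equal(circadian_baseline(4, 1, 15, 15), 5)
  expect_equal(circadian_baseline(4, 1, 15, 3), 4)
  tt <- seq(0, 24, length.out = 2401)[-2401]
  expect_equal(mean(circadian_baseline(4, 1, 15, tt)), 4.5,
               tolerance = 1e-10)
  expect_equal(circadian_baseline(4, 1, 15, 15 + 24),
               circadian_baseline(4, 1, 15, 15))
})

test_that("damping coefficient sign-classifies the eigenstructure", {
  expect_equal(damping_coefficient(diag(c(-1, -3))), 0.25)
  expect_equal(damping_coefficient(matrix(c(-1, 1, -1, -1), 2, 2)), -1)
  expect_equal(damping_coefficient(matrix(c(-1, 0, 1, -1), 2, 2)), 0)
  expect_error(damping_coefficient(matrix(c(1, 0, 0, -1), 2, 2)),
               "undefined")
  # oracle agreement on random stable 2x2 drifts: sign(damping) ==
  # sign classification from the eigen discriminant
  set.seed(5)
  for (i in 1:200) {
    repeat {
      W <- matrix(rnorm(4), 2, 2)
      ev <- eigen(W, only.values = TRUE)$values
      if (all(Re(ev) < 0) && abs(sum(diag(W))) > 1e-6) break
    }
    dc <- damping_coefficient(W)
    complex_ev <- is.complex(eigen(W, only.values = TRUE)$values) &&
      any(abs(Im(eigen(W, only.values = TRUE)$values)) > 1e-12)
    expect_identical(dc < 0, complex_ev)
  }
})

test_that("half_life matches analytic limits", {
  # time-scale separation: decay dominated by the slow eigenvalue
  p <- glucose_params(100, 1, 1, 0.5, 0.1, heights = c(m = 1))
  lam_slow <- max(Re(eigen(matrix(c(-100, 1, -1, -0.5), 2, 2),
                           only.values = TRUE)$values))
  expect_equal(half_life(p), log(2) / abs(lam_slow), tolerance = 0.01)
  # rate rescaling: doubling all rates halves the half-life
  p1 <- glucose_params(0.9, 0.5, 0.7, 1.1, 0.1)
  p2 <- glucose_params(1.8, 1.0, 1.4, 2.2, 0.1)
  expect_equal(half_life(p2), half_life(p1) / 2, tolerance = 1e-6)
  # near-critical damping ~ t exp(-a t), a = 1: half-life after the peak
  # at t = 1 is the root of t e^-t = 0.5 e^-1, minus 1 (~ 1.678)
  pc <- glucose_params(1, 1e-4, 1e-4, 1, 0.1)
  oracle <- uniroot(function(t) t * exp(-t) - 0.5 * exp(-1), c(1, 10),
                    tol = 1e-10)$root - 1
  expect_equal(half_life(pc), oracle, tolerance = 1e-3)
  expect_equal(oracle, 1.678, tolerance = 1e-3)
})

test_that("model1 log-likelihood agrees with the dense oracle and the generic engine", {
  p <- glucose_params(0.8, 0.6, 0.6, 0.9, 0.2,
                      heights = c(a = 1, b = 0.7), A0 = 4.5, A1 = 0.9,
                      phi = 15, sigma = 0.3)
  meals <- meal_log(c(0.6, 1.9, 3.1), c("a", "b", "a"))
  times <- seq(0.25, 2, by = 0.25)  # T = 8
  set.seed(8)
  y <- 4.5 + rnorm(8, 0, 0.5)
  rec <- make_glucose_record(times, y, meals)
  ll <- model1_loglik(p, rec)
  expect_equal(ll, model1_loglik(p, rec, engine = "generic"),
               tolerance = 1e-10)
  m <- model1_mean(p, meals, times)
  sys <- glucose_system(p)
  expect_equal(ll, joint_loglik(sys, times, matrix(y - m, ncol = 1),
                                H = matrix(c(0, 1), 1, 2), R = p$sigma^2),
               tolerance = 1e-8)
  # missingness: cpp and generic agree with gaps too
  rec2 <- make_glucose_record(times, y, meals,
                              missing = c(FALSE, TRUE, FALSE, FALSE, TRUE,
                                          FALSE, FALSE, FALSE))
  expect_equal(model1_loglik(p, rec2),
               model1_loglik(p, rec2, engine = "generic"),
               tolerance = 1e-10)
})

test_that("noise-free data reproduce the deterministic mean exactly", {
  p <- true_glucose_params()
  p$B22 <- 0
  meals <- meal_log(c(8, 13, 19), c("breakfast", "lunch", "dinner"))
  times <- seq(0.25, 48, by = 0.25)
  m <- model1_mean(p, meals, times)
  rec <- make_glucose_record(times, m, meals)
  # residuals y - (r + g) are exactly zero; with sigma fixed the loglik is
  # the iid normal density at zero
  expect_equal(model1_loglik(p, rec),
               sum(dnorm(0, 0, p$sigma, log = TRUE)) * length(times),
               tolerance = 1e-8)
})

test_that("large sigma approaches the iid Gaussian limit", {
  p <- glucose_params(1, 0.7, 0.7, 1, 1e-6, heights = c(m = 1),
                      A0 = 5, A1 = 0, phi = 0, sigma = 50)
  times <- seq(0.5, 24, by = 0.5)
  set.seed(3)
  y <- 5 + rnorm(length(times), 0, 0.3)
  rec <- make_glucose_record(times, y, meal_log(12, "m"))
  m <- model1_mean(p, rec$meals, times)
  iid <- sum(dnorm(y, m, p$sigma, log = TRUE))
  expect_equal(model1_loglik(p, rec), iid, tolerance = 1e-4)
})

test_that("the no-circadian variant nests the full model at A1 = 0", {
  p <- true_glucose_params()
  p$A1 <- 0
  gen <- generate_participant(scenario_spec(seed = 9, duration_days = 2,
                                            glucose = p))
  l_full <- model1_loglik(p, gen$record, circadian = TRUE)
  l_red <- model1_loglik(p, gen$record, circadian = FALSE)
  expect_equal(l_full, l_red, tolerance = 1e-10)
})

test_that("glucose_metrics reports event-weighted mean meal height", {
  p <- true_glucose_params(heights = c(a = 1, b = 2))
  ml <- meal_log(c(1, 2, 3), c("a", "a", "b"))
  m <- glucose_metrics(p, ml)
  expect_equal(m$mean_meal_height, (1 + 1 + 2) / 3)
  expect_equal(m$circadian_amplitude, 0.8)
  expect_equal(m$half_life, 1.5, tolerance = 1e-4)
  expect_equal(m$damping, -0.5, tolerance = 1e-12)
})
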