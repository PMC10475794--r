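test_that("the diffusion matrix encodes rho as a correlation", {
  p0 <- cardio_params(1, 1, 2, 1, 1.5, 1, 1, 1, rho = 0)
  expect_equal(wearssm:::cardio_Q(p0), diag(c(1, 1, 1)))
  p <- cardio_params(1, 1, 2, 1, 1.5, 1, 1, 1, rho = 0.99)
  ev <- eigen(wearssm:::cardio_Q(p)[2:3, 2:3], only.values = TRUE)$values
  expect_equal(sort(ev), c(0.01, 1.99), tolerance = 1e-12)
  expect_error(cardio_params(1, 1, 2, 1, 1.5, 1, 1, 1, rho = 1), "rho")
  # asymmetric intensities: off-diagonal is rho * sqrt(D22 D33)
  p2 <- cardio_params(1, 1, 2, 1, 1.5, 1, 4, 9, rho = 0.5)
  expect_equal(wearssm:::cardio_Q(p2)[2, 3], 0.5 * 6)
})

test_that("decoupled channels factorize the likelihood", {
  cp <- cardio_params(1, 0, 2, 0, 1.5, 1, 1, 1, rho = 0,
                      circ = list(act = c(0, 0.5, 14), hr = c(0, 0.4, 16),
                                  hrv = c(0, 0.3, 4)))
  sys <- build_cardio_system(cp)
  tt <- seq(0.25, 24, by = 0.25)
  m <- wearssm:::cardio_mean(cp, tt)
  set.seed(12)
  sim <- simulate_path(sys, tt, H = diag(3), m = m, R = diag(cp$sigma^2))
  rec <- make_cardio_record(tt, sim$y)
  l_joint <- model2_loglik(cp, rec)
  rates <- c(1, 2, 1.5)
  l_sum <- sum(vapply(1:3, function(j) {
    s1 <- lti_system(matrix(-rates[j]), matrix(1))
    kalman_filter(s1, tt, matrix(sim$y[, j], ncol = 1), H = 1,
                  m = matrix(m[, j], ncol = 1), R = cp$sigma[j]^2)$loglik
  }, 0))
  expect_equal(l_joint, l_sum, tolerance = 1e-8)
})

test_that("model2 likelihood matches the dense joint-Gaussian oracle", {
  cp <- true_cardio_params()
  sys <- build_cardio_system(cp)
  tt <- seq(0.3, 1.5, by = 0.3)  # T = 5
  m <- wearssm:::cardio_mean(cp, tt)
  set.seed(13)
  sim <- simulate_path(sys, tt, H = diag(3), m = m, R = diag(cp$sigma^2))
  y <- sim$y
  y[2, 3] <- NA; y[4, ] <- NA
  rec <- make_cardio_record(tt, y, missing = NULL)
  rec$series$hrv$values[2] <- NA; rec$series$hrv$missing[2] <- TRUE
  for (ch in wearssm:::cardio_channels) {
    rec$series[[ch]]$values[4] <- NA
    rec$series[[ch]]$missing[4] <- TRUE
  }
  expect_equal(model2_loglik(cp, rec),
               joint_loglik(sys, tt, y, H = diag(3), m = m,
                            R = diag(cp$sigma^2)),
               tolerance = 1e-8)
})

test_that("correlated HR-HRV noise is detected by the likelihood", {
  # data generated at rho = 0.8 prefer rho = 0.8 over rho = 0
  cp8 <- cardio_params(2, 3, 4, 2, 4, 2, 1.5, 1.5, rho = 0.8,
                       sigma = c(0.2, 0.2, 0.2))
  cp0 <- cp8; cp0$rho <- 0
  wins <- 0
  for (i in 1:10) {
    set.seed(300 + i)
    tt <- seq(0.1, 24, by = 0.1)
    sys <- build_cardio_system(cp8)
    m <- wearssm:::cardio_mean(cp8, tt)
    sim <- simulate_path(sys, tt, H = diag(3), m = m, R = diag(cp8$sigma^2))
    rec <- make_cardio_record(tt, sim$y)
    wins <- wins + (model2_loglik(cp8, rec) > model2_loglik(cp0, rec))
  }
  expect_gte(wins, 9)  # spec example: >= 18/20; run at 10 replicates
})

test_that("conditional predictions honour the information structure", {
  cp <- true_cardio_params()
  tt <- seq(0.25, 48, by = 0.25)
  set.seed(14)
  sys <- build_cardio_system(cp)
  m <- wearssm:::cardio_mean(cp, tt)
  sim <- simulate_path(sys, tt, H = diag(3), m = m, R = diag(cp$sigma^2))
  rec <- make_cardio_record(tt, sim$y)
  # empty included set -> exactly the circadian curve
  p0 <- conditional_prediction(cp, rec, "hr", character())
  expect_equal(p0$pred, m[, 2], tolerance = 1e-12)
  # decoupled limit: activity carries no information about HR
  cpd <- cardio_params(2, 0, 4, 0, 4, 2, 1.5, 1.5, rho = 0,
                       circ = cp$circ, sigma = cp$sigma)
  pd <- conditional_prediction(cpd, rec, "hr", "activity")
  expect_equal(pd$pred, wearssm:::cardio_mean(cpd, tt)[, 2],
               tolerance = 1e-8)
})

test_that("explained variance grows with the included-channel set", {
  # high rho makes HR informative about HRV beyond activity alone
  cp <- cardio_params(2, 3, 4, 2, 4, 2, 1.5, 1.5, rho = 0.9,
                      circ = list(act = c(0, 0.5, 14), hr = c(0, 0.5, 16),
                                  hrv = c(0, 0.4, 4)),
                      sigma = c(0.2, 0.2, 0.2))
  sys <- build_cardio_system(cp)
  better <- 0
  for (i in 1:8) {
    set.seed(400 + i)
    tt <- seq(0.25, 48, by = 0.25)
    m <- wearssm:::cardio_mean(cp, tt)
    sim <- simulate_path(sys, tt, H = diag(3), m = m, R = diag(cp$sigma^2))
    rec <- make_cardio_record(tt, sim$y)
    tab <- cardio_variance_table(cp, rec)
    better <- better +
      (tab["hrv_circadian_activity_hr"] > tab["hrv_circadian_activity"])
  }
  expect_gte(better, 7)  # spec example at 20 replicates; run at 8
})

test_that("likelihood is equivariant under channel renormalization", {
  cp <- true_cardio_params()
  tt <- seq(0.25, 12, by = 0.25)
  set.seed(15)
  sys <- build_cardio_system(cp)
  m <- wearssm:::cardio_mean(cp, tt)
  sim <- simulate_path(sys, tt, H = diag(3), m = m, R = diag(cp$sigma^2))
  rec <- make_cardio_record(tt, sim$y)
  # rescale the activity channel by c and map parameters accordingly:
  # x_act' = c x_act  =>  D11' = c^2 D11, C21' = C21 / c, C31' = C31 / c,
  # circadian and sigma for activity scaled by c; loglik shifts by
  # -T log(c) (change of variables)
  cc <- 2.5
  rec2 <- rec
  rec2$series$activity$values <- rec$series$activity$values * cc
  cp2 <- cp
  cp2$D11 <- cp$D11 * cc^2
  cp2$C21 <- cp$C21 / cc
  cp2$C31 <- cp$C31 / cc
  cp2$circ$act <- c(cp$circ$act[1] * cc, cp$circ$act[2] * cc,
                    cp$circ$act[3])
  cp2$sigma <- c(cp$sigma[1] * cc, cp$sigma[2:3])
  expect_equal(model2_loglik(cp2, rec2),
               model2_loglik(cp, rec) - length(tt) * log(cc),
               tolerance = 1e-8)
})
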