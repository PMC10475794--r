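test_that("zero couplings reduce the glucose marginal to Model 1", {
  gen <- generate_participant(scenario_spec(seed = 5, model = "combined",
                                            duration_days = 2,
                                            gap_rate_per_day = 0))
  rec <- gen$record_normalized
  gp <- true_glucose_params()
  cp <- combined_params(true_cardio_params(), gp, c(0, 0, 0))
  cd <- wearssm:::combined_data(rec)
  l_joint <- model3_loglik(cp, rec)
  yaux <- cd$y; yaux[, 4] <- NA
  l_aux <- kalman_filter(build_combined_system(cp), cd$times, yaux,
                         H = wearssm:::combined_H(),
                         m = wearssm:::combined_mean(cp, rec$meals, cd$times),
                         R = c(cp$cardio$sigma^2, gp$sigma^2))$loglik
  # glucose conditional on aux equals the glucose marginal when decoupled
  expect_equal(l_joint - l_aux, model1_loglik(gp, rec), tolerance = 1e-8)
})

test_that("combined likelihood matches the dense 5-D oracle", {
  cp <- combined_params(true_cardio_params(), true_glucose_params(),
                        c(-0.5, 0.4, 0.1))
  sys <- build_combined_system(cp)
  tt <- seq(0.25, 1.25, by = 0.25)  # T = 5
  meals <- meal_log(0.4, "breakfast")
  m <- wearssm:::combined_mean(cp, meals, tt)
  set.seed(16)
  sim <- simulate_path(sys, tt, H = wearssm:::combined_H(), m = m,
                       R = diag(c(cp$cardio$sigma^2, cp$glucose$sigma^2)))
  y <- sim$y
  y[3, 2] <- NA
  expect_equal(
    joint_loglik(sys, tt, y, H = wearssm:::combined_H(), m = m,
                 R = diag(c(cp$cardio$sigma^2, cp$glucose$sigma^2))),
    kalman_filter(sys, tt, y, H = wearssm:::combined_H(), m = m,
                  R = c(cp$cardio$sigma^2, cp$glucose$sigma^2))$loglik,
    tolerance = 1e-8)
})

test_that("couplings shift the deterministic glucose steady state", {
  cp <- combined_params(true_cardio_params(), true_glucose_params(),
                        c(-0.5, 0.4, 0.1))
  W <- wearssm:::combined_W(cp)
  # with the aux states pinned at constant levels x_aux, the glucose block
  # settles at W_g x = -W_{g,aux} x_aux; the couplings enter only row 5
  x_aux <- c(0.8, 0.5, -0.2)
  expect_equal(drop(W[4:5, 1:3] %*% x_aux), c(0, sum(cp$C5 * x_aux)))
  x_ss <- drop(solve(W[4:5, 4:5], -W[4:5, 1:3] %*% x_aux))
  # analytic elimination of the latent: x5 = A11 c'u / (A21 A12 + A11 A22)
  gp <- cp$glucose
  expect_equal(x_ss[2],
               gp$A11 * sum(cp$C5 * x_aux) /
                 (gp$A21 * gp$A12 + gp$A11 * gp$A22),
               tolerance = 1e-10)
})

test_that("weighted_aux_sum combines channels and imputes only gaps", {
  gen <- generate_participant(scenario_spec(seed = 6, model = "combined",
                                            duration_days = 2))
  rec <- gen$record_normalized
  cp <- gen$truth$combined
  cd <- wearssm:::combined_data(rec)
  # unit activity coefficient returns the aggregated activity series
  cp1 <- cp; cp1$C5 <- c(1, 0, 0)
  w <- weighted_aux_sum(cp1, rec)
  expect_equal(w$sum, cd$y[, 1])
  # all-zero coefficients give the zero series
  cp0 <- cp; cp0$C5 <- c(0, 0, 0)
  expect_equal(weighted_aux_sum(cp0, rec)$sum, rep(0, length(cd$times)))
  # imputation only changes missing-aux grid points
  w_raw <- weighted_aux_sum(cp, rec, impute = FALSE)
  w_imp <- weighted_aux_sum(cp, rec, impute = TRUE)
  gaps <- is.na(w_raw$sum)
  if (any(gaps)) expect_true(all(is.finite(w_imp$sum[gaps])))
  expect_equal(w_imp$sum[!gaps], w_raw$sum[!gaps], tolerance = 1e-12)
})

test_that("cross_correlation peaks where it should", {
  set.seed(17)
  x <- rnorm(500)
  cc <- cross_correlation(x, x, dt = 0.25, max_lag = 3)
  expect_equal(attr(cc, "peak_lag"), 0)
  expect_equal(max(cc$correlation, na.rm = TRUE), 1)
  # x vs x shifted by +4 grid steps peaks at +4 steps
  y <- c(rep(NA, 4), x[1:(500 - 4)])
  cc2 <- cross_correlation(x, y, dt = 0.25, max_lag = 3)
  expect_equal(attr(cc2, "peak_lag"), 4 * 0.25)
  # white-noise pair: all |corr| below ~3/sqrt(n)
  wins <- 0
  for (i in 1:10) {
    set.seed(500 + i)
    a <- rnorm(1000); b <- rnorm(1000)
    cc3 <- cross_correlation(a, b, dt = 1, max_lag = 10)
    wins <- wins + (max(abs(cc3$correlation), na.rm = TRUE) < 0.15)
  }
  expect_gte(wins, 9)
  # too little overlap is masked
  cc4 <- cross_correlation(c(1, 2, NA, NA), c(1, 2, NA, NA), dt = 1,
                           max_lag = 1)
  expect_true(is.na(cc4$correlation[cc4$lag_hours == 1]))
})

test_that("single-input activity variant recovers a negative coupling", {
  ok <- 0
  for (i in 1:5) {
    sp <- scenario_spec(seed = 600 + i, model = "combined",
                        duration_days = 3, C5 = c(-0.5, 0, 0),
                        gap_rate_per_day = 0.3)
    gen <- generate_participant(sp)
    si <- single_input_variant(gen$truth$combined, gen$record_normalized,
                               "activity")
    ok <- ok + (si$coupling < 0)
  }
  expect_gte(ok, 4)  # spec example: >= 18/20; run at 5 replicates (MAP)
})

test_that("variance decomposition is exact in the degenerate cases", {
  gen <- generate_participant(scenario_spec(seed = 8, model = "combined",
                                            duration_days = 2,
                                            gap_rate_per_day = 0))
  rec <- gen$record_normalized
  cp0 <- gen$truth$combined
  cp0$C5 <- c(0, 0, 0)
  vd <- glucose_variance_decomposition(cp0, rec)
  # zero couplings: aux channels add nothing
  expect_equal(vd$draws[1, 1], vd$draws[1, 2], tolerance = 1e-8)
  # perfect prediction has EV 1
  y <- wearssm:::combined_data(rec)$y[, 4]
  expect_equal(explained_variance(y, y), 1)
})

test_that("strong couplings add explained glucose variance", {
  gained <- 0
  for (i in 1:5) {
    sp <- scenario_spec(seed = 700 + i, model = "combined",
                        duration_days = 3, C5 = c(-1.2, 0.9, 0),
                        gap_rate_per_day = 0)
    gen <- generate_participant(sp)
    vd <- glucose_variance_decomposition(gen$truth$combined,
                                         gen$record_normalized)
    gained <- gained + (vd$draws[1, 2] - vd$draws[1, 1] > 0.05)
  }
  expect_gte(gained, 4)  # spec example: >= 18/20; run at 5 replicates
})

test_that("locked cardio parameters are untouched by Model-3 fitting", {
  gen <- generate_participant(scenario_spec(seed = 10, model = "combined",
                                            duration_days = 2))
  cardio <- gen$truth$combined$cardio
  before <- unclass(cardio)
  si <- single_input_variant(gen$truth$combined, gen$record_normalized,
                             "hr")
  expect_identical(unclass(si$params$cardio), before)
})
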